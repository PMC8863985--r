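#' Waypoint ROIs and bundle definitions
#'
#' A bundle is defined by 2-3 ordered *include* waypoint ROIs that a
#' streamline must pass through in order, any number of *exclude* ROIs that
#' it must avoid, and a probability map used to break ties when a streamline
#' qualifies for several bundles.
#'
#' @param mask A [binary_mask] (nonempty).
#' @param order Integer >= 1; traversal order among the include waypoints.
#' @param role `"include"` or `"exclude"`.
#' @return A `waypoint_roi`.
#' @export
waypoint_roi <- function(mask, order = 1L, role = c("include", "exclude")) {
  role <- match.arg(role)
  stopifnot(is_binary_mask(mask))
  if (!any(mask$grid)) stop("waypoint mask is empty")
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("waypoint order must be >= 1")
  structure(list(mask = mask, order = order, role = role),
            class = "waypoint_roi")
}

#' @rdname waypoint_roi
#' @param name Bundle name; hemispheric bundles carry a `_L` / `_R` suffix
#'   (x < 0 is left), cross-hemispheric bundles (FcMa, FcMi) none.
#' @param waypoints List of [waypoint_roi]s with >= 2 includes whose orders
#'   are unique.
#' @param probability_map A [scalar_volume] with values in \[0, 1\], or NULL.
#' @export
bundle_definition <- function(name, waypoints, probability_map = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!all(vapply(waypoints, inherits, logical(1), "waypoint_roi")))
    stop("waypoints must be waypoint_roi objects")
  inc <- Filter(function(w) w$role == "include", waypoints)
  if (length(inc) < 2L) stop("a bundle needs at least 2 include waypoints")
  orders <- vapply(inc, function(w) w$order, integer(1))
  if (anyDuplicated(orders)) stop("include waypoint orders must be unique")
  if (!is.null(probability_map)) {
    stopifnot(is_scalar_volume(probability_map))
    if (any(probability_map$grid[probability_map$valid] < 0))
      stop("probability map must be nonnegative")
  }
  structure(list(name = name,
                 waypoints = waypoints[order(vapply(
                   waypoints, function(w) w$order, integer(1)))],
                 probability_map = probability_map),
            class = "bundle_definition")
}

#' @rdname waypoint_roi
#' @param definitions List of [bundle_definition]s with unique names.
#' @param template_affine [affine4x4] of the space the ROIs live in.
#' @param space Space tag: `"template"` or `"subject"`.
#' @export
bundle_atlas <- function(definitions, template_affine,
                         space = c("template", "subject")) {
  space <- match.arg(space)
  nm <- vapply(definitions, function(d) d$name, character(1))
  if (anyDuplicated(nm)) stop("bundle names must be unique")
  names(definitions) <- nm
  structure(list(definitions = definitions,
                 template_affine = affine4x4(template_affine),
                 space = space),
            class = "bundle_atlas")
}

#' @export
print.bundle_atlas <- function(x, ...) {
  cat(sprintf("<bundle_atlas> %d bundles (%s space)\n",
              length(x$definitions), x$space))
  invisible(x)
}

resample_mask_nn <- function(mask, xfm_inv, ref_dims, ref_affine) {
  centers <- as.matrix(expand.grid(i = 0:(ref_dims[1] - 1L),
                                   j = 0:(ref_dims[2] - 1L),
                                   k = 0:(ref_dims[3] - 1L)))
  world <- voxel_to_world(centers, ref_affine)
  tmpl <- apply_affine(xfm_inv, world)
  vox <- round(world_to_voxel(tmpl, mask$affine))
  d <- dim(mask$grid)
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] & vox[, 2] >= 0 & vox[, 2] < d[2] &
            vox[, 3] >= 0 & vox[, 3] < d[3]
  out <- logical(nrow(vox))
  lin <- 1L + vox[inside, 1] + d[1] * (vox[inside, 2] + d[2] * vox[inside, 3])
  out[inside] <- mask$grid[lin]
  binary_mask(array(out, ref_dims), ref_affine)
}

resample_prob_trilinear <- function(vol, xfm_inv, ref_dims, ref_affine) {
  centers <- as.matrix(expand.grid(i = 0:(ref_dims[1] - 1L),
                                   j = 0:(ref_dims[2] - 1L),
                                   k = 0:(ref_dims[3] - 1L)))
  world <- voxel_to_world(centers, ref_affine)
  tmpl <- apply_affine(xfm_inv, world)
  vals <- interp_trilinear(vol, tmpl, missing = "lenient")
  vals[is.na(vals)] <- 0
  scalar_volume(array(vals, ref_dims), ref_affine, units = "a.u.")
}

#' Transform an atlas from template to subject space
#'
#' Applies an affine template-to-subject transform and resamples every
#' waypoint mask (nearest neighbour) and probability map (trilinear) onto
#' the subject reference grid.
#'
#' @param atlas A [bundle_atlas] in template space.
#' @param xfm 4x4 affine mapping template RAS mm to subject RAS mm.
#' @param reference A [scalar_volume] or [binary_mask] defining the subject
#'   grid.
#' @return A [bundle_atlas] in subject space.
#' @export
transform_rois_to_subject <- function(atlas, xfm, reference) {
  if (missing(xfm) || is.null(xfm)) stop("template-to-subject transform missing")
  xfm <- affine4x4(xfm)
  xfm_inv <- affine_inverse(xfm)
  ref_dims <- dim(reference$grid)
  ref_affine <- reference$affine
  defs <- lapply(atlas$definitions, function(def) {
    wps <- lapply(def$waypoints, function(w) {
      waypoint_roi(resample_mask_nn(w$mask, xfm_inv, ref_dims, ref_affine),
                   order = w$order, role = w$role)
    })
    pm <- if (is.null(def$probability_map)) NULL else
      resample_prob_trilinear(def$probability_map, xfm_inv, ref_dims, ref_affine)
    bundle_definition(def$name, wps, pm)
  })
  bundle_atlas(defs, ref_affine, space = "subject")
}
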