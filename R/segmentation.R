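#' Waypoint candidacy of a single streamline
#'
#' A streamline is a candidate for a bundle iff (a) it touches every include
#' waypoint, (b) the arc-length positions of first contact respect the
#' waypoint order in one traversal direction (either direction is
#' acceptable; the matched direction is returned as the orientation flag),
#' and (c) no point lies inside any exclude waypoint. "Touching" is
#' vertex-in-voxel membership after densifying the polyline to steps of at
#' most half the waypoint voxel size.
#'
#' @param s n x 3 streamline matrix (RAS mm).
#' @param def A [bundle_definition] in subject space.
#' @param densify_step Densification step in mm; defaults to half the
#'   smallest voxel edge of the first include waypoint.
#' @return List: `candidate` (logical), `flipped` (logical; TRUE when the
#'   matched direction is end-to-start).
#' @export
streamline_passes_waypoints <- function(s, def, densify_step = NULL) {
  inc <- Filter(function(w) w$role == "include", def$waypoints)
  exc <- Filter(function(w) w$role == "exclude", def$waypoints)
  if (is.null(densify_step))
    densify_step <- min(voxel_sizes(inc[[1]]$mask$affine)) / 2
  dense <- densify_polyline(s, densify_step)
  verdict_from_dense(dense, inc, exc)
}

voxel_sizes <- function(affine) {
  m <- unclass(affine)
  sqrt(colSums(m[1:3, 1:3]^2))
}

points_in_mask <- function(points, mask) {
  vox <- round(world_to_voxel(points, mask$affine))
  d <- dim(mask$grid)
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] & vox[, 2] >= 0 & vox[, 2] < d[2] &
            vox[, 3] >= 0 & vox[, 3] < d[3]
  out <- logical(nrow(points))
  if (any(inside)) {
    lin <- 1L + vox[inside, 1] + d[1] * (vox[inside, 2] + d[2] * vox[inside, 3])
    out[inside] <- mask$grid[lin]
  }
  out
}

verdict_from_dense <- function(dense, inc, exc, lin = NULL, mask_grids = NULL) {
  no <- list(candidate = FALSE, flipped = FALSE)
  for (w in exc) {
    hit <- if (is.null(lin)) points_in_mask(dense, w$mask)
           else mask_lookup(w$mask, lin)
    if (any(hit)) return(no)
  }
  n <- nrow(dense)
  first_fwd <- integer(length(inc))
  first_rev <- integer(length(inc))
  for (i in seq_along(inc)) {
    hit <- if (is.null(lin)) points_in_mask(dense, inc[[i]]$mask)
           else mask_lookup(inc[[i]]$mask, lin)
    idx <- which(hit)
    if (length(idx) == 0L) return(no)
    first_fwd[i] <- idx[1L]
    first_rev[i] <- n + 1L - idx[length(idx)]
  }
  if (all(diff(first_fwd) > 0)) return(list(candidate = TRUE, flipped = FALSE))
  if (all(diff(first_rev) > 0)) return(list(candidate = TRUE, flipped = TRUE))
  no
}

# fast path: all masks on one shared grid, densified points converted to
# linear voxel indices once per streamline
mask_lookup <- function(mask, lin) {
  out <- logical(length(lin))
  ok <- !is.na(lin)
  out[ok] <- mask$grid[lin[ok]]
  out
}

lin_index_for <- function(points, affine, dims) {
  vox <- round(world_to_voxel(points, affine))
  inside <- vox[, 1] >= 0 & vox[, 1] < dims[1] &
            vox[, 2] >= 0 & vox[, 2] < dims[2] &
            vox[, 3] >= 0 & vox[, 3] < dims[3]
  lin <- rep(NA_integer_, nrow(points))
  lin[inside] <- 1L + vox[inside, 1] +
    dims[1] * (vox[inside, 2] + dims[2] * vox[inside, 3])
  lin
}

#' Resolve multi-bundle candidates with the probabilistic atlas
#'
#' Each streamline qualifying for more than one bundle is assigned to the
#' bundle whose probability map has the highest mean (trilinear) value along
#' the streamline's vertices. Exact ties go to the lexicographically first
#' bundle name, with a warning.
#'
#' @param candidacies List (one element per streamline) of character vectors
#'   of qualifying bundle names (possibly empty).
#' @param set The [streamline_set].
#' @param atlas The [bundle_atlas] carrying probability maps.
#' @return Character vector of assigned bundle names (NA when unassigned).
#' @export
resolve_candidates <- function(candidacies, set, atlas) {
  n <- length(candidacies)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cand <- sort(candidacies[[i]])
    if (length(cand) == 0L) next
    if (length(cand) == 1L) { out[i] <- cand; next }
    score <- vapply(cand, function(nm) {
      pm <- atlas$definitions[[nm]]$probability_map
      if (is.null(pm)) stop("probability map missing for bundle ", nm)
      v <- interp_trilinear(pm, set$streamlines[[i]], missing = "lenient")
      mean(v, na.rm = TRUE)
    }, numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1L)
      warning(sprintf("probability tie for streamline %d between %s; taking %s",
                      i, paste(cand[best], collapse = ", "), cand[best[1]]))
    out[i] <- cand[best[1]]
  }
  out
}

#' A segmented bundle
#'
#' @param name Bundle name.
#' @param member_indices Unique indices into the parent [streamline_set].
#' @param flipped Logical per member: TRUE when the member matched the
#'   waypoint order in the end-to-start direction.
#' @param n_removed_cleaning Streamlines removed by outlier cleaning.
#' @return A `segmented_bundle`.
#' @export
segmented_bundle <- function(name, member_indices = integer(),
                             flipped = logical(length(member_indices)),
                             n_removed_cleaning = 0L) {
  member_indices <- as.integer(member_indices)
  if (anyDuplicated(member_indices)) stop("member indices must be unique")
  stopifnot(length(flipped) == length(member_indices))
  structure(list(name = name, member_indices = member_indices,
                 flipped = as.logical(flipped),
                 n_removed_cleaning = as.integer(n_removed_cleaning)),
            class = "segmented_bundle")
}

#' @export
print.segmented_bundle <- function(x, ...) {
  cat(sprintf("<segmented_bundle> %s: %d members (%d removed by cleaning)\n",
              x$name, length(x$member_indices), x$n_removed_cleaning))
  invisible(x)
}

#' Oriented member polylines of a bundle
#'
#' Returns the member streamlines with the candidacy orientation flags
#' applied, so that all members traverse the waypoints in the same
#' direction (node 1 nearest the order-1 waypoint).
#'
#' @param bundle A [segmented_bundle].
#' @param set The parent [streamline_set].
#' @return List of n x 3 matrices.
#' @export
bundle_members <- function(bundle, set) {
  lapply(seq_along(bundle$member_indices), function(j) {
    s <- set$streamlines[[bundle$member_indices[j]]]
    if (bundle$flipped[j]) s[rev(seq_len(nrow(s))), , drop = FALSE] else s
  })
}

member_node_array <- function(members, n_nodes) {
  arr <- array(NA_real_, c(length(members), n_nodes, 3L))
  for (m in seq_along(members))
    arr[m, , ] <- resample_to_nodes(members[[m]], n_nodes)
  arr
}

node_stats <- function(arr, reg = 0.01) {
  n_nodes <- dim(arr)[2]
  core <- apply(arr, c(2, 3), mean)
  covs <- array(NA_real_, c(3, 3, n_nodes))
  for (k in seq_len(n_nodes)) {
    X <- arr[, k, , drop = FALSE]
    dim(X) <- c(dim(arr)[1], 3L)
    cv <- if (nrow(X) > 1L) stats::cov(X) else matrix(0, 3, 3)
    covs[, , k] <- cv + diag(reg, 3)
  }
  list(core = core, cov = covs)
}

gauss_distances <- function(arr, stats) {
  n_m <- dim(arr)[1]; n_nodes <- dim(arr)[2]
  d <- matrix(NA_real_, n_m, n_nodes)
  for (k in seq_len(n_nodes)) {
    X <- arr[, k, , drop = FALSE]
    dim(X) <- c(n_m, 3L)
    Xc <- sweep(X, 2, stats$core[k, ])
    inv <- solve(stats$cov[, , k])
    d[, k] <- sqrt(pmax(rowSums((Xc %*% inv) * Xc), 0))
  }
  rowMeans(d)
}

#' Clean a bundle by gaussian (Mahalanobis) distance from its core
#'
#' Iteratively resamples the members to `n_nodes` equidistant nodes,
#' computes the per-node core (mean position) and 3x3 covariance
#' (regularised by adding (0.1 mm)^2 to the diagonal so near-parallel
#' bundles never yield a singular matrix), scores each member by the mean
#' over nodes of the Mahalanobis distance of its node points, and removes
#' members whose score exceeds `max_gauss_dist` standard deviations.
#' Repeats until no member is removed or `max_iter` passes, because
#' removing outliers shifts the core.
#'
#' @param bundle A [segmented_bundle].
#' @param set The parent [streamline_set].
#' @param max_gauss_dist Removal threshold in SD units (default 4).
#' @param max_iter Maximum cleaning passes (default 5).
#' @param n_nodes Nodes for the core computation (default 100).
#' @return The cleaned [segmented_bundle]; bundles with fewer than 5
#'   members are returned unchanged with a warning.
#' @export
clean_bundle <- function(bundle, set, max_gauss_dist = 4, max_iter = 5L,
                         n_nodes = 100L) {
  if (length(bundle$member_indices) == 0L) return(bundle)
  if (length(bundle$member_indices) < 5L) {
    warning(sprintf("bundle %s has < 5 members; skipping cleaning", bundle$name))
    return(bundle)
  }
  keep <- seq_along(bundle$member_indices)
  arr <- member_node_array(bundle_members(bundle, set), n_nodes)
  removed <- 0L
  for (it in seq_len(max_iter)) {
    st <- node_stats(arr[keep, , , drop = FALSE])
    d <- gauss_distances(arr[keep, , , drop = FALSE], st)
    out <- d > max_gauss_dist
    if (!any(out)) break
    removed <- removed + sum(out)
    keep <- keep[!out]
    if (length(keep) < 5L) break
  }
  segmented_bundle(bundle$name,
                   bundle$member_indices[keep],
                   bundle$flipped[keep],
                   bundle$n_removed_cleaning + removed)
}

#' Segment a whole-brain streamline set into bundles
#'
#' The full waypoint pipeline: candidacy for every (streamline, bundle)
#' pair, probabilistic-atlas resolution of multi-bundle candidates, then
#' Mahalanobis outlier cleaning per bundle. Bundles with no members are
#' returned empty, not as errors. The result is a partition: no streamline
#' belongs to two bundles.
#'
#' @param set A nonempty [streamline_set] in subject RAS mm.
#' @param atlas A [bundle_atlas] in subject space.
#' @param clean Logical; run [clean_bundle] on each bundle (default TRUE).
#' @param max_gauss_dist,max_iter,n_nodes Cleaning parameters.
#' @param densify_step Densification step in mm for waypoint membership;
#'   defaults to half the smallest atlas voxel size.
#' @return Named list of [segmented_bundle]s, one per atlas definition.
#' @export
segment_all <- function(set, atlas, clean = TRUE, max_gauss_dist = 4,
                        max_iter = 5L, n_nodes = 100L, densify_step = NULL) {
  stopifnot(is_streamline_set(set), length(set$streamlines) > 0L)
  defs <- atlas$definitions
  first_mask <- defs[[1]]$waypoints[[1]]$mask
  if (is.null(densify_step))
    densify_step <- min(voxel_sizes(first_mask$affine)) / 2
  # fast path when every waypoint mask shares one grid
  shared <- TRUE
  ref_aff <- first_mask$affine; ref_dim <- dim(first_mask$grid)
  for (def in defs) for (w in def$waypoints) {
    if (!identical(dim(w$mask$grid), ref_dim) ||
        max(abs(unclass(w$mask$affine) - unclass(ref_aff))) > 1e-9) {
      shared <- FALSE; break
    }
  }
  n <- length(set$streamlines)
  cand <- vector("list", n)
  flip <- vector("list", n)
  for (i in seq_len(n)) {
    dense <- densify_polyline(set$streamlines[[i]], densify_step)
    lin <- if (shared) lin_index_for(dense, ref_aff, ref_dim) else NULL
    hits <- character(0); fl <- logical(0)
    for (def in defs) {
      inc <- Filter(function(w) w$role == "include", def$waypoints)
      exc <- Filter(function(w) w$role == "exclude", def$waypoints)
      v <- verdict_from_dense(dense, inc, exc, lin = lin)
      if (v$candidate) {
        hits <- c(hits, def$name)
        fl <- c(fl, v$flipped)
      }
    }
    cand[[i]] <- hits
    flip[[i]] <- stats::setNames(fl, hits)
  }
  assigned <- resolve_candidates(cand, set, atlas)
  bundles <- lapply(defs, function(def) {
    idx <- which(!is.na(assigned) & assigned == def$name)
    segmented_bundle(def$name, idx,
                     vapply(idx, function(i) flip[[i]][[def$name]], logical(1)))
  })
  if (clean)
    bundles <- lapply(bundles, clean_bundle, set = set,
                      max_gauss_dist = max_gauss_dist, max_iter = max_iter,
                      n_nodes = n_nodes)
  names(bundles) <- vapply(defs, function(d) d$name, character(1))
  bundles
}

#' Rasterise a bundle to a binary mask
#'
#' A voxel is set iff at least one member point (after arc-length
#' densification to steps of at most half the reference voxel size) falls
#' inside it.
#'
#' @param bundle A [segmented_bundle].
#' @param set The parent [streamline_set].
#' @param reference A [scalar_volume] or [binary_mask] defining the grid.
#' @return A [binary_mask].
#' @export
bundle_to_mask <- function(bundle, set, reference) {
  dims <- dim(reference$grid)
  aff <- reference$affine
  step <- min(voxel_sizes(aff)) / 2
  grid <- array(FALSE, dims)
  for (s in bundle_members(bundle, set)) {
    dense <- densify_polyline(s, step)
    lin <- lin_index_for(dense, aff, dims)
    lin <- lin[!is.na(lin)]
    grid[lin] <- TRUE
  }
  binary_mask(grid, aff)
}

#' Dice coefficient between two binary masks
#'
#' DC = 2 |A intersect B| / (|A| + |B|) over voxels of a shared grid;
#' defined as 0 (with a warning) when both masks are empty.
#'
#' @param A,B [binary_mask]s on the same grid.
#' @return A `dice_result` list: `value`, `n_A`, `n_B`, `n_intersection`.
#' @export
dice_coefficient <- function(A, B) {
  stopifnot(is_binary_mask(A), is_binary_mask(B))
  if (!same_grid(A, B)) stop("masks are on different grids")
  nA <- sum(A$grid); nB <- sum(B$grid)
  nI <- sum(A$grid & B$grid)
  value <- if (nA + nB == 0L) {
    warning("both masks empty; dice defined as 0")
    0
  } else 2 * nI / (nA + nB)
  structure(list(value = value, n_A = nA, n_B = nB, n_intersection = nI),
            class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> %.4f (|A| = %d, |B| = %d, |A&B| = %d)\n",
              x$value, x$n_A, x$n_B, x$n_intersection))
  invisible(x)
}
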