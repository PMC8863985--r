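#' The 24 bundle names
#'
#' Eleven bundle types per hemisphere (`_L` / `_R` suffix, x < 0 left) plus
#' two cross-hemispheric forceps: anterior thalamic radiation (ATR),
#' cortico-spinal tract (CS), posterior arcuate (pAF), vertical occipital
#' fasciculus (VOF), forceps major (FcMa), forceps minor (FcMi), arcuate
#' (AF), uncinate (UCI), superior longitudinal fasciculus (SLF), cingulum
#' cingulate (CC), inferior longitudinal fasciculus (ILF), inferior frontal
#' occipital fasciculus (IFOF), middle longitudinal fasciculus (MLF).
#'
#' @return Character vector of 24 bundle names.
#' @export
bundle_names <- function() {
  types <- phantom_bundle_types()
  unlist(lapply(seq_len(nrow(types)), function(i) {
    if (types$bilateral[i]) paste0(types$type[i], c("_L", "_R"))
    else types$type[i]
  }), use.names = FALSE)
}

# geometry layout: bilateral types live at a lateral lane |x| and a (y, z)
# sector; arcs run along y with a bow in z; "curvy" types add an S-shaped
# x-wiggle and a third waypoint. FcMa / FcMi cross the midline along x.
phantom_bundle_types <- function() {
  data.frame(
    type     = c("ATR", "CS", "pAF", "VOF", "AF", "UCI", "SLF", "CC",
                 "ILF", "IFOF", "MLF", "FcMa", "FcMi"),
    bilateral = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, FALSE, FALSE),
    lane     = c(20, 20, 20, 42, 42, 42, 20, 20, 42, 20, 42, NA, NA),
    y_c      = c(40, 0, -40, -40, 0, 40, 0, 40, -40, -40, 0, -60, 60),
    z_c      = c(-35, -35, 25, 25, 25, -35, 25, 25, -35, -35, -35, -5, -5),
    curvy    = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                 FALSE, FALSE, FALSE, FALSE, FALSE),
    # newborn per-bundle mean R1 (s^-1): grand mean over the 24 bundles is
    # exactly 0.46, range 0.42-0.55, projection bundles highest, FcMi and
    # IFOF lowest
    r1_newborn = c(0.530, 0.550, 0.445, 0.450, 0.445, 0.440, 0.460, 0.455,
                   0.435, 0.425, 0.440, 0.470, 0.420),
    stringsAsFactors = FALSE)
}

phantom_bundle_table <- function() {
  types <- phantom_bundle_types()
  rows <- list()
  for (i in seq_len(nrow(types))) {
    r <- types[i, ]
    if (r$bilateral) {
      for (side in c("_L", "_R")) {
        rr <- r
        rr$name <- paste0(r$type, side)
        rr$sign <- if (side == "_L") -1 else 1
        rows[[length(rows) + 1L]] <- rr
      }
    } else {
      r$name <- r$type
      r$sign <- 0
      rows[[length(rows) + 1L]] <- r
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

phantom_centerline <- function(row, n = 120L, half_span = 14, z_bow = 8,
                               x_wiggle = 6) {
  t <- seq(0, 1, length.out = n)
  if (is.na(row$lane)) {
    # cross-hemispheric: runs along x with a small z bow
    cbind(x = -45 + 90 * t,
          y = rep(row$y_c, n),
          z = row$z_c + 5 * sin(pi * t))
  } else {
    x <- row$sign * (row$lane + if (row$curvy) x_wiggle * sin(2 * pi * t) else 0)
    cbind(x = x,
          y = row$y_c + half_span * (2 * t - 1),
          z = row$z_c + z_bow * sin(pi * t))
  }
}

default_phantom_sessions <- function() {
  nb_sub <- c(sprintf("S%02d", 1:6), sprintf("S%02d", 11:13))
  later_sub <- sprintf("S%02d", 1:10)
  rbind(
    data.frame(subject = nb_sub, age_days = 10L + seq(-8L, 8L, 2L),
               timepoint = "0m"),
    data.frame(subject = later_sub, age_days = 100L + seq(-9L, 9L, 2L),
               timepoint = "3m"),
    data.frame(subject = later_sub, age_days = 190L + seq(-9L, 9L, 2L),
               timepoint = "6m"))
}

#' Phantom configuration
#'
#' All tunables of the synthetic longitudinal phantom. The defaults are the
#' study conditions the package is validated under: 24 bundles on an
#' 80-cubed 2 mm grid, 50 streamlines per bundle with 1 mm smooth radial
#' jitter, 500 random distractors, per-bundle newborn R1 means with grand
#' mean 0.46 s^-1 (range 0.42-0.55 s^-1), a development-rate field
#' combining spatial gradients (per z-scored coordinate) with a negative
#' dependence on newborn R1, a 0.01 s^-1 subject random intercept and
#' 0.01 s^-1 voxel noise, and a 13-subject longitudinal design (9/10/10
#' sessions at nominal ages 10/100/190 days). The seed is mandatory.
#'
#' @param seed Integer RNG seed (required; never defaulted).
#' @param grid_shape Grid dimensions (default 80^3).
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param streamlines_per_bundle Planted members per bundle (default 50).
#' @param jitter_sd_mm SD of the smooth radial streamline jitter (default 1).
#' @param n_distractors Random non-bundle streamlines (default 500).
#' @param newborn_r1_bundle_means Named per-bundle newborn R1 means in
#'   s^-1; defaults as above.
#' @param slope_model List of generating coefficients: `gamma0` (mean rate,
#'   s^-1/day), `gamma_x`, `gamma_y`, `gamma_z`, `gamma_xy`, `gamma_xz`,
#'   `gamma_yz` (per z-scored coordinate), `lambda_speedup` (day^-1 per
#'   s^-1 of newborn R1 above/below the grand mean).
#' @param subject_intercept_sd SD of the per-subject R1 offset (s^-1).
#' @param residual_sd SD of the per-voxel R1 noise (s^-1).
#' @param sessions data.frame(subject, age_days, timepoint).
#' @param newborn_ref_age Age in days at which the R1 field equals the
#'   newborn calibration (default 10, the nominal newborn session age).
#' @param n_nodes Nodes per bundle for ground-truth profiles (default 100).
#' @param tube_radius_mm Painted bundle tube radius (default 7).
#' @param waypoint_halfwidth_mm Waypoint box half-width (default 5).
#' @param prob_sigma_mm Probability-map kernel SD (default 3).
#' @param min_separation_mm Minimum allowed centerline separation; closer
#'   layouts are a configuration error (default 12).
#' @param texture_amp Amplitude of the smooth spatial texture added to the
#'   newborn R1 field (default 0.002 s^-1).
#' @param md_intercept,md_r1_coupling Newborn MD field as a linear function
#'   of the newborn R1 base (mm^2/s): md = intercept + coupling * R1.
#' @param md_slope0 Mean MD development rate (mm^2/s per day, negative).
#' @param md_noise_sd Per-voxel MD noise SD (mm^2/s).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(seed,
                           grid_shape = c(80L, 80L, 80L),
                           voxel_mm = 2,
                           streamlines_per_bundle = 50L,
                           jitter_sd_mm = 1,
                           n_distractors = 500L,
                           newborn_r1_bundle_means = NULL,
                           slope_model = list(),
                           subject_intercept_sd = 0.01,
                           residual_sd = 0.01,
                           sessions = default_phantom_sessions(),
                           newborn_ref_age = 10,
                           n_nodes = 100L,
                           tube_radius_mm = 7,
                           waypoint_halfwidth_mm = 5,
                           prob_sigma_mm = 3,
                           min_separation_mm = 12,
                           texture_amp = 0.002,
                           md_intercept = 2.0e-3,
                           md_r1_coupling = -1.8e-3,
                           md_slope0 = -1.1e-6,
                           md_noise_sd = 2e-5) {
  if (missing(seed) || is.null(seed)) stop("phantom seed is mandatory")
  sm <- utils::modifyList(
    list(gamma0 = 0.16 / 180,
         gamma_x = 4.19e-5, gamma_y = -1.10e-4, gamma_z = 1.68e-4,
         gamma_xy = -4.74e-5, gamma_xz = 0, gamma_yz = 1.05e-4,
         lambda_speedup = -0.003),
    slope_model)
  tab <- phantom_bundle_table()
  means <- stats::setNames(tab$r1_newborn, tab$name)
  if (!is.null(newborn_r1_bundle_means)) {
    if (is.null(names(newborn_r1_bundle_means)) ||
        !all(names(newborn_r1_bundle_means) %in% tab$name))
      stop("newborn_r1_bundle_means must be named by bundle")
    means[names(newborn_r1_bundle_means)] <- newborn_r1_bundle_means
  }
  stopifnot(jitter_sd_mm >= 0, residual_sd >= 0, subject_intercept_sd >= 0)
  structure(list(
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    voxel_mm = voxel_mm,
    streamlines_per_bundle = as.integer(streamlines_per_bundle),
    jitter_sd_mm = jitter_sd_mm, n_distractors = as.integer(n_distractors),
    newborn_r1_bundle_means = means, slope_model = sm,
    subject_intercept_sd = subject_intercept_sd, residual_sd = residual_sd,
    sessions = sessions, newborn_ref_age = newborn_ref_age,
    n_nodes = as.integer(n_nodes), tube_radius_mm = tube_radius_mm,
    waypoint_halfwidth_mm = waypoint_halfwidth_mm,
    prob_sigma_mm = prob_sigma_mm, min_separation_mm = min_separation_mm,
    texture_amp = texture_amp,
    md_intercept = md_intercept, md_r1_coupling = md_r1_coupling,
    md_slope0 = md_slope0, md_noise_sd = md_noise_sd),
    class = "phantom_config")
}

phantom_affine <- function(config) {
  v <- config$voxel_mm
  origin <- -(config$grid_shape - 1) / 2 * v
  affine_scale(v, origin)
}

phantom_texture <- function(x, y, z, amp) {
  amp * sin(2 * pi * x / 37) * sin(2 * pi * y / 41) * sin(2 * pi * z / 43)
}

#' Phantom bundle geometry and node-level ground truth
#'
#' Builds the 24 centerlines, checks their mutual separation, and tabulates
#' per-node truth: coordinates, newborn R1 (bundle base + texture) and the
#' generating development rate. Coordinates are z-scored (and interaction
#' columns centred) over the every-10th-node records, matching the
#' convention of the slope models; the same standardization is applied to
#' voxels when volumes are painted.
#'
#' @param config A [phantom_config].
#' @return List: `table` (per-bundle geometry rows), `centerlines` (named
#'   list of matrices), `nodes` (data.frame bundle, node, x, y, z, x_abs,
#'   newborn_r1, slope), `zstats` (standardization parameters), `beta`
#'   (the generating coefficient vector).
#' @export
phantom_geometry <- function(config) {
  tab <- phantom_bundle_table()
  centerlines <- lapply(seq_len(nrow(tab)),
                        function(i) phantom_centerline(tab[i, ]))
  names(centerlines) <- tab$name
  check_separation(centerlines, config$min_separation_mm)
  nodes <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    p <- resample_to_nodes(centerlines[[i]], config$n_nodes)
    data.frame(bundle = tab$name[i], node = seq_len(config$n_nodes),
               x = p[, 1], y = p[, 2], z = p[, 3],
               r1_base = unname(config$newborn_r1_bundle_means[tab$name[i]]))
  }))
  nodes$x_abs <- abs(nodes$x)
  nodes$newborn_r1 <- nodes$r1_base +
    phantom_texture(nodes$x, nodes$y, nodes$z, config$texture_amp)
  sub <- nodes[nodes$node %% 10L == 0L, , drop = FALSE]
  zstats <- list(
    mean = c(x_abs = mean(sub$x_abs), y = mean(sub$y), z = mean(sub$z)),
    sd = c(x_abs = stats::sd(sub$x_abs), y = stats::sd(sub$y),
           z = stats::sd(sub$z)))
  zx <- (sub$x_abs - zstats$mean["x_abs"]) / zstats$sd["x_abs"]
  zy <- (sub$y - zstats$mean["y"]) / zstats$sd["y"]
  zz <- (sub$z - zstats$mean["z"]) / zstats$sd["z"]
  zstats$int_mean <- c(xy = mean(zx * zy), xz = mean(zx * zz),
                       yz = mean(zy * zz))
  grand <- mean(config$newborn_r1_bundle_means[tab$name])
  zstats$r1_grand_mean <- grand
  nodes$slope <- phantom_slope_at(nodes$x_abs, nodes$y, nodes$z,
                                  nodes$r1_base, config, zstats)
  sm <- config$slope_model
  beta <- c(intercept = sm$gamma0, x_abs = sm$gamma_x, y = sm$gamma_y,
            z = sm$gamma_z, xy = sm$gamma_xy, xz = sm$gamma_xz,
            yz = sm$gamma_yz, lambda_speedup = sm$lambda_speedup)
  list(table = tab, centerlines = centerlines,
       nodes = nodes[, c("bundle", "node", "x", "y", "z", "x_abs",
                         "r1_base", "newborn_r1", "slope")],
       zstats = zstats, beta = beta)
}

# development rate at arbitrary locations: spatial gradients on z-scored
# coordinates (interactions centred over the node records so the grand-mean
# rate stays gamma0) plus the newborn-value dependence
phantom_slope_at <- function(x_abs, y, z, r1_base, config, zstats) {
  sm <- config$slope_model
  zx <- (x_abs - zstats$mean["x_abs"]) / zstats$sd["x_abs"]
  zy <- (y - zstats$mean["y"]) / zstats$sd["y"]
  zz <- (z - zstats$mean["z"]) / zstats$sd["z"]
  sm$gamma0 +
    sm$gamma_x * zx + sm$gamma_y * zy + sm$gamma_z * zz +
    sm$gamma_xy * (zx * zy - zstats$int_mean["xy"]) +
    sm$gamma_xz * (zx * zz - zstats$int_mean["xz"]) +
    sm$gamma_yz * (zy * zz - zstats$int_mean["yz"]) +
    sm$lambda_speedup * (r1_base - zstats$r1_grand_mean)
}

check_separation <- function(centerlines, min_mm) {
  nms <- names(centerlines)
  sub <- lapply(centerlines, function(cl)
    cl[round(seq(1, nrow(cl), length.out = 40L)), , drop = FALSE])
  for (i in seq_along(sub)) for (j in seq_len(i - 1L)) {
    a <- sub[[i]]; b <- sub[[j]]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    if (min(d2) < min_mm^2)
      stop(sprintf("bundle centerlines %s and %s are %.1f mm apart (< %g mm)",
                   nms[i], nms[j], sqrt(max(min(d2), 0)), min_mm))
  }
  invisible(TRUE)
}

smooth_jitter <- function(t, sd_mm) {
  c0 <- stats::rnorm(3, 0, sd_mm * sqrt(0.5))
  c1 <- stats::rnorm(3, 0, sd_mm * sqrt(0.7))
  c2 <- stats::rnorm(3, 0, sd_mm * sqrt(0.3))
  cbind(c0[1] + c1[1] * sin(pi * t) + c2[1] * sin(2 * pi * t),
        c0[2] + c1[2] * sin(pi * t) + c2[2] * sin(2 * pi * t),
        c0[3] + c1[3] * sin(pi * t) + c2[3] * sin(2 * pi * t))
}

phantom_streamlines <- function(config, geom) {
  streams <- list()
  labels <- character(0)
  t <- seq(0, 1, length.out = 60L)
  for (nm in names(geom$centerlines)) {
    cl <- resample_to_nodes(geom$centerlines[[nm]], 60L)
    for (m in seq_len(config$streamlines_per_bundle)) {
      s <- cl + smooth_jitter(t, config$jitter_sd_mm)
      if (stats::runif(1) < 0.5) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
      streams[[length(streams) + 1L]] <- s
      labels <- c(labels, nm)
    }
  }
  half <- (config$grid_shape[1] - 10) / 2 * config$voxel_mm
  for (d in seq_len(config$n_distractors)) {
    ctr <- stats::runif(3, -half * 0.8, half * 0.8)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    perp <- stats::rnorm(3); perp <- perp - sum(perp * dir) * dir
    perp <- perp / sqrt(sum(perp^2))
    len <- stats::runif(1, 50, 90)
    bow <- stats::runif(1, -10, 10)
    tt <- seq(-0.5, 0.5, length.out = 40L)
    s <- t(vapply(seq_along(tt), function(i)
      ctr + dir * len * tt[i] + perp * bow * sin(pi * (tt[i] + 0.5)),
      numeric(3)))
    streams[[length(streams) + 1L]] <- s
    labels <- c(labels, NA_character_)
  }
  list(set = streamline_set(streams), labels = labels)
}

phantom_atlas <- function(config, geom) {
  aff <- phantom_affine(config)
  dims <- config$grid_shape
  centers <- voxel_grid_coords(dims, aff)
  defs <- lapply(seq_len(nrow(geom$table)), function(i) {
    row <- geom$table[i, ]
    cl <- geom$centerlines[[row$name]]
    fr <- if (row$curvy %in% TRUE) c(0.25, 0.5, 0.75) else c(0.25, 0.75)
    cln <- resample_to_nodes(cl, 101L)
    wps <- lapply(seq_along(fr), function(k) {
      ctr <- cln[round(fr[k] * 100) + 1L, ]
      hw <- config$waypoint_halfwidth_mm
      g <- abs(centers[, 1] - ctr[1]) <= hw &
           abs(centers[, 2] - ctr[2]) <= hw &
           abs(centers[, 3] - ctr[3]) <= hw
      waypoint_roi(binary_mask(array(g, dims), aff), order = k,
                   role = "include")
    })
    pm <- phantom_prob_map(cl, config, centers, dims, aff)
    bundle_definition(row$name, wps, pm)
  })
  bundle_atlas(defs, aff, space = "subject")
}

voxel_grid_coords <- function(dims, affine) {
  centers <- as.matrix(expand.grid(i = 0:(dims[1] - 1L),
                                   j = 0:(dims[2] - 1L),
                                   k = 0:(dims[3] - 1L)))
  voxel_to_world(centers, affine)
}

phantom_prob_map <- function(cl, config, centers, dims, aff) {
  sigma <- config$prob_sigma_mm
  reach <- config$tube_radius_mm + 3 * sigma
  cls <- resample_to_nodes(cl, 60L)
  box_lo <- apply(cls, 2, min) - reach
  box_hi <- apply(cls, 2, max) + reach
  inbox <- which(centers[, 1] >= box_lo[1] & centers[, 1] <= box_hi[1] &
                 centers[, 2] >= box_lo[2] & centers[, 2] <= box_hi[2] &
                 centers[, 3] >= box_lo[3] & centers[, 3] <= box_hi[3])
  g <- array(0, dims)
  if (length(inbox) > 0L) {
    p <- centers[inbox, , drop = FALSE]
    g[inbox] <- exp(-min_dist2_to_polyline(p, cls) / (2 * sigma^2))
  }
  scalar_volume(g, aff, units = "a.u.")
}

min_dist2_to_polyline <- function(points, cl) {
  d2 <- outer(rowSums(points^2), rowSums(cl^2), "+") - 2 * points %*% t(cl)
  # row minima via max.col (C-level), much faster than apply(d2, 1, min)
  pmax(d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))], 0)
}

#' Seed-independent phantom ingredients
#'
#' Geometry, atlas, painted newborn / rate fields and the ventricle-analog
#' mask depend only on the non-seed configuration fields, so they can be
#' computed once and reused across seeds of repeated experiments via the
#' `static` argument of [generate_phantom].
#'
#' @param config A [phantom_config].
#' @return List of deterministic phantom ingredients.
#' @export
phantom_static <- function(config) {
  geom <- phantom_geometry(config)
  atlas <- phantom_atlas(config, geom)
  aff <- phantom_affine(config)
  dims <- config$grid_shape
  centers <- voxel_grid_coords(dims, aff)
  # painted fields: bundle base within each tube, background elsewhere; the
  # rate field references the bundle base (grand mean in the background, so
  # the newborn-dependence term vanishes outside the tubes)
  base_paint <- array(0.35, dims)
  lambda_ref <- array(geom$zstats$r1_grand_mean, dims)
  reach <- config$tube_radius_mm
  for (nm in names(geom$centerlines)) {
    cls <- resample_to_nodes(geom$centerlines[[nm]], 80L)
    box_lo <- apply(cls, 2, min) - reach - 1
    box_hi <- apply(cls, 2, max) + reach + 1
    inbox <- which(centers[, 1] >= box_lo[1] & centers[, 1] <= box_hi[1] &
                   centers[, 2] >= box_lo[2] & centers[, 2] <= box_hi[2] &
                   centers[, 3] >= box_lo[3] & centers[, 3] <= box_hi[3])
    d2 <- min_dist2_to_polyline(centers[inbox, , drop = FALSE], cls)
    tube <- inbox[d2 <= reach^2]
    base_paint[tube] <- config$newborn_r1_bundle_means[nm]
    lambda_ref[tube] <- config$newborn_r1_bundle_means[nm]
  }
  texture <- array(phantom_texture(centers[, 1], centers[, 2], centers[, 3],
                                   config$texture_amp), dims)
  newborn_field <- base_paint + texture
  slope_field <- array(phantom_slope_at(abs(centers[, 1]), centers[, 2],
                                        centers[, 3], as.vector(lambda_ref),
                                        config, geom$zstats), dims)
  md_newborn <- config$md_intercept + config$md_r1_coupling * lambda_ref
  md_slope <- config$md_slope0 * slope_field / config$slope_model$gamma0
  vent <- rowSums(centers^2) <= 8^2
  list(geom = geom, atlas = atlas, affine = aff,
       newborn_field = newborn_field, slope_field = slope_field,
       md_newborn = md_newborn, md_slope = md_slope,
       ventricle_mask = binary_mask(array(vent, dims), aff))
}

rician <- function(x, sd) {
  if (sd <= 0) return(x)
  n <- length(x)
  sqrt((x + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}

#' Generate the full longitudinal phantom
#'
#' Produces everything the pipeline consumes, with known ground truth:
#' planted bundle streamlines plus random distractors, the waypoint /
#' probability-map atlas (already in subject space; template and subject
#' grids coincide in the phantom), per-session R1 and MD volumes, a
#' central ventricle-analog exclusion mask, and the truth record.
#'
#' Newborn R1 is the per-bundle base plus a small smooth texture; the
#' R1 volume of a session at age a is newborn + rate * (a - newborn_ref_age)
#' + subject intercept + Rician voxel noise, where the rate field combines
#' the spatial gradients with the newborn-value dependence (see
#' [phantom_geometry]). MD mirrors R1 with negative rates.
#'
#' @param config A [phantom_config].
#' @param metrics Which volumes to generate per session (default both).
#' @param static Optional precomputed [phantom_static] ingredients for the
#'   same configuration (reusable across seeds).
#' @return List: `config`, `geometry`, `streamlines` ([streamline_set]),
#'   `atlas`, `sessions` (list of `meta` / `r1` / `md`), `ventricle_mask`,
#'   `truth` (per-streamline labels, node table with true newborn R1 and
#'   rate, generating beta vector, subject intercepts, commissure-analog
#'   origin).
#' @export
generate_phantom <- function(config, metrics = c("r1", "md"),
                             static = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(static)) static <- phantom_static(config)
  set.seed(config$seed)
  geom <- static$geom
  sl <- phantom_streamlines(config, geom)
  atlas <- static$atlas
  aff <- static$affine
  dims <- config$grid_shape
  newborn_field <- static$newborn_field
  slope_field <- static$slope_field
  md_newborn <- static$md_newborn
  md_slope <- static$md_slope
  ventricle_mask <- static$ventricle_mask

  subjects <- unique(config$sessions$subject)
  intercepts <- stats::setNames(
    stats::rnorm(length(subjects), 0, config$subject_intercept_sd), subjects)

  sessions <- lapply(seq_len(nrow(config$sessions)), function(i) {
    s <- config$sessions[i, ]
    meta <- session_meta(s$subject, s$age_days, s$timepoint)
    dt <- s$age_days - config$newborn_ref_age
    out <- list(meta = meta)
    if ("r1" %in% metrics) {
      g <- newborn_field + slope_field * dt + intercepts[s$subject]
      g <- array(rician(as.vector(g), config$residual_sd), dims)
      g[ventricle_mask$grid] <- NA_real_
      out$r1 <- scalar_volume(g, aff, units = "s^-1")
    }
    if ("md" %in% metrics) {
      g <- md_newborn + md_slope * dt +
        intercepts[s$subject] * abs(config$md_r1_coupling)
      g <- array(rician(as.vector(g), config$md_noise_sd), dims)
      g[ventricle_mask$grid] <- NA_real_
      out$md <- scalar_volume(g, aff, units = "mm^2/s")
    }
    out
  })

  list(config = config, geometry = geom, streamlines = sl$set, atlas = atlas,
       sessions = sessions, ventricle_mask = ventricle_mask,
       truth = list(labels = sl$labels, nodes = geom$nodes,
                    beta = geom$beta, subject_intercepts = intercepts,
                    origin = c(0, 0, 0)))
}

#' Forward-simulate an inversion-recovery series from a T1 volume
#'
#' Per-voxel forward magnitude signal with a = 1000, b = 2 plus Rician
#' noise. Invalid T1 voxels produce pure noise.
#'
#' @param t1_volume A [scalar_volume] of T1 in ms.
#' @param schedule A [ti_schedule].
#' @param noise_sd Rician noise SD in signal units.
#' @param seed RNG seed for the noise.
#' @param a,b Signal-model parameters.
#' @return 4D array (x, y, z, TI).
#' @export
generate_ir_series <- function(t1_volume, schedule = ti_schedule(),
                               noise_sd = 0, seed = 1L, a = 1000, b = 2) {
  set.seed(seed)
  dims <- dim(t1_volume$grid)
  nt <- length(schedule$times_ms)
  out <- array(0, c(dims, nt))
  t1 <- as.vector(t1_volume$grid)
  ok <- as.vector(t1_volume$valid) & is.finite(t1) & t1 > 0
  for (j in seq_len(nt)) {
    sig <- numeric(length(t1))
    sig[ok] <- abs(a * (1 - b * exp(-schedule$times_ms[j] / t1[ok])))
    out[, , , j] <- array(rician(sig, noise_sd), dims)
  }
  out
}

#' Simulate node-level development-rate records
#'
#' Draws per-node development rates directly from the generating model at
#' the phantom's every-k-th node locations — the fast, record-level
#' counterpart of the full volumetric phantom, used for coefficient
#' recovery experiments. `effects` selects which part of the model
#' generates: spatial gradients only, newborn-value dependence only
#' (the speed-up mechanism), or both.
#'
#' @param config A [phantom_config] (its `slope_model` supplies the
#'   coefficients).
#' @param effects `"spatial"`, `"speedup"` or `"both"`.
#' @param residual_sd Node-level residual SD (s^-1/day), default 2e-5.
#' @param bundle_sd SD of an optional per-bundle random intercept; the
#'   record-level model is purely fixed-effects + residual, so the default
#'   is 0.
#' @param k Node subsampling stride (default 10: nodes 10, 20, ..., 100).
#' @param seed RNG seed.
#' @return data.frame bundle, node, x_abs, y, z, newborn_mean, slope,
#'   true_slope — directly consumable by [fit_slope_models] (which
#'   z-scores the coordinates).
#' @export
simulate_slope_records <- function(config, effects = c("both", "spatial",
                                                       "speedup"),
                                   residual_sd = 2e-5, bundle_sd = 0,
                                   k = 10L, seed = 1L) {
  effects <- match.arg(effects)
  set.seed(seed)
  geom <- phantom_geometry(config)
  sub <- geom$nodes[geom$nodes$node %% k == 0L, , drop = FALSE]
  sm <- config$slope_model
  zs <- geom$zstats
  zx <- (sub$x_abs - zs$mean["x_abs"]) / zs$sd["x_abs"]
  zy <- (sub$y - zs$mean["y"]) / zs$sd["y"]
  zz <- (sub$z - zs$mean["z"]) / zs$sd["z"]
  true_slope <- rep(sm$gamma0, nrow(sub))
  if (effects %in% c("spatial", "both"))
    true_slope <- true_slope +
      sm$gamma_x * zx + sm$gamma_y * zy + sm$gamma_z * zz +
      sm$gamma_xy * zx * zy + sm$gamma_xz * zx * zz + sm$gamma_yz * zy * zz
  if (effects %in% c("speedup", "both"))
    true_slope <- true_slope +
      sm$lambda_speedup * (sub$newborn_r1 - zs$r1_grand_mean)
  bundles <- unique(sub$bundle)
  u <- stats::setNames(stats::rnorm(length(bundles), 0, bundle_sd), bundles)
  slope <- true_slope + u[sub$bundle] + stats::rnorm(nrow(sub), 0, residual_sd)
  data.frame(bundle = sub$bundle, node = sub$node,
             x_abs = sub$x_abs, y = sub$y, z = sub$z,
             newborn_mean = sub$newborn_r1,
             slope = as.vector(slope), true_slope = as.vector(true_slope),
             stringsAsFactors = FALSE)
}
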