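#' Resample a streamline to equidistant nodes
#'
#' Places `n` points at arc-length fractions k/(n-1), k = 0..n-1, by
#' piecewise-linear interpolation along the polyline, so consecutive nodes
#' are equally spaced in arc length along the path.
#'
#' @param s n x 3 polyline matrix.
#' @param n Number of nodes (>= 2); 100 throughout the package.
#' @return n x 3 matrix of node coordinates.
#' @export
resample_to_nodes <- function(s, n = 100L) {
  s <- as.matrix(s)
  if (n < 2L) stop("need at least 2 nodes")
  seg <- s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE]
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
  total <- cum[length(cum)]
  if (total <= 0) stop("zero-length streamline")
  target <- total * (seq_len(n) - 1) / (n - 1)
  # rule = 2 guards the last node against floating-point overshoot of the
  # total arc length
  out <- cbind(stats::approx(cum, s[, 1], xout = target, ties = "ordered",
                             rule = 2)$y,
               stats::approx(cum, s[, 2], xout = target, ties = "ordered",
                             rule = 2)$y,
               stats::approx(cum, s[, 3], xout = target, ties = "ordered",
                             rule = 2)$y)
  dimnames(out) <- NULL
  out
}

#' A tract profile
#'
#' Per-node summaries of a scalar map along a bundle: the core coordinate,
#' the node covariance, and the (weighted) mean, standard error and sample
#' count of the scalar. Node 1 corresponds to the order-1 waypoint end of
#' the bundle (canonical orientation); node indices are 1-based everywhere.
#'
#' @param bundle Bundle name.
#' @param metric Metric tag (e.g. `"r1"`, `"md"`).
#' @param core_xyz n_nodes x 3 matrix of core coordinates (RAS mm).
#' @param node_cov 3 x 3 x n_nodes covariance array (mm^2).
#' @param value_mean,value_se,n_contrib Per-node scalar statistics.
#' @return A `tract_profile`.
#' @export
tract_profile <- function(bundle, metric, core_xyz, node_cov,
                          value_mean, value_se, n_contrib) {
  n <- nrow(core_xyz)
  stopifnot(length(value_mean) == n, length(value_se) == n,
            length(n_contrib) == n, dim(node_cov)[3] == n)
  if (any(!is.finite(value_mean[n_contrib > 0])))
    stop("value_mean must be finite wherever n_contrib > 0")
  structure(list(bundle = bundle, metric = metric, n_nodes = as.integer(n),
                 core_xyz = core_xyz, node_cov = node_cov,
                 value_mean = value_mean, value_se = value_se,
                 n_contrib = as.integer(n_contrib)),
            class = "tract_profile")
}

#' @export
print.tract_profile <- function(x, ...) {
  cat(sprintf("<tract_profile> %s / %s, %d nodes, mean value %.4g\n",
              x$bundle, x$metric, x$n_nodes,
              mean(x$value_mean, na.rm = TRUE)))
  invisible(x)
}

#' Canonicalize member orientation of a bundle
#'
#' Applies the candidacy orientation flags so every member is traversed
#' with node 1 nearest the order-1 waypoint, and returns the oriented
#' member polylines. Downstream node-wise statistics (core, covariance,
#' profiles) require this consistent direction.
#'
#' @param bundle A [segmented_bundle].
#' @param set The parent [streamline_set].
#' @return List of n x 3 member matrices in canonical orientation.
#' @export
canonicalize_orientation <- function(bundle, set) {
  bundle_members(bundle, set)
}

as_members <- function(x, set = NULL) {
  if (inherits(x, "segmented_bundle")) {
    if (is.null(set)) stop("a streamline_set is required with a segmented_bundle")
    bundle_members(x, set)
  } else x
}

#' Bundle core and node covariance
#'
#' The core is the per-node mean position over members; the covariance is
#' the per-node 3x3 sample covariance, regularised by adding (0.1 mm)^2 to
#' the diagonal (single-member bundles get the regularisation floor).
#'
#' @param members List of oriented member polylines (or a
#'   [segmented_bundle] together with `set`).
#' @param set Parent [streamline_set] when `members` is a bundle.
#' @param n_nodes Number of nodes (default 100).
#' @return List with `core_xyz` (n x 3) and `node_cov` (3 x 3 x n).
#' @export
compute_core <- function(members, set = NULL, n_nodes = 100L) {
  members <- as_members(members, set)
  if (length(members) < 1L) stop("bundle has no members")
  arr <- member_node_array(members, n_nodes)
  st <- node_stats(arr)
  list(core_xyz = st$core, node_cov = st$cov)
}

#' Sample a scalar volume at world points
#'
#' Trilinear interpolation with missing-data handling around invalid voxels
#' (see [interp_trilinear]); the default strict mode keeps values that
#' neighbour masked voxels (e.g. ventricles) out of profiles.
#'
#' @param vol A [scalar_volume].
#' @param points n x 3 matrix (or length-3 vector) of RAS-mm points.
#' @param missing `"strict"` (default) or `"lenient"`.
#' @return Numeric vector; NA where missing or outside the grid.
#' @export
sample_scalar <- function(vol, points, missing = "strict") {
  interp_trilinear(vol, points, missing = missing)
}

#' Compute a tract profile of a scalar map
#'
#' Resamples every (cleaned, canonically oriented) member to `n_nodes`
#' equidistant nodes, samples the scalar volume at each member node point,
#' and averages per node. With gaussian weighting (the default) member m at
#' node k gets weight exp(-d_mk^2 / 2), where d_mk is the Mahalanobis
#' distance of its node point to the node distribution, renormalised over
#' the non-missing samples; uniform weighting is a plain mean. The standard
#' error uses the effective sample size (sum w)^2 / sum w^2.
#'
#' @param members List of oriented member polylines, or a
#'   [segmented_bundle] (then pass `set`).
#' @param vol A [scalar_volume].
#' @param weighting `"gaussian"` or `"uniform"`.
#' @param set Parent [streamline_set] when `members` is a bundle.
#' @param n_nodes Number of nodes (default 100).
#' @param bundle_name Name recorded in the profile (taken from the bundle
#'   when one is given).
#' @param metric Metric tag recorded in the profile.
#' @param missing Missing-data mode for sampling (see [sample_scalar]).
#' @return A [tract_profile]. Nodes with no non-missing samples get
#'   `value_mean = NA`, `n_contrib = 0`.
#' @export
compute_profile <- function(members, vol, weighting = c("gaussian", "uniform"),
                            set = NULL, n_nodes = 100L,
                            bundle_name = NULL, metric = "value",
                            missing = "strict") {
  weighting <- match.arg(weighting)
  if (inherits(members, "segmented_bundle") && is.null(bundle_name))
    bundle_name <- members$name
  members <- as_members(members, set)
  if (is.null(bundle_name)) bundle_name <- "bundle"
  if (length(members) < 1L) stop("bundle has no members")
  n_m <- length(members)
  arr <- member_node_array(members, n_nodes)
  st <- node_stats(arr)
  pts <- matrix(arr, n_m * n_nodes, 3)
  vals <- matrix(sample_scalar(vol, pts, missing = missing), n_m, n_nodes)
  if (weighting == "gaussian" && n_m > 1L) {
    w <- matrix(NA_real_, n_m, n_nodes)
    for (k in seq_len(n_nodes)) {
      X <- arr[, k, , drop = FALSE]; dim(X) <- c(n_m, 3L)
      Xc <- sweep(X, 2, st$core[k, ])
      inv <- solve(st$cov[, , k])
      d2 <- pmax(rowSums((Xc %*% inv) * Xc), 0)
      w[, k] <- exp(-d2 / 2)
    }
  } else {
    w <- matrix(1, n_m, n_nodes)
  }
  value_mean <- rep(NA_real_, n_nodes)
  value_se <- rep(NA_real_, n_nodes)
  n_contrib <- integer(n_nodes)
  for (k in seq_len(n_nodes)) {
    ok <- !is.na(vals[, k])
    n_contrib[k] <- sum(ok)
    if (n_contrib[k] == 0L) next
    wk <- w[ok, k]; vk <- vals[ok, k]
    wk <- wk / sum(wk)
    m <- sum(wk * vk)
    value_mean[k] <- m
    if (n_contrib[k] > 1L) {
      var_w <- sum(wk * (vk - m)^2)
      n_eff <- 1 / sum(wk^2)
      value_se[k] <- sqrt(var_w / n_eff)
    } else value_se[k] <- 0
  }
  tract_profile(bundle_name, metric, st$core, st$cov,
                value_mean, value_se, n_contrib)
}

#' Per-node average (|x|, y, z) coordinates across newborn sessions
#'
#' The spatial-gradient models place each node at its average newborn
#' location; the x coordinate enters as |x| so left and right hemispheres
#' share one medial-to-lateral axis.
#'
#' @param tab Long profile table (from [profile_table]) restricted or not;
#'   only rows with timepoint `"0m"` are used when the column is present.
#' @return data.frame with columns bundle, node, x_abs, y, z.
#' @export
node_coordinates_table <- function(tab) {
  if ("timepoint" %in% names(tab) && any(tab$timepoint == "0m", na.rm = TRUE))
    tab <- tab[!is.na(tab$timepoint) & tab$timepoint == "0m", , drop = FALSE]
  if (nrow(tab) == 0L) stop("no newborn sessions in table")
  tab <- tab[!duplicated(tab[, c("subject", "bundle", "node")]), , drop = FALSE]
  agg <- stats::aggregate(cbind(x_abs = abs(tab$x), y = tab$y, z = tab$z),
                          by = list(bundle = tab$bundle, node = tab$node),
                          FUN = mean)
  agg <- agg[order(agg$bundle, agg$node), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
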