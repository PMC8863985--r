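#' Linear mixed-model specification
#'
#' A thin description of the LMMs used throughout: a response column, fixed
#' terms (column names; interaction columns are precomputed by
#' [zscore_coords]), a grouping column receiving a random intercept, and
#' optionally a random slope on the first fixed term.
#'
#' @param response Response column name.
#' @param fixed_terms Character vector of fixed-effect column names (the
#'   intercept is always included).
#' @param group Grouping column for the random intercept.
#' @param random_slope Logical; add a random slope on `fixed_terms[1]`.
#' @return An `lmm_spec`.
#' @export
lmm_spec <- function(response, fixed_terms, group, random_slope = FALSE) {
  stopifnot(length(response) == 1L, length(group) == 1L,
            length(fixed_terms) >= 1L)
  structure(list(response = response, fixed_terms = fixed_terms,
                 group = group, random_slope = isTRUE(random_slope)),
            class = "lmm_spec")
}

lmm_formula <- function(spec) {
  re <- if (spec$random_slope)
    sprintf("(1 + %s | %s)", spec$fixed_terms[1], spec$group)
  else sprintf("(1 | %s)", spec$group)
  stats::as.formula(paste(spec$response, "~ 1 +",
                          paste(spec$fixed_terms, collapse = " + "), "+", re))
}

quiet_lmer <- function(formula, data, reml = TRUE, with_p = TRUE,
                       fast = FALSE) {
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore", check.conv.grad = "ignore",
    check.conv.hess = "ignore", calc.derivs = !fast)
  fitter <- if (with_p) lmerTest::lmer else lme4::lmer
  withCallingHandlers(
    suppressMessages(fitter(formula, data = data, REML = reml,
                            control = ctrl)),
    warning = function(w) {
      if (grepl(paste0("singular|converge|unable to evaluate scaled gradient",
                       "|different scales"), conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Fit a linear mixed model
#'
#' Restricted-maximum-likelihood fit of `response ~ 1 + terms + (1 | group)`
#' (random slope optional) via lme4, with Satterthwaite p-values. The
#' marginal R^2 is the squared correlation between the fixed-effects-only
#' prediction and the response; the adjusted version applies the standard
#' 1 - (1 - R^2)(n - 1)/(n - p - 1) penalty. For likelihood-ratio tests the
#' model is refit by maximum likelihood ([refit_ml]).
#'
#' @param table Long-format data.frame.
#' @param spec An [lmm_spec].
#' @param reml Fit by REML (default) or ML.
#' @return An `lmm_fit`: `beta`, `se`, `pvalue`, `ci_lower`, `ci_upper`
#'   (Wald 95%), `var_random_intercept`, `var_residual`, `loglik`, `n_obs`,
#'   `n_groups`, `r2_marginal`, `r2_adjusted`, plus the underlying `model`.
#' @export
fit_lmm <- function(table, spec, reml = TRUE) {
  need <- c(spec$response, spec$fixed_terms, spec$group)
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[, need, drop = FALSE]), ,
               drop = FALSE]
  if (length(unique(dat[[spec$group]])) < 2L)
    stop("need at least 2 groups for a random intercept")
  X <- as.matrix(cbind(1, dat[, spec$fixed_terms, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effects design")
  fit <- quiet_lmer(lmm_formula(spec), dat, reml = reml)
  co <- stats::coef(summary(fit))
  beta <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  pv <- if ("Pr(>|t|)" %in% colnames(co)) co[, "Pr(>|t|)"] else
    rep(NA_real_, nrow(co))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == spec$group & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)][1]
  var_res <- vc$vcov[vc$grp == "Residual"][1]
  y <- dat[[spec$response]]
  pred_fixed <- as.vector(X %*% beta)
  r2 <- if (stats::sd(pred_fixed) > 0) stats::cor(pred_fixed, y)^2 else 0
  n <- nrow(dat); p <- length(spec$fixed_terms)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(beta = beta, se = se, pvalue = pv,
                 ci_lower = beta - 1.96 * se, ci_upper = beta + 1.96 * se,
                 var_random_intercept = var_int, var_residual = var_res,
                 loglik = as.numeric(stats::logLik(fit)),
                 reml = reml, n_obs = n,
                 n_groups = length(unique(dat[[spec$group]])),
                 r2_marginal = r2, r2_adjusted = r2_adj,
                 spec = spec, model = fit, data = dat),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, n = %d obs / %d groups, R2 = %.3f (adj %.3f)\n",
              deparse(lmm_formula(x$spec)), x$n_obs, x$n_groups,
              x$r2_marginal, x$r2_adjusted))
  print(data.frame(beta = x$beta, se = x$se, p = x$pvalue))
  invisible(x)
}

#' @rdname fit_lmm
#' @param fit An `lmm_fit`.
#' @export
refit_ml <- function(fit) {
  if (!fit$reml) return(fit)
  fit_lmm(fit$data, fit$spec, reml = FALSE)
}

#' Likelihood-ratio test of random slopes
#'
#' Compares the ML fits of the random-intercept model against the model
#' with an added per-group random slope on the first fixed term. The
#' statistic is twice the log-likelihood difference, referred to a
#' chi-square with 2 degrees of freedom (slope variance + intercept-slope
#' covariance); this reference is conservative at the variance boundary.
#'
#' @param table Long-format data.frame.
#' @param spec An [lmm_spec] with `random_slope = FALSE`.
#' @param alpha Significance level for the verdict.
#' @return List: `statistic`, `df`, `pvalue`, `favors_random_slope`,
#'   `loglik_intercept`, `loglik_slope`.
#' @export
compare_random_slope <- function(table, spec, alpha = 0.05) {
  if (spec$random_slope) stop("spec must be the random-intercept model")
  f0 <- fit_lmm(table, spec, reml = FALSE)
  spec1 <- lmm_spec(spec$response, spec$fixed_terms, spec$group,
                    random_slope = TRUE)
  f1 <- fit_lmm(table, spec1, reml = FALSE)
  stat <- max(0, 2 * (f1$loglik - f0$loglik))
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  list(statistic = stat, df = 2, pvalue = p,
       favors_random_slope = p < alpha,
       loglik_intercept = f0$loglik, loglik_slope = f1$loglik)
}

bundle_session_means <- function(tab, metric) {
  tab <- tab[tab$metric == metric & !is.na(tab$value), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for metric '", metric, "'")
  agg <- stats::aggregate(
    list(value = tab$value),
    by = list(subject = tab$subject, age_days = tab$age_days,
              timepoint = tab$timepoint, bundle = tab$bundle),
    FUN = mean)
  agg[order(agg$bundle, agg$subject, agg$age_days), , drop = FALSE]
}

#' Mean-bundle development models
#'
#' Averages the metric over the 100 nodes of each bundle in each session
#' (missing nodes dropped), then fits one LMM per bundle relating the
#' bundle mean to age in days with a random intercept per subject. Also
#' reports each bundle's measured newborn mean and SE across newborn
#' subjects.
#'
#' @param tab Long profile table across sessions (from [profile_table]).
#' @param metric Metric tag to model (e.g. `"r1"`).
#' @return List with `fits` (named list of [fit_lmm] results per bundle),
#'   `summary` (data.frame: bundle, newborn_mean, newborn_se, intercept,
#'   slope_per_day, slope_se, r2_adjusted) and `session_means`.
#' @export
fit_mean_bundle_development <- function(tab, metric = "r1") {
  means <- bundle_session_means(tab, metric)
  tps <- unique(means$timepoint[!is.na(means$timepoint)])
  if ((length(tps) > 0L && length(tps) < 2L) ||
      length(unique(means$age_days)) < 2L)
    stop(">=2 timepoints required to model development")
  spec <- lmm_spec("value", "age_days", "subject")
  bundles <- sort(unique(means$bundle))
  fits <- list()
  rows <- list()
  for (b in bundles) {
    d <- means[means$bundle == b, , drop = FALSE]
    fit <- fit_lmm(d, spec)
    nb <- d[!is.na(d$timepoint) & d$timepoint == "0m", , drop = FALSE]
    nb_mean <- if (nrow(nb) > 0) mean(nb$value) else NA_real_
    nb_se <- if (nrow(nb) > 1) stats::sd(nb$value) / sqrt(nrow(nb)) else NA_real_
    fits[[b]] <- fit
    rows[[b]] <- data.frame(bundle = b, newborn_mean = nb_mean,
                            newborn_se = nb_se,
                            intercept = unname(fit$beta[1]),
                            slope_per_day = unname(fit$beta["age_days"]),
                            slope_se = unname(fit$se["age_days"]),
                            r2_adjusted = fit$r2_adjusted)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(fits = fits, summary = summary, session_means = means)
}

#' Node-wise development map
#'
#' One LMM per (bundle, node) relating the metric to age in days with a
#' random intercept per subject; the slope estimates the local development
#' rate. Newborn means come from the newborn sessions, node coordinates
#' from [node_coordinates_table] (average |x|, y, z across newborns).
#'
#' @param tab Long profile table across sessions.
#' @param metric Metric tag.
#' @param nodes Optional integer vector restricting which nodes are fit
#'   (e.g. `seq(10, 100, 10)`); default all.
#' @return A `development_map` data.frame: bundle, node, newborn_mean,
#'   slope, slope_se, x_abs, y, z. Nodes whose values are all missing get
#'   NA slopes rather than an error.
#' @export
fit_nodewise_development <- function(tab, metric = "r1", nodes = NULL) {
  d <- tab[tab$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for metric '", metric, "'")
  if (!is.null(nodes)) d <- d[d$node %in% nodes, , drop = FALSE]
  coords <- node_coordinates_table(d)
  form <- value ~ age_days + (1 | subject)
  keys <- unique(d[, c("bundle", "node")])
  keys <- keys[order(keys$bundle, keys$node), , drop = FALSE]
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    b <- keys$bundle[i]; k <- keys$node[i]
    di <- d[d$bundle == b & d$node == k & !is.na(d$value), , drop = FALSE]
    nb <- di[!is.na(di$timepoint) & di$timepoint == "0m", , drop = FALSE]
    slope <- slope_se <- NA_real_
    if (nrow(di) >= 3L && length(unique(di$subject)) >= 2L &&
        length(unique(di$age_days)) >= 2L) {
      fit <- quiet_lmer(form, di, fast = TRUE, with_p = FALSE)
      co <- stats::coef(summary(fit))
      slope <- co["age_days", "Estimate"]
      slope_se <- co["age_days", "Std. Error"]
    }
    rows[[i]] <- data.frame(
      bundle = b, node = k,
      newborn_mean = if (nrow(nb) > 0) mean(nb$value) else NA_real_,
      slope = slope, slope_se = slope_se)
  }
  map <- do.call(rbind, rows)
  map <- merge(map, coords, by = c("bundle", "node"), all.x = TRUE)
  map <- map[order(map$bundle, map$node), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("development_map", "data.frame")
  map
}

#' Keep every k-th node of a development map
#'
#' Keeps 1-based nodes k, 2k, ..., so `k = 10` retains nodes 10, 20, ...,
#' 100 — ten spatially separated nodes per bundle, avoiding the strong
#' dependence of neighbouring nodes.
#'
#' @param map A `development_map` (or any data.frame with a node column).
#' @param k Subsampling stride (k = 1 is the identity).
#' @return The subsampled map.
#' @export
subsample_every_kth <- function(map, k = 10L) {
  stopifnot(k >= 1L)
  out <- map[map$node %% k == 0L | k == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Z-score node coordinates and form interaction columns
#'
#' Centres and scales |x|, y, z to mean 0 and sample SD 1 (n - 1
#' denominator) across the included rows, then forms the pairwise
#' interaction columns xy, xz, yz from the standardized coordinates —
#' interactions are built only after standardization.
#'
#' @param map data.frame with columns x_abs, y, z.
#' @return The map with x_abs, y, z standardized and xy, xz, yz added.
#' @export
zscore_coords <- function(map) {
  if (nrow(map) < 2L) stop("need >= 2 rows to z-score")
  for (col in c("x_abs", "y", "z")) {
    s <- stats::sd(map[[col]])
    if (!is.finite(s) || s == 0) stop("zero-variance coordinate: ", col)
    map[[col]] <- (map[[col]] - mean(map[[col]])) / s
  }
  map$xy <- map$x_abs * map$y
  map$xz <- map$x_abs * map$z
  map$yz <- map$y * map$z
  map
}

#' The three staged slope models and their comparison
#'
#' Fits, on a node-subsampled development map with standardized
#' coordinates:
#' \itemize{
#'   \item model 1 (initial-value dependence):
#'     slope ~ 1 + newborn_mean + (1 | bundle)
#'   \item model 2 (spatial gradients):
#'     slope ~ 1 + |x| + y + z + |x|y + |x|z + yz + (1 | bundle)
#'   \item model 3 (combined): the union of both fixed-effect sets
#' }
#' and runs the likelihood-ratio test of model 3 against model 2 (ML
#' refits, 1 df: the newborn term).
#'
#' @param map A subsampled `development_map`; coordinates are z-scored
#'   internally when the interaction columns are absent.
#' @return List: `model1`, `model2`, `model3` ([fit_lmm] objects, REML),
#'   `lrt` (statistic, df, pvalue comparing 3 vs 2).
#' @export
fit_slope_models <- function(map) {
  if (length(unique(map$bundle)) < 2L) stop("need >= 2 bundles")
  dat <- as.data.frame(map)
  dat <- dat[stats::complete.cases(
    dat[, c("slope", "newborn_mean", "x_abs", "y", "z")]), , drop = FALSE]
  if (!all(c("xy", "xz", "yz") %in% names(dat))) dat <- zscore_coords(dat)
  spatial <- c("x_abs", "y", "z", "xy", "xz", "yz")
  m1 <- fit_lmm(dat, lmm_spec("slope", "newborn_mean", "bundle"))
  m2 <- fit_lmm(dat, lmm_spec("slope", spatial, "bundle"))
  m3 <- fit_lmm(dat, lmm_spec("slope", c("newborn_mean", spatial), "bundle"))
  ll2 <- refit_ml(m2)$loglik
  ll3 <- refit_ml(m3)$loglik
  stat <- max(0, 2 * (ll3 - ll2))
  list(model1 = m1, model2 = m2, model3 = m3,
       lrt = list(statistic = stat, df = 1,
                  pvalue = stats::pchisq(stat, 1, lower.tail = FALSE)))
}

#' Refit the combined slope model excluding the bundle ends
#'
#' Drops the first and last `exclude_first` / `exclude_last` nodes of every
#' bundle (where partial-volume effects with cortical gray matter are
#' strongest), re-subsamples every k-th node, and refits model 3.
#'
#' @param map A full (non-subsampled) `development_map`.
#' @param exclude_first,exclude_last Number of nodes to drop at each end.
#' @param k Subsampling stride applied after exclusion.
#' @param n_nodes Total nodes per bundle (default 100).
#' @return The model-3 [fit_lmm] on the restricted map.
#' @export
refit_excluding_node_range <- function(map, exclude_first = 10L,
                                       exclude_last = 10L, k = 10L,
                                       n_nodes = 100L) {
  keep <- map$node > exclude_first & map$node <= n_nodes - exclude_last
  sub <- subsample_every_kth(map[keep, , drop = FALSE], k)
  if (nrow(sub) == 0L) stop("empty table after node exclusion")
  fit_slope_models(sub)$model3
}

#' Across-bundle ordinary correlation
#'
#' Ordinary least-squares R^2 and two-sided p-value for an across-bundle
#' scatter (one point per bundle), e.g. newborn mean versus development
#' slope.
#'
#' @param xs,ys Numeric vectors (>= 3 finite pairs, non-constant x).
#' @return List: `r2`, `pvalue`, `slope`, `n`.
#' @export
correlate_across_bundles <- function(xs, ys) {
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3L) stop("need >= 3 pairs")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) stop("constant input")
  fit <- stats::lm(ys ~ xs)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  list(r2 = sm$r.squared,
       pvalue = sm$coefficients["xs", "Pr(>|t|)"],
       slope = unname(stats::coef(fit)["xs"]),
       n = length(xs))
}
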