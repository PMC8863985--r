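test_that("zero-noise mixed data is recovered exactly", {
  set.seed(1)
  subjects <- sprintf("s%02d", 1:8)
  u <- rnorm(8, 0, 0.01)
  dat <- expand.grid(subject = subjects, age_days = c(10, 100, 190))
  dat$value <- 0.46 + 8.9e-4 * dat$age_days + u[match(dat$subject, subjects)]
  fit <- fit_lmm(dat, lmm_spec("value", "age_days", "subject"))
  expect_lt(abs(fit$beta[["age_days"]] - 8.9e-4), 1e-8)
  # the fixed intercept absorbs the sample mean of the group intercepts
  expect_lt(abs(fit$beta[["(Intercept)"]] - (0.46 + mean(u))), 1e-6)
  expect_identical(fit$n_groups, 8L)
})

test_that("with no group effect the LMM collapses to ordinary least squares", {
  set.seed(2)
  dat <- expand.grid(subject = sprintf("s%d", 1:10), age_days = 1:5)
  dat$value <- 2 + 0.3 * dat$age_days + rnorm(nrow(dat), 0, 0.5)
  fit <- fit_lmm(dat, lmm_spec("value", "age_days", "subject"))
  expect_lt(fit$var_random_intercept, 1e-8)
  ols <- stats::lm(value ~ age_days, dat)
  expect_lt(max(abs(fit$beta - stats::coef(ols))), 1e-6)
})

test_that("the fitter rejects broken designs", {
  dat <- data.frame(subject = rep("a", 6), age_days = 1:6,
                    value = rnorm(6))
  expect_error(fit_lmm(dat, lmm_spec("value", "age_days", "subject")),
               "2 groups")
  dat2 <- expand.grid(subject = c("a", "b"), age_days = 1:4)
  dat2$value <- rnorm(8)
  dat2$dup <- dat2$age_days * 2   # collinear
  expect_error(fit_lmm(dat2, lmm_spec("value", c("age_days", "dup"),
                                      "subject")), "singular")
  expect_error(fit_lmm(dat2, lmm_spec("value", "nope", "subject")),
               "missing columns")
})

test_that("slope estimates are unbiased over repeated simulations", {
  set.seed(33)
  true_slope <- 8.9e-4
  ests <- replicate(200, {
    u <- rnorm(10, 0, 0.01)
    dat <- expand.grid(subject = 1:10, age_days = c(10, 100, 190))
    dat$value <- 0.46 + true_slope * dat$age_days + u[dat$subject] +
      rnorm(nrow(dat), 0, 0.01)
    fit <- fit_lmm(dat, lmm_spec("value", "age_days", "subject"))
    fit$beta[["age_days"]]
  })
  mc_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_slope), 2 * mc_se)
})

test_that("random-slope comparison holds its size and finds real slopes", {
  spec <- lmm_spec("value", "age_days", "subject")
  set.seed(44)
  # null: no per-subject slope variation -> rejection rate <= alpha + margin
  rejections <- replicate(200, {
    u <- rnorm(6, 0, 0.01)
    dat <- expand.grid(subject = 1:6, age_days = c(0, 60, 120, 180))
    dat$value <- 0.4 + 8e-4 * dat$age_days + u[dat$subject] +
      rnorm(nrow(dat), 0, 0.01)
    compare_random_slope(dat, spec)$favors_random_slope
  })
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  # strong per-subject slopes are detected
  set.seed(45)
  u_slope <- rnorm(8, 0, 5e-4)
  dat <- expand.grid(subject = 1:8, age_days = c(0, 60, 120, 180))
  dat$value <- 0.4 + (8e-4 + u_slope[dat$subject]) * dat$age_days +
    rnorm(nrow(dat), 0, 0.005)
  out <- compare_random_slope(dat, spec)
  expect_true(out$favors_random_slope)
  expect_gte(out$statistic, 0)
})

test_that("mean-bundle development needs longitudinal data", {
  tab <- small_phantom_profiles()
  nb_only <- tab[tab$timepoint == "0m", ]
  expect_error(fit_mean_bundle_development(nb_only, "r1"), "2 timepoints")
  expect_error(fit_mean_bundle_development(tab, "nope"), "no rows")
})

test_that("mean-bundle fits recover the phantom's generating rates", {
  sp <- small_phantom()
  tab <- small_phantom_profiles()
  dev <- fit_mean_bundle_development(tab, "r1")
  expect_identical(nrow(dev$summary), 24L)
  truth <- sp$ph$truth$nodes
  true_bundle_slope <- tapply(truth$slope, truth$bundle, mean)
  for (i in seq_len(nrow(dev$summary))) {
    row <- dev$summary[i, ]
    expect_lt(abs(row$slope_per_day - true_bundle_slope[[row$bundle]]),
              2 * row$slope_se + 2e-5)
  }
  # newborn means match the configured bundle means
  expect_lt(max(abs(dev$summary$newborn_mean -
                      sp$cfg$newborn_r1_bundle_means[dev$summary$bundle])),
            0.02)
})

test_that("node-wise maps have one row per bundle and node", {
  # 24 bundles x 100 nodes with too-few observations per node: the map
  # keeps every row and flags the unfittable slopes as missing
  grid <- expand.grid(subject = c("a", "b"), bundle = bundle_names(),
                      node = 1:100, stringsAsFactors = FALSE)
  grid$age_days <- ifelse(grid$subject == "a", 10, 190)
  grid$timepoint <- ifelse(grid$subject == "a", "0m", "6m")
  grid$metric <- "r1"
  grid$value <- 0.5
  grid$x <- 10; grid$y <- 0; grid$z <- 5
  map <- fit_nodewise_development(grid, "r1")
  expect_identical(nrow(map), 2400L)
  expect_true(all(is.na(map$slope)))
  expect_equal(map$newborn_mean, rep(0.5, 2400))
})

test_that("node-wise slopes recover a node-varying developmental gradient", {
  set.seed(55)
  nodes <- seq(10, 100, 10)
  true_slope <- 5e-4 + 6e-6 * nodes  # faster at the far end
  rows <- list()
  for (s in 1:6) {
    u <- rnorm(1, 0, 0.01)
    for (age in c(10, 100, 190)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("s%d", s), age_days = age,
        timepoint = c("0m", "3m", "6m")[match(age, c(10, 100, 190))],
        bundle = "CS_L", node = nodes, metric = "r1",
        value = 0.5 + true_slope * (age - 10) + u +
          rnorm(length(nodes), 0, 0.002),
        x = -20, y = nodes / 2, z = 0)
    }
  }
  tab <- do.call(rbind, rows)
  map <- fit_nodewise_development(tab, "r1", nodes = nodes)
  expect_identical(nrow(map), length(nodes))
  expect_gt(stats::cor(map$slope, true_slope), 0.95)
  # constant-in-time data gives slopes indistinguishable from zero
  tab0 <- tab
  tab0$value <- 0.5 + rnorm(nrow(tab0), 0, 0.002)
  map0 <- fit_nodewise_development(tab0, "r1", nodes = nodes)
  expect_gte(mean(abs(map0$slope) < 2 * map0$slope_se), 0.8)
})

test_that("node subsampling keeps every k-th node", {
  map <- expand.grid(bundle = bundle_names(), node = 1:100,
                     stringsAsFactors = FALSE)
  s10 <- subsample_every_kth(map, 10)
  expect_identical(nrow(s10), 240L)
  expect_identical(sort(unique(s10$node)), seq(10L, 100L, 10L))
  expect_identical(nrow(subsample_every_kth(map, 1)), 2400L)
  s100 <- subsample_every_kth(map, 100)
  expect_identical(nrow(s100), 24L)
  expect_true(all(s100$node == 100L))
})

test_that("coordinate z-scoring follows the sample-SD convention", {
  map <- data.frame(x_abs = c(10, 20), y = c(-5, 5), z = c(0, 8))
  zs <- zscore_coords(map)
  expect_equal(zs$x_abs, c(-1, 1) / sqrt(2))  # sample SD convention
  set.seed(66)
  map2 <- data.frame(x_abs = runif(50, 0, 40), y = rnorm(50, 0, 30),
                     z = rnorm(50, 0, 25))
  zs2 <- zscore_coords(map2)
  for (col in c("x_abs", "y", "z")) {
    expect_lt(abs(mean(zs2[[col]])), 1e-12)
    expect_equal(stats::sd(zs2[[col]]), 1, tolerance = 1e-12)
  }
  # mean of an interaction of z-scored columns is the sample correlation
  # (up to the n/(n-1) factor between the two conventions)
  n <- nrow(zs2)
  expect_equal(mean(zs2$xy) * n / (n - 1), stats::cor(map2$x_abs, map2$y),
               tolerance = 1e-12)
  expect_error(zscore_coords(data.frame(x_abs = c(1, 1), y = c(1, 2),
                                        z = c(1, 2))), "zero-variance")
})

test_that("staged slope models distinguish the generating mechanisms", {
  cfg <- small_phantom_config()
  # pure speed-up: slope depends only on newborn value, negatively
  rec_s <- simulate_slope_records(cfg, effects = "speedup",
                                  residual_sd = 2e-5, seed = 3)
  fits_s <- fit_slope_models(rec_s)
  b_nb <- fits_s$model1$beta[["newborn_mean"]]
  expect_lt(b_nb, 0)
  expect_lt(fits_s$model1$pvalue[["newborn_mean"]], 0.001)
  expect_gt(fits_s$model1$r2_marginal, fits_s$model2$r2_marginal)
  # pure spatial: the spatial model dominates
  rec_g <- simulate_slope_records(cfg, effects = "spatial",
                                  residual_sd = 2e-5, seed = 4)
  fits_g <- fit_slope_models(rec_g)
  expect_gt(fits_g$model2$r2_marginal, fits_g$model1$r2_marginal)
  # both mechanisms: the combined model beats the spatial model by LRT
  rec_b <- simulate_slope_records(cfg, effects = "both",
                                  residual_sd = 2e-5, seed = 5)
  fits_b <- fit_slope_models(rec_b)
  expect_lt(fits_b$lrt$pvalue, 0.05)
  # nesting: model 3 can never have lower ML log-likelihood than model 2
  expect_gte(refit_ml(fits_b$model3)$loglik, refit_ml(fits_b$model2)$loglik)
})

test_that("spatial-model LRT keeps its size under the spatial null", {
  cfg <- small_phantom_config()
  set.seed(99)
  nonsig <- replicate(50, {
    rec <- simulate_slope_records(cfg, effects = "spatial",
                                  residual_sd = 2e-5,
                                  seed = sample.int(1e6, 1))
    fit_slope_models(rec)$lrt$pvalue >= 0.05
  })
  expect_gte(mean(nonsig), 0.9)
})

test_that("z-scored and raw coordinates give the same fitted model", {
  cfg <- small_phantom_config()
  rec <- simulate_slope_records(cfg, effects = "spatial", residual_sd = 0,
                                bundle_sd = 0, seed = 6)
  zs <- zscore_coords(rec)
  raw <- rec
  raw$xy <- raw$x_abs * raw$y; raw$xz <- raw$x_abs * raw$z
  raw$yz <- raw$y * raw$z
  spec <- lmm_spec("slope", c("x_abs", "y", "z", "xy", "xz", "yz"), "bundle")
  f_z <- fit_lmm(zs, spec)
  f_raw <- fit_lmm(raw, spec)
  # the reparameterization is linear, so fitted values and R^2 agree
  pz <- as.vector(cbind(1, as.matrix(zs[, spec$fixed_terms])) %*% f_z$beta)
  praw <- as.vector(cbind(1, as.matrix(raw[, spec$fixed_terms])) %*% f_raw$beta)
  expect_lt(max(abs(pz - praw)), 1e-10)
  expect_equal(f_z$r2_marginal, f_raw$r2_marginal, tolerance = 1e-8)
})

test_that("generating coefficients fall inside their 95% CIs most of the time", {
  cfg <- small_phantom_config()
  terms <- c("newborn_mean", "x_abs", "y", "z", "xy", "yz")
  truth <- c(cfg$slope_model$lambda_speedup, cfg$slope_model$gamma_x,
             cfg$slope_model$gamma_y, cfg$slope_model$gamma_z,
             cfg$slope_model$gamma_xy, cfg$slope_model$gamma_yz)
  hits <- matrix(NA, 100, length(terms))
  for (r in 1:100) {
    rec <- simulate_slope_records(cfg, effects = "both", residual_sd = 2e-5,
                                  seed = 1000 + r)
    m3 <- fit_slope_models(rec)$model3
    hits[r, ] <- truth >= m3$ci_lower[terms] & truth <= m3$ci_upper[terms]
  }
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("model 3 keeps its effects when the bundle ends are excluded", {
  cfg <- small_phantom_config()
  set.seed(77)
  geomrec <- simulate_slope_records(cfg, effects = "both",
                                    residual_sd = 2e-5, k = 1, seed = 8)
  full_fit <- refit_excluding_node_range(geomrec, 0, 0)
  sub_fit <- fit_slope_models(subsample_every_kth(geomrec, 10))$model3
  expect_equal(full_fit$beta, sub_fit$beta, tolerance = 1e-10)
  trimmed <- refit_excluding_node_range(geomrec, 10, 10)
  for (tm in c("newborn_mean", "z", "y"))
    expect_identical(sign(trimmed$beta[[tm]]), sign(sub_fit$beta[[tm]]))
  expect_error(refit_excluding_node_range(geomrec, 50, 50), "empty table")
})

test_that("across-bundle correlation matches closed forms and the null", {
  x <- 1:10
  expect_equal(correlate_across_bundles(x, 2 + 3 * x)$r2, 1)
  neg <- correlate_across_bundles(x, -x)
  expect_equal(neg$r2, 1)
  expect_lt(neg$slope, 0)
  expect_error(correlate_across_bundles(rep(1, 5), rnorm(5)), "constant")
  expect_error(correlate_across_bundles(1:2, 1:2), "3 pairs")
  # independent noise: E[R^2] = 1/(n - 1)
  set.seed(88)
  n <- 24
  r2s <- replicate(500, correlate_across_bundles(rnorm(n), rnorm(n))$r2)
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * stats::sd(r2s) / sqrt(500))
})
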