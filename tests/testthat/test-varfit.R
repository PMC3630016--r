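test_that("null fits match hand ANOVA on the 2-blocks-of-3 toy", {
  tu <- toy_two_blocks()
  f0 <- fit_null(tu)
  expect_equal(f0$sigma2_e, 3.5)
  expect_equal(f0$df_error, 5)
  fb <- fit_null(tu, c(1, 3))
  expect_equal(fb$sigma2_e, 1.0)
  expect_equal(unname(fb$components["block"]), 25 / 6)
  expect_equal(fb$df_error, 4)
})

test_that("closed-form estimates equal constrained REML (lme4) on balanced toys", {
  tu <- toy_two_blocks()
  fb <- fit_null(tu, c(1, 3))
  m <- lme4::lmer(value ~ 1 + (1 | b),
                  data = data.frame(value = tu$data$value,
                                    b = factor(rep(1:2, each = 3))),
                  REML = TRUE)
  expect_equal(unname(fb$components["block"]),
               as.numeric(lme4::VarCorr(m)$b), tolerance = 1e-4)
  expect_equal(fb$sigma2_e, sigma(m)^2, tolerance = 1e-4)
  expect_equal(fb$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)

  # boundary case: between-block mean square below within => component 0
  tz <- uniformity_with_values(strip_layout(4), c(1, 5, 3, 7))
  fz <- fit_null(tz, c(1, 2))
  expect_equal(unname(fz$components["block"]), 0)
  expect_equal(fz$sigma2_e, 8)
})

test_that("no-blocking error variance is the plain sample variance", {
  u <- default_zone(seed = 4)
  expect_equal(fit_null(u)$sigma2_e, stats::var(u$data$value))
})

test_that("rows-and-columns null fit recovers the residual mean square", {
  lay <- grid_layout(3, 24)
  u <- default_zone(seed = 5)
  arr <- blocking_arrangement(3, 4, rows_columns = TRUE)
  fit <- fit_null(u, arr)
  blk <- make_blocks(lay, arr)
  ref <- stats::anova(stats::lm(u$data$value ~ blk$block + blk$row + blk$col))
  expect_equal(fit$sigma2_e, ref["Residuals", "Mean Sq"])
  expect_equal(fit$df_error, ref["Residuals", "Df"])
  expect_true(all(fit$components >= 0))
})

test_that("constant data yields zero components", {
  cu <- uniformity_with_values(strip_layout(6), rep(7, 6))
  f <- fit_null(cu, c(1, 3))
  expect_equal(f$sigma2_e, 0)
  expect_equal(unname(f$components["block"]), 0)
})

test_that("CRD pairwise variances follow the standard formula 2 s2 / r", {
  lay <- grid_layout(3, 24)
  u <- default_zone(seed = 6)
  d <- make_crd(36, 2, lay, seed = 1)
  f <- fit_treatment_model(u, d)
  expect_equal(f$sigma2diff_bar, 2 * f$sigma2_e / 2, tolerance = 1e-10)
  expect_equal(f$df_error, 36)
  D <- f$pairdiff_var
  expect_true(isSymmetric(D))
  expect_true(all(abs(D[upper.tri(D)] - f$sigma2_e) < 1e-8))
  expect_equal(mean_pairwise_variance(f), f$sigma2diff_bar)
})

test_that("RCBD GLS estimates equal block-adjusted treatment means (v=3, b=2)", {
  # balanced toy: 2 replicate blocks of 3 cells, v = 3
  s6 <- strip_layout(6)
  tu <- uniformity_with_values(s6, c(10, 12, 17, 20, 19, 24))
  d <- make_rcbd(3, s6, rep_shape = c(1, 3), seed = 2)
  f <- fit_treatment_model(tu, d, variance_model("none", fixed_blocks = TRUE))
  # in a balanced complete-block layout, adjusted means = raw treatment means
  means <- as.vector(tapply(tu$data$value, d$cells$treatment, mean))
  eff_hand <- means - means[1]
  expect_equal(unname(f$treatment_effects), eff_hand, tolerance = 1e-10)
  expect_equal(f$df_error, (3 - 1) * (2 - 1))
})

test_that("orthogonal trend column leaves treatment estimates unchanged", {
  lay <- grid_layout(3, 24)
  u <- default_zone(seed = 7)
  d <- make_trend_free(36, 2, lay, rep_shape = c(3, 12), seed = 3)
  expect_equal(d$provenance$Q, 0)
  f_no <- fit_treatment_model(u, d, variance_model("none"))
  f_tr <- fit_treatment_model(u, d, variance_model("global"))
  expect_lt(max(abs(f_no$treatment_effects - f_tr$treatment_effects)), 1e-10)
})

test_that("prediction variances are invariant to treatment relabelling", {
  lay <- grid_layout(3, 24)
  u <- default_zone(seed = 8)
  d <- make_crd(36, 2, lay, seed = 4)
  f1 <- fit_treatment_model(u, d)
  perm <- sample(36)
  d2 <- d
  d2$cells$treatment <- perm[d$cells$treatment]
  f2 <- fit_treatment_model(u, d2)
  D1 <- f1$pairdiff_var
  D2 <- f2$pairdiff_var[perm, perm]
  expect_equal(D1, D2, tolerance = 1e-8)
})

test_that("mixed-model fit recovers inter-block information for an IBD", {
  lay <- grid_layout(3, 24)
  u <- default_zone(seed = 9)
  d <- make_resolved_ibd(36, 2, lay, block_shape = c(3, 1), seed = 5)
  f <- fit_treatment_model(u, d, variance_model("none",
                                                random = c("replicate", "block")))
  expect_true(all(f$components >= 0))
  expect_gt(f$sigma2diff_bar, 0)
  expect_equal(f$df_error,
               error_df(d, variance_model("none",
                                          random = c("replicate", "block"))))
})

test_that("error df bookkeeping matches the classical ANOVA counts", {
  lay <- grid_layout(3, 24)
  crd <- make_crd(36, 2, lay, seed = 1)
  expect_equal(error_df(crd, variance_model("none")), 36)
  rcbd <- make_rcbd(36, lay, c(3, 12), seed = 2)
  expect_equal(error_df(rcbd, variance_model("none", fixed_blocks = TRUE)), 35)
  expect_equal(error_df(rcbd, variance_model("block_equal",
                                             fixed_blocks = TRUE)), 34)
})

test_that("inestimable configurations raise explicit errors", {
  lay <- grid_layout(3, 24)
  u <- default_zone(seed = 10)
  # single-replicate saturated design: unequal slopes cannot be estimated
  d1 <- make_trend_free(72, 1, lay, block_shape = c(3, 12), seed = 6)
  expect_error(fit_treatment_model(u, d1,
                                   variance_model("block_unequal",
                                                  fixed_blocks = TRUE)))
  d2 <- make_trend_free(36, 2, lay, rep_shape = c(3, 12), seed = 7)
  expect_error(fit_treatment_model(u, d2, variance_model("block_unequal")),
               "block")
})

test_that("boundary-adjusted REMLRT matches chi-square quantile oracles", {
  p1 <- remlrt(list(loglik = 0), list(loglik = 2.706 / 2), boundary = TRUE)
  expect_equal(p1$statistic, 2.706)
  expect_equal(p1$p_value, 0.5 * stats::pchisq(2.706, 1, lower.tail = FALSE))
  expect_equal(p1$p_value, 0.05, tolerance = 1e-3)

  p2 <- remlrt(list(loglik = 0), list(loglik = 3.841 / 2), boundary = FALSE)
  expect_equal(p2$p_value, stats::pchisq(3.841, 1, lower.tail = FALSE))
  expect_equal(p2$p_value, 0.05, tolerance = 1e-3)

  # alternative below null: statistic truncates to zero, mixture gives 0.5
  p0 <- remlrt(list(loglik = 1), list(loglik = 0.2), boundary = TRUE)
  expect_equal(p0$statistic, 0)
  expect_equal(p0$p_value, 0.5)

  # an in-package likelihood pair: blocks vs no blocks on the toy
  tu <- toy_two_blocks()
  f0 <- fit_null(tu)
  fb <- fit_null(tu, c(1, 3))
  r <- remlrt(f0, fb, boundary = TRUE)
  expect_gte(r$statistic, 0)
  expect_lte(r$p_value, 0.5)
})

test_that("trend-aware REML null fit recovers generator truth", {
  lay <- grid_layout(3, 24)
  arr <- c(3, 2) # 12 blocks of 6
  blocks <- make_blocks(lay, arr)$block
  f <- make_field(lay, field_params(zone_mean = 70, zone_sd = 10,
                                    pos_slope = 1, block_sd = 5))
  reps <- 200
  est <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("s2b", "s2e", "beta")))
  for (i in seq_len(reps)) {
    u <- simulate_uniformity(f, seed = 5000 + i, blocks = blocks)
    fit <- fit_null(u, arr, trend = TRUE)
    est[i, ] <- c(fit$components["block"], fit$sigma2_e,
                  fit$fixed[["score"]])
  }
  target <- c(s2b = 25, s2e = 100, beta = 1)
  for (k in colnames(est)) {
    mc_se <- stats::sd(est[, k]) / sqrt(reps)
    expect_lt(abs(mean(est[, k]) - target[[k]]), 3 * mc_se + 1e-12,
              label = paste("recovery of", k))
  }
})

test_that("fit results serialize to JSON", {
  fb <- fit_null(toy_two_blocks(), c(1, 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fb, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$sigma2_e, 1.0)
  expect_true(j$converged)
})
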