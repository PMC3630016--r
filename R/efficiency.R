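#' Modified A-optimality criterion AP
#'
#' `AP = F(1, d, 1 - alpha) * sigma2diff_bar`: the mean variance of pairwise
#' treatment-prediction differences weighted by the F quantile, so that
#' designs with fewer error degrees of freedom are penalized. Smaller AP is
#' better.
#'
#' @param sigma2diff_bar Mean variance of all pairwise prediction differences.
#' @param d Error degrees of freedom (>= 1).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An `ap_criterion` object: `sigma2diff_bar`, `d`, `alpha`,
#'   `f_quantile`, `ap`.
#' @examples
#' ap(1, 35)$ap # F quantile for 1 and 35 df at 95%
#' @export
ap <- function(sigma2diff_bar, d, alpha = 0.05) {
  if (d < 1) stop("error degrees of freedom must be >= 1")
  stopifnot(sigma2diff_bar >= 0, alpha > 0, alpha < 1)
  fq <- stats::qf(1 - alpha, 1, d)
  structure(list(sigma2diff_bar = sigma2diff_bar, d = d, alpha = alpha,
                 f_quantile = fq, ap = fq * sigma2diff_bar),
            class = "ap_criterion")
}

#' @export
print.ap_criterion <- function(x, ...) {
  cat(sprintf("AP = %.5g  (sigma2diff_bar = %.5g, d = %.4g, F = %.4f)\n",
              x$ap, x$sigma2diff_bar, x$d, x$f_quantile))
  invisible(x)
}

#' Relative precision of a blocking arrangement on uniformity data
#'
#' `100 * (no-blocking error variance) / (arrangement's error variance)`,
#' the no-blocking error variance being the sample variance of all
#' observations. Values above 100 favour blocking.
#'
#' @param data A `uniformity_data` object.
#' @param arrangement A [blocking_arrangement()] or `c(lanes, positions)`;
#'   append `rows_columns = TRUE` via a full arrangement object for the
#'   rows-and-columns series.
#' @return Scalar percentage (`Inf`, with a warning, if the arrangement's
#'   error variance is 0).
#' @export
relative_precision <- function(data, arrangement) {
  s2_none <- stats::var(data$data$value)
  fit <- fit_null(data, arrangement)
  if (fit$sigma2_e == 0) {
    warning("degenerate arrangement: zero error variance, infinite precision")
    return(Inf)
  }
  100 * s2_none / fit$sigma2_e
}

#' Precision impact of separating the position trend
#'
#' Fits a Lane + Position model ("Positions separated") and a Lane-only model
#' ("Positions pooled" into error) to a zone's uniformity data and returns
#' both residual standard deviations along with the relative precision
#' `100 * pooled variance / separated variance`. Ratios above 100 mean
#' isolating positions pays.
#'
#' @param data A `uniformity_data` object on a lanes x positions grid.
#' @return List `sd_separated`, `sd_pooled`, `relative_precision`.
#' @export
pool_vs_separate_positions <- function(data) {
  d <- data$data
  lane_f <- factor(d$lane)
  pos_f <- factor(d$position)
  sep <- stats::lm(d$value ~ lane_f + pos_f)
  pool <- stats::lm(d$value ~ lane_f)
  v_sep <- summary(sep)$sigma^2
  v_pool <- summary(pool)$sigma^2
  list(sd_separated = sqrt(v_sep), sd_pooled = sqrt(v_pool),
       relative_precision = 100 * v_pool / v_sep)
}

#' Exact AP for a completely randomized design
#'
#' Standard-formula path: with overall sample variance `s2` of the uniformity
#' data, every pairwise difference of treatment means has variance `2 s2 / r`
#' and the error df is `N - v`.
#'
#' @param data A `uniformity_data` object.
#' @param v,r Treatments and replication (`v * r` = cell count).
#' @param alpha Significance level.
#' @return An `ap_criterion`.
#' @export
ap_crd_exact <- function(data, v, r, alpha = 0.05) {
  n <- nrow(data$data)
  if (v * r != n) stop("v * r must equal the cell count")
  s2 <- stats::var(data$data$value)
  ap(2 * s2 / r, n - v, alpha)
}

#' Exact AP for a randomized complete block design
#'
#' Uses the randomization expectation of the error mean square, which for an
#' RCBD on uniformity data equals the pooled within-block mean square of the
#' null blocked analysis; the error df is `(v - 1)(b - 1)`.
#'
#' @param data A `uniformity_data` object.
#' @param v Treatments (= replicate block size).
#' @param rep_shape Replicate block tile shape, e.g. `c(3, 12)`.
#' @param alpha Significance level.
#' @return An `ap_criterion`.
#' @export
ap_rcbd_exact <- function(data, v, rep_shape = c(3, 12), alpha = 0.05) {
  fit <- fit_null(data, rep_shape)
  n <- nrow(data$data)
  b <- n / v
  r <- b
  d <- (v - 1) * (b - 1)
  ap(2 * fit$sigma2_e / r, d, alpha)
}

#' Monte-Carlo AP over the randomization distribution of a design
#'
#' Draws `n_samples` randomizations of `design` (restricted moves, full
#' re-randomization, or optimizer regeneration, as the design class permits),
#' overlays each on the uniformity data, fits the treatment model, and
#' averages the mean pairwise-difference variances and the error df over the
#' sample. AP is built from the two means; the Monte-Carlo standard error of
#' the AP estimate is reported. Non-converged fits are dropped with a count;
#' more than 1% failures aborts.
#'
#' @param data A `uniformity_data` object.
#' @param design A `design` object.
#' @param model A [variance_model()].
#' @param n_samples Number of randomizations (full-scale defaults are 5000,
#'   or 1000 with regeneration for trend-free designs).
#' @param alpha Significance level.
#' @param seed Root seed; per-iteration seeds are spawned from it.
#' @param regenerate Regenerate trend-free designs instead of restricted
#'   moves.
#' @param budget Optimizer budget per regeneration.
#' @return An `ap_criterion` with extra fields `mc_se`, `n_samples`,
#'   `n_failed`, `mean_df`.
#' @export
monte_carlo_ap <- function(data, design, model = variance_model(),
                           n_samples = 500, alpha = 0.05, seed = 1L,
                           regenerate = FALSE, budget = 4000) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  s2d <- numeric(n_samples)
  dfs <- numeric(n_samples)
  ok <- logical(n_samples)
  for (i in seq_len(n_samples)) {
    res <- tryCatch({
      di <- randomize_design(design, seed = seeds[i], regenerate = regenerate,
                             budget = budget)
      fit <- fit_treatment_model(data, di, model, keep_loglik = FALSE)
      if (!fit$converged) NULL else c(fit$sigma2diff_bar, fit$df_error)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      s2d[i] <- res[1]; dfs[i] <- res[2]; ok[i] <- TRUE
    }
  }
  n_failed <- sum(!ok)
  if (n_failed > 0.01 * n_samples)
    stop("more than 1% of Monte-Carlo fits failed (", n_failed, "/",
         n_samples, ")")
  s2d <- s2d[ok]; dfs <- dfs[ok]
  out <- ap(mean(s2d), mean(dfs), alpha)
  out$mc_se <- out$f_quantile * stats::sd(s2d) / sqrt(length(s2d))
  out$n_samples <- length(s2d)
  out$n_failed <- n_failed
  out$mean_df <- mean(dfs)
  out
}

#' The standard design/analysis menu
#'
#' The ten design-and-analysis strategies compared for equally-replicated
#' experiments on a 3-lane by 24-position zone: CRD with and without linear
#' position-trend adjustment, a trend-free design, RCBD with replicates of
#' 3 x 12 (with and without within-block trend adjustment), a trend-free
#' complete-block design with equal slopes, a resolved row-column design, and
#' resolved incomplete block designs with blocks of 3 x 1, 1 x 4 and 3 x 6.
#' With 24 thrice-replicated lines the analogous menu uses replicates of
#' 3 x 8 and nearly trend-free designs with equal or unequal slopes.
#'
#' @param v Number of lines: 36 (r = 2) or 24 (r = 3).
#' @param layout A [grid_layout()] (3 x 24 by default).
#' @return Named list of menu entries; each has `generator(seed)`, `model`,
#'   `regenerate`, and a `samples_factor` (trend-free entries use 1/5 the
#'   Monte-Carlo sample per the 5000 vs 1000 convention).
#' @export
design_menu <- function(v = 36, layout = grid_layout(3, 24)) {
  n <- n_cells(layout)
  r <- n / v
  if (r != round(r)) stop("v must divide the cell count")
  rs <- c(layout$n_lanes, layout$n_positions / r) # replicate tile
  entry <- function(gen, model, regenerate = FALSE, samples_factor = 1)
    list(generator = gen, model = model, regenerate = regenerate,
         samples_factor = samples_factor)
  menu <- list(
    CRD = entry(function(seed) make_crd(v, r, layout, seed),
                variance_model("none")),
    `CRD+Adj` = entry(function(seed) make_crd(v, r, layout, seed),
                      variance_model("global")),
    TFD = entry(function(seed) make_trend_free(v, r, layout, rep_shape = rs,
                                               seed = seed),
                variance_model("global"), regenerate = TRUE,
                samples_factor = 1 / 5),
    RCBD = entry(function(seed) make_rcbd(v, layout, rep_shape = rs,
                                          seed = seed),
                 variance_model("none", fixed_blocks = TRUE)),
    `RCBD+Adj` = entry(function(seed) make_rcbd(v, layout, rep_shape = rs,
                                                seed = seed),
                       variance_model("block_equal", fixed_blocks = TRUE)),
    TFCBDEqLin = entry(function(seed)
      make_trend_free(v, r, layout, rep_shape = rs, block_shape = rs,
                      seed = seed),
      variance_model("block_equal", fixed_blocks = TRUE),
      regenerate = TRUE, samples_factor = 1 / 5),
    RRCD = entry(function(seed) make_row_column(v, layout, rep_shape = rs,
                                                seed = seed),
                 variance_model("none", random = c("replicate", "row", "col"))),
    RIBD3x1 = entry(function(seed)
      make_resolved_ibd(v, r, layout, block_shape = c(layout$n_lanes, 1),
                        rep_shape = rs, seed = seed),
      variance_model("none", random = c("replicate", "block"))),
    RIBD1x4 = entry(function(seed)
      make_resolved_ibd(v, r, layout, block_shape = c(1, 4),
                        rep_shape = rs, seed = seed),
      variance_model("none", random = c("replicate", "block"))),
    RIBD3x6 = entry(function(seed)
      make_resolved_ibd(v, r, layout, block_shape = c(layout$n_lanes, 6),
                        rep_shape = rs, seed = seed),
      variance_model("none", random = c("replicate", "block")))
  )
  if (v == 24) {
    # with three replicates only nearly trend-free block designs exist and
    # unequal slopes between blocks become estimable
    menu$NTFCBDUneqLin <- entry(function(seed)
      make_trend_free(v, r, layout, rep_shape = rs, block_shape = rs,
                      seed = seed),
      variance_model("block_unequal", fixed_blocks = TRUE),
      regenerate = TRUE, samples_factor = 1 / 5)
  }
  menu
}

#' Compare a menu of designs by Monte-Carlo relative efficiency
#'
#' For each menu entry, estimates AP over the entry's randomization
#' distribution and reports the relative efficiency
#' `RE_PDA = 100 * AP_CRD / AP_PDA`, where AP_CRD is computed once per
#' dataset from the closed-form CRD analysis. Designs at least 10% more
#' efficient than the CRD (RE >= 110) are the ones worth adopting.
#'
#' @param data A `uniformity_data` object.
#' @param menu A [design_menu()] or named subset of one.
#' @param n_samples Base Monte-Carlo sample size (entries scale it by their
#'   `samples_factor`).
#' @param alpha Significance level.
#' @param seed Root seed.
#' @param v,r Lines and replication implied by the menu (inferred from the
#'   first generated design).
#' @return Data frame `design, re_percent, ap, mc_se, n_samples, mean_df`.
#' @export
compare_designs <- function(data, menu = design_menu(), n_samples = 500,
                            alpha = 0.05, seed = 1L) {
  if (is.null(names(menu)) || any(!nzchar(names(menu))))
    stop("menu entries must be named; valid names come from design_menu()")
  probe <- menu[[1]]$generator(1L)
  v <- probe$v; r <- probe$r
  ap_crd <- ap_crd_exact(data, v, r, alpha)

  set.seed(as.integer(seed))
  entry_seeds <- sample.int(.Machine$integer.max - 1L, length(menu))
  rows <- vector("list", length(menu))
  for (i in seq_along(menu)) {
    nm <- names(menu)[i]
    ent <- menu[[i]]
    if (nm == "CRD") {
      rows[[i]] <- data.frame(design = nm, re_percent = 100,
                              ap = ap_crd$ap, mc_se = 0,
                              n_samples = 0, mean_df = ap_crd$d)
      next
    }
    ns <- max(1L, round(n_samples * ent$samples_factor))
    base <- ent$generator(entry_seeds[i])
    mc <- monte_carlo_ap(data, base, ent$model, n_samples = ns,
                         alpha = alpha, seed = entry_seeds[i],
                         regenerate = ent$regenerate)
    rows[[i]] <- data.frame(design = nm,
                            re_percent = 100 * ap_crd$ap / mc$ap,
                            ap = mc$ap, mc_se = mc$mc_se,
                            n_samples = mc$n_samples, mean_df = mc$mean_df)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
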