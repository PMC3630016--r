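#' @title Null and treatment model fitting
#' @description Variance-component estimation for blocking arrangements on
#'   uniformity data (exact balanced ANOVA / method-of-moments, equal to
#'   nonnegativity-constrained REML on the balanced structures this package
#'   constructs), generalized-least-squares treatment models with recovery of
#'   inter-block information (via lme4 when random block terms are present),
#'   pairwise-difference prediction variances, containment-style error
#'   degrees of freedom, and boundary-adjusted REML likelihood-ratio tests.
#' @name varfit
NULL

# Dense-matrix Gaussian REML log-likelihood at given variance components.
# V = s2e I + sum_k comps[k] Z_k Z_k'; l_R = -1/2 [ (n-p) log(2pi) + log|V|
#   + log|X' V^-1 X| + y' P y ].
reml_loglik <- function(y, X, Zlist = list(), comps = numeric(0), s2e) {
  n <- length(y)
  p <- qr(X)$rank
  if (s2e <= 0) return(NA_real_)
  V <- diag(s2e, n)
  for (k in seq_along(Zlist))
    if (comps[k] > 0) V <- V + comps[k] * tcrossprod(Zlist[[k]])
  ch <- chol(V)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  resid <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), resid))
  yPy <- sum(resid * Vi_r)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + logdetV +
                       determinant(XtViX, logarithm = TRUE)$modulus + yPy))
}

dummy_matrix <- function(f) {
  f <- droplevels(as.factor(f))
  if (nlevels(f) < 2) return(matrix(1, length(f), 1))
  stats::model.matrix(~ f - 1)
}

new_fit_result <- function(...) structure(list(...), class = "fit_result")

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", x$method, "\n")
  if (length(x$components))
    cat("  components:", paste(sprintf("%s=%.4g", names(x$components),
                                       x$components), collapse = ", "), "\n")
  cat(sprintf("  sigma2_e=%.4g  df_error=%.4g  loglik=%.4f  converged=%s\n",
              x$sigma2_e, x$df_error, x$loglik, x$converged))
  invisible(x)
}

#' Null (uniformity) mixed-model analysis for a blocking arrangement
#'
#' Fits the model that ignores any treatments: random block-type terms plus a
#' single residual variance. Estimates are exact closed-form balanced ANOVA
#' (method-of-moments) estimators truncated at zero, which on the balanced
#' rectangular arrangements this package constructs coincide with
#' nonnegativity-constrained REML. With no blocking, the error variance is the
#' plain sample variance (n - 1 divisor) of all observations.
#'
#' @param data A `uniformity_data` object.
#' @param blocking `NULL` for no blocking, a [blocking_arrangement()] (or
#'   `c(block_lanes, block_positions)`), or a data frame of factors as from
#'   [make_blocks()] (`block`, optionally `row`, `col`).
#' @param trend Also fit a fixed linear position-trend term (centered scores
#'   over the layout). The fit is then REML (lme4) rather than closed-form
#'   ANOVA, because the trend is not orthogonal to position-band blocks; the
#'   slope estimate is returned in `fixed["score"]`.
#' @return A `fit_result`: `components` (named variance-component estimates),
#'   `sigma2_e`, REML `loglik` evaluated at the estimates, `df_error`, `n`,
#'   `converged`, and `fixed` when `trend = TRUE`.
#' @examples
#' u <- simulate_uniformity(make_field(grid_layout(3, 24), field_params()))
#' fit_null(u, c(3, 1))$sigma2_e
#' @export
fit_null <- function(data, blocking = NULL, trend = FALSE) {
  y <- data$data$value
  n <- length(y)
  if (trend) return(fit_null_trend(data, blocking))
  if (is.null(blocking)) {
    s2 <- stats::var(y)
    ll <- reml_loglik(y, matrix(1, n, 1), s2e = s2)
    return(new_fit_result(components = numeric(0), sigma2_e = s2,
                          loglik = ll, df_error = n - 1, n = n,
                          converged = TRUE, method = "anova/no-blocking"))
  }
  if (!is.data.frame(blocking))
    blocking <- make_blocks(data$layout,
                            if (inherits(blocking, "blocking_arrangement"))
                              blocking else
                                blocking_arrangement(blocking[1], blocking[2],
                                                     rows_columns = length(blocking) > 2 && blocking[3]))
  blk <- droplevels(as.factor(blocking$block))
  b <- nlevels(blk)
  k <- n / b
  X <- matrix(1, n, 1)

  if (is.null(blocking$row)) {
    # one-way random blocks
    m <- tapply(y, blk, mean)
    ssb <- k * sum((m - mean(y))^2)
    ssw <- sum((y - m[blk])^2)
    msb <- if (b > 1) ssb / (b - 1) else 0
    msw <- ssw / (b * (k - 1))
    s2e <- msw
    s2b <- max(0, (msb - msw) / k)
    comps <- c(block = s2b)
    Zl <- list(dummy_matrix(blk))
    ll <- reml_loglik(y, X, Zl, comps, s2e)
    return(new_fit_result(components = comps, sigma2_e = s2e, loglik = ll,
                          df_error = b * (k - 1), n = n, converged = TRUE,
                          method = "anova/blocks"))
  }

  # blocks with rows and columns nested in blocks; residual = row x col
  # interaction within blocks
  row_f <- droplevels(as.factor(blocking$row))
  col_f <- droplevels(as.factor(blocking$col))
  nr <- nlevels(row_f) / b   # rows per block
  nc <- nlevels(col_f) / b   # cols per block
  fit <- if (b > 1) stats::lm(y ~ blk + row_f + col_f)
         else stats::lm(y ~ row_f + col_f)
  aov_tab <- stats::anova(fit)
  mse <- aov_tab["Residuals", "Mean Sq"]
  df_e <- aov_tab["Residuals", "Df"]
  ms_row <- aov_tab["row_f", "Mean Sq"]
  ms_col <- aov_tab["col_f", "Mean Sq"]
  ms_blk <- if (b > 1) aov_tab["blk", "Mean Sq"] else 0
  s2e <- mse
  s2_row <- max(0, (ms_row - mse) / nc)
  s2_col <- max(0, (ms_col - mse) / nr)
  s2_blk <- if (b > 1)
    max(0, (ms_blk - nc * s2_row - nr * s2_col - mse) / (nr * nc)) else 0
  comps <- c(block = s2_blk, row = s2_row, col = s2_col)
  Zl <- list(dummy_matrix(blk), dummy_matrix(row_f), dummy_matrix(col_f))
  ll <- reml_loglik(y, X, Zl, comps, s2e)
  new_fit_result(components = comps, sigma2_e = s2e, loglik = ll,
                 df_error = df_e, n = n, converged = TRUE,
                 method = "anova/rows-columns")
}

# REML null fit with a fixed linear position trend plus random blocks.
fit_null_trend <- function(data, blocking = NULL) {
  y <- data$data$value
  n <- length(y)
  score <- position_scores(data$layout)
  if (is.null(blocking)) {
    fit <- stats::lm(y ~ score)
    s2e <- summary(fit)$sigma^2
    return(new_fit_result(components = numeric(0), sigma2_e = s2e,
                          loglik = reml_loglik(y, stats::model.matrix(fit),
                                               s2e = s2e),
                          df_error = fit$df.residual, n = n, converged = TRUE,
                          fixed = stats::coef(fit), method = "ols/trend"))
  }
  if (!is.data.frame(blocking))
    blocking <- make_blocks(data$layout,
                            if (inherits(blocking, "blocking_arrangement"))
                              blocking else
                                blocking_arrangement(blocking[1], blocking[2]))
  blk <- droplevels(as.factor(blocking$block))
  conv <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(y ~ score + (1 | blk), REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) { conv <<- FALSE; invokeRestart("muffleWarning") })
  vc <- lme4::VarCorr(fit)
  comps <- c(block = as.numeric(vc$blk))
  s2e <- attr(vc, "sc")^2
  X <- lme4::getME(fit, "X")
  d <- n - qr(cbind(X, dummy_matrix(blk)))$rank
  new_fit_result(components = comps, sigma2_e = s2e,
                 loglik = reml_loglik(y, X, list(dummy_matrix(blk)), comps,
                                      s2e),
                 df_error = d, n = n, converged = conv,
                 fixed = lme4::fixef(fit), method = "reml/trend")
}

#' Analysis model specification for a treatment fit
#'
#' @param trend One of `"none"`, `"global"` (one linear position-trend slope,
#'   centered over the layout), `"block_equal"` (per-block centered scores,
#'   one common slope), `"block_unequal"` (per-block centered scores with a
#'   separate slope per block; requires >= 2 blocks).
#' @param random Character subset of `c("replicate", "block", "row", "col")`
#'   fitted as random intercepts (recovering inter-block information).
#' @param fixed_blocks Fit the block factor as fixed (the classical RCBD
#'   analysis; equivalent to random blocks there by orthogonality).
#' @return A `variance_model` object.
#' @export
variance_model <- function(trend = c("none", "global", "block_equal",
                                     "block_unequal"),
                           random = character(0), fixed_blocks = FALSE) {
  trend <- match.arg(trend)
  stopifnot(all(random %in% c("replicate", "block", "row", "col")))
  structure(list(trend = trend, random = random,
                 fixed_blocks = isTRUE(fixed_blocks)),
            class = "variance_model")
}

model_frame_for <- function(data, design, model) {
  cells <- design$cells
  key_d <- paste(data$data$lane, data$data$position)
  key_c <- paste(cells$lane, cells$position)
  df <- data.frame(value = data$data$value[match(key_c, key_d)],
                   treatment = factor(cells$treatment,
                                      levels = seq_len(design$v)))
  for (f in c("replicate", "block", "row", "col"))
    if (!is.null(cells[[f]])) df[[f]] <- droplevels(as.factor(cells[[f]]))
  if (model$trend != "none") {
    if (model$trend %in% c("block_equal", "block_unequal")) {
      if (is.null(df$block)) stop("per-block trend terms require blocks")
      df$score <- position_scores(design$layout, blocks = df$block)
    } else df$score <- position_scores(design$layout)
  }
  df
}

#' Treatment mixed-model fit with prediction variances
#'
#' Fits treatments (fixed) plus the trend and block terms of a
#' [variance_model()] to uniformity data overlaid with a design. With random
#' block-type terms the fit is REML (lme4) followed by generalized least
#' squares for the fixed effects, so treatment predictions combine intra- and
#' inter-block information; without random terms it is ordinary least
#' squares. Returns the variances of all pairwise treatment-prediction
#' differences, the inputs of the modified A-optimality criterion.
#'
#' @param data A `uniformity_data` object.
#' @param design A `design` object on the same layout.
#' @param model A [variance_model()].
#' @param keep_loglik Evaluate the REML log-likelihood at the estimates
#'   (skipped inside Monte-Carlo loops for speed).
#' @return A `fit_result` with `pairdiff_var` (v x v matrix of pairwise
#'   difference variances), `sigma2diff_bar`, `treatment_effects` (contrasts
#'   to treatment 1), `components`, `sigma2_e`, `df_error`, `converged`.
#' @export
fit_treatment_model <- function(data, design, model = variance_model(),
                                keep_loglik = TRUE) {
  df <- model_frame_for(data, design, model)
  v <- design$v
  n <- nrow(df)

  fixed <- "value ~ treatment"
  if (model$fixed_blocks) {
    if (is.null(df$block)) stop("fixed_blocks requires a blocked design")
    fixed <- paste(fixed, "+ block")
  }
  fixed <- switch(model$trend,
                  none = fixed,
                  global = paste(fixed, "+ score"),
                  block_equal = paste(fixed, "+ score"),
                  block_unequal = {
                    if (is.null(df$block) || nlevels(df$block) < 2)
                      stop("unequal per-block slopes require >= 2 blocks")
                    paste(fixed, "+ block:score")
                  })
  for (rt in model$random)
    if (is.null(df[[rt]]))
      stop("random term '", rt, "' not present in the design")

  if (length(model$random) == 0) {
    fit <- stats::lm(stats::as.formula(fixed), data = df)
    cf <- stats::coef(fit)
    slope_terms <- grep("score", names(cf), value = TRUE)
    if (anyNA(cf[slope_terms]) || anyNA(cf[grep("^treatment", names(cf))]))
      stop("model is inestimable for this design (aliased terms)")
    Vb <- stats::vcov(fit)
    comps <- numeric(0)
    s2e <- summary(fit)$sigma^2
    beta <- cf
    conv <- TRUE
    X <- stats::model.matrix(fit)
    d <- n - qr(X)$rank
    ll <- if (keep_loglik) reml_loglik(df$value, X, s2e = s2e) else NA_real_
  } else {
    rand <- paste(sprintf("(1 | %s)", model$random), collapse = " + ")
    form <- stats::as.formula(paste(fixed, "+", rand))
    conv <- TRUE
    fit <- withCallingHandlers(
      lme4::lmer(form, data = df, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      warning = function(w) {
        conv <<- FALSE
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(fit)
    if (anyNA(beta)) stop("model is inestimable for this design (aliased terms)")
    Vb <- as.matrix(stats::vcov(fit))
    vc <- lme4::VarCorr(fit)
    comps <- vapply(model$random, function(g) as.numeric(vc[[g]]), numeric(1))
    s2e <- attr(vc, "sc")^2
    X <- lme4::getME(fit, "X")
    Z <- as.matrix(lme4::getME(fit, "Z"))
    d <- n - qr(cbind(X, Z))$rank
    ll <- if (keep_loglik)
      reml_loglik(df$value, X,
                  lapply(model$random, function(g) dummy_matrix(df[[g]])),
                  comps, s2e) else NA_real_
  }
  if (d <= 0) stop("over-parameterized design: error df <= 0")

  # pairwise-difference variances: with treatment contrasts, pred_i - pred_j
  # only involves the treatment dummy coefficients (baseline treatment 1)
  tn <- paste0("treatment", seq_len(v))
  idx <- match(tn[-1], colnames(Vb))
  if (anyNA(idx)) stop("treatment coefficients missing from the fit")
  Vt <- matrix(0, v, v)
  Vt[2:v, 2:v] <- Vb[idx, idx, drop = FALSE]
  D <- outer(diag(Vt), diag(Vt), "+") - 2 * Vt
  diag(D) <- 0
  eff <- c(0, beta[match(tn[-1], names(beta))])

  new_fit_result(components = comps, sigma2_e = s2e, loglik = ll,
                 df_error = d, n = n, converged = conv,
                 method = if (length(model$random)) "reml/gls" else "ols",
                 pairdiff_var = D,
                 sigma2diff_bar = mean(D[upper.tri(D)]),
                 treatment_effects = eff, model = model)
}

#' Mean variance of pairwise treatment-prediction differences
#'
#' Arithmetic mean over all v(v-1)/2 unordered treatment pairs.
#' @param fit A `fit_result` from [fit_treatment_model()].
#' @return Scalar, the criterion input usually written sigma2diff-bar.
#' @export
mean_pairwise_variance <- function(fit) {
  D <- fit$pairdiff_var
  if (is.null(D) || nrow(D) < 2) stop("fit has no treatment pair variances")
  mean(D[upper.tri(D)])
}

#' Error degrees of freedom of a design/model combination
#'
#' Containment-style degrees of freedom: `N - rank([X | Z])` where X holds the
#' fixed-effect columns (intercept, treatments, fixed blocks, trend terms) and
#' Z the dummy columns of the random terms. For orthogonal designs this equals
#' the classical ANOVA error df (e.g. RCBD with v = 36, r = 2: d = 35).
#'
#' @param design A `design` object.
#' @param model A [variance_model()].
#' @param data Optional `uniformity_data` (any values; only the layout is
#'   used). Defaults to a zero-filled surface on the design's layout.
#' @return Integer error df; errors if d <= 0.
#' @export
error_df <- function(design, model = variance_model(), data = NULL) {
  if (is.null(data)) {
    lay <- design$layout
    dat <- lay$cells
    dat$value <- 0
    data <- structure(list(layout = lay, data = dat, metadata = list()),
                      class = "uniformity_data")
  }
  df <- model_frame_for(data, design, model)
  X <- matrix(1, nrow(df), 1)
  X <- cbind(X, dummy_matrix(df$treatment))
  if (model$fixed_blocks) X <- cbind(X, dummy_matrix(df$block))
  if (model$trend %in% c("global", "block_equal")) X <- cbind(X, df$score)
  if (model$trend == "block_unequal")
    X <- cbind(X, dummy_matrix(df$block) * df$score)
  for (rt in model$random) X <- cbind(X, dummy_matrix(df[[rt]]))
  d <- nrow(df) - qr(X)$rank
  if (d <= 0) stop("over-parameterized design: error df <= 0")
  d
}

#' Boundary-adjusted REML likelihood-ratio test
#'
#' Statistic `2 (l_alt - l_null)` truncated at zero, referred to a chi-square
#' with 1 df; when the tested component is constrained nonnegative (the
#' boundary case) the p-value uses the 50:50 mixture of a point mass at zero
#' and chi-square(1), i.e. it is halved.
#'
#' @param fit_null,fit_alt `fit_result` objects of nested models with the same
#'   fixed structure (the alternative adds one variance component).
#' @param boundary Is the tested component constrained to be nonnegative?
#' @return List with `statistic`, `p_value`, `boundary`.
#' @examples
#' # statistic 2.706 with the boundary adjustment gives p = 0.05
#' @export
remlrt <- function(fit_null, fit_alt, boundary = TRUE) {
  ll0 <- if (inherits(fit_null, "fit_result")) fit_null$loglik else as.numeric(fit_null)
  ll1 <- if (inherits(fit_alt, "fit_result")) fit_alt$loglik else as.numeric(fit_alt)
  if (is.na(ll0) || is.na(ll1)) stop("fits must carry REML log-likelihoods")
  if (inherits(fit_null, "fit_result") && inherits(fit_alt, "fit_result") &&
      length(fit_alt$components) < length(fit_null$components))
    stop("models are not nested (alternative has fewer components)")
  stat <- max(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary) p <- 0.5 * p
  list(statistic = stat, p_value = p, boundary = boundary)
}

#' Serialize a fit result to JSON
#' @param fit A `fit_result`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(components = as.list(fit$components),
                            sigma2_e = fit$sigma2_e,
                            df_error = fit$df_error,
                            loglik = fit$loglik,
                            converged = fit$converged,
                            method = fit$method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
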