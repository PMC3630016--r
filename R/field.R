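#' Deterministic microclimate expectation surface
#'
#' Builds the expected response for every cart cell:
#' `zone_mean + pos_slope * (position - mean(position)) + lane_effect`,
#' multiplied by `shade_penalty` for shaded lanes. Because position scores are
#' centered, `zone_mean` is the prediction at the centre of a lane.
#'
#' @param layout A [grid_layout()].
#' @param params A [field_params()].
#' @return A `field_surface` object: the layout plus an `expectation` vector
#'   (one value per cell, in `layout$cells` order).
#' @examples
#' f <- make_field(grid_layout(3, 24), field_params(pos_slope = 0))
#' all(f$expectation == 71.62)
#' @export
make_field <- function(layout, params) {
  check_params_layout(params, layout)
  cells <- layout$cells
  zm <- rep_len(params$zone_mean, length(layout$zone_bounds))
  le <- rep_len(params$lane_effects, layout$n_lanes)
  mu <- zm[cells$zone] +
    params$pos_slope * (cells$position - mean(seq_len(layout$n_positions))) +
    le[cells$lane]
  shaded <- cells$lane %in% params$shaded_lanes
  mu[shaded] <- mu[shaded] * params$shade_penalty
  structure(list(layout = layout, params = params, expectation = mu),
            class = "field_surface")
}

#' Simulate a uniformity trial on a field surface
#'
#' Adds Gaussian noise to the deterministic expectation of a
#' [make_field()] surface. Noise has per-zone standard deviation
#' `params$zone_sd`; when `params$ar1_rho != 0` the noise within each lane
#' follows a stationary first-order autoregression along positions with the
#' same marginal variance. When `blocks` is supplied and `params$block_sd > 0`,
#' an iid `N(0, block_sd^2)` effect is added per block (a device for
#' generating data with a known between-block variance component).
#'
#' A uniformity trial carries no treatments: its values expose the background
#' spatial variation against which candidate designs are later compared.
#'
#' @param field A `field_surface` from [make_field()].
#' @param params Optional [field_params()]; defaults to those stored in `field`.
#' @param seed Integer seed; defaults to `params$seed`. Fixed seed gives
#'   bit-identical output.
#' @param blocks Optional block factor (one level per cell) for the random
#'   block effects.
#' @return A `uniformity_data` object: `layout`, a `data` data frame
#'   (lane, position, zone, side, value), and `metadata` (params, seed).
#' @export
simulate_uniformity <- function(field, params = field$params,
                                seed = params$seed, blocks = NULL) {
  layout <- field$layout
  check_params_layout(params, layout)
  cells <- layout$cells
  zsd <- rep_len(params$zone_sd, length(layout$zone_bounds))
  rho <- params$ar1_rho

  set.seed(as.integer(seed))
  if (rho == 0) {
    eps <- stats::rnorm(nrow(cells), 0, zsd[cells$zone])
  } else {
    # stationary AR1 per lane: e_1 ~ N(0, s^2), e_p = rho e_{p-1} + innov
    eps <- numeric(nrow(cells))
    for (l in seq_len(layout$n_lanes)) {
      idx <- which(cells$lane == l)
      idx <- idx[order(cells$position[idx])]
      s <- zsd[cells$zone[idx[1]]]
      z <- stats::rnorm(length(idx))
      e <- numeric(length(idx))
      e[1] <- s * z[1]
      if (length(idx) > 1)
        for (p in 2:length(idx))
          e[p] <- rho * e[p - 1] + s * sqrt(1 - rho^2) * z[p]
      eps[idx] <- e
    }
  }
  value <- field$expectation + eps
  if (!is.null(blocks) && params$block_sd > 0) {
    blocks <- as.factor(blocks)
    stopifnot(length(blocks) == nrow(cells))
    be <- stats::rnorm(nlevels(blocks), 0, params$block_sd)
    value <- value + be[as.integer(blocks)]
  }
  dat <- cbind(cells, value = value)
  structure(list(layout = layout, data = dat,
                 metadata = list(params = params, seed = as.integer(seed))),
            class = "uniformity_data")
}

#' @export
print.uniformity_data <- function(x, ...) {
  cat(sprintf("uniformity_data: %d cells, mean %.2f, sd %.2f\n",
              nrow(x$data), mean(x$data$value), stats::sd(x$data$value)))
  invisible(x)
}

#' Summary statistics of uniformity data
#'
#' Per-group mean, standard deviation (n - 1 divisor) and coefficient of
#' variation `CV% = 100 * sd / mean`, grouped by zone, lane, or the whole grid.
#'
#' @param data A `uniformity_data` object.
#' @param grouping One of `"zone"`, `"lane"`, `"grid"`.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, `cv`. A group
#'   with mean 0 gets `cv = NA` with a warning rather than being dropped.
#' @examples
#' u <- simulate_uniformity(make_field(grid_layout(3, 24), field_params()))
#' uniformity_summary(u, "grid")
#' @export
uniformity_summary <- function(data, grouping = c("zone", "lane", "grid")) {
  grouping <- match.arg(grouping)
  d <- data$data
  g <- switch(grouping,
              zone = factor(d$zone),
              lane = factor(d$lane),
              grid = factor(rep("all", nrow(d))))
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    v <- d$value[g == lev]
    data.frame(group = lev, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  out$cv <- ifelse(out$mean == 0, NA_real_, 100 * out$sd / out$mean)
  if (anyNA(out$cv)) warning("CV undefined for group(s) with zero mean")
  rownames(out) <- NULL
  out
}

#' Write / read uniformity data as CSV
#'
#' Columns `lane, position, zone, value`, header required, UTF-8.
#' @param data A `uniformity_data` object.
#' @param path File path.
#' @export
write_uniformity_csv <- function(data, path) {
  utils::write.csv(data$data[, c("lane", "position", "zone", "value")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_uniformity_csv
#' @param layout Optional [grid_layout()]; reconstructed from the file's lane
#'   and position ranges when omitted.
#' @export
read_uniformity_csv <- function(path, layout = NULL) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("lane", "position", "zone", "value")
  if (!all(need %in% names(d))) stop("uniformity CSV must have columns ",
                                     paste(need, collapse = ", "))
  if (is.null(layout)) {
    nl <- max(d$lane); np <- max(d$position)
    zb <- lapply(split(d$lane, d$zone), function(l) sort(unique(l)))
    layout <- grid_layout(nl, np, zone_bounds = unname(zb),
                          side_split = if (np %% 2 == 0) NULL else (np + 1) %/% 2)
  }
  d <- d[order(d$lane, d$position), ]
  cells <- layout$cells
  if (nrow(d) != nrow(cells)) stop("cell count does not match layout")
  dat <- cells
  key_file <- paste(d$lane, d$position)
  key_lay <- paste(cells$lane, cells$position)
  if (!setequal(key_file, key_lay)) stop("cells in file do not match layout")
  dat$value <- d$value[match(key_lay, key_file)]
  structure(list(layout = layout, data = dat,
                 metadata = list(source = path)),
            class = "uniformity_data")
}
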