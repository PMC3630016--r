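#' The three standard blocking-arrangement series
#'
#' The screening grid used on uniformity data: (i) blocks confined to a
#' single lane with 2, 3, 4, 6, 8, 12 or 24 carts; (ii) blocks spanning all
#' 3 lanes and 1, 2, 3, 4, 6, 8 or 12 positions; (iii) rows-and-columns
#' blocks of 3 lanes by 2, 3, 4, 6, 8, 12 or 24 positions.
#'
#' @param layout A [grid_layout()] (the widths are tailored to 3 x 24).
#' @return Data frame `series, block_lanes, block_positions, rows_columns`.
#' @export
blocking_series <- function(layout = grid_layout(3, 24)) {
  widths <- c(2, 3, 4, 6, 8, 12, 24)
  rbind(
    data.frame(series = "within-lane", block_lanes = 1,
               block_positions = widths, rows_columns = FALSE),
    data.frame(series = "cross-lane", block_lanes = layout$n_lanes,
               block_positions = c(1, 2, 3, 4, 6, 8, 12),
               rows_columns = FALSE),
    data.frame(series = "rows-columns", block_lanes = layout$n_lanes,
               block_positions = widths, rows_columns = TRUE)
  )
}

#' Relative precision of every arrangement in the standard series
#'
#' @param data A `uniformity_data` object.
#' @param series Data frame as from [blocking_series()].
#' @return The series data frame with `relative_precision` and `df_error`
#'   columns appended.
#' @export
evaluate_blocking <- function(data, series = blocking_series(data$layout)) {
  series$relative_precision <- NA_real_
  series$df_error <- NA_real_
  for (i in seq_len(nrow(series))) {
    arr <- blocking_arrangement(series$block_lanes[i],
                                series$block_positions[i],
                                rows_columns = series$rows_columns[i])
    fit <- fit_null(data, arr)
    series$relative_precision[i] <- 100 * stats::var(data$data$value) /
      fit$sigma2_e
    series$df_error[i] <- fit$df_error
  }
  series
}

#' Flat key-value run configuration
#'
#' A run configuration collects the layout, field parameters, tactic, menu
#' and Monte-Carlo settings of a full pipeline run. It round-trips losslessly
#' through a flat `key = value` text file.
#'
#' @param n_lanes,n_positions Layout dimensions.
#' @param zone_mean,zone_sd,pos_slope,lane_effects,shaded_lanes,shade_penalty,ar1_rho
#'   Field parameters; see [field_params()].
#' @param tactic_name Optional tactic to simulate (`""` to skip).
#' @param n_timepoints Imaging time points for the tactic stage.
#' @param v Number of lines for the design comparison.
#' @param n_samples Base Monte-Carlo sample size (500 by default; ask for the
#'   full-scale 5000 explicitly when wanted).
#' @param alpha Significance level.
#' @param seed Root seed; every stochastic stage draws its seed from it.
#' @param out_dir Output directory for result files.
#' @return A `run_config` object (a named list).
#' @export
run_config <- function(n_lanes = 3, n_positions = 24, zone_mean = 71.62,
                       zone_sd = 20.2, pos_slope = 0.5, lane_effects = 0,
                       shaded_lanes = integer(0), shade_penalty = 0.75,
                       ar1_rho = 0, tactic_name = "", n_timepoints = 14,
                       v = 36, n_samples = 500, alpha = 0.05, seed = 1L,
                       out_dir = "results") {
  structure(list(n_lanes = n_lanes, n_positions = n_positions,
                 zone_mean = zone_mean, zone_sd = zone_sd,
                 pos_slope = pos_slope, lane_effects = lane_effects,
                 shaded_lanes = shaded_lanes, shade_penalty = shade_penalty,
                 ar1_rho = ar1_rho, tactic_name = tactic_name,
                 n_timepoints = n_timepoints, v = v, n_samples = n_samples,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path for the flat key = value form.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- run_config()
  for (p in kv) {
    k <- trimws(p[1])
    vtxt <- trimws(paste(p[-1], collapse = "="))
    vals <- strsplit(vtxt, ",", fixed = TRUE)[[1]]
    out[[k]] <- if (k %in% c("tactic_name", "out_dir")) vals else {
      num <- suppressWarnings(as.numeric(vals))
      if (anyNA(num)) vals else num
    }
  }
  out$seed <- as.integer(out$seed)
  if (length(out$shaded_lanes) == 0 ||
      identical(out$shaded_lanes, "")) out$shaded_lanes <- integer(0)
  class(out) <- "run_config"
  out
}

#' Run the full evaluation pipeline
#'
#' Executes: uniformity simulation, an optional tactic simulation with
#' exposure accounting, the blocking-precision sweep over the three standard
#' arrangement series, and the Monte-Carlo design comparison. All tables are
#' written as CSV under `config$out_dir` together with a JSON manifest
#' (seeds, parameters, per-stage timings, Monte-Carlo failure counts).
#' Identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param menu Optional named subset of [design_menu()] names to run
#'   (default: the full menu).
#' @return Invisibly, a list with the in-memory results (`uniformity`,
#'   `tactic`, `blocking`, `efficiency`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), menu = NULL) {
  lay0 <- grid_layout(config$n_lanes, config$n_positions)
  full_menu <- design_menu(config$v, lay0)
  if (!is.null(menu)) {
    bad <- setdiff(menu, names(full_menu))
    if (length(bad))
      stop("unknown menu name(s): ", paste(bad, collapse = ", "),
           "; valid names: ", paste(names(full_menu), collapse = ", "))
    full_menu <- full_menu[menu]
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)
  manifest <- list(config = unclass(config), stage_seeds = stage_seeds,
                   stages = list())
  t_all <- proc.time()[3]

  lay <- grid_layout(config$n_lanes, config$n_positions)
  par <- field_params(zone_mean = config$zone_mean, zone_sd = config$zone_sd,
                      pos_slope = config$pos_slope,
                      lane_effects = config$lane_effects,
                      shaded_lanes = config$shaded_lanes,
                      shade_penalty = config$shade_penalty,
                      ar1_rho = config$ar1_rho, seed = stage_seeds[1])
  t0 <- proc.time()[3]
  uni <- simulate_uniformity(make_field(lay, par))
  write_uniformity_csv(uni, file.path(config$out_dir, "uniformity.csv"))
  utils::write.csv(uniformity_summary(uni, "grid"),
                   file.path(config$out_dir, "uniformity_summary.csv"),
                   row.names = FALSE)
  manifest$stages$simulate <- list(seconds = proc.time()[3] - t0,
                                   seed = stage_seeds[1])

  tact <- NULL
  if (nzchar(config$tactic_name)) {
    t0 <- proc.time()[3]
    tc <- tactic(config$tactic_name)
    sched <- build_schedule(tc, lay, config$n_timepoints)
    full <- grid_layout(24, config$n_positions)
    fpar <- field_params(zone_mean = config$zone_mean,
                         zone_sd = config$zone_sd,
                         pos_slope = config$pos_slope,
                         shaded_lanes = config$shaded_lanes,
                         shade_penalty = config$shade_penalty,
                         seed = stage_seeds[2])
    ffield <- make_field(full, fpar)
    tact <- simulate_tactic_response(sched, ffield, seed = stage_seeds[2])
    write_schedule_csv(sched, file.path(config$out_dir, "schedule.csv"))
    utils::write.csv(tact$trajectory,
                     file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    manifest$stages$tactic <- list(seconds = proc.time()[3] - t0,
                                   seed = stage_seeds[2],
                                   tactic = config$tactic_name)
  }

  t0 <- proc.time()[3]
  blocking <- evaluate_blocking(uni)
  utils::write.csv(blocking, file.path(config$out_dir, "blocking_precision.csv"),
                   row.names = FALSE)
  manifest$stages$blocking <- list(seconds = proc.time()[3] - t0,
                                   n_arrangements = nrow(blocking))

  t0 <- proc.time()[3]
  eff <- compare_designs(uni, full_menu, n_samples = config$n_samples,
                         alpha = config$alpha, seed = stage_seeds[3])
  utils::write.csv(eff, file.path(config$out_dir, "design_efficiency.csv"),
                   row.names = FALSE)
  manifest$stages$efficiency <- list(seconds = proc.time()[3] - t0,
                                     seed = stage_seeds[3],
                                     n_samples = config$n_samples)

  manifest$total_seconds <- proc.time()[3] - t_all
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(uniformity = uni, tactic = tact, blocking = blocking,
                 efficiency = eff, manifest = manifest))
}
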