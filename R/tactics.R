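#' Plant-relocation tactics
#'
#' A tactic is a policy for moving (or not moving) the 72 plants of a zone
#' between imaging time points:
#' \describe{
#'   \item{bench}{plants on fixed benches, never relocated (home lanes 1-3 of
#'     a bench-like grid).}
#'   \item{same_lane}{plants on the conveyor, always returned to the same
#'     cell (lanes 1-3).}
#'   \item{half_lane}{plants start in lanes 4-6; after each imaging the
#'     western half of a lane moves to the eastern half of the same lane and
#'     the eastern half moves to the western half of the next lane, cycling
#'     through the 16 half-lane slots of lanes 4-11 (lane 11 east wraps to
#'     lane 4 west).}
#'   \item{next_lane}{plants start in lanes 12-14; after each imaging a whole
#'     lane moves to the next lane, position unchanged, cycling through lanes
#'     12-24 (lane 24 wraps to lane 12).}
#' }
#'
#' @param name One of `"bench"`, `"same_lane"`, `"half_lane"`, `"next_lane"`.
#' @return A `tactic` object with `name`, `home_lanes`, `cycle_lanes`.
#' @export
tactic <- function(name = c("bench", "same_lane", "half_lane", "next_lane")) {
  name <- match.arg(name)
  home <- switch(name, bench = 1:3, same_lane = 1:3,
                 half_lane = 4:6, next_lane = 12:14)
  cycle <- switch(name, bench = 1:3, same_lane = 1:3,
                  half_lane = 4:11, next_lane = 12:24)
  structure(list(name = name, home_lanes = home, cycle_lanes = cycle),
            class = "tactic")
}

#' Build the per-plant occupancy schedule of a tactic
#'
#' Enumerates, for each of the 72 plants of a zone (3 home lanes by
#' `n_positions` positions) and each imaging time point, the (lane, position)
#' cell the plant occupies. Moves happen after every imaging, so the cell at
#' time point t reflects t - 1 moves. Half-lane moves are order-preserving:
#' position p maps to p + half within the same lane and back to p - half in
#' the next lane, so plants keep their east-west order within a half-lane
#' group.
#'
#' @param tactic A [tactic()].
#' @param layout A [grid_layout()] giving `n_positions` (must be even for
#'   half_lane); its lane count is not used - schedules live on the tactic's
#'   own absolute lanes.
#' @param n_timepoints Number of imaging time points (default 14).
#' @return A `schedule` object: data frame `plant, timepoint, lane, position`
#'   plus `home` (data frame of starting cells) and `n_timepoints`.
#' @examples
#' s <- build_schedule(tactic("next_lane"), grid_layout(3, 24), 14)
#' subset(s$occupancy, plant == 1 & timepoint <= 3)
#' @export
build_schedule <- function(tactic, layout, n_timepoints = 14) {
  stopifnot(inherits(tactic, "tactic"), n_timepoints >= 1)
  np <- layout$n_positions
  if (tactic$name == "half_lane" && np %% 2 != 0)
    stop("half_lane requires an even number of positions")
  home <- expand.grid(position = seq_len(np), lane = tactic$home_lanes)
  home <- home[, c("lane", "position")]
  if (nrow(home) != 3 * np)
    stop("plant count incompatible with a 3-lane by ", np, "-position start")
  home$plant <- seq_len(nrow(home))

  occ_one <- function(lane0, pos0, t) {
    k <- t - 1L # moves performed so far
    switch(tactic$name,
      bench = ,
      same_lane = c(lane0, pos0),
      half_lane = {
        half <- np %/% 2L
        nslots <- 2L * length(tactic$cycle_lanes)
        slot0 <- 2L * (lane0 - min(tactic$cycle_lanes)) + as.integer(pos0 > half)
        slot <- (slot0 + k) %% nslots
        off <- ((pos0 - 1L) %% half) + 1L
        c(min(tactic$cycle_lanes) + slot %/% 2L, off + half * (slot %% 2L))
      },
      next_lane = {
        nl <- length(tactic$cycle_lanes)
        lane <- min(tactic$cycle_lanes) + ((lane0 - min(tactic$cycle_lanes) + k) %% nl)
        c(lane, pos0)
      })
  }

  occ <- expand.grid(timepoint = seq_len(n_timepoints), plant = home$plant)
  occ <- occ[, c("plant", "timepoint")]
  lp <- t(mapply(function(p, tp) occ_one(home$lane[p], home$position[p], tp),
                 occ$plant, occ$timepoint))
  occ$lane <- as.integer(lp[, 1])
  occ$position <- as.integer(lp[, 2])

  # occupancy must be injective at every time point
  for (tp in seq_len(n_timepoints)) {
    cells <- occ[occ$timepoint == tp, c("lane", "position")]
    if (anyDuplicated(cells))
      stop("internal error: occupancy not injective at time point ", tp)
  }
  structure(list(occupancy = occ, home = home, tactic = tactic,
                 n_timepoints = as.integer(n_timepoints), layout = layout),
            class = "schedule")
}

#' Exposure accounting for a schedule
#'
#' Counts the number of time points each plant spends in each part of a
#' partition of the grid: individual cells, lanes, or the west/east halves.
#' Row sums always equal the number of time points.
#'
#' @param schedule A [build_schedule()] result.
#' @param partition One of `"cell"`, `"lane"`, `"half"`.
#' @return A plants-by-parts integer matrix of counts.
#' @export
exposure_matrix <- function(schedule, partition = c("cell", "lane", "half")) {
  partition <- match.arg(partition)
  occ <- schedule$occupancy
  half <- schedule$layout$n_positions %/% 2
  part <- switch(partition,
                 cell = paste0("L", occ$lane, "P", occ$position),
                 lane = paste0("L", occ$lane),
                 half = ifelse(occ$position <= half, "west", "east"))
  tab <- table(factor(occ$plant, levels = schedule$home$plant), part)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(plant = rownames(tab), part = colnames(tab)))
  stopifnot(all(rowSums(m) == schedule$n_timepoints))
  m
}

#' Simulate plant growth along a tactic schedule
#'
#' Multiplicative growth on the log scale: over each of the
#' `n_timepoints - 1` intervals between imagings, a plant's log-area increases
#' by `rate` times the relative microclimate multiplier of the cell it
#' occupies during that interval (the cell at the interval's starting time
#' point), plus optional Gaussian log-noise. The multiplier of a cell is its
#' field expectation divided by the mean expectation over the field, so a
#' flat field gives uniform growth `rate` per interval.
#'
#' @param schedule A [build_schedule()] result.
#' @param field A `field_surface` covering every (lane, position) the schedule
#'   visits.
#' @param growth List with `rate` (mean log-growth per interval, >= 0),
#'   `initial` (starting area, default 1), `noise_sd` (sd of log-noise per
#'   interval, default 0).
#' @param seed Integer seed.
#' @return List with `trajectory` (data frame plant, timepoint, value) and
#'   `final`, the day-final values as a `uniformity_data` object on the
#'   plants' home grid.
#' @export
simulate_tactic_response <- function(schedule, field,
                                     growth = list(rate = 0.3, initial = 1,
                                                   noise_sd = 0),
                                     seed = 1L) {
  rate <- growth$rate
  if (is.null(rate) || rate < 0) stop("growth rate must be nonnegative")
  initial <- if (is.null(growth$initial)) 1 else growth$initial
  noise_sd <- if (is.null(growth$noise_sd)) 0 else growth$noise_sd

  fcells <- field$layout$cells
  key <- paste(fcells$lane, fcells$position)
  mult <- field$expectation / mean(field$expectation)
  occ <- schedule$occupancy
  idx <- match(paste(occ$lane, occ$position), key)
  if (anyNA(idx)) stop("field does not cover every cell the schedule visits")
  occ$mult <- mult[idx]

  Tn <- schedule$n_timepoints
  plants <- schedule$home$plant
  set.seed(as.integer(seed))
  noise <- matrix(if (noise_sd > 0)
    stats::rnorm(length(plants) * max(Tn - 1, 0), 0, noise_sd)
    else 0, nrow = length(plants))

  traj <- expand.grid(timepoint = seq_len(Tn), plant = plants)[, c("plant", "timepoint")]
  logv <- numeric(nrow(traj))
  for (i in seq_along(plants)) {
    p <- plants[i]
    m <- occ$mult[occ$plant == p][seq_len(Tn)]
    lv <- numeric(Tn)
    lv[1] <- log(initial)
    if (Tn > 1)
      for (tp in 2:Tn)
        lv[tp] <- lv[tp - 1] + rate * m[tp - 1] +
          (if (noise_sd > 0) noise[i, tp - 1] else 0)
    logv[traj$plant == p] <- lv
  }
  traj$value <- exp(logv)

  final <- traj$value[traj$timepoint == Tn]
  home <- schedule$home
  lay <- grid_layout(3, schedule$layout$n_positions)
  dat <- lay$cells
  dat$value <- final[order(home$lane, home$position)]
  fin <- structure(list(layout = lay, data = dat,
                        metadata = list(tactic = schedule$tactic$name,
                                        seed = as.integer(seed),
                                        growth = growth)),
                   class = "uniformity_data")
  list(trajectory = traj, final = fin)
}

#' Export a schedule as CSV (plant, timepoint, lane, position)
#' @param schedule A [build_schedule()] result.
#' @param path File path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$occupancy, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
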