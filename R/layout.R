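#' Grid layout of a Smarthouse zone
#'
#' Describes the cart grid of (part of) a conveyor greenhouse: `n_lanes` lanes
#' running south (lane 1) to north, each holding `n_positions` cart positions
#' running west (position 1) to east. Lanes are partitioned into contiguous
#' zones, and positions are split into a western and an eastern side at
#' `side_split`.
#'
#' @param n_lanes Number of lanes (rows), numbered 1..n_lanes south to north.
#' @param n_positions Number of cart positions per lane, numbered 1..n_positions
#'   west to east.
#' @param zone_bounds List of integer vectors, each a contiguous range of lane
#'   indices; the ranges must be disjoint and cover 1..n_lanes in order.
#'   Default: a single zone spanning all lanes.
#' @param side_split Position index at and below which a cart is on the western
#'   side. Defaults to `n_positions / 2` (requires an even `n_positions` unless
#'   supplied explicitly).
#'
#' @return An object of class `grid_layout` with fields `n_lanes`,
#'   `n_positions`, `zone_bounds`, `side_split`, and `cells`, a data frame with
#'   one row per cart holding `lane`, `position`, `zone`, `side`.
#' @examples
#' lay <- grid_layout(3, 24)
#' nrow(lay$cells) # 72
#' @export
grid_layout <- function(n_lanes = 3, n_positions = 24,
                        zone_bounds = list(seq_len(n_lanes)),
                        side_split = NULL) {
  stopifnot(n_lanes >= 1, n_positions >= 1)
  n_lanes <- as.integer(n_lanes)
  n_positions <- as.integer(n_positions)
  covered <- as.integer(sort(unname(unlist(zone_bounds))))
  if (!identical(covered, seq_len(n_lanes)))
    stop("zone_bounds must be disjoint contiguous ranges covering 1..n_lanes")
  for (zb in zone_bounds)
    if (!identical(as.integer(zb), seq(min(zb), max(zb))))
      stop("each zone must be a contiguous lane range")
  if (is.null(side_split)) {
    if (n_positions %% 2 != 0)
      stop("side_split must be given explicitly when n_positions is odd")
    side_split <- n_positions %/% 2
  }
  side_split <- as.integer(side_split)
  stopifnot(side_split >= 1, side_split < n_positions)

  cells <- expand.grid(position = seq_len(n_positions), lane = seq_len(n_lanes))
  cells <- cells[, c("lane", "position")]
  zone_of_lane <- integer(n_lanes)
  for (z in seq_along(zone_bounds)) zone_of_lane[zone_bounds[[z]]] <- z
  cells$zone <- zone_of_lane[cells$lane]
  cells$side <- ifelse(cells$position <= side_split, "west", "east")
  rownames(cells) <- NULL

  structure(list(n_lanes = n_lanes, n_positions = n_positions,
                 zone_bounds = lapply(zone_bounds, as.integer),
                 side_split = side_split, cells = cells),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("grid_layout: %d lanes x %d positions (%d carts), %d zone(s)\n",
              x$n_lanes, x$n_positions, x$n_lanes * x$n_positions,
              length(x$zone_bounds)))
  invisible(x)
}

n_cells <- function(layout) layout$n_lanes * layout$n_positions

#' Centered linear position scores
#'
#' Scores `position - mean(position)` used for linear west-east trend terms and
#' for (nearly) trend-free design construction. When `blocks` is supplied,
#' scores are centered within each block.
#'
#' @param layout A [grid_layout()].
#' @param blocks Optional block factor (one level per cell, in `layout$cells`
#'   order); centering is then per block.
#' @return Numeric vector of scores, one per cell in `layout$cells` order.
#' @export
position_scores <- function(layout, blocks = NULL) {
  pos <- layout$cells$position
  if (is.null(blocks)) return(pos - mean(pos))
  stopifnot(length(blocks) == length(pos))
  stats::ave(pos, blocks, FUN = function(p) p - mean(p))
}

#' Microclimate field parameters
#'
#' Parameters of the expected response surface and noise model for a
#' Smarthouse grid. The response scale is total projected shoot area in
#' thousands of pixels, the primary trait of conveyor phenotyping platforms.
#'
#' @param zone_mean Expected response at the grid centre, per zone (recycled
#'   across zones). Default 71.62 (a typical day-51 wheat total area).
#' @param zone_sd Residual plant-to-plant standard deviation per zone
#'   (recycled). Default 20.2, i.e. a plant-to-plant CV near 28%.
#' @param pos_slope Linear west-east trend: change in expected response per
#'   position step, applied to centered position scores. Default 0.5.
#' @param lane_effects Additive effect per lane (length `n_lanes` or scalar 0);
#'   encodes a south-north trend. Default 0 (lanes within a zone of three are
#'   typically homogeneous).
#' @param shaded_lanes Integer vector of lane indices shaded (e.g. by imaging
#'   equipment at the northern end); default none.
#' @param shade_penalty Multiplicative factor in (0, 1] applied to the expected
#'   response of shaded lanes. Default 0.75.
#' @param ar1_rho First-order autoregressive correlation of the noise along
#'   positions within a lane, |rho| < 1. Default 0 (independent noise).
#' @param block_sd Standard deviation of optional iid random block effects
#'   (used with a blocking arrangement passed to [simulate_uniformity()]);
#'   default 0.
#' @param seed Integer seed recorded with the parameters and used as the
#'   default by [simulate_uniformity()].
#'
#' @return An object of class `field_params`.
#' @export
field_params <- function(zone_mean = 71.62, zone_sd = 20.2, pos_slope = 0.5,
                         lane_effects = 0, shaded_lanes = integer(0),
                         shade_penalty = 0.75, ar1_rho = 0, block_sd = 0,
                         seed = 1L) {
  stopifnot(all(zone_sd >= 0), shade_penalty > 0, shade_penalty <= 1,
            abs(ar1_rho) < 1, block_sd >= 0)
  structure(list(zone_mean = zone_mean, zone_sd = zone_sd,
                 pos_slope = pos_slope, lane_effects = lane_effects,
                 shaded_lanes = as.integer(shaded_lanes),
                 shade_penalty = shade_penalty, ar1_rho = ar1_rho,
                 block_sd = block_sd, seed = as.integer(seed)),
            class = "field_params")
}

check_params_layout <- function(params, layout) {
  if (length(params$shaded_lanes) &&
      (min(params$shaded_lanes) < 1 || max(params$shaded_lanes) > layout$n_lanes))
    stop("shaded lane index outside 1..n_lanes")
  nz <- length(layout$zone_bounds)
  if (!(length(params$zone_mean) %in% c(1L, nz)))
    stop("zone_mean must have length 1 or one value per zone")
  if (!(length(params$zone_sd) %in% c(1L, nz)))
    stop("zone_sd must have length 1 or one value per zone")
  le <- params$lane_effects
  if (!(length(le) %in% c(1L, layout$n_lanes)))
    stop("lane_effects must be scalar or one value per lane")
  invisible(TRUE)
}
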