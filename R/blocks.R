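#' Rectangular blocking arrangements
#'
#' A blocking arrangement tiles the grid with equal rectangular blocks of
#' `block_lanes` lanes by `block_positions` positions. Three series are used
#' when screening arrangements on uniformity data: blocks within a single
#' lane, blocks spanning all lanes of a zone, and blocks with rows and
#' columns (lanes and positions) nested inside them.
#'
#' @param block_lanes Lanes per block; must divide the layout's lane count.
#' @param block_positions Positions per block; must divide the layout's
#'   position count.
#' @param rows_columns Logical: also carry row (lane) and column (position)
#'   factors nested within blocks.
#' @return A `blocking_arrangement` object.
#' @export
blocking_arrangement <- function(block_lanes, block_positions,
                                 rows_columns = FALSE) {
  stopifnot(block_lanes >= 1, block_positions >= 1)
  structure(list(block_lanes = as.integer(block_lanes),
                 block_positions = as.integer(block_positions),
                 rows_columns = isTRUE(rows_columns)),
            class = "blocking_arrangement")
}

#' Block (and row/column) factors for a layout
#'
#' Partitions the cells of `layout` into the equal rectangular blocks of an
#' arrangement. For a rows-and-columns arrangement, row and column factors
#' nested in blocks are returned as well.
#'
#' @param layout A [grid_layout()].
#' @param arrangement A [blocking_arrangement()], or two integers
#'   `c(block_lanes, block_positions)`.
#' @return Data frame aligned with `layout$cells`: `block` (factor) and, for
#'   rows-and-columns arrangements, `row` and `col` factors nested in blocks.
#' @examples
#' b <- make_blocks(grid_layout(3, 24), c(3, 1))
#' nlevels(b$block) # 24 blocks of 3
#' @export
make_blocks <- function(layout, arrangement) {
  if (!inherits(arrangement, "blocking_arrangement"))
    arrangement <- blocking_arrangement(arrangement[1], arrangement[2])
  bl <- arrangement$block_lanes
  bp <- arrangement$block_positions
  if (layout$n_lanes %% bl != 0)
    stop("block_lanes (", bl, ") does not divide n_lanes (", layout$n_lanes, ")")
  if (layout$n_positions %% bp != 0)
    stop("block_positions (", bp, ") does not divide n_positions (",
         layout$n_positions, ")")
  cells <- layout$cells
  lane_band <- (cells$lane - 1L) %/% bl
  pos_band <- (cells$position - 1L) %/% bp
  block <- factor(paste0("B", lane_band + 1L, ".", pos_band + 1L))
  out <- data.frame(block = block)
  if (arrangement$rows_columns) {
    out$row <- factor(paste0(block, ":r", ((cells$lane - 1L) %% bl) + 1L))
    out$col <- factor(paste0(block, ":c", ((cells$position - 1L) %% bp) + 1L))
  }
  out
}
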