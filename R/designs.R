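#' @title Experimental designs on a Smarthouse grid
#' @description Generators for the design menu used to compare design and
#'   analysis strategies: completely randomized, randomized complete block,
#'   resolved incomplete block, resolved row-column, and (nearly) trend-free
#'   designs. Optimized designs use a seeded interchange algorithm; all
#'   generators record their provenance so [randomize_design()] can apply the
#'   restricted randomization appropriate to each design class.
#' @name designs
NULL

new_design <- function(layout, cells, v, r, provenance) {
  structure(list(layout = layout, cells = cells, v = as.integer(v),
                 r = as.integer(r), provenance = provenance),
            class = "design")
}

#' @export
print.design <- function(x, ...) {
  cat(sprintf("design (%s): v=%d, r=%d on %d lanes x %d positions",
              x$provenance$type, x$v, x$r, x$layout$n_lanes,
              x$layout$n_positions))
  if (!is.null(x$provenance$Q)) cat(sprintf(", Q=%.4g", x$provenance$Q))
  cat("\n")
  invisible(x)
}

# replicate factor from a tiling shape c(lanes, positions)
replicate_factor <- function(layout, rep_shape) {
  make_blocks(layout, blocking_arrangement(rep_shape[1], rep_shape[2]))$block
}

#' Validate the structural invariants of a design
#'
#' Checks equal replication, resolution (each replicate complete) when a
#' replicate factor is present, completeness of RCBD blocks, and the
#' no-repeat-in-block rule for incomplete blocks.
#'
#' @param design A `design` object.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_design <- function(design) {
  cells <- design$cells
  tab <- table(cells$treatment)
  if (length(tab) != design$v || any(tab != design$r))
    stop("treatments are not equally replicated r times")
  if (!is.null(cells$replicate)) {
    for (rp in levels(factor(cells$replicate))) {
      tr <- cells$treatment[cells$replicate == rp]
      if (length(unique(tr)) != design$v || length(tr) != design$v)
        stop("replicate ", rp, " does not contain each treatment exactly once")
    }
  }
  if (!is.null(cells$block)) {
    for (b in levels(factor(cells$block))) {
      tr <- cells$treatment[cells$block == b]
      if (anyDuplicated(tr))
        stop("treatment repeated within block ", b)
    }
  }
  invisible(TRUE)
}

#' Completely randomized design
#'
#' @param v Number of treatments.
#' @param r Replication per treatment; `v * r` must equal the cell count.
#' @param layout A [grid_layout()].
#' @param seed Integer seed.
#' @return A `design` object.
#' @export
make_crd <- function(v, r, layout, seed = 1L) {
  n <- n_cells(layout)
  if (v * r != n) stop("v * r (", v * r, ") must equal the cell count (", n, ")")
  set.seed(as.integer(seed))
  cells <- layout$cells
  cells$treatment <- sample(rep(seq_len(v), r))
  new_design(layout, cells, v, r, list(type = "crd", seed = as.integer(seed)))
}

#' Randomized complete block design
#'
#' Each replicate block (a rectangular tile of shape `rep_shape`) receives an
#' independent random permutation of all `v` treatments.
#'
#' @param v Number of treatments; must equal the cell count of a replicate.
#' @param layout A [grid_layout()].
#' @param rep_shape `c(lanes, positions)` of a replicate block; e.g. `c(3, 12)`
#'   for two replicates of 3 lanes by 12 positions on a 3 x 24 grid.
#' @param seed Integer seed.
#' @return A `design` object with `replicate` (= block) annotations.
#' @export
make_rcbd <- function(v, layout, rep_shape = c(3, 12), seed = 1L) {
  if (prod(rep_shape) != v)
    stop("replicate shape holds ", prod(rep_shape), " cells but v = ", v)
  rep_f <- replicate_factor(layout, rep_shape)
  r <- n_cells(layout) / v
  if (r != round(r)) stop("layout not divisible into complete replicates")
  set.seed(as.integer(seed))
  cells <- layout$cells
  cells$replicate <- rep_f
  cells$block <- rep_f
  cells$treatment <- NA_integer_
  for (b in levels(rep_f))
    cells$treatment[rep_f == b] <- sample(seq_len(v))
  d <- new_design(layout, cells, v, as.integer(r),
                  list(type = "rcbd", seed = as.integer(seed),
                       rep_shape = rep_shape))
  validate_design(d)
  d
}

# cyclic no-repeat initial assignment within replicates: blocks get
# consecutive treatment labels, so a block of size k <= v is repeat-free
init_resolved <- function(v, rep_f, block_f) {
  treatment <- integer(length(rep_f))
  for (rp in levels(rep_f)) {
    idx <- which(rep_f == rp)
    idx <- idx[order(block_f[idx])]
    treatment[idx] <- rep_len(seq_len(v), length(idx))
  }
  treatment
}

ibd_objective <- function(treatment, block_f, v) {
  b <- nlevels(block_f)
  N <- matrix(tabulate((treatment - 1L) * b + as.integer(block_f), nbins = b * v),
              nrow = b)
  C <- crossprod(N)
  repeats <- sum(N * (N - 1L)) / 2
  lam <- C[upper.tri(C)]
  sum(lam^2) + 1e6 * repeats
}

#' Resolved incomplete block design via interchange optimization
#'
#' Replicates (tiles of `rep_shape`) each contain a complete set of the `v`
#' treatments; incomplete blocks of shape `block_shape` nest inside
#' replicates. Starting from a cyclic repeat-free layout, a seeded interchange
#' optimizer swaps treatments between blocks within a replicate, accepting the
#' first strictly improving swap of each random scan, to minimize the spread
#' of pairwise treatment concurrences across blocks (sum of squared
#' concurrence counts; within-block repeats carry a prohibitive penalty).
#'
#' @param v Number of treatments.
#' @param r Replicates (must equal cell count / v).
#' @param layout A [grid_layout()].
#' @param block_shape `c(lanes, positions)` of an incomplete block; must nest
#'   in `rep_shape` and hold fewer than `v` cells.
#' @param rep_shape Replicate tile shape; default `c(n_lanes, n_positions / r)`.
#' @param seed Integer seed.
#' @param budget Number of swap proposals (default 20000).
#' @return A `design` with `replicate` and `block` annotations; provenance
#'   records the achieved objective.
#' @export
make_resolved_ibd <- function(v, r, layout, block_shape,
                              rep_shape = c(layout$n_lanes,
                                            layout$n_positions / r),
                              seed = 1L, budget = 20000) {
  if (v * r != n_cells(layout)) stop("v * r must equal the cell count")
  if (prod(rep_shape) != v) stop("replicate shape must hold exactly v cells")
  k <- prod(block_shape)
  if (k >= v) stop("block size (", k, ") must be smaller than v (", v, ")")
  if (rep_shape[1] %% block_shape[1] != 0 || rep_shape[2] %% block_shape[2] != 0)
    stop("blocks must nest within replicates")

  rep_f <- replicate_factor(layout, rep_shape)
  block_f <- make_blocks(layout, blocking_arrangement(block_shape[1],
                                                      block_shape[2]))$block
  set.seed(as.integer(seed))
  treatment <- init_resolved(v, rep_f, block_f)
  # diversify: random treatment relabelling
  relab <- sample(seq_len(v))
  treatment <- relab[treatment]

  obj <- ibd_objective(treatment, block_f, v)
  rep_idx <- split(seq_along(treatment), rep_f)
  for (prop in seq_len(budget)) {
    rp <- rep_idx[[sample.int(length(rep_idx), 1)]]
    ij <- sample(rp, 2)
    if (treatment[ij[1]] == treatment[ij[2]] ||
        block_f[ij[1]] == block_f[ij[2]]) next
    cand <- treatment
    cand[ij] <- cand[rev(ij)]
    cobj <- ibd_objective(cand, block_f, v)
    if (cobj < obj - 1e-9) {
      treatment <- cand
      obj <- cobj
    }
  }
  cells <- layout$cells
  cells$replicate <- rep_f
  cells$block <- block_f
  cells$treatment <- treatment
  d <- new_design(layout, cells, v, r,
                  list(type = "resolved_ibd", seed = as.integer(seed),
                       rep_shape = rep_shape, block_shape = block_shape,
                       objective = obj - 0, budget = budget))
  validate_design(d)
  d
}

rc_objective <- function(treatment, lane, colidx, v) {
  Nl <- matrix(tabulate((treatment - 1L) * max(lane) + lane,
                        nbins = max(lane) * v), nrow = max(lane))
  Nc <- matrix(tabulate((treatment - 1L) * max(colidx) + colidx,
                        nbins = max(colidx) * v), nrow = max(colidx))
  sum(Nl^2) + sum(Nc^2)
}

#' Resolved row-column design via interchange optimization
#'
#' Each replicate (tile of `rep_shape`, rows x columns = v) contains every
#' treatment once; a seeded interchange optimizer swaps treatments within
#' replicates to balance each treatment's occurrences across physical rows
#' (lanes) and across within-replicate column indices, minimizing the sum of
#' squared treatment-by-row and treatment-by-column counts.
#'
#' @inheritParams make_resolved_ibd
#' @param rep_shape `c(rows, columns)` of a replicate with
#'   `rows * columns = v`.
#' @return A `design` with `replicate`, `row`, `col` annotations.
#' @export
make_row_column <- function(v, layout, rep_shape = c(3, 12), seed = 1L,
                            budget = 20000) {
  if (prod(rep_shape) != v) stop("rows x columns of a replicate must equal v")
  r <- n_cells(layout) / v
  if (r != round(r)) stop("layout not divisible into complete replicates")
  rep_f <- replicate_factor(layout, rep_shape)
  cells <- layout$cells
  lane <- cells$lane
  colidx <- ((cells$position - 1L) %% rep_shape[2]) + 1L

  set.seed(as.integer(seed))
  treatment <- integer(nrow(cells))
  for (rp in levels(rep_f))
    treatment[rep_f == rp] <- sample(seq_len(v))

  obj <- rc_objective(treatment, lane, colidx, v)
  rep_idx <- split(seq_along(treatment), rep_f)
  for (prop in seq_len(budget)) {
    rp <- rep_idx[[sample.int(length(rep_idx), 1)]]
    ij <- sample(rp, 2)
    if (treatment[ij[1]] == treatment[ij[2]]) next
    cand <- treatment
    cand[ij] <- cand[rev(ij)]
    cobj <- rc_objective(cand, lane, colidx, v)
    if (cobj < obj - 1e-9) {
      treatment <- cand
      obj <- cobj
    }
  }
  cells$replicate <- rep_f
  cells$row <- factor(paste0(rep_f, ":r", ((lane - 1L) %% rep_shape[1]) + 1L))
  cells$col <- factor(paste0(rep_f, ":c", colidx))
  cells$treatment <- treatment
  d <- new_design(layout, cells, v, as.integer(r),
                  list(type = "row_column", seed = as.integer(seed),
                       rep_shape = rep_shape, objective = obj, budget = budget))
  validate_design(d)
  d
}

trend_Q <- function(treatment, scores, v) {
  S <- tapply(scores, factor(treatment, levels = seq_len(v)), sum, default = 0)
  sum(S^2)
}

#' (Nearly) trend-free design via interchange optimization
#'
#' Arranges treatments to be orthogonal (trend-free, Q = 0) or as close as
#' possible to orthogonal (nearly trend-free) to the linear position trend.
#' The criterion is `Q = sum over treatments of (sum of centered position
#' scores of that treatment's cells)^2`; scores are centered per block when a
#' block structure is present, else over the whole layout. A seeded
#' interchange optimizer accepts the first strictly improving swap in a random
#' scan (swaps stay within replicates when the design is resolved) and stops
#' early if Q reaches 0.
#'
#' @param v Number of treatments.
#' @param r Replication; `v * r` must equal the cell count.
#' @param layout A [grid_layout()].
#' @param rep_shape Optional replicate tile shape for a resolved design
#'   (`NULL` for an unresolved assignment).
#' @param block_shape Optional incomplete/complete block tile shape; blocks
#'   imply per-block centered scores and are recorded for the analysis model.
#' @param seed Integer seed.
#' @param budget Number of swap proposals (default 20000).
#' @return A `design`; `provenance$Q` holds the achieved criterion and
#'   `provenance$trend_free` is `TRUE` when Q = 0.
#' @export
make_trend_free <- function(v, r, layout, rep_shape = NULL, block_shape = NULL,
                            seed = 1L, budget = 20000) {
  if (v * r != n_cells(layout)) stop("v * r must equal the cell count")
  cells <- layout$cells
  rep_f <- if (!is.null(rep_shape)) replicate_factor(layout, rep_shape) else NULL
  block_f <- if (!is.null(block_shape))
    make_blocks(layout, blocking_arrangement(block_shape[1], block_shape[2]))$block
  else NULL
  scores <- position_scores(layout, blocks = block_f)

  set.seed(as.integer(seed))
  if (!is.null(rep_f)) {
    if (prod(rep_shape) != v) stop("replicate shape must hold exactly v cells")
    treatment <- init_resolved(v, rep_f, factor(cells$position))
    relab <- sample(seq_len(v))
    treatment <- relab[treatment]
    swap_pool <- split(seq_along(treatment), rep_f)
  } else {
    treatment <- sample(rep(seq_len(v), r))
    swap_pool <- list(seq_along(treatment))
  }

  S <- as.numeric(tapply(scores, factor(treatment, levels = seq_len(v)),
                         sum, default = 0))
  Q <- sum(S^2)
  for (prop in seq_len(budget)) {
    if (Q < 1e-12) break
    rp <- swap_pool[[sample.int(length(swap_pool), 1)]]
    ij <- sample(rp, 2)
    a <- treatment[ij[1]]; b <- treatment[ij[2]]
    if (a == b) next
    ds <- scores[ij[2]] - scores[ij[1]]
    Sa <- S[a] + ds; Sb <- S[b] - ds
    dQ <- (Sa^2 + Sb^2) - (S[a]^2 + S[b]^2)
    if (dQ < -1e-12) {
      treatment[ij] <- c(b, a)
      S[a] <- Sa; S[b] <- Sb
      Q <- Q + dQ
    }
  }
  Q <- max(Q, 0)
  if (!is.null(rep_f)) cells$replicate <- rep_f
  if (!is.null(block_f)) cells$block <- block_f
  cells$treatment <- treatment
  d <- new_design(layout, cells, v, r,
                  list(type = "trend_free", seed = as.integer(seed),
                       rep_shape = rep_shape, block_shape = block_shape,
                       Q = Q, trend_free = (Q < 1e-12), budget = budget))
  validate_design(d)
  d
}

#' Restricted randomization of a design
#'
#' Applies exactly the moves a design's construction permits. CRD and RCBD
#' are fully re-randomized within their structure. Optimized designs
#' (incomplete block, row-column, trend-free) get the restricted moves:
#' reversal of the whole set of positions with probability 1/2, a random
#' permutation of the lanes, and, when incomplete blocks are present, a
#' random permutation of block order within each replicate. Trend-free
#' designs may instead be regenerated (a fresh optimizer run) with
#' `regenerate = TRUE`. All moves preserve the block structure and the trend
#' criterion Q (reversal negates every centered score, permutations shuffle
#' identical score sets).
#'
#' @param design A `design` object.
#' @param seed Integer seed.
#' @param regenerate For trend-free designs: rerun the interchange optimizer
#'   with a fresh seed instead of applying the restricted moves.
#' @param budget Optimizer budget used when regenerating.
#' @return A new `design` object.
#' @export
randomize_design <- function(design, seed = 1L, regenerate = FALSE,
                             budget = design$provenance$budget) {
  prov <- design$provenance
  lay <- design$layout
  if (prov$type == "crd")
    return(make_crd(design$v, design$r, lay, seed = seed))
  if (prov$type == "rcbd")
    return(make_rcbd(design$v, lay, rep_shape = prov$rep_shape, seed = seed))
  if (prov$type == "trend_free" && regenerate)
    return(make_trend_free(design$v, design$r, lay,
                           rep_shape = prov$rep_shape,
                           block_shape = prov$block_shape,
                           seed = seed, budget = budget))

  set.seed(as.integer(seed))
  cells <- design$cells
  M <- lay$n_positions
  # map: new cell (l, p) takes the treatment of source cell (sl, sp)
  src_lane <- seq_len(lay$n_lanes)
  perm_lane <- sample(src_lane)           # new lane l sources from perm_lane[l]
  reverse <- stats::runif(1) < 0.5

  key <- function(l, p) (l - 1L) * M + p
  src <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    l <- cells$lane[i]; p <- cells$position[i]
    sp <- if (reverse) M + 1L - p else p
    src[i] <- key(perm_lane[l], sp)
  }
  ord <- key(cells$lane, cells$position)
  treatment <- cells$treatment[match(src, ord)]

  # permute block order within replicates (congruent blocks only)
  if (!is.null(cells$block) && prov$type != "rcbd") {
    rep_f <- if (!is.null(cells$replicate)) cells$replicate
             else factor(rep("R1", nrow(cells)))
    newt <- treatment
    for (rp in levels(factor(rep_f))) {
      idx <- which(rep_f == rp)
      blks <- levels(droplevels(factor(cells$block[idx])))
      perm <- sample(seq_along(blks))
      for (bi in seq_along(blks)) {
        dest <- idx[cells$block[idx] == blks[bi]]
        from <- idx[cells$block[idx] == blks[perm[bi]]]
        # align cells within congruent blocks by (lane-offset, position-offset)
        dest <- dest[order(cells$lane[dest], cells$position[dest])]
        from <- from[order(cells$lane[from], cells$position[from])]
        newt[dest] <- treatment[from]
      }
    }
    treatment <- newt
  }
  cells$treatment <- treatment
  out <- new_design(lay, cells, design$v, design$r,
                    utils::modifyList(prov, list(randomized_seed = as.integer(seed))))
  validate_design(out)
  out
}

#' Export / import a design as CSV
#'
#' Columns `lane, position, replicate, block, row, column, treatment` (empty
#' strings for absent annotations), plus a companion JSON summary with v, r,
#' type, Q and seed via [write_design_summary()].
#' @param design A `design` object.
#' @param path File path.
#' @export
write_design_csv <- function(design, path) {
  cells <- design$cells
  out <- data.frame(lane = cells$lane, position = cells$position,
                    replicate = if (is.null(cells$replicate)) "" else as.character(cells$replicate),
                    block = if (is.null(cells$block)) "" else as.character(cells$block),
                    row = if (is.null(cells$row)) "" else as.character(cells$row),
                    column = if (is.null(cells$col)) "" else as.character(cells$col),
                    treatment = cells$treatment)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8",
                       colClasses = list(replicate = "character",
                                         block = "character",
                                         row = "character",
                                         column = "character"))
  nl <- max(d$lane); np <- max(d$position)
  lay <- grid_layout(nl, np,
                     side_split = if (np %% 2 == 0) NULL else (np + 1) %/% 2)
  d <- d[order(d$lane, d$position), ]
  cells <- lay$cells
  cells$treatment <- as.integer(d$treatment)
  if (any(nzchar(d$replicate))) cells$replicate <- factor(d$replicate)
  if (any(nzchar(d$block))) cells$block <- factor(d$block)
  if (any(nzchar(d$row))) cells$row <- factor(d$row)
  if (any(nzchar(d$column))) cells$col <- factor(d$column)
  v <- length(unique(cells$treatment))
  new_design(lay, cells, v, nrow(cells) / v, list(type = "imported",
                                                  source = path))
}

#' @rdname write_design_csv
#' @export
write_design_summary <- function(design, path) {
  prov <- design$provenance
  jsonlite::write_json(list(v = design$v, r = design$r, type = prov$type,
                            Q = prov$Q, objective = prov$objective,
                            seed = prov$seed),
                       path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
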