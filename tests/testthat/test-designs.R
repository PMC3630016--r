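lay <- grid_layout(3, 24)

test_that("blocking arrangements tile the grid correctly", {
  expect_equal(nlevels(make_blocks(lay, c(3, 24))$block), 1)
  expect_equal(nlevels(make_blocks(lay, c(1, 12))$block), 6)
  expect_equal(nlevels(make_blocks(lay, c(3, 1))$block), 24)
  b <- make_blocks(lay, blocking_arrangement(3, 4, rows_columns = TRUE))
  expect_equal(nlevels(b$block), 6)
  expect_equal(nlevels(b$row), 18)   # 3 rows in each of 6 blocks
  expect_equal(nlevels(b$col), 24)   # 4 columns in each of 6 blocks
  expect_error(make_blocks(lay, c(2, 12)), "n_lanes")
  expect_error(make_blocks(lay, c(3, 5)), "n_positions")
})

test_that("CRD is a uniform random permutation of the treatment multiset", {
  d <- make_crd(72, 1, lay, seed = 1)
  expect_equal(sort(d$cells$treatment), 1:72)
  d2 <- make_crd(36, 2, lay, seed = 2)
  expect_true(all(table(d2$cells$treatment) == 2))
  expect_error(make_crd(30, 2, lay), "must equal")

  # frequency over the 6 distinct assignments of {1,1,2,2} to 4 cells
  small <- strip_layout(4)
  draws <- vapply(1:2000, function(s)
    paste(make_crd(2, 2, small, seed = s)$cells$treatment, collapse = ""),
    character(1))
  freq <- table(draws) / 2000
  expect_equal(length(freq), 6L)
  expect_true(all(abs(freq - 1 / 6) < 0.03))
})

test_that("RCBD blocks each contain every treatment exactly once", {
  d <- make_rcbd(36, lay, c(3, 12), seed = 3)
  tab <- table(d$cells$block, d$cells$treatment)
  expect_true(all(tab == 1))
  expect_equal(nlevels(d$cells$replicate), 2)
  # v = 1 degenerate case: all cells the same label
  one <- make_rcbd(1, grid_layout(1, 4, side_split = 2), c(1, 1), seed = 1)
  expect_true(all(one$cells$treatment == 1))
  expect_error(make_rcbd(30, lay, c(3, 12)), "v = 30")
})

test_that("resolved IBD attains the brute-force concurrence optimum (v=4)", {
  small <- strip_layout(8)
  d <- make_resolved_ibd(4, 2, small, block_shape = c(1, 2),
                         rep_shape = c(1, 4), seed = 4)
  validate_design(d)
  # brute force over all resolved designs: each replicate is a permutation
  # of 1..4 over its fixed cells, blocks are cell pairs (1,2) and (3,4)
  perms <- function(x) {
    if (length(x) == 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out <- c(out, list(c(x[i], p)))
    out
  }
  p4 <- perms(1:4)
  block_f <- factor(rep(1:4, each = 2))
  best <- Inf
  for (a in p4) for (b in p4) {
    tr <- c(a, b)
    N <- table(block_f, factor(tr, levels = 1:4))
    C <- crossprod(N)
    obj <- sum(C[upper.tri(C)]^2)
    best <- min(best, obj)
  }
  expect_equal(d$provenance$objective, best)
  # at the optimum every treatment pair concurs at most once
  N <- table(d$cells$block, d$cells$treatment)
  C <- crossprod(N); diag(C) <- 0
  expect_true(all(C <= 1))
})

test_that("RIBD3x1 on the full zone has no within-block repeats and near-balanced concurrence", {
  d <- make_resolved_ibd(36, 2, lay, block_shape = c(3, 1), seed = 5)
  validate_design(d)
  expect_equal(nlevels(d$cells$block), 24)
  N <- table(d$cells$block, d$cells$treatment)
  expect_true(all(N <= 1))
  C <- crossprod(N); diag(C) <- 0
  expect_true(all(C <= 1)) # 24 blocks of 3: a pair never concurs twice
  expect_error(make_resolved_ibd(36, 2, lay, block_shape = c(3, 12)),
               "smaller than v")
})

test_that("row-column optimizer reaches enumeration-level balance", {
  # v = 4 in 2 x 2 replicates on a 2 x 4 grid: Latin-square-like balance
  small <- grid_layout(2, 4)
  d <- make_row_column(4, small, rep_shape = c(2, 2), seed = 6)
  validate_design(d)
  perms <- function(x) {
    if (length(x) == 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in perms(x[-i])) out <- c(out, list(c(x[i], p)))
    out
  }
  p4 <- perms(1:4)
  lane <- small$cells$lane
  colidx <- ((small$cells$position - 1) %% 2) + 1
  rep_f <- ifelse(small$cells$position <= 2, 1, 2) # replicate tiles 2x2
  best <- Inf
  for (a in p4) for (b in p4) {
    tr <- integer(8)
    tr[rep_f == 1] <- a
    tr[rep_f == 2] <- b
    obj <- sum(table(tr, lane)^2) + sum(table(tr, colidx)^2)
    best <- min(best, obj)
  }
  expect_equal(d$provenance$objective, best)

  dz <- make_row_column(36, lay, rep_shape = c(3, 12), seed = 7)
  expect_true(all(table(dz$cells$replicate, dz$cells$treatment) == 1))
  expect_true(all(table(dz$cells$treatment, dz$cells$lane) <= 1))
})

test_that("trend-free optimizer reaches Q = 0 where symmetry allows and the
           brute-force optimum on the 90-assignment instance", {
  # v=2, r=2 on 4 positions: A B B A gives Q = 0
  s4 <- strip_layout(4)
  d <- make_trend_free(2, 2, s4, seed = 8)
  expect_equal(d$provenance$Q, 0)
  expect_true(d$provenance$trend_free)

  # v=3, r=2 on 6 positions: brute force over all 6!/(2!2!2!) = 90 assignments
  s6 <- strip_layout(6)
  scores <- position_scores(s6)
  # enumerate multiset permutations of {1,1,2,2,3,3}
  enum <- function(counts, prefix = integer(0)) {
    if (all(counts == 0)) return(list(prefix))
    out <- list()
    for (t in which(counts > 0)) {
      c2 <- counts; c2[t] <- c2[t] - 1
      out <- c(out, enum(c2, c(prefix, t)))
    }
    out
  }
  all_asgn <- enum(c(2, 2, 2))
  expect_equal(length(all_asgn), 90)
  qs <- vapply(all_asgn, q_of, numeric(1), scores = scores)
  d6 <- make_trend_free(3, 2, s6, seed = 9)
  expect_equal(d6$provenance$Q, min(qs))

  # r = 1: Q is forced to the sum of squared scores; no swap can improve it
  d1 <- make_trend_free(6, 1, s6, seed = 10)
  expect_equal(d1$provenance$Q, sum(scores^2))
})

test_that("zone-scale trend-free designs reach Q = 0 with and without blocks", {
  d <- make_trend_free(36, 2, lay, rep_shape = c(3, 12), seed = 11)
  validate_design(d)
  expect_equal(d$provenance$Q, 0)
  db <- make_trend_free(36, 2, lay, rep_shape = c(3, 12),
                        block_shape = c(3, 12), seed = 12)
  scores_b <- position_scores(lay, blocks = db$cells$block)
  expect_equal(q_of(db$cells$treatment, scores_b), db$provenance$Q)
  expect_equal(db$provenance$Q, 0)
})

test_that("restricted randomization preserves structure, Q, and determinism", {
  d <- make_trend_free(36, 2, lay, rep_shape = c(3, 12), seed = 13)
  scores <- position_scores(lay)
  r1 <- randomize_design(d, seed = 21)
  r2 <- randomize_design(d, seed = 21)
  expect_identical(r1$cells$treatment, r2$cells$treatment)
  expect_false(identical(r1$cells$treatment,
                         randomize_design(d, seed = 22)$cells$treatment))
  validate_design(r1)
  expect_equal(q_of(r1$cells$treatment, scores), 0)

  # block-order permutation keeps incomplete-block structure intact
  dib <- make_resolved_ibd(36, 2, lay, block_shape = c(1, 4), seed = 14)
  rib <- randomize_design(dib, seed = 23)
  validate_design(rib)
  # the multiset of block contents is preserved within each replicate
  content <- function(des) {
    sapply(split(des$cells$treatment, list(des$cells$replicate,
                                           des$cells$block), drop = TRUE),
           function(x) paste(sort(x), collapse = "-"))
  }
  expect_setequal(unname(content(rib)), unname(content(dib)))

  # trend-free regeneration yields a fresh design, still trend-free
  rg <- randomize_design(d, seed = 31, regenerate = TRUE)
  expect_equal(rg$provenance$Q, 0)
  expect_false(identical(rg$cells$treatment, d$cells$treatment))
})

test_that("position reversal maps position p to M + 1 - p for every cell", {
  # with lanes of 1 the only restricted moves are reversal (p = 1/2) and the
  # trivial lane permutation, so across seeds both outcomes must appear
  s6 <- strip_layout(6)
  d <- make_trend_free(3, 2, s6, seed = 15)
  seen <- character(0)
  for (s in 1:20) {
    r <- randomize_design(d, seed = s)
    if (identical(r$cells$treatment, d$cells$treatment))
      seen <- union(seen, "identity")
    if (identical(r$cells$treatment, rev(d$cells$treatment)))
      seen <- union(seen, "reversal")
  }
  expect_setequal(seen, c("identity", "reversal"))
})

test_that("design CSV and summary JSON round-trip", {
  d <- make_resolved_ibd(36, 2, lay, block_shape = c(3, 1), seed = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  d2 <- read_design_csv(path)
  expect_equal(d2$cells$treatment, d$cells$treatment)
  expect_equal(as.character(d2$cells$block), as.character(d$cells$block))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_design_summary(d, jpath)
  j <- jsonlite::read_json(jpath)
  expect_equal(j$v, 36)
  expect_equal(j$type, "resolved_ibd")
})
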