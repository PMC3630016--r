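# fixtures built in code: tiny grids with hand-settable values

# a 1 x n strip layout (side split after the first position for odd n)
strip_layout <- function(n) {
  grid_layout(1, n, side_split = if (n %% 2 == 0) NULL else 1)
}

# uniformity data with exactly the given values on a layout
uniformity_with_values <- function(layout, values) {
  stopifnot(length(values) == nrow(layout$cells))
  dat <- layout$cells
  dat$value <- values
  structure(list(layout = layout, data = dat, metadata = list()),
            class = "uniformity_data")
}

# the classic 2-blocks-of-3 toy: values {1,2,3} and {4,5,6} on a 1 x 6 strip;
# hand ANOVA: within-block MS 1.0, overall variance 3.5, block component 25/6
toy_two_blocks <- function() {
  uniformity_with_values(strip_layout(6), c(1, 2, 3, 4, 5, 6))
}

default_zone <- function(seed = 1) {
  simulate_uniformity(make_field(grid_layout(3, 24), field_params()),
                      seed = seed)
}

# trend criterion of an assignment, recomputed independently of the package
q_of <- function(treatment, scores) {
  sum(tapply(scores, factor(treatment), sum)^2)
}
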