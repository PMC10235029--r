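# small fixtures shared across test files; everything is generated in code

# piecewise two-level tissue used in recovery tests
two_level_truth <- function(shape = c(8, 8)) {
  make_ground_truth(shape, "piecewise",
                    levels = list(delta_b = c(1, 100),
                                  delta_alpha = c(0.1, 0.5)))
}

# interior axial rows of a piecewise map, excluding the jump row where a
# finite difference legitimately averages the two levels
interior_rows <- function(n_axial) {
  setdiff(seq_len(n_axial - 1), ceiling(n_axial / 2))
}

rmse <- function(est, tru) sqrt(mean((est - tru)^2))

# small homogeneous speckle frame (matrix) for envelope statistics
speckle_frame <- function(n_lines = 8, axial_mm = 20, seed = 5) {
  gt <- make_ground_truth(c(1, 1), "constant", axial_spacing_mm = axial_mm)
  simulate_rf(gt, n_lines = n_lines, seed = seed)
}
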