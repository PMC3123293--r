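# Small deterministic worlds used across the test files.

cfg_small <- function(width = 8, height = 8, n_initial_states = 6, seed = 1, ...) {
  war_config(width = width, height = height, n_initial_states = n_initial_states,
             seed = seed, ...)
}

# two states splitting a 2x2 grid into left/right columns
two_state_world <- function(res = c(20, 20), alpha = c(1, 1), w = 0.5, ...) {
  cfg <- war_config(width = 2, height = 2, n_initial_states = 2, w = w, ...)
  owner <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  as_war_world(owner, data.frame(
    id = 1:2, alpha = alpha, resources = res,
    capital_row = c(1, 1), capital_col = c(1, 2)), cfg)
}

# 1x3 strip: state 1 (winner) owns column 1, state 2 (loser) owns columns 2-3
strip_world <- function(loser_capital_col, alpha = c(1, 2)) {
  cfg <- war_config(width = 3, height = 1, n_initial_states = 2)
  owner <- matrix(c(1L, 2L, 2L), 1, 3)
  as_war_world(owner, data.frame(
    id = 1:2, alpha = alpha, resources = c(10, 20),
    capital_row = c(1, 1), capital_col = c(1, loser_capital_col)), cfg)
}

# U-shaped loser (state 1) whose bend hosts its capital; the winner (state 2)
# touches the loser only at the bend. Fillers 3-5 pad the rest of the grid.
u_world <- function() {
  cfg <- war_config(width = 3, height = 5, n_initial_states = 5)
  owner <- matrix(0L, 5, 3)
  owner[1:3, 1] <- 1L; owner[1:3, 3] <- 1L; owner[4, ] <- 1L
  owner[1:3, 2] <- 3L
  owner[5, ] <- c(4L, 2L, 5L)
  as_war_world(owner, data.frame(
    id = 1:5, alpha = c(2.5, 1, 1, 1, 1),
    resources = c(90, 10, 30, 10, 10),
    capital_row = c(4, 5, 2, 5, 5),
    capital_col = c(2, 2, 2, 1, 3)), cfg)
}

# 1x3 line: state 2 in the middle flanked by states 1 and 3, with chosen
# resources and confidence for the middle state
line3_world <- function(res = c(5, 10, 20), alpha_mid = 1, w = 0.5, k = 5,
                        csf_form = "log_odds") {
  cfg <- war_config(width = 3, height = 1, n_initial_states = 3, w = w, k = k,
                    csf_form = csf_form)
  owner <- matrix(c(1L, 2L, 3L), 1, 3)
  as_war_world(owner, data.frame(
    id = 1:3, alpha = c(1, alpha_mid, 1), resources = res,
    capital_row = c(1, 1, 1), capital_col = c(1, 2, 3)), cfg)
}

# n singleton states tiling a grid, given alphas (row-major placement)
singleton_world <- function(alpha, width, height, ...) {
  n <- width * height
  stopifnot(length(alpha) == n)
  cfg <- war_config(width = width, height = height, n_initial_states = n, ...)
  owner <- matrix(seq_len(n), height, width, byrow = TRUE)
  cells <- data.frame(row = rep(seq_len(height), each = width),
                      col = rep(seq_len(width), times = height))
  as_war_world(owner, data.frame(
    id = seq_len(n), alpha = alpha, resources = rep(10, n),
    capital_row = cells$row, capital_col = cells$col), cfg)
}

expect_world_invariants <- function(world) {
  expect_silent(validate_world(world))
  expect_identical(sum(world_states(world)$n_provinces),
                   world$config$width * world$config$height)
}
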