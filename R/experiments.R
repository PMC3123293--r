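#' Deterministic child seeds
#'
#' Derives the seed for run `index` of a batch from a base seed with a
#' Lehmer-style integer hash modulo 2^31 - 1 (computed exactly in double
#' arithmetic). Seeds are reproducible and independent of the order in which
#' runs execute.
#'
#' @param base_seed Integer base seed.
#' @param index Run index (vectorised).
#' @return Integer seeds in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(base_seed, index) {
  m <- 2147483647
  h <- as.numeric(base_seed) %% m
  vapply(as.numeric(index), function(i) {
    x <- (h * 48271) %% m
    x <- (x + i * 69621) %% m
    x <- (x * 48271) %% m
    if (x == 0) x <- 1
    as.integer(x)
  }, integer(1))
}

#' Run a batch of simulations
#'
#' Replicates [run_simulation()] `n_runs` times with distinct seeds derived
#' deterministically from `base_seed` (see [child_seed()]), and aggregates:
#' per-run summaries, and a cross-run trajectory of the median confidence in
#' which runs that have already terminated contribute their final value to
#' later steps (carry-forward), so the aggregate curve is defined at every
#' step.
#'
#' @param config A [war_config()].
#' @param n_runs Number of replicate runs.
#' @param base_seed Base seed; defaults to `config$seed`.
#' @return A `war_batch` object: `runs` (one-row-per-run tibble),
#'   `trajectory` (`step`, `median_alpha` aggregated across runs,
#'   `n_running` runs still active), `config`, `n_runs`, `base_seed`.
#' @examples
#' b <- run_batch(war_config(width = 8, height = 8, n_initial_states = 6),
#'                n_runs = 3, base_seed = 11)
#' glance(b)
#' @export
run_batch <- function(config, n_runs, base_seed = config$seed) {
  stopifnot(inherits(config, "war_config"), n_runs >= 1)
  seeds <- child_seed(base_seed, seq_len(n_runs))
  sims <- purrr::map(seeds, function(s) run_simulation(config, seed = s))
  runs <- dplyr::bind_rows(purrr::map(sims, glance))
  runs <- dplyr::mutate(runs, run = dplyr::row_number(), .before = 1)

  max_t <- max(runs$steps)
  traj_mat <- vapply(sims, function(sim) {
    v <- sim$series$median_alpha
    c(v, rep(v[length(v)], max_t + 1 - length(v)))
  }, numeric(max_t + 1))
  traj_mat <- matrix(traj_mat, nrow = max_t + 1)
  trajectory <- tibble::tibble(
    step = 0:max_t,
    median_alpha = apply(traj_mat, 1, median),
    n_running = vapply(0:max_t, function(s) sum(runs$steps > s), integer(1)))

  structure(
    list(config = config, n_runs = as.integer(n_runs),
         base_seed = base_seed, runs = runs, trajectory = trajectory),
    class = "war_batch")
}

#' @export
print.war_batch <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<war_batch> %d runs; median final median alpha = %.3f\n",
              g$n_runs, g$median_final_alpha))
  cat(sprintf("  %.0f%% ended with one state; mean length %.1f steps\n",
              100 * g$share_one_state, g$mean_steps))
  invisible(x)
}

#' Per-run summaries of a batch
#' @param x A `war_batch`.
#' @param ... Unused.
#' @return The one-row-per-run tibble.
#' @export
tidy.war_batch <- function(x, ...) x$runs

#' One-row summary of a batch
#' @param x A `war_batch`.
#' @param ... Unused.
#' @return A tibble: `n_runs`, `median_final_alpha` (median across runs of
#'   each run's final median confidence), `share_one_state`, `mean_steps`.
#' @export
glance.war_batch <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs,
    median_final_alpha = median(x$runs$final_median_alpha),
    share_one_state = mean(x$runs$termination == "one_state_left"),
    mean_steps = mean(x$runs$steps))
}

#' Plot the aggregated confidence trajectory of a batch
#' @param object A `war_batch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.war_batch <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$step, y = .data$median_alpha)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step",
                  y = "median confidence (aggregated across runs)") +
    ggplot2::theme_minimal()
}

#' The factorial robustness grid
#'
#' The full robustness design crosses grid size \{20, 30, 40\} (square),
#' torus \{no, yes\}, initial polarity \{10, 50, 100\}, decisiveness k
#' \{3, 5, 7\} and confidence spread sigma \{0.5, 1.0, 1.5\} — 162 cells.
#' The reduced design is an 8-cell two-level fractional factorial
#' (resolution III) over the extreme levels of the same five factors,
#' suitable for desk-scale robustness checks.
#'
#' @param reduced If `TRUE`, return the 8-cell corner design instead of the
#'   full 162-cell factorial.
#' @return A tibble with columns `grid_size`, `torus`, `n_initial_states`,
#'   `k`, `alpha_sigma`.
#' @export
s1_parameter_grid <- function(reduced = FALSE) {
  if (!reduced) {
    return(tidyr::expand_grid(
      grid_size = c(20L, 30L, 40L), torus = c(FALSE, TRUE),
      n_initial_states = c(10L, 50L, 100L), k = c(3, 5, 7),
      alpha_sigma = c(0.5, 1.0, 1.5)))
  }
  base <- tidyr::expand_grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1))
  base$D <- base$A * base$B
  base$E <- base$A * base$C
  pick <- function(x, lo, hi) ifelse(x < 0, lo, hi)
  tibble::tibble(
    grid_size = as.integer(pick(base$A, 20, 40)),
    torus = base$B > 0,
    n_initial_states = as.integer(pick(base$C, 10, 100)),
    k = pick(base$D, 3, 7),
    alpha_sigma = pick(base$E, 0.5, 1.5))
}

#' Parameter sweep
#'
#' Runs a batch of simulations in every cell of a parameter grid and reports
#' the cell-level median of the runs' final median confidence factors
#' (median-of-run-level-medians). War costs are zero and `w = 0.5`,
#' `alpha_mu = 0` unless overridden via `config`.
#'
#' @param grid A tibble of parameter combinations; recognised columns are
#'   `grid_size` (sets both width and height) and any [war_config()] field.
#'   See [s1_parameter_grid()].
#' @param n_runs Runs per cell.
#' @param base_seed Base seed; cell `i`, run `j` uses
#'   `child_seed(child_seed(base_seed, i), j)`.
#' @param config Baseline configuration the grid columns override.
#' @return A `war_sweep` tibble: the grid columns plus `n_runs` and
#'   `median_final_alpha`.
#' @export
parameter_sweep <- function(grid, n_runs, base_seed = config$seed,
                            config = war_config()) {
  stopifnot(nrow(grid) >= 1, n_runs >= 1)
  cell_seeds <- child_seed(base_seed, seq_len(nrow(grid)))
  vals <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    row <- as.list(grid[i, ])
    if (!is.null(row$grid_size)) {
      row$width <- as.integer(row$grid_size)
      row$height <- as.integer(row$grid_size)
      row$grid_size <- NULL
    }
    cfg <- do.call(config_with, c(list(config), row))
    glance(run_batch(cfg, n_runs, base_seed = cell_seeds[i]))$median_final_alpha
  })
  out <- dplyr::mutate(tibble::as_tibble(grid),
                       n_runs = as.integer(n_runs),
                       median_final_alpha = vals)
  class(out) <- c("war_sweep", class(out))
  out
}

experiment_curve <- function(param, values, n_runs, config, base_seed) {
  grid <- tibble::tibble(!!param := values)
  out <- parameter_sweep(grid, n_runs, base_seed = base_seed, config = config)
  class(out) <- setdiff(class(out), "war_sweep")
  attr(out, "spearman_rho") <-
    if (length(values) > 1) cor(values, out$median_final_alpha, method = "spearman")
    else NA_real_
  attr(out, "param") <- param
  class(out) <- c("war_curve", class(out))
  out
}

#' War-cost experiment
#'
#' Sweeps the war-cost share `q`, running a batch at each level (default
#' configuration otherwise) and recording the median final confidence. The
#' Spearman correlation between `q` and the medians is attached as attribute
#' `spearman_rho`; a negative value is the directional signature that rising
#' war costs erode the advantage of overconfidence.
#'
#' @param q_values War-cost shares to sweep.
#' @param n_runs Runs per level.
#' @param config Baseline configuration.
#' @param base_seed Base seed.
#' @return A `war_curve` tibble: `q`, `n_runs`, `median_final_alpha`.
#' @export
war_cost_experiment <- function(q_values = c(0, 0.1, 0.2, 0.4), n_runs,
                                config = war_config(),
                                base_seed = config$seed) {
  experiment_curve("q", q_values, n_runs, config, base_seed)
}

#' Attack-threshold experiment
#'
#' Sweeps the attack threshold `w`. Low thresholds (`w < 0.5`) license
#' attacks even by states that expect to lose, favouring underconfident
#' strategies; high thresholds (`w > 0.5`) mean unbiased and underconfident
#' states shirk winnable wars, favouring overconfidence even more strongly.
#'
#' @param w_values Attack thresholds to sweep.
#' @param n_runs Runs per level.
#' @param config Baseline configuration.
#' @param base_seed Base seed.
#' @return A `war_curve` tibble: `w`, `n_runs`, `median_final_alpha`.
#' @export
threshold_experiment <- function(w_values = c(0.3, 0.5, 0.7), n_runs,
                                 config = war_config(),
                                 base_seed = config$seed) {
  experiment_curve("w", w_values, n_runs, config, base_seed)
}

#' Plot an experiment curve
#' @param object A `war_curve` from [war_cost_experiment()] or
#'   [threshold_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.war_curve <- function(object, ...) {
  param <- attr(object, "param")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[param]],
                                       y = .data$median_final_alpha)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = param, y = "median final confidence") +
    ggplot2::theme_minimal()
}
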