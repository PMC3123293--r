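#' Run one simulation to termination
#'
#' Builds the initial world from the configuration and repeatedly applies
#' the five-phase step until a termination criterion is met: only one state
#' remains (`"one_state_left"`), there have been
#' `config$peace_steps_to_stop` consecutive steps with no battles
#' (`"peace"`), or the step cap is reached (`"max_steps"`, a recorded
#' outcome rather than an error).
#'
#' @param config A [war_config()].
#' @param seed Integer seed; defaults to `config$seed`. `NULL` draws from
#'   the current RNG state.
#' @param capture If `TRUE`, keep an ownership snapshot of the grid at step
#'   0 and after every step (needed by [export_frames()]).
#' @param world Optional starting `war_world` (e.g. from [as_war_world()]);
#'   when supplied, its configuration is used and no initial world is drawn.
#' @return A `war_run` object with elements `config`, `seed`, `series` (a
#'   tibble `step`, `n_states`, `median_alpha`, `battles`, one row per step
#'   including step 0), `termination`, `final_world`, and `snapshots`
#'   (a list of ownership matrices, or `NULL`).
#' @examples
#' run <- run_simulation(war_config(width = 8, height = 8,
#'                                  n_initial_states = 6, seed = 3))
#' glance(run)
#' @export
run_simulation <- function(config, seed = config$seed, capture = FALSE,
                           world = NULL) {
  if (!is.null(world)) {
    stopifnot(inherits(world, "war_world"))
    config <- world$config
    if (missing(seed)) seed <- config$seed
  }
  stopifnot(inherits(config, "war_config"))
  if (!is.null(seed)) set.seed(seed)
  res <- if (is.null(world)) {
    cpp_run(cfg_for_cpp(config), isTRUE(capture))
  } else {
    cpp_run_world(cfg_for_cpp(config), world$owner, states_for_cpp(world$states),
                  world$t, world$peace_streak, isTRUE(capture))
  }
  series <- tibble::tibble(
    step = as.integer(res$series[, 1]),
    n_states = as.integer(res$series[, 2]),
    median_alpha = res$series[, 3],
    battles = as.integer(res$series[, 4]))
  world <- world_from_cpp(res, config, t = res$t, peace_streak = res$peace_streak)
  snaps <- NULL
  if (isTRUE(capture)) {
    snaps <- lapply(res$snapshots, function(v)
      matrix(v, nrow = config$height, ncol = config$width, byrow = TRUE))
  }
  structure(
    list(config = config, seed = seed, series = series,
         termination = c("one_state_left", "peace", "max_steps")[res$termination],
         final_world = world, snapshots = snaps),
    class = "war_run")
}

#' @export
print.war_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<war_run> %d steps, terminated: %s\n", g$steps, g$termination))
  cat(sprintf("  %d surviving state%s, final median alpha = %.3f\n",
              g$final_n_states, if (g$final_n_states == 1) "" else "s",
              g$final_median_alpha))
  invisible(x)
}

#' Tidy the per-step time series of a run
#'
#' @param x A `war_run`.
#' @param ... Unused.
#' @return A tibble `step`, `n_states`, `median_alpha`, `battles`.
#' @export
tidy.war_run <- function(x, ...) x$series

#' One-row summary of a run
#'
#' @param x A `war_run`.
#' @param ... Unused.
#' @return A tibble with `steps`, `termination`, `final_n_states`,
#'   `final_median_alpha`, `total_battles`, `seed`.
#' @export
glance.war_run <- function(x, ...) {
  s <- x$series
  tibble::tibble(
    steps = max(s$step),
    termination = x$termination,
    final_n_states = s$n_states[nrow(s)],
    final_median_alpha = s$median_alpha[nrow(s)],
    total_battles = sum(s$battles),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Plot the trajectory of a run
#'
#' Median confidence of the surviving states and the number of states over
#' time, faceted; the dashed line marks the unbiased level alpha = 1.
#'
#' @param object A `war_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.war_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series,
                              c("median_alpha", "n_states"),
                              names_to = "measure", values_to = "value")
  ref <- tibble::tibble(measure = "median_alpha", y = 1)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          median_alpha = "median confidence (alpha)",
                          n_states = "number of states"))) +
    ggplot2::labs(x = "step", y = NULL) +
    ggplot2::theme_minimal()
}
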