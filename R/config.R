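#' Simulation configuration
#'
#' Bundles every parameter of the lattice war model. Defaults are the
#' model's canonical settings: a 30 x 30 bounded grid tiled by N = 50
#' initial states, conflict decisiveness k = 5, equal-odds share r0 = 0.5,
#' attack threshold w = 0.5, no war costs (q = 0), confidence factors drawn
#' from a lognormal with underlying mean 0 and standard deviation 1 (so the
#' population median confidence is 1, i.e. unbiased on the whole), 10
#' resource units per province at birth, and termination after 50
#' consecutive peaceful steps or when a single state remains.
#'
#' @param width,height Grid dimensions in cells (provinces).
#' @param torus If `TRUE` the grid wraps around (no boundary cells).
#' @param n_initial_states Initial polarity N: number of states the grid is
#'   partitioned into at step 0. Must not exceed `width * height`.
#' @param k Decisiveness of conflict: slope of the conflict success
#'   function. Larger k makes resource differentials more decisive.
#' @param r0 Share of committed resources at which the odds of winning are
#'   equal; kept at 0.5 in all canonical experiments.
#' @param w Attack threshold: a state attacks only if its perceived win
#'   probability strictly exceeds `w`.
#' @param q War-cost share in `[0, 1)`: each battle costs a belligerent
#'   `q` times the resources its opponent committed to that front.
#' @param alpha_mu,alpha_sigma Mean and standard deviation of the normal
#'   distribution underlying the lognormal confidence factors, so the
#'   population median confidence is `exp(alpha_mu)`.
#' @param initial_resources_per_province Resource stock per province granted
#'   at state birth (initial states and newborn successor states alike).
#' @param peace_steps_to_stop Run terminates after this many consecutive
#'   steps with no battles.
#' @param max_steps Hard cap on steps; reaching it is a recorded outcome,
#'   not an error.
#' @param seed Integer seed used by [build_world()] and [run_simulation()].
#' @param csf_form `"log_odds"` (default): logistic in the log-odds of the
#'   resource share, equal to `ra^k / (ra^k + rt^k)` when `r0 = 0.5`, with
#'   win-probability asymptotes at 0 and 1. `"share_linear"`: logistic in
#'   the share itself (bounded range for finite k). See
#'   [success_probability()].
#' @param allocation_weights How a state splits its stock across multiple
#'   simultaneous fronts: in proportion to each opponent's total resource
#'   stock (`"resources"`, default) or province count (`"provinces"`).
#'
#' @return A `war_config` object (a validated named list).
#' @examples
#' cfg <- war_config(width = 10, height = 10, n_initial_states = 5, seed = 42)
#' cfg$k
#' @export
war_config <- function(width = 30L, height = 30L, torus = FALSE,
                       n_initial_states = 50L,
                       k = 5, r0 = 0.5, w = 0.5, q = 0,
                       alpha_mu = 0, alpha_sigma = 1,
                       initial_resources_per_province = 10,
                       peace_steps_to_stop = 50L, max_steps = 10000L,
                       seed = 1L,
                       csf_form = c("log_odds", "share_linear"),
                       allocation_weights = c("resources", "provinces")) {
  csf_form <- match.arg(csf_form)
  allocation_weights <- match.arg(allocation_weights)
  chk_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
      abort(sprintf("`%s` must be a single integer >= %d", name, min))
    as.integer(x)
  }
  chk_num <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    ok <- length(x) == 1 && is.numeric(x) && !is.na(x) &&
      (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
    if (!ok) abort(sprintf("`%s` is out of range", name))
    as.numeric(x)
  }
  width <- chk_count(width, "width")
  height <- chk_count(height, "height")
  n_initial_states <- chk_count(n_initial_states, "n_initial_states")
  if (n_initial_states > width * height)
    abort("`n_initial_states` exceeds the number of provinces on the grid")
  cfg <- list(
    width = width, height = height, torus = isTRUE(torus),
    n_initial_states = n_initial_states,
    k = chk_num(k, "k", 0, Inf, lo_open = TRUE),
    r0 = chk_num(r0, "r0", 0, 1, lo_open = TRUE, hi_open = TRUE),
    w = chk_num(w, "w", 0, 1, lo_open = TRUE, hi_open = TRUE),
    q = chk_num(q, "q", 0, 1, hi_open = TRUE),
    alpha_mu = chk_num(alpha_mu, "alpha_mu", -Inf, Inf),
    alpha_sigma = chk_num(alpha_sigma, "alpha_sigma", 0, Inf),
    initial_resources_per_province =
      chk_num(initial_resources_per_province, "initial_resources_per_province",
              0, Inf, lo_open = TRUE),
    peace_steps_to_stop = chk_count(peace_steps_to_stop, "peace_steps_to_stop"),
    max_steps = chk_count(max_steps, "max_steps"),
    seed = if (is.null(seed)) NULL else chk_count(seed, "seed", min = 0),
    csf_form = csf_form,
    allocation_weights = allocation_weights
  )
  structure(cfg, class = "war_config")
}

#' @export
print.war_config <- function(x, ...) {
  cat(sprintf("<war_config> %dx%d%s grid, N = %d\n",
              x$width, x$height, if (x$torus) " torus" else "",
              x$n_initial_states))
  cat(sprintf("  k = %g, r0 = %g, w = %g, q = %g, csf = %s\n",
              x$k, x$r0, x$w, x$q, x$csf_form))
  cat(sprintf("  alpha ~ lognormal(mu = %g, sigma = %g); %g resources/province\n",
              x$alpha_mu, x$alpha_sigma, x$initial_resources_per_province))
  cat(sprintf("  stop: %d peaceful steps | 1 state | %d steps; seed = %s\n",
              x$peace_steps_to_stop, x$max_steps,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

# amend a config, revalidating
config_with <- function(config, ...) {
  stopifnot(inherits(config, "war_config"))
  changes <- list(...)
  cfg <- unclass(config)
  cfg[names(changes)] <- changes
  do.call(war_config, cfg)
}
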