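#' @title The five-phase step procedure
#' @description
#' Each simulation step executes five sub-procedures synchronously across
#' all states, strictly in order: (1) resource extraction, (2) attack
#' decisions on a common post-extraction snapshot, (3) allocation of each
#' belligerent's full stock across its active fronts, (4) battle resolution
#' by independent Bernoulli draws from the conflict success function of the
#' true allocations, and (5) structural change (province transfer, capital
#' capture, cut-off fragmentation), plus the optional war-cost deduction
#' between phases 4 and 5. The wrappers below expose each phase on a
#' `war_world` for inspection and testing; they call the exact code the
#' compiled full-run loop uses, consuming the same RNG stream.
#' @name dynamics
NULL

world_call <- function(world, fn, ...) {
  fn(cfg_for_cpp(world$config), world$owner, states_for_cpp(world$states), ...)
}

#' Extraction phase
#'
#' Every living state extracts one resource unit from each province it owns.
#'
#' @param world A `war_world`.
#' @return The world after extraction.
#' @export
extract_resources <- function(world) {
  res <- world_call(world, cpp_extract)
  world_from_cpp(res, world$config, t = world$t, peace_streak = world$peace_streak)
}

#' Decision phase
#'
#' Each state evaluates its perceived probability of defeating every
#' neighbour — feeding `alpha` times its own full stock and the neighbour's
#' true full stock into the conflict success function (diversions to other
#' fronts cannot be anticipated) — and names the neighbour with the highest
#' perceived probability as its target, provided that probability strictly
#' exceeds the attack threshold `w`. Ties among maximising targets are
#' broken uniformly at random.
#'
#' @param world A `war_world` (normally just after [extract_resources()]).
#' @return A tibble `attacker`, `target`, `p_perceived`, one row per
#'   attacking state.
#' @export
decide_attacks <- function(world) {
  tibble::as_tibble(world_call(world, cpp_decide))
}

#' Build active fronts from the declared attacks
#'
#' One front per unordered pair of states at war this step, whoever
#' initiated it; mutual attacks collapse to a single front with
#' `mutual = TRUE` (the lower id is labelled attacker for reporting
#' determinism).
#'
#' @param attacks Output of [decide_attacks()].
#' @return A tibble `attacker`, `defender`, `mutual`.
#' @export
build_fronts <- function(attacks) {
  tibble::as_tibble(cpp_fronts(as.integer(attacks$attacker),
                               as.integer(attacks$target)))
}

#' Allocation phase
#'
#' Each belligerent divides its full resource stock across its active fronts
#' in proportion to the size of each opponent (total resource stock by
#' default, province count if the configuration says so). A single-front
#' state commits everything.
#'
#' @param world A `war_world`.
#' @param fronts Output of [build_fronts()].
#' @return `fronts` with columns `attacker_alloc`, `defender_alloc` added.
#' @export
allocate_resources <- function(world, fronts) {
  al <- world_call(world, cpp_allocate,
                   as.integer(fronts$attacker), as.integer(fronts$defender),
                   as.logical(fronts$mutual))
  dplyr::mutate(fronts,
                attacker_alloc = al$attacker_alloc,
                defender_alloc = al$defender_alloc)
}

#' Interaction phase
#'
#' Resolves each front by an independent Bernoulli draw with success
#' probability given by the conflict success function of the two sides'
#' true allocations (confidence factors play no role in outcomes).
#'
#' @param world A `war_world` (supplies the CSF parameters).
#' @param fronts Output of [allocate_resources()].
#' @return `fronts` with `p_attacker` and `winner` columns added.
#' @export
resolve_battles <- function(world, fronts) {
  res <- cpp_resolve(cfg_for_cpp(world$config),
                     as.integer(fronts$attacker), as.integer(fronts$defender),
                     fronts$attacker_alloc, fronts$defender_alloc)
  dplyr::mutate(fronts, p_attacker = res$p_attacker, winner = res$winner)
}

#' War-cost deduction
#'
#' With war-cost share `q > 0`, fighting itself is costly: on every front
#' each belligerent's stock is reduced by `q` times the resources its
#' opponent committed to that front, floored at zero. With `q = 0` (the
#' baseline model) the world is returned unchanged.
#'
#' @param world A `war_world`.
#' @param fronts Output of [allocate_resources()] (or later phases).
#' @return The world after costs are paid; the total paid is attached as
#'   attribute `costs_paid`.
#' @export
apply_war_costs <- function(world, fronts) {
  res <- world_call(world, cpp_war_costs,
                    as.integer(fronts$attacker), as.integer(fronts$defender),
                    fronts$attacker_alloc, fronts$defender_alloc)
  out <- world_from_cpp(res, world$config, t = world$t,
                        peace_streak = world$peace_streak)
  attr(out, "costs_paid") <- res$costs_paid
  out
}

#' Structural-change phase
#'
#' Applies battle resolutions in uniformly random order. For each (winner,
#' loser) pair still valid — both alive, territories still adjacent — the
#' winner annexes one uniformly chosen loser province adjacent to its own
#' territory. If that province is the loser's capital the loser dissolves
#' and every remaining loser province becomes an independent single-province
#' state inheriting the loser's confidence factor, with
#' `initial_resources_per_province` resources and itself as capital.
#' Otherwise any part of the loser's territory cut off from its capital
#' sheds into such newborn states likewise. Resolutions invalidated by
#' earlier changes are skipped.
#'
#' @param world A `war_world`.
#' @param resolutions Data frame with columns `winner` and `loser` (one row
#'   per resolved front), or the output of [resolve_battles()] from which
#'   losers are inferred.
#' @return The world after all changes; a one-row summary tibble
#'   (`provinces_transferred`, `states_destroyed`, `newborn_states`) is
#'   attached as attribute `report` and the per-front event table as
#'   attribute `events`.
#' @export
apply_structural_change <- function(world, resolutions) {
  if (!"loser" %in% names(resolutions)) {
    resolutions <- dplyr::mutate(
      resolutions,
      loser = ifelse(.data$winner == .data$attacker, .data$defender, .data$attacker))
  }
  res <- world_call(world, cpp_struct_change,
                    as.integer(resolutions$winner), as.integer(resolutions$loser))
  out <- world_from_cpp(res, world$config, t = world$t,
                        peace_streak = world$peace_streak)
  attr(out, "report") <- tibble::tibble(
    provinces_transferred = res$transferred,
    states_destroyed = res$destroyed,
    newborn_states = res$newborns)
  attr(out, "events") <- tibble::as_tibble(res$events)
  out
}

#' Advance the world one full step
#'
#' Runs the five phases in order (with war costs between interaction and
#' structural change), increments the step counter, and updates the peace
#' streak (incremented on a step with zero battles, reset otherwise).
#'
#' @param world A `war_world`.
#' @return The stepped world. The step report (a one-row tibble: `step`,
#'   `attacks`, `battles`, `provinces_transferred`, `states_destroyed`,
#'   `newborn_states`, `war_costs_paid`) is available via
#'   [last_step_report()] and the per-front event log via
#'   [last_step_events()].
#' @examples
#' w <- build_world(war_config(width = 6, height = 6, n_initial_states = 4, seed = 1))
#' w2 <- step_world(w)
#' last_step_report(w2)
#' @export
step_world <- function(world) {
  res <- world_call(world, cpp_step, world$t, world$peace_streak)
  out <- world_from_cpp(res, world$config, t = res$t,
                        peace_streak = res$peace_streak)
  out$last_report <- tibble::as_tibble(res$report)
  out$last_events <- tibble::as_tibble(res$events)
  out
}

#' @rdname step_world
#' @export
last_step_report <- function(world) world$last_report

#' @rdname step_world
#' @export
last_step_events <- function(world) world$last_events
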