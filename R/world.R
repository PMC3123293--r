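#' @title World objects
#' @description
#' A `war_world` is the full simulation state: the configuration, an
#' ownership matrix (`height` x `width`, entries are state ids), a registry
#' of every state ever created (dead states keep their row with
#' `alive = FALSE`, so confidence lineages can be traced), the step counter
#' and the current streak of consecutive peaceful steps.
#' @name war_world
NULL

new_war_world <- function(config, owner, states, t = 0L, peace_streak = 0L) {
  structure(
    list(config = config, owner = owner, states = states,
         t = as.integer(t), peace_streak = as.integer(peace_streak)),
    class = "war_world")
}

# config in the flat form the C++ layer expects
cfg_for_cpp <- function(config) unclass(config)

states_for_cpp <- function(states) {
  list(id = as.integer(states$id), alpha = as.numeric(states$alpha),
       resources = as.numeric(states$resources),
       capital_row = as.integer(states$capital_row),
       capital_col = as.integer(states$capital_col),
       alive = as.logical(states$alive))
}

world_from_cpp <- function(res, config, t = 0L, peace_streak = 0L) {
  states <- tibble::as_tibble(res$states)
  new_war_world(config, res$owner, states, t = t, peace_streak = peace_streak)
}

#' Build the initial world
#'
#' Places the configured number of capitals uniformly at random on distinct
#' cells, then grows territories outward by synchronous multi-source
#' breadth-first search (each frontier cell joins a uniformly chosen owned
#' neighbouring cell's state), which guarantees every territory is one
#' 4-connected block containing its capital. Each state draws its confidence
#' factor independently from `lognormal(alpha_mu, alpha_sigma)` and starts
#' with `initial_resources_per_province` resources per province owned.
#'
#' @param config A [war_config()].
#' @param seed Integer seed; defaults to `config$seed`. Use `NULL` to draw
#'   from the current RNG state.
#' @return A `war_world` object.
#' @examples
#' w <- build_world(war_config(width = 8, height = 8, n_initial_states = 4, seed = 7))
#' world_states(w)
#' @export
build_world <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "war_config"))
  if (!is.null(seed)) set.seed(seed)
  world_from_cpp(cpp_build_world(cfg_for_cpp(config)), config)
}

#' Assemble a world from explicit parts
#'
#' Constructs (and validates) a `war_world` from an ownership matrix and a
#' state table — the way unit tests and worked micro-topologies set up exact
#' scenarios. State ids must be consecutive from 1.
#'
#' @param owner Integer matrix, `config$height` x `config$width`; entry
#'   `[r, c]` is the id of the state owning province (r, c).
#' @param states Data frame with columns `id`, `alpha`, `resources`,
#'   `capital_row`, `capital_col` and optionally `alive` (default all
#'   living).
#' @param config A [war_config()] whose grid dimensions match `owner`.
#' @param t,peace_streak Step counter and peace streak (default 0).
#' @return A validated `war_world`.
#' @export
as_war_world <- function(owner, states, config, t = 0L, peace_streak = 0L) {
  stopifnot(inherits(config, "war_config"))
  states <- tibble::as_tibble(states)
  if (!"alive" %in% names(states)) states$alive <- TRUE
  states <- states[order(states$id),
                   c("id", "alpha", "resources", "capital_row", "capital_col", "alive")]
  if (!identical(as.integer(states$id), seq_len(nrow(states))))
    abort("state ids must be consecutive integers starting at 1")
  owner <- matrix(as.integer(owner), nrow = config$height, ncol = config$width)
  world <- new_war_world(config, owner, states, t = t, peace_streak = peace_streak)
  validate_world(world)
  world
}

#' Check the structural invariants of a world
#'
#' Asserts that every cell is owned by a living state, that every living
#' state's territory is non-empty and 4-connected, that each living state
#' has exactly one capital lying inside its own territory, and that all
#' confidence factors are positive. Called by [as_war_world()] and available
#' for use in property tests.
#'
#' @param world A `war_world`.
#' @return `world`, invisibly; aborts with a message if an invariant fails.
#' @export
validate_world <- function(world) {
  cfg <- world$config
  st <- world$states
  if (any(st$alpha <= 0)) abort("confidence factors must be positive")
  if (any(st$resources < 0)) abort("resources must be non-negative")
  living <- st$id[st$alive]
  owned <- sort(unique(as.vector(world$owner)))
  if (!setequal(owned, living))
    abort("the set of grid owners must equal the set of living states")
  for (id in living) {
    cells <- which(world$owner == id, arr.ind = TRUE)
    cap <- c(st$capital_row[st$id == id], st$capital_col[st$id == id])
    if (!any(cells[, 1] == cap[1] & cells[, 2] == cap[2]))
      abort(sprintf("state %d's capital lies outside its territory", id))
    comp <- cpp_components(cells[, 1], cells[, 2], cfg$width, cfg$height, cfg$torus)
    if (max(comp) != 1L)
      abort(sprintf("state %d's territory is not 4-connected", id))
  }
  invisible(world)
}

#' @export
print.war_world <- function(x, ...) {
  n <- sum(x$states$alive)
  cat(sprintf("<war_world> %dx%d%s grid, t = %d, %d living state%s, median alpha = %.3f\n",
              x$config$width, x$config$height,
              if (x$config$torus) " torus" else "", x$t, n,
              if (n == 1) "" else "s", median_confidence(x)))
  invisible(x)
}

#' State table of a world
#'
#' @param world A `war_world`.
#' @param living_only Drop dead states (default `TRUE`).
#' @return A tibble with one row per state: `id`, `alpha`, `resources`,
#'   `capital_row`, `capital_col`, `alive`, `n_provinces`.
#' @export
world_states <- function(world, living_only = TRUE) {
  st <- world$states
  counts <- tabulate(world$owner, nbins = nrow(st))
  st$n_provinces <- counts
  if (living_only) st <- st[st$alive, ]
  st
}

#' Province table of a world
#'
#' Long-format ownership map, the plain-text serialisation of the lattice.
#'
#' @param world A `war_world`.
#' @return A tibble with one row per cell: `row`, `col`, `state_id`,
#'   `is_capital`.
#' @export
world_provinces <- function(world) {
  cfg <- world$config
  st <- world$states
  grid <- tidyr::expand_grid(row = seq_len(cfg$height), col = seq_len(cfg$width))
  grid$state_id <- world$owner[cbind(grid$row, grid$col)]
  caps <- st[st$alive, ]
  grid$is_capital <- FALSE
  grid$is_capital[match(
    paste(caps$capital_row, caps$capital_col),
    paste(grid$row, grid$col))] <- TRUE
  grid
}

#' Neighbouring states
#'
#' States owning at least one province 4-adjacent (torus-wrapped if the
#' world is a torus) to the given state's territory.
#'
#' @param world A `war_world`.
#' @param id A living state id.
#' @return Sorted integer vector of neighbouring state ids (excluding `id`
#'   itself); empty if the state has the whole grid.
#' @export
neighbour_states <- function(world, id) {
  adj <- state_adjacency(world)
  sort(unique(c(adj$b[adj$a == id], adj$a[adj$b == id])))
}

#' All adjacent state pairs
#'
#' @param world A `war_world`.
#' @return A tibble of unordered adjacent pairs, `a < b`.
#' @export
state_adjacency <- function(world) {
  m <- cpp_neighbour_pairs(world$owner, world$config$torus)
  tibble::tibble(a = m[, 1], b = m[, 2])
}

#' Connected components of a territory
#'
#' Partitions a set of cells into maximal 4-connected components, honouring
#' torus wraparound when requested.
#'
#' @param territory Data frame or matrix with columns/cols `row`, `col`
#'   (1-based).
#' @param width,height Grid dimensions.
#' @param torus Wraparound flag.
#' @return A tibble `row`, `col`, `component` (components numbered by first
#'   appearance).
#' @examples
#' connected_components(data.frame(row = c(1, 1), col = c(1, 5)),
#'                      width = 5, height = 5, torus = TRUE)
#' @export
connected_components <- function(territory, width, height, torus = FALSE) {
  territory <- as.data.frame(territory)
  if (is.null(colnames(territory)) || !all(c("row", "col") %in% names(territory))) {
    names(territory)[1:2] <- c("row", "col")
  }
  if (nrow(territory) == 0) abort("territory must be non-empty")
  lab <- cpp_components(as.integer(territory$row), as.integer(territory$col),
                        as.integer(width), as.integer(height), isTRUE(torus))
  tibble::tibble(row = as.integer(territory$row),
                 col = as.integer(territory$col),
                 component = as.integer(lab))
}

#' Von Neumann neighbours of a cell
#'
#' @param row,col 1-based cell coordinates.
#' @param width,height Grid dimensions.
#' @param torus Wraparound flag.
#' @return A tibble of neighbouring cells (2 to 4 rows on a bounded grid,
#'   exactly 4 on a torus with both dimensions > 1).
#' @export
lattice_neighbours <- function(row, col, width, height, torus = FALSE) {
  cand <- rbind(c(row - 1, col), c(row + 1, col), c(row, col - 1), c(row, col + 1))
  if (torus) {
    if (height > 1) cand[, 1] <- ((cand[, 1] - 1) %% height) + 1
    if (width > 1) cand[, 2] <- ((cand[, 2] - 1) %% width) + 1
  }
  keep <- cand[, 1] >= 1 & cand[, 1] <= height & cand[, 2] >= 1 & cand[, 2] <= width &
    !(cand[, 1] == row & cand[, 2] == col)
  cand <- unique(cand[keep, , drop = FALSE])
  tibble::tibble(row = cand[, 1], col = cand[, 2])
}

#' Median confidence of the living states
#'
#' The headline summary of a world: the unweighted median confidence factor
#' over living states (ties in even counts resolved as the mean of the two
#' middle values, as in [stats::median()]).
#'
#' @param world A `war_world`.
#' @return A positive scalar.
#' @export
median_confidence <- function(world) {
  st <- world$states
  median(st$alpha[st$alive])
}
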