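#' Render a world as a text grid
#'
#' One glyph per cell. Overconfident states (alpha > 1) render as `R`/`r`,
#' unbiased or underconfident states as `G`/`g` — uppercase on border cells
#' (cells adjacent to another state or, on a bounded grid, to the edge),
#' lowercase in the interior — and capitals as `*`. The rendering is
#' deterministic for a given world.
#'
#' @param world A `war_world`.
#' @param show_capitals Mark capital cells with `*` (default `TRUE`).
#' @param show_borders Distinguish border cells by case (default `TRUE`).
#' @return A character matrix of class `war_snapshot` with a `print` method.
#' @examples
#' w <- build_world(war_config(width = 6, height = 6, n_initial_states = 3, seed = 5))
#' render_snapshot(w)
#' @export
render_snapshot <- function(world, show_capitals = TRUE, show_borders = TRUE) {
  cfg <- world$config
  st <- world$states
  over <- st$alpha > 1
  glyph <- matrix("", cfg$height, cfg$width)
  for (r in seq_len(cfg$height)) {
    for (cc in seq_len(cfg$width)) {
      id <- world$owner[r, cc]
      border <- FALSE
      if (show_borders) {
        nb <- lattice_neighbours(r, cc, cfg$width, cfg$height, cfg$torus)
        border <- nrow(nb) < 4 && !cfg$torus
        if (!border) border <- any(world$owner[cbind(nb$row, nb$col)] != id)
      }
      g <- if (over[id]) "r" else "g"
      if (border) g <- toupper(g)
      glyph[r, cc] <- g
    }
  }
  if (show_capitals) {
    live <- st[st$alive, ]
    glyph[cbind(live$capital_row, live$capital_col)] <- "*"
  }
  structure(glyph, class = "war_snapshot")
}

#' @export
print.war_snapshot <- function(x, ...) {
  cat(apply(unclass(x), 1, paste, collapse = ""), sep = "\n")
  invisible(x)
}

#' Plot a world
#'
#' Map of the lattice with the canonical colour rule: red for overconfident
#' states (alpha > 1), green for unbiased or underconfident states; state
#' borders drawn as tile outlines and capitals as black dots.
#'
#' @param object A `war_world`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.war_world <- function(object, ...) {
  prov <- world_provinces(object)
  st <- object$states
  prov$confidence <- ifelse(st$alpha[prov$state_id] > 1,
                            "overconfident", "unbiased/underconfident")
  caps <- dplyr::filter(prov, .data$is_capital)
  ggplot2::ggplot(prov, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$confidence,
                                    group = .data$state_id),
                       colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_point(data = caps, size = 1, colour = "black") +
    ggplot2::scale_fill_manual(values = c(
      "overconfident" = "#c0392b", "unbiased/underconfident" = "#27ae60")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.war_world
#' @param world A `war_world`.
#' @export
plot_world <- function(world) autoplot(world)

#' Write / read a run's time series
#'
#' CSV round-trip of the per-step series (`step`, `n_states`,
#' `median_alpha`, `battles`); numeric fields round-trip at full precision.
#'
#' @param run A `war_run` (or its tidy series).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(run, path) {
  series <- if (inherits(run, "war_run")) run$series else tibble::as_tibble(run)
  needed <- c("step", "n_states", "median_alpha", "battles")
  if (!all(needed %in% names(series)))
    abort("series must have columns step, n_states, median_alpha, battles")
  if (nrow(series) == 0) abort("refusing to write an empty time series")
  out <- series[needed]
  # 17 significant digits round-trip doubles exactly
  out$median_alpha <- sprintf("%.17g", out$median_alpha)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @return For `read_timeseries`, the series tibble.
#' @export
read_timeseries <- function(path) {
  # base strtod parsing is exact for the %.17g representation written above
  df <- utils::read.csv(path, colClasses = c(
    step = "integer", n_states = "integer",
    median_alpha = "numeric", battles = "integer"))
  tibble::as_tibble(df)
}

#' Write a run manifest
#'
#' JSON sidecar recording the full configuration, the seed, a configuration
#' hash and the package version, so any output file can be regenerated.
#'
#' @param config A [war_config()].
#' @param seed The seed used.
#' @param path Output path (`.json`).
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, seed, path, extra = list()) {
  manifest <- c(list(
    config = unclass(config),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("bellicose"))),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Export snapshot frames of a run
#'
#' Writes the captured ownership grids of a run as numbered plain-text
#' frames (one glyph per cell, same encoding as [render_snapshot()] without
#' capitals), plus a JSON manifest, for external movie assembly.
#'
#' @param run A `war_run` executed with `capture = TRUE`.
#' @param dir Output directory (created if needed).
#' @param every_n Keep frames for steps 0, `every_n`, `2 * every_n`, ...
#' @return Tibble of written frames (`step`, `file`), invisibly.
#' @export
export_frames <- function(run, dir, every_n = 1) {
  if (is.null(run$snapshots))
    abort("run was not executed with `capture = TRUE`")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  steps <- seq_along(run$snapshots) - 1L
  keep <- steps %% every_n == 0
  over <- run$final_world$states$alpha > 1
  files <- character(0)
  for (i in which(keep)) {
    owner <- run$snapshots[[i]]
    glyph <- matrix(ifelse(over[owner], "r", "g"), nrow(owner), ncol(owner))
    file <- file.path(dir, sprintf("frame_%06d.txt", steps[i]))
    writeLines(apply(glyph, 1, paste, collapse = ""), file)
    files <- c(files, file)
  }
  write_run_manifest(run$config, run$seed, file.path(dir, "manifest.json"),
                     extra = list(frames = length(files), every_n = every_n,
                                  termination = run$termination))
  invisible(tibble::tibble(step = steps[keep], file = files))
}

#' Write a sweep table
#'
#' @param sweep A `war_sweep` or `war_curve` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  readr::write_csv(tibble::as_tibble(sweep), path)
  invisible(path)
}
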