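#' Built-in benchmark configurations
#'
#' Returns the declarative configuration of one of the five bundled
#' benchmarks. Grid sizes, schedules, seeding geometry and obstacle
#' placement follow the published protocols; the energy parameters are
#' package defaults (documented in the methods vignette) since the protocols
#' reference simulator example files rather than printing values. Every
#' field can be overridden.
#'
#' Benchmarks:
#' \describe{
#'   \item{game_of_life}{50 x 50 torus, random initial condition (density
#'     0.5), 500 synchronous steps, PNG every 20 steps.}
#'   \item{protrusion}{A single Act-model cell at the centre of a 200 x 200
#'     grid, two immutable obstacle discs of radius 10 placed 50 pixels to
#'     its left and right, 15,000 MCS, centroid log every 10 MCS, PNG every
#'     250 MCS.}
#'   \item{cell_sorting}{Differential-adhesion sorting: 50 + 50 cells of two
#'     kinds seeded within a circle of radius 67 around the midpoint of a
#'     200 x 200 grid, 2000 MCS, statistics every 10 MCS, PNG every 100 MCS.}
#'   \item{cell_division}{Growth and division: 20 founder cells seeded in a
#'     circle of radius 35 around the midpoint of a 500 x 500 grid, 40,000
#'     MCS, cell-count log every 100 MCS, PNG every 1000 MCS.}
#' }
#'
#' @param name One of `"game_of_life"`, `"protrusion"`, `"cell_sorting"`,
#'   `"cell_division"`.
#' @param overrides Named list of config blocks merged over the default
#'   (e.g. `list(schedule = list(n_mcs = 100))`).
#' @return A validated `cpm_config` (for `game_of_life`, a list with class
#'   `gol_config`).
#' @export
benchmark_config <- function(name = c("game_of_life", "protrusion",
                                      "cell_sorting", "cell_division"),
                             overrides = list()) {
  name <- match.arg(name)
  cfg <- switch(name,
    game_of_life = structure(list(
      grid = list(width = 50, height = 50, torus_x = TRUE, torus_y = TRUE),
      density = 0.5,
      schedule = list(n_steps = 500, png_every = 20)
    ), class = "gol_config"),
    protrusion = list(
      grid = list(width = 200, height = 200),
      kinds = list(list(name = "cell"), list(name = "obstacle")),
      hamiltonian = list(
        temperature = 20,
        J = list(c(0, 20, 20), c(20, 0, 20), c(20, 20, 0)),
        lambda_v = c(50, 0), target_v = c(500, 0),
        lambda_p = c(2, 0), target_p = c(340, 0),
        lambda_act = c(200, 0), max_act = c(80, 0)),
      processes = list(
        list(type = "seed_circle", counts = 1, kinds = 1, radius = 1,
             burn_in = 30),
        list(type = "obstacles",
             centers = list(c(50, 100), c(150, 100)), radius = 10, kind = 2)),
      schedule = list(n_mcs = 15000, log_every = 10, png_every = 250)
    ),
    cell_sorting = list(
      grid = list(width = 200, height = 200),
      kinds = list(list(name = "dark"), list(name = "light")),
      hamiltonian = list(
        temperature = 10,
        J = list(c(0, 16, 16), c(16, 6, 20), c(16, 20, 6)),
        lambda_v = c(2, 2), target_v = c(125, 125)),
      processes = list(
        list(type = "seed_circle", counts = c(50, 50), kinds = c(1, 2),
             radius = 67, burn_in = 50)),
      schedule = list(n_mcs = 2000, log_every = 10, png_every = 100)
    ),
    cell_division = list(
      grid = list(width = 500, height = 500),
      kinds = list(list(name = "cell")),
      hamiltonian = list(
        temperature = 10,
        J = list(c(0, 12), c(12, 6)),
        lambda_v = 5, target_v = 100),
      processes = list(
        list(type = "seed_circle", counts = 20, kinds = 1, radius = 35,
             burn_in = 30),
        list(type = "grow_divide", growth_rate = 0.2, division_volume = 180,
             base_target_v = 100, axis_mode = "minor-axis")),
      schedule = list(n_mcs = 40000, log_every = 100, png_every = 1000)
    ))
  if (length(overrides)) cfg <- merge_config(cfg, overrides)
  if (name == "game_of_life") cfg else validate_config(unclass(cfg))
}

# Merge override blocks over a base config. Named sub-lists (grid, schedule,
# hamiltonian, ...) merge key-wise; unnamed lists (processes, kinds, J rows)
# replace the block wholesale, which modifyList alone would silently skip.
merge_config <- function(base, ov) {
  cl <- class(base)
  base <- unclass(base)
  for (nm in names(ov)) {
    if (nm %in% names(base) && is.list(base[[nm]]) && is.list(ov[[nm]]) &&
        !is.null(names(ov[[nm]])) && all(nzchar(names(ov[[nm]]))))
      base[[nm]] <- merge_config(base[[nm]], ov[[nm]])
    else base[[nm]] <- ov[[nm]]
  }
  class(base) <- cl
  base
}

#' Run a benchmark or arbitrary configuration
#'
#' Executes seeding, obstacles and dynamics with the scheduled logging and
#' rendering, writing PNG frames (`frame_<mcs>.png`, including MCS 0), tidy
#' CSV statistics (`stats_cells.csv`, `stats_global.csv`, including the
#' initial state row) and a `manifest.json` recording the full config, seed,
#' wall time and MCS/s, to `out_dir`. The run is a pure function of
#' (config, seed).
#'
#' @param config A `cpm_config`, a `gol_config`, or a benchmark name
#'   accepted by [benchmark_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param draw Set `FALSE` to suppress all PNG output (no-draw mode, used
#'   when timing).
#' @param overrides Passed to [benchmark_config()] when `config` is a name.
#' @return Invisibly, a list with `state` (final), `records` (stat records),
#'   `events` (division events, if any) and `manifest`.
#' @export
run_experiment <- function(config, out_dir, seed = 1L, draw = TRUE,
                           overrides = list()) {
  if (is.character(config)) config <- benchmark_config(config, overrides)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(config, "gol_config"))
    return(run_gol_experiment(config, out_dir, seed, draw))

  ham <- config_hamiltonian(config)
  set.seed(seed)
  state <- config_initial_state(config, ham)

  sched <- config$schedule
  records <- list()
  events <- new.env(); events$events <- NULL
  hooks <- list()
  if (!is.na(sched$log_every %||% NA))
    hooks <- c(hooks, list(list(every = sched$log_every, fn = function(s, m) {
      records[[length(records) + 1L]] <<- stat_record(s, m, ham$kernel)
      s
    })))
  if (draw && !is.na(sched$png_every %||% NA)) {
    pal <- default_palette(length(config$kinds))
    hooks <- c(hooks, list(list(every = sched$png_every, fn = function(s, m) {
      fr <- render_frame(s, pal, config$outputs$draw_mode,
                         config$outputs$zoom)
      write_frame_png(fr, file.path(out_dir, sprintf("frame_%06d.png", m)))
      s
    })))
  }
  for (p in config$processes %||% list())
    if (p$type == "grow_divide") {
      rule <- division_rule(p$growth_rate, p$division_volume,
                            p$base_target_v, p$axis_mode %||% "minor-axis",
                            kinds = p$kinds)
      hooks <- c(hooks, list(list(every = 1L, fn = grow_and_divide(rule, events))))
    }

  t0 <- proc.time()[["elapsed"]]
  state <- run_simulation(state, ham, sched$n_mcs, hooks = hooks)
  wall <- proc.time()[["elapsed"]] - t0

  if (length(records)) write_stat_log(records, file.path(out_dir, "stats"))
  manifest <- list(config = unclass(config), seed = seed, draw = draw,
                   n_mcs = sched$n_mcs, wall_seconds = wall,
                   mcs_per_second = sched$n_mcs / max(wall, 1e-9))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(state = state, records = records, events = events$events,
                 manifest = manifest))
}

run_gol_experiment <- function(config, out_dir, seed = 1L, draw = TRUE) {
  set.seed(seed)
  g <- config$grid
  spec <- grid_spec(g$width, g$height, g$torus_x %||% TRUE,
                    g$torus_y %||% TRUE)
  state <- gol_random_init(spec, config$density %||% 0.5)
  n_steps <- config$schedule$n_steps
  png_every <- config$schedule$png_every %||% NA
  emit <- function(s, step) {
    if (draw && !is.na(png_every) && step %% png_every == 0L)
      write_frame_png(render_frame(s),
                      file.path(out_dir, sprintf("frame_%06d.png", step)))
  }
  counts <- integer(n_steps + 1L)
  t0 <- proc.time()[["elapsed"]]
  emit(state, 0L); counts[1] <- sum(state$alive)
  for (step in seq_len(n_steps)) {
    state <- gol_step(state)
    counts[step + 1L] <- sum(state$alive)
    emit(state, step)
  }
  wall <- proc.time()[["elapsed"]] - t0
  utils::write.csv(data.frame(step = 0:n_steps, alive = counts),
                   file.path(out_dir, "stats_global.csv"), row.names = FALSE)
  manifest <- list(config = unclass(config), seed = seed, draw = draw,
                   n_steps = n_steps, wall_seconds = wall)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(state = state, counts = counts, manifest = manifest))
}

#' Scalability sweep of the cell-sorting model
#'
#' For each cell count `n`, the total cell pixel budget is
#' `P_tot = 2 * n * target_v` (two kinds), the square grid side is
#' `ceil(fill_factor * sqrt(P_tot))` and cells are seeded within radius
#' `seed_radius_factor * sqrt(P_tot / pi)` of the midpoint — so doubling
#' `P_tot` doubles the grid area. Runs use the cell-sorting energies, are
#' executed without any image output, and the achieved MCS/s is recorded.
#'
#' @param cells_per_kind Integer vector of cell counts per kind.
#' @param fill_factor Grid sizing coefficient (default 1.5).
#' @param seed_radius_factor Seeding radius coefficient (default 0.8).
#' @param target_v Per-cell target volume used for the pixel budget.
#' @param n_mcs MCS per timed run.
#' @param seed RNG seed.
#' @param csv Optional path: write the results as CSV.
#' @return A data.frame with columns `cells_per_kind`, `p_tot`, `grid_side`,
#'   `seed_radius`, `wall_seconds`, `mcs_per_second`.
#' @export
scalability_sweep <- function(cells_per_kind = c(1, 5, 10, 50, 100, 500, 1000),
                              fill_factor = 1.5, seed_radius_factor = 0.8,
                              target_v = 125, n_mcs = 100, seed = 1L,
                              csv = NULL) {
  base <- benchmark_config("cell_sorting")
  rows <- lapply(cells_per_kind, function(n) {
    p_tot <- 2 * n * target_v
    side <- ceiling(fill_factor * sqrt(p_tot))
    if (side < 3) stop("grid side ", side, " below minimum", call. = FALSE)
    radius <- seed_radius_factor * sqrt(p_tot / pi)
    cfg <- merge_config(unclass(base), list(
      grid = list(width = side, height = side),
      hamiltonian = list(target_v = c(target_v, target_v)),
      processes = list(list(type = "seed_circle", counts = c(n, n),
                            kinds = c(1, 2), radius = radius, burn_in = 30)),
      schedule = list(n_mcs = n_mcs, log_every = NA, png_every = NA)))
    cfg <- validate_config(cfg)
    ham <- config_hamiltonian(cfg)
    set.seed(seed)
    state <- config_initial_state(cfg, ham)
    t0 <- proc.time()[["elapsed"]]
    state <- run_simulation(state, ham, n_mcs)
    wall <- proc.time()[["elapsed"]] - t0
    data.frame(cells_per_kind = n, p_tot = p_tot, grid_side = side,
               seed_radius = radius, wall_seconds = wall,
               mcs_per_second = n_mcs / max(wall, 1e-9))
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
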