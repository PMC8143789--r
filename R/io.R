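#' Default kind palette
#'
#' A fixed, documented palette so regression images are comparable across
#' runs: background is white, cell kinds cycle through a colour-blind-safe
#' sequence.
#'
#' @param n_kinds Number of non-background kinds.
#' @return Character vector of hex colours, background first.
#' @export
default_palette <- function(n_kinds) {
  base <- c("#333333", "#D55E00", "#0072B2", "#009E73", "#CC79A7",
            "#E69F00", "#56B4E9", "#F0E442")
  c("#FFFFFF", rep_len(base, max(n_kinds, 1L))[seq_len(n_kinds)])
}

#' Render a lattice state to a raster frame
#'
#' One image pixel per lattice site (times an integer zoom), coloured by
#' kind. Modes: `"kind"` fills every cell pixel with its kind colour;
#' `"cell"` alternates two shades per kind by cell id so individual cells are
#' distinguishable; `"border"` draws only pixels that touch a different
#' identity (cheaper to draw, used by the scalability protocol). Rendering
#' is a deterministic function of the state.
#'
#' @param state A `cpm_state` or `ca_state`.
#' @param palette Hex colours, background first; defaults to
#'   [default_palette()].
#' @param draw_mode One of `"kind"`, `"cell"`, `"border"`.
#' @param zoom Integer magnification.
#' @return A character matrix of hex colours (height x width rows so it can
#'   be passed to `as.raster`), class `cpm_frame`.
#' @export
render_frame <- function(state, palette = NULL,
                         draw_mode = c("kind", "cell", "border"), zoom = 1L) {
  draw_mode <- match.arg(draw_mode)
  if (inherits(state, "ca_state")) {
    id <- matrix(as.integer(state$alive), nrow = state$spec$width)
    kind_of <- c(0L, 1L)
    n_kinds <- 1L
  } else {
    id <- state$identity
    kind_of <- state$kind_of
    n_kinds <- state$n_kinds
  }
  if (is.null(palette)) palette <- default_palette(n_kinds)
  if (length(palette) < n_kinds + 1L)
    stop("palette must cover the background plus all ", n_kinds, " kinds",
         call. = FALSE)
  kind_px <- matrix(kind_of[id + 1L], nrow = nrow(id))
  col <- matrix(palette[kind_px + 1L], nrow = nrow(id))
  if (draw_mode == "cell") {
    shade <- function(hex, f) {
      m <- grDevices::col2rgb(hex)
      grDevices::rgb(t(pmin(255, m * f + (1 - f) * 255)), maxColorValue = 255)
    }
    odd <- id %% 2L == 1L & id > 0L
    col[odd] <- shade(col[odd], 0.6)
  } else if (draw_mode == "border") {
    spec <- if (inherits(state, "ca_state")) state$spec else state$spec
    border <- matrix(FALSE, nrow(id), ncol(id))
    k <- moore_kernel()
    for (r in seq_len(nrow(k))) {
      sp <- shifted_pairs(spec, id, k[r, 1], k[r, 2])
      sub <- matrix(FALSE, nrow(id), ncol(id))
      sub[sp$xi + 1L, sp$yi + 1L] <- sp$a != sp$b
      border <- border | sub
    }
    col[!border & id > 0L] <- palette[1]
  }
  # transpose: raster rows are y (downward), columns are x
  fr <- t(col)
  if (zoom > 1L)
    fr <- fr[rep(seq_len(nrow(fr)), each = zoom),
             rep(seq_len(ncol(fr)), each = zoom), drop = FALSE]
  structure(fr, class = c("cpm_frame", class(fr)))
}

#' Write a rendered frame as PNG
#'
#' @param frame A `cpm_frame` from [render_frame()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  grDevices::png(path, width = ncol(frame), height = nrow(frame))
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(unclass(frame)),
                        0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}

# NB: schedule's log_every/png_every stay absent (not NA) when unset so the
# normalised form survives a JSON round-trip; readers use `%||% NA`.
config_defaults <- list(
  grid = list(torus_x = TRUE, torus_y = TRUE),
  schedule = list(),
  outputs = list(draw_mode = "kind", zoom = 1)
)

known_keys <- list(
  top = c("grid", "kinds", "hamiltonian", "processes", "schedule", "outputs"),
  grid = c("width", "height", "torus_x", "torus_y"),
  hamiltonian = c("temperature", "J", "lambda_v", "target_v", "lambda_p",
                  "target_p", "lambda_act", "max_act"),
  schedule = c("n_mcs", "log_every", "png_every", "seed"),
  outputs = c("draw_mode", "zoom"),
  seed_circle = c("type", "counts", "kinds", "center", "radius", "burn_in"),
  obstacles = c("type", "centers", "radius", "kind"),
  grow_divide = c("type", "growth_rate", "division_volume", "base_target_v",
                  "axis_mode", "kinds")
)

#' Validate and normalise a simulation configuration
#'
#' Checks the full declarative run description (grid, kinds, Hamiltonian,
#' processes, schedule, outputs) against the documented schema, collecting
#' *all* violations rather than stopping at the first. Unknown keys are
#' rejected; `J` must be square, symmetric and cover the background plus all
#' kinds; missing optional blocks are filled with documented defaults.
#'
#' @param raw A nested list, typically from [load_config()].
#' @return A normalised list of class `cpm_config`.
#' @export
validate_config <- function(raw) {
  errs <- character()
  bad_keys <- function(block, name) {
    extra <- setdiff(names(block), known_keys[[name]])
    if (length(extra))
      errs <<- c(errs, paste0("unknown key(s) in ", name, ": ",
                              paste(extra, collapse = ", ")))
  }
  if (!is.list(raw)) return(stop("config must be a list", call. = FALSE))
  bad_keys(raw, "top")
  for (req in c("grid", "kinds", "hamiltonian", "schedule"))
    if (is.null(raw[[req]])) errs <- c(errs, paste0("missing block: ", req))

  if (!is.null(raw$grid)) {
    bad_keys(raw$grid, "grid")
    g <- utils::modifyList(config_defaults$grid, raw$grid)
    if (is.null(g$width) || is.null(g$height))
      errs <- c(errs, "grid needs width and height")
    else if (g$width < 3 || g$height < 3)
      errs <- c(errs, "grid dimensions must be >= 3")
    raw$grid <- g
  }

  n_kinds <- length(raw$kinds)
  if (n_kinds < 1) errs <- c(errs, "at least one non-background kind required")

  if (!is.null(raw$hamiltonian)) {
    bad_keys(raw$hamiltonian, "hamiltonian")
    h <- raw$hamiltonian
    if (is.null(h$temperature) || h$temperature <= 0)
      errs <- c(errs, "hamiltonian temperature must be > 0")
    if (!is.null(h$J)) {
      J <- do.call(rbind, lapply(h$J, as.numeric))
      if (nrow(J) != ncol(J) || nrow(J) != n_kinds + 1)
        errs <- c(errs, sprintf(
          "J must be %d x %d (background + %d kinds)", n_kinds + 1,
          n_kinds + 1, n_kinds))
      else {
        asym <- which(J != t(J), arr.ind = TRUE)
        if (nrow(asym)) {
          i <- asym[1, 1]; j <- asym[1, 2]
          errs <- c(errs, sprintf(
            "J is not symmetric: J[%d,%d] = %g but J[%d,%d] = %g",
            i, j, J[i, j], j, i, J[j, i]))
        }
      }
    }
    for (nm in c("lambda_v", "target_v", "lambda_p", "target_p",
                 "lambda_act", "max_act"))
      if (!is.null(h[[nm]]) && !length(h[[nm]]) %in% c(1L, n_kinds, n_kinds + 1L))
        errs <- c(errs, paste0("hamiltonian ", nm,
                               " must have length 1, n_kinds or n_kinds + 1"))
  }

  if (!is.null(raw$processes)) {
    for (i in seq_along(raw$processes)) {
      p <- raw$processes[[i]]
      if (is.null(p$type) || !p$type %in% c("seed_circle", "obstacles",
                                            "grow_divide"))
        errs <- c(errs, paste0("process ", i, ": unknown type '",
                               p$type %||% "<missing>", "'"))
      else bad_keys(p, p$type)
    }
  }

  if (!is.null(raw$schedule)) {
    bad_keys(raw$schedule, "schedule")
    s <- utils::modifyList(config_defaults$schedule, raw$schedule)
    if (is.null(s$n_mcs) || s$n_mcs < 1)
      errs <- c(errs, "schedule n_mcs must be >= 1")
    raw$schedule <- s
  }
  raw$outputs <- utils::modifyList(config_defaults$outputs,
                                   raw$outputs %||% list())
  bad_keys(raw$outputs, "outputs")
  if (!raw$outputs$draw_mode %in% c("kind", "cell", "border"))
    errs <- c(errs, "outputs draw_mode must be kind, cell or border")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  class(raw) <- "cpm_config"
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load / save a simulation configuration (JSON)
#'
#' Configurations are plain JSON following the schema enforced by
#' [validate_config()]. `save_config()` writes the normalised form, so
#' `save_config(load_config(x))` is a fixed point.
#'
#' @param path File path.
#' @return `load_config`: a validated `cpm_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config A `cpm_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Build the Hamiltonian declared by a configuration
#'
#' @param config A `cpm_config`.
#' @return A [hamiltonian_spec()].
#' @export
config_hamiltonian <- function(config) {
  h <- config$hamiltonian
  n_kinds <- length(config$kinds)
  J <- if (is.null(h$J)) NULL else do.call(rbind, lapply(h$J, as.numeric))
  hamiltonian_spec(
    n_kinds, J = J,
    lambda_v = h$lambda_v %||% 0, target_v = h$target_v %||% 0,
    lambda_p = h$lambda_p %||% 0, target_p = h$target_p %||% 0,
    lambda_act = h$lambda_act %||% 0, max_act = h$max_act %||% 0,
    temperature = h$temperature)
}

#' Build the initial lattice declared by a configuration
#'
#' Creates the empty lattice and applies the configured processes that act
#' at initialisation (circle seeding, obstacles). Growth/division hooks are
#' attached by [run_experiment()].
#'
#' @param config A `cpm_config`.
#' @param ham Hamiltonian (for seeding burn-in); built from the config when
#'   omitted.
#' @return A `cpm_state`.
#' @export
config_initial_state <- function(config, ham = NULL) {
  g <- config$grid
  spec <- grid_spec(g$width, g$height, g$torus_x, g$torus_y)
  state <- new_lattice(spec, n_kinds = length(config$kinds))
  if (is.null(ham)) ham <- config_hamiltonian(config)
  for (p in config$processes %||% list()) {
    if (p$type == "seed_circle") {
      counts <- as.integer(p$counts)
      names(counts) <- as.integer(p$kinds %||% seq_along(counts))
      plan <- seeding_plan(counts,
                           region_center = if (is.null(p$center)) NULL
                                           else as.numeric(p$center),
                           region_radius = p$radius,
                           burn_in_mcs = p$burn_in %||% 0L)
      state <- seed_cells_in_circle(state, plan, ham)
    } else if (p$type == "obstacles") {
      centers <- lapply(p$centers, as.numeric)
      state <- place_obstacles(state, centers, p$radius, as.integer(p$kind))
    }
  }
  state
}
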