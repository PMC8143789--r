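#' Seeding plan for circle-confined initial conditions
#'
#' @param n_cells_per_kind Named or positional integer vector: number of
#'   cells to seed for each kind (names are kind ids; unnamed vectors are
#'   taken as kinds `1, 2, ...`).
#' @param region_center `c(x, y)`; defaults (in [seed_cells_in_circle()]) to
#'   the grid midpoint.
#' @param region_radius Seeding radius in pixels; must not exceed half the
#'   smaller grid dimension.
#' @param burn_in_mcs MCS of relaxation under the Hamiltonian after seeding,
#'   letting single-pixel seeds grow toward their target volume.
#' @return An object of class `cpm_seeding_plan`.
#' @export
seeding_plan <- function(n_cells_per_kind, region_center = NULL,
                         region_radius, burn_in_mcs = 0L) {
  n <- as.integer(n_cells_per_kind)
  if (any(n < 0)) stop("cell counts must be >= 0", call. = FALSE)
  kinds <- if (!is.null(names(n_cells_per_kind)))
    as.integer(names(n_cells_per_kind)) else seq_along(n)
  structure(list(kinds = kinds, counts = n,
                 region_center = region_center,
                 region_radius = as.numeric(region_radius),
                 burn_in_mcs = as.integer(burn_in_mcs)),
            class = "cpm_seeding_plan")
}

#' Seed single-pixel cells within a circle
#'
#' Places each requested cell as a single-pixel seed at a uniform random
#' unoccupied site within `region_radius` of the region center (torus
#' metric). Each seed receives a fresh cell id. An optional burn-in then
#' relaxes the state under the supplied Hamiltonian so the volume constraint
#' grows seeds toward their targets.
#'
#' @param state A `cpm_state`.
#' @param plan A [seeding_plan()].
#' @param ham Hamiltonian used for the burn-in; required if
#'   `plan$burn_in_mcs > 0`.
#' @return The updated state.
#' @export
seed_cells_in_circle <- function(state, plan, ham = NULL) {
  spec <- state$spec
  center <- plan$region_center
  if (is.null(center)) center <- c(spec$width / 2, spec$height / 2)
  if (plan$region_radius > min(spec$width, spec$height) / 2)
    stop("seeding radius exceeds half the smaller grid dimension",
         call. = FALSE)
  xs <- rep(0:(spec$width - 1L), times = spec$height)
  ys <- rep(0:(spec$height - 1L), each = spec$width)
  inside <- torus_dist2(spec, xs, ys, center[[1]], center[[2]]) <=
    plan$region_radius^2
  free <- inside & as.integer(state$identity) == 0L
  idx <- which(free)
  total <- sum(plan$counts)
  if (total > length(idx))
    stop("requested ", total, " seeds but only ", length(idx),
         " free sites in the region", call. = FALSE)
  if (total == 0L) return(state)
  chosen <- sample(idx, total)
  k_seq <- rep(plan$kinds, plan$counts)
  for (i in seq_len(total)) {
    reg <- register_cell(state, k_seq[i])
    state <- reg$state
    state <- set_pixel(state, c(xs[chosen[i]], ys[chosen[i]]), reg$id)
  }
  if (plan$burn_in_mcs > 0L) {
    if (is.null(ham)) stop("burn-in requested but no Hamiltonian supplied",
                           call. = FALSE)
    state <- run_mcs(state, ham, plan$burn_in_mcs)
  }
  state
}

#' Place immutable obstacle discs
#'
#' Each disc becomes a fresh cell of the obstacle kind, and the kind is
#' marked immutable: the dynamics never select obstacle pixels as copy
#' targets nor copy their identity outward, so the pixel sets are invariant
#' for the whole run. Adhesion with obstacles stays expressible through `J`.
#'
#' @param state A `cpm_state`.
#' @param centers List (or n x 2 matrix) of disc centers `c(x, y)`.
#' @param radius Disc radius in pixels.
#' @param kind Obstacle kind id.
#' @return The updated state.
#' @export
place_obstacles <- function(state, centers, radius, kind) {
  if (is.matrix(centers)) centers <- split(centers, seq_len(nrow(centers)))
  for (ctr in centers) {
    sites <- disc_sites(state$spec, ctr, radius)
    occ <- state$identity[cbind(sites[, 1] + 1L, sites[, 2] + 1L)]
    if (any(occ != 0L))
      stop("obstacle disc overlaps an existing cell", call. = FALSE)
    reg <- register_cell(state, kind)
    state <- reg$state
    for (r in seq_len(nrow(sites)))
      state <- set_pixel(state, sites[r, ], reg$id)
  }
  set_kind_immutable(state, kind, TRUE)
}

#' Cell growth and division rule
#'
#' @param growth_rate Target-volume increment per MCS (pixels/MCS).
#' @param division_volume Actual-volume threshold (pixels, >= 2) at which a
#'   cell divides.
#' @param base_target_v Target volume daughters are reset to after division.
#' @param axis_mode `"minor-axis"` (split perpendicular to the principal
#'   axis, through the centroid) or `"random"` (random orientation).
#' @param kinds Kind ids the rule applies to (default: all cell kinds).
#' @return An object of class `cpm_division_rule`.
#' @export
division_rule <- function(growth_rate, division_volume, base_target_v,
                          axis_mode = c("minor-axis", "random"),
                          kinds = NULL) {
  axis_mode <- match.arg(axis_mode)
  division_volume <- as.integer(division_volume)
  if (division_volume < 2L) stop("division_volume must be >= 2", call. = FALSE)
  structure(list(growth_rate = as.numeric(growth_rate),
                 division_volume = division_volume,
                 base_target_v = as.numeric(base_target_v),
                 axis_mode = axis_mode, kinds = kinds),
            class = "cpm_division_rule")
}

# Torus-unwrapped pixel coordinates of a cell, centered near its centroid.
cell_pixel_coords <- function(state, cell_id) {
  w <- which(state$identity == cell_id)
  if (!length(w)) stop("cell ", cell_id, " is empty", call. = FALSE)
  W <- state$spec$width; H <- state$spec$height
  x <- (w - 1L) %% W
  y <- (w - 1L) %/% W
  cen <- centroid(state, cell_id)
  if (state$spec$torus_x) x <- cen[1] + ((x - cen[1] + W / 2) %% W) - W / 2
  if (state$spec$torus_y) y <- cen[2] + ((y - cen[2] + H / 2) %% H) - H / 2
  cbind(x = x, y = y)
}

#' Split one cell in two
#'
#' Partitions the cell's pixels by a line through its centroid. In
#' `"minor-axis"` mode the line is perpendicular to the principal axis (the
#' eigenvector of the larger eigenvalue of the second central moments,
#' torus-unwrapped around the centroid), so daughters separate along the
#' cell's long axis; `"random"` mode draws a uniform orientation. One side
#' keeps the parent id, the other gets a fresh id of the same kind; both
#' target volumes are reset to `rule$base_target_v`. Pixels exactly on the
#' line are assigned to balance daughter volumes, ties broken
#' lexicographically.
#'
#' @param state A `cpm_state`.
#' @param cell_id Id of the cell to divide (volume >= 2, else skipped with a
#'   warning).
#' @param rule A [division_rule()].
#' @return A list with `state` and `event` (NULL if skipped; otherwise a
#'   data.frame row with parent/daughter ids and volumes).
#' @export
divide_cell <- function(state, cell_id, rule) {
  v <- state$volume_of[cell_id + 1L]
  if (v < 2L) {
    warning("cell ", cell_id, " has volume < 2; division skipped")
    return(list(state = state, event = NULL))
  }
  px <- cell_pixel_coords(state, cell_id)
  ctr <- colMeans(px)
  dx <- px[, 1] - ctr[1]; dy <- px[, 2] - ctr[2]
  if (rule$axis_mode == "random") {
    th <- stats::runif(1, 0, pi)
    ax <- c(cos(th), sin(th))
  } else {
    # principal axis from second central moments
    sxx <- mean(dx * dx); syy <- mean(dy * dy); sxy <- mean(dx * dy)
    e <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
    ax <- e$vectors[, 1]
  }
  # canonical orientation (eigenvector sign is otherwise arbitrary): the
  # fresh id always goes to the +axis side, deterministically
  if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
  proj <- dx * ax[1] + dy * ax[2]
  side <- proj > 1e-9
  on_line <- abs(proj) <= 1e-9
  if (any(on_line)) {
    # pixels exactly on the split line: hand each (in lexicographic order)
    # to whichever daughter is currently smaller; ties go to the keep side
    ord <- order(px[on_line, 1], px[on_line, 2])
    for (i in which(on_line)[ord]) {
      n_new <- sum(side)
      side[i] <- n_new < nrow(px) - n_new - 1L
    }
  }
  if (all(side) || !any(side)) {
    # degenerate geometry (e.g. all pixels projected together): median split
    side <- proj > stats::median(proj)
    if (all(side) || !any(side)) side <- seq_len(nrow(px)) > nrow(px) / 2
  }
  reg <- register_cell(state, state$kind_of[cell_id + 1L],
                       target_v = rule$base_target_v)
  state <- reg$state
  W <- state$spec$width; H <- state$spec$height
  for (i in which(side)) {
    sx <- ((round(px[i, 1]) %% W) + W) %% W
    sy <- ((round(px[i, 2]) %% H) + H) %% H
    state <- set_pixel(state, c(sx, sy), reg$id,
                       activity = state$activity[sx + 1L, sy + 1L])
  }
  state$target_v_of[cell_id + 1L] <- rule$base_target_v
  list(state = state,
       event = data.frame(parent = cell_id, daughter = reg$id,
                          parent_volume = v,
                          vol_kept = v - sum(side), vol_new = sum(side)))
}

#' Growth-and-division per-MCS hook
#'
#' Returns a hook `function(state, mcs)` for [run_simulation()]: each MCS it
#' raises every eligible cell's target volume by `growth_rate`, and divides
#' any cell whose actual volume has reached `division_volume`. Division
#' events are appended to `event_log` (an environment with a `events`
#' data.frame) when one is supplied.
#'
#' @param rule A [division_rule()].
#' @param event_log Optional environment collecting division events.
#' @return A hook function.
#' @export
grow_and_divide <- function(rule, event_log = NULL) {
  function(state, mcs) {
    if (mcs == 0L) return(state)
    ids <- which(state$volume_of > 0) - 1L
    ids <- ids[ids > 0L]
    if (!is.null(rule$kinds))
      ids <- ids[state$kind_of[ids + 1L] %in% rule$kinds]
    ids <- ids[!state$immutable_kind[state$kind_of[ids + 1L] + 1L]]
    if (!length(ids)) return(state)
    tv <- state$target_v_of[ids + 1L]
    tv[is.na(tv)] <- rule$base_target_v
    state$target_v_of[ids + 1L] <- tv + rule$growth_rate
    for (id in ids[state$volume_of[ids + 1L] >= rule$division_volume]) {
      res <- divide_cell(state, id, rule)
      state <- res$state
      if (!is.null(event_log) && !is.null(res$event))
        event_log$events <- rbind(event_log$events,
                                  cbind(mcs = mcs, res$event))
    }
    state
  }
}
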