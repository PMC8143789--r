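#' Grid geometry specification
#'
#' Describes the 2D lattice on which a simulation lives: its dimensions and
#' whether each axis wraps around (torus) or is bounded. Coordinates are
#' 0-based integers `(x, y)` with `x` indexing width and `y` indexing height;
#' `y` increases downward in rendered images.
#'
#' @param width,height Grid dimensions in pixels; both must be at least 3.
#' @param torus_x,torus_y Logical; whether the x / y axis is periodic.
#'   Defaults to a full torus, the usual choice for CPM benchmarks because it
#'   avoids wall artefacts.
#' @return An object of class `cpm_grid_spec`.
#' @examples
#' grid_spec(50, 50)
#' grid_spec(20, 10, torus_x = FALSE, torus_y = FALSE)
#' @export
grid_spec <- function(width, height, torus_x = TRUE, torus_y = TRUE) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 3L || height < 3L)
    stop("grid dimensions must be integers >= 3", call. = FALSE)
  structure(
    list(width = width, height = height,
         torus_x = isTRUE(torus_x), torus_y = isTRUE(torus_y)),
    class = "cpm_grid_spec"
  )
}

#' @export
print.cpm_grid_spec <- function(x, ...) {
  bx <- if (x$torus_x) "torus" else "bounded"
  by <- if (x$torus_y) "torus" else "bounded"
  cat(sprintf("<grid %d x %d, x: %s, y: %s>\n", x$width, x$height, bx, by))
  invisible(x)
}

#' Neighborhood kernels
#'
#' A kernel is an ordered integer matrix of `(dx, dy)` offsets, excluding
#' `(0, 0)`. The Moore (8-neighbor) kernel is the package default for copy
#' attempts, interface energies and connectivity.
#'
#' @return An integer matrix with columns `dx`, `dy`.
#' @export
moore_kernel <- function() {
  k <- expand.grid(dx = -1:1, dy = -1:1)
  k <- as.matrix(k[!(k$dx == 0 & k$dy == 0), ])
  storage.mode(k) <- "integer"
  rownames(k) <- NULL
  k
}

#' @rdname moore_kernel
#' @export
von_neumann_kernel <- function() {
  k <- matrix(c(0L, -1L, -1L, 0L, 1L, 0L, 0L, 1L), ncol = 2, byrow = TRUE)
  colnames(k) <- c("dx", "dy")
  k
}

wrap_coord <- function(v, n, torus) {
  if (torus) v %% n else v
}

#' Neighbor sites of a lattice site
#'
#' Applies the kernel offsets to `site`, wrapping on torus axes and dropping
#' offsets that fall off a bounded axis. The order of the returned sites
#' follows the kernel order deterministically.
#'
#' @param spec A [grid_spec()].
#' @param site Integer vector `c(x, y)`, 0-based, canonical (in range).
#' @param kernel Offset matrix, default [moore_kernel()].
#' @return Integer matrix with columns `x`, `y`, one row per in-grid neighbor.
#' @export
neighbors <- function(spec, site, kernel = moore_kernel()) {
  x <- site[[1]] + kernel[, 1]
  y <- site[[2]] + kernel[, 2]
  keep <- rep(TRUE, length(x))
  if (spec$torus_x) x <- x %% spec$width else keep <- keep & x >= 0 & x < spec$width
  if (spec$torus_y) y <- y %% spec$height else keep <- keep & y >= 0 & y < spec$height
  out <- cbind(x = as.integer(x[keep]), y = as.integer(y[keep]))
  out
}

#' Create an empty lattice state
#'
#' The lattice state couples the grid of pixel identities with per-cell
#' bookkeeping: each pixel holds a cell id (0 = background), each cell id maps
#' to a cell kind (0 = background kind), and cached volumes are maintained
#' incrementally so they always equal an exact recount. An activity matrix
#' supports the Act protrusion model (0 everywhere when unused).
#'
#' @param spec A [grid_spec()].
#' @param n_kinds Number of non-background cell kinds to register (kinds are
#'   numbered `1..n_kinds`; kind 0 is the background).
#' @return An object of class `cpm_state`.
#' @export
new_lattice <- function(spec, n_kinds = 1L) {
  stopifnot(inherits(spec, "cpm_grid_spec"))
  n_kinds <- as.integer(n_kinds)
  if (n_kinds < 0L) stop("n_kinds must be >= 0", call. = FALSE)
  structure(
    list(
      spec = spec,
      identity = matrix(0L, nrow = spec$width, ncol = spec$height),
      activity = matrix(0L, nrow = spec$width, ncol = spec$height),
      kind_of = 0L,                                  # index = cell id + 1
      volume_of = spec$width * spec$height,          # id 0 = background count
      target_v_of = NA_real_,                        # per-cell target volume
      immutable_kind = rep(FALSE, n_kinds + 1L),     # index = kind + 1
      n_kinds = n_kinds
    ),
    class = "cpm_state"
  )
}

#' @export
print.cpm_state <- function(x, ...) {
  ncell <- sum(x$volume_of[-1] > 0)
  cat(sprintf("<cpm_state %d x %d, %d kinds, %d live cells, %d background px>\n",
              x$spec$width, x$spec$height, x$n_kinds, ncell, x$volume_of[1]))
  invisible(x)
}

#' Register a new cell id
#'
#' Cell ids are assigned sequentially and never reused within a run. The new
#' cell starts with zero pixels.
#'
#' @param state A `cpm_state`.
#' @param kind Kind id in `1..n_kinds`.
#' @param target_v Optional per-cell target volume (used by the growth /
#'   division process); `NA` means "use the kind default from the Hamiltonian".
#' @return A list with elements `state` (updated) and `id` (the new cell id).
#' @export
register_cell <- function(state, kind, target_v = NA_real_) {
  kind <- as.integer(kind)
  if (kind < 1L || kind > state$n_kinds)
    stop("kind ", kind, " not registered (n_kinds = ", state$n_kinds, ")",
         call. = FALSE)
  id <- length(state$kind_of)          # next id (ids are 0-based)
  state$kind_of <- c(state$kind_of, kind)
  state$volume_of <- c(state$volume_of, 0L)
  state$target_v_of <- c(state$target_v_of, target_v)
  list(state = state, id = id)
}

#' Overwrite one pixel's identity
#'
#' The mutation primitive of the CPM: sets the identity at `site` and updates
#' the cached volumes of both old and new owner. Activity at the site is set
#' to `activity` (0 by default; the dynamics pass the copying kind's
#' `max_act`); background pixels always carry activity 0.
#'
#' @param state A `cpm_state`.
#' @param site `c(x, y)`, 0-based canonical coordinates.
#' @param new_id A registered cell id (or 0 for background).
#' @param activity Activity value to stamp on the site.
#' @return The updated state.
#' @export
set_pixel <- function(state, site, new_id, activity = 0L) {
  new_id <- as.integer(new_id)
  if (new_id < 0L || new_id >= length(state$kind_of))
    stop("cell id ", new_id, " is not registered", call. = FALSE)
  i <- site[[1]] + 1L; j <- site[[2]] + 1L
  old_id <- state$identity[i, j]
  if (old_id == new_id) return(state)
  state$identity[i, j] <- new_id
  state$volume_of[old_id + 1L] <- state$volume_of[old_id + 1L] - 1L
  state$volume_of[new_id + 1L] <- state$volume_of[new_id + 1L] + 1L
  state$activity[i, j] <- if (new_id == 0L) 0L else as.integer(activity)
  state
}

#' Paint a disc-shaped cell (fixture generator)
#'
#' Assigns every site within Euclidean distance `radius` of `center` (torus
#' metric on periodic axes) to `cell_id`. Used to build deterministic test
#' fixtures and obstacle discs.
#'
#' @inheritParams set_pixel
#' @param center `c(x, y)` disc center.
#' @param radius Non-negative radius in pixels.
#' @param cell_id Registered cell id.
#' @return The updated state.
#' @export
make_disc_cell <- function(state, center, radius, cell_id) {
  sites <- disc_sites(state$spec, center, radius)
  for (r in seq_len(nrow(sites)))
    state <- set_pixel(state, sites[r, ], cell_id)
  state
}

# All canonical sites within torus-metric distance <= radius of center.
disc_sites <- function(spec, center, radius) {
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, , drop = FALSE]
  x <- center[[1]] + off$dx
  y <- center[[2]] + off$dy
  keep <- rep(TRUE, length(x))
  if (spec$torus_x) x <- x %% spec$width else keep <- keep & x >= 0 & x < spec$width
  if (spec$torus_y) y <- y %% spec$height else keep <- keep & y >= 0 & y < spec$height
  unique(cbind(x = as.integer(x[keep]), y = as.integer(y[keep])))
}

# Torus-aware squared distance between coordinate vectors and a point.
torus_dist2 <- function(spec, x, y, cx, cy) {
  dx <- abs(x - cx); dy <- abs(y - cy)
  if (spec$torus_x) dx <- pmin(dx, spec$width - dx)
  if (spec$torus_y) dy <- pmin(dy, spec$height - dy)
  dx^2 + dy^2
}

#' Lattice round-trip through a plain integer matrix
#'
#' `lattice_to_matrix()` returns the raw identity matrix (width x height,
#' `[x+1, y+1]` indexing); `lattice_from_matrix()` rebuilds a consistent state
#' from such a matrix plus a per-cell kind map, recomputing all cached
#' volumes. Together they give a plain-text serialisation for fixtures.
#'
#' @param state A `cpm_state`.
#' @return For `lattice_to_matrix`, an integer matrix.
#' @export
lattice_to_matrix <- function(state) state$identity

#' @rdname lattice_to_matrix
#' @param spec A [grid_spec()] matching the matrix dimensions.
#' @param m Integer identity matrix, `m[x+1, y+1]`.
#' @param kind_of Integer vector mapping cell id to kind, indexed `id + 1`
#'   (so `kind_of[1]` must be 0, the background kind).
#' @export
lattice_from_matrix <- function(spec, m, kind_of) {
  stopifnot(nrow(m) == spec$width, ncol(m) == spec$height)
  kind_of <- as.integer(kind_of)
  if (kind_of[1] != 0L) stop("kind_of[1] (background) must be 0", call. = FALSE)
  ids <- sort(unique(as.integer(m)))
  if (any(ids < 0L) || max(ids) + 1L > length(kind_of))
    stop("identity matrix contains unregistered cell ids", call. = FALSE)
  st <- new_lattice(spec, n_kinds = max(kind_of))
  st$identity <- matrix(as.integer(m), nrow = spec$width)
  st$kind_of <- kind_of
  st$volume_of <- as.integer(tabulate(as.integer(m) + 1L,
                                      nbins = length(kind_of)))
  st$target_v_of <- rep(NA_real_, length(kind_of))
  st
}

#' Recount cell volumes from scratch
#'
#' Brute-force recount of pixels per cell id, used as the oracle for the
#' incremental volume bookkeeping.
#'
#' @param state A `cpm_state`.
#' @return Integer vector indexed `id + 1`, aligned with `state$volume_of`.
#' @export
recount_volumes <- function(state) {
  as.integer(tabulate(as.integer(state$identity) + 1L,
                      nbins = length(state$kind_of)))
}

#' Mark a cell kind as immutable (barrier)
#'
#' Pixels owned by an immutable kind are never selected as copy targets, and
#' their identity is never copied outward; obstacle cells use this.
#'
#' @param state A `cpm_state`.
#' @param kind Kind id.
#' @param immutable Logical.
#' @return The updated state.
#' @export
set_kind_immutable <- function(state, kind, immutable = TRUE) {
  kind <- as.integer(kind)
  if (kind < 0L || kind > state$n_kinds) stop("unknown kind ", kind, call. = FALSE)
  state$immutable_kind[kind + 1L] <- isTRUE(immutable)
  state
}
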