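#' Game-of-Life state
#'
#' Conway's Game of Life on the same lattice geometry as the CPM: a logical
#' matrix of alive flags, Moore neighborhood, synchronous updates.
#'
#' @param spec A [grid_spec()].
#' @param alive Logical matrix (`width x height`, `[x+1, y+1]`), default all
#'   dead.
#' @return An object of class `ca_state`.
#' @export
ca_state <- function(spec, alive = NULL) {
  if (is.null(alive))
    alive <- matrix(FALSE, nrow = spec$width, ncol = spec$height)
  stopifnot(nrow(alive) == spec$width, ncol(alive) == spec$height)
  structure(list(spec = spec, alive = alive), class = "ca_state")
}

#' Random Game-of-Life initial condition
#'
#' Each site is independently alive with probability `density`.
#'
#' @param spec A [grid_spec()].
#' @param density Probability in `[0, 1]`; 0.5 by default.
#' @return A `ca_state`.
#' @export
gol_random_init <- function(spec, density = 0.5) {
  if (density < 0 || density > 1) stop("density must be in [0, 1]", call. = FALSE)
  a <- matrix(stats::runif(spec$width * spec$height) < density,
              nrow = spec$width)
  ca_state(spec, a)
}

# Shift a logical matrix by (dx, dy), wrapping on torus axes and padding
# with FALSE (dead) on bounded axes.
shift_logical <- function(spec, m, dx, dy) {
  W <- spec$width; H <- spec$height
  out <- matrix(FALSE, W, H)
  xs <- 0:(W - 1L); ys <- 0:(H - 1L)
  nx <- xs + dx; ny <- ys + dy
  if (spec$torus_x) { nx <- nx %% W; okx <- rep(TRUE, W) }
  else okx <- nx >= 0 & nx < W
  if (spec$torus_y) { ny <- ny %% H; oky <- rep(TRUE, H) }
  else oky <- ny >= 0 & ny < H
  out[xs[okx] + 1L, ys[oky] + 1L] <- m[nx[okx] + 1L, ny[oky] + 1L]
  out
}

#' One synchronous Game-of-Life step
#'
#' Standard B3/S23 rules on the Moore neighborhood: a live cell survives
#' with 2 or 3 live neighbors; a dead cell becomes alive with exactly 3;
#' everything else dies. Pure function: same input, same output.
#'
#' @param state A `ca_state`.
#' @return The updated `ca_state`.
#' @export
gol_step <- function(state) {
  k <- moore_kernel()
  n <- matrix(0L, state$spec$width, state$spec$height)
  for (r in seq_len(nrow(k)))
    n <- n + shift_logical(state$spec, state$alive, k[r, 1], k[r, 2])
  state$alive <- (state$alive & (n == 2L | n == 3L)) | (!state$alive & n == 3L)
  state
}
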