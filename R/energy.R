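#' Hamiltonian specification
#'
#' Bundles the energy terms and their parameters. The global energy is
#' \deqn{H = \sum_{(i,j)} J_{k(i),k(j)} \,[id_i \ne id_j]
#'       + \sum_c \lambda_V (v_c - V_c^*)^2
#'       + \sum_c \lambda_P (p_c - P^*)^2}
#' where the first sum runs over unordered neighbor pixel pairs with
#' differing identities, \eqn{v_c} is cell volume (pixel count) and
#' \eqn{p_c} the cell perimeter, counted as the number of ordered
#' (member-pixel, non-member in-grid neighbor) pairs under the kernel.
#' The Act protrusion term contributes to \eqn{\Delta H} only (see
#' [delta_act()]); it is not a state energy.
#'
#' Per-kind parameter vectors have one entry per kind including the
#' background (index 1 = kind 0); a vector of length `n_kinds` is taken to
#' describe the cell kinds, with the background entry filled with 0, and a
#' scalar is recycled over all cell kinds. Background weights must be 0.
#'
#' @param n_kinds Number of non-background kinds.
#' @param J Symmetric `(n_kinds+1) x (n_kinds+1)` matrix of interface
#'   energies indexed by kind (background first). `J[a, b]` is the energy of
#'   one heterolithic neighbor pair between kinds `a-1` and `b-1`.
#' @param lambda_v,target_v Volume-elasticity weight and target volume
#'   (pixels) per kind.
#' @param lambda_p,target_p Perimeter-elasticity weight and target interface
#'   count per kind.
#' @param lambda_act,max_act Act protrusion weight and activity memory (in
#'   MCS) per kind; `max_act = 0` disables the term for that kind.
#' @param temperature Simulation temperature `T > 0` (energy units); larger
#'   `T` accepts more unfavourable copies via `exp(-dH/T)`.
#' @param kernel Neighborhood kernel used for interfaces and copy attempts.
#' @return An object of class `cpm_hamiltonian`.
#' @export
hamiltonian_spec <- function(n_kinds, J = NULL,
                             lambda_v = 0, target_v = 0,
                             lambda_p = 0, target_p = 0,
                             lambda_act = 0, max_act = 0,
                             temperature,
                             kernel = moore_kernel()) {
  n_kinds <- as.integer(n_kinds)
  nk1 <- n_kinds + 1L
  if (is.null(J)) J <- matrix(0, nk1, nk1)
  J <- as.matrix(J)
  if (!all(dim(J) == nk1))
    stop("J must be a ", nk1, " x ", nk1, " matrix (background included)",
         call. = FALSE)
  if (!isTRUE(all.equal(J, t(J))))
    stop("J must be symmetric", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a single value > 0", call. = FALSE)

  pad <- function(v, name, weight = FALSE) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- c(0, rep(v, n_kinds))
    else if (length(v) == n_kinds) v <- c(0, v)
    else if (length(v) != nk1)
      stop(name, " must have length 1, n_kinds or n_kinds + 1", call. = FALSE)
    if (weight && v[1] != 0)
      stop("background ", name, " must be 0", call. = FALSE)
    if (weight && any(v < 0))
      stop(name, " must be non-negative", call. = FALSE)
    v
  }

  h <- structure(
    list(n_kinds = n_kinds, J = J,
         lambda_v = pad(lambda_v, "lambda_v", weight = TRUE),
         target_v = pad(target_v, "target_v"),
         lambda_p = pad(lambda_p, "lambda_p", weight = TRUE),
         target_p = pad(target_p, "target_p"),
         lambda_act = pad(lambda_act, "lambda_act", weight = TRUE),
         max_act = pad(max_act, "max_act"),
         temperature = as.numeric(temperature),
         kernel = kernel),
    class = "cpm_hamiltonian")
  if (any(h$lambda_act > 0 & h$max_act == 0))
    stop("lambda_act > 0 requires max_act > 0 for that kind", call. = FALSE)
  h
}

#' @export
print.cpm_hamiltonian <- function(x, ...) {
  cat(sprintf("<hamiltonian: %d kinds, T = %g, terms:%s%s%s%s>\n",
              x$n_kinds, x$temperature,
              if (any(x$J != 0)) " adhesion" else "",
              if (any(x$lambda_v > 0)) " volume" else "",
              if (any(x$lambda_p > 0)) " perimeter" else "",
              if (any(x$lambda_act > 0)) " act" else ""))
  invisible(x)
}

check_kinds_registered <- function(state, ham) {
  if (state$n_kinds > ham$n_kinds)
    stop("state has kinds not registered in the Hamiltonian", call. = FALSE)
  invisible(TRUE)
}

# Shift an identity matrix by (dx, dy); returns list(a, b) of aligned
# value matrices restricted to pairs whose neighbor is in-grid.
shifted_pairs <- function(spec, m, dx, dy) {
  W <- spec$width; H <- spec$height
  xs <- 0:(W - 1L); ys <- 0:(H - 1L)
  if (spec$torus_x) xi <- xs else xi <- xs[xs + dx >= 0 & xs + dx < W]
  if (spec$torus_y) yi <- ys else yi <- ys[ys + dy >= 0 & ys + dy < H]
  nx <- if (spec$torus_x) (xi + dx) %% W else xi + dx
  ny <- if (spec$torus_y) (yi + dy) %% H else yi + dy
  list(a = m[xi + 1L, yi + 1L, drop = FALSE],
       b = m[nx + 1L, ny + 1L, drop = FALSE],
       xi = xi, yi = yi)
}

# Offsets covering each unordered pair exactly once (for symmetric kernels).
half_kernel <- function(kernel) {
  keep <- kernel[, 2] > 0 | (kernel[, 2] == 0 & kernel[, 1] > 0)
  kernel[keep, , drop = FALSE]
}

#' Per-cell perimeters (brute force)
#'
#' Counts, for each cell, the ordered (member pixel, non-member in-grid
#' neighbor) pairs under the kernel. Pure-R oracle; the dynamics engine keeps
#' the same quantity incrementally.
#'
#' @param state A `cpm_state`.
#' @param kernel Neighborhood kernel.
#' @return Numeric vector indexed `id + 1`.
#' @export
cell_perimeters <- function(state, kernel = moore_kernel()) {
  p <- numeric(length(state$kind_of))
  for (r in seq_len(nrow(kernel))) {
    sp <- shifted_pairs(state$spec, state$identity, kernel[r, 1], kernel[r, 2])
    diff <- sp$a != sp$b
    cnt <- tabulate(sp$a[diff] + 1L, nbins = length(p))
    p <- p + cnt
  }
  p
}

#' Global energy H (brute-force oracle)
#'
#' Computes the full Hamiltonian by direct summation over all neighbor pairs
#' and all cells. This is the reference implementation against which the
#' incremental [delta_H()] is verified; it is exact for integer parameters.
#'
#' @param state A `cpm_state`.
#' @param ham A [hamiltonian_spec()].
#' @return The energy (a single number).
#' @export
total_H <- function(state, ham) {
  check_kinds_registered(state, ham)
  H <- 0
  # adhesion: each unordered neighbor pair with differing identity once
  if (any(ham$J != 0)) {
    hk <- half_kernel(ham$kernel)
    for (r in seq_len(nrow(hk))) {
      sp <- shifted_pairs(state$spec, state$identity, hk[r, 1], hk[r, 2])
      diff <- sp$a != sp$b
      if (any(diff)) {
        ka <- state$kind_of[sp$a[diff] + 1L]
        kb <- state$kind_of[sp$b[diff] + 1L]
        H <- H + sum(ham$J[cbind(ka + 1L, kb + 1L)])
      }
    }
  }
  # all registered cells, including extinct (volume-0) ones: a cell driven
  # to zero volume still carries its quadratic penalties, which keeps the
  # incremental delta_H exactly consistent with this oracle
  ids <- seq_len(length(state$kind_of) - 1L)
  if (length(ids)) {
    kinds <- state$kind_of[ids + 1L]
    lv <- ham$lambda_v[kinds + 1L]
    if (any(lv > 0)) {
      tv <- ifelse(is.na(state$target_v_of[ids + 1L]),
                   ham$target_v[kinds + 1L], state$target_v_of[ids + 1L])
      H <- H + sum(lv * (state$volume_of[ids + 1L] - tv)^2)
    }
    lp <- ham$lambda_p[kinds + 1L]
    if (any(lp > 0)) {
      per <- cell_perimeters(state, ham$kernel)
      H <- H + sum(lp * (per[ids + 1L] - ham$target_p[kinds + 1L])^2)
    }
  }
  H
}

#' Energy change of a proposed copy
#'
#' Returns `H(after copying the source identity onto the target) - H(before)`,
#' computed incrementally from the local neighborhood, plus the Act
#' protrusion contribution when enabled. Exactly equals the [total_H()]
#' difference (plus [delta_act()]) for any valid attempt.
#'
#' @param state A `cpm_state`.
#' @param ham A [hamiltonian_spec()].
#' @param source,target Neighboring sites `c(x, y)` with differing
#'   identities; the source identity would be copied onto the target.
#' @return The energy change (a single number).
#' @export
delta_H <- function(state, ham, source, target) {
  check_kinds_registered(state, ham)
  is_ <- state$identity[source[[1]] + 1L, source[[2]] + 1L]
  it <- state$identity[target[[1]] + 1L, target[[2]] + 1L]
  if (is_ == it)
    stop("source and target identities are equal; not a valid copy attempt",
         call. = FALSE)
  per <- if (any(ham$lambda_p > 0)) cell_perimeters(state, ham$kernel)
         else numeric(length(state$kind_of))
  cpp_delta_h(state$identity, state$activity,
              as.integer(state$kind_of), as.numeric(state$volume_of),
              as.numeric(state$target_v_of), as.numeric(per),
              ham$J, ham$lambda_v, ham$target_v, ham$lambda_p, ham$target_p,
              ham$lambda_act, ham$max_act,
              state$spec$torus_x, state$spec$torus_y, ham$kernel,
              as.integer(source[[1]]), as.integer(source[[2]]),
              as.integer(target[[1]]), as.integer(target[[2]]))
}

# Geometric mean of activity over a site and its same-cell kernel neighbors;
# 0 for background sites. Pure R, used as the delta_act reference.
act_geom_mean <- function(state, site, kernel = moore_kernel()) {
  id <- state$identity[site[[1]] + 1L, site[[2]] + 1L]
  if (id == 0L) return(0)
  vals <- state$activity[site[[1]] + 1L, site[[2]] + 1L]
  nb <- neighbors(state$spec, site, kernel)
  for (r in seq_len(nrow(nb))) {
    if (state$identity[nb[r, 1] + 1L, nb[r, 2] + 1L] == id)
      vals <- c(vals, state$activity[nb[r, 1] + 1L, nb[r, 2] + 1L])
  }
  if (any(vals == 0)) return(0)
  exp(mean(log(vals)))
}

#' Act protrusion energy change
#'
#' The actin-inspired migration term: recently gained pixels carry an
#' activity value that decays by 1 each MCS; copies from active regions into
#' less active ones are favoured. For a proposed copy,
#' \deqn{\Delta H_{act} = -\frac{\lambda_{act}}{max_{act}}
#'   \left(GM_{source} - GM_{target}\right)}
#' where `GM` is the geometric mean of activity over the site and its kernel
#' neighbors belonging to the same cell as that site (background sites give
#' 0, and any zero activity in the set makes the whole GM 0). The
#' \eqn{\lambda_{act}/max_{act}} scaling uses the source pixel's kind when
#' the term is enabled for it, otherwise the target pixel's kind.
#'
#' @inheritParams delta_H
#' @return The Act contribution to the energy change.
#' @export
delta_act <- function(state, ham, source, target) {
  is_ <- state$identity[source[[1]] + 1L, source[[2]] + 1L]
  it <- state$identity[target[[1]] + 1L, target[[2]] + 1L]
  ks <- state$kind_of[is_ + 1L]; kt <- state$kind_of[it + 1L]
  k <- if (is_ != 0L && ham$max_act[ks + 1L] > 0) ks
       else if (it != 0L && ham$max_act[kt + 1L] > 0) kt
       else return(0)
  lam <- ham$lambda_act[k + 1L]; mx <- ham$max_act[k + 1L]
  if (lam == 0) return(0)
  if (mx == 0) stop("lambda_act > 0 with max_act == 0", call. = FALSE)
  gs <- act_geom_mean(state, source, ham$kernel)
  gt <- act_geom_mean(state, target, ham$kernel)
  -(lam / mx) * (gs - gt)
}

#' Metropolis acceptance probability
#'
#' Energetically favourable changes (`delta <= 0`) always succeed;
#' unfavourable ones succeed with probability `exp(-delta / temperature)`.
#'
#' @param delta Energy change of the proposed copy.
#' @param temperature Temperature `T > 0`.
#' @return Probability in `[0, 1]` (vectorised over `delta`).
#' @export
acceptance_probability <- function(delta, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a single value > 0", call. = FALSE)
  ifelse(delta <= 0, 1, exp(-delta / temperature))
}

# Resolve n independent Bernoulli acceptances for a given delta; this is the
# single code path used both by step_attempt (n = 1) and distributional tests.
resolve_acceptance <- function(delta, temperature, n = 1L) {
  p <- acceptance_probability(delta, temperature)
  stats::runif(n) < p
}
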