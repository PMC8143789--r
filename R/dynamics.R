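#' Propose a single copy attempt
#'
#' Picks a uniform random target site and a uniform random kernel neighbor
#' as the source (target-then-source sampling). Returns `NULL` (a "null
#' attempt") when the two identities are equal, when the source offset falls
#' off a bounded grid, or when either pixel belongs to an immutable
#' (barrier) kind.
#'
#' @param state A `cpm_state`.
#' @param kernel Neighborhood kernel.
#' @return A list with `source`, `target` (each `c(x, y)`), or `NULL`.
#' @export
propose_attempt <- function(state, kernel = moore_kernel()) {
  W <- state$spec$width; H <- state$spec$height
  t <- sample.int(W * H, 1L) - 1L
  tx <- t %% W; ty <- t %/% W
  r <- sample.int(nrow(kernel), 1L)
  sx <- tx + kernel[r, 1]; sy <- ty + kernel[r, 2]
  if (state$spec$torus_x) sx <- sx %% W else if (sx < 0 || sx >= W) return(NULL)
  if (state$spec$torus_y) sy <- sy %% H else if (sy < 0 || sy >= H) return(NULL)
  is_ <- state$identity[sx + 1L, sy + 1L]
  it <- state$identity[tx + 1L, ty + 1L]
  if (is_ == it) return(NULL)
  if (state$immutable_kind[state$kind_of[it + 1L] + 1L] ||
      state$immutable_kind[state$kind_of[is_ + 1L] + 1L]) return(NULL)
  list(source = c(sx, sy), target = c(tx, ty))
}

#' Resolve one copy attempt
#'
#' Computes the energy change of the attempt, accepts it with the Metropolis
#' probability [acceptance_probability()], and on acceptance applies the copy
#' and stamps the target pixel's activity with the copying kind's `max_act`.
#' A rejected attempt leaves the state bit-identical.
#'
#' @param state A `cpm_state`.
#' @param ham A [hamiltonian_spec()].
#' @param attempt A list with `source` and `target` sites (as produced by
#'   [propose_attempt()]).
#' @return A list with `state` (possibly updated) and `attempt` (augmented
#'   with `delta` and `accepted`).
#' @export
step_attempt <- function(state, ham, attempt) {
  d <- delta_H(state, ham, attempt$source, attempt$target)
  ok <- resolve_acceptance(d, ham$temperature, 1L)
  if (ok) {
    is_ <- state$identity[attempt$source[[1]] + 1L, attempt$source[[2]] + 1L]
    a <- if (is_ == 0L) 0L else ham$max_act[state$kind_of[is_ + 1L] + 1L]
    state <- set_pixel(state, attempt$target, is_, activity = a)
  }
  attempt$delta <- d
  attempt$accepted <- ok
  list(state = state, attempt = attempt)
}

#' Run Monte Carlo Steps
#'
#' One MCS performs `width * height` copy-attempt resolutions (null attempts
#' consume an attempt slot) and then decrements every positive activity value
#' by 1. The whole loop runs in compiled code and draws from R's global RNG
#' stream, so a trajectory is a pure function of (state, Hamiltonian, seed).
#'
#' @param state A `cpm_state`.
#' @param ham A [hamiltonian_spec()].
#' @param n_mcs Number of MCS to run.
#' @return The updated state; attributes `n_attempts`, `n_accepted` and
#'   `n_null` carry the attempt tallies of this call.
#' @export
run_mcs <- function(state, ham, n_mcs = 1L) {
  check_kinds_registered(state, ham)
  res <- cpp_run_mcs(state$identity, state$activity,
                     as.integer(state$kind_of), as.numeric(state$volume_of),
                     as.numeric(state$target_v_of),
                     state$immutable_kind,
                     ham$J, ham$lambda_v, ham$target_v,
                     ham$lambda_p, ham$target_p,
                     ham$lambda_act, ham$max_act,
                     ham$temperature, state$spec$torus_x, state$spec$torus_y,
                     ham$kernel, as.integer(n_mcs))
  state$identity <- res$identity
  state$activity <- res$activity
  state$volume_of <- as.integer(res$volume_of)
  attr(state, "n_attempts") <- res$n_attempts
  attr(state, "n_accepted") <- res$n_accepted
  attr(state, "n_null") <- res$n_null
  state
}

# Normalise a hook: either a function(state, mcs) -> state, or a list with
# elements fn and every (fire when mcs %% every == 0).
normalize_hook <- function(h) {
  if (is.function(h)) list(fn = h, every = 1L)
  else if (is.list(h) && is.function(h$fn))
    list(fn = h$fn, every = as.integer(if (is.null(h$every)) 1L else h$every))
  else stop("hook must be a function or list(fn=, every=)", call. = FALSE)
}

#' Run a full simulation with per-MCS hooks
#'
#' Runs `n_mcs` Monte Carlo Steps, firing registered hooks in registration
#' order. Each hook is a `function(state, mcs)` returning the (possibly
#' modified) state, optionally wrapped as `list(fn =, every =)` to fire only
#' every `every` MCS. All hooks also fire once at `mcs = 0` on the initial
#' state, so logs include the initial configuration. Between hook firings the
#' dynamics run in a single compiled call.
#'
#' @param state A `cpm_state`.
#' @param ham A [hamiltonian_spec()].
#' @param n_mcs Number of MCS.
#' @param seed Optional integer seed; when given, `set.seed(seed)` is called
#'   first so the trajectory is reproducible.
#' @param hooks List of hooks (see above).
#' @return The final state.
#' @export
run_simulation <- function(state, ham, n_mcs, seed = NULL, hooks = list()) {
  if (!is.null(seed)) set.seed(seed)
  hooks <- lapply(hooks, normalize_hook)
  for (h in hooks) state <- h$fn(state, 0L)
  if (n_mcs < 1L) return(state)
  mcs <- 0L
  while (mcs < n_mcs) {
    # advance to the next MCS at which any hook is due
    if (length(hooks)) {
      nxt <- min(vapply(hooks, function(h)
        ((mcs %/% h$every) + 1L) * h$every, numeric(1)))
      chunk <- min(nxt, n_mcs) - mcs
    } else chunk <- n_mcs - mcs
    state <- run_mcs(state, ham, chunk)
    mcs <- mcs + chunk
    for (h in hooks)
      if (mcs %% h$every == 0L) state <- h$fn(state, mcs)
  }
  state
}
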