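# Fixtures and independent oracles shared across test files.

# A state with n_cells random blobby cells of alternating kind, built by
# repeated random set_pixel growth so shapes are irregular.
random_blob_state <- function(width = 20, height = 20, n_cells = 3,
                              n_kinds = 2, growth = 60,
                              torus_x = TRUE, torus_y = TRUE) {
  st <- new_lattice(grid_spec(width, height, torus_x, torus_y), n_kinds)
  for (i in seq_len(n_cells)) {
    reg <- register_cell(st, (i - 1L) %% n_kinds + 1L)
    st <- reg$state
    site <- c(sample(0:(width - 1), 1), sample(0:(height - 1), 1))
    st <- set_pixel(st, site, reg$id)
    frontier <- list(site)
    for (g in seq_len(growth)) {
      base <- frontier[[sample.int(length(frontier), 1)]]
      nb <- neighbors(st$spec, base)
      cand <- nb[sample.int(nrow(nb), 1), ]
      st <- set_pixel(st, cand, reg$id)
      frontier <- c(frontier, list(cand))
    }
  }
  st
}

# Integer-parameter Hamiltonian with all three state-energy terms.
integer_hamiltonian <- function(n_kinds = 2) {
  J <- matrix(5, n_kinds + 1, n_kinds + 1)
  J[1, ] <- J[, 1] <- c(0, rep(8, n_kinds))
  diag(J) <- c(0, rep(2, n_kinds))
  if (n_kinds >= 2) { J[2, 3] <- J[3, 2] <- 11 }
  hamiltonian_spec(n_kinds, J = J,
                   lambda_v = rep(2, n_kinds), target_v = rep(30, n_kinds),
                   lambda_p = rep(1, n_kinds), target_p = rep(40, n_kinds),
                   temperature = 10)
}

# Brute-force heterotypic interface: enumerate ordered neighbor pairs via
# neighbors() and halve (independent of the compiled counter).
brute_heterotypic <- function(state, kernel = moore_kernel()) {
  n <- 0
  W <- state$spec$width; H <- state$spec$height
  for (x in 0:(W - 1)) for (y in 0:(H - 1)) {
    a <- state$identity[x + 1, y + 1]
    if (a == 0) next
    ka <- state$kind_of[a + 1]
    nb <- neighbors(state$spec, c(x, y), kernel)
    for (r in seq_len(nrow(nb))) {
      b <- state$identity[nb[r, 1] + 1, nb[r, 2] + 1]
      if (b == 0) next
      if (state$kind_of[b + 1] != ka) n <- n + 1
    }
  }
  n / 2
}

# Apply a copy attempt destructively (no energy bookkeeping beyond volumes).
apply_copy <- function(state, source, target) {
  is_ <- state$identity[source[1] + 1, source[2] + 1]
  set_pixel(state, target, is_)
}

# A minimal valid config list (null model on a small grid).
minimal_config <- function() {
  list(
    grid = list(width = 10, height = 10),
    kinds = list(list(name = "a")),
    hamiltonian = list(temperature = 5,
                      J = list(c(0, 0), c(0, 0))),
    schedule = list(n_mcs = 2)
  )
}
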