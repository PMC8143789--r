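test_that("total_H matches hand-computed cases", {
  sp <- grid_spec(20, 20)
  st <- new_lattice(sp, 1)
  ham <- hamiltonian_spec(1, J = matrix(c(0, 16, 16, 0), 2), temperature = 10)
  expect_equal(total_H(st, ham), 0)  # all background

  reg <- register_cell(st, 1); st1 <- reg$state
  st1 <- set_pixel(st1, c(10, 10), reg$id)
  expect_equal(total_H(st1, ham), 8 * 16)  # 8 heterotypic Moore pairs

  # cell at target volume, zero J: H == 0
  hamv <- hamiltonian_spec(1, lambda_v = 2, target_v = 25, temperature = 10)
  st2 <- make_disc_cell(reg$state, c(10, 10), 2.9, reg$id)
  expect_equal(st2$volume_of[reg$id + 1], 25)
  expect_equal(total_H(st2, hamv), 0)
})

test_that("delta_H matches hand-computed cases and errors on equal ids", {
  sp <- grid_spec(20, 20)
  st <- new_lattice(sp, 1)
  reg <- register_cell(st, 1); st <- reg$state
  st <- set_pixel(st, c(10, 10), reg$id)
  ham <- hamiltonian_spec(1, J = matrix(c(0, 16, 16, 0), 2), temperature = 10)
  # removing the isolated pixel erases all 128 units of interface energy
  expect_equal(delta_H(st, ham, c(9, 10), c(10, 10)), -128)

  # gaining one pixel at target volume costs lambda * 1^2
  hamv <- hamiltonian_spec(1, lambda_v = 2, target_v = 25, temperature = 10)
  st25 <- make_disc_cell(st, c(10, 10), 2.9, reg$id)
  expect_equal(delta_H(st25, hamv, c(10, 8), c(10, 7)), 2)

  # null Hamiltonian: every attempt is free
  ham0 <- hamiltonian_spec(1, temperature = 10)
  expect_equal(delta_H(st, ham0, c(9, 10), c(10, 10)), 0)

  expect_error(delta_H(st, ham, c(0, 0), c(1, 1)), "equal")
})

test_that("incremental delta_H equals the brute-force total_H difference", {
  set.seed(101)
  ham <- integer_hamiltonian(2)
  n_checked <- 0
  while (n_checked < 1200) {
    st <- random_blob_state(15, 15, n_cells = 4)
    for (i in 1:400) {
      a <- propose_attempt(st)
      if (is.null(a)) next
      d <- delta_H(st, ham, a$source, a$target)
      h0 <- total_H(st, ham)
      st_after <- apply_copy(st, a$source, a$target)
      expect_identical(d, total_H(st_after, ham) - h0)
      n_checked <- n_checked + 1
      if (runif(1) < 0.4) st <- st_after  # walk through state space
    }
  }
  expect_gt(n_checked, 1000)
})

test_that("delta_act follows the geometric-mean formula", {
  sp <- grid_spec(11, 11)
  st <- new_lattice(sp, 1)
  reg <- register_cell(st, 1); st <- reg$state
  # 5x5 uniformly active cell
  for (x in 3:7) for (y in 3:7) {
    st <- set_pixel(st, c(x, y), reg$id, activity = 20L)
  }
  ham <- hamiltonian_spec(1, lambda_act = 100, max_act = 20, temperature = 10)
  # protrusion: source on the cell (GM = 20), target background (GM = 0)
  expect_equal(delta_act(st, ham, c(7, 5), c(8, 5)), -(100 / 20) * 20)
  # retraction is the mirror image
  expect_equal(delta_act(st, ham, c(8, 5), c(7, 5)), +(100 / 20) * 20)
  # disabled term
  ham0 <- hamiltonian_spec(1, lambda_act = 0, max_act = 20, temperature = 10)
  expect_equal(delta_act(st, ham0, c(7, 5), c(8, 5)), 0)
  # a zero activity anywhere in the neighborhood zeroes the GM
  st0 <- st
  st0$activity[7, 6] <- 0L   # one same-cell neighbor of (6, 5)
  expect_equal(cellpotts:::act_geom_mean(st0, c(6, 5)), 0)
  expect_gt(cellpotts:::act_geom_mean(st0, c(4, 4)), 0)

  # compiled delta_H agrees with the pure-R act formula when only the Act
  # term is active
  set.seed(5)
  st2 <- st
  st2$activity[4:8, 4:8] <- matrix(sample(0:20, 25, replace = TRUE), 5)
  for (i in 1:200) {
    a <- propose_attempt(st2)
    if (is.null(a)) next
    expect_equal(delta_H(st2, ham, a$source, a$target),
                 delta_act(st2, ham, a$source, a$target), tolerance = 1e-12)
  }
})

test_that("acceptance probability implements the Boltzmann rule", {
  expect_equal(acceptance_probability(-5, 20), 1)
  expect_equal(acceptance_probability(0, 20), 1)
  expect_equal(acceptance_probability(20, 20), exp(-1))
  expect_error(acceptance_probability(1, 0), "> 0")
  # monotone in delta, monotone in T for delta > 0
  d <- seq(0.5, 50, by = 0.5)
  p <- acceptance_probability(d, 7)
  expect_true(all(diff(p) < 0))
  ts <- seq(1, 40, by = 1)
  pt <- vapply(ts, function(T) acceptance_probability(5, T), numeric(1))
  expect_true(all(diff(pt) > 0))
})

test_that("H is invariant under kind relabelling with J permuted", {
  set.seed(21)
  st <- random_blob_state(18, 18, n_cells = 6, n_kinds = 2)
  ham <- integer_hamiltonian(2)
  h1 <- total_H(st, ham)
  # swap kinds 1 <-> 2 everywhere and permute J accordingly
  st2 <- st
  st2$kind_of <- c(0L, 3L - st$kind_of[-1])
  perm <- c(1, 3, 2)
  ham2 <- ham
  ham2$J <- ham$J[perm, perm]
  ham2$lambda_v <- ham$lambda_v[perm]; ham2$target_v <- ham$target_v[perm]
  ham2$lambda_p <- ham$lambda_p[perm]; ham2$target_p <- ham$target_p[perm]
  expect_equal(total_H(st2, ham2), h1)
})

test_that("hamiltonian_spec validates its inputs", {
  expect_error(hamiltonian_spec(1, J = matrix(c(0, 1, 2, 0), 2),
                                temperature = 1), "symmetric")
  expect_error(hamiltonian_spec(1, temperature = 0), "> 0")
  expect_error(hamiltonian_spec(1, lambda_v = c(1, 1), temperature = 1),
               "background")
  expect_error(hamiltonian_spec(1, lambda_act = 5, max_act = 0,
                                temperature = 1), "max_act")
})
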