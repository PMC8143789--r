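test_that("circle seeding places the requested cells inside the region", {
  sp <- grid_spec(200, 200)
  for (s in 1:3) {
    set.seed(s)
    st <- new_lattice(sp, 2)
    plan <- seeding_plan(c(`1` = 50, `2` = 50), region_radius = 67)
    st <- seed_cells_in_circle(st, plan)
    ids <- which(st$volume_of > 0) - 1L
    ids <- ids[ids > 0]
    expect_length(ids, 100)
    expect_equal(sum(st$kind_of[ids + 1] == 1), 50)
    expect_equal(sum(st$kind_of[ids + 1] == 2), 50)
    expect_true(all(st$volume_of[ids + 1] == 1))
    # post-hoc geometric audit: every seeded pixel within the radius
    w <- which(st$identity != 0)
    x <- (w - 1) %% 200; y <- (w - 1) %/% 200
    expect_true(all((x - 100)^2 + (y - 100)^2 <= 67^2))
  }
})

test_that("seeding edge cases: empty plan, overfull region", {
  st <- new_lattice(grid_spec(20, 20), 1)
  p0 <- seeding_plan(c(`1` = 0), region_radius = 5)
  expect_identical(seed_cells_in_circle(st, p0), st)
  pbig <- seeding_plan(c(`1` = 1000), region_radius = 5)
  expect_error(seed_cells_in_circle(st, pbig), "free sites")
  ptoobig <- seeding_plan(c(`1` = 1), region_radius = 11)
  expect_error(seed_cells_in_circle(st, ptoobig), "radius")
})

test_that("burn-in grows seeds toward their target volume", {
  set.seed(4)
  st <- new_lattice(grid_spec(60, 60), 1)
  ham <- hamiltonian_spec(1, J = matrix(c(0, 8, 8, 4), 2),
                          lambda_v = 5, target_v = 30, temperature = 10)
  plan <- seeding_plan(c(`1` = 6), region_radius = 20, burn_in_mcs = 40)
  st <- seed_cells_in_circle(st, plan, ham)
  vols <- st$volume_of[-1]
  expect_true(all(vols > 15))
})

test_that("obstacles are immutable discs with exact geometry", {
  cfg <- benchmark_config("protrusion")
  ham <- config_hamiltonian(cfg)
  set.seed(2)
  st <- config_initial_state(cfg, ham)
  obs <- which(st$kind_of == 2) - 1L
  expect_length(obs, 2)
  brute <- sum(outer(-15:15, -15:15, function(dx, dy) dx^2 + dy^2 <= 100))
  expect_equal(st$volume_of[obs + 1], rep(brute, 2))
  # the two discs sit 50 px left and right of the grid midpoint
  cens <- t(sapply(obs, function(i) centroid(st, i)))
  expect_equal(cens[order(cens[, 1]), ], rbind(c(50, 100), c(150, 100)),
               ignore_attr = TRUE)
  expect_true(st$immutable_kind[3])
  # overlap with an existing cell is refused
  st2 <- new_lattice(grid_spec(50, 50), 2)
  reg <- register_cell(st2, 1); st2 <- reg$state
  st2 <- make_disc_cell(st2, c(25, 25), 5, reg$id)
  expect_error(place_obstacles(st2, list(c(27, 25)), 4, 2), "overlap")
})

test_that("obstacle pixel sets survive dynamics unchanged", {
  set.seed(9)
  st <- new_lattice(grid_spec(40, 40), 2)
  reg <- register_cell(st, 1); st <- reg$state
  st <- make_disc_cell(st, c(10, 10), 4, reg$id)
  st <- place_obstacles(st, list(c(28, 28)), 6, 2)
  obs_id <- length(st$kind_of) - 1L
  before <- which(st$identity == obs_id)
  ham <- hamiltonian_spec(2, J = matrix(c(0, 4, 4, 4, 2, 6, 4, 6, 0), 3),
                          lambda_v = c(3, 0), target_v = c(50, 0),
                          temperature = 20)
  st <- run_mcs(st, ham, 50)
  expect_identical(which(st$identity == obs_id), before)
})

test_that("minor-axis division splits a 4x2 rectangle into 2x2 daughters", {
  st <- new_lattice(grid_spec(12, 12), 1)
  reg <- register_cell(st, 1); st <- reg$state
  for (x in 4:7) for (y in 5:6) st <- set_pixel(st, c(x, y), reg$id)
  rule <- division_rule(growth_rate = 0, division_volume = 8,
                        base_target_v = 4)
  res <- divide_cell(st, reg$id, rule)
  st2 <- res$state
  d <- res$event$daughter
  expect_equal(res$event$vol_kept, 4)
  expect_equal(res$event$vol_new, 4)
  parent_px <- which(st2$identity == reg$id)
  child_px <- which(st2$identity == d)
  px_x <- function(w) (w - 1) %% 12
  # the split line is vertical through the centroid: x {4,5} vs {6,7}
  expect_setequal(px_x(parent_px), c(4, 5))
  expect_setequal(px_x(child_px), c(6, 7))
  expect_equal(st2$kind_of[d + 1], st2$kind_of[reg$id + 1])
})

test_that("division conserves pixels and never reuses ids", {
  set.seed(13)
  rule <- division_rule(growth_rate = 0, division_volume = 10,
                        base_target_v = 20, axis_mode = "random")
  for (i in 1:15) {
    st <- random_blob_state(16, 16, n_cells = 1, growth = 40)
    id <- 1L
    v <- st$volume_of[id + 1]
    res <- divide_cell(st, id, rule)
    ev <- res$event
    expect_equal(ev$vol_kept + ev$vol_new, v)
    expect_gt(ev$vol_new, 0)
    expect_gt(ev$vol_kept, 0)
    expect_equal(ev$daughter, length(st$kind_of))  # fresh id, never reused
    expect_identical(res$state$volume_of, recount_volumes(res$state))
  }
  # degenerate: volume-1 cell is skipped with a warning
  st1 <- new_lattice(grid_spec(10, 10), 1)
  reg <- register_cell(st1, 1); st1 <- reg$state
  st1 <- set_pixel(st1, c(5, 5), reg$id)
  expect_warning(res <- divide_cell(st1, reg$id, rule), "skipped")
  expect_identical(res$state, st1)
})

test_that("grow_and_divide raises targets and keeps cell count non-decreasing", {
  set.seed(23)
  cfg <- benchmark_config("cell_division", overrides = list(
    grid = list(width = 120, height = 120),
    processes = list(
      list(type = "seed_circle", counts = 6, kinds = 1, radius = 20,
           burn_in = 30),
      list(type = "grow_divide", growth_rate = 0.4, division_volume = 150,
           base_target_v = 100, axis_mode = "minor-axis")),
    schedule = list(n_mcs = 500, log_every = 50, png_every = NA)))
  res <- run_experiment(cfg, out_dir = tempfile("div"), seed = 5, draw = FALSE)
  counts <- vapply(res$records, function(r) r$global[["cell_count"]], numeric(1))
  expect_equal(counts[1], 6)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], 6)   # growth_rate > 0 actually divides
  if (!is.null(res$events))
    expect_true(all(res$events$vol_kept + res$events$vol_new ==
                    res$events$parent_volume))
})
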