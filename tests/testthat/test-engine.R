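test_that("initial population is homogeneous at epsilon with zero increments", {
  m <- default_model(N = 4L)
  pop <- init_population(m)
  expect_equal(pop$damages, rep(0.1, 4))
  expect_equal(pop$increments, rep(0L, 4))
  expect_identical(pop$t_steps, 0)
  s <- summarize_population(pop)
  expect_identical(s$f0, 1)
  expect_identical(s$mean_damage, 0.1)
  expect_equal(s$histogram, 1)
})

test_that("summary statistics are exact arithmetic on the state", {
  m <- default_model(N = 4L)
  pop <- init_population(m)
  pop$damages <- c(0.1, 0.1, 0.3, 0.5)
  s <- summarize_population(pop)
  expect_identical(s$f0, 0.5)
  expect_identical(s$mean_damage, 0.25)
  pop$damages <- rep(1, 4)
  s <- summarize_population(pop)
  expect_identical(s$f0, 0)
  expect_identical(s$mean_damage, 1)
})

test_that("undamaged populations are frozen and fully damaged ones absorbing", {
  m <- suppressWarnings(default_model(N = 10L, epsilon = 0))
  pop <- init_population(m)
  set.seed(1)
  pop <- step_population(pop, 1000)
  expect_equal(pop$damages, rep(0, 10))
  expect_identical(pop$t_steps, 1000)

  for (mo in c("symmetric", "asymmetric")) for (to in c("well_mixed", "ring_1d")) {
    m1 <- suppressWarnings(default_model(N = 6L, epsilon = 1, mode = mo,
                                         topology = to))
    pop1 <- init_population(m1)
    set.seed(2)
    pop1 <- step_population(pop1, 500)
    expect_equal(pop1$damages, rep(1, 6))
  }
})

test_that("two-cell absorbing closure: death plus copy keeps the state at all-ones", {
  m <- suppressWarnings(default_model(N = 2L, epsilon = 1, p = 0))
  pop <- init_population(m)
  set.seed(3)
  pop <- step_population(pop, 200)
  expect_equal(pop$damages, c(1, 1))
})

test_that("population size and time accounting are exact; no-mutation runs never leave epsilon", {
  m <- default_model(N = 50L, p = 0)
  tr <- run_simulation(m, max_time_units = 30)
  expect_equal(nrow(tr$summary), 31)  # t = 0..30
  expect_true(all(tr$summary$f0 == 1))
  expect_equal(tr$summary$mean_damage, rep(0.1, 31))
  expect_length(tr$final$damages, 50)
  expect_identical(tr$final$t_steps, 50 * 30)
})

test_that("a run from epsilon = 1 is collapsed at time zero", {
  m <- suppressWarnings(default_model(N = 10L, epsilon = 1))
  tr <- run_simulation(m, max_time_units = 5, stop_criterion = "f0_zero")
  expect_true(tr$collapsed)
  expect_identical(tr$collapse_time, 0)
  tr2 <- run_simulation(m, max_time_units = 5, stop_criterion = "all_damage_one")
  expect_true(tr2$collapsed)
  expect_identical(tr2$collapse_time, 0)
})

test_that("fixed seeds give bit-identical trajectories", {
  m <- default_model(N = 80L, topology = "ring_1d", seed = 7L)
  t1 <- run_simulation(m, 50, record_kymograph = TRUE)
  t2 <- run_simulation(m, 50, record_kymograph = TRUE)
  expect_identical(t1$summary, t2$summary)
  expect_identical(t1$kymograph, t2$kymograph)
  expect_identical(t1$final$damages, t2$final$damages)
})

test_that("the population minimum damage never decreases (irreversibility)", {
  for (mo in c("symmetric", "asymmetric")) {
    m <- default_model(N = 40L, p = 0.3, mode = mo, topology = "ring_1d",
                       seed = 11L)
    tr <- run_simulation(m, 100, record_kymograph = TRUE)
    mins <- apply(tr$kymograph, 1, min)
    expect_true(all(diff(mins) >= 0))
  }
})

test_that("increment counters and damage levels agree through the lattice map", {
  for (mo in c("symmetric", "asymmetric")) {
    m <- default_model(N = 60L, p = 0.25, mode = mo, seed = 13L)
    tr <- run_simulation(m, 150)
    s <- if (mo == "symmetric") m$delta / 2 else m$delta
    d <- tr$final$damages
    k <- tr$final$increments
    unclamped <- d < 1
    expect_true(all(abs(d[unclamped] - (m$epsilon + k[unclamped] * s)) < 1e-9))
    expect_true(all(m$epsilon + k[!unclamped] * s >= 1 - 1e-9))
  }
})

test_that("f0 uses exact equality: inherited damage is copied, not recomputed", {
  m <- default_model(N = 200L, epsilon = 0.1, p = 0.15, seed = 5L)
  tr <- run_simulation(m, 200)
  # cells with zero increments must compare equal to epsilon bit-for-bit
  f0_from_inc <- mean(tr$final$increments == 0L)
  f0_from_damage <- mean(tr$final$damages == m$epsilon)
  expect_identical(f0_from_damage, f0_from_inc)
})

test_that("well-mixed plateau statistics track the analytic steady state", {
  m <- default_model(N = 1000L, seed = 3L)
  tr <- run_simulation(m, 250)
  ps <- plateau_stats(tr, c(80, 250))
  ss <- steady_state(m)
  expect_lt(abs(ps$mean_damage - ss$d_star), 0.01)
  expect_lt(abs(ps$f0 - ss$x0), 0.03)
})
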