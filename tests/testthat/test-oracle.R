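test_that("reachable-state enumeration on two-level lattices", {
  # symmetric, delta = 1: a mutated division promotes both daughters, so the
  # mixed two-cell state is never reached from the homogeneous start
  m2 <- default_model(N = 2L, epsilon = 0.5, p = 0.5, delta = 1.0)
  sp <- enumerate_states(m2)
  expect_identical(length(sp$states), 2L)
  expect_equal(sp$levels, c(0.5, 1.0))

  m3 <- tiny_model()
  sp3 <- enumerate_states(m3)
  expect_identical(length(sp3$states), 4L)  # counts (3,0),(2,1),(1,2),(0,3)
  expect_identical(length(sp3$absorbing_all_one), 1L)

  m0 <- default_model(N = 3L, epsilon = 0.5, p = 0, delta = 1.0)
  sp0 <- enumerate_states(m0)
  expect_identical(length(sp0$states), 1L)

  expect_error(enumerate_states(default_model(N = 100L, delta = 0.01),
                                max_states = 1000), "bound exceeded")
})

test_that("transition rows are stochastic; absorbing and frozen rows are identity", {
  m3 <- tiny_model()
  sp <- enumerate_states(m3)
  P <- transition_matrix(sp)
  expect_true(all(abs(Matrix::rowSums(P) - 1) < 1e-12))
  iabs <- sp$absorbing_all_one
  expect_equal(as.numeric(P[iabs, iabs]), 1)

  m0 <- default_model(N = 3L, epsilon = 0.5, p = 0, delta = 1.0)
  sp0 <- enumerate_states(m0)
  P0 <- transition_matrix(sp0)
  expect_equal(as.numeric(P0[1, 1]), 1)
})

test_that("two-cell transition row matches the hand-enumerated branches", {
  # from (0.5, 0.5): select either cell, die w.p. 0.5; the other divides;
  # mutated (0.5) -> both daughters clamp to 1; else state unchanged.
  # P[stay] = 0.5 + 0.5*0.5 = 0.75, P[-> all-ones] = 0.25
  m2 <- default_model(N = 2L, epsilon = 0.5, p = 0.5, delta = 1.0)
  sp <- enumerate_states(m2)
  P <- as.matrix(transition_matrix(sp))
  i0 <- sp$initial
  i1 <- sp$absorbing_all_one
  expect_equal(P[i0, i0], 0.75)
  expect_equal(P[i0, i1], 0.25)
})

test_that("expected absorption time: degenerate starts and impossible absorption", {
  m1 <- suppressWarnings(default_model(N = 3L, epsilon = 1, p = 0.3, delta = 1))
  sp1 <- enumerate_states(m1)
  ea1 <- expected_absorption_time(sp1, transition_matrix(sp1), m1)
  expect_identical(ea1$expected_tau, 0)

  m0 <- default_model(N = 3L, epsilon = 0.5, p = 0, delta = 1.0)
  sp0 <- enumerate_states(m0)
  ea0 <- expected_absorption_time(sp0, transition_matrix(sp0), m0)
  expect_false(ea0$finite)
  expect_identical(ea0$expected_tau, Inf)
})

test_that("expected absorption time decreases with the mutation probability", {
  taus <- sapply(c(0.1, 0.2, 0.4, 0.8), function(p) {
    m <- default_model(N = 3L, epsilon = 0.5, p = p, delta = 1.0)
    sp <- enumerate_states(m)
    expected_absorption_time(sp, transition_matrix(sp), m)$expected_tau
  })
  expect_true(all(diff(taus) < 0))
})

test_that("loss of the initial-level class is faster than full saturation", {
  # needs an intermediate damage level: on a two-level lattice the criteria
  # coincide, so use levels {0.4, 0.7, 1.0}
  m <- default_model(N = 3L, epsilon = 0.4, p = 0.3, delta = 0.6)
  sp <- enumerate_states(m)
  P <- transition_matrix(sp)
  t_f0 <- expected_absorption_time(sp, P, m, criterion = "f0_zero")
  t_all <- expected_absorption_time(sp, P, m, criterion = "all_damage_one")
  expect_lt(t_f0$expected_tau, t_all$expected_tau)
})

test_that("ring and well-mixed agree on the smallest instances where they coincide", {
  # at N = 3 on a ring both neighbours are exactly the other two cells, so the
  # divider law coincides with the well-mixed one
  mw <- tiny_model()
  mr <- tiny_model(topology = "ring_1d")
  sw <- enumerate_states(mw)
  sr <- enumerate_states(mr)
  ew <- expected_absorption_time(sw, transition_matrix(sw), mw)
  er <- expected_absorption_time(sr, transition_matrix(sr), mr)
  expect_equal(ew$expected_tau, er$expected_tau, tolerance = 1e-12)
})
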