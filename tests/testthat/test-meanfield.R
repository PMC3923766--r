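test_that("hierarchy right-hand side matches a hand-expanded two-class state", {
  # x = (0.9, 0.1, 0, ...), eps = 0.1, p = 0.1, delta = 0.2, symmetric:
  # d0 = 0.1, d1 = 0.2, <d> = 0.9*0.1 + 0.1*0.2 = 0.11
  # xdot0 = 0.9*(-0.1 + 0.8*0.11)          = -0.0108
  # xdot1 = 0.1*(-0.2 + 0.8*0.11) + 2*0.1*0.11*0.9 = 0.0086
  # xdot2 = 2*0.1*0.11*0.1                 = 0.0022
  m <- default_model()
  x <- c(0.9, 0.1, 0, 0, 0)
  r <- meanfield_rhs(x, m, mode = "symmetric")
  expect_equal(r[1:3], c(-0.0108, 0.0086, 0.0022), tolerance = 1e-12)
  expect_equal(r[4:5], c(0, 0))
})

test_that("a point mass at class zero with p = 0 is stationary", {
  m <- default_model(p = 0)
  x <- c(1, rep(0, 10))
  expect_equal(meanfield_rhs(x, m, mode = "symmetric"), rep(0, 11))
  expect_equal(meanfield_rhs(x, m, mode = "asymmetric"), rep(0, 11))
})

test_that("the right-hand side conserves total fraction for random states", {
  set.seed(21)
  m <- default_model(p = 0.2)
  for (i in 1:50) {
    x <- runif(15)
    x <- x / sum(x)
    for (mo in c("symmetric", "asymmetric"))
      expect_lt(abs(sum(meanfield_rhs(x, m, mode = mo))), 1e-12)
  }
})

test_that("numerical integration reproduces the analytic steady state", {
  m <- default_model()
  for (mo in c("symmetric", "asymmetric")) {
    mf <- meanfield_integrate(m, mode = mo)
    ss <- steady_state(m, mode = mo)
    expect_true(mf$converged)
    expect_lt(abs(mf$mean_damage - ss$d_star), 1e-6)
    expect_lt(mf$norm_error, 1e-9)
    # full stationary distribution agrees with the Poisson law
    pois <- poisson_pmf(ss$lambda, mf$k_max)
    expect_lt(max(abs(mf$x - pois)), 1e-6)
  }
})

test_that("closed forms: d*, lambda, x0 and their self-consistency", {
  m <- default_model()
  ss <- steady_state(m, mode = "symmetric")
  expect_equal(ss$d_star, 0.125)
  expect_equal(ss$lambda, 0.25)
  expect_equal(ss$x0, exp(-0.25))
  expect_equal(ss$d_star, m$epsilon + (m$delta / 2) * ss$lambda)

  sa <- steady_state(m, mode = "asymmetric")
  expect_equal(sa$d_star, 0.1 / 0.9)
  expect_equal(sa$lambda, 0.1 * (0.1 / 0.9) / 0.2)
  expect_equal(sa$x0, exp(-sa$lambda))
  expect_equal(sa$d_star, m$epsilon + m$delta * sa$lambda)

  m0 <- default_model(p = 0)
  for (mo in c("symmetric", "asymmetric")) {
    s0 <- steady_state(m0, mode = mo)
    expect_equal(s0$d_star, m0$epsilon)
    expect_equal(s0$lambda, 0)
    expect_equal(s0$x0, 1)
  }
})

test_that("non-existence is encoded, not raised", {
  expect_false(steady_state(default_model(p = 0.5), mode = "symmetric")$exists)
  expect_true(steady_state(default_model(p = 0.5), mode = "asymmetric")$exists)
  # d* > 1 also leaves the admissible range
  expect_false(steady_state(default_model(epsilon = 0.9, p = 0.3),
                            mode = "symmetric")$exists)
})

test_that("truncated Poisson vector is normalised and correct at the origin", {
  p0 <- poisson_pmf(0, 10)
  expect_equal(p0, c(1, rep(0, 10)), ignore_attr = TRUE)
  p1 <- poisson_pmf(0.25, 30)
  expect_equal(p1[1], exp(-0.25), tolerance = 1e-12)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_lt(abs(attr(p1, "renorm_error")), 1e-12)
})

test_that("post-collapse states shift the base level one lattice step per generation", {
  m <- default_model()
  g0 <- post_collapse_state(m, generation = 0)
  expect_equal(g0$d_star, steady_state(m)$d_star)
  g1 <- post_collapse_state(m, generation = 1)
  ref <- steady_state(default_model(epsilon = 0.2))
  expect_equal(g1$d_star, ref$d_star)
  expect_equal(g1$lambda, ref$lambda)
  # lambda increases down the generations while states exist
  lams <- sapply(0:3, function(g) post_collapse_state(m, generation = g)$lambda)
  expect_true(all(diff(lams) > 0))
})

test_that("asymmetric partitioning dominates: lower d*, higher x0", {
  cmp <- compare_modes(default_model())
  expect_true(cmp$d_star_asym_lower)
  expect_true(cmp$x0_asym_higher)
  cmp0 <- compare_modes(default_model(p = 0))
  expect_true(cmp0$d_star_asym_lower)  # equality at the degenerate boundary
  expect_true(cmp0$x0_asym_higher)
})

test_that("symmetric d* is invariant to the split reading; lambda halves", {
  m <- default_model()
  h <- steady_state(m, split = "half")
  f <- steady_state(m, split = "full")
  expect_equal(h$d_star, f$d_star)
  expect_equal(h$lambda / f$lambda, 2)
})
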