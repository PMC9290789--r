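test_that("the single-population recursion has the expected fixed points", {
  expect_equal(step_single(0, 0.8, 0.9), 0)
  expect_equal(step_single(1, 0.5, 1), 1)
  # the larger quadratic root is a fixed point to machine precision
  eq <- stable_unstable_equilibria(0.8, 0.9)
  expect_lt(abs(step_single(eq[["stable"]], 0.8, 0.9) - eq[["stable"]]), 1e-12)
  expect_lt(abs(step_single(eq[["unstable"]], 0.8, 0.9) - eq[["unstable"]]), 1e-12)
})

test_that("equilibria solve the invasion quadratic and flag lost bistability", {
  expect_equal(stable_unstable_equilibria(0.9, 1), c(stable = 1, unstable = 0))
  eq <- stable_unstable_equilibria(0.8, 0.99)
  roots <- sort(Re(polyroot(c(1 - 0.99, -0.8, 0.8 * 0.99))))
  expect_equal(unname(eq), rev(roots), tolerance = 1e-12)
  # for near-perfect transmission the invasion threshold is about (1 - t)/c
  expect_equal(eq[["unstable"]], (1 - 0.99) / 0.8, tolerance = 0.02)
  # discriminant sign: c below 4t(1-t) has no interior equilibria
  expect_error(stable_unstable_equilibria(0.5, 0.7), class = "ciflow_no_threshold")
})

test_that("frequencies stay within [0, 1] across random parameters and states", {
  set.seed(42)
  for (i in 1:1000) {
    cc <- runif(1)
    tt <- runif(1, 0.01, 1)
    p <- runif(1000)
    out <- step_single(p, cc, tt)
    expect_true(all(out >= 0 & out <= 1))
  }
  # two-population steps, both modes
  for (i in 1:200) {
    pp <- dynamics_params("unidirectional", c = runif(1), t = runif(1, 0.01, 1),
                          m = runif(1, 0, 0.5))
    st <- sim_state(matrix(runif(2), ncol = 1))
    nx <- step_two_pop(st, pp)
    expect_true(all(nx$freq >= 0 & nx$freq <= 1))
    ab <- sort(runif(2))
    xy <- matrix(runif(4), ncol = 2)
    xy <- xy / pmax(rowSums(xy), 1) # strain frequencies must sum <= 1
    bb <- dynamics_params("bidirectional", a = ab[2], b = ab[1],
                          t = runif(1, 0.5, 1), m = runif(1, 0, 0.5))
    nb <- step_two_pop(sim_state(xy), bb)
    expect_true(all(nb$freq >= 0 & nb$freq <= 1))
    expect_true(all(rowSums(nb$freq) <= 1 + 1e-12))
  }
})

test_that("two-population steps respect migration structure", {
  pp0 <- dynamics_params("unidirectional", c = 0.8, t = 0.95, m = 0)
  st <- sim_state(matrix(c(0.9, 0.2), ncol = 1))
  nx <- step_two_pop(st, pp0)
  # no migration: each population follows its own single-population recursion
  expect_equal(nx$freq[, 1], step_single(c(0.9, 0.2), 0.8, 0.95))
  expect_equal(nx$generation, 1L)

  # maximal mixing of identical populations leaves the state unchanged by
  # migration; the update reduces to local reproduction
  pp5 <- dynamics_params("unidirectional", c = 0.8, t = 0.95, m = 0.5)
  same <- sim_state(matrix(c(0.6, 0.6), ncol = 1))
  expect_equal(step_two_pop(same, pp5)$freq[, 1],
               step_single(c(0.6, 0.6), 0.8, 0.95))
})

test_that("isolated populations converge to the basin of their starting side", {
  for (par in list(c(0.8, 0.95), c(0.738, 0.9))) {
    eq <- stable_unstable_equilibria(par[1], par[2])
    up <- eq[["unstable"]] * 1.05
    dn <- eq[["unstable"]] * 0.95
    for (gen in 1:2000) {
      up <- step_single(up, par[1], par[2])
      dn <- step_single(dn, par[1], par[2])
    }
    expect_equal(up, eq[["stable"]], tolerance = 1e-6)
    expect_lt(dn, 1e-6)
  }
})

test_that("migration above the threshold drives invasion of population 2", {
  cc <- 0.8; tt <- 0.95
  eq <- stable_unstable_equilibria(cc, tt)
  mk <- unidirectional_mk(cc, tt)
  run <- function(m, gens = 5000) {
    st <- sim_state(matrix(c(eq[["stable"]], 0), ncol = 1))
    pp <- dynamics_params("unidirectional", c = cc, t = tt, m = m)
    for (g in seq_len(gens)) st <- step_two_pop(st, pp)
    st$freq[2, 1]
  }
  expect_gt(run(2 * mk), eq[["unstable"]])   # invades and approaches fixation
  expect_gt(run(2 * mk), 0.9 * eq[["stable"]])
  expect_lt(run(0.5 * mk), eq[["unstable"]]) # held below the invasion threshold
})

test_that("bisection locates thresholds consistent with the closed forms", {
  # unidirectional: oracle against the closed form at the published strengths
  m_sim <- find_critical_migration("unidirectional", c = 0.8, t = 0.99)
  expect_lt(abs(m_sim - unidirectional_mk(0.8, 0.99)) / m_sim, 0.05)

  # bidirectional at complete CI
  m_bi <- find_critical_migration("bidirectional", a = 1, b = 1)
  expect_lt(abs(m_bi - bidirectional_mk(1, 1)) / m_bi, 0.05)

  # doubling the horizon does not move the threshold (no slow transients)
  m_long <- find_critical_migration("unidirectional", c = 0.8, t = 0.99,
                                    horizon = 20000L)
  expect_lt(abs(m_long - m_sim), 2e-6)

  # the threshold is monotone nonincreasing in transmission
  ms <- vapply(c(0.875, 0.9, 0.95, 0.99), function(t) {
    find_critical_migration("unidirectional", c = 0.8, t = t)
  }, numeric(1))
  expect_true(all(diff(ms) <= 0))

  # perfect transmission: any migration seeds an always-spreading strain
  expect_lt(find_critical_migration("unidirectional", c = 0.9, t = 1), 2e-6)

  # a bracket that excludes the threshold is reported as such
  expect_error(
    find_critical_migration("unidirectional", c = 0.8, t = 0.99,
                            m_range = c(0.4, 0.5)),
    class = "ciflow_no_threshold")
})

test_that("the closed forms are lower bounds for symmetric two-way migration", {
  # the bound is tight away from the bistability boundary ...
  tight <- find_critical_migration("unidirectional", c = 0.8, t = 0.9,
                                   scheme = "symmetric")
  expect_gte(tight * (1 + 1e-3), unidirectional_mk(0.8, 0.9))
  expect_lt(abs(tight - unidirectional_mk(0.8, 0.9)) / tight, 0.05)
  # ... and looser near it (c = 0.5, t = 0.875 sits close to c = 4t(1-t))
  near_fold <- find_critical_migration("unidirectional", c = 0.5, t = 0.875,
                                       scheme = "symmetric")
  expect_gt(near_fold, unidirectional_mk(0.5, 0.875))
  # symmetric bidirectional CI bifurcates well above the mainland-island bound
  sym_bi <- find_critical_migration("bidirectional", a = 1, b = 1,
                                    scheme = "symmetric")
  expect_gt(sym_bi, bidirectional_mk(1, 1))
})
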