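test_that("mismatch similarity is the concentration-weighted mean weight", {
  expect_equal(mismatch_similarity(rep(1, 7)), 1)
  expect_equal(mismatch_similarity(exp(-2), 3.2), exp(-2))
  expect_equal(mismatch_similarity(c(1, exp(-1)), c(2, 1)),
               (2 + exp(-1)) / 3)
  expect_equal(mismatch_similarity(numeric(0)), 0)
  expect_error(mismatch_similarity(c(1, -0.1)), "nonnegative")
  expect_error(mismatch_similarity(1, -2), "nonnegative")
  expect_error(mismatch_similarity(c(1, 1), 1), "equal length")
})

test_that("single-gene crosstalk probabilities match the occupancy model", {
  # no TFs present: required-bound site surely unbound, no foreign binding
  p0 <- crosstalk_probabilities(thermo_state(0.3, 0.4, c = 0))
  expect_equal(unname(p0), c(1, 0))
  # direct evaluation at c = 100, s = 0.01, t = 0.5
  p <- crosstalk_probabilities(thermo_state(0.01, 0.5, 100))
  expect_equal(p[["x_bound"]], 2 / 202)
  expect_equal(p[["x_unbound"]], 0.5)
  # c -> infinity: x_unbound -> 1, x_bound -> s t / (1 + s t)
  pl <- crosstalk_probabilities(thermo_state(0.01, 0.5, 1e9))
  expect_equal(pl[["x_unbound"]], 1, tolerance = 1e-6)
  expect_equal(pl[["x_bound"]], 0.005 / 1.005, tolerance = 1e-6)
  # undefined cognate concentration at t = 0
  expect_error(crosstalk_probabilities(thermo_state(0.01, 0, 10)),
               "undefined")
})

test_that("the energy gap only shifts the concentration scale", {
  # exact identity: (c, Ea) and (c * exp(Ea), 0) describe the same state
  for (Ea in c(-2, 0.7, 3)) {
    a <- crosstalk_probabilities(thermo_state(0.05, 0.3, 12, Ea = Ea))
    b <- crosstalk_probabilities(thermo_state(0.05, 0.3, 12 * exp(Ea)))
    expect_equal(a, b)
    expect_equal(global_crosstalk(thermo_state(0.05, 0.3, 12, Ea = Ea)),
                 global_crosstalk(thermo_state(0.05, 0.3, 12 * exp(Ea))))
  }
})

test_that("global crosstalk is the availability-weighted error fraction", {
  # t = 0: only unbound-type errors remain
  st0 <- thermo_state(0.02, 0, 50)
  expect_equal(global_crosstalk(st0), 1 * 0.02 * 50 / (1 + 0.02 * 50) / 1)
  st <- thermo_state(0.01, 0.5, 100)
  expect_equal(global_crosstalk(st), 0.5 * 2 / 202 + 0.5 * 0.5)
})

test_that("minimal crosstalk agrees with brute-force minimization", {
  # frozen spot values
  m <- minimize_crosstalk(0.01, 0.5)
  expect_equal(m$x_star, 0.5 * (2 * sqrt(0.005) - 0.005))
  expect_equal(m$regime, "III_regulation")
  expect_equal(minimize_crosstalk(1e-9, 0)$x_star, 0)
  mI <- minimize_crosstalk(4, 0.5)   # s(1-t) = 2 >= 1
  expect_equal(mI$x_star, 0.5)
  expect_equal(mI$c_star, 0)
  expect_equal(mI$regime, "I_no_regulation")
  # regime II must be reported as divergent, never as a huge finite c
  mII <- minimize_crosstalk(0.01, 1)
  expect_true(is.infinite(mII$c_star))
  expect_equal(mII$x_star, 0.01 / 1.01)
  # oracle sweep: closed forms vs independent brute force
  set.seed(42)
  for (i in 1:200) {
    s <- 10^stats::runif(1, -4, 1)
    t <- stats::runif(1)
    m <- minimize_crosstalk(s, t)
    expect_equal(m$x_star, brute_force_xstar(s, t), tolerance = 1e-6)
    # X* is a true lower bound over finite concentrations
    cs <- 10^stats::runif(5, -6, 6)
    for (cv in cs) {
      expect_gte(global_crosstalk(thermo_state(s, t, cv)) + 1e-9,
                 m$x_star)
    }
  }
})

test_that("analytic and numeric minimization routes agree", {
  set.seed(7)
  for (i in 1:50) {
    s <- 10^stats::runif(1, -4, 1)
    t <- stats::runif(1)
    a <- minimize_crosstalk(s, t, method = "analytic")
    n <- minimize_crosstalk(s, t, method = "numeric")
    expect_equal(a$x_star, n$x_star, tolerance = 1e-6)
    expect_equal(a$regime, n$regime)
  }
})

test_that("minimal crosstalk is invariant in the energy gap", {
  # minimize over c at fixed (s, t) for several gaps: identical optima
  for (st in list(c(0.01, 0.5), c(0.3, 0.8), c(2, 0.2))) {
    vals <- vapply(c(-2, 0, 3), function(Ea) {
      stats::optimize(function(lc) {
        global_crosstalk(thermo_state(st[1], st[2], exp(lc), Ea = Ea))
      }, c(-25, 25), tol = 1e-13)$objective
    }, numeric(1))
    expect_lt(max(vals) - min(vals), 1e-9)
  }
})

test_that("regime boundaries reproduce the limiting branches", {
  set.seed(11)
  for (i in 1:30) {
    s <- 10^stats::runif(1, -3, 0.5)
    t <- stats::runif(1)
    expect_equal(global_crosstalk(thermo_state(s, t, 0)), t)
    expect_equal(global_crosstalk(thermo_state(s, t, 1e8)),
                 1 - t / (1 + s * t), tolerance = 1e-4)
  }
})

test_that("minimal crosstalk grows with similarity in the regulation regime", {
  set.seed(13)
  for (i in 1:100) {
    t <- stats::runif(1, 0.05, 0.95)
    s1 <- 10^stats::runif(1, -4, 0)
    s2 <- s1 * 1.25
    if (s2 * (1 - t) < 1) {
      expect_gte(xstar_law(s2, t), xstar_law(s1, t) - 1e-12)
    }
  }
})

test_that("the crosstalk maximum sits at high availability", {
  for (s in 10^seq(-6, 0, length.out = 8)) {
    expect_gte(xstar_argmax_t(s), 2 / 3 - 1e-6)
  }
  # s -> 0 limit maximizes t * sqrt(1 - t): argmax 2/3
  expect_equal(xstar_argmax_t(1e-7), 2 / 3, tolerance = 1e-3)
})

test_that("xstar_curve tabulates the minimization over a t grid", {
  cur <- xstar_curve(c(1e-3, 1e-2), t_points = 21L)
  expect_equal(nrow(cur), 42L)
  expect_true(all(cur$x_star >= 0 & cur$x_star <= 1))
  expect_true(all(cur$x_star[cur$t == 0] == 0))
  one <- cur[cur$s == 1e-2, ]
  expect_equal(one$x_star,
               vapply(one$t, function(t) minimize_crosstalk(1e-2, t)$x_star,
                      numeric(1)))
})

test_that("domain validation rejects bad states", {
  expect_error(thermo_state(-1, 0.5, 1), "positive")
  expect_error(thermo_state(0.1, 1.5, 1), "\\[0, 1\\]")
  expect_error(thermo_state(0.1, 0.5, -1), "nonnegative")
  expect_error(minimize_crosstalk(0, 0.5), "positive")
  expect_error(minimize_crosstalk(0.1, 2), "\\[0, 1\\]")
})
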