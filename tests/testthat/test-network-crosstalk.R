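test_that("realized crosstalk matches a hand-built two-gene oracle", {
  # no TFs available: nothing binds anywhere
  net <- sym_network(4, 3)
  expect_equal(realized_crosstalk(net, integer(0), 10), 0)
  expect_error(realized_crosstalk(net, 1:2, -1), "positive")

  # symmetric 2-gene network, both TFs available: per-gene x_bound with
  # cognate concentration C/2 and foreign weight (C/2) exp(-eps0)
  eps0 <- 2
  net2 <- sym_network(2, eps0)
  for (C in c(0.5, 5, 50)) {
    N <- (C / 2) * exp(-eps0)
    hand <- (1 + N) / (C / 2 + 1 + N)
    expect_equal(realized_crosstalk(net2, 1:2, C), hand)
  }
  # one TF available: its gene is bound-type, the other unbound-type
  C <- 8
  N_unbound <- C * exp(-eps0)
  hand <- mean(c(1 / (C + 1), N_unbound / (1 + N_unbound)))
  expect_equal(realized_crosstalk(net2, 1, C), hand)
})

test_that("realized crosstalk equals exhaustive per-subset evaluation", {
  # independent oracle: naive loops straight from the occupancy formulas
  oracle <- function(net, avail, C, Ea = 0) {
    n <- length(net$tf_ids)
    conc <- rep(0, n)
    conc[avail] <- C / length(avail)
    xs <- vapply(seq_len(net$M), function(gi) {
      cog <- net$genes$cognates[[gi]]
      Nk <- mean(vapply(cog, function(site) {
        tot <- 0
        for (l in avail) {
          if (!(l %in% cog)) {
            tot <- tot + conc[l] * exp(-net$energy_table[site, l])
          }
        }
        tot
      }, numeric(1)))
      Ccog <- sum(conc[intersect(avail, cog)])
      if (Ccog > 0) {
        (exp(-Ea) + Nk) / (Ccog + exp(-Ea) + Nk)
      } else {
        Nk / (exp(-Ea) + Nk)
      }
    }, numeric(1))
    mean(xs)
  }
  set.seed(55)
  E <- matrix(stats::runif(25, 0.5, 6), 5, 5)
  diag(E) <- 0
  # gene g4 is regulated by two TFs; the rest one each
  regulon <- data.frame(
    tf_id = c("tf01", "tf02", "tf03", "tf04", "tf05", "tf05"),
    gene_id = c("g1", "g2", "g3", "g4", "g4", "g5"))
  net <- manual_network(E, regulon = regulon)
  for (k in 1:5) {
    subsets <- utils::combn(5, k)
    for (j in seq_len(ncol(subsets))) {
      avail <- subsets[, j]
      expect_equal(realized_crosstalk(net, avail, 3),
                   oracle(net, avail, 3))
    }
  }
  # the energy gap cancels once the concentration is rescaled with it
  expect_equal(realized_crosstalk(net, 1:3, 3 * exp(1.5), Ea = 1.5),
               oracle(net, 1:3, 3 * exp(1.5), Ea = 1.5))
})

test_that("crosstalk curves are seeded and vanish at zero availability", {
  net <- hetero_network(12, seed = 3)
  tg <- c(0, 0.25, 0.5, 0.75, 1)
  a <- min_crosstalk_curve(net, t_grid = tg, n_draws = 10, seed = 9)
  b <- min_crosstalk_curve(net, t_grid = tg, n_draws = 10, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$mean_xstar[a$t == 0], 0)
  expect_true(all(a$mean_xstar >= 0 & a$mean_xstar <= 1))
  expect_true(all(a$sd_xstar >= 0))
  expect_error(min_crosstalk_curve(net, t_grid = tg, n_draws = 10),
               "seed")
  # non-achievable availabilities are rounded, with notice
  expect_message(
    min_crosstalk_curve(net, t_grid = c(0.13), n_draws = 2, seed = 1),
    "rounded")
})

test_that("a symmetric network reproduces the analytic crosstalk law", {
  n <- 40
  eps0 <- 6
  w <- exp(-eps0)
  s_constr <- (n - 1) * w
  net <- sym_network(n, eps0)
  tg <- seq(0.2, 1, length.out = 9)
  cur <- min_crosstalk_curve(net, t_grid = tg, n_draws = 20, seed = 14)
  ana <- xstar_law(s_constr, cur$t)
  # deterministic residual bound: the analytic law sees (n-1) competitors
  # where an available subset of k offers k-1 (bound sites) or k (unbound),
  # a relative similarity offset of at most 1/(n-1) + (n-k)/(k(n-1));
  # X* responds with elasticity <= 1/2
  k <- cur$k
  slack <- 2 * cur$sd_xstar / sqrt(20) +
    ana * 0.5 * (1 / (n - 1) + (n - k) / (k * (n - 1)))
  expect_true(all(abs(cur$mean_xstar - ana) <= slack + 1e-12))
  # the optimal concentration is interior away from full availability
  expect_false(any(cur$edge_pinned[cur$t < 0.95]))
})

test_that("widening the concentration grid never raises the minimum", {
  net <- hetero_network(10, seed = 6)
  tg <- c(0.3, 0.6)
  narrow <- net$M * 10^seq(-1, 2, length.out = 20L)
  wide <- c(net$M * 10^seq(-5, -1.2, length.out = 10L), narrow,
            net$M * 10^seq(2.2, 6, length.out = 10L))
  a <- min_crosstalk_curve(net, t_grid = tg, n_draws = 10,
                           concentration_grid = narrow, seed = 4)
  b <- min_crosstalk_curve(net, t_grid = tg, n_draws = 10,
                           concentration_grid = wide, seed = 4)
  expect_true(all(b$mean_xstar <= a$mean_xstar + 1e-12))
})

test_that("effective-similarity fitting recovers known parameters", {
  tg <- seq(0.05, 0.95, length.out = 12)
  exact <- data.frame(t = tg, mean_xstar = xstar_law(0.02, tg))
  fit <- fit_s_effective(exact)
  expect_equal(unname(coef(fit)), 0.02, tolerance = 1e-6)
  expect_lt(fit$ssr, 1e-12)
  # noisy curve: recovery within 10 percent
  set.seed(71)
  noisy <- exact
  noisy$mean_xstar <- noisy$mean_xstar + stats::rnorm(12, 0, 0.001)
  fn <- fit_s_effective(noisy)
  expect_lt(abs(coef(fn) / 0.02 - 1), 0.1)
  # degenerate inputs
  expect_error(fit_s_effective(data.frame(t = c(0.1, 0.2),
                                          mean_xstar = c(0.1, 0.2))),
               "at least 3")
  expect_error(fit_s_effective(data.frame(t = tg, mean_xstar = 0 * tg)),
               "unidentifiable")
})

test_that("the fitted model object behaves like a classed fit", {
  tg <- seq(0.1, 0.9, length.out = 9)
  fit <- fit_s_effective(data.frame(t = tg,
                                    mean_xstar = xstar_law(0.05, tg)))
  expect_s3_class(fit, "seff_fit")
  expect_named(coef(fit), "s_effective")
  expect_equal(predict(fit), fit$fitted)
  expect_equal(predict(fit, newdata = c(0.5)),
               xstar_law(coef(fit)[[1]], 0.5))
  expect_equal(residuals(fit), fit$observed - fit$fitted)
  expect_output(print(fit), "s_effective")
  expect_output(summary(fit), "residual")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("heterogeneous promiscuity bends the curve away from one shared s", {
  # with a broad mix of promiscuities the single-s analytic fit misses
  # most at intermediate availability, not at the ends
  net <- hetero_network(60, seed = 21)
  tg <- round(c(0.05, seq(0.1, 0.9, 0.1), 0.95) * 60) / 60
  cur <- min_crosstalk_curve(net, t_grid = tg, n_draws = 60, seed = 22)
  fit <- fit_s_effective(cur)
  dev <- abs(residuals(fit))
  expect_gt(max(dev), max(dev[1], dev[length(dev)]))
})
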