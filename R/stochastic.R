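#' Stochastic gene-activity model
#'
#' Each of the `M` genes is regulated (its cognate TF is present) with its
#' own probability `gamma[i]`, independently of the others. Alternatively,
#' supply per-gene demands `D_i` (probability the gene product is needed)
#' plus the per-gene regulation mode: an activator-regulated gene needs its
#' regulator exactly when its product is needed (`gamma = D`), a
#' repressor-regulated gene when it is not (`gamma = 1 - D`).
#'
#' @param M total gene count, positive integer.
#' @param gamma per-gene regulation probabilities (length `M` or a scalar,
#'   recycled). Either `gamma` or `demand` + `mode` must be given.
#' @param demand optional per-gene demands in `[0, 1]`.
#' @param mode optional per-gene regulation form, `"activator"` or
#'   `"repressor"` (recycled).
#' @return Object of class `"gene_activity_model"` with fields `M`,
#'   `gamma`, and, when supplied, `demand` and `mode`.
#' @examples
#' gene_activity_model(3000, gamma = 0.12)
#' gene_activity_model(4, demand = c(0.9, 0.9, 0.1, 0.1),
#'                     mode = c("repressor", "repressor",
#'                              "activator", "activator"))
#' @export
gene_activity_model <- function(M, gamma = NULL, demand = NULL,
                                mode = NULL) {
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 1L)
    stop("'M' must be a positive integer")
  if (is.null(gamma)) {
    if (is.null(demand) || is.null(mode))
      stop("supply either 'gamma' or both 'demand' and 'mode'")
    demand <- rep_len(as.numeric(demand), M)
    mode <- rep_len(match.arg(mode, c("activator", "repressor"),
                              several.ok = TRUE), M)
    if (any(demand < 0 | demand > 1)) stop("'demand' must lie in [0, 1]")
    gamma <- ifelse(mode == "activator", demand, 1 - demand)
  } else {
    gamma <- rep_len(as.numeric(gamma), M)
  }
  if (anyNA(gamma) || any(gamma < 0 | gamma > 1))
    stop("'gamma' must lie in [0, 1]")
  structure(list(M = M, gamma = gamma, demand = demand, mode = mode),
            class = "gene_activity_model")
}

#' @export
print.gene_activity_model <- function(x, ...) {
  cat(sprintf(
    "Stochastic gene-activity model: M = %d genes, <gamma> = %.4g\n",
    x$M, mean(x$gamma)))
  invisible(x)
}

# Exact Poisson-binomial pmf of T = sum Bernoulli(gamma_i), by iterative
# convolution; O(M^2) but vectorized per step.
poisson_binomial_pmf <- function(gamma) {
  f <- 1
  for (g in gamma) {
    f <- c(f * (1 - g), 0) + c(0, f * g)
  }
  f
}

#' Distribution of the fraction of available TF species
#'
#' The number of available TF species `T = sum_i Bernoulli(gamma_i)`
#' follows a Poisson-binomial distribution; the availability fraction is
#' `t = T / M`. Three methods are offered: `"exact"` (iterative
#' convolution of the Bernoulli pmfs), `"gaussian"` (central-limit normal
#' with matching mean and variance) and `"montecarlo"`.
#'
#' The exact mean is `mean(gamma)` and the exact variance
#' `sum(gamma (1 - gamma)) / M^2` (the variance of `T` scaled by `1/M^2`).
#'
#' @param model a [gene_activity_model()].
#' @param method `"exact"`, `"gaussian"` or `"montecarlo"`.
#' @param exact_cap refuse `method = "exact"` beyond this `M` (the
#'   convolution is quadratic in `M`); raise it deliberately if needed.
#' @param n_draws,seed Monte-Carlo settings.
#' @return Object of class `"availability_distribution"`: list with
#'   `support` (achievable `t = k/M`, for the exact/Monte-Carlo methods),
#'   `pmf` (summing to 1) or `density` function, `mean`, `variance` and
#'   `method`.
#' @examples
#' m <- gene_activity_model(2, gamma = 0.5)
#' availability_distribution(m)$pmf   # 0.25 0.50 0.25
#' @export
availability_distribution <- function(model,
                                      method = c("exact", "gaussian",
                                                 "montecarlo"),
                                      exact_cap = 5000L,
                                      n_draws = 1e5, seed = NULL) {
  stopifnot(inherits(model, "gene_activity_model"))
  method <- match.arg(method)
  M <- model$M
  g <- model$gamma
  mu <- mean(g)
  v <- sum(g * (1 - g)) / M^2
  out <- switch(method,
    exact = {
      if (M > exact_cap)
        stop("M = ", M, " exceeds the exact-method cap (", exact_cap,
             "); use method = 'gaussian' or 'montecarlo', or raise ",
             "'exact_cap'")
      pmf <- poisson_binomial_pmf(g)
      list(support = (0:M) / M, pmf = pmf, density = NULL)
    },
    gaussian = {
      dens <- function(t) stats::dnorm(t, mean = mu, sd = sqrt(v))
      list(support = NULL, pmf = NULL, density = dens)
    },
    montecarlo = {
      if (is.null(seed)) stop("method = 'montecarlo' requires a 'seed'")
      draws <- sample_availability_counts(g, n_draws, seed)
      pmf <- tabulate(draws + 1L, nbins = M + 1L) / n_draws
      list(support = (0:M) / M, pmf = pmf, density = NULL)
    })
  structure(c(out, list(mean = mu, variance = v, method = method, M = M)),
            class = "availability_distribution")
}

#' @export
print.availability_distribution <- function(x, ...) {
  cat(sprintf(
    "Availability distribution (%s): M = %d, mean t = %.4g, sd = %.4g\n",
    x$method, x$M, x$mean, sqrt(x$variance)))
  invisible(x)
}

# Draw n realizations of T = sum_i Bernoulli(gamma_i), chunked to bound
# memory. Identical-gamma models reduce to a binomial but the generic
# per-gene draw is kept so that arbitrary gamma vectors follow one path.
sample_availability_counts <- function(gamma, n, seed,
                                       chunk = 200000L) {
  set.seed(seed)
  M <- length(gamma)
  per_chunk <- max(1L, chunk %/% M)
  out <- integer(n)
  done <- 0L
  while (done < n) {
    k <- min(per_chunk, n - done)
    u <- matrix(stats::runif(M * k), nrow = M)
    out[(done + 1L):(done + k)] <- colSums(u < gamma)
    done <- done + k
  }
  out
}

# ---- minimal-crosstalk distribution under stochastic availability -------

# Forward map t -> X*(t; s) and its regime partition over t in [0, 1].
# Regime II occupies t in (t_max, 1]; regime I occupies u = s(1-t) >= 1,
# i.e. t <= 1 - 1/s (only when s > 1); regime III the rest.
xstar_regime_of_t <- function(s, t) {
  u <- s * (1 - t)
  r <- sqrt(pmax(u, 0))
  reg <- integer(length(t))
  reg[u >= 1] <- 1L
  den <- ifelse(t > 0, r / t - s * (1 - r), Inf)
  reg[u < 1 & den <= 0] <- 2L
  reg[reg == 0L] <- 3L
  reg[t == 0] <- 3L
  reg
}

# Boundary t_max(s) between regimes III and II (smallest t with divergent
# optimal concentration); 1 if regime II is never reached.
t_max_boundary <- function(s) {
  f <- function(t) {
    r <- sqrt(s * (1 - t))
    r / t - s * (1 - r)
  }
  if (f(1) > 0) return(1)
  lo <- if (s > 1) 1 - 1 / s else 1e-12
  if (f(lo) <= 0) return(lo)
  stats::uniroot(f, c(lo, 1), tol = 1e-12)$root
}

#' Distribution of minimal crosstalk under stochastic availability
#'
#' Transforms the availability distribution `f_t` through the minimal
#' crosstalk map `X*(t; s)` by the change-of-variables rule
#' \eqn{f_{X^*}(x) = \sum_i f_t(g_i^{-1}(x)) |dg_i^{-1}/dx|}, with one
#' inverse branch per regime: regime I has `g^{-1}(x) = x` with unit
#' derivative; regime II has `g^{-1}(x) = (1 - x) / (1 - s + s x)` with
#' derivative `-(1 - s + s x)^{-2}`; regime III (and the rising/falling
#' branches around the maximizer `t*`) is inverted numerically by
#' bisection on each monotone branch, with the derivative from the
#' inverse-function rule via a centered finite difference of the forward
#' map.
#'
#' With `method = "exact"` the discrete Poisson-binomial pmf is pushed
#' through the map, giving the exact discrete distribution of `X*` (pmf
#' over the achievable values); with `method = "gaussian"` a continuous
#' density is returned.
#'
#' @param model a [gene_activity_model()].
#' @param s rescaled similarity, positive.
#' @param method availability method, `"exact"` or `"gaussian"`.
#' @param exact_cap passed to [availability_distribution()].
#' @return Object of class `"xstar_distribution"`: list with `s`,
#'   `method`; for `"exact"`: `support` (X* values on the availability
#'   lattice), `pmf`, plus `cdf(x)`; for `"gaussian"`: `density(x)` and
#'   `cdf(x)` functions plus the branch bookkeeping (`t_star`, `t_max`).
#' @examples
#' m <- gene_activity_model(100, gamma = 0.12)
#' d <- xstar_distribution(m, s = 0.01)
#' sum(d$pmf)
#' @export
xstar_distribution <- function(model, s, method = c("exact", "gaussian"),
                               exact_cap = 5000L) {
  stopifnot(inherits(model, "gene_activity_model"))
  method <- match.arg(method)
  if (!is.finite(s) || s <= 0) stop("'s' must be a positive number")
  M <- model$M

  if (method == "exact") {
    av <- availability_distribution(model, "exact", exact_cap = exact_cap)
    tg <- av$support
    xv <- xstar_closed(s, tg)
    # aggregate probability over lattice points mapping to equal X*
    o <- order(xv)
    xs <- xv[o]; ps <- av$pmf[o]
    grp <- cumsum(c(TRUE, diff(xs) > 1e-15))
    support <- as.numeric(tapply(xs, grp, `[`, 1L))
    pmf <- as.numeric(tapply(ps, grp, sum))
    cdfv <- cumsum(pmf)
    cdf <- function(x) {
      idx <- findInterval(x, support + 1e-300)
      ifelse(idx == 0L, 0, cdfv[pmax(idx, 1L)])
    }
    return(structure(list(s = s, method = "exact", support = support,
                          pmf = pmf, cdf = cdf, M = M),
                     class = "xstar_distribution"))
  }

  av <- availability_distribution(model, "gaussian")
  ft <- av$density
  Ft <- function(t) stats::pnorm(t, mean = av$mean,
                                 sd = sqrt(av$variance))
  t_star <- xstar_argmax_t(s)
  t_mx <- t_max_boundary(s)
  t_reg1 <- if (s > 1) 1 - 1 / s else 0   # t <= t_reg1 is regime I
  x_peak <- xstar_closed(s, t_star)

  # numeric inverse of the forward map on a monotone branch [lo, hi]
  inv_branch <- function(x, lo, hi, increasing) {
    vapply(x, function(xi) {
      f <- function(t) xstar_closed(s, t) - xi
      flo <- f(lo); fhi <- f(hi)
      if (increasing) {
        if (xi < xstar_closed(s, lo) || xi > xstar_closed(s, hi))
          return(NA_real_)
      } else {
        if (xi > xstar_closed(s, lo) || xi < xstar_closed(s, hi))
          return(NA_real_)
      }
      if (flo == 0) return(lo)
      if (fhi == 0) return(hi)
      stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    }, numeric(1))
  }
  fwd_deriv <- function(t, h = 1e-6) {
    hl <- pmin(h, t); hr <- pmin(h, 1 - t)
    (xstar_closed(s, t + hr) - xstar_closed(s, t - hl)) / (hr + hl)
  }
  # branches of the forward map over t: rising on (t_reg1, t_star],
  # falling on [t_star, 1]; regime I identity on [0, t_reg1]
  density <- function(x) {
    out <- numeric(length(x))
    if (t_reg1 > 0) {                      # regime I: identity
      ok <- x >= 0 & x <= t_reg1
      out[ok] <- out[ok] + ft(x[ok])
    }
    lo1 <- t_reg1
    ti <- inv_branch(x, lo1, t_star, TRUE)
    ok <- !is.na(ti)
    out[ok] <- out[ok] + ft(ti[ok]) / abs(fwd_deriv(ti[ok]))
    if (t_star < 1) {
      ti2 <- inv_branch(x, t_star, 1, FALSE)
      ok2 <- !is.na(ti2)
      out[ok2] <- out[ok2] + ft(ti2[ok2]) / abs(fwd_deriv(ti2[ok2]))
    }
    out
  }
  cdf <- function(x) {
    vapply(x, function(xi) {
      p <- 0
      if (t_reg1 > 0) p <- p + max(0, min(Ft(min(xi, t_reg1)), Ft(t_reg1)))
      ti <- inv_branch(xi, t_reg1, t_star, TRUE)
      p <- p + if (!is.na(ti)) Ft(ti) - Ft(t_reg1)
               else if (xi >= x_peak) Ft(t_star) - Ft(t_reg1) else 0
      if (t_star < 1) {
        ti2 <- inv_branch(xi, t_star, 1, FALSE)
        p <- p + if (!is.na(ti2)) Ft(1) - Ft(ti2)
                 else if (xi >= x_peak) Ft(1) - Ft(t_star) else 0
      }
      p
    }, numeric(1))
  }
  structure(list(s = s, method = "gaussian", density = density,
                 cdf = cdf, t_star = t_star, t_max = t_mx, M = M),
            class = "xstar_distribution")
}

#' @export
print.xstar_distribution <- function(x, ...) {
  cat(sprintf("Minimal-crosstalk distribution (s = %g, %s method)\n",
              x$s, x$method))
  if (x$method == "exact")
    cat(sprintf("  mean X* = %.5g, sd = %.3g over %d support points\n",
                sum(x$support * x$pmf),
                sqrt(sum(x$support^2 * x$pmf) -
                       sum(x$support * x$pmf)^2),
                length(x$support)))
  invisible(x)
}

#' Regime-II inverse of the minimal-crosstalk map
#'
#' In the divergent-concentration regime, `X*(t) = 1 - t / (1 + alpha t)`
#' with `alpha = s`; the inverse is
#' `t(x) = (1 - x) / (1 - alpha + alpha x)` and its derivative (by direct
#' differentiation) `-(1 - alpha + alpha x)^{-2}`.
#'
#' @param x crosstalk value(s).
#' @param alpha similarity parameter (the `c -> Inf` limit slope), `= s`.
#' @return List with `t` and `dtdx`.
#' @examples
#' regime2_inverse(2/3, alpha = 1)$t    # 0.5
#' @export
regime2_inverse <- function(x, alpha) {
  den <- 1 - alpha + alpha * x
  list(t = (1 - x) / den, dtdx = -1 / den^2)
}

#' Monte-Carlo sample of minimal crosstalk
#'
#' Per realization, each gene's regulator is drawn present with its
#' probability `gamma[i]`; the availability fraction `t = T / M` is formed
#' and the minimal crosstalk `X*(t; s)` evaluated (memoized over the
#' `M + 1` achievable `t` values).
#'
#' @param model a [gene_activity_model()].
#' @param s rescaled similarity, positive.
#' @param n_realizations sample size (the full-scale study used 1e6;
#'   scale to taste).
#' @param seed integer seed; required, for reproducibility.
#' @return Numeric vector of `n_realizations` minimal-crosstalk values.
#' @examples
#' m <- gene_activity_model(100, gamma = 0.12)
#' x <- xstar_samples(m, s = 0.01, n_realizations = 100, seed = 1)
#' @export
xstar_samples <- function(model, s, n_realizations = 1e6, seed) {
  stopifnot(inherits(model, "gene_activity_model"))
  if (missing(seed)) stop("'seed' is required")
  if (n_realizations < 1) stop("'n_realizations' must be >= 1")
  counts <- sample_availability_counts(model$gamma, n_realizations, seed)
  lut <- xstar_closed(s, (0:model$M) / model$M)
  lut[counts + 1L]
}
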