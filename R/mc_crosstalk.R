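#' Global crosstalk of a network for one availability realization
#'
#' Evaluates the thermodynamic crosstalk of every gene given a fixed set
#' of available TFs sharing the total concentration equally (or given
#' per-TF concentrations), and averages over genes. A gene whose cognate
#' TF(s) are (partly) available is a required-bound site and contributes
#' \eqn{(e^{-E_a} + N_k) / (C_{cog,k} + e^{-E_a} + N_k)}; a gene with no
#' available cognate contributes \eqn{N_k / (e^{-E_a} + N_k)}. Here
#' \eqn{N_k = \sum_{l\, noncognate, avail} C_l e^{-E^{kl}}} is the foreign
#' binding weight at the gene's site (averaged over candidate sites for
#' multi-cognate genes) and \eqn{C_{cog,k}} the summed concentration of
#' the gene's available cognates.
#'
#' @param network a [tf_network()].
#' @param available TF ids or indices present; may be empty.
#' @param total_concentration total TF concentration shared equally among
#'   the available TFs; positive.
#' @param Ea cognate bound/unbound energy gap (kT), default 0 (it cancels
#'   at the concentration optimum).
#' @param per_tf_concentrations optional explicit per-TF concentration
#'   vector (full length, absent TFs ignored); overrides the equal split.
#' @return Global crosstalk `X` in `[0, 1]`.
#' @export
realized_crosstalk <- function(network, available, total_concentration,
                               Ea = 0, per_tf_concentrations = NULL) {
  stopifnot(inherits(network, "tf_network"))
  if (network$M == 0L) stop("network has no genes")
  if (!is.finite(total_concentration) || total_concentration <= 0)
    stop("'total_concentration' must be positive")
  avail <- if (length(available) == 0L) integer(0)
           else resolve_tf_subset(network, available)
  prof <- crosstalk_profile(network, avail, Ea = Ea,
                            per_tf = per_tf_concentrations)
  prof(total_concentration)
}

# Precomputes the per-gene foreign weights and cognate multiplicities for
# a fixed availability subset and returns X as a vectorized function of
# the total concentration.
crosstalk_profile <- function(network, avail, Ea = 0, per_tf = NULL) {
  M <- network$M
  eEa <- exp(-Ea)
  k <- length(avail)
  if (k == 0L) {
    return(function(C) rep(0, length(C)))
  }
  W <- exp(-network$energy_table)
  if (is.null(per_tf)) {
    rel <- rep(1 / k, k)            # equal split of the total
  } else {
    rel <- per_tf[avail] / sum(per_tf[avail])
  }
  A <- numeric(M)   # sum of rel-weighted foreign Boltzmann weights
  mcog <- numeric(M)  # rel-weight of available cognates
  for (gi in seq_len(M)) {
    cog <- network$genes$cognates[[gi]]
    noncog <- !(avail %in% cog)
    A[gi] <- mean(vapply(cog, function(site) {
      sum(rel[noncog] * W[site, avail[noncog]])
    }, numeric(1)))
    mcog[gi] <- sum(rel[!noncog])
  }
  bound <- mcog > 0
  function(C) {
    N <- outer(A, C)                 # M x length(C)
    Ccog <- outer(mcog, C)
    x <- (eEa + N) / (Ccog + eEa + N)
    if (any(!bound)) x[!bound, ] <- (N / (eEa + N))[!bound, ]
    colMeans(x)
  }
}

#' Concentration-optimized crosstalk curve of a network
#'
#' For each target availability fraction `t`, draws random subsets of
#' `round(t * n_tf)` available TFs, computes the draw-averaged global
#' crosstalk on a log-spaced concentration grid, and keeps the
#' concentration minimizing the average -- the Monte-Carlo analogue of
#' minimizing the analytic crosstalk over `c`. The spread across draws at
#' the optimal concentration is recorded.
#'
#' @param network a [tf_network()].
#' @param t_grid availability fractions in `[0, 1]`; non-achievable values
#'   are rounded to the nearest `k / n_tf` (with a message).
#' @param n_draws random availability subsets per `t` (default 100).
#' @param concentration_grid positive concentrations scanned; default a
#'   log grid spanning `M * 10^-6` to `M * 10^6`.
#' @param Ea energy gap (kT), default 0.
#' @param seed integer seed; required.
#' @return Object of class `"crosstalk_curve"`: data frame with columns
#'   `t`, `k`, `mean_xstar`, `sd_xstar`, `c_opt`, `edge_pinned`, plus
#'   attributes `n_draws`, `seed`, `n_tf`, `M`, `concentration_grid`.
#'   `edge_pinned` flags optima sitting on a grid edge (the Monte-Carlo
#'   mirror of the divergent-concentration anomaly).
#' @export
min_crosstalk_curve <- function(network,
                                t_grid = seq(0.05, 1, length.out = 20L),
                                n_draws = 100L,
                                concentration_grid = NULL,
                                Ea = 0, seed) {
  stopifnot(inherits(network, "tf_network"))
  if (missing(seed)) stop("'seed' is required")
  if (n_draws < 1L) stop("'n_draws' must be >= 1")
  n <- length(network$tf_ids)
  if (is.null(concentration_grid)) {
    concentration_grid <- network$M * 10^seq(-6, 6, length.out = 97L)
  }
  cg <- sort(as.numeric(concentration_grid))
  if (any(cg <= 0)) stop("concentrations must be positive")

  ks <- as.integer(round(t_grid * n))
  if (any(abs(ks / n - t_grid) > 1e-9)) {
    message("some t values are not multiples of 1/", n,
            "; rounded to the nearest achievable availability")
  }
  set.seed(seed)
  rows <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    if (k == 0L) {
      return(data.frame(t = 0, k = 0L, mean_xstar = 0, sd_xstar = 0,
                        c_opt = NA_real_, edge_pinned = FALSE))
    }
    profs <- vector("list", n_draws)
    draws <- matrix(0, n_draws, length(cg))
    for (d in seq_len(n_draws)) {
      avail <- sort(sample.int(n, k))
      profs[[d]] <- crosstalk_profile(network, avail, Ea = Ea)
      draws[d, ] <- profs[[d]](cg)
    }
    avg_at <- function(C) {
      mean(vapply(profs, function(p) p(C), numeric(1)))
    }
    avg <- colMeans(draws)
    j <- which.min(avg)
    pinned <- j == 1L || j == length(cg)
    if (!pinned) {
      # local refinement between the neighbouring grid points
      opt <- stats::optimize(function(lc) avg_at(exp(lc)),
                             log(c(cg[j - 1L], cg[j + 1L])), tol = 1e-10)
      c_opt <- exp(opt$minimum)
      xbar <- opt$objective
    } else {
      c_opt <- cg[j]
      xbar <- avg[j]
    }
    per_draw <- vapply(profs, function(p) p(c_opt), numeric(1))
    data.frame(t = k / n, k = k, mean_xstar = xbar,
               sd_xstar = stats::sd(per_draw),
               c_opt = c_opt, edge_pinned = pinned)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("crosstalk_curve", "data.frame"),
            n_draws = n_draws, seed = seed, n_tf = n, M = network$M,
            concentration_grid = cg)
}

#' @export
print.crosstalk_curve <- function(x, ...) {
  cat(sprintf(
    "Concentration-optimized crosstalk curve: %d t values, %d draws each (%d TFs, %d genes)\n",
    nrow(x), attr(x, "n_draws"), attr(x, "n_tf"), attr(x, "M")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fit an effective similarity to a crosstalk curve
#'
#' Scalar least-squares fit of the analytic minimal-crosstalk law
#' \eqn{X^*(t; s)} (with full regime handling) to the numerically
#' computed `mean_xstar` over the curve's `t` grid: the single similarity
#' value a fully symmetric network would need to reproduce the observed
#' crosstalk. The search is a log-spaced scan followed by local
#' refinement.
#'
#' @param curve a [min_crosstalk_curve()] result, or any data frame with
#'   columns `t` and `mean_xstar`.
#' @param s_range positive search interval for `s`.
#' @param n_scan scan resolution.
#' @return Object of class `"seff_fit"`: list with `s_effective`, `ssr`
#'   (sum of squared residuals), `t_grid`, `observed`, `fitted`,
#'   `curve`. Methods: `print`, `summary`, `coef`, `predict` (at new `t`),
#'   `residuals`, `plot`.
#' @examples
#' tg <- seq(0.1, 0.9, length.out = 9)
#' curve <- data.frame(t = tg, mean_xstar = xstar_law(0.02, tg))
#' coef(fit_s_effective(curve))
#' @export
fit_s_effective <- function(curve, s_range = c(1e-8, 1e2),
                            n_scan = 400L) {
  if (!all(c("t", "mean_xstar") %in% names(curve)))
    stop("'curve' needs columns 't' and 'mean_xstar'")
  keep <- is.finite(curve$t) & is.finite(curve$mean_xstar)
  tg <- curve$t[keep]
  y <- curve$mean_xstar[keep]
  if (sum(keep) < 3L || length(unique(tg)) < 3L)
    stop("need at least 3 non-degenerate t points to fit s_effective")
  if (all(y == 0)) stop("all-zero crosstalk curve: s is unidentifiable")
  ssr <- function(ls) {
    s <- exp(ls)
    sum((xstar_closed(s, tg) - y)^2)
  }
  lg <- seq(log(s_range[1]), log(s_range[2]), length.out = n_scan)
  v <- vapply(lg, ssr, numeric(1))
  i <- which.min(v)
  lo <- lg[max(1L, i - 1L)]
  hi <- lg[min(n_scan, i + 1L)]
  opt <- stats::optimize(ssr, c(lo, hi), tol = 1e-12)
  s_eff <- exp(opt$minimum)
  structure(list(s_effective = s_eff, ssr = opt$objective, t_grid = tg,
                 observed = y, fitted = xstar_closed(s_eff, tg),
                 curve = curve),
            class = "seff_fit")
}

#' Analytic minimal-crosstalk law
#'
#' Vectorized closed-form \eqn{X^*(t; s)} with regime handling (the curve
#' that [fit_s_effective()] fits).
#'
#' @param s similarity, positive scalar.
#' @param t availability fraction(s) in `[0, 1]`.
#' @return Minimal crosstalk value(s).
#' @export
xstar_law <- function(s, t) {
  stopifnot(length(s) == 1L, is.finite(s), s > 0,
            all(t >= 0 & t <= 1))
  xstar_closed(s, t)
}

#' @export
print.seff_fit <- function(x, ...) {
  cat(sprintf("Effective similarity fit: s_effective = %.6g (SSR = %.3g over %d t values)\n",
              x$s_effective, x$ssr, length(x$t_grid)))
  invisible(x)
}

#' @export
summary.seff_fit <- function(object, ...) {
  res <- object$observed - object$fitted
  cat(sprintf("Effective similarity fit over %d t values\n",
              length(object$t_grid)))
  cat(sprintf("  s_effective = %.6g\n", object$s_effective))
  cat(sprintf("  SSR = %.4g, RMS residual = %.4g, max |residual| = %.4g\n",
              object$ssr, sqrt(mean(res^2)), max(abs(res))))
  invisible(object)
}

#' @export
coef.seff_fit <- function(object, ...) {
  c(s_effective = object$s_effective)
}

#' @export
predict.seff_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t_grid
       else if (is.data.frame(newdata)) newdata$t
       else as.numeric(newdata)
  xstar_closed(object$s_effective, t)
}

#' @export
residuals.seff_fit <- function(object, ...) {
  object$observed - object$fitted
}

#' @export
plot.seff_fit <- function(x, ...) {
  tt <- seq(0, 1, length.out = 201L)
  plot(x$t_grid, x$observed, pch = 16,
       xlab = "fraction of available TFs t",
       ylab = "minimal global crosstalk X*", ...)
  graphics::lines(tt, xstar_closed(x$s_effective, tt), col = 2)
  graphics::legend("topleft", legend = c("numerical curve",
                                         sprintf("analytic fit, s_eff = %.3g",
                                                 x$s_effective)),
                   pch = c(16, NA), lty = c(NA, 1), col = c(1, 2),
                   bty = "n")
  invisible(x)
}
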