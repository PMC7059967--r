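#' Concentration-weighted mean Boltzmann similarity
#'
#' Average similarity between one binding site and a set of competing
#' (non-cognate) sites, defined as the concentration-weighted mean of the
#' competitors' Boltzmann weights \eqn{e^{-\epsilon d}}. With equal
#' concentrations this reduces to the plain mean \eqn{(1/T)\sum_j w_j}.
#'
#' @param boltzmann_weights numeric vector of nonnegative Boltzmann weights,
#'   one per competitor (e.g. `exp(-eps * d)` for `d` mismatches).
#' @param concentrations numeric vector of nonnegative concentrations, one
#'   per competitor. Defaults to equal concentrations.
#' @return A single similarity value in `[0, max(weights)]`; `0` for an
#'   empty competitor set.
#' @examples
#' mismatch_similarity(exp(-2))                    # single competitor
#' mismatch_similarity(c(1, exp(-1)), c(2, 1))     # weighted mean
#' @export
mismatch_similarity <- function(boltzmann_weights,
                                concentrations = NULL) {
  w <- as.numeric(boltzmann_weights)
  if (length(w) == 0L) return(0)
  if (is.null(concentrations)) concentrations <- rep(1, length(w))
  cc <- as.numeric(concentrations)
  if (length(cc) != length(w))
    stop("'boltzmann_weights' and 'concentrations' must have equal length")
  if (anyNA(w) || anyNA(cc) || any(w < 0) || any(cc < 0))
    stop("weights and concentrations must be nonnegative and non-missing")
  if (sum(cc) == 0) return(0)
  sum(cc * w) / sum(cc)
}

#' Rescaled thermodynamic state of the symmetric crosstalk model
#'
#' Bundles the macroscopic variables of the symmetric many-genes model:
#' rescaled inter-site similarity `s` (= S * M), fraction of available TF
#' species `t` (= T / M), rescaled total TF concentration `c` (= C / M) and
#' the cognate bound/unbound energy gap `Ea` in kT units. All crosstalk
#' quantities are invariant under the joint substitution
#' `(c, Ea) -> (c * exp(Ea), 0)`, so `Ea` only shifts the concentration
#' scale; minimal crosstalk does not depend on it at all.
#'
#' @param s rescaled similarity, positive.
#' @param t fraction of available TF species, in `[0, 1]`.
#' @param c rescaled total TF concentration, nonnegative.
#' @param Ea cognate bound/unbound energy gap (kT). Default 0.
#' @return An object of class `"thermo_state"`.
#' @examples
#' st <- thermo_state(s = 0.01, t = 0.5, c = 100)
#' crosstalk_probabilities(st)
#' global_crosstalk(st)
#' @export
thermo_state <- function(s, t, c, Ea = 0) {
  stopifnot(length(s) == 1L, length(t) == 1L, length(c) == 1L,
            length(Ea) == 1L)
  if (!is.finite(s) || s <= 0) stop("'s' must be a positive number")
  if (!is.finite(t) || t < 0 || t > 1) stop("'t' must lie in [0, 1]")
  if (is.na(c) || c < 0) stop("'c' must be nonnegative")
  if (!is.finite(Ea)) stop("'Ea' must be finite")
  structure(list(s = s, t = t, c = c, Ea = Ea), class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf(
    "Thermodynamic state: s = %g, t = %g, c = %g, Ea = %g kT\n",
    x$s, x$t, x$c, x$Ea))
  invisible(x)
}

#' Single-gene crosstalk probabilities
#'
#' Equilibrium probabilities that a gene is in an erroneous regulatory
#' state, split by the gene's desired state. `x_bound` applies to genes
#' whose site should be occupied by its cognate TF (crosstalk: site empty
#' or bound by a foreign TF); `x_unbound` to genes whose site should stay
#' empty (crosstalk: any binding).
#'
#' @param state a [thermo_state()].
#' @return Named numeric vector `c(x_bound =, x_unbound =)`, both in
#'   `[0, 1]`. When `t = 0` the cognate concentration `c / t` is undefined
#'   and `x_bound` cannot be formed; an error is raised.
#' @examples
#' crosstalk_probabilities(thermo_state(0.01, 0.5, 100))
#' @export
crosstalk_probabilities <- function(state) {
  stopifnot(inherits(state, "thermo_state"))
  # canonical rescaling: exact identity (c, Ea) -> (c * exp(Ea), 0)
  ce <- state$c * exp(state$Ea)
  s <- state$s
  t <- state$t
  x_unbound <- if (ce == 0) 0 else ce * s / (1 + ce * s)
  if (t == 0) {
    if (ce == 0) {
      x_bound <- 1  # no TFs at all: a required-bound site is surely empty
    } else {
      stop("x_bound is undefined for t = 0: cognate concentration c/t ",
           "does not exist")
    }
  } else {
    x_bound <- (1 + ce * s) / (ce / t + 1 + ce * s)
  }
  c(x_bound = x_bound, x_unbound = x_unbound)
}

#' Global crosstalk of the symmetric model
#'
#' Average fraction of genes in an erroneous regulatory state,
#' \eqn{X = t x_{bound} + (1 - t) x_{unbound}}. Depends on the regulatory
#' design only through the fraction of available TF species `t`.
#'
#' @inheritParams crosstalk_probabilities
#' @return Global crosstalk `X` in `[0, 1]`.
#' @examples
#' global_crosstalk(thermo_state(0.01, 0.5, 100))
#' @export
global_crosstalk <- function(state) {
  stopifnot(inherits(state, "thermo_state"))
  t <- state$t
  if (t == 0) {
    ce <- state$c * exp(state$Ea)
    return(if (ce == 0) 0 else ce * state$s / (1 + ce * state$s))
  }
  xp <- crosstalk_probabilities(state)
  unname(t * xp["x_bound"] + (1 - t) * xp["x_unbound"])
}

# Vectorized global crosstalk in the canonical (Ea = 0) scale.
# `c` may be a vector; s, t scalars.
xtalk_at <- function(c, s, t) {
  xu <- ifelse(c == 0, 0, c * s / (1 + c * s))
  if (t == 0) return(xu)
  xb <- (1 + c * s) / (c / t + 1 + c * s)
  t * xb + (1 - t) * xu
}

# Closed-form minimal crosstalk, vectorized over t (scalar s).
# Regime I  (u = s(1-t) >= 1):      X* = t,                 c* = 0
# Regime II (interior optimum lost): X* = 1 - t/(1 + s t),  c* -> Inf
# Regime III:                        X* = t (2 sqrt(u) - u),
#   c* = (1 - sqrt(u)) / (sqrt(u)/t - s (1 - sqrt(u)))
# The regime II/III boundary is where the c* denominator changes sign.
xstar_closed <- function(s, t) {
  u <- s * (1 - t)
  r <- sqrt(u)
  x <- numeric(length(t))
  reg1 <- u >= 1
  den <- r / t - s * (1 - r)          # NaN/Inf handled below
  reg2 <- !reg1 & t > 0 & den <= 0
  reg3 <- !reg1 & !reg2
  x[reg1] <- t[reg1]
  x[reg2] <- 1 - t[reg2] / (1 + s * t[reg2])
  x[reg3] <- t[reg3] * (2 * r[reg3] - u[reg3])
  x[t == 0] <- 0
  x
}

xstar_regime_labels <- c("I_no_regulation", "II_divergent_concentration",
                         "III_regulation")

#' Minimal global crosstalk over TF concentration
#'
#' Minimizes the global crosstalk \eqn{X(c; s, t)} over the rescaled total
#' TF concentration \eqn{c \ge 0}, including the \eqn{c \to \infty} limit,
#' and classifies the optimum into one of three regimes:
#' \describe{
#'   \item{I (no regulation)}{`c* = 0`, `X* = t`; occurs when
#'     `s (1 - t) >= 1` -- sites are so similar that any TF present does
#'     more harm than good.}
#'   \item{II (divergent concentration)}{the infimum is only approached as
#'     `c -> Inf`, `X* = 1 - t / (1 + s t)`; `c_star` is reported as
#'     `Inf`, never as a large finite number.}
#'   \item{III (regulation)}{an interior optimum `0 < c* < Inf` with
#'     `X* = t (2 sqrt(s (1 - t)) - s (1 - t))`.}
#' }
#'
#' @param s rescaled inter-site similarity, positive.
#' @param t fraction of available TF species, in `[0, 1]`.
#' @param method `"analytic"` (closed forms, default) or `"numeric"`
#'   (log-spaced concentration scan plus local refinement, with explicit
#'   three-way comparison of the `c = 0`, interior and `c -> Inf`
#'   candidates; ties broken toward smaller `c`).
#' @param c_range,n_scan scan window and resolution for
#'   `method = "numeric"`.
#' @return Object of class `"min_crosstalk"`: list with `x_star`,
#'   `c_star` (0, finite, or `Inf`), `regime` (one of
#'   `"I_no_regulation"`, `"II_divergent_concentration"`,
#'   `"III_regulation"`), `s`, `t`.
#' @examples
#' minimize_crosstalk(0.01, 0.5)       # regime III
#' minimize_crosstalk(4, 0.5)          # regime I: s(1-t) = 2 >= 1
#' minimize_crosstalk(0.01, 1)         # regime II: t = 1
#' @export
minimize_crosstalk <- function(s, t, method = c("analytic", "numeric"),
                               c_range = c(1e-8, 1e8), n_scan = 200L) {
  method <- match.arg(method)
  stopifnot(length(s) == 1L, length(t) == 1L)
  if (!is.finite(s) || s <= 0) stop("'s' must be a positive number")
  if (!is.finite(t) || t < 0 || t > 1) stop("'t' must lie in [0, 1]")

  if (t == 0) {
    return(new_min_crosstalk(0, 0, "I_no_regulation", s, t))
  }
  u <- s * (1 - t)
  if (method == "analytic") {
    if (u >= 1) {
      return(new_min_crosstalk(t, 0, "I_no_regulation", s, t))
    }
    r <- sqrt(u)
    den <- r / t - s * (1 - r)
    if (den <= 0) {
      return(new_min_crosstalk(1 - t / (1 + s * t), Inf,
                               "II_divergent_concentration", s, t))
    }
    return(new_min_crosstalk(t * (2 * r - u), (1 - r) / den,
                             "III_regulation", s, t))
  }

  # numeric route: scan + refine, then explicit three-way comparison
  cg <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n_scan))
  xv <- xtalk_at(cg, s, t)
  i <- which.min(xv)
  lo <- log(cg[max(1L, i - 1L)])
  hi <- log(cg[min(n_scan, i + 1L)])
  opt <- stats::optimize(function(lc) xtalk_at(exp(lc), s, t),
                         interval = c(lo, hi), tol = 1e-12)
  x_int <- opt$objective
  c_int <- exp(opt$minimum)
  x0 <- t                       # X(c = 0)
  xinf <- 1 - t / (1 + s * t)   # c -> Inf limit
  tol <- 1e-9
  # ties broken toward smaller c: c = 0, then interior, then Inf
  if (x0 <= x_int + tol && x0 <= xinf + tol) {
    return(new_min_crosstalk(x0, 0, "I_no_regulation", s, t))
  }
  at_edge <- i >= n_scan - 1L
  if (xinf < x_int - tol || (at_edge && abs(x_int - xinf) < 1e-6)) {
    return(new_min_crosstalk(xinf, Inf, "II_divergent_concentration", s, t))
  }
  new_min_crosstalk(x_int, c_int, "III_regulation", s, t)
}

new_min_crosstalk <- function(x_star, c_star, regime, s, t) {
  structure(list(x_star = x_star, c_star = c_star, regime = regime,
                 s = s, t = t),
            class = "min_crosstalk")
}

#' @export
print.min_crosstalk <- function(x, ...) {
  cat(sprintf("Minimal global crosstalk (s = %g, t = %g)\n", x$s, x$t))
  cat(sprintf("  X* = %.6g   c* = %s   regime %s\n", x$x_star,
              if (is.infinite(x$c_star)) "Inf (divergent)"
              else format(x$c_star, digits = 6),
              x$regime))
  invisible(x)
}

#' Minimal crosstalk along an availability grid
#'
#' Convenience wrapper evaluating [minimize_crosstalk()] on a grid of `t`
#' values at one or more similarities; the data behind the
#' crosstalk-versus-availability curves.
#'
#' @param s numeric vector of similarities.
#' @param t_points number of equally spaced `t` values in `[0, 1]`.
#' @param method passed to [minimize_crosstalk()].
#' @return Data frame with columns `s`, `t`, `x_star`, `c_star`, `regime`.
#' @examples
#' head(xstar_curve(c(1e-3, 1e-2), t_points = 11))
#' @export
xstar_curve <- function(s, t_points = 101L, method = "analytic") {
  tg <- seq(0, 1, length.out = t_points)
  out <- do.call(rbind, lapply(s, function(si) {
    rows <- lapply(tg, function(ti) {
      m <- minimize_crosstalk(si, ti, method = method)
      data.frame(s = si, t = ti, x_star = m$x_star, c_star = m$c_star,
                 regime = m$regime, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  out
}

#' Availability maximizing minimal crosstalk
#'
#' Location of the maximum of \eqn{X^*(t; s)} over `t`. In the small-`s`
#' limit \eqn{X^* \approx 2 t \sqrt{s (1 - t)}} whose maximizer is
#' `t = 2/3`; for finite `s` the maximizer moves right, never left.
#'
#' @param s similarity, positive scalar.
#' @return The maximizing `t` in `[0, 1]`.
#' @export
xstar_argmax_t <- function(s) {
  stats::optimize(function(t) xstar_closed(s, t),
                  interval = c(0, 1), maximum = TRUE,
                  tol = 1e-10)$maximum
}
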