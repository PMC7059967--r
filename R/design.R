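#' TF usage implied by a regulatory design
#'
#' Given the fraction `p` of activator-regulated genes and the fraction `q`
#' of genes required active, computes the fraction `a` of genes that are
#' both active and activator-regulated under an extreme design, and the
#' implied fraction of TF species in use `t = 1 - p - q + 2 a`.
#'
#' The "busy" design implements the Savageau demand rule (high-demand genes
#' under activators): as many active genes as possible are
#' activator-regulated, `a = min(p, q)`, giving `t = 1 - |p - q|`. The
#' "idle" design is the opposite (each gene's default state is its commonly
#' needed one): `a = q - min(1 - p, q)`, giving `t = |1 - p - q|`. For any
#' admissible hybrid, `t_idle <= t <= t_busy`.
#'
#' @param p fraction of activator-regulated genes, in `[0, 1]`.
#' @param q fraction of genes required active, in `[0, 1]`.
#' @param design `"busy"`, `"idle"`, or `"custom"` (then `a` must be
#'   given).
#' @param a for `design = "custom"`: the activator-regulated active
#'   fraction, in `[max(0, p + q - 1), min(p, q)]`.
#' @return Object of class `"design_point"`: list with `p`, `q`, `a`, `t`,
#'   `design`.
#' @examples
#' design_tf_usage(0.3, 0.3, "busy")   # t = 1: full TF usage
#' design_tf_usage(0.7, 0.3, "idle")   # t = 0: no TF needed
#' @export
design_tf_usage <- function(p, q, design = c("busy", "idle", "custom"),
                            a = NULL) {
  design <- match.arg(design)
  stopifnot(length(p) == 1L, length(q) == 1L)
  if (!is.finite(p) || p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  if (!is.finite(q) || q < 0 || q > 1) stop("'q' must lie in [0, 1]")
  a_lo <- max(0, p + q - 1)
  a_hi <- min(p, q)
  a <- switch(design,
    busy = a_hi,
    idle = q - min(1 - p, q),
    custom = {
      if (is.null(a)) stop("design = 'custom' requires 'a'")
      if (a < a_lo - 1e-12 || a > a_hi + 1e-12)
        stop(sprintf("'a' must lie in [%g, %g]", a_lo, a_hi))
      a
    })
  t <- 1 - p - q + 2 * a
  structure(list(p = p, q = q, a = a, t = t, design = design),
            class = "design_point")
}

#' @export
print.design_point <- function(x, ...) {
  cat(sprintf("%s design: p = %g, q = %g, a = %g  ->  t = %g\n",
              x$design, x$p, x$q, x$a, x$t))
  invisible(x)
}

#' Busy-versus-idle comparison over the (p, q) plane
#'
#' Evaluates both extreme designs on a grid of `(p, q)` values: TF usage
#' under each design, their difference, minimal crosstalk under each via
#' [minimize_crosstalk()], the crosstalk difference
#' `delta_xstar = X*_idle - X*_busy`, the ratio of optimizing
#' concentrations, the winning design per cell, and an anomalous-regime
#' mask (cells where either design's optimum has divergent concentration).
#'
#' @param p_grid,q_grid ordered numeric breakpoints in `[0, 1]`.
#' @param s rescaled similarity, positive.
#' @return Object of class `"design_grid"`: list of the two grids, `s`,
#'   and per-cell matrices `t_busy`, `t_idle`, `delta_t`, `xstar_busy`,
#'   `xstar_idle`, `delta_xstar`, `cstar_ratio` (busy/idle),
#'   `winning_design` (`"busy"`, `"idle"` or `"tie"`; `NA` on anomalous
#'   cells) and `anomalous_mask` (logical). Rows index `p_grid`, columns
#'   `q_grid`. `as.data.frame()` flattens to one row per cell.
#' @examples
#' g <- design_comparison_grid(seq(0, 1, 0.25), seq(0, 1, 0.25), s = 0.01)
#' head(as.data.frame(g))
#' @export
design_comparison_grid <- function(p_grid = seq(0, 1, length.out = 101L),
                                   q_grid = seq(0, 1, length.out = 101L),
                                   s = 0.01) {
  p_grid <- as.numeric(p_grid)
  q_grid <- as.numeric(q_grid)
  if (length(p_grid) == 0L || length(q_grid) == 0L)
    stop("'p_grid' and 'q_grid' must be non-empty")
  if (any(p_grid < 0 | p_grid > 1) || any(q_grid < 0 | q_grid > 1))
    stop("grid values must lie in [0, 1]")
  if (!is.finite(s) || s <= 0) stop("'s' must be a positive number")

  np <- length(p_grid); nq <- length(q_grid)
  t_busy <- outer(p_grid, q_grid, function(p, q) 1 - abs(p - q))
  t_idle <- outer(p_grid, q_grid, function(p, q) abs(1 - p - q))

  # minimal crosstalk depends on t only: memoize over the unique t values
  tv <- sort(unique(c(t_busy, t_idle)))
  mm <- lapply(tv, function(ti) minimize_crosstalk(s, ti))
  xs <- vapply(mm, `[[`, numeric(1), "x_star")
  cs <- vapply(mm, `[[`, numeric(1), "c_star")
  rg <- vapply(mm, `[[`, character(1), "regime")
  look <- function(tm, what) {
    idx <- match(round(tm, 12), round(tv, 12))
    matrix(what[idx], np, nq)
  }
  xstar_busy <- look(t_busy, xs); xstar_idle <- look(t_idle, xs)
  cstar_busy <- look(t_busy, cs); cstar_idle <- look(t_idle, cs)
  reg_busy <- look(t_busy, rg);   reg_idle <- look(t_idle, rg)

  anomalous <- reg_busy == "II_divergent_concentration" |
    reg_idle == "II_divergent_concentration"
  delta_x <- xstar_idle - xstar_busy
  winner <- matrix(NA_character_, np, nq)
  eps <- 1e-12
  winner[!anomalous & delta_x >  eps] <- "busy"
  winner[!anomalous & delta_x < -eps] <- "idle"
  winner[!anomalous & abs(delta_x) <= eps] <- "tie"

  structure(list(
    p_grid = p_grid, q_grid = q_grid, s = s,
    t_busy = t_busy, t_idle = t_idle, delta_t = t_busy - t_idle,
    xstar_busy = xstar_busy, xstar_idle = xstar_idle,
    delta_xstar = delta_x,
    cstar_busy = cstar_busy, cstar_idle = cstar_idle,
    cstar_ratio = cstar_busy / cstar_idle,
    winning_design = winner, anomalous_mask = anomalous),
    class = "design_grid")
}

#' @export
print.design_grid <- function(x, ...) {
  cells <- length(x$p_grid) * length(x$q_grid)
  cat(sprintf("Busy/idle design comparison: %d x %d grid, s = %g\n",
              length(x$p_grid), length(x$q_grid), x$s))
  tab <- table(factor(x$winning_design,
                      levels = c("busy", "idle", "tie")), useNA = "ifany")
  cat(sprintf("  idle wins %d / %d cells, busy wins %d, ties %d, anomalous %d\n",
              tab[["idle"]], cells, tab[["busy"]], tab[["tie"]],
              sum(x$anomalous_mask)))
  invisible(x)
}

#' @export
as.data.frame.design_grid <- function(x, ...) {
  np <- length(x$p_grid); nq <- length(x$q_grid)
  data.frame(
    p = rep(x$p_grid, times = nq),
    q = rep(x$q_grid, each = np),
    t_busy = as.vector(x$t_busy), t_idle = as.vector(x$t_idle),
    delta_t = as.vector(x$delta_t),
    xstar_busy = as.vector(x$xstar_busy),
    xstar_idle = as.vector(x$xstar_idle),
    delta_xstar = as.vector(x$delta_xstar),
    cstar_busy = as.vector(x$cstar_busy),
    cstar_idle = as.vector(x$cstar_idle),
    cstar_ratio = as.vector(x$cstar_ratio),
    winning_design = as.vector(x$winning_design),
    anomalous = as.vector(x$anomalous_mask),
    stringsAsFactors = FALSE)
}
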