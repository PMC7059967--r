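# Builders shared across test files.

# Fully symmetric network: n TFs, one gene each, every off-diagonal
# binding energy equal to eps0 (so every off-diagonal Boltzmann weight is
# w = exp(-eps0) and the construction similarity is s = (n - 1) * w).
sym_network <- function(n, eps0) {
  tfs <- lapply(seq_len(n), function(i) {
    energy_matrix(matrix(c(0, 5, 5, 5), 4, 6), sprintf("tf%02d", i))
  })
  net <- tf_network(tfs)
  E <- matrix(eps0, n, n)
  diag(E) <- 0
  dimnames(E) <- dimnames(net$energy_table)
  net$energy_table <- E
  net
}

# Heterogeneous-promiscuity network: a fraction of "promiscuous" TFs with
# low binding energies to every site, the rest specific.
hetero_network <- function(n, eps_lo = 3, eps_hi = 12, frac_prom = 0.15,
                           seed = 1) {
  set.seed(seed)
  tfs <- lapply(seq_len(n), function(i) {
    energy_matrix(matrix(c(0, 5, 5, 5), 4, 6), sprintf("tf%02d", i))
  })
  net <- tf_network(tfs)
  promiscuous <- stats::runif(n) < frac_prom
  E <- matrix(0, n, n)
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      if (k != l) {
        E[k, l] <- if (promiscuous[l]) {
          stats::runif(1, eps_lo, eps_lo + 2)
        } else {
          stats::runif(1, eps_hi - 2, eps_hi + 4)
        }
      }
    }
  }
  dimnames(E) <- dimnames(net$energy_table)
  net$energy_table <- E
  net
}

# Network with fully specified energy table and regulon, for hand-built
# oracle cases.
manual_network <- function(E, regulon = NULL) {
  n <- nrow(E)
  tfs <- lapply(seq_len(n), function(i) {
    energy_matrix(matrix(c(0, 5, 5, 5), 4, 6), sprintf("tf%02d", i))
  })
  net <- tf_network(tfs, regulon = regulon)
  dimnames(E) <- list(site = net$tf_ids, tf = net$tf_ids)
  net$energy_table <- E
  net
}

# Independent brute-force minimizer of the global crosstalk over the
# rescaled concentration, written directly from the occupancy
# probabilities (not via minimize_crosstalk).
brute_force_xstar <- function(s, t) {
  X <- function(c) {
    xu <- ifelse(c == 0, 0, c * s / (1 + c * s))
    if (t == 0) return(xu)
    xb <- (1 + c * s) / (c / t + 1 + c * s)
    t * xb + (1 - t) * xu
  }
  cg <- 10^seq(-9, 9, length.out = 500)
  v <- X(cg)
  i <- which.min(v)
  opt <- stats::optimize(function(lc) X(exp(lc)),
                         log(c(cg[max(1, i - 1)], cg[min(500, i + 1)])),
                         tol = 1e-14)
  min(opt$objective, X(0), 1 - t / (1 + s * t))
}
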