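#' Summary statistics driving the synthetic motif generator
#'
#' Fits (or supplies defaults for) the three empirical distributions the
#' generator draws from: the nucleotide composition of consensus
#' sequences, the motif-length distribution, and the distribution of
#' non-consensus mismatch energies. Real motif collections in budding
#' yeast are AT-rich in their consensus bases, with motif lengths of
#' roughly 6-15 bp and mismatch penalties of order a few kT; the
#' documented defaults emulate exactly that and are used when no input
#' matrices are given.
#'
#' @param energy_matrices optional list of [energy_matrix()] objects to
#'   fit from (their consensus and off-consensus entries are pooled).
#' @param composition default consensus composition over A, C, G, T.
#' @param lengths,length_probs default motif-length support and pmf.
#' @param energy_breaks,energy_probs default histogram of non-consensus
#'   energies (gamma-shaped, shape 2, scale 1, truncated to
#'   `[0.2, 8]` kT, on 40 bins).
#' @return Object of class `"generator_stats"`: list with `composition`
#'   (sums to 1), `lengths`, `length_probs`, `energy_breaks`,
#'   `energy_probs`, `source` (`"fitted"` or `"default"`).
#' @examples
#' fit_generator_stats()            # the documented defaults
#' @export
fit_generator_stats <- function(energy_matrices = NULL,
                                composition = c(A = 0.35, C = 0.15,
                                                G = 0.15, T = 0.35),
                                lengths = 6:15,
                                length_probs = NULL,
                                energy_breaks = NULL,
                                energy_probs = NULL) {
  if (!is.null(energy_matrices) && length(energy_matrices) > 0L) {
    stopifnot(all(vapply(energy_matrices, inherits, logical(1),
                         "energy_matrix")))
    cons <- vapply(energy_matrices, `[[`, character(1), "consensus")
    ch <- unlist(strsplit(cons, ""))
    composition <- table(factor(ch, levels = DNA_BASES))
    composition <- as.numeric(composition) / length(ch)
    names(composition) <- DNA_BASES
    Ls <- vapply(energy_matrices, `[[`, integer(1), "L")
    lengths <- sort(unique(Ls))
    length_probs <- as.numeric(table(factor(Ls, levels = lengths))) /
      length(Ls)
    ev <- unlist(lapply(energy_matrices, function(e) {
      e$epsilon[e$epsilon > 1e-12]
    }))
    h <- graphics::hist(ev, breaks = 40, plot = FALSE)
    energy_breaks <- h$breaks
    energy_probs <- h$counts / sum(h$counts)
    src <- "fitted"
  } else {
    if (is.null(length_probs))
      length_probs <- rep(1 / length(lengths), length(lengths))
    if (is.null(energy_breaks)) {
      energy_breaks <- seq(0.2, 8, length.out = 41L)
      mids <- (energy_breaks[-1] + energy_breaks[-41]) / 2
      w <- stats::dgamma(mids, shape = 2, scale = 1)
      energy_probs <- w / sum(w)
    }
    src <- "default"
  }
  composition <- composition / sum(composition)
  stopifnot(length(composition) == 4L,
            length(length_probs) == length(lengths),
            abs(sum(length_probs) - 1) < 1e-9,
            length(energy_probs) == length(energy_breaks) - 1L)
  structure(list(composition = composition, lengths = as.integer(lengths),
                 length_probs = length_probs,
                 energy_breaks = energy_breaks,
                 energy_probs = energy_probs, source = src),
            class = "generator_stats")
}

#' @export
print.generator_stats <- function(x, ...) {
  cat(sprintf(
    "Motif generator statistics (%s): composition A/C/G/T = %s, lengths %d-%d\n",
    x$source, paste(round(x$composition, 3), collapse = "/"),
    min(x$lengths), max(x$lengths)))
  invisible(x)
}

draw_energy_values <- function(stats, n) {
  bin <- sample.int(length(stats$energy_probs), n, replace = TRUE,
                    prob = stats$energy_probs)
  stats::runif(n, stats$energy_breaks[bin], stats$energy_breaks[bin + 1L])
}

#' Generate a synthetic TF network
#'
#' Fabricates `n_tf` synthetic transcription factors: each gets a motif
#' length and a consensus sequence drawn from the generator statistics,
#' and an energy matrix whose consensus entries are 0 and whose
#' off-consensus entries are drawn from the non-consensus energy
#' distribution. The inter-TF binding-energy table is then built with
#' [binding_energy()], each candidate site being its cognate TF's
#' consensus, and a TF-to-gene map is attached.
#'
#' @param n_tf number of TFs (default 300, a full-network scale).
#' @param stats a [fit_generator_stats()] object; defaults used if `NULL`.
#' @param genes_per_tf either `1` (one gene per TF, matching the analytic
#'   model) or a function `(n)` returning `n` positive integer gene
#'   counts, to exercise the multi-gene pathway.
#' @param seed integer seed; required.
#' @return A [tf_network()].
#' @examples
#' net <- generate_network(n_tf = 5, seed = 1)
#' diag(net$energy_table)    # all zero: consensus on own motif
#' @export
generate_network <- function(n_tf = 300L, stats = NULL, genes_per_tf = 1,
                             seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_tf < 2L) stop("'n_tf' must be at least 2")
  if (is.null(stats)) stats <- fit_generator_stats()
  set.seed(seed)
  tfs <- vector("list", n_tf)
  for (i in seq_len(n_tf)) {
    L <- sample(stats$lengths, 1L, prob = stats$length_probs)
    cons_idx <- sample.int(4L, L, replace = TRUE,
                           prob = stats$composition)
    eps <- matrix(0, 4L, L)
    vals <- draw_energy_values(stats, 3L * L)
    k <- 1L
    for (j in seq_len(L)) {
      for (b in seq_len(4L)) {
        if (b != cons_idx[j]) {
          eps[b, j] <- vals[k]
          k <- k + 1L
        }
      }
    }
    tfs[[i]] <- energy_matrix(eps, tf_id = sprintf("syn%03d", i))
  }
  regulon <- NULL
  if (is.function(genes_per_tf)) {
    counts <- as.integer(genes_per_tf(n_tf))
    if (any(counts < 1L)) stop("genes_per_tf must yield positive counts")
    regulon <- data.frame(
      tf_id = rep(sprintf("syn%03d", seq_len(n_tf)), counts),
      gene_id = paste0("g", seq_len(sum(counts))),
      stringsAsFactors = FALSE)
  } else if (!identical(as.numeric(genes_per_tf), 1)) {
    stop("'genes_per_tf' must be 1 or a function")
  }
  tf_network(tfs, regulon = regulon)
}

#' Extract a subnetwork of TFs
#'
#' Restricts a network to a subset of its TFs, either drawn uniformly at
#' random (`mode = "random"`) or deterministically as the `size` TFs with
#' the highest similarity `s_i` computed against the *full* network
#' (`mode = "ordered"`, the most promiscuous factors). The energy table
#' and regulon are restricted accordingly; genes losing all their cognate
#' TFs drop out.
#'
#' @param network a [tf_network()].
#' @param size number of TFs to keep, `2 <= size <= n_tf`.
#' @param mode `"random"` or `"ordered"`.
#' @param seed integer seed (used by `mode = "random"`).
#' @return A [tf_network()] over the selected TFs.
#' @export
sample_subnetwork <- function(network, size, mode = c("random", "ordered"),
                              seed = NULL) {
  stopifnot(inherits(network, "tf_network"))
  mode <- match.arg(mode)
  n <- length(network$tf_ids)
  if (size < 2L || size > n) stop("'size' must lie in [2, n_tf]")
  idx <- if (mode == "random") {
    if (is.null(seed)) stop("mode = 'random' requires a 'seed'")
    set.seed(seed)
    sort(sample.int(n, size))
  } else {
    # inter-TF promiscuity: mean Boltzmann weight over both directions of
    # the TF's binding relations (its site attracting others, and it
    # binding others' sites) -- the energy table is asymmetric and a TF
    # is promiscuous in either role
    W <- exp(-network$energy_table)
    diag(W) <- NA
    tf_s <- (rowMeans(W, na.rm = TRUE) + colMeans(W, na.rm = TRUE)) / 2
    sort(order(tf_s, decreasing = TRUE)[seq_len(size)])
  }
  subset_network(network, idx)
}

subset_network <- function(network, idx) {
  ids <- network$tf_ids[idx]
  keep_gene <- vapply(network$genes$cognates, function(cg) {
    any(cg %in% idx)
  }, logical(1))
  genes <- network$genes[keep_gene, , drop = FALSE]
  regulon <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    cg <- intersect(genes$cognates[[i]], idx)
    data.frame(tf_id = network$tf_ids[cg], gene_id = genes$gene_id[i],
               stringsAsFactors = FALSE)
  }))
  net <- tf_network(network$tfs[idx], regulon = regulon,
                    concentrations = network$concentrations[idx])
  # reuse the precomputed energy table instead of recomputing
  net$energy_table <- network$energy_table[idx, idx, drop = FALSE]
  net
}

#' Subnetwork sampling study of the effective similarity
#'
#' For each of `n_networks` independently generated full networks, draws
#' one random and one ordered subnetwork of every requested size (each
#' full network sampled once per size, to avoid correlations), computes
#' the concentration-optimized crosstalk curve of each subnetwork, and
#' fits its effective similarity. Quantifies how well partial motif data
#' estimate whole-network crosstalk.
#'
#' @param sizes subnetwork sizes (TF counts).
#' @param n_networks number of independent full networks (default 100).
#' @param n_tf full-network size (default 300).
#' @param stats generator statistics, see [fit_generator_stats()].
#' @param t_grid,n_draws passed to [min_crosstalk_curve()].
#' @param seed integer seed; required. Every derived seed is recorded.
#' @return Object of class `"seff_study"`: data frame with columns
#'   `network`, `size`, `mode`, `s_effective`, `seed_network`,
#'   `seed_subnet`, `seed_curve`; attribute `consensus_length_cor`, the
#'   per-network Pearson correlation of TF promiscuity `s_i` with
#'   consensus length (sign not asserted), and attribute `sizes`.
#' @export
seffective_study <- function(sizes, n_networks = 100L, n_tf = 300L,
                             stats = NULL,
                             t_grid = seq(0.1, 1, length.out = 10L),
                             n_draws = 30L, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (any(sizes < 2L | sizes > n_tf)) stop("sizes out of range")
  sizes <- sort(unique(as.integer(sizes)))
  rows <- list()
  len_cor <- numeric(n_networks)
  for (w in seq_len(n_networks)) {
    seed_net <- seed + 1000L * w
    net <- generate_network(n_tf = n_tf, stats = stats, seed = seed_net)
    # promiscuity vs consensus length across this network's TFs
    sim <- network_similarities(net)
    lens <- vapply(net$tfs, `[[`, integer(1), "L")
    len_cor[w] <- suppressWarnings(stats::cor(sim$s, lens))
    for (size in sizes) {
      for (mode in c("random", "ordered")) {
        seed_sub <- seed_net + size * 10L +
          if (mode == "random") 1L else 2L
        sub <- sample_subnetwork(net, size, mode = mode,
                                 seed = seed_sub)
        # curve seed independent of mode: at full size both modes hold
        # the identical network and must yield identical curves
        seed_curve <- seed_net + size * 10L + 7L
        cur <- suppressMessages(
          min_crosstalk_curve(sub, t_grid = t_grid, n_draws = n_draws,
                              seed = seed_curve))
        fit <- fit_s_effective(cur)
        rows[[length(rows) + 1L]] <- data.frame(
          network = w, size = size, mode = mode,
          s_effective = fit$s_effective,
          seed_network = seed_net, seed_subnet = seed_sub,
          seed_curve = seed_curve, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("seff_study", "data.frame"),
            sizes = sizes, consensus_length_cor = len_cor)
}

#' @export
print.seff_study <- function(x, ...) {
  cat(sprintf("Subnetwork s_effective study: %d networks, sizes %s\n",
              max(x$network), paste(attr(x, "sizes"), collapse = ", ")))
  med <- stats::aggregate(s_effective ~ size + mode, data = x,
                          FUN = stats::median)
  print(med, row.names = FALSE)
  invisible(x)
}

#' Emit an integer PCM consistent with an energy matrix
#'
#' Inverse of [energy_matrix_from_pcm()] up to rounding: builds a count
#' matrix whose pseudocounted log-ratios reproduce the given energies
#' approximately, for round-trip testing of the PCM pipeline.
#'
#' @param em an [energy_matrix()].
#' @param n_sites total count per position (default 100).
#' @param delta pseudocount assumed (default 0.1).
#' @return A [pcm()].
#' @export
pcm_from_energy <- function(em, n_sites = 100L, delta = 0.1) {
  stopifnot(inherits(em, "energy_matrix"))
  w <- exp(-em$epsilon)
  counts <- apply(w, 2, function(col) {
    raw <- col / sum(col) * n_sites
    k <- floor(raw)
    rem <- n_sites - sum(k)
    if (rem > 0) {
      o <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
      k[o] <- k[o] + 1L
    }
    k
  })
  pcm(counts, tf_id = em$tf_id)
}
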