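#' Assemble a TF-gene network
#'
#' Binds together a set of TFs (mismatch-energy matrices with their
#' consensus sequences), a TF-to-gene regulation map, per-TF relative
#' concentrations, and the asymmetric table of binding energies
#' \eqn{E^{kl}} of every TF `l` to every candidate binding site `k` (each
#' candidate site is the consensus sequence of its cognate TF, so
#' \eqn{E^{kk} = 0} and in general \eqn{E^{kl} \ne E^{lk}}).
#'
#' @param tfs list of [energy_matrix()] objects with unique `tf_id`s.
#' @param regulon data frame with columns `tf_id`, `gene_id`, one row per
#'   regulatory edge. Default: one synthetic gene per TF, named after it.
#' @param concentrations optional numeric vector of per-TF relative
#'   concentrations (named by `tf_id` or in `tfs` order); default equal.
#' @return Object of class `"tf_network"`: list with `tfs`, `tf_ids`,
#'   `consensus`, `energy_table` (n_tf x n_tf, rows = candidate sites
#'   indexed by the TF whose consensus they are), `genes` (data frame
#'   `gene_id` + list-column `cognates` of TF indices), `concentrations`,
#'   `M` (gene count).
#' @examples
#' em <- function(id, L) energy_matrix(matrix(rep(c(0, 1, 1, 1), L),
#'                                            4, L), id)
#' net <- tf_network(list(em("tf1", 4), em("tf2", 4)))
#' net$energy_table
#' @export
tf_network <- function(tfs, regulon = NULL, concentrations = NULL) {
  stopifnot(is.list(tfs), length(tfs) >= 1L,
            all(vapply(tfs, inherits, logical(1), "energy_matrix")))
  tf_ids <- vapply(tfs, `[[`, character(1), "tf_id")
  if (anyDuplicated(tf_ids)) stop("duplicated tf_id in 'tfs'")
  n <- length(tfs)
  cons <- vapply(tfs, `[[`, character(1), "consensus")

  E <- matrix(0, n, n, dimnames = list(site = tf_ids, tf = tf_ids))
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      E[k, l] <- binding_energy(tfs[[l]], cons[k])
    }
  }

  if (is.null(regulon)) {
    regulon <- data.frame(tf_id = tf_ids, gene_id = paste0("g_", tf_ids),
                          stringsAsFactors = FALSE)
  }
  if (!all(c("tf_id", "gene_id") %in% names(regulon)))
    stop("'regulon' needs columns 'tf_id' and 'gene_id'")
  if (!all(regulon$tf_id %in% tf_ids))
    stop("regulon refers to unknown TFs: ",
         paste(setdiff(regulon$tf_id, tf_ids), collapse = ", "))
  gene_ids <- unique(regulon$gene_id)
  cognates <- lapply(gene_ids, function(g) {
    sort(match(unique(regulon$tf_id[regulon$gene_id == g]), tf_ids))
  })
  if (any(lengths(cognates) == 0L))
    stop("every gene must have at least one cognate TF")
  genes <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  genes$cognates <- cognates

  if (is.null(concentrations)) {
    concentrations <- rep(1, n)
  } else if (!is.null(names(concentrations))) {
    concentrations <- concentrations[tf_ids]
  }
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) != n || anyNA(concentrations) ||
      any(concentrations < 0))
    stop("'concentrations' must be nonnegative, one per TF")

  structure(list(tfs = tfs, tf_ids = tf_ids, consensus = cons,
                 energy_table = E, genes = genes,
                 concentrations = concentrations, M = length(gene_ids)),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf(
    "TF network: %d TFs, %d genes, motif lengths %d-%d\n",
    length(x$tf_ids), x$M,
    min(vapply(x$tfs, `[[`, integer(1), "L")),
    max(vapply(x$tfs, `[[`, integer(1), "L"))))
  invisible(x)
}

resolve_tf_subset <- function(network, available) {
  if (is.null(available)) return(seq_along(network$tf_ids))
  if (is.character(available)) {
    idx <- match(available, network$tf_ids)
    if (anyNA(idx)) stop("unknown TF id in 'available'")
  } else {
    idx <- as.integer(available)
    if (any(idx < 1L | idx > length(network$tf_ids)))
      stop("'available' index out of range")
  }
  sort(unique(idx))
}

#' Per-gene similarity measures of a network
#'
#' For each candidate binding site `k` (the consensus of one of the
#' gene's cognate TFs), the similarity is the concentration-weighted mean
#' Boltzmann weight of non-cognate binding,
#' \eqn{S_k = \sum_{l \ne cognates} C_l e^{-E^{kl}} / \sum_l C_l}, the
#' sums running over the available TFs; at equal concentrations this is
#' `(1/T) * sum(exp(-E))`. Genes with several cognate TFs get the
#' arithmetic mean of their candidate-site values. The rescaled
#' `s = S * M` (M = gene count) is reported alongside.
#'
#' @param network a [tf_network()].
#' @param available TF ids or indices treated as present; `NULL` (default)
#'   means all TFs, the availability-blind variant used for descriptive
#'   similarity histograms.
#' @return Data frame with one row per gene: `gene_id`, `S`, `s`.
#' @export
network_similarities <- function(network, available = NULL) {
  stopifnot(inherits(network, "tf_network"))
  avail <- resolve_tf_subset(network, available)
  W <- exp(-network$energy_table)
  conc <- network$concentrations
  ctot <- sum(conc[avail])
  if (ctot == 0) stop("no concentration among available TFs")
  S <- vapply(seq_len(network$M), function(gi) {
    cog <- network$genes$cognates[[gi]]
    noncog <- setdiff(avail, cog)
    mean(vapply(cog, function(k) {
      sum(conc[noncog] * W[k, noncog]) / ctot
    }, numeric(1)))
  }, numeric(1))
  data.frame(gene_id = network$genes$gene_id, S = S, s = S * network$M,
             stringsAsFactors = FALSE)
}
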