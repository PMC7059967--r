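DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position count matrix
#'
#' A position count matrix (PCM) tabulates, for each position of a TF's
#' binding site, how many of the known site sequences carry each
#' nucleotide: a 4 x L integer table with rows A, C, G, T.
#'
#' @param counts 4 x L matrix of nonnegative counts (rows A, C, G, T; a
#'   matching `rownames` order is enforced if present).
#' @param tf_id identifier for the factor.
#' @return Object of class `"pcm"`: list with `tf_id`, `counts`, `L`.
#' @examples
#' pcm(matrix(c(9, 1, 0, 0, 0, 0, 8, 2), nrow = 4), tf_id = "toy")
#' @export
pcm <- function(counts, tf_id = "tf") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("'counts' must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!identical(toupper(rownames(counts)), DNA_BASES))
      stop("'counts' rows must be ordered A, C, G, T")
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  dimnames(counts) <- list(DNA_BASES, NULL)
  structure(list(tf_id = as.character(tf_id), counts = counts,
                 L = ncol(counts)),
            class = "pcm")
}

#' @export
print.pcm <- function(x, ...) {
  cat(sprintf("PCM '%s': %d positions, column totals %s\n", x$tf_id, x$L,
              paste(colSums(x$counts), collapse = " ")))
  invisible(x)
}

#' Read motif count matrices from JASPAR-style PFM files
#'
#' Accepts the common JASPAR dialects -- a `>id name` header followed by
#' four rows, either bracketed (`A [ 1 2 3 ]`) or plain whitespace-
#' separated numbers -- as well as a bare 4 x L table with an optional
#' header line. Rows must be in A, C, G, T order (enforced when row labels
#' are present). Several motifs may share one file.
#'
#' @param paths character vector of file paths.
#' @return List of [pcm()] objects.
#' @export
read_pfm <- function(paths) {
  out <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("no such motif file: ", path)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L)
      stop("malformed motif file (empty): ", path)
    # split into blocks at '>' headers; headerless files form one block
    hdr <- startsWith(lines, ">")
    block_id <- cumsum(hdr)
    if (block_id[1] == 0L) block_id <- block_id + 1L
    for (b in unique(block_id)) {
      bl <- lines[block_id == b]
      if (startsWith(bl[1], ">")) {
        id <- strsplit(sub("^>", "", bl[1]), "[ \t]+")[[1]][1]
        bl <- bl[-1]
      } else {
        id <- sub("\\.[^.]*$", "", basename(path))
      }
      rows <- lapply(bl, parse_pfm_row, path = path)
      labs <- vapply(rows, `[[`, character(1), "label")
      if (length(rows) != 4L)
        stop("malformed motif file (expected 4 nucleotide rows): ", path)
      if (any(nzchar(labs)) && !identical(toupper(labs), DNA_BASES))
        stop("malformed motif file (rows not in A,C,G,T order): ", path)
      vals <- lapply(rows, `[[`, "values")
      if (length(unique(lengths(vals))) != 1L)
        stop("malformed motif file (ragged rows): ", path)
      out[[length(out) + 1L]] <- pcm(do.call(rbind, vals), tf_id = id)
    }
  }
  out
}

parse_pfm_row <- function(line, path) {
  label <- ""
  m <- regmatches(line, regexec("^([ACGTacgt])[ :|]", line))[[1]]
  if (length(m)) {
    label <- toupper(m[2])
    line <- sub("^[ACGTacgt][ :|]", "", line)
  }
  line <- gsub("[][]", " ", line)
  toks <- strsplit(trimws(line), "[ \t,]+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) == 0L || anyNA(vals))
    stop("malformed motif file (non-numeric counts): ", path)
  list(label = label, values = vals)
}

#' Load and filter position count matrices
#'
#' Applies the two admission rules used before energy-matrix estimation:
#' the column totals must be equal across all positions (unequal totals
#' bias the occurrence statistics), and that common total must be at least
#' `min_counts_per_position` (count sufficiency). Rejected matrices are
#' reported via a message naming the failed rule.
#'
#' @param paths motif file paths (see [read_pfm()]), or a list of [pcm()]
#'   objects.
#' @param min_counts_per_position minimum common column total (default 5).
#' @return List of surviving [pcm()] objects; an empty-result warning is
#'   raised if nothing survives.
#' @export
load_and_filter_pcms <- function(paths, min_counts_per_position = 5) {
  pcms <- if (is.list(paths) && all(vapply(paths, inherits, logical(1),
                                           "pcm"))) {
    paths
  } else {
    read_pfm(paths)
  }
  keep <- list()
  for (p in pcms) {
    tot <- colSums(p$counts)
    if (length(unique(tot)) != 1L) {
      message(sprintf("dropping '%s': unequal column totals (%s)",
                      p$tf_id, paste(tot, collapse = " ")))
    } else if (tot[1] < min_counts_per_position) {
      message(sprintf(
        "dropping '%s': column total %g below minimum %g",
        p$tf_id, tot[1], min_counts_per_position))
    } else {
      keep[[length(keep) + 1L]] <- p
    }
  }
  if (length(keep) == 0L)
    warning("no position count matrices survived filtering")
  keep
}

#' Mismatch-energy matrix from a position count matrix
#'
#' Converts counts to mismatch penalties
#' \eqn{\epsilon_{ij} = \ln((c_{mj} + \delta) / (c_{ij} + \delta))} in kT
#' units, where \eqn{c_{mj}} is the column maximum; a pseudocount
#' \eqn{\delta} added to every entry keeps all energies finite. Each
#' column's most-common nucleotide gets exactly 0; all other entries are
#' positive.
#'
#' @param x a [pcm()].
#' @param delta pseudocount, positive (default 0.1).
#' @return Object of class `"energy_matrix"`: list with `tf_id`,
#'   `epsilon` (4 x L, rows A, C, G, T), `consensus`, `delta`, `L`.
#' @examples
#' p <- pcm(matrix(c(10, 0, 0, 0), nrow = 4), "toy")
#' energy_matrix_from_pcm(p)$epsilon   # 0, log(101), log(101), log(101)
#' @export
energy_matrix_from_pcm <- function(x, delta = 0.1) {
  stopifnot(inherits(x, "pcm"))
  if (!is.finite(delta) || delta <= 0)
    stop("'delta' must be a positive pseudocount")
  cc <- x$counts + delta
  cm <- apply(cc, 2, max)
  eps <- sweep(-log(cc), 2, log(cm), `+`)
  energy_matrix(eps, tf_id = x$tf_id, delta = delta)
}

#' Construct an energy matrix directly
#'
#' @param epsilon 4 x L matrix of nonnegative mismatch energies (kT),
#'   rows A, C, G, T; each column must attain 0.
#' @param tf_id identifier.
#' @param delta pseudocount used to derive it, if any.
#' @return Object of class `"energy_matrix"`.
#' @export
energy_matrix <- function(epsilon, tf_id = "tf", delta = NA_real_) {
  epsilon <- as.matrix(epsilon)
  if (nrow(epsilon) != 4L) stop("'epsilon' must have 4 rows (A, C, G, T)")
  if (anyNA(epsilon) || any(!is.finite(epsilon)) || any(epsilon < -1e-12))
    stop("energies must be finite and nonnegative")
  epsilon[epsilon < 0] <- 0
  if (any(abs(apply(epsilon, 2, min)) > 1e-9))
    stop("each column must attain energy 0 at its consensus nucleotide")
  dimnames(epsilon) <- list(DNA_BASES, NULL)
  cons <- paste(DNA_BASES[apply(epsilon, 2, which.min)], collapse = "")
  structure(list(tf_id = as.character(tf_id), epsilon = epsilon,
                 consensus = cons, delta = delta, L = ncol(epsilon)),
            class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("Energy matrix '%s': L = %d, consensus %s\n",
              x$tf_id, x$L, x$consensus))
  invisible(x)
}

#' Consensus sequence of a count matrix
#'
#' The per-position most-common nucleotide; ties are broken by the fixed
#' order A < C < G < T.
#'
#' @param x a [pcm()] or [energy_matrix()].
#' @return Nucleotide string of length `L`.
#' @examples
#' consensus_sequence(pcm(matrix(c(9, 1, 0, 0, 0, 0, 8, 2), nrow = 4)))
#' @export
consensus_sequence <- function(x) {
  if (inherits(x, "energy_matrix")) return(x$consensus)
  stopifnot(inherits(x, "pcm"))
  paste(DNA_BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Binding energy of a TF to a site sequence
#'
#' Slides the factor's energy matrix along the site and returns the lowest
#' total mismatch energy over all full-containment placements of the
#' shorter sequence within the longer. When the motif is longer than the
#' site, motif positions falling outside the site contribute the column
#' average over the four nucleotides, \eqn{E_{2j} = \sum_i
#' \epsilon_{ij} / 4}; the total is the inside (sequence-read) part plus
#' these outside averages, again minimized over placements.
#'
#' @param tf an [energy_matrix()].
#' @param site nucleotide string (A/C/G/T).
#' @return Binding energy `E >= 0` in kT.
#' @examples
#' em <- energy_matrix(matrix(c(0, 1, 1, 1), 4, 2), "toy")
#' binding_energy(em, "CAA")   # best offset matches "AA": E = 0
#' @export
binding_energy <- function(tf, site) {
  stopifnot(inherits(tf, "energy_matrix"))
  idx <- site_indices(site)
  n <- length(idx)
  L <- tf$L
  eps <- tf$epsilon
  if (L <= n) {
    offs <- 0:(n - L)
    e <- vapply(offs, function(o) {
      sum(eps[cbind(idx[(o + 1):(o + L)], 1:L)])
    }, numeric(1))
  } else {
    colavg <- colMeans(eps)
    # site fully inside the motif footprint: motif column o+1 .. o+n read
    # from the site, all other columns averaged
    offs <- 0:(L - n)
    e <- vapply(offs, function(o) {
      inside <- sum(eps[cbind(idx, (o + 1):(o + n))])
      outside <- sum(colavg) - sum(colavg[(o + 1):(o + n)])
      inside + outside
    }, numeric(1))
  }
  min(e)
}

site_indices <- function(site) {
  stopifnot(is.character(site), length(site) == 1L, nzchar(site))
  ch <- strsplit(toupper(site), "")[[1]]
  idx <- match(ch, DNA_BASES)
  if (anyNA(idx))
    stop("site contains non-ACGT characters: ", site)
  idx
}
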