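write_tmp <- function(lines, ext = ".pfm") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("JASPAR-style and plain motif files parse identically", {
  jaspar <- write_tmp(c(
    ">MA0001 toyA",
    "A [ 9 0 ]",
    "C [ 1 0 ]",
    "G [ 0 8 ]",
    "T [ 0 2 ]"))
  plain <- write_tmp(c(
    ">toyB",
    "9 0",
    "1 0",
    "0 8",
    "0 2"))
  a <- read_pfm(jaspar)[[1]]
  b <- read_pfm(plain)[[1]]
  expect_equal(a$tf_id, "MA0001")
  expect_equal(b$tf_id, "toyB")
  expect_equal(a$counts, b$counts)
  expect_equal(consensus_sequence(a), "AG")
  # several motifs per file
  multi <- write_tmp(c(readLines(jaspar), readLines(plain)))
  expect_length(read_pfm(multi), 2L)
})

test_that("malformed motif files are rejected by name", {
  ragged <- write_tmp(c(">x", "1 2", "1 2 3", "1 2", "1 2"))
  expect_error(read_pfm(ragged), "ragged")
  nonnum <- write_tmp(c(">x", "1 a", "1 2", "1 2", "1 2"))
  expect_error(read_pfm(nonnum), "non-numeric")
  disorder <- write_tmp(c(">x", "T [ 1 ]", "C [ 1 ]", "G [ 1 ]",
                          "A [ 1 ]"))
  expect_error(read_pfm(disorder), "order")
  expect_error(read_pfm(tempfile()), "no such motif file")
})

test_that("filtering enforces equal and sufficient column totals", {
  ok <- pcm(matrix(c(5, 3, 1, 1, 2, 2, 3, 3, 10, 0, 0, 0), 4), "ok")
  unequal <- pcm(matrix(c(5, 3, 1, 1, 2, 2, 3, 2, 10, 0, 0, 0), 4),
                 "unequal")
  small <- pcm(matrix(c(2, 1, 1, 0, 1, 1, 1, 1), 4), "small")
  expect_message(kept <- load_and_filter_pcms(list(ok, unequal, small)),
                 "unequal")
  expect_equal(vapply(kept, `[[`, character(1), "tf_id"), "ok")
  # idempotent: refiltering the survivors changes nothing
  expect_silent(again <- load_and_filter_pcms(kept))
  expect_equal(again, kept)
  suppressMessages(
    expect_warning(load_and_filter_pcms(list(small)), "survived"))
})

test_that("energy matrices are pseudocounted log count ratios", {
  p <- pcm(matrix(c(10, 0, 0, 0), 4), "col")
  em <- energy_matrix_from_pcm(p, delta = 0.1)
  expect_equal(as.vector(em$epsilon),
               c(0, log(10.1 / 0.1), log(10.1 / 0.1), log(10.1 / 0.1)))
  # flat columns carry no preference at all
  u <- energy_matrix_from_pcm(pcm(matrix(5, 4, 3), "flat"))
  expect_true(all(u$epsilon == 0))
  expect_error(energy_matrix_from_pcm(p, delta = 0), "positive")
  # every column attains zero exactly at its consensus letter
  set.seed(21)
  r <- pcm(matrix(rpois(4 * 8, 6), 4), "rand")
  er <- energy_matrix_from_pcm(r)
  expect_true(all(apply(er$epsilon, 2, min) == 0))
  expect_true(all(er$epsilon >= 0))
})

test_that("consensus uses the fixed A<C<G<T tie-break and matches energies", {
  expect_equal(consensus_sequence(
    pcm(matrix(c(9, 1, 0, 0, 0, 0, 8, 2), 4), "x")), "AG")
  expect_equal(consensus_sequence(
    pcm(matrix(c(5, 5, 0, 0), 4), "tie")), "A")
  expect_equal(consensus_sequence(
    pcm(matrix(c(0, 0, 3, 3), 4), "tie2")), "G")
  # consensus is the zero-energy path of the derived energy matrix
  set.seed(8)
  for (i in 1:5) {
    p <- pcm(matrix(rpois(4 * 6, 4), 4), "r")
    em <- energy_matrix_from_pcm(p)
    expect_equal(em$consensus, consensus_sequence(p))
    idx <- match(strsplit(em$consensus, "")[[1]], c("A", "C", "G", "T"))
    expect_equal(sum(em$epsilon[cbind(idx, 1:6)]), 0)
  }
})

test_that("adding counts uniformly shrinks energies and keeps consensus", {
  set.seed(12)
  p <- pcm(matrix(rpois(4 * 5, 5), 4), "base")
  e0 <- energy_matrix_from_pcm(p)
  prev <- e0$epsilon
  for (add in c(5, 20, 100)) {
    e1 <- energy_matrix_from_pcm(pcm(p$counts + add, "shift"))
    expect_equal(e1$consensus, e0$consensus)
    expect_true(all(e1$epsilon <= prev + 1e-12))
    prev <- e1$epsilon
  }
})

test_that("binding energy minimizes over full-containment placements", {
  em2 <- energy_matrix(matrix(c(0, 1, 1, 1), 4, 2), "m2")
  # motif on its own consensus: zero
  expect_equal(binding_energy(em2, em2$consensus), 0)
  # motif L=2, site "CAA": offsets give 1 and 0
  expect_equal(binding_energy(em2, "CAA"), 0)
  expect_equal(binding_energy(em2, "CCA"), 1)
  # motif longer than the site: outside columns average to 3/4 each
  em3 <- energy_matrix(matrix(c(0, 1, 1, 1), 4, 3), "m3")
  expect_equal(binding_energy(em3, "AA"), 0.75)
  expect_equal(binding_energy(em3, "CC"), 2.75)
  expect_error(binding_energy(em2, "ANA"), "non-ACGT")
})

test_that("binding energy equals a brute-force placement oracle", {
  # independent oracle: direct loops over every placement
  oracle <- function(eps, site) {
    idx <- match(strsplit(site, "")[[1]], c("A", "C", "G", "T"))
    L <- ncol(eps)
    n <- length(idx)
    best <- Inf
    if (L <= n) {
      for (o in 0:(n - L)) {
        e <- 0
        for (j in 1:L) e <- e + eps[idx[o + j], j]
        best <- min(best, e)
      }
    } else {
      for (o in 0:(L - n)) {
        e <- 0
        for (j in 1:L) {
          inside <- j > o && j <= o + n
          e <- e + if (inside) eps[idx[j - o], j] else mean(eps[, j])
        }
        best <- min(best, e)
      }
    }
    best
  }
  set.seed(33)
  for (i in 1:30) {
    L <- sample(2:7, 1)
    eps <- matrix(stats::runif(4 * L, 0, 4), 4, L)
    eps <- sweep(eps, 2, apply(eps, 2, min))
    em <- energy_matrix(eps, "r")
    n <- sample(2:7, 1)
    site <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    expect_equal(binding_energy(em, site), oracle(eps, site))
    expect_gte(binding_energy(em, site), 0)
  }
})

test_that("network binding-energy table is asymmetric with zero diagonal", {
  set.seed(44)
  tfs <- lapply(1:4, function(i) {
    L <- sample(3:6, 1)
    eps <- matrix(stats::runif(4 * L, 0.5, 4), 4, L)
    eps <- sweep(eps, 2, apply(eps, 2, min))
    energy_matrix(eps, paste0("tf", i))
  })
  net <- tf_network(tfs)
  expect_equal(unname(diag(net$energy_table)), rep(0, 4))
  expect_true(all(net$energy_table >= 0))
  expect_false(isSymmetric(unname(net$energy_table)))
})

test_that("similarities follow the concentration-weighted mean convention", {
  # two TFs with mutual energies 2: S_1 = exp(-2) / T with T = 2
  E <- matrix(c(0, 2, 2, 0), 2, 2)
  net <- manual_network(E)
  sim <- network_similarities(net)
  expect_equal(sim$S, rep(exp(-2) / 2, 2))
  expect_equal(sim$s, rep(exp(-2) / 2 * 2, 2))
  # orthogonal motifs: similarity vanishes
  E2 <- matrix(c(0, 1e6, 1e6, 0), 2, 2)
  expect_equal(network_similarities(manual_network(E2))$S, c(0, 0),
               tolerance = 1e-12)
  # unequal concentrations weight the competitors
  E3 <- matrix(0, 3, 3)
  E3[1, 2] <- 1; E3[1, 3] <- 2
  E3[2, 1] <- E3[2, 3] <- E3[3, 1] <- E3[3, 2] <- 5
  net3 <- manual_network(E3)
  net3$concentrations <- c(1, 2, 3)
  s1 <- network_similarities(net3)$S[1]
  expect_equal(s1, (2 * exp(-1) + 3 * exp(-2)) / 6)
})

test_that("multi-cognate genes average their candidate-site similarities", {
  # gene g1 has two cognate TFs (sites 1, 2); TF3 is the lone competitor
  E <- matrix(0, 3, 3)
  w1 <- 0.06; w2 <- 0.12   # chosen so S candidates are 0.02 and 0.04
  E[1, 3] <- -log(w1); E[2, 3] <- -log(w2)
  E[1, 2] <- E[2, 1] <- 50; E[3, 1] <- E[3, 2] <- 50
  regulon <- data.frame(tf_id = c("tf01", "tf02", "tf03"),
                        gene_id = c("g1", "g1", "g3"))
  net <- manual_network(E, regulon = regulon)
  sim <- network_similarities(net)
  g1 <- sim[sim$gene_id == "g1", ]
  expect_equal(g1$S, mean(c(w1 / 3, w2 / 3)))
  expect_equal(g1$S, 0.03)
  # rescaling uses the gene count
  expect_equal(g1$s, 0.03 * 2)
})

test_that("availability restriction drops absent competitors", {
  E <- matrix(0, 3, 3)
  E[1, 2] <- 1; E[1, 3] <- 2
  E[2, 1] <- E[2, 3] <- E[3, 1] <- E[3, 2] <- 3
  net <- manual_network(E)
  all_in <- network_similarities(net)$S[1]
  no3 <- network_similarities(net, available = c("tf01", "tf02"))$S[1]
  expect_equal(all_in, (exp(-1) + exp(-2)) / 3)
  expect_equal(no3, exp(-1) / 2)
})
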