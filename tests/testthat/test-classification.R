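test_that("pairwise identity counts matching aligned columns", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "TGCA"), 0.0)
  # 300 nt with exactly 30 substitutions, no indels
  set.seed(10)
  a <- random_dna_str(300)
  b <- strsplit(a, "")[[1]]
  pos <- sample(300, 30)
  for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  expect_equal(pairwise_identity(a, paste(b, collapse = "")), 0.9)
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("family clustering separates groups at the identity threshold", {
  m2 <- matrix(c(1, .95, .6, .6,
                 .95, 1, .6, .6,
                 .6, .6, 1, .95,
                 .6, .6, .95, 1), 4, 4)
  f2 <- cluster_families(m2, 0.8)
  expect_equal(f2$n_families, 2L)
  expect_equal(f2$family[1], f2$family[2])
  expect_equal(f2$family[3], f2$family[4])
  expect_equal(cluster_families(matrix(1, 5, 5), 0.8)$n_families, 1L)
  # labels ordered by size then leftmost coordinate
  m3 <- diag(1, 3)
  m3[1, 2] <- m3[2, 1] <- 0.9
  f3 <- cluster_families(m3, 0.8, coords = c(100, 200, 50))
  expect_equal(f3$family, c(1L, 1L, 2L))
})

test_that("planted simulator families are recovered and clustering is order-invariant", {
  fx <- fixture_heavy()
  vseg <- fx$sim$segments[fx$sim$segments$kind == "V", ]
  seqs <- substring(fx$sim$genome, vseg$start, vseg$end)
  idm <- identity_matrix(seqs)
  fam <- cluster_families(idm, 0.8)
  expect_equal(fam$n_families, length(unique(vseg$family)))
  # same partition as planted truth (up to label names)
  expect_equal(length(unique(paste(fam$family, vseg$family))),
               fam$n_families)
  # order invariance
  perm <- sample(length(seqs))
  fam2 <- cluster_families(idm[perm, perm], 0.8)
  expect_equal(fam2$family[order(perm)][1] == fam2$family[order(perm)],
               fam$family[1] == fam$family)
})

test_that("p and K2P distances follow their closed forms with pairwise deletion", {
  # P = 0.1 transitions, Q = 0 over 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))  # A->G transitions
  expect_equal(p_distance(a, b), 0.1)
  expect_equal(k2p_distance(a, b), 0.5 * log(1 / 0.8), tolerance = 1e-12)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(k2p_distance("ACGT", "ACGT"), 0)
  # gap columns removed pairwise: 3 valid sites
  expect_equal(p_distance("AC-T", "ACGT"), 0)
  s <- igloci:::valid_pair_sites("AC-T", "ACGT")
  expect_length(s$a, 3L)
  # k2p >= p for moderate divergence
  set.seed(11)
  x <- random_dna_str(500)
  y <- strsplit(x, "")[[1]]
  pos <- sample(500, 60)
  for (p in pos) y[p] <- setdiff(c("A", "C", "G", "T"), y[p])[sample(3, 1)]
  y <- paste(y, collapse = "")
  expect_gte(k2p_distance(x, y), p_distance(x, y))
  # saturation flagged
  expect_warning(ksat <- k2p_distance(strrep("A", 20), strrep("G", 20)),
                 "saturated")
  expect_true(is.na(ksat))
})

test_that("gamma-corrected K2P matches the independent ape implementation", {
  set.seed(12)
  seqs <- character(4)
  base <- random_dna_str(400)
  for (i in 1:4) {
    y <- strsplit(base, "")[[1]]
    pos <- sample(400, 25 * i)
    for (p in pos) y[p] <- setdiff(c("A", "C", "G", "T"), y[p])[sample(3, 1)]
    seqs[i] <- paste(y, collapse = "")
  }
  names(seqs) <- paste0("t", 1:4)
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(tolower(s), "")[[1]])))
  for (g in list(NULL, 5)) {
    mine <- distance_matrix(seqs, "k2p", gamma_shape = g)
    theirs <- as.matrix(ape::dist.dna(bin, model = "K80",
                                      gamma = if (is.null(g)) FALSE else g,
                                      pairwise.deletion = TRUE))
    expect_equal(mine, theirs[rownames(mine), colnames(mine)],
                 tolerance = 1e-8)
  }
  expect_equal(distance_matrix(seqs, "p")["t1", "t2"],
               as.matrix(ape::dist.dna(bin, model = "raw",
                                       pairwise.deletion = TRUE))["t1", "t2"])
})

test_that("neighbour joining recovers additive trees exactly", {
  # 3 taxa: closed-form star resolution
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(D), colnames(D)], D, tolerance = 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")

  # random additive matrices from random trees, cross-checked against ape::nj
  set.seed(13)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(true)
    mine <- nj_tree(D)
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(true), mine), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    theirs <- ape::nj(D)
    expect_equal(ape::dist.topo(theirs, mine), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
  }
})

test_that("tied merges are broken deterministically and negatives are clamped", {
  # ultrametric with two tied closest pairs
  D <- matrix(2, 4, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  diag(D) <- 0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  t1 <- nj_tree(D)
  t2 <- nj_tree(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))
})

test_that("bootstrap support is reproducible and saturates for clean clades", {
  set.seed(14)
  a <- strrep("A", 60)
  t <- strrep("T", 60)
  aln <- c(x1 = a, x2 = a, y1 = t, y2 = t)
  tr <- bootstrap_support(aln, n_reps = 100, seed = 3)
  sup <- as.numeric(tr$node.label)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(100 %in% sup)  # the two-clade split is always recovered
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 3)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("entropy profile obeys its closed forms and consensus rules", {
  expect_error(entropy_profile(character(0)), "empty")
  aln <- c("A", "A", "A", "A")
  expect_equal(entropy_profile(aln)$entropy_bits, 0)
  expect_equal(entropy_profile(c("A", "C", "G", "T"))$entropy_bits, 2)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(entropy_profile(aa20)$entropy_bits, log2(20), tolerance = 1e-12)
  # gap-majority and plurality rules
  p <- entropy_profile(c("A-", "--", "-C", "A-"))
  expect_equal(p$consensus, c("A", "-"))
  q <- entropy_profile(c("AA", "CA", "GA", "TA", "AA"))
  expect_equal(q$consensus, c("?", "A"))  # 2/5 plurality is below 0.5
  expect_equal(q$entropy_bits[2], 0)
})

test_that("center-star alignment is gap-consistent and round-trips", {
  ident <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  msa <- center_star_msa(ident)
  expect_true(all(!grepl("-", msa, fixed = TRUE)))
  # one sequence with a 3-nt insertion: a single 3-column gap block elsewhere
  ins <- c(a = "ACGTACGTACGT", b = "ACGTTTTACGTACGT", c = "ACGTACGTACGT")
  msa2 <- center_star_msa(ins)
  expect_equal(length(unique(nchar(msa2))), 1L)
  expect_true(grepl("---", msa2["a"], fixed = TRUE))
  # round trip: removing gaps recovers the inputs
  set.seed(15)
  for (i in 1:5) {
    seqs <- stats::setNames(sapply(1:4, function(k) random_dna_str(sample(40:60, 1))),
                            paste0("s", 1:4))
    m <- center_star_msa(seqs)
    expect_equal(length(unique(nchar(m))), 1L)
    expect_equal(gsub("-", "", m, fixed = TRUE), seqs)
  }
})
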