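mk_rep <- function(counts, junctions = NULL, v = "IGHV3-1-1*01",
                   j = "IGHJ1-1*01", sample_id = "s") {
  n <- length(counts)
  if (is.null(junctions)) {
    junctions <- vapply(seq_len(n), function(i) {
      paste(sample(c("TGT", "GCT", "GGT", "TGG"), 5, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  data.frame(sequence_id = sprintf("%s_c%03d", sample_id, seq_len(n)),
             v_call = rep_len(v, n), j_call = rep_len(j, n),
             junction = junctions,
             junction_aa = vapply(junctions, igloci::translate_nt, character(1),
                                  USE.NAMES = FALSE),
             productive = TRUE, duplicate_count = counts,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

test_that("rarefaction matches closed-form expectations and is exact at full depth", {
  set.seed(30)
  rep1 <- mk_rep(c(9L, 1L))
  # depth 1 -> always one clonotype; full depth -> observed richness, sd 0
  r1 <- rarefaction_curve(rep1, depths = c(1, 10), n_reps = 20, seed = 1)
  expect_equal(r1$mean_unique[1], 1)
  expect_equal(r1$mean_unique[2], 2)
  expect_equal(r1$sd[2], 0)
  # worked example: counts (9,1), depth 2 -> E[distinct] = 1.2
  expect_equal(oracle_expected_distinct(c(9, 1), 2), 1.2)
  r2 <- rarefaction_curve(rep1, depths = 2, n_reps = 4000, seed = 2)
  se <- r2$sd / sqrt(4000)
  expect_lt(abs(r2$mean_unique - 1.2), 3 * se + 1e-9)
  expect_error(rarefaction_curve(rep1, depths = 11), "depth exceeds")
  # monotone in expectation on a larger example
  rep2 <- mk_rep(c(50L, 30L, 10L, 5L, 5L))
  r3 <- rarefaction_curve(rep2, depths = c(10, 40, 100), n_reps = 50, seed = 3)
  expect_true(all(diff(r3$mean_unique) >= 0))
})

test_that("D50 follows the cumulative-rank definition", {
  expect_equal(d50(mk_rep(rep(10L, 10))), 50)
  expect_equal(d50(mk_rep(c(60L, rep(40 / 99, 99)))), 1)
  expect_error(d50(mk_rep(1L)[0, ]), "empty")
  # random abundance vectors equal the brute-force scan
  set.seed(31)
  for (i in 1:20) {
    counts <- sample(1:50, sample(5:40, 1), replace = TRUE)
    rp <- mk_rep(counts)
    expect_equal(d50(rp), oracle_d50(counts, rp$junction))
  }
  # D50 is in (0, 100] and never increases when the top clone gains reads
  counts <- c(30L, 10L, 5L, 5L, 2L)
  rp <- mk_rep(counts)
  base <- d50(rp)
  rp2 <- rp
  rp2$duplicate_count[which.max(rp2$duplicate_count)] <- 60L
  expect_lte(d50(rp2), base)
  expect_gt(base, 0)
  expect_lte(base, 100)
})

test_that("CDR3 length statistics pool unique clonotypes", {
  one <- mk_rep(5L, junctions = strrep("TGT", 13))
  expect_equal(cdr3_length_stats(one)$mean, 13)
  two <- mk_rep(c(1L, 1L), junctions = c(strrep("GCT", 12), strrep("GGT", 14)))
  expect_equal(cdr3_length_stats(two)$mean, 13)
  expect_equal(cdr3_length_stats(list(one, two))$n, 3L)
  expect_equal(cdr3_length_stats(two, unit = "nt")$mean, 39)
})

test_that("germline CDR3 length divides nucleotides by three, fractions kept", {
  expect_equal(germline_cdr3_length(list(germ_cdr3_nt = 15L)), 5)
  expect_equal(germline_cdr3_length(list(germ_cdr3_nt = 16L)), 16 / 3)
  expect_error(germline_cdr3_length(list(germ_cdr3_nt = NA)), "not annotated")
})

test_that("length correlation matches its construction", {
  germ <- data.frame(name = c("Va", "Vb", "Vc"), kind = "V",
                     germ_cdr3_nt = c(9L, 15L, 21L), stringsAsFactors = FALSE)
  cl <- data.frame(v_call = rep(c("Va", "Vb", "Vc"), each = 4),
                   junction_aa = strrep("A", rep(c(5, 7, 9), each = 4)),
                   stringsAsFactors = FALSE)
  r <- length_correlation(cl, germ)
  expect_equal(r$r, 1.0, tolerance = 1e-12)
  cl$junction_aa <- strrep("A", rep(c(9, 7, 5), each = 4))
  expect_equal(length_correlation(cl, germ)$r, -1.0, tolerance = 1e-12)
  cl$junction_aa <- strrep("A", 7)
  expect_true(is.na(length_correlation(cl, germ)$r))
  # independence: |r| small at moderate n
  set.seed(32)
  cl2 <- data.frame(v_call = sample(c("Va", "Vb", "Vc"), 300, replace = TRUE),
                    junction_aa = strrep("A", sample(10:16, 300, replace = TRUE)),
                    stringsAsFactors = FALSE)
  expect_lt(abs(length_correlation(cl2, germ)$r), 0.2)
})

test_that("usage vectors and correlations behave at the boundaries", {
  a <- mk_rep(rep(1L, 4), v = c("V1*01", "V1*01", "V2*01", "V3*01"))
  u <- gene_usage(a)
  expect_equal(sum(u), 1)
  expect_equal(unname(u["V1*01"]), 0.5)
  two <- list(s1 = a, s2 = a)
  uc <- usage_correlation(two)
  expect_equal(uc$mean, 1.0, tolerance = 1e-12)
  expect_true(is.na(usage_correlation(two["s1"])$mean))
  # disjoint single-gene usage across two genes: r = -1 (degenerate)
  d1 <- mk_rep(rep(1L, 3), v = "VX*01")
  d2 <- mk_rep(rep(1L, 3), v = "VY*01")
  expect_equal(usage_correlation(list(a = d1, b = d2))$mean, -1)
  # replicate exclusion
  uc2 <- usage_correlation(list(s1 = a, s2 = a, s2b = d1), exclude = "s2b")
  expect_equal(uc2$mean, 1.0)
})

test_that("J-group ratios mirror the clonotype arithmetic", {
  cl <- mk_rep(rep(1L, 86), j = c(rep("IGHJ1-1*01", 76), rep("IGHJ2-1*01", 10)))
  expect_equal(j_ratio(cl, "IGHJ1", "IGHJ2"), 7.6)
  cl0 <- mk_rep(rep(1L, 10), j = "IGHJ1-1*01")
  expect_equal(j_ratio(cl0, "IGHJ1", "IGHJ2"), Inf)
  expect_true(is.na(j_ratio(cl0, "IGHJ3", "IGHJ4")))
  expect_error(j_ratio(cl, "IGHJ1", "IGHJ1"))
})

test_that("sharing partitions follow set algebra", {
  r1 <- mk_rep(rep(1L, 3), junctions = c("TGTGCTTGG", "TGTGGTTGG", "TGTTGGTGG"))
  r2 <- r1
  p <- sharing_partition(list(f1 = r1, f2 = r2))
  expect_equal(unname(p$per_fish[, "shared_by_all"]), c(1, 1))
  expect_equal(p$shared_by_all_count, 3L)
  # fully disjoint repertoires
  r3 <- mk_rep(rep(1L, 2), junctions = c("GCTGCTGCT", "GGTGGTGGT"))
  r4 <- mk_rep(rep(1L, 2), junctions = c("TGGTGGTGG", "TGTTGTTGT"))  # WWW, CCC
  r5 <- mk_rep(rep(1L, 2), junctions = c("AAAAAAAAA", "GATGATGAT"))  # KKK, DDD
  p3 <- sharing_partition(list(a = r3, b = r4, c = r5))
  expect_equal(unname(p3$per_fish[, "unique"]), c(1, 1, 1))
  expect_equal(p3$shared_by_all_count, 0L)
  expect_true(all(abs(rowSums(p3$per_fish) - 1) < 1e-9))
  expect_error(sharing_partition(list(r1, r2)), "named")
  # random repertoires with planted public clones: equals brute-force sets
  set.seed(33)
  pub <- c("TGTAAATGG", "TGTCCCTGG")
  reps <- lapply(1:4, function(i) {
    own <- replicate(6, paste(sample(c("TGT", "GCT", "GGT", "TGG", "GCA"), 4,
                                     replace = TRUE), collapse = ""))
    mk_rep(rep(1L, 8), junctions = c(pub, own), sample_id = paste0("f", i))
  })
  names(reps) <- paste0("f", 1:4)
  p4 <- sharing_partition(reps)
  sets <- lapply(reps, function(r) unique(r$junction_aa))
  prev <- table(unlist(lapply(sets, unique)))
  expect_equal(p4$shared_by_all_count, sum(prev == 4))
  expect_equal(p4$total_distinct, length(prev))
  # per-fish proportions sum to one and order does not matter
  expect_true(all(abs(rowSums(p4$per_fish) - 1) < 1e-9))
  p4r <- sharing_partition(rev(reps))
  expect_equal(p4r$shared_by_all_count, p4$shared_by_all_count)
})

test_that("replicate overlap reports Jaccard and containment", {
  a <- mk_rep(rep(1L, 80), junctions = sprintf("TGT%03dAAATGG", 1:80))
  a$junction_aa <- sprintf("aa%03d", 1:80)
  b <- a[1:40, ]
  b$junction_aa <- c(sprintf("aa%03d", 1:20), sprintf("bb%03d", 1:20))
  ov <- replicate_overlap(a, b)
  expect_equal(ov$jaccard, 100 * 20 / 100)
  expect_equal(ov$containment_a, 25)
  expect_equal(ov$containment_b, 50)
  same <- replicate_overlap(a, a)
  expect_equal(same$jaccard, 100)
  expect_equal(replicate_overlap(a, mk_rep(1L, junctions = "GGTGGTGGT"))$jaccard, 0)
})
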