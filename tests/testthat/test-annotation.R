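test_that("a clean simulated locus is annotated at exact planted coordinates", {
  fx <- fixture_heavy()
  t <- fx$sim$segments
  a <- fx$ann$segments
  expect_equal(nrow(a), nrow(t))
  m <- merge(t[, c("kind", "start", "end", "strand", "functionality", "unit")],
             a[, c("kind", "start", "end", "strand", "functionality", "unit")],
             by = c("kind", "start"), all = TRUE)
  expect_false(anyNA(m$end.y))
  expect_equal(m$end.y, m$end.x)
  expect_equal(m$strand.y, m$strand.x)
  expect_equal(m$functionality.y, m$functionality.x)
  # germline CDR3 contributions match the planted truth
  tv <- t[t$kind == "V", ]
  av <- a[a$kind == "V", ]
  expect_equal(av$germ_cdr3_nt[order(av$start)],
               tv$germ_cdr3_nt[order(tv$start)])
})

test_that("every planted lesion maps to the matching pseudogene reason", {
  lesions <- c("internal_stop", "frameshift", "missing_RSS",
               "missing_promoter", "noncanonical_splice")
  for (les in lesions) {
    mix <- stats::setNames(as.numeric(lesions == les), lesions)
    bp <- locus_blueprint("IGH", n_units = 1, v_per_unit = 2L,
                          d_per_unit = 1L, pseudogene_rate = 1,
                          lesion_mix = mix, seed = 17)
    sim <- generate_germline_locus(bp)
    ann <- annotate_locus(sim$genome, sim$refs, "IGH")
    av <- ann$segments[ann$segments$kind == "V", ]
    expect_equal(av$functionality, rep("pseudogene", 2), label = les)
    expect_equal(av$reasons, rep(les, 2), label = les)
    tv <- sim$segments[sim$segments$kind == "V", ]
    expect_equal(av$start[order(av$start)], tv$start[order(tv$start)],
                 label = les)
    expect_equal(av$end[order(av$start)], tv$end[order(tv$start)],
                 label = les)
  }
})

test_that("a stop codon in the final two codons before the heptamer stays functional", {
  bp <- locus_blueprint("IGH", n_units = 1, v_per_unit = 3L, d_per_unit = 1L,
                        pseudogene_rate = 0, terminal_stop_rate = 1, seed = 9)
  sim <- generate_germline_locus(bp)
  expect_true(all(sim$segments$terminal_stop[sim$segments$kind == "V"]))
  ann <- annotate_locus(sim$genome, sim$refs, "IGH")
  av <- ann$segments[ann$segments$kind == "V", ]
  expect_equal(av$functionality, rep("functional", 3))
})

test_that("promoter detection finds planted pairs and matches the enumeration oracle", {
  cfg <- annotation_config()
  set.seed(21)
  # planted octamer + 20 nt + TATA
  win <- paste0(random_dna_str(60), "ATGCAAAT", random_dna_str(20), "TATAAAT",
                random_dna_str(60))
  p <- detect_promoter(win, cfg)
  expect_equal(p$gap_nt, 20L)
  expect_equal(p$octamer_seq, "ATGCAAAT")
  expect_equal(p$mismatches, 0L)
  # motif-free window
  clean <- gsub("TATA|TGCA|ATGC", "CCGG", random_dna_str(300))
  expect_null(detect_promoter(clean, cfg))
  # windows with competing pairs equal the enumeration oracle
  for (i in 1:12) {
    w <- paste0(random_dna_str(30), "ATGCAAAT", random_dna_str(sample(5:40, 1)),
                "TATATAT", random_dna_str(20), "ATGCAAAT",
                random_dna_str(sample(5:40, 1)), "TATAAAA", random_dna_str(30))
    got <- detect_promoter(w, cfg)
    want <- oracle_promoter(w, cfg)
    expect_equal(got$octamer_start, want$o)
    expect_equal(got$tata_start, want$t)
    expect_equal(got$mismatches, want$mm)
  }
})

test_that("D segments require two intact inward-facing 12-spacer RSS", {
  set.seed(31)
  rssP <- function() paste0("CACAGTG", random_dna_str(12), "ACAAAAACC")
  core <- paste0("GGG", random_dna_str(9), "GGG")
  good <- paste0(random_dna_str(80), rc_str(rssP()), core, rssP(),
                 random_dna_str(80))
  d <- find_d_segments(good)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 80L + 28L + 1L)
  expect_equal(d$end, 80L + 28L + nchar(core))
  expect_equal(d$functionality, "functional")
  # destroyed nonamer on one side: absent under the default (no rescue)
  broken5 <- paste0("CACTGTG", random_dna_str(12), "TGATCGTAG")
  bad <- paste0(random_dna_str(80), rc_str(broken5), core, rssP(),
                random_dna_str(80))
  expect_equal(nrow(find_d_segments(bad)), 0L)
})

test_that("J segments need similarity, a 5' RSS and the [FW]GxG motif", {
  fx <- fixture_heavy()
  jref <- fx$sim$refs[fx$sim$refs$kind == "J", ][1, , drop = FALSE]
  set.seed(41)
  rss23 <- paste0("CACAGTG", random_dna_str(23), "ACAAAAACC")
  genome <- paste0(random_dna_str(300), rc_str(rss23), jref$seq,
                   random_dna_str(300))
  j <- find_j_segments(genome, jref, "IGH")
  expect_equal(nrow(j), 1L)
  expect_equal(j$start, 300L + 39L + 1L)
  expect_equal(j$end, 300L + 39L + nchar(jref$seq))
  expect_equal(j$functionality, "functional")
  expect_equal(j$anchor_nt, jref$anchor)
  # broken RSS -> pseudogene
  genome2 <- paste0(random_dna_str(300), "ATTCGAT", random_dna_str(23),
                    "TGATCGTAG", jref$seq, random_dna_str(300))
  j2 <- find_j_segments(genome2, jref, "IGH")
  expect_equal(nrow(j2), 1L)
  expect_equal(j2$functionality, "pseudogene")
  expect_equal(j2$reasons, "missing_RSS")
})

test_that("organization inference groups translocons and mini-clusters", {
  fx <- fixture_heavy()
  expect_equal(nrow(fx$ann$units), 2L)
  expect_true(all(fx$ann$units$unit_type == "translocon"))
  expect_equal(fx$ann$segments$unit[order(fx$ann$segments$start)],
               fx$sim$segments$unit[order(fx$sim$segments$start)])
  # mini-clusters
  bp <- locus_blueprint("IGI2_sigma", n_units = 5, seed = 12)
  sim <- generate_germline_locus(bp)
  ann <- annotate_locus(sim$genome, sim$refs, "IGI2_sigma")
  expect_equal(nrow(ann$units), 5L)
  expect_true(all(ann$units$unit_type == "mini_cluster"))
  # degenerate: one V alone forms a one-member unit
  one <- infer_organization(data.frame(kind = "V", start = 100L, end = 400L,
                                       strand = "+"))
  expect_equal(nrow(one$units), 1L)
  expect_equal(one$units$unit_type, "mini_cluster")
  expect_equal(one$units$n_segments, 1L)
})

test_that("inverted kappa V genes are annotated on the minus strand inside their cluster", {
  bp <- locus_blueprint("IGI1_kappa", n_units = 5, inverted_v_fraction = 1,
                        family_weights = 1, pseudogene_rate = 0, seed = 8)
  sim <- generate_germline_locus(bp)
  ann <- annotate_locus(sim$genome, sim$refs, "IGI1_kappa")
  av <- ann$segments[ann$segments$kind == "V", ]
  expect_equal(nrow(av), 5L)
  expect_true(all(av$strand == "-"))
  expect_equal(nrow(ann$units), 5L)
  expect_true(all(ann$units$unit_type == "mini_cluster"))
  # V12-23J structure holds in every cluster
  s <- ann$segments
  for (u in unique(s$unit)) {
    v <- s[s$unit == u & s$kind == "V", ]
    j <- s[s$unit == u & s$kind == "J", ]
    expect_true(check_1223(v, j))
  }
})

test_that("inter-cluster distances summarize unit gaps", {
  u2 <- data.frame(start = c(1L, 2001L), end = c(1000L, 3000L))
  d2 <- intercluster_distances(u2)
  expect_equal(d2$mean, 1000)
  expect_equal(d2$min, 1000)
  expect_equal(d2$max, 1000)
  u3 <- data.frame(start = c(1L, 1501L, 3501L), end = c(1000L, 2000L, 4000L))
  d3 <- intercluster_distances(u3)
  expect_equal(d3$mean, 1000)
  expect_equal(d3$min, 500)
  expect_equal(d3$max, 1500)
  expect_length(intercluster_distances(u2[1, , drop = FALSE]), 0L)
  # simulated mini-cluster gaps match the truth exactly
  bp <- locus_blueprint("IGI2_sigma", n_units = 6, seed = 3)
  sim <- generate_germline_locus(bp)
  ann <- annotate_locus(sim$genome, sim$refs, "IGI2_sigma")
  got <- intercluster_distances(ann$units)
  want <- intercluster_distances(sim$units)
  expect_equal(got$distances, want$distances)
})

test_that("nomenclature follows the family-translocon-ordinal and cluster-number rules", {
  seg <- data.frame(
    kind = c("V", "V", "V", "V"),
    start = c(100L, 500L, 900L, 1300L), end = c(400L, 800L, 1200L, 1600L),
    strand = "+", family = c(1L, 1L, 1L, 2L), unit = 2L,
    stringsAsFactors = FALSE)
  named <- assign_nomenclature(seg, NULL, "IGH")
  expect_equal(named$name[3], "IGHV1-2-3*01")
  expect_equal(named$name[4], "IGHV2-2-1*01")
  # a cluster missing its J skips that number; duplicates get a letter suffix
  lseg <- data.frame(
    kind = c("V", "J", "C", "V", "C", "V", "V", "J", "C"),
    start = c(1, 2, 3, 11, 13, 21, 22, 23, 24) * 100L,
    end = c(1, 2, 3, 11, 13, 21, 22, 23, 24) * 100L + 50L,
    strand = "+", family = 1L,
    unit = c(1L, 1L, 1L, 5L, 5L, 7L, 7L, 7L, 7L),
    stringsAsFactors = FALSE)
  lnamed <- assign_nomenclature(lseg, NULL, "IGI2_sigma")
  expect_true("IGIV2-5*01" %in% lnamed$name)
  expect_true("IGIC2-5*01" %in% lnamed$name)
  expect_false("IGIJ2-5*01" %in% lnamed$name)
  expect_true(all(c("IGIV2-7*01", "IGIV2-7b*01") %in% lnamed$name))
  expect_false(anyDuplicated(lnamed$name) > 0)
  expect_error(assign_nomenclature(transform(seg, family = NA), NULL, "IGH"),
               "family")
})

test_that("annotation is deterministic", {
  fx <- fixture_heavy()
  again <- annotate_locus(fx$sim$genome, fx$sim$refs, "IGH",
                          genome_id = fx$sim$genome_id)
  expect_identical(again$segments, fx$ann$segments)
  expect_identical(again$units, fx$ann$units)
})

test_that("candidate seeding handles degenerate genomes", {
  fx <- fixture_heavy()
  expect_equal(nrow(seed_gene_candidates(strrep("N", 5000), fx$sim$refs, "V")),
               0L)
})
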