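test_that("sliding-window trimming cuts at the first failing window", {
  q30 <- rep(30L, 50)
  r <- sliding_window_trim(strrep("A", 50), q30)
  expect_equal(nchar(r$seq), 50L)
  # brute-force oracle over a read with a low-quality tail
  qual <- c(rep(35L, 30), rep(10L, 20))
  seq <- strrep("C", 50)
  got <- sliding_window_trim(seq, qual, min_q = 20, window = 4)
  cut_oracle <- NA
  for (i in 1:(50 - 4 + 1)) {
    if (mean(qual[i:(i + 3)]) < 20) { cut_oracle <- i - 1L; break }
  }
  expect_equal(nchar(got$seq), cut_oracle)
  # hopeless read collapses to empty
  r2 <- sliding_window_trim(strrep("G", 30), rep(2L, 30))
  expect_equal(r2$seq, "")
  # phred+33 string input
  r3 <- sliding_window_trim("ACGT", "IIII")
  expect_equal(r3$qual, rep(40L, 4))
})

test_that("germline assignment picks the best call with deterministic ties", {
  fx <- fixture_heavy()
  germ <- fx$germ
  v1 <- germ[germ$kind == "V", ][1, ]
  frag <- substr(v1$seq, 20, 140)
  call <- assign_germline(frag, germ, "V")
  expect_equal(call$name, v1$name)
  expect_equal(call$identity, 1.0)
  # two identical germline J genes: lexicographically smaller name wins
  jd <- germ[germ$kind == "J", ]
  same <- jd$seq[1]
  twins <- data.frame(name = c("JB", "JA"), kind = "J", chain = "IGH",
                      seq = same, family = 1L, cys_start = NA, germ_cdr3_nt = NA,
                      anchor_nt = jd$anchor_nt[1], functional = TRUE,
                      stringsAsFactors = FALSE)
  class(twins) <- c("ig_germline", "data.frame")
  expect_equal(assign_germline(same, twins, "J")$name, "JA")
  # garbage gets no call
  expect_true(is.na(assign_germline(strrep("AT", 40), germ, "V")$name))
})

test_that("V calls from reads with 1% error are almost always family-correct", {
  fx <- fixture_heavy()
  pars <- recombination_params("IGH", n_clones = 40L, depth = 300L,
                               error_rate = 0.01, seed = 21)
  clones <- simulate_recombination(fx$germ, pars)
  rd <- simulate_reads(clones, fx$germ, pars)
  vrows <- fx$germ[fx$germ$kind == "V", ]
  calls <- igloci:::germline_call_batch(rd$read2$seq, vrows, 40L, 0.6)
  truth_v <- clones$v_name[match(rd$read_truth$clone_id, clones$clone_id)]
  fam_true <- vrows$family[match(truth_v, vrows$name)]
  fam_call <- vrows$family[match(calls$name, vrows$name)]
  expect_gte(mean(fam_call == fam_true, na.rm = TRUE), 0.99)
  expect_lte(mean(is.na(calls$name)), 0.02)
})

test_that("CDR3 extraction recovers planted junctions, insertions included", {
  fx <- fixture_heavy()
  germ <- fx$germ
  vrow <- germ[germ$kind == "V", ][2, ]
  jrow <- germ[germ$kind == "J", ][1, ]
  # zero-trimming junction: exact V tail + J contribution
  junction <- paste0(substr(vrow$seq, vrow$cys_start, nchar(vrow$seq)),
                     substr(jrow$seq, 1, jrow$anchor_nt + 2))
  read <- paste0(substr(vrow$seq, vrow$cys_start - 40, vrow$cys_start - 1),
                 junction,
                 substring(jrow$seq, jrow$anchor_nt + 3))
  expect_equal(extract_cdr3(read, vrow, jrow), junction)
  # a 4-nt N insertion appears verbatim
  junction_n <- paste0(substr(vrow$seq, vrow$cys_start, nchar(vrow$seq)),
                       "ACGT",
                       substr(jrow$seq, 1, jrow$anchor_nt + 2))
  read_n <- paste0(substr(vrow$seq, vrow$cys_start - 40, vrow$cys_start - 1),
                   junction_n,
                   substring(jrow$seq, jrow$anchor_nt + 3))
  expect_equal(extract_cdr3(read_n, vrow, jrow), junction_n)
  # simulated error-free reads: extraction matches clone truth for all reads
  rx <- fixture_reads()
  sense1 <- sapply(rx$reads$read1$seq, rc_str, USE.NAMES = FALSE)
  truth_j <- rx$clones$junction[match(rx$reads$read_truth$clone_id,
                                      rx$clones$clone_id)]
  truth_vn <- rx$clones$v_name[match(rx$reads$read_truth$clone_id,
                                     rx$clones$clone_id)]
  truth_jn <- rx$clones$j_name[match(rx$reads$read_truth$clone_id,
                                     rx$clones$clone_id)]
  take <- seq_len(min(200L, length(sense1)))
  got <- sapply(take, function(i) {
    extract_cdr3(sense1[i],
                 germ[germ$name == truth_vn[i], ],
                 germ[germ$name == truth_jn[i], ])
  })
  expect_equal(got, truth_j[take])
})

test_that("productivity requires frame and absence of stops", {
  expect_true(is_productive("TGTGCTGCTTGG"))
  expect_false(is_productive("TGTTAAGCTTGG"))     # in-frame stop
  expect_false(is_productive("TGTGCTGCTTGGA"))    # length 1 mod 3
  expect_false(is_productive(NA_character_))
})

test_that("clonotype assembly applies collapse, voting and the read-count filter", {
  fx <- fixture_heavy()
  germ <- fx$germ
  vrow <- germ[germ$kind == "V", ][1, ]
  jrow <- germ[germ$kind == "J", ][1, ]
  crow <- germ[germ$kind == "C", ][1, ]
  mk_pair <- function(extra_n) {
    junction <- paste0(substr(vrow$seq, vrow$cys_start, nchar(vrow$seq)),
                       extra_n, substr(jrow$seq, 1, jrow$anchor_nt + 2))
    transcript <- paste0(substr(vrow$seq, 1, vrow$cys_start - 1), junction,
                         substring(jrow$seq, jrow$anchor_nt + 3),
                         substr(crow$seq, 1, 40))
    r1 <- rc_str(substring(transcript, nchar(transcript) - 149))
    r2 <- substr(transcript, 1, 150)
    list(r1 = r1, r2 = r2, junction = junction)
  }
  a <- mk_pair("GGTGGT")   # in-frame junction
  b <- mk_pair("GCTGCT")
  n_a <- 10L; n_b <- 4L
  reads1 <- data.frame(id = sprintf("r%02d", 1:(n_a + n_b)),
                       seq = c(rep(a$r1, n_a), rep(b$r1, n_b)),
                       qual = strrep("F", 150), stringsAsFactors = FALSE)
  reads2 <- data.frame(id = reads1$id,
                       seq = c(rep(a$r2, n_a), rep(b$r2, n_b)),
                       qual = strrep("F", 150), stringsAsFactors = FALSE)
  out <- assemble_clonotypes(reads1, reads2, germ, sample_id = "t")
  expect_equal(nrow(out), 1L)                  # 4 reads fall below the filter
  expect_equal(out$junction, a$junction)
  expect_equal(out$duplicate_count, n_a)
  expect_equal(out$v_call, vrow$name)
  expect_equal(out$j_call, jrow$name)
  expect_true(out$productive)
  # exactly 5 reads is retained ("less than 5" are discarded)
  out5 <- assemble_clonotypes(reads1[c(1:5, 11:14), ], reads2[c(1:5, 11:14), ],
                              germ, sample_id = "t")
  expect_equal(out5$duplicate_count, 5L)
  # order independence
  perm <- sample(nrow(reads1))
  out_p <- assemble_clonotypes(reads1[perm, ], reads2[perm, ], germ,
                               sample_id = "t")
  expect_equal(out_p$junction, out$junction)
  expect_equal(out_p$duplicate_count, out$duplicate_count)
})

test_that("simulated repertoires are recovered exactly at zero error", {
  fx <- fixture_heavy()
  rx <- fixture_reads()
  rep1 <- assemble_clonotypes(rx$reads$read1, rx$reads$read2, fx$germ,
                              sample_id = "fish1")
  tr <- rx$reads$clones[rx$reads$clones$productive, ]
  agg <- stats::aggregate(read_count ~ junction, tr, sum)
  agg <- agg[agg$read_count >= 5, ]
  expect_setequal(rep1$junction, agg$junction)
  m <- merge(agg, rep1, by = "junction")
  expect_equal(m$duplicate_count, m$read_count)
  expect_lte(sum(rep1$duplicate_count), nrow(rx$reads$read1))
  # collapsing is idempotent: re-assembling the table's own support changes nothing
  again <- assemble_clonotypes(rx$reads$read1, rx$reads$read2, fx$germ,
                               sample_id = "fish1")
  expect_identical(again$junction, rep1$junction)
  expect_identical(again$duplicate_count, rep1$duplicate_count)
})
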