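test_that("planted segment counts follow the blueprint and runs are reproducible", {
  bp <- locus_blueprint("IGH", n_units = 3, v_per_unit = 5L, d_per_unit = 2L,
                        j_per_unit = 2L, c_per_unit = 2L, pseudogene_rate = 0,
                        seed = 101)
  sim <- generate_germline_locus(bp)
  counts <- table(sim$segments$kind)
  expect_equal(unname(counts[c("V", "D", "J", "C")]),
               structure(c(15L, 6L, 6L, 6L), class = "table"), ignore_attr = TRUE)
  expect_true(all(sim$segments$functionality == "functional"))
  # byte-identical regeneration under the same seed
  sim2 <- generate_germline_locus(bp)
  expect_identical(sim$genome, sim2$genome)
  expect_identical(sim$segments, sim2$segments)
  # a different seed gives a different genome
  bp2 <- locus_blueprint("IGH", n_units = 3, v_per_unit = 5L, d_per_unit = 2L,
                         pseudogene_rate = 0, seed = 102)
  expect_false(identical(generate_germline_locus(bp2)$genome, sim$genome))
})

test_that("lesion counts are recorded exactly and distributed binomially", {
  n_lesioned <- vapply(1:20, function(s) {
    bp <- locus_blueprint("IGH", n_units = 1, v_per_unit = 20L,
                          d_per_unit = 1L, pseudogene_rate = 0.2, seed = s)
    sim <- generate_germline_locus(bp)
    v <- sim$segments[sim$segments$kind == "V", ]
    expect_equal(sum(v$functionality == "pseudogene"), sum(!is.na(v$lesion)))
    sum(!is.na(v$lesion))
  }, numeric(1))
  # mean of Binomial(20, 0.2) is 4; across 20 seeds se = sqrt(3.2/20) = 0.4
  expect_lt(abs(mean(n_lesioned) - 4), 4 * 0.4 + 1e-9)
})

test_that("with all junction parameters zero the junction is an exact V(D)J concatenation", {
  fx <- fixture_heavy()
  germ <- fx$germ
  pars <- recombination_params("IGH", n_clones = 25L, del_v = 0, del_d5 = 0,
                               del_d3 = 0, del_j = 0, n_ins_lambda = 0,
                               p_nt_prob = 0, seed = 5)
  cl <- simulate_recombination(germ, pars)
  for (i in seq_len(nrow(cl))) {
    v <- germ[germ$name == cl$v_name[i], ]
    d <- germ[germ$name == cl$d_name[i], ]
    j <- germ[germ$name == cl$j_name[i], ]
    want <- paste0(substr(v$seq, v$cys_start, nchar(v$seq)), d$seq,
                   substr(j$seq, 1, j$anchor_nt + 2))
    expect_identical(cl$junction[i], want)
  }
  expect_true(all(cl$n_ins == 0L & cl$p_ins == 0L & cl$del_v == 0L))
})

test_that("light-chain mode with zero deletions pins expressed length to the germline", {
  bp <- locus_blueprint("IGI1_kappa", seed = 55)
  germ <- germline_set(generate_germline_locus(bp))
  pars <- recombination_params("IGI1_kappa", n_clones = 300L, del_v = 0,
                               del_j = 0, seed = 6)
  cl <- simulate_recombination(germ, pars)
  clp <- cl[cl$productive, ]
  # junction length = 3 (CYS) + germline tail + constant J contribution
  j_contrib <- unique(germ$anchor_nt[germ$kind == "J"]) + 2
  expect_length(j_contrib, 1L)
  expect_equal(nchar(clp$junction), 3 + clp$v_germ_cdr3_nt + j_contrib)
  expect_equal(stats::cor(clp$v_germ_cdr3_nt, nchar(clp$junction)), 1.0)
})

test_that("heavy junction lengths match the analytic expectation", {
  fx <- fixture_heavy()
  germ <- fx$germ
  pars <- recombination_params("IGH", n_clones = 4000L, p_nt_prob = 0, seed = 8)
  cl <- simulate_recombination(germ, pars)
  # E[len] = 3 + E[germ tail] + E[D] + 2*lambda + j_contrib - sum of E[del]
  v <- germ[germ$kind == "V", ]
  d <- germ[germ$kind == "D", ]
  j <- germ[germ$kind == "J", ]
  mean_del <- function(m, cap) {
    p <- 1 / (1 + m)
    k <- 0:cap
    w <- (1 - p)^k * p
    sum(k * w) / sum(w)
  }
  jp <- if (length(unique(j$family)) > 1) {
    w <- ifelse(j$family == 1, 7.6 / sum(j$family == 1), 1 / sum(j$family == 2))
    w / sum(w)
  } else rep(1 / nrow(j), nrow(j))
  exp_del_v <- mean(vapply(v$germ_cdr3_nt, function(cap) mean_del(3, cap),
                           numeric(1)))
  exp_del_j <- sum(jp * vapply(j$anchor_nt - 1, function(cap) mean_del(3, cap),
                               numeric(1)))
  # D deletions: 5' capped at len-1, then 3' capped at what remains; the
  # expectation is approximated with the marginal caps (error << se)
  exp_d <- mean(nchar(d$seq))
  exp_del_d <- mean(vapply(nchar(d$seq) - 1, function(cap) mean_del(3, cap),
                           numeric(1)))
  want <- 3 + mean(v$germ_cdr3_nt) + exp_d + 2 * 1.5 +
    sum(jp * (j$anchor_nt + 2)) - exp_del_v - exp_del_j - 2 * exp_del_d
  got <- mean(nchar(cl$junction))
  se <- stats::sd(nchar(cl$junction)) / sqrt(nrow(cl))
  expect_lt(abs(got - want), 3 * se + 0.35)
})

test_that("read simulation is seeded, error-free reads carry the junction verbatim", {
  rx <- fixture_reads()
  fx <- fixture_heavy()
  sense1 <- vapply(rx$reads$read1$seq, rc_str, character(1), USE.NAMES = FALSE)
  truth_j <- rx$clones$junction[match(rx$reads$read_truth$clone_id,
                                      rx$clones$clone_id)]
  hit <- mapply(function(s, j) grepl(j, s, fixed = TRUE), sense1, truth_j)
  expect_true(all(hit))
  # read counts multinomial: total equals depth, reproducible under the seed
  expect_equal(sum(rx$reads$clones$read_count), rx$pars$depth)
  again <- simulate_reads(rx$clones, fx$germ, rx$pars)
  expect_identical(again$read1$seq, rx$reads$read1$seq)
  expect_identical(again$read2$seq, rx$reads$read2$seq)
})
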