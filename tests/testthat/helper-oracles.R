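# Independent brute-force oracles and shared fixtures.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_str <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

# Exhaustive per-window RSS enumeration, independent of scan_rss: explicit
# loop over every start position, spacer length and strand.
oracle_scan_rss <- function(seq, spacer_class, cfg) {
  rows <- list()
  L <- nchar(seq)
  heps <- lapply(cfg$heptamer_consensus, function(h) strsplit(h, "")[[1]])
  non <- strsplit(cfg$nonamer_consensus, "")[[1]]
  nf <- cfg$heptamer_fixed
  for (strand in c("+", "-")) {
    x <- strsplit(if (strand == "+") seq else rc_str(seq), "")[[1]]
    for (sp in (spacer_class - cfg$spacer_slack):(spacer_class + cfg$spacer_slack)) {
      if (sp < 0) next
      W <- 16L + sp
      if (L < W) next
      for (i in seq_len(L - W + 1L)) {
        hw <- x[i:(i + 6L)]
        hm_best <- NA_integer_
        for (h in heps) {
          if (any(hw[seq_len(nf)] != h[seq_len(nf)])) next
          hm <- sum(hw != h)
          if (hm <= cfg$heptamer_tol &&
              (is.na(hm_best) || hm < hm_best)) hm_best <- hm
        }
        if (is.na(hm_best)) next
        nw <- x[(i + 7L + sp):(i + 15L + sp)]
        nm <- sum(nw != non)
        if (nm > cfg$nonamer_tol) next
        s <- if (strand == "+") i else L - (i + W - 1L) + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + W - 1L, strand = strand,
          heptamer_seq = paste(hw, collapse = ""),
          nonamer_seq = paste(nw, collapse = ""),
          spacer_len = sp, spacer_class = spacer_class,
          heptamer_mismatches = hm_best, nonamer_mismatches = nm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), heptamer_seq = character(0),
                      nonamer_seq = character(0), spacer_len = integer(0),
                      spacer_class = integer(0),
                      heptamer_mismatches = integer(0),
                      nonamer_mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand, out$spacer_len), , drop = FALSE]
}

same_hits <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  rownames(a) <- rownames(b) <- NULL
  isTRUE(all.equal(a[order(a$start, a$strand, a$spacer_len), ],
                   b[order(b$start, b$strand, b$spacer_len), ],
                   check.attributes = FALSE))
}

# Exhaustive promoter pair enumeration (octamer both orientations, TATA
# forward), ranked by total mismatches, then smaller gap, then 3'-most.
oracle_promoter <- function(window, cfg) {
  x <- strsplit(window, "")[[1]]
  L <- length(x)
  oct_f <- strsplit(cfg$octamer_consensus, "")[[1]]
  oct_r <- strsplit(rc_str(cfg$octamer_consensus), "")[[1]]
  tata <- igloci:::pattern_positions(cfg$tata_pattern)
  tlen <- length(tata)
  best <- NULL
  for (o in seq_len(max(0L, L - 7L))) {
    ow <- x[o:(o + 7L)]
    om <- min(sum(ow != oct_f), sum(ow != oct_r))
    if (om > cfg$octamer_tol) next
    for (t in seq_len(max(0L, L - tlen + 1L))) {
      gap <- t - (o + 8L)
      if (gap < 0L || gap > cfg$promoter_max_gap) next
      tm <- 0L
      for (k in seq_len(tlen)) {
        if (!(x[t + k - 1L] %in% tata[[k]])) tm <- tm + 1L
      }
      if (tm > cfg$tata_tol) next
      key <- c(om + tm, gap, -t, -o)
      if (is.null(best) || igloci:::lexico_less(key, best$key)) {
        best <- list(o = o, t = t, gap = gap, mm = om + tm, key = key)
      }
    }
  }
  best
}

# closed-form expected number of distinct clonotypes in a subsample
oracle_expected_distinct <- function(counts, depth) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

# brute-force D50: cumulative scan over ranked abundances
oracle_d50 <- function(counts, keys) {
  ord <- order(-counts, keys)
  cc <- counts[ord]
  run <- 0
  for (k in seq_along(cc)) {
    run <- run + cc[k]
    if (run >= 0.5 * sum(cc)) return(100 * k / length(cc))
  }
}

# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture_heavy <- function() {
  if (is.null(.fixtures$heavy)) {
    bp <- locus_blueprint("IGH", n_units = 2, v_per_unit = c(4L, 4L),
                          d_per_unit = 2L, pseudogene_rate = 0.25, seed = 42)
    sim <- generate_germline_locus(bp)
    ann <- annotate_locus(sim$genome, sim$refs, "IGH",
                          genome_id = sim$genome_id)
    .fixtures$heavy <- list(bp = bp, sim = sim, ann = ann,
                            germ = germline_set(sim))
  }
  .fixtures$heavy
}

fixture_reads <- function() {
  if (is.null(.fixtures$reads)) {
    fx <- fixture_heavy()
    pars <- recombination_params("IGH", n_clones = 60L, depth = 3000L,
                                 seed = 7)
    clones <- simulate_recombination(fx$germ, pars)
    reads <- simulate_reads(clones, fx$germ, pars)
    .fixtures$reads <- list(pars = pars, clones = clones, reads = reads)
  }
  .fixtures$reads
}
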