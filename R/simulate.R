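# Synthetic germline loci, V(D)J recombination and 5'RACE-style reads with
# known truth. The generator emulates the organization of teleost Ig loci:
# heavy-chain translocons ((V)n (D)n (J)n (C)n, one orientation) and
# light-chain V-J-C mini-clusters (kappa-like loci with inverted V genes),
# pseudogene lesions, junctional deletions and P/N additions without somatic
# hypermutation, clonal abundance skew and flat sequencing error.

BASES <- c("A", "C", "G", "T")

# sample() that never interprets a length-1 x as 1:x
safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

random_dna <- function(n, prob = NULL) {
  if (n <= 0L) return("")
  paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# Intergenic filler is kept free of motif seeds that the annotation rules
# treat as signal (RSS heptamer cores, promoter octamer core, TATA) so that
# the planted truth is unambiguous. Documented in the methods vignette.
SCRUB_MOTIFS <- c("CACAG", "CTGTG", "TGCAA", "TTGCA", "TATA")

scrub_motifs <- function(seq, motifs = SCRUB_MOTIFS) {
  if (nchar(seq) < 4L) return(seq)
  for (iter in 1:20) {
    hit <- FALSE
    for (m in motifs) {
      repeat {
        p <- regexpr(m, seq, fixed = TRUE)
        if (p < 0) break
        hit <- TRUE
        mid <- p + nchar(m) %/% 2L
        old <- substr(seq, mid, mid)
        substr(seq, mid, mid) <- sample(setdiff(BASES, old), 1L)
      }
    }
    if (!hit) break
  }
  seq
}

filler_dna <- function(n) scrub_motifs(random_dna(n))

STOP_CODONS <- c("TAA", "TAG", "TGA")
SAFE_CODONS <- setdiff(names(GENETIC_CODE_TAB), STOP_CODONS)

random_codons <- function(n_codons) {
  if (n_codons <= 0L) return("")
  paste(sample(SAFE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# Substitution-only divergence keeping a set of positions fixed and the
# reading frame free of stop codons (mutated codons that would create a stop
# are reverted).
mutate_coding <- function(seq, rate, protect = integer(0)) {
  ch <- seq_chars(seq)
  n <- length(ch)
  hits <- which(stats::runif(n) < rate)
  hits <- setdiff(hits, protect)
  if (!length(hits)) return(seq)
  orig <- ch
  for (i in hits) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  out <- paste(ch, collapse = "")
  n_cod <- n %/% 3L
  codons <- substring(out, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  bad <- which(codons %in% STOP_CODONS)
  for (b in bad) {
    idx <- (3L * b - 2L):(3L * b)
    ch[idx] <- orig[idx]
  }
  paste(ch, collapse = "")
}

#' Locus blueprint for the germline generator
#'
#' Captures the structural parameters of a simulated immunoglobulin locus.
#' Chain-specific defaults mirror the organization reported for the Atlantic
#' cod: three heavy-chain translocons with 18/38/25 V genes (family sizes
#' 4/6/69/2, ~22\% pseudogenes), and light-chain V-J-C mini-clusters (kappa
#' with mostly inverted V genes and bimodal germline CDR3 lengths; sigma with
#' uniform germline CDR3 length; lambda-2 with one J gene six nucleotides
#' longer than the others). Heavy germline CDR3 contributions are narrowly
#' distributed around 15 nt (junctional, not germline, variation dominates
#' heavy CDR3 length), while kappa germline contributions are bimodal
#' (18/24 nt), the mechanism behind the strong germline-to-expressed CDR3
#' length correlation of light chains.
#'
#' @param chain one of \code{"IGH"}, \code{"IGI1_kappa"}, \code{"IGI2_sigma"},
#'   \code{"IGI4_lambda2"}.
#' @param n_units number of translocons (heavy) or mini-clusters (light).
#' @param v_per_unit,d_per_unit,j_per_unit,c_per_unit per-unit segment counts
#'   (vectors recycled to \code{n_units}; light chains use 1/0/1/1).
#' @param pseudogene_rate per-V probability of a disabling lesion.
#' @param lesion_mix named probabilities over lesion types
#'   \code{internal_stop}, \code{frameshift}, \code{missing_RSS},
#'   \code{missing_promoter}, \code{noncanonical_splice}.
#' @param terminal_stop_rate probability that a functional V carries an
#'   in-frame stop within the final two codons before the recombination site
#'   (still functional: recombination deletes at least two nucleotides).
#' @param c_pseudogene_rate per-C probability of an internal stop lesion.
#' @param family_weights relative sizes of the V families.
#' @param v_divergence per-base substitution rate of a V gene against its
#'   family consensus.
#' @param germ_cdr3_lengths,germ_cdr3_probs distribution of germline CDR3
#'   contributions (nt after the 2nd-CYS codon, multiples of 3).
#' @param d_core_lengths D core lengths sampled uniformly (heavy only).
#' @param j_anchor_codon codon index of the J [FW]GxG anchor phenylalanine/
#'   tryptophan (J CDR3 contribution = 3 x anchor codon).
#' @param j_long_clusters cluster indices whose J gene carries the anchor two
#'   codons later (six nucleotides longer CDR3 contribution; lambda-2).
#' @param inverted_v_fraction fraction of light-chain V genes in the
#'   orientation opposite to their J and C genes.
#' @param inter_unit_gap,v_gap,block_gap,d_gap,j_gap,c_gap length-2 vectors:
#'   uniform ranges (nt) for the respective intergenic gaps.
#' @param seed RNG seed; the generator is bit-reproducible given the seed.
#' @return list of class \code{"locus_blueprint"}.
#' @export
locus_blueprint <- function(chain = "IGH",
                            n_units = NULL,
                            v_per_unit = NULL, d_per_unit = NULL,
                            j_per_unit = NULL, c_per_unit = NULL,
                            pseudogene_rate = NULL,
                            lesion_mix = c(internal_stop = 0.3, frameshift = 0.3,
                                           missing_RSS = 0.2, missing_promoter = 0.1,
                                           noncanonical_splice = 0.1),
                            terminal_stop_rate = NULL,
                            c_pseudogene_rate = NULL,
                            family_weights = NULL,
                            v_divergence = 0.05,
                            germ_cdr3_lengths = NULL, germ_cdr3_probs = NULL,
                            d_core_lengths = c(6, 9, 12, 15, 18, 21, 24),
                            j_anchor_codon = 5L,
                            j_long_clusters = integer(0),
                            inverted_v_fraction = NULL,
                            inter_unit_gap = NULL,
                            v_gap = c(800, 2500), block_gap = c(600, 1200),
                            d_gap = c(200, 500), j_gap = c(250, 450),
                            c_gap = c(400, 800),
                            seed = 1L) {
  stopifnot(chain %in% ig_chains)
  heavy <- chain == "IGH"
  def <- switch(chain,
    IGH = list(n_units = 3L, v = c(18L, 38L, 25L), d = c(2L, 3L, 3L),
               j = c(2L, 2L, 2L), cc = c(2L, 2L, 2L),
               prate = 18 / 81, tstop = 0.07, crate = 0,
               fam = c(4, 6, 69, 2), glen = c(12L, 15L, 18L),
               gprob = c(0.04, 0.92, 0.04), inv = 0,
               gap = c(24000, 30000), jlong = integer(0)),
    IGI1_kappa = list(n_units = 16L, v = 1L, d = 0L, j = 1L, cc = 1L,
               prate = 6 / 104, tstop = 0, crate = 0,
               fam = c(0.95, 0.05), glen = c(18L, 24L), gprob = c(0.5, 0.5),
               inv = 0.95, gap = c(712, 9573), jlong = integer(0)),
    IGI2_sigma = list(n_units = 14L, v = 1L, d = 0L, j = 1L, cc = 1L,
               prate = 0, tstop = 0, crate = 1 / 15,
               fam = 1, glen = 18L, gprob = 1, inv = 0,
               gap = c(375, 3298), jlong = integer(0)),
    IGI4_lambda2 = list(n_units = 4L, v = 1L, d = 0L, j = 1L, cc = 1L,
               prate = 0, tstop = 0, crate = 0,
               fam = 1, glen = 15L, gprob = 1, inv = 0,
               gap = c(5320, 8890), jlong = 2L)
  )
  n_units <- as.integer(if (is.null(n_units)) def$n_units else n_units)
  bp <- list(
    chain = chain, heavy = heavy, n_units = n_units,
    v_per_unit = rep(as.integer(if (is.null(v_per_unit)) def$v else v_per_unit),
                     length.out = n_units),
    d_per_unit = rep(as.integer(if (is.null(d_per_unit)) def$d else d_per_unit),
                     length.out = n_units),
    j_per_unit = rep(as.integer(if (is.null(j_per_unit)) def$j else j_per_unit),
                     length.out = n_units),
    c_per_unit = rep(as.integer(if (is.null(c_per_unit)) def$cc else c_per_unit),
                     length.out = n_units),
    pseudogene_rate = if (is.null(pseudogene_rate)) def$prate else pseudogene_rate,
    lesion_mix = lesion_mix / sum(lesion_mix),
    terminal_stop_rate = if (is.null(terminal_stop_rate)) def$tstop else terminal_stop_rate,
    c_pseudogene_rate = if (is.null(c_pseudogene_rate)) def$crate else c_pseudogene_rate,
    family_weights = if (is.null(family_weights)) def$fam else family_weights,
    v_divergence = v_divergence,
    germ_cdr3_lengths = as.integer(if (is.null(germ_cdr3_lengths)) def$glen else germ_cdr3_lengths),
    germ_cdr3_probs = if (is.null(germ_cdr3_probs)) def$gprob else germ_cdr3_probs,
    d_core_lengths = as.integer(d_core_lengths),
    j_anchor_codon = as.integer(j_anchor_codon),
    j_long_clusters = as.integer(if (is.null(j_long_clusters) || !length(j_long_clusters)) def$jlong else j_long_clusters),
    inverted_v_fraction = if (is.null(inverted_v_fraction)) def$inv else inverted_v_fraction,
    inter_unit_gap = if (is.null(inter_unit_gap)) def$gap else inter_unit_gap,
    v_gap = v_gap, block_gap = block_gap, d_gap = d_gap, j_gap = j_gap,
    c_gap = c_gap,
    seed = as.integer(seed)
  )
  stopifnot(all(bp$germ_cdr3_lengths %% 3L == 0L),
            abs(sum(bp$germ_cdr3_probs) - 1) < 1e-9,
            bp$pseudogene_rate >= 0, bp$pseudogene_rate <= 1)
  class(bp) <- "locus_blueprint"
  bp
}

#' @export
print.locus_blueprint <- function(x, ...) {
  cat(sprintf("locus blueprint: %s, %d %s, %d V genes, pseudogene rate %.2f, seed %d\n",
              x$chain, x$n_units,
              if (x$heavy) "translocons" else "mini-clusters",
              sum(x$v_per_unit), x$pseudogene_rate, x$seed))
  invisible(x)
}

V_PREFIX_CODONS <- 80L   # FR1..FR3 plus the conserved 2nd-CYS (codon 80)
V_CYS_OFFSET <- 3L * (V_PREFIX_CODONS - 1L) + 1L  # nt 238 within the exon
LEADER_LEN <- 51L
INTRON_LEN <- 80L
C_EXON_CODONS <- 100L
J_TOTAL_CODONS <- 13L

make_family_consensus <- function() {
  prefix <- paste0(random_codons(V_PREFIX_CODONS - 1L), "TGT")
  prefix
}

make_j_coding <- function(anchor_codon, heavy) {
  pre <- random_codons(anchor_codon - 1L)
  anchor <- if (heavy) "TGG" else "TTT"        # W for heavy, F for light
  motif <- paste0(anchor, "GGT", sample(SAFE_CODONS, 1L), "GGA")
  post <- random_codons(J_TOTAL_CODONS - anchor_codon - 3L)
  paste0(pre, motif, post)
}

rand_gap <- function(range) {
  as.integer(round(stats::runif(1, range[1], range[2])))
}

rss_plus <- function(spacer_len, heptamer = "CACAGTG", nonamer = "ACAAAAACC") {
  paste0(heptamer, scrub_motifs(random_dna(spacer_len)), nonamer)
}

# Build one V gene unit on the local plus strand. Returns the unit sequence
# and feature coordinates local to the unit (1-based).
make_v_unit <- function(prefix_consensus, tail_len, ref_tail_len, v_spacer,
                        divergence, lesion, terminal_stop, heavy) {
  parts <- character(0)
  pos <- 0L
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
    pos
  }
  add(filler_dna(40L))
  octamer <- if (identical(lesion, "missing_promoter")) "GGACCGGT" else "ATGCAAAT"
  oct_start <- pos + 1L; add(octamer)
  add(filler_dna(23L))
  tata <- if (identical(lesion, "missing_promoter")) "GCGCGCG" else "TATAAAT"
  tata_start <- pos + 1L; add(tata)
  add(filler_dna(50L))
  leader_start <- pos + 1L
  add(paste0("ATG", random_codons((LEADER_LEN - 3L) %/% 3L)))
  leader_end <- pos
  intron_interior <- random_dna(INTRON_LEN - 4L)
  intron_interior <- scrub_motifs(intron_interior, c("GT", SCRUB_MOTIFS))
  acceptor <- if (identical(lesion, "noncanonical_splice")) "CC" else "AG"
  add(paste0("GT", intron_interior, acceptor))
  exon_start <- pos + 1L

  prefix <- mutate_coding(prefix_consensus, divergence,
                          protect = V_CYS_OFFSET:(V_CYS_OFFSET + 2L))
  if (identical(lesion, "internal_stop")) {
    cod <- sample(10:70, 1L)
    substr(prefix, 3L * cod - 2L, 3L * cod) <- "TAA"
  }
  if (identical(lesion, "frameshift")) {
    del_at <- sample(90:200, 1L)
    prefix <- paste0(substr(prefix, 1L, del_at - 1L),
                     substr(prefix, del_at + 1L, nchar(prefix)))
  }
  if (identical(lesion, "missing_RSS")) tail_len <- ref_tail_len
  tail <- random_codons(tail_len %/% 3L)
  if (terminal_stop && tail_len >= 3L) {
    substr(tail, nchar(tail) - 2L, nchar(tail)) <- "TAA"
  }
  add(prefix)
  cys_start <- exon_start + nchar(prefix) - 3L
  add(tail)
  exon_end <- pos
  rss_start <- pos + 1L
  if (identical(lesion, "missing_RSS")) {
    add(paste0("ATTCGAT", scrub_motifs(random_dna(v_spacer)), "TGATCGTAG"))
  } else {
    hept <- if (heavy) sample(c("CACAGTG", "CACAGCA"), 1L) else "CACAGTG"
    add(rss_plus(v_spacer, heptamer = hept))
  }
  rss_end <- pos
  add(filler_dna(30L))
  list(
    seq = paste(parts, collapse = ""),
    len = pos,
    oct_start = oct_start, tata_start = tata_start,
    leader_start = leader_start, leader_end = leader_end,
    exon_start = exon_start, exon_end = exon_end,
    cys_start = cys_start, rss_start = rss_start, rss_end = rss_end,
    germ_cdr3_nt = exon_end - (cys_start + 2L)
  )
}

make_d_unit <- function(core_len, spacer = 12L) {
  rss5 <- revcomp(rss_plus(spacer))
  core <- paste(sample(BASES, core_len, replace = TRUE,
                       prob = c(0.15, 0.15, 0.55, 0.15)), collapse = "")
  core <- scrub_motifs(core)
  rss3 <- rss_plus(spacer)
  list(seq = paste0(rss5, core, rss3),
       core_start = nchar(rss5) + 1L,
       core_end = nchar(rss5) + core_len,
       len = nchar(rss5) + core_len + nchar(rss3))
}

make_j_unit <- function(j_coding, spacer, broken_rss = FALSE) {
  rss <- if (broken_rss) {
    paste0("ATTCGAT", scrub_motifs(random_dna(spacer)), "TGATCGTAG")
  } else {
    rss_plus(spacer)
  }
  rss_rc <- revcomp(rss)
  list(seq = paste0(rss_rc, j_coding),
       j_start = nchar(rss_rc) + 1L,
       j_end = nchar(rss_rc) + nchar(j_coding),
       len = nchar(rss_rc) + nchar(j_coding))
}

#' Generate a germline immunoglobulin locus with known truth
#'
#' Emits a chromosome-like sequence embedding V genes (promoter octamer/TATA,
#' leader exon, GT..AG intron, coding exon ending at the conserved 2nd-CYS
#' plus CDR3 tail, 3' RSS), D cores flanked by two inward-facing 12-spacer
#' RSS, J genes with a 5' RSS and an in-frame [FW]GxG motif, and first C
#' exons. Pseudogene lesions are applied at the blueprint rate with recorded
#' reasons; for light chains, a configurable fraction of V genes is inverted.
#' Seeded and bit-reproducible.
#'
#' @param bp a \code{\link{locus_blueprint}}.
#' @return list of class \code{"ig_sim_locus"}: \code{genome} (sequence
#'   string), \code{genome_id}, \code{segments} (truth table with 1-based
#'   inclusive coordinates, strand, functionality, lesion reasons, CYS/anchor
#'   positions and unit membership), \code{units}, \code{refs} (reference
#'   segment set for similarity seeding, one per family/subtype), and the
#'   blueprint.
#' @export
generate_germline_locus <- function(bp) {
  stopifnot(inherits(bp, "locus_blueprint"))
  set.seed(bp$seed)
  rc <- chain_rss_classes(bp$chain)
  n_fam <- length(bp$family_weights)

  fam_prefix <- replicate(n_fam, make_family_consensus())
  fam_tail_len <- safe_sample(bp$germ_cdr3_lengths, n_fam, replace = TRUE,
                         prob = bp$germ_cdr3_probs)
  fam_ref <- vapply(seq_len(n_fam), function(f) {
    paste0(fam_prefix[f], random_codons(fam_tail_len[f] %/% 3L))
  }, character(1))

  heavy <- bp$heavy
  n_j_fam <- if (heavy) 2L else 1L
  j_anchor <- bp$j_anchor_codon
  j_coding <- vapply(seq_len(n_j_fam), function(f) make_j_coding(j_anchor, heavy),
                     character(1))
  j_coding_long <- if (length(bp$j_long_clusters)) {
    make_j_coding(j_anchor + 2L, heavy)
  } else NA_character_
  n_c_sub <- if (heavy) 2L else 1L
  c_ref <- vapply(seq_len(n_c_sub), function(i) random_codons(C_EXON_CODONS),
                  character(1))

  # D core and V germline-CDR3 tail lengths are dealt from shuffled balanced
  # pools rather than drawn independently, so the locus composition (and with
  # it the mean and variance of junction lengths) is stable across seeds
  d_total <- sum(bp$d_per_unit)
  d_len_seq <- integer(0)
  if (d_total > 0L) {
    nset <- length(bp$d_core_lengths)
    pool <- c(rep(bp$d_core_lengths, d_total %/% nset),
              safe_sample(bp$d_core_lengths, d_total %% nset))
    d_len_seq <- safe_sample(pool, d_total)
  }
  v_total <- sum(bp$v_per_unit)
  cnt <- round(bp$germ_cdr3_probs * v_total)
  while (sum(cnt) > v_total) cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
  while (sum(cnt) < v_total) cnt[which.max(bp$germ_cdr3_probs)] <-
    cnt[which.max(bp$germ_cdr3_probs)] + 1L
  v_tail_seq <- safe_sample(rep(bp$germ_cdr3_lengths, times = cnt), v_total)

  parts <- character(0)
  pos <- 0L
  add <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
    invisible(pos)
  }
  seg <- list()
  push_seg <- function(...) seg[[length(seg) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  unit_rows <- list()

  add(filler_dna(600L))
  v_id <- 0L; d_id <- 0L; j_id <- 0L; c_id <- 0L
  for (u in seq_len(bp$n_units)) {
    if (u > 1L) add(filler_dna(rand_gap(bp$inter_unit_gap)))
    # unit span is derived from member segments after assembly
    # --- V block ---
    for (k in seq_len(bp$v_per_unit[u])) {
      if (k > 1L) add(filler_dna(rand_gap(bp$v_gap)))
      v_id <- v_id + 1L
      fam <- sample.int(n_fam, 1L, prob = bp$family_weights)
      lesion <- NA_character_
      if (stats::runif(1) < bp$pseudogene_rate) {
        lesion <- sample(names(bp$lesion_mix), 1L, prob = bp$lesion_mix)
      }
      tstop <- is.na(lesion) && stats::runif(1) < bp$terminal_stop_rate
      tail_len <- v_tail_seq[v_id]
      unit <- make_v_unit(fam_prefix[fam], tail_len, fam_tail_len[fam],
                          rc$V, bp$v_divergence, lesion, tstop, heavy)
      inverted <- !heavy && stats::runif(1) < bp$inverted_v_fraction &&
        (n_fam == 1L || fam == 1L)
      if (inverted) {
        useq <- revcomp(unit$seq)
        flip <- function(a, b) c(unit$len - b + 1L, unit$len - a + 1L)
        ex <- flip(unit$exon_start, unit$exon_end)
        cys <- flip(unit$cys_start, unit$cys_start + 2L)
        rs <- flip(unit$rss_start, unit$rss_end)
        strand <- "-"
      } else {
        useq <- unit$seq
        ex <- c(unit$exon_start, unit$exon_end)
        cys <- c(unit$cys_start, unit$cys_start + 2L)
        rs <- c(unit$rss_start, unit$rss_end)
        strand <- "+"
      }
      off <- pos
      add(useq)
      push_seg(id = sprintf("V%03d", v_id), kind = "V", chain = bp$chain,
               start = off + ex[1], end = off + ex[2], strand = strand,
               family = fam, unit = u,
               functionality = if (is.na(lesion)) "functional" else "pseudogene",
               lesion = lesion,
               germ_cdr3_nt = unit$germ_cdr3_nt,
               cys_start = off + cys[1],
               rss_start = off + rs[1], rss_end = off + rs[2],
               anchor_nt = NA_integer_, terminal_stop = tstop)
    }
    # --- D block (heavy) ---
    if (bp$d_per_unit[u] > 0L) {
      add(filler_dna(rand_gap(bp$block_gap)))
      for (k in seq_len(bp$d_per_unit[u])) {
        if (k > 1L) add(filler_dna(rand_gap(bp$d_gap)))
        d_id <- d_id + 1L
        core_len <- d_len_seq[d_id]
        unit <- make_d_unit(core_len, rc$D[1])
        off <- pos
        add(unit$seq)
        push_seg(id = sprintf("D%03d", d_id), kind = "D", chain = bp$chain,
                 start = off + unit$core_start, end = off + unit$core_end,
                 strand = "+", family = 1L, unit = u,
                 functionality = "functional", lesion = NA_character_,
                 germ_cdr3_nt = NA_integer_, cys_start = NA_integer_,
                 rss_start = NA_integer_, rss_end = NA_integer_,
                 anchor_nt = NA_integer_, terminal_stop = FALSE)
      }
    }
    # --- J block ---
    if (bp$j_per_unit[u] > 0L) {
      add(filler_dna(rand_gap(bp$block_gap)))
      for (k in seq_len(bp$j_per_unit[u])) {
        if (k > 1L) add(filler_dna(rand_gap(bp$j_gap)))
        j_id <- j_id + 1L
        jfam <- if (heavy) ((k - 1L) %% n_j_fam) + 1L else 1L
        long <- !heavy && u %in% bp$j_long_clusters
        coding <- if (long) j_coding_long else j_coding[jfam]
        unit <- make_j_unit(coding, rc$J)
        off <- pos
        add(unit$seq)
        anchor_codon <- if (long) j_anchor + 2L else j_anchor
        push_seg(id = sprintf("J%03d", j_id), kind = "J", chain = bp$chain,
                 start = off + unit$j_start, end = off + unit$j_end,
                 strand = "+", family = if (long) 2L else jfam, unit = u,
                 functionality = "functional", lesion = NA_character_,
                 germ_cdr3_nt = NA_integer_, cys_start = NA_integer_,
                 rss_start = NA_integer_, rss_end = NA_integer_,
                 anchor_nt = 3L * (anchor_codon - 1L) + 1L,
                 terminal_stop = FALSE)
      }
    }
    # --- C block ---
    if (bp$c_per_unit[u] > 0L) {
      add(filler_dna(rand_gap(bp$block_gap)))
      for (k in seq_len(bp$c_per_unit[u])) {
        if (k > 1L) add(filler_dna(rand_gap(bp$c_gap)))
        c_id <- c_id + 1L
        sub <- if (heavy) ((k - 1L) %% n_c_sub) + 1L else 1L
        cseq <- mutate_coding(c_ref[sub], 0.01)
        lesion <- NA_character_
        if (stats::runif(1) < bp$c_pseudogene_rate) {
          lesion <- "internal_stop"
          cod <- sample(10:(C_EXON_CODONS - 5L), 1L)
          substr(cseq, 3L * cod - 2L, 3L * cod) <- "TAA"
        }
        off <- pos
        add(cseq)
        push_seg(id = sprintf("C%03d", c_id), kind = "C", chain = bp$chain,
                 start = off + 1L, end = off + nchar(cseq),
                 strand = "+", family = sub, unit = u,
                 functionality = if (is.na(lesion)) "functional" else "pseudogene",
                 lesion = lesion,
                 germ_cdr3_nt = NA_integer_, cys_start = NA_integer_,
                 rss_start = NA_integer_, rss_end = NA_integer_,
                 anchor_nt = NA_integer_, terminal_stop = FALSE)
      }
    }
    unit_rows[[u]] <- data.frame(index = u,
                                 unit_type = if (heavy) "translocon" else "mini_cluster",
                                 stringsAsFactors = FALSE)
  }
  add(filler_dna(600L))

  genome <- paste(parts, collapse = "")
  segments <- do.call(rbind, seg)
  rownames(segments) <- NULL
  # units are delimited by their member gene segments (5'-most to 3'-most)
  units <- do.call(rbind, unit_rows)
  units$start <- as.integer(
    tapply(segments$start, segments$unit, min)[as.character(units$index)])
  units$end <- as.integer(
    tapply(segments$end, segments$unit, max)[as.character(units$index)])

  refs <- rbind(
    data.frame(name = sprintf("%s_V%d_ref", bp$chain, seq_len(n_fam)),
               kind = "V", chain = bp$chain, family = seq_len(n_fam),
               seq = fam_ref, cys = V_CYS_OFFSET, anchor = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(name = sprintf("%s_J%d_ref", bp$chain, seq_len(n_j_fam)),
               kind = "J", chain = bp$chain, family = seq_len(n_j_fam),
               seq = j_coding, cys = NA_integer_,
               anchor = 3L * (j_anchor - 1L) + 1L, stringsAsFactors = FALSE),
    data.frame(name = sprintf("%s_C%d_ref", bp$chain, seq_len(n_c_sub)),
               kind = "C", chain = bp$chain, family = seq_len(n_c_sub),
               seq = c_ref, cys = NA_integer_, anchor = NA_integer_,
               stringsAsFactors = FALSE)
  )
  if (length(bp$j_long_clusters)) {
    refs <- rbind(refs, data.frame(
      name = sprintf("%s_Jlong_ref", bp$chain), kind = "J", chain = bp$chain,
      family = 2L, seq = j_coding_long, cys = NA_integer_,
      anchor = 3L * (j_anchor + 1L) + 1L, stringsAsFactors = FALSE))
  }

  out <- list(genome = genome, genome_id = sprintf("sim_%s_locus", bp$chain),
              segments = segments, units = units,
              refs = refs, blueprint = bp)
  class(out) <- "ig_sim_locus"
  out
}

#' @export
print.ig_sim_locus <- function(x, ...) {
  tab <- table(x$segments$kind)
  cat(sprintf("simulated %s locus: %d nt, %d units; segments: %s; %d pseudogenes\n",
              x$blueprint$chain, nchar(x$genome), nrow(x$units),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              sum(x$segments$functionality == "pseudogene")))
  invisible(x)
}

#' Germline reference set from a simulated locus
#'
#' Extracts the planted segment sequences (strand-corrected) together with
#' the anchor bookkeeping (CYS codon position for V, [FW]GxG anchor offset
#' for J) used by the recombination simulator and the repertoire aligner.
#'
#' @param sim an \code{"ig_sim_locus"}.
#' @param functional_only keep functional segments only (default).
#' @return data.frame of class \code{"ig_germline"} with columns \code{name},
#'   \code{kind}, \code{chain}, \code{seq}, \code{family},
#'   \code{cys_start} (position of the 2nd-CYS codon within \code{seq}),
#'   \code{germ_cdr3_nt}, \code{anchor_nt}, \code{functional}.
#' @export
germline_set <- function(sim, functional_only = TRUE) {
  stopifnot(inherits(sim, "ig_sim_locus"))
  s <- sim$segments
  seqs <- substring(sim$genome, s$start, s$end)
  minus <- s$strand == "-"
  seqs[minus] <- vapply(seqs[minus], revcomp, character(1), USE.NAMES = FALSE)
  g <- data.frame(
    name = s$id, kind = s$kind, chain = s$chain, seq = seqs,
    family = s$family,
    cys_start = ifelse(s$kind == "V", s$end - s$start + 1L - s$germ_cdr3_nt - 2L,
                       NA_integer_),
    germ_cdr3_nt = s$germ_cdr3_nt,
    anchor_nt = s$anchor_nt,
    functional = s$functionality == "functional",
    stringsAsFactors = FALSE
  )
  if (functional_only) g <- g[g$functional, , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("ig_germline", "data.frame")
  g
}
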