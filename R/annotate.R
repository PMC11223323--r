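# Germline annotation: similarity seeding (BLAST+) to define candidate
# regions, then motif rules to fix boundaries and classify functionality:
# the 3' V RSS locates the recombination site, GT..AG splice signals locate
# the leader intron, octamer/TATA locate the promoter, paired 12-spacer RSS
# locate D cores, and a 5' RSS plus the [FW]GxG motif validate J genes.

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

run_blastn <- function(genome, genome_id, refs, evalue, task = "blastn") {
  if (!blast_available()) {
    stop("NCBI BLAST+ (makeblastdb/blastn) not found on PATH")
  }
  td <- tempfile("igloci_blast_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  db <- file.path(td, "genome.fa")
  qf <- file.path(td, "refs.fa")
  writeLines(c(paste0(">", genome_id), genome), db)
  writeLines(as.vector(rbind(paste0(">", refs$name), refs$seq)), qf)
  system2(Sys.which("makeblastdb"),
          c("-in", db, "-dbtype", "nucl"), stdout = FALSE, stderr = FALSE)
  out <- system2(Sys.which("blastn"),
                 c("-task", task, "-query", qf, "-db", db,
                   "-evalue", format(evalue, scientific = FALSE),
                   "-dust", "no", "-soft_masking", "false",
                   "-max_target_seqs", "100000",
                   "-outfmt", shQuote(paste("6 qseqid pident length mismatch",
                                            "gapopen qstart qend sstart send",
                                            "evalue bitscore"))),
                 stdout = TRUE, stderr = FALSE)
  cols <- c("qseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(out) == 0L) {
    hits <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols), stringsAsFactors = FALSE)
    hits[] <- lapply(hits, as.numeric)
    hits$qseqid <- character(0)
    return(hits)
  }
  hits <- utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE,
                            col.names = cols)
  hits$strand <- ifelse(hits$send >= hits$sstart, "+", "-")
  s1 <- pmin(hits$sstart, hits$send)
  s2 <- pmax(hits$sstart, hits$send)
  hits$gstart <- s1
  hits$gend <- s2
  hits
}

#' Seed gene candidates by two-tier similarity search
#'
#' A lenient e-value pass defines regions of interest; a strict pass defines
#' the candidates (the lenient threshold is retained for J genes because of
#' their short length). Overlapping hits to the same locus are merged,
#' keeping the highest-scoring hit (ties broken by leftmost start).
#'
#' @param genome nucleotide string.
#' @param genome_id sequence identifier.
#' @param refs reference segment set: data.frame with \code{name},
#'   \code{kind}, \code{chain}, \code{seq} (see
#'   \code{\link{read_germline_fasta}}).
#' @param kind \code{"V"}, \code{"J"} or \code{"C"}.
#' @param cfg an \code{\link{annotation_config}}.
#' @return data.frame of candidate regions: genomic \code{start}/\code{end},
#'   \code{strand}, best \code{ref_name}, \code{score}, \code{evalue},
#'   \code{pident}, \code{align_length}, reference coordinates
#'   \code{qstart}/\code{qend} and \code{ref_len}.
#' @export
seed_gene_candidates <- function(genome, refs, kind, cfg = annotation_config(),
                                 genome_id = "genome") {
  stopifnot(kind %in% c("V", "J", "C"))
  rk <- refs[refs$kind == kind, , drop = FALSE]
  if (nrow(rk) == 0L) stop("no reference segments of kind ", kind)
  empty <- data.frame(ref_name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), evalue = numeric(0),
                      pident = numeric(0), align_length = integer(0),
                      qstart = integer(0), qend = integer(0),
                      ref_len = integer(0), stringsAsFactors = FALSE)
  if (is.null(genome) || nchar(gsub("N", "", genome)) == 0L) return(empty)
  task <- if (kind == "J") "blastn-short" else "blastn"
  hits <- run_blastn(genome, genome_id, rk, cfg$e_value_loose, task)
  if (nrow(hits) == 0L) return(empty)
  strict_e <- if (kind == "J") cfg$e_value_j else cfg$e_value_strict
  strict <- hits[hits$evalue <= strict_e, , drop = FALSE]
  if (nrow(strict) == 0L) return(empty)
  # group strict hits into overlapping clusters
  strict <- strict[order(strict$gstart, strict$gend), , drop = FALSE]
  grp <- integer(nrow(strict))
  g <- 0L
  cur_end <- -Inf
  for (i in seq_len(nrow(strict))) {
    if (strict$gstart[i] > cur_end) {
      g <- g + 1L
      cur_end <- strict$gend[i]
    } else {
      cur_end <- max(cur_end, strict$gend[i])
    }
    grp[i] <- g
  }
  ref_len <- stats::setNames(nchar(rk$seq), rk$name)
  cands <- lapply(split(strict, grp), function(h) {
    best <- h[order(-h$bitscore, h$gstart), , drop = FALSE][1, ]
    data.frame(ref_name = best$qseqid,
               start = as.integer(best$gstart), end = as.integer(best$gend),
               strand = best$strand, score = best$bitscore,
               evalue = best$evalue, pident = best$pident,
               align_length = as.integer(best$length),
               qstart = as.integer(best$qstart), qend = as.integer(best$qend),
               ref_len = as.integer(ref_len[best$qseqid]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cands)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Global-local alignment of a reference (pattern, aligned in full) against a
# region; returns the subject position of every pattern position plus indel
# widths (for frameshift calls).
align_map <- function(ref, region) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(region),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 10, gapExtension = 4)
  pat <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sub <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  map <- integer(nchar(ref))
  pi <- 0L
  si <- Biostrings::start(Biostrings::subject(al)) - 1L
  widths <- integer(0)
  run <- 0L
  for (k in seq_along(pat)) {
    gap <- pat[k] == "-" || sub[k] == "-"
    if (gap) run <- run + 1L else if (run > 0L) {
      widths <- c(widths, run); run <- 0L
    }
    if (sub[k] != "-") si <- si + 1L
    if (pat[k] != "-") {
      pi <- pi + 1L
      map[pi] <- si
    }
  }
  if (run > 0L) widths <- c(widths, run)
  list(map = map, indel_widths = widths, score = Biostrings::score(al),
       subject_start = Biostrings::start(Biostrings::subject(al)))
}

# Extract an oriented region around a candidate; returns local<->plus strand
# coordinate converters.
oriented_region <- function(genome, start, end, strand, margin) {
  L <- nchar(genome)
  gs <- max(1L, start - margin)
  ge <- min(L, end + margin)
  region <- substr(genome, gs, ge)
  if (strand == "-") region <- revcomp(region)
  rlen <- ge - gs + 1L
  to_plus <- function(a, b) {
    if (strand == "+") c(gs + a - 1L, gs + b - 1L) else c(ge - b + 1L, ge - a + 1L)
  }
  list(seq = region, len = rlen, gs = gs, ge = ge, strand = strand,
       to_plus = to_plus)
}

#' Detect an octamer/TATA promoter in an upstream window
#'
#' Returns the highest-scoring octamer + TATA-box pair (octamer 5' of the
#' TATA on the coding strand, gap between 0 and
#' \code{cfg$promoter_max_gap} nt). Pairs are ranked by fewest total
#' mismatches, ties broken by smaller gap, then by the 3'-most pair. The
#' octamer is searched in both orientations; the TATA motif on the coding
#' strand only.
#'
#' @param upstream nucleotide window (coding-strand orientation, gene start at
#'   its 3' end).
#' @param cfg an \code{\link{annotation_config}}.
#' @return list with \code{octamer_start}, \code{tata_start} (1-based within
#'   the window), \code{octamer_seq}, \code{tata_seq}, \code{gap_nt},
#'   \code{mismatches}; or \code{NULL} when no pair passes the tolerances.
#' @export
detect_promoter <- function(upstream, cfg = annotation_config()) {
  tata_pos <- pattern_positions(cfg$tata_pattern)
  tlen <- length(tata_pos)
  if (is.null(upstream) || nchar(upstream) < 8L + tlen) return(NULL)
  x <- seq_chars(upstream)
  oct_f <- window_mismatch_profile(x, seq_chars(cfg$octamer_consensus))
  oct_r <- window_mismatch_profile(x, seq_chars(revcomp(cfg$octamer_consensus)))
  oct_mm <- pmin(oct_f, oct_r)
  oct_hits <- which(oct_mm <= cfg$octamer_tol)
  if (!length(oct_hits)) return(NULL)
  tata_mm <- window_class_mismatch_profile(x, tata_pos)
  tata_hits <- which(tata_mm <= cfg$tata_tol)
  if (!length(tata_hits)) return(NULL)
  best <- NULL
  for (o in oct_hits) {
    for (t in tata_hits) {
      gap <- t - (o + 8L)
      if (gap < 0L || gap > cfg$promoter_max_gap) next
      mm <- oct_mm[o] + tata_mm[t]
      key <- c(mm, gap, -t, -o)
      if (is.null(best) || lexico_less(key, best$key)) {
        best <- list(o = o, t = t, mm = mm, gap = gap, key = key)
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(octamer_start = best$o, tata_start = best$t,
       octamer_seq = substr(upstream, best$o, best$o + 7L),
       tata_seq = substr(upstream, best$t, best$t + tlen - 1L),
       gap_nt = best$gap, mismatches = best$mm)
}

lexico_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' Refine a V candidate into an annotated gene segment
#'
#' Maps the reference coding start and conserved 2nd-CYS codon onto the
#' genome through a global-local alignment, locates the 3' RSS (canonical
#' scan in a window downstream of the CYS codon, with optional
#' genome-specific profile rescue), the leader exon (nearest GT..AG intron
#' upstream of the coding start) and the promoter, then classifies
#' functionality. A stop codon within the final two codons before the
#' heptamer does not mark a pseudogene (such V genes can still produce
#' functional chains after junctional deletion of at least two nucleotides).
#'
#' @param candidate one row of \code{\link{seed_gene_candidates}} output.
#' @param genome nucleotide string.
#' @param refs reference segment set (provides the reference sequence and its
#'   CYS codon offset).
#' @param chain chain type (fixes the V RSS spacer class).
#' @param cfg an \code{\link{annotation_config}}.
#' @param profile optional \code{"rss_profile"} used to rescue non-canonical
#'   RSS.
#' @return one-row data.frame describing the segment (coordinates, strand,
#'   functionality and reasons, RSS and promoter features,
#'   \code{germ_cdr3_nt}).
#' @export
refine_v_segment <- function(candidate, genome, refs, chain,
                             cfg = annotation_config(), profile = NULL) {
  ref_row <- refs[refs$name == candidate$ref_name, ]
  ref <- ref_row$seq[1]
  cys <- ref_row$cys[1]
  if (is.na(cys)) stop("V reference lacks a CYS offset")
  spacer <- chain_rss_classes(chain)$V
  reg <- oriented_region(genome, candidate$start, candidate$end,
                         candidate$strand, cfg$refine_margin)
  prefix <- substr(ref, 1L, cys + 2L)
  am <- align_map(prefix, reg$seq)
  coding_start <- am$map[1]
  cys_end <- am$map[cys + 2L]
  frameshift <- any(am$indel_widths %% 3L != 0L)
  reasons <- character(0)
  if (frameshift) reasons <- c(reasons, "frameshift")

  # --- 3' RSS ---
  win_s <- cys_end + 1L
  win_e <- min(reg$len, cys_end + cfg$v_rss_search)
  window <- substr(reg$seq, win_s, win_e)
  rss <- scan_rss(window, spacer, cfg)
  rss <- rss[rss$strand == "+", , drop = FALSE]
  rss_row <- NULL
  rss_canonical <- NA
  if (nrow(rss) > 0L) {
    rss <- rss[order(rss$heptamer_mismatches + rss$nonamer_mismatches,
                     rss$start), , drop = FALSE]
    rss_row <- rss[1, ]
    rss_canonical <- TRUE
  } else if (!is.null(profile)) {
    hits <- profile_scan(window, profile)
    if (nrow(hits) > 0L) {
      h <- hits[1, ]
      rss_row <- data.frame(start = h$start, end = h$end, strand = "+",
                            heptamer_seq = substr(window, h$start, h$start + 6L),
                            nonamer_seq = substr(window, h$end - 8L, h$end),
                            spacer_len = (h$end - h$start + 1L) - 16L,
                            spacer_class = spacer,
                            heptamer_mismatches = NA_integer_,
                            nonamer_mismatches = NA_integer_,
                            stringsAsFactors = FALSE)
      rss_canonical <- FALSE
    }
  }
  ref_tail <- nchar(ref) - (cys + 2L)
  if (is.null(rss_row)) {
    reasons <- c(reasons, "missing_RSS")
    v_end <- min(reg$len, cys_end + ref_tail)
    rss_abs <- c(NA_integer_, NA_integer_)
    spacer_len <- NA_integer_
    hep_mm <- NA_integer_; non_mm <- NA_integer_
    hep_seq <- NA_character_; non_seq <- NA_character_
  } else {
    v_end <- win_s + rss_row$start - 1L - 1L
    rss_abs <- reg$to_plus(win_s + rss_row$start - 1L, win_s + rss_row$end - 1L)
    spacer_len <- rss_row$spacer_len
    hep_mm <- rss_row$heptamer_mismatches
    non_mm <- rss_row$nonamer_mismatches
    hep_seq <- rss_row$heptamer_seq
    non_seq <- rss_row$nonamer_seq
  }
  germ_cdr3 <- v_end - cys_end

  # --- internal stop codons (frame unreliable after a frameshift) ---
  if (!frameshift) {
    coding <- substr(reg$seq, coding_start, v_end)
    aa <- translate_nt(coding)
    stops <- which(seq_chars(aa) == "*")
    n_cod <- nchar(aa)
    if (any(stops <= n_cod - 2L)) reasons <- c(reasons, "internal_stop")
  }

  # --- leader exon: nearest GT..AG intron upstream of the coding start ---
  leader <- NULL
  acceptor_ok <- coding_start >= 3L &&
    substr(reg$seq, coding_start - 2L, coding_start - 1L) == "AG"
  if (acceptor_ok) {
    don <- NULL
    for (ilen in cfg$min_intron:cfg$max_intron) {
      p <- coding_start - ilen
      if (p < 1L) break
      if (substr(reg$seq, p, p + 1L) == "GT") { don <- p; break }
    }
    if (!is.null(don)) {
      le <- don - 1L
      atg <- NULL
      for (ls in (le - 2L):max(1L, le - cfg$max_leader + 1L)) {
        if (substr(reg$seq, ls, ls + 2L) == "ATG") atg <- ls
      }
      if (!is.null(atg)) leader <- c(atg, le)
    }
  }
  if (is.null(leader)) reasons <- c(reasons, "noncanonical_splice")

  # --- promoter upstream of the leader (or coding) start ---
  anchor <- if (!is.null(leader)) leader[1] else coding_start
  pw_s <- max(1L, anchor - cfg$promoter_window)
  prom <- if (anchor - 1L >= pw_s) {
    detect_promoter(substr(reg$seq, pw_s, anchor - 1L), cfg)
  } else NULL
  if (is.null(prom)) reasons <- c(reasons, "missing_promoter")

  seg_abs <- reg$to_plus(coding_start, v_end)
  leader_abs <- if (!is.null(leader)) reg$to_plus(leader[1], leader[2]) else c(NA_integer_, NA_integer_)
  cys_abs <- reg$to_plus(cys_end - 2L, cys_end)
  data.frame(
    kind = "V", chain = chain,
    start = seg_abs[1], end = seg_abs[2], strand = candidate$strand,
    functionality = if (length(reasons)) "pseudogene" else "functional",
    reasons = paste(reasons, collapse = ","),
    germ_cdr3_nt = germ_cdr3,
    cys_start = cys_abs[1],
    rss_start = rss_abs[1], rss_end = rss_abs[2],
    rss_spacer_class = if (is.null(rss_row)) NA_integer_ else spacer,
    rss_spacer_len = spacer_len,
    rss_canonical = rss_canonical,
    rss_heptamer = hep_seq, rss_nonamer = non_seq,
    rss_heptamer_mm = hep_mm, rss_nonamer_mm = non_mm,
    leader_start = leader_abs[1], leader_end = leader_abs[2],
    promoter_gap = if (is.null(prom)) NA_integer_ else prom$gap_nt,
    promoter_octamer = if (is.null(prom)) NA_character_ else prom$octamer_seq,
    promoter_tata = if (is.null(prom)) NA_character_ else prom$tata_seq,
    anchor_nt = NA_integer_,
    ref_name = candidate$ref_name, score = candidate$score,
    stringsAsFactors = FALSE
  )
}

#' Find D gene segments by paired proximal RSS
#'
#' D cores are flanked on both sides by inward-facing 12-spacer RSS: a
#' minus-strand RSS whose heptamer abuts the core 5' end and a plus-strand
#' RSS starting immediately after the core, with the core length inside the
#' configured range. Both RSS must be intact for a functional D; by default a
#' core with one degenerate RSS is not reported at all
#' (\code{cfg$d_single_rss_rescue} enables rescue as a pseudogene).
#'
#' @param genome nucleotide string (or a region of it).
#' @param cfg an \code{\link{annotation_config}}.
#' @param chain chain type (heavy only in practice).
#' @param exclude optional data.frame with \code{start}/\code{end} columns;
#'   cores overlapping these intervals are dropped.
#' @param offset added to reported coordinates (when scanning a region).
#' @return data.frame of D segments.
#' @export
find_d_segments <- function(genome, cfg = annotation_config(), chain = "IGH",
                            exclude = NULL, offset = 0L) {
  spacer <- chain_rss_classes(chain)$D[1]
  rss <- scan_rss(genome, spacer, cfg)
  minus <- rss[rss$strand == "-", , drop = FALSE]
  plus <- rss[rss$strand == "+", , drop = FALSE]
  rows <- list()
  if (nrow(minus) && nrow(plus)) {
    for (i in seq_len(nrow(minus))) {
      for (k in seq_len(nrow(plus))) {
        core_len <- plus$start[k] - minus$end[i] - 1L
        if (core_len < cfg$d_core_min || core_len > cfg$d_core_max) next
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "D", chain = chain,
          start = minus$end[i] + 1L + offset,
          end = plus$start[k] - 1L + offset,
          strand = "+", functionality = "functional", reasons = "",
          rss5_start = minus$start[i] + offset,
          rss3_end = plus$end[k] + offset,
          rss_spacer_class = spacer,
          mm = minus$heptamer_mismatches[i] + minus$nonamer_mismatches[i] +
            plus$heptamer_mismatches[k] + plus$nonamer_mismatches[k],
          slack = abs(minus$spacer_len[i] - spacer) +
            abs(plus$spacer_len[k] - spacer),
          stringsAsFactors = FALSE)
      }
    }
  }
  # the spacer slack lets one planted RSS pair match at shifted windows:
  # resolve overlapping cores, keeping the best-matching pair
  if (length(rows) > 1L) {
    cand <- do.call(rbind, rows)
    cand <- cand[order(cand$mm, cand$slack, cand$start), , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (!any(cand$start[i] <= cand$end[kept] &
                 cand$end[i] >= cand$start[kept])) {
        kept <- c(kept, i)
      }
    }
    rows <- lapply(kept, function(i) cand[i, , drop = FALSE])
  }
  rows <- lapply(rows, function(r) r[, setdiff(names(r), c("mm", "slack")),
                                     drop = FALSE])
  if (!length(rows)) {
    return(data.frame(kind = character(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), functionality = character(0),
                      reasons = character(0), rss5_start = integer(0),
                      rss3_end = integer(0), rss_spacer_class = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (!is.null(exclude) && nrow(exclude)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      !any(out$start[i] <= exclude$end & out$end[i] >= exclude$start)
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find J gene segments
#'
#' Similarity-seeded J candidates are validated by a 5' RSS of the
#' chain-appropriate spacer class (its heptamer abutting the J coding start
#' on the upstream side) and an in-frame [FW]GxG motif. Candidates without
#' the motif are discarded; candidates with a degenerate RSS are reported as
#' pseudogenes (intact RSS is required for J functionality).
#'
#' @inheritParams refine_v_segment
#' @return data.frame of J segments with the anchor position
#'   (\code{anchor_nt}, codon start of the F/W within the segment).
#' @export
find_j_segments <- function(genome, refs, chain, cfg = annotation_config(),
                            genome_id = "genome") {
  cands <- seed_gene_candidates(genome, refs, "J", cfg, genome_id)
  spacer <- chain_rss_classes(chain)$J
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    if (cand$align_length < 0.8 * cand$ref_len || cand$pident < 70) next
    ref <- refs$seq[refs$name == cand$ref_name][1]
    reg <- oriented_region(genome, cand$start, cand$end, cand$strand, 60L)
    am <- align_map(ref, reg$seq)
    j_start <- am$map[1]
    j_end <- am$map[nchar(ref)]
    jseq <- substr(reg$seq, j_start, j_end)
    aa <- translate_nt(jseq)
    m <- regexpr("[FW]G.G", aa)
    if (m < 0) next
    anchor_nt <- 3L * (as.integer(m) - 1L) + 1L
    reasons <- character(0)
    win_s <- max(1L, j_start - 7L - spacer - 9L - cfg$spacer_slack - 2L)
    window <- substr(reg$seq, win_s, j_start - 1L)
    rss <- scan_rss(window, spacer, cfg)
    rss <- rss[rss$strand == "-" & rss$end == nchar(window), , drop = FALSE]
    if (nrow(rss) == 0L) reasons <- c(reasons, "missing_RSS")
    if (grepl("*", aa, fixed = TRUE)) reasons <- c(reasons, "internal_stop")
    seg_abs <- reg$to_plus(j_start, j_end)
    rss_abs <- if (nrow(rss)) {
      reg$to_plus(win_s + rss$start[1] - 1L, win_s + rss$end[1] - 1L)
    } else c(NA_integer_, NA_integer_)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "J", chain = chain, start = seg_abs[1], end = seg_abs[2],
      strand = cand$strand,
      functionality = if (length(reasons)) "pseudogene" else "functional",
      reasons = paste(reasons, collapse = ","),
      anchor_nt = anchor_nt,
      rss_start = rss_abs[1], rss_end = rss_abs[2],
      rss_spacer_class = if (nrow(rss)) spacer else NA_integer_,
      rss_spacer_len = if (nrow(rss)) rss$spacer_len[1] else NA_integer_,
      ref_name = cand$ref_name, score = cand$score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(kind = character(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), functionality = character(0),
                      reasons = character(0), anchor_nt = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find first constant exons
#'
#' C genes are located by similarity seeding of the first constant exon only;
#' functionality requires the detected exon to be free of internal stops and
#' frameshifts.
#'
#' @inheritParams refine_v_segment
#' @return data.frame of C segments.
#' @export
find_c_segments <- function(genome, refs, chain, cfg = annotation_config(),
                            genome_id = "genome") {
  cands <- seed_gene_candidates(genome, refs, "C", cfg, genome_id)
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    if (cand$align_length < 0.5 * cand$ref_len) next
    ref <- refs$seq[refs$name == cand$ref_name][1]
    reg <- oriented_region(genome, cand$start, cand$end, cand$strand, 60L)
    am <- align_map(ref, reg$seq)
    c_start <- am$map[1]
    c_end <- am$map[nchar(ref)]
    reasons <- character(0)
    if (any(am$indel_widths %% 3L != 0L)) {
      reasons <- c(reasons, "frameshift")
    } else if (has_internal_stop(substr(reg$seq, c_start, c_end))) {
      reasons <- c(reasons, "internal_stop")
    }
    seg_abs <- reg$to_plus(c_start, c_end)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "C", chain = chain, start = seg_abs[1], end = seg_abs[2],
      strand = cand$strand,
      functionality = if (length(reasons)) "pseudogene" else "functional",
      reasons = paste(reasons, collapse = ","),
      ref_name = cand$ref_name, score = cand$score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(kind = character(0), chain = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), functionality = character(0),
                      reasons = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer locus organization
#'
#' Greedy left-to-right grouping of coordinate-sorted segments: a new unit
#' starts whenever the segment kind order (V, D, J, C) resets or the gap to
#' the previous segment exceeds \code{cfg$cluster_gap}. Units containing D
#' genes or more than one segment of a kind are translocons; units with at
#' most one V, J and C are mini-clusters (a V in the opposite orientation to
#' its J and C, as in kappa loci, is tolerated).
#'
#' @param segments data.frame with \code{kind}, \code{start}, \code{end},
#'   sorted or not (sorted internally).
#' @param cfg an \code{\link{annotation_config}}.
#' @return list with \code{segments} (input plus a \code{unit} column) and
#'   \code{units} (index, unit_type, span).
#' @export
infer_organization <- function(segments, cfg = annotation_config()) {
  if (nrow(segments) == 0L) {
    return(list(segments = segments,
                units = data.frame(index = integer(0), unit_type = character(0),
                                   start = integer(0), end = integer(0))))
  }
  s <- segments[order(segments$start), , drop = FALSE]
  rank <- c(V = 1L, D = 2L, J = 3L, C = 4L)[s$kind]
  unit <- integer(nrow(s))
  u <- 1L
  for (i in seq_len(nrow(s))) {
    if (i > 1L) {
      gap <- s$start[i] - s$end[i - 1L] - 1L
      if (rank[i] < rank[i - 1L] || gap > cfg$cluster_gap) u <- u + 1L
    }
    unit[i] <- u
  }
  s$unit <- unit
  units <- do.call(rbind, lapply(split(seq_len(nrow(s)), unit), function(ix) {
    k <- table(factor(s$kind[ix], levels = c("V", "D", "J", "C")))
    type <- if (k["D"] > 0L || any(k[c("V", "J", "C")] > 1L)) {
      "translocon"
    } else {
      "mini_cluster"
    }
    data.frame(index = s$unit[ix[1]], unit_type = type,
               start = min(s$start[ix]), end = max(s$end[ix]),
               n_segments = length(ix), stringsAsFactors = FALSE)
  }))
  units <- units[order(units$index), , drop = FALSE]
  rownames(units) <- NULL
  list(segments = s, units = units)
}

#' Distances between locus units
#'
#' @param units data.frame from \code{\link{infer_organization}} (or any
#'   table with \code{start}/\code{end} sorted by position).
#' @return list with \code{mean}, \code{min}, \code{max} (nt between the end
#'   of one unit and the start of the next) and the vector of
#'   \code{distances}; empty list when fewer than two units.
#' @export
intercluster_distances <- function(units) {
  if (is.null(units) || nrow(units) < 2L) return(list())
  u <- units[order(units$start), , drop = FALSE]
  d <- u$start[-1L] - u$end[-nrow(u)] - 1L
  list(mean = mean(d), min = min(d), max = max(d), distances = d)
}

#' Assign nomenclature
#'
#' Heavy V genes are named \code{IGHV<family>-<translocon>-<n>} where
#' \code{n} numbers the genes of a family by genomic position; D, J and C
#' genes are numbered within kind (J genes per family). Light-chain V, J and
#' C genes of one mini-cluster share the cluster ordinal
#' (\code{IGIV/IGIJ/IGIC<subgroup>-<cluster>}); a cluster missing its J or C
#' simply skips that number. A second copy of a kind within one cluster
#' receives a letter suffix. All names carry the \code{*01} allele suffix and
#' are checked for uniqueness.
#'
#' @param segments segment table with \code{kind}, \code{family} and
#'   \code{unit} columns.
#' @param units unit table from \code{\link{infer_organization}}.
#' @param chain chain type.
#' @return \code{segments} with a \code{name} column.
#' @export
assign_nomenclature <- function(segments, units, chain) {
  if (nrow(segments) == 0L) return(segments)
  if (any(is.na(segments$family) & segments$kind == "V")) {
    stop("V segments must carry family labels before naming")
  }
  s <- segments[order(segments$start), , drop = FALSE]
  name <- character(nrow(s))
  if (chain == "IGH") {
    for (kind in c("V", "D", "J", "C")) {
      ix <- which(s$kind == kind)
      if (!length(ix)) next
      if (kind == "V") {
        for (f in sort(unique(s$family[ix]))) {
          fx <- ix[s$family[ix] == f]
          name[fx] <- sprintf("IGHV%d-%d-%d", f, s$unit[fx], seq_along(fx))
        }
      } else if (kind == "J") {
        for (f in sort(unique(s$family[ix]))) {
          fx <- ix[s$family[ix] == f]
          name[fx] <- sprintf("IGHJ%d-%d", f, seq_along(fx))
        }
      } else {
        name[ix] <- sprintf("IGH%s%d", kind, seq_along(ix))
      }
    }
  } else {
    sub <- c(IGI1_kappa = 1L, IGI2_sigma = 2L, IGI4_lambda2 = 4L)[chain]
    for (kind in c("V", "J", "C")) {
      ix <- which(s$kind == kind)
      if (!length(ix)) next
      base <- sprintf("IGI%s%d-%d", kind, sub, s$unit[ix])
      # duplicated kind within one cluster: letter suffix on later copies
      dup <- stats::ave(seq_along(ix), s$unit[ix], FUN = seq_along)
      suff <- ifelse(dup > 1L, letters[dup], "")
      name[ix] <- paste0(base, suff)
    }
  }
  name <- paste0(name, "*01")
  if (anyDuplicated(name)) stop("nomenclature produced duplicate names")
  s$name <- name
  s
}
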