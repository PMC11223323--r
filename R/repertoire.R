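# Repertoire assembly: 5'RACE paired reads to productive, abundance-filtered
# CDR3 clonotypes. Read 1 (C side) sequences the junction; read 2 (V 5' end)
# carries the V identity. Clonotypes are collapsed on the CDR3 nucleotide
# sequence, C-gene assignment is not attempted (C genes are too similar to
# distinguish), and clonotypes with fewer than 5 reads are discarded.

phred_to_int <- function(qual) {
  if (is.numeric(qual)) return(as.integer(qual))
  utf8ToInt(qual) - 33L
}

#' Sliding-window quality trimming
#'
#' Scans 5' to 3' and cuts the read at the first window whose mean quality
#' drops below \code{min_q} (the read keeps everything before that window).
#' Reads shorter than the window are kept only if their overall mean quality
#' passes.
#'
#' @param seq read sequence.
#' @param qual per-base qualities: integer vector or phred+33 string.
#' @param min_q minimum mean window quality (default 20).
#' @param window window length (default 4).
#' @return list with trimmed \code{seq} and integer \code{qual} (possibly
#'   empty).
#' @export
sliding_window_trim <- function(seq, qual, min_q = 20, window = 4L) {
  stopifnot(window >= 1L)
  q <- phred_to_int(qual)
  L <- length(q)
  stopifnot(nchar(seq) == L)
  if (L == 0L) return(list(seq = "", qual = integer(0)))
  if (L < window) {
    if (mean(q) < min_q) return(list(seq = "", qual = integer(0)))
    return(list(seq = seq, qual = q))
  }
  cs <- cumsum(c(0, q))
  means <- (cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]) / window
  bad <- which(means < min_q)
  if (!length(bad)) return(list(seq = seq, qual = q))
  cut <- bad[1] - 1L
  list(seq = substr(seq, 1L, cut), qual = q[seq_len(cut)])
}

# Batch local alignment of reads against one germline set; returns the best
# call per read under the thresholds (NA when no germline qualifies).
germline_call_batch <- function(seqs, germ_rows, min_span,
                                min_identity = 0.6) {
  n <- length(seqs)
  best <- data.frame(name = rep(NA_character_, n), score = -Inf,
                     identity = NA_real_, read_start = NA_integer_,
                     read_end = NA_integer_, germ_start = NA_integer_,
                     germ_end = NA_integer_, stringsAsFactors = FALSE)
  if (n == 0L || nrow(germ_rows) == 0L) return(best)
  # fast path: a read that is an exact substring of a germline already has
  # the maximal local score; ties resolved by lexicographically smaller name
  todo <- rep(TRUE, n)
  for (i in which(nchar(seqs) >= min_span)) {
    hit <- which(vapply(germ_rows$seq, function(g) {
      grepl(seqs[i], g, fixed = TRUE)
    }, logical(1), USE.NAMES = FALSE))
    if (length(hit)) {
      g <- hit[order(germ_rows$name[hit])][1]
      pos <- regexpr(seqs[i], germ_rows$seq[g], fixed = TRUE)
      best$name[i] <- germ_rows$name[g]
      best$score[i] <- 2 * nchar(seqs[i])
      best$identity[i] <- 1
      best$read_start[i] <- 1L
      best$read_end[i] <- nchar(seqs[i])
      best$germ_start[i] <- as.integer(pos)
      best$germ_end[i] <- as.integer(pos) + nchar(seqs[i]) - 1L
      todo[i] <- FALSE
    }
  }
  if (!any(todo)) return(best)
  sub_ix <- which(todo)
  pats <- Biostrings::DNAStringSet(seqs[sub_ix])
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  ord <- order(germ_rows$name)
  for (g in ord) {
    al <- Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(germ_rows$seq[g]), type = "local",
      substitutionMatrix = submat, gapOpening = 6, gapExtension = 2)
    sc <- Biostrings::score(al)
    idf <- Biostrings::pid(al, type = "PID1") / 100
    span <- Biostrings::width(Biostrings::pattern(al))
    cur_sc <- best$score[sub_ix]
    cur_id <- best$identity[sub_ix]
    ok <- span >= min_span & idf >= min_identity
    upd <- ok & (sc > cur_sc + 1e-9 |
                   (abs(sc - cur_sc) <= 1e-9 &
                      (is.na(cur_id) | idf > cur_id + 1e-12)))
    # lexicographic name tie-break: germlines visited in name order, so an
    # exact tie never replaces an earlier (smaller) name
    if (any(upd)) {
      gi <- sub_ix[upd]
      best$name[gi] <- germ_rows$name[g]
      best$score[gi] <- sc[upd]
      best$identity[gi] <- idf[upd]
      best$read_start[gi] <- Biostrings::start(Biostrings::pattern(al))[upd]
      best$read_end[gi] <- Biostrings::end(Biostrings::pattern(al))[upd]
      best$germ_start[gi] <- Biostrings::start(Biostrings::subject(al))[upd]
      best$germ_end[gi] <- Biostrings::end(Biostrings::subject(al))[upd]
    }
  }
  best
}

#' Assign the best-matching germline segment to a sequence
#'
#' Best-scoring local alignment against the germline set of the requested
#' kind, with ties broken by higher identity, then lexicographically smaller
#' name; calls below the identity/span thresholds return no call.
#'
#' @param seq nucleotide string (sense orientation).
#' @param germ an \code{"ig_germline"} set.
#' @param kind \code{"V"} or \code{"J"}.
#' @param cfg an \code{\link{annotation_config}} (thresholds).
#' @return list with \code{name} (NA when no call), \code{score},
#'   \code{identity} and the aligned spans on read and germline.
#' @export
assign_germline <- function(seq, germ, kind = c("V", "J"),
                            cfg = annotation_config()) {
  kind <- match.arg(kind)
  rows <- germ[germ$kind == kind, , drop = FALSE]
  if (nrow(rows) == 0L) stop("germline set has no segments of kind ", kind)
  min_span <- if (kind == "V") cfg$min_v_span else cfg$min_j_span
  b <- germline_call_batch(seq, rows, min_span, cfg$min_score_identity)
  as.list(b[1, ])
}

# walk aligned strings to map a subject position onto the pattern
walk_map <- function(pat_str, sub_str, pstart, sstart, spos) {
  pat <- seq_chars(pat_str)
  sub <- seq_chars(sub_str)
  pi <- pstart - 1L
  si <- sstart - 1L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") pi <- pi + 1L
    if (sub[k] != "-") {
      si <- si + 1L
      if (si == spos) return(if (pat[k] == "-") NA_integer_ else pi)
    }
  }
  NA_integer_
}

# map a subject (germline) position to the pattern (read) position through a
# single local alignment; NA when not covered
map_subject_position <- function(al, spos) {
  walk_map(as.character(Biostrings::alignedPattern(al)),
           as.character(Biostrings::alignedSubject(al)),
           Biostrings::start(Biostrings::pattern(al)),
           Biostrings::start(Biostrings::subject(al)), spos)
}

# locate the CYS codon start in a sense read given the V germline row and
# the J anchor end position (exact probe match first, alignment fallback)
locate_cys <- function(seq, v_row, anchor_end) {
  cys <- v_row$cys_start
  probe_s <- max(1L, cys - 12L)
  probe <- substr(v_row$seq, probe_s, cys + 2L)
  off <- cys - probe_s
  hits <- gregexpr(probe, seq, fixed = TRUE)[[1]]
  if (hits[1] != -1L) {
    starts <- as.integer(hits) + off
    starts <- starts[starts + 2L < anchor_end]
    if (length(starts)) return(max(starts))
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  pal <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(probe), Biostrings::DNAString(seq),
    type = "global-local", substitutionMatrix = submat,
    gapOpening = 6, gapExtension = 2)
  am <- align_map(probe, seq)
  cand <- am$map[off + 1L]
  if (!is.na(cand) && cand > 0L && cand + 2L < anchor_end &&
      Biostrings::pid(pal, type = "PID1") >= 75) {
    return(cand)
  }
  NA_integer_
}

#' Extract the CDR3 junction from a read
#'
#' The CDR3 spans from the conserved 2nd-CYS codon of the V (inclusive) to
#' the J [FW]GxG anchor codon (inclusive of the F/W). The CYS position is
#' located with a short germline probe ending at the CYS codon; the J anchor
#' is transferred from the germline annotation through the read-to-J
#' alignment.
#'
#' @param seq read sequence in sense (mRNA) orientation covering the
#'   junction.
#' @param v_row,j_row single rows of an \code{"ig_germline"} set (the V and J
#'   calls).
#' @return the junction nucleotide string, or \code{NA} when an anchor is
#'   not locatable.
#' @export
extract_cdr3 <- function(seq, v_row, j_row) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  jal <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq), Biostrings::DNAString(j_row$seq),
    type = "local", substitutionMatrix = submat,
    gapOpening = 6, gapExtension = 2)
  anchor_end <- map_subject_position(jal, j_row$anchor_nt + 2L)
  if (is.na(anchor_end)) return(NA_character_)
  cys_pos <- locate_cys(seq, v_row, anchor_end)
  if (is.na(cys_pos) || anchor_end <= cys_pos) return(NA_character_)
  substr(seq, cys_pos, anchor_end)
}

#' Is a junction productive?
#'
#' Productive junctions are a multiple of three in the V reading frame (the
#' junction starts at the CYS codon, so frame 0) and translate without stop
#' codons.
#'
#' @param cdr3_nt junction nucleotide string.
#' @return logical.
#' @export
is_productive <- function(cdr3_nt) {
  if (is.na(cdr3_nt) || nchar(cdr3_nt) == 0L) return(FALSE)
  nchar(cdr3_nt) %% 3L == 0L && !has_internal_stop(cdr3_nt)
}

#' Assemble clonotypes from paired 5'RACE reads
#'
#' The full read-to-clonotype pipeline: sliding-window quality trimming,
#' orientation (read 1 sequences the junction 3'-5' and is
#' reverse-complemented), duplicate-read collapapsing, germline V/J calls
#' (V from read 2 when present, mirroring the forward/reverse read roles of
#' the protocol), CDR3 extraction, collapse by exact CDR3 nucleotide
#' sequence with majority V/J voting, productive-only filtering and the
#' minimum read-count filter (clonotypes with fewer than \code{min_reads}
#' assigned reads are discarded; exactly \code{min_reads} is kept).
#'
#' @param read1 data.frame with \code{id}, \code{seq}, \code{qual} (C-side
#'   read).
#' @param read2 optional matching data.frame (V-side read).
#' @param germ an \code{"ig_germline"} set for the chain.
#' @param sample_id sample identifier recorded per clonotype.
#' @param min_reads minimum assigned reads per clonotype (default 5).
#' @param cfg an \code{\link{annotation_config}} (aligner thresholds).
#' @param productive_only keep productive clonotypes only (default TRUE).
#' @return AIRR-style data.frame: \code{sequence_id}, \code{v_call},
#'   \code{j_call}, \code{junction}, \code{junction_aa}, \code{productive},
#'   \code{duplicate_count}, \code{sample_id}; attribute \code{"log"} counts
#'   reads lost at each stage.
#' @export
assemble_clonotypes <- function(read1, read2 = NULL, germ,
                                sample_id = "sample", min_reads = 5L,
                                cfg = annotation_config(),
                                productive_only = TRUE) {
  n_in <- nrow(read1)
  sense1 <- revcomp_many(vapply(seq_len(n_in), function(i) {
    sliding_window_trim(read1$seq[i], read1$qual[i])$seq
  }, character(1)))
  if (!is.null(read2)) {
    stopifnot(nrow(read2) == n_in)
    sense2 <- vapply(seq_len(n_in), function(i) {
      sliding_window_trim(read2$seq[i], read2$qual[i])$seq
    }, character(1))
  } else {
    sense2 <- rep("", n_in)
  }
  ok_len <- nchar(sense1) >= 30L
  sense1 <- sense1[ok_len]; sense2 <- sense2[ok_len]

  key <- paste(sense1, sense2, sep = "|")
  grp <- match(key, unique(key))
  counts <- tabulate(grp)
  first <- match(seq_along(counts), grp)
  u1 <- sense1[first]
  u2 <- sense2[first]

  vrows <- germ[germ$kind == "V", , drop = FALSE]
  jrows <- germ[germ$kind == "J", , drop = FALSE]
  v_src <- if (!is.null(read2)) u2 else u1
  vcall <- germline_call_batch(v_src, vrows, cfg$min_v_span,
                               cfg$min_score_identity)
  jcall <- germline_call_batch(u1, jrows, cfg$min_j_span,
                               cfg$min_score_identity)

  n_u <- length(u1)
  junction <- rep(NA_character_, n_u)
  ok_ix <- which(!is.na(vcall$name) & !is.na(jcall$name))
  jmap <- split(jrows, jrows$name)
  vmap <- split(vrows, vrows$name)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  for (i in ok_ix) {
    jr <- jmap[[jcall$name[i]]][1, ]
    # fast path: the post-anchor J tail is not touched by junctional
    # trimming, so an error-free read carries it verbatim
    tail_probe <- substring(jr$seq, jr$anchor_nt + 3L)
    anchor_end <- NA_integer_
    if (nchar(tail_probe) >= 6L) {
      pos <- regexpr(tail_probe, u1[i], fixed = TRUE)
      if (pos > 0L) anchor_end <- as.integer(pos) - 1L
    }
    if (is.na(anchor_end)) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(u1[i]), Biostrings::DNAString(jr$seq),
        type = "local", substitutionMatrix = submat,
        gapOpening = 6, gapExtension = 2)
      anchor_end <- map_subject_position(al, jr$anchor_nt + 2L)
    }
    if (is.na(anchor_end) || anchor_end < 4L) next
    vr <- vmap[[vcall$name[i]]][1, ]
    cys_pos <- locate_cys(u1[i], vr, anchor_end)
    if (is.na(cys_pos) || anchor_end <= cys_pos) next
    junction[i] <- substr(u1[i], cys_pos, anchor_end)
  }

  keep <- !is.na(junction)
  log <- c(input_reads = n_in, trimmed_out = n_in - sum(ok_len),
           unique_sequences = n_u,
           no_call = sum(is.na(vcall$name) | is.na(jcall$name)),
           no_junction = sum(!keep) -
             sum(is.na(vcall$name) | is.na(jcall$name)))
  if (!any(keep)) {
    out <- data.frame(sequence_id = character(0), v_call = character(0),
                      j_call = character(0), junction = character(0),
                      junction_aa = character(0), productive = logical(0),
                      duplicate_count = integer(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "log") <- log
    return(out)
  }
  jx <- junction[keep]
  cn <- counts[keep]
  vq <- vcall[keep, ]; jq <- jcall[keep, ]

  majority_call <- function(names, weights, scores) {
    w <- tapply(weights, names, sum)
    s <- tapply(scores * weights, names, sum)
    ord <- order(-as.vector(w), -as.vector(s), names(w))
    names(w)[ord[1]]
  }
  ujx <- unique(jx)
  rows <- lapply(seq_along(ujx), function(q) {
    ix <- which(jx == ujx[q])
    data.frame(
      v_call = majority_call(vq$name[ix], cn[ix], vq$score[ix]),
      j_call = majority_call(jq$name[ix], cn[ix], jq$score[ix]),
      junction = ujx[q],
      duplicate_count = sum(cn[ix]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$junction_aa <- vapply(out$junction, translate_nt, character(1),
                            USE.NAMES = FALSE)
  out$productive <- vapply(out$junction, is_productive, logical(1),
                           USE.NAMES = FALSE)
  if (productive_only) out <- out[out$productive, , drop = FALSE]
  out <- out[out$duplicate_count >= min_reads, , drop = FALSE]
  out <- out[order(-out$duplicate_count, out$junction), , drop = FALSE]
  if (nrow(out)) {
    out$sequence_id <- sprintf("%s_clonotype%04d", sample_id,
                               seq_len(nrow(out)))
  } else {
    out$sequence_id <- character(0)
  }
  out$sample_id <- sample_id
  out <- out[, c("sequence_id", "v_call", "j_call", "junction", "junction_aa",
                 "productive", "duplicate_count", "sample_id"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- log
  out
}
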