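ANN_COLUMNS <- c("kind", "chain", "start", "end", "strand", "functionality",
                 "reasons", "family", "unit", "germ_cdr3_nt", "cys_start",
                 "anchor_nt", "rss_start", "rss_end", "rss_spacer_class",
                 "rss_spacer_len", "rss_canonical", "rss_heptamer",
                 "rss_nonamer", "rss_heptamer_mm", "rss_nonamer_mm",
                 "rss5_start", "rss3_end", "leader_start", "leader_end",
                 "promoter_gap", "promoter_octamer", "promoter_tata",
                 "ref_name", "score", "name")

normalize_segment_df <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(NULL)
  for (col in setdiff(ANN_COLUMNS, names(df))) df[[col]] <- NA
  df[, ANN_COLUMNS, drop = FALSE]
}

segment_sequences <- function(segments, genome) {
  if (nrow(segments) == 0L) return(character(0))
  seqs <- substring(genome, segments$start, segments$end)
  minus <- segments$strand == "-"
  seqs[minus] <- vapply(seqs[minus], revcomp, character(1), USE.NAMES = FALSE)
  seqs
}

#' Annotate an immunoglobulin locus
#'
#' Full annotation of one chain on one genomic sequence: two-tier similarity
#' seeding of V, J and C candidates, motif-rule refinement (RSS, promoter,
#' splice sites) and functionality classification, RSS-profile rescue of V
#' genes lacking a canonical RSS, D detection by paired proximal 12-spacer
#' RSS (heavy chains), organization inference, V-family clustering at the
#' 80\% identity threshold and nomenclature assignment.
#'
#' @param genome nucleotide string.
#' @param refs reference segment set (data.frame with \code{name},
#'   \code{kind}, \code{chain}, \code{seq}, \code{cys}, \code{anchor}).
#' @param chain chain type.
#' @param cfg an \code{\link{annotation_config}}.
#' @param genome_id sequence identifier used in output.
#' @param family_threshold identity threshold separating V families.
#' @return object of class \code{"ig_annotation"}: \code{segments} (one row
#'   per gene segment with coordinates, strand, functionality and reasons,
#'   RSS/promoter/leader features, family, unit and name), \code{units},
#'   \code{chain}, \code{genome_id}, \code{genome_length}, \code{config}.
#' @export
annotate_locus <- function(genome, refs, chain, cfg = annotation_config(),
                           genome_id = "genome", family_threshold = 0.8) {
  stopifnot(chain %in% ig_chains)
  genome <- toupper(genome)
  refs <- refs[refs$chain == chain, , drop = FALSE]

  v_cands <- seed_gene_candidates(genome, refs, "V", cfg, genome_id)
  v_rows <- lapply(seq_len(nrow(v_cands)), function(i) {
    refine_v_segment(v_cands[i, ], genome, refs, chain, cfg)
  })
  v_seg <- if (length(v_rows)) do.call(rbind, v_rows) else NULL

  # genome-specific RSS rescue: profile from canonical-RSS V genes, applied
  # to V candidates whose canonical scan failed
  if (!is.null(v_seg) && any(grepl("missing_RSS", v_seg$reasons))) {
    nominal <- chain_rss_classes(chain)$V
    canon <- which(!is.na(v_seg$rss_canonical) & v_seg$rss_canonical &
                     v_seg$rss_spacer_len == nominal)
    if (length(canon)) {
      win <- segment_sequences(
        data.frame(start = v_seg$rss_start[canon], end = v_seg$rss_end[canon],
                   strand = v_seg$strand[canon]), genome)
      prof <- derive_rss_profile(win, nominal, cfg)
      redo <- which(grepl("missing_RSS", v_seg$reasons))
      for (i in redo) {
        v_seg[i, ] <- refine_v_segment(v_cands[i, ], genome, refs, chain,
                                       cfg, profile = prof)
      }
    }
  }

  j_seg <- find_j_segments(genome, refs, chain, cfg, genome_id)
  c_seg <- find_c_segments(genome, refs, chain, cfg, genome_id)

  d_seg <- NULL
  if (chain == "IGH") {
    known <- rbind(
      if (!is.null(v_seg)) data.frame(start = v_seg$start - 50L,
                                      end = pmax(v_seg$end, v_seg$rss_end,
                                                 na.rm = TRUE) + 10L),
      if (nrow(j_seg)) data.frame(start = j_seg$start - 50L,
                                  end = j_seg$end + 10L),
      if (nrow(c_seg)) data.frame(start = c_seg$start - 10L,
                                  end = c_seg$end + 10L)
    )
    d_seg <- find_d_segments(genome, cfg, chain, exclude = known)
  }

  segments <- do.call(rbind, Filter(Negate(is.null), list(
    normalize_segment_df(v_seg), normalize_segment_df(d_seg),
    normalize_segment_df(j_seg), normalize_segment_df(c_seg))))
  if (is.null(segments) || nrow(segments) == 0L) {
    segments <- normalize_segment_df(
      data.frame(kind = character(0), stringsAsFactors = FALSE))
    out <- list(segments = segments, units = data.frame(), chain = chain,
                genome_id = genome_id, genome_length = nchar(genome),
                config = cfg)
    class(out) <- "ig_annotation"
    return(out)
  }

  org <- infer_organization(segments, cfg)
  segments <- org$segments

  # V families: single-linkage clusters at the identity threshold
  vix <- which(segments$kind == "V")
  if (length(vix) > 1L) {
    vseqs <- segment_sequences(segments[vix, ], genome)
    fam <- cluster_families(identity_matrix(vseqs), family_threshold,
                            coords = segments$start[vix])
    segments$family[vix] <- fam$family
  } else if (length(vix) == 1L) {
    segments$family[vix] <- 1L
  }
  jix <- which(segments$kind == "J")
  if (length(jix) > 1L) {
    jseqs <- segment_sequences(segments[jix, ], genome)
    fam <- cluster_families(identity_matrix(jseqs), family_threshold,
                            coords = segments$start[jix])
    segments$family[jix] <- fam$family
  } else if (length(jix) == 1L) {
    segments$family[jix] <- 1L
  }
  cix <- which(segments$kind == "C")
  segments$family[cix] <- 1L
  dix <- which(segments$kind == "D")
  segments$family[dix] <- 1L

  segments <- assign_nomenclature(segments, org$units, chain)
  rownames(segments) <- NULL
  out <- list(segments = segments, units = org$units, chain = chain,
              genome_id = genome_id, genome_length = nchar(genome),
              config = cfg)
  class(out) <- "ig_annotation"
  out
}

#' @export
print.ig_annotation <- function(x, ...) {
  tab <- table(factor(x$segments$kind, levels = c("V", "D", "J", "C")))
  ps <- table(factor(x$segments$kind[x$segments$functionality == "pseudogene"],
                     levels = c("V", "D", "J", "C")))
  cat(sprintf("ig_annotation: %s on %s (%d nt)\n", x$chain, x$genome_id,
              x$genome_length))
  cat(sprintf("  segments: %s\n",
              paste(sprintf("%s %d (%d pseudo)", names(tab), tab, ps),
                    collapse = ", ")))
  if (nrow(x$units)) {
    cat(sprintf("  organization: %s\n",
                paste(sprintf("%d %s", table(x$units$unit_type),
                              names(table(x$units$unit_type))),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.ig_annotation <- function(object, ...) {
  s <- object$segments
  out <- list(
    chain = object$chain,
    counts = table(factor(s$kind, levels = c("V", "D", "J", "C"))),
    pseudogenes = table(factor(s$kind[s$functionality == "pseudogene"],
                               levels = c("V", "D", "J", "C"))),
    families = if (any(s$kind == "V")) table(s$family[s$kind == "V"]) else NULL,
    units = object$units,
    distances = intercluster_distances(object$units)
  )
  class(out) <- "summary.ig_annotation"
  out
}

#' @export
print.summary.ig_annotation <- function(x, ...) {
  cat(sprintf("%s locus summary\n", x$chain))
  cat("  segment counts (pseudogenes):",
      paste(sprintf("%s %d (%d)", names(x$counts), x$counts, x$pseudogenes),
            collapse = ", "), "\n")
  if (!is.null(x$families)) {
    cat("  V families:", paste(sprintf("%s: %d", names(x$families), x$families),
                               collapse = ", "), "\n")
  }
  if (length(x$distances)) {
    cat(sprintf("  inter-unit distance: mean %.0f nt (range %d-%d)\n",
                x$distances$mean, min(x$distances$distances),
                max(x$distances$distances)))
  }
  invisible(x)
}

#' @export
as.data.frame.ig_annotation <- function(x, ...) x$segments

#' Germline reference set from an annotation
#'
#' Extracts strand-corrected segment sequences and anchor positions from an
#' annotated locus for use by the repertoire aligner and the recombination
#' simulator.
#'
#' @param ann an \code{"ig_annotation"}.
#' @param genome the annotated genomic sequence.
#' @param functional_only keep functional segments only (default).
#' @return an \code{"ig_germline"} data.frame (see \code{\link{germline_set}}).
#' @export
germline_set_from_annotation <- function(ann, genome, functional_only = TRUE) {
  stopifnot(inherits(ann, "ig_annotation"))
  s <- ann$segments
  seqs <- segment_sequences(s, genome)
  g <- data.frame(
    name = s$name, kind = s$kind, chain = s$chain, seq = seqs,
    family = s$family,
    cys_start = ifelse(s$kind == "V",
                       nchar(seqs) - s$germ_cdr3_nt - 2L, NA_integer_),
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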