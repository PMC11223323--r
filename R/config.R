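#' Annotation configuration
#'
#' Builds the parameter set used by the germline annotation functions. Defaults
#' follow the motif rules used throughout the package: two-tier similarity
#' seeding (a lenient e-value pass to define regions of interest, a strict pass
#' to define candidates, with the lenient threshold retained for the short J
#' genes), canonical RSS heptamer/nonamer consensus search with configurable
#' mismatch tolerances, and octamer/TATA promoter detection.
#'
#' @param e_value_loose lenient e-value for the region-of-interest pass.
#' @param e_value_strict strict e-value for the candidate-defining pass.
#' @param e_value_j e-value used for J genes (kept lenient because of their
#'   short length).
#' @param heptamer_consensus character vector of accepted canonical heptamers.
#'   Both teleost variants \code{CACAGTG} and \code{CACAGCA} are accepted by
#'   default.
#' @param nonamer_consensus canonical nonamer.
#' @param heptamer_tol,nonamer_tol maximum mismatches tolerated in the heptamer
#'   and nonamer. The first \code{heptamer_fixed} heptamer positions
#'   (\code{CAC}) are invariant and must match exactly.
#' @param heptamer_fixed number of invariant 5' heptamer positions.
#' @param spacer_slack tolerated deviation (nt) from the nominal 12/23 spacer.
#' @param promoter_window nucleotides upstream of the gene searched for the
#'   promoter.
#' @param octamer_consensus promoter octamer consensus (its reverse complement
#'   is also searched).
#' @param octamer_tol maximum octamer mismatches.
#' @param tata_pattern TATA-box motif, as a fixed-length IUPAC-free pattern
#'   with \code{[..]} character classes.
#' @param tata_tol maximum TATA mismatches.
#' @param promoter_max_gap maximum octamer-to-TATA gap considered (nt).
#' @param cluster_gap gap (nt) that splits locus units during organization
#'   inference.
#' @param d_core_min,d_core_max allowed D core length range (nt).
#' @param d_single_rss_rescue if \code{TRUE}, a D core flanked by one intact
#'   and one degenerate RSS is still reported (as a pseudogene); off by
#'   default.
#' @param min_intron,max_intron allowed leader intron length range (nt).
#' @param max_leader maximum leader exon length searched upstream of the
#'   intron (nt).
#' @param refine_margin margin (nt) around a seeded candidate extracted for
#'   refinement.
#' @param v_rss_search window (nt) downstream of the conserved 2nd-CYS codon
#'   searched for the V RSS.
#' @param profile_threshold_frac fraction of the mean training score used as
#'   acceptance threshold when rescreening with a genome-specific RSS profile.
#' @param shared_promoter if \code{TRUE}, a V gene within 1.5 kb downstream of
#'   another V with no intervening promoter inherits the nearest upstream
#'   promoter.
#' @param min_score_identity,min_v_span,min_j_span germline-call thresholds
#'   used by the repertoire aligner (identity fraction and minimum aligned
#'   spans for V and J).
#'
#' @return A list of class \code{"ig_config"}.
#' @export
annotation_config <- function(e_value_loose = 0.1,
                              e_value_strict = 1e-5,
                              e_value_j = 0.1,
                              heptamer_consensus = c("CACAGTG", "CACAGCA"),
                              nonamer_consensus = "ACAAAAACC",
                              heptamer_tol = 1L,
                              nonamer_tol = 3L,
                              heptamer_fixed = 3L,
                              spacer_slack = 1L,
                              promoter_window = 300L,
                              octamer_consensus = "ATGCAAAT",
                              octamer_tol = 1L,
                              tata_pattern = "TATA[AT]A[AT]",
                              tata_tol = 1L,
                              promoter_max_gap = 80L,
                              cluster_gap = 20000L,
                              d_core_min = 6L,
                              d_core_max = 40L,
                              d_single_rss_rescue = FALSE,
                              min_intron = 60L,
                              max_intron = 200L,
                              max_leader = 70L,
                              refine_margin = 400L,
                              v_rss_search = 90L,
                              profile_threshold_frac = 0.5,
                              shared_promoter = FALSE,
                              min_score_identity = 0.6,
                              min_v_span = 40L,
                              min_j_span = 18L) {
  stopifnot(heptamer_tol >= 0, nonamer_tol >= 0, spacer_slack >= 0)
  stopifnot(all(nchar(heptamer_consensus) == 7L), nchar(nonamer_consensus) == 9L)
  cfg <- list(
    e_value_loose = e_value_loose, e_value_strict = e_value_strict,
    e_value_j = e_value_j,
    heptamer_consensus = toupper(heptamer_consensus),
    nonamer_consensus = toupper(nonamer_consensus),
    heptamer_tol = as.integer(heptamer_tol),
    nonamer_tol = as.integer(nonamer_tol),
    heptamer_fixed = as.integer(heptamer_fixed),
    spacer_slack = as.integer(spacer_slack),
    promoter_window = as.integer(promoter_window),
    octamer_consensus = toupper(octamer_consensus),
    octamer_tol = as.integer(octamer_tol),
    tata_pattern = toupper(tata_pattern),
    tata_tol = as.integer(tata_tol),
    promoter_max_gap = as.integer(promoter_max_gap),
    cluster_gap = as.integer(cluster_gap),
    # window arithmetic: 7 + spacer + 9
    rss_window_12 = 7L + 12L + 9L,
    rss_window_23 = 7L + 23L + 9L,
    d_core_min = as.integer(d_core_min), d_core_max = as.integer(d_core_max),
    d_single_rss_rescue = isTRUE(d_single_rss_rescue),
    min_intron = as.integer(min_intron), max_intron = as.integer(max_intron),
    max_leader = as.integer(max_leader),
    refine_margin = as.integer(refine_margin),
    v_rss_search = as.integer(v_rss_search),
    profile_threshold_frac = profile_threshold_frac,
    shared_promoter = isTRUE(shared_promoter),
    min_score_identity = min_score_identity,
    min_v_span = as.integer(min_v_span),
    min_j_span = as.integer(min_j_span)
  )
  stopifnot(cfg$rss_window_12 == 28L, cfg$rss_window_23 == 39L)
  class(cfg) <- "ig_config"
  cfg
}

#' RSS spacer classes per chain
#'
#' The 12/23 rule implies per-chain spacer geometry: heavy chains are
#' V23-(12)D(12)-23J; kappa and sigma light chains are V12-23J; lambda-2 is
#' V23-12J.
#'
#' @param chain one of \code{"IGH"}, \code{"IGI1_kappa"}, \code{"IGI2_sigma"},
#'   \code{"IGI4_lambda2"}.
#' @return list with elements \code{V}, \code{J} and (heavy only) \code{D}.
#' @export
chain_rss_classes <- function(chain) {
  switch(chain,
    IGH          = list(V = 23L, D = c(12L, 12L), J = 23L),
    IGI1_kappa   = list(V = 12L, J = 23L),
    IGI2_sigma   = list(V = 12L, J = 23L),
    IGI4_lambda2 = list(V = 23L, J = 12L),
    stop("unknown chain: ", chain)
  )
}

ig_chains <- c("IGH", "IGI1_kappa", "IGI2_sigma", "IGI4_lambda2")

#' @export
print.ig_config <- function(x, ...) {
  cat("igloci annotation configuration\n")
  cat(sprintf("  e-values: loose %g / strict %g / J %g\n",
              x$e_value_loose, x$e_value_strict, x$e_value_j))
  cat(sprintf("  RSS: heptamer %s (<=%d mm, %d fixed), nonamer %s (<=%d mm), spacer slack +/-%d\n",
              paste(x$heptamer_consensus, collapse = "/"), x$heptamer_tol,
              x$heptamer_fixed, x$nonamer_consensus, x$nonamer_tol,
              x$spacer_slack))
  cat(sprintf("  promoter: octamer %s (<=%d mm), TATA %s (<=%d mm), window %d nt\n",
              x$octamer_consensus, x$octamer_tol, x$tata_pattern, x$tata_tol,
              x$promoter_window))
  cat(sprintf("  cluster gap %d nt; D core %d-%d nt\n",
              x$cluster_gap, x$d_core_min, x$d_core_max))
  invisible(x)
}
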