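#' Scan a sequence for recombination signal sequences
#'
#' Finds every heptamer-spacer-nonamer window, on both strands, whose heptamer
#' and nonamer each match the canonical consensus within the configured
#' mismatch tolerances and whose spacer length lies within
#' \code{spacer_class +/- cfg$spacer_slack}. The first \code{cfg$heptamer_fixed}
#' heptamer positions (\code{CAC}) are invariant: a mismatch there disqualifies
#' the window regardless of the tolerance.
#'
#' Coordinates are 1-based inclusive on the plus strand of \code{seq}; for a
#' minus-strand match \code{start..end} is the plus-strand footprint of the
#' window and \code{heptamer_seq}/\code{nonamer_seq} are reported as read on
#' the minus strand.
#'
#' @param seq nucleotide string (A/C/G/T/N).
#' @param spacer_class 12 or 23.
#' @param cfg an \code{\link{annotation_config}}.
#' @return data.frame with columns \code{start}, \code{end}, \code{strand},
#'   \code{heptamer_seq}, \code{nonamer_seq}, \code{spacer_len},
#'   \code{spacer_class}, \code{heptamer_mismatches},
#'   \code{nonamer_mismatches}, sorted by \code{start}.
#' @export
scan_rss <- function(seq, spacer_class, cfg = annotation_config()) {
  if (!spacer_class %in% c(12L, 23L)) {
    stop("spacer_class must be 12 or 23")
  }
  spacer_class <- as.integer(spacer_class)
  empty <- data.frame(
    start = integer(0), end = integer(0), strand = character(0),
    heptamer_seq = character(0), nonamer_seq = character(0),
    spacer_len = integer(0), spacer_class = integer(0),
    heptamer_mismatches = integer(0), nonamer_mismatches = integer(0),
    stringsAsFactors = FALSE
  )
  if (is.null(seq) || nchar(seq) == 0L) return(empty)
  seq <- toupper(seq)
  L <- nchar(seq)

  res <- list(scan_rss_strand(seq_chars(seq), spacer_class, cfg, "+", L))
  res[[2]] <- scan_rss_strand(seq_chars(revcomp(seq)), spacer_class, cfg, "-", L)
  out <- do.call(rbind, res)
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$start, out$strand, out$spacer_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One-strand vectorised scan over shifted character comparisons. For the
# minus strand, x_chars is the reverse complement and window coordinates are
# mapped back onto the plus strand.
scan_rss_strand <- function(x_chars, spacer_class, cfg, strand, L) {
  spacers <- (spacer_class - cfg$spacer_slack):(spacer_class + cfg$spacer_slack)
  spacers <- spacers[spacers >= 0L]
  heps <- lapply(cfg$heptamer_consensus, seq_chars)
  non <- seq_chars(cfg$nonamer_consensus)
  nf <- cfg$heptamer_fixed
  rows <- list()
  for (sp in spacers) {
    W <- 7L + sp + 9L
    ns <- length(x_chars) - W + 1L
    if (ns < 1L) next
    # heptamer: best over accepted canonical alternatives, invariant prefix
    hep_mm <- NULL
    for (h in heps) {
      mm <- integer(ns)
      pref_bad <- logical(ns)
      for (k in 1:7) {
        d <- x_chars[k:(ns + k - 1L)] != h[k]
        mm <- mm + d
        if (k <= nf) pref_bad <- pref_bad | d
      }
      mm[pref_bad | mm > cfg$heptamer_tol] <- NA_integer_
      hep_mm <- if (is.null(hep_mm)) mm else pmin(hep_mm, mm, na.rm = TRUE)
    }
    ok_h <- which(!is.na(hep_mm))
    if (!length(ok_h)) next
    non_mm <- integer(ns)
    off <- 7L + sp
    for (k in 1:9) {
      non_mm <- non_mm + (x_chars[(off + k):(ns + off + k - 1L)] != non[k])
    }
    hit <- ok_h[non_mm[ok_h] <= cfg$nonamer_tol]
    if (!length(hit)) next
    for (i in hit) {
      hep_seq <- paste(x_chars[i:(i + 6L)], collapse = "")
      non_seq <- paste(x_chars[(i + off):(i + off + 8L)], collapse = "")
      if (strand == "+") {
        s <- i
      } else {
        s <- L - (i + W - 1L) + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = s, end = s + W - 1L, strand = strand,
        heptamer_seq = hep_seq, nonamer_seq = non_seq,
        spacer_len = sp, spacer_class = spacer_class,
        heptamer_mismatches = hep_mm[i], nonamer_mismatches = non_mm[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame())
  }
  do.call(rbind, rows)
}

#' Check the 12/23 rule for a V-J segment pair
#'
#' A productive join pairs one 12-spacer RSS with one 23-spacer RSS. Kappa,
#' sigma and sigma-2 light chains are V12-23J, lambda(-2) is V23-12J; both
#' satisfy the rule.
#'
#' @param v,j gene segments (rows of an annotation segment table, or any list
#'   with an \code{rss_spacer_class} field).
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when either segment lacks an
#'   RSS (indeterminate, distinct from a violation).
#' @export
check_1223 <- function(v, j) {
  sv <- v$rss_spacer_class
  sj <- j$rss_spacer_class
  if (is.null(sv) || is.null(sj) || length(sv) != 1L || length(sj) != 1L ||
      is.na(sv) || is.na(sj)) {
    return(NA)
  }
  sort(c(sv, sj))[1] == 12L && sort(c(sv, sj))[2] == 23L
}

#' Derive a genome-specific RSS profile
#'
#' Builds a per-position frequency profile from the terminal RSS windows of V
#' genes carrying a canonical RSS: 28 nt for the 12-spacer class
#' (7 + 12 + 9), 39 nt for the 23-spacer class (7 + 23 + 9). V candidates that
#' lack a canonical RSS can then be rescreened against the profile
#' (\code{\link{profile_scan}}), recovering genome-specific signals.
#'
#' @param windows character vector of RSS window sequences, all of the class
#'   window length.
#' @param spacer_class 12 or 23.
#' @param pseudocount added to each base count.
#' @return object of class \code{"rss_profile"}: list with the position
#'   frequency matrix \code{pfm} (4 x window length), \code{spacer_class},
#'   \code{window_length}, per-training-sequence log-odds \code{train_scores}
#'   and the acceptance \code{threshold}.
#' @export
derive_rss_profile <- function(windows, spacer_class,
                               cfg = annotation_config(), pseudocount = 0.5) {
  if (length(windows) == 0L) stop("at least one canonical RSS window required")
  if (!spacer_class %in% c(12L, 23L)) stop("spacer_class must be 12 or 23")
  wlen <- 7L + as.integer(spacer_class) + 9L
  if (!all(nchar(windows) == wlen)) {
    stop("all windows must have length ", wlen)
  }
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, nrow = 4, ncol = wlen, dimnames = list(bases, NULL))
  for (w in toupper(windows)) {
    ch <- seq_chars(w)
    for (p in seq_len(wlen)) {
      if (ch[p] %in% bases) mat[ch[p], p] <- mat[ch[p], p] + 1
    }
  }
  pfm <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  lod <- log2(pfm / 0.25)
  # scoring is restricted to informative columns (the conserved heptamer and
  # nonamer); spacer columns vary between genes and carry no signal
  ic <- 2 + apply(pfm, 2, function(f) sum(ifelse(f > 0, f * log2(f), 0)))
  informative <- which(ic >= 0.5)
  score1 <- function(w) {
    ch <- seq_chars(w)
    s <- 0
    for (p in informative) {
      s <- s + if (ch[p] %in% bases) lod[ch[p], p] else min(lod[, p])
    }
    s
  }
  train <- vapply(toupper(windows), score1, numeric(1), USE.NAMES = FALSE)
  out <- list(
    pfm = pfm, lod = lod, spacer_class = as.integer(spacer_class),
    window_length = wlen, information = ic, informative = informative,
    train_scores = train,
    threshold = cfg$profile_threshold_frac * mean(train)
  )
  class(out) <- "rss_profile"
  out
}

#' Scan a sequence with an RSS profile
#'
#' Slides the profile log-odds over the plus strand of \code{seq} and returns
#' all window positions scoring at or above the profile threshold.
#'
#' @param seq nucleotide string.
#' @param profile an \code{\link{derive_rss_profile}} result.
#' @param threshold optional score threshold overriding the profile's own.
#' @return data.frame with \code{start}, \code{end}, \code{score}, sorted by
#'   decreasing score.
#' @export
profile_scan <- function(seq, profile, threshold = NULL) {
  stopifnot(inherits(profile, "rss_profile"))
  thr <- if (is.null(threshold)) profile$threshold else threshold
  wlen <- profile$window_length
  x <- seq_chars(seq)
  ns <- length(x) - wlen + 1L
  if (ns < 1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  bases <- rownames(profile$lod)
  sc <- numeric(ns)
  worst <- apply(profile$lod, 2, min)
  for (k in profile$informative) {
    col <- profile$lod[, k]
    seg <- x[k:(ns + k - 1L)]
    v <- col[match(seg, bases)]
    v[is.na(v)] <- worst[k]
    sc <- sc + v
  }
  hit <- which(sc >= thr)
  out <- data.frame(start = hit, end = hit + wlen - 1L, score = sc[hit])
  out[order(-out$score, out$start), , drop = FALSE]
}

#' @export
print.rss_profile <- function(x, ...) {
  cat(sprintf("RSS position profile: %d-spacer class, window %d nt, %d training sequences\n",
              x$spacer_class, x$window_length, length(x$train_scores)))
  cat(sprintf("  acceptance threshold %.2f bits (training mean %.2f)\n",
              x$threshold, mean(x$train_scores)))
  invisible(x)
}
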