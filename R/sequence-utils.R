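# Low-level nucleotide helpers shared across modules. Sequences travel as
# plain upper-case character scalars; Biostrings objects are used at module
# boundaries (file IO, alignment).

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(COMPLEMENT[chars])), collapse = "")
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# vectorised reverse complement for read batches
revcomp_many <- function(x) {
  if (!length(x)) return(character(0))
  out <- rep("", length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])))
  }
  out
}

# Codon table restricted to unambiguous codons; anything containing N -> X.
GENETIC_CODE_TAB <- local({
  b <- c("T", "C", "A", "G")
  # codons enumerated with the third base varying fastest
  codons <- character(64)
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

#' Translate a nucleotide sequence
#'
#' Frame-0 translation; trailing partial codons are dropped and codons with
#' ambiguous bases translate to \code{X}.
#'
#' @param nt nucleotide string.
#' @return amino-acid string (stop codons as \code{*}).
#' @export
translate_nt <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_TAB[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

has_internal_stop <- function(nt) {
  aa <- translate_nt(nt)
  grepl("*", aa, fixed = TRUE)
}

# mismatch count between two equal-length strings
str_mismatches <- function(a, b) {
  sum(seq_chars(a) != seq_chars(b))
}

# Expand a fixed-length pattern with [..] classes, e.g. TATA[AT]A[AT], into a
# list of per-position allowed character vectors.
pattern_positions <- function(pattern) {
  out <- list()
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE) + i - 1L
      out[[length(out) + 1L]] <- seq_chars(substr(pattern, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    }
  }
  out
}

# Vectorised mismatch profile of a plain pattern over all windows of x_chars.
# Returns integer vector over start positions 1..(n-w+1); length 0 if the
# sequence is shorter than the pattern.
window_mismatch_profile <- function(x_chars, pat_chars) {
  w <- length(pat_chars)
  ns <- length(x_chars) - w + 1L
  if (ns < 1L) return(integer(0))
  mm <- integer(ns)
  for (k in seq_len(w)) {
    mm <- mm + (x_chars[k:(ns + k - 1L)] != pat_chars[k])
  }
  mm
}

# As above but pat is a list of allowed characters per position.
window_class_mismatch_profile <- function(x_chars, pat_list) {
  w <- length(pat_list)
  ns <- length(x_chars) - w + 1L
  if (ns < 1L) return(integer(0))
  mm <- integer(ns)
  for (k in seq_len(w)) {
    allowed <- pat_list[[k]]
    seg <- x_chars[k:(ns + k - 1L)]
    ok <- seg == allowed[1L]
    if (length(allowed) > 1L) {
      for (a in allowed[-1L]) ok <- ok | (seg == a)
    }
    mm <- mm + !ok
  }
  mm
}
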