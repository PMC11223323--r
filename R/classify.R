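# V-segment classification and germline variability: pairwise identity and
# family clustering at the 80% similarity threshold, p/K2P distances with
# pairwise deletion, neighbour-joining trees with bootstrap support, and
# per-column Shannon entropy profiles.

#' Pairwise sequence identity
#'
#' Identity from a global (Needleman-Wunsch, affine-gap) alignment: matching
#' columns divided by aligned columns, excluding columns where both
#' sequences are gapped.
#'
#' @param a,b nucleotide (or amino-acid, with \code{type = "AA"}) strings.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b, type = "DNA") {
  if (is.null(a) || is.null(b) || nchar(a) == 0L || nchar(b) == 0L) {
    stop("both sequences must be non-empty")
  }
  if (type == "DNA") {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 8, gapExtension = 2)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      gapOpening = 10, gapExtension = 2)
  }
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sb <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  valid <- !(pa == "-" & sb == "-")
  sum(pa[valid] == sb[valid]) / sum(valid)
}

#' All-against-all identity matrix
#'
#' @param seqs character vector of sequences.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @return symmetric matrix of identity fractions (unit diagonal).
#' @export
identity_matrix <- function(seqs, type = "DNA") {
  n <- length(seqs)
  m <- diag(1, n)
  if (n > 1L) {
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                       baseOnly = FALSE)
    for (i in seq_len(n - 1L)) {
      others <- (i + 1L):n
      al <- if (type == "DNA") {
        Biostrings::pairwiseAlignment(
          Biostrings::DNAStringSet(seqs[others]),
          Biostrings::DNAString(seqs[i]), type = "global",
          substitutionMatrix = submat, gapOpening = 8, gapExtension = 2)
      } else {
        Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(seqs[others]),
          Biostrings::AAString(seqs[i]), type = "global",
          gapOpening = 10, gapExtension = 2)
      }
      pa <- as.character(Biostrings::alignedPattern(al))
      sb <- as.character(Biostrings::alignedSubject(al))
      ident <- vapply(seq_along(others), function(q) {
        a <- seq_chars(pa[q]); b <- seq_chars(sb[q])
        valid <- !(a == "-" & b == "-")
        sum(a[valid] == b[valid]) / sum(valid)
      }, numeric(1))
      m[i, others] <- m[others, i] <- ident
    }
  }
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Cluster segments into families
#'
#' Single-linkage connected components of the graph joining pairs with
#' identity at or above the threshold; families in different components have
#' less than the threshold similarity under single linkage. Family labels
#' are ordered by descending size, ties by the leftmost genomic coordinate.
#'
#' @param idmat square identity matrix.
#' @param threshold identity threshold (default 0.80).
#' @param coords optional genomic start coordinates for tie-breaking.
#' @return list of class \code{"family_assignment"}: \code{family} (integer
#'   labels), \code{threshold}, \code{n_families}.
#' @export
cluster_families <- function(idmat, threshold = 0.8, coords = NULL) {
  n <- nrow(idmat)
  stopifnot(n == ncol(idmat))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k > i && idmat[i, k] >= threshold) {
        ri <- find(i); rk <- find(k)
        if (ri != rk) parent[rk] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  if (is.null(coords)) coords <- seq_len(n)
  sizes <- table(comp)
  first <- tapply(coords, comp, min)
  ord <- order(-as.vector(sizes), as.vector(first))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  fam <- as.integer(relabel[as.character(comp)])
  out <- list(family = fam, threshold = threshold,
              n_families = length(unique(fam)))
  class(out) <- "family_assignment"
  out
}

#' @export
print.family_assignment <- function(x, ...) {
  cat(sprintf("family assignment: %d families at %.0f%% identity; sizes: %s\n",
              x$n_families, 100 * x$threshold,
              paste(table(x$family), collapse = ", ")))
  invisible(x)
}

valid_pair_sites <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  ok <- ca %in% BASES & cb %in% BASES
  list(a = ca[ok], b = cb[ok])
}

#' p-distance between aligned sequences
#'
#' Proportion of differing sites with pairwise deletion: gap or ambiguous
#' columns are removed for each pair separately.
#'
#' @param a,b equal-length aligned nucleotide strings.
#' @return substitutions per site.
#' @export
p_distance <- function(a, b) {
  s <- valid_pair_sites(a, b)
  if (!length(s$a)) return(NA_real_)
  mean(s$a != s$b)
}

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance
#'
#' \eqn{d = \frac12\ln\frac{1}{1-2P-Q} + \frac14\ln\frac{1}{1-2Q}} with
#' transition fraction P and transversion fraction Q over pairwise-deleted
#' sites. With a gamma shape parameter \eqn{a}, the rate-variation-corrected
#' form \eqn{d = \frac a2[(1-2P-Q)^{-1/a}-1] + \frac a4[(1-2Q)^{-1/a}-1]} is
#' used. Saturated pairs (log/power argument not positive) return \code{NA}
#' with a warning.
#'
#' @param a,b equal-length aligned nucleotide strings.
#' @param gamma_shape optional gamma shape parameter for among-site rate
#'   variation.
#' @return substitutions per site.
#' @export
k2p_distance <- function(a, b, gamma_shape = NULL) {
  s <- valid_pair_sites(a, b)
  n <- length(s$a)
  if (!n) return(NA_real_)
  diff <- s$a != s$b
  ts <- diff & (TRANSITIONS[s$a] == s$b)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("saturated pair: K2P distance undefined")
    return(NA_real_)
  }
  if (is.null(gamma_shape)) {
    0.5 * log(1 / w1) + 0.25 * log(1 / w2)
  } else {
    g <- gamma_shape
    (g / 2) * (w1^(-1 / g) - 1) + (g / 4) * (w2^(-1 / g) - 1)
  }
}

#' Distance matrix over an alignment
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param model \code{"p"} or \code{"k2p"}.
#' @param gamma_shape passed to \code{\link{k2p_distance}}.
#' @return symmetric distance matrix.
#' @export
distance_matrix <- function(aln, model = c("p", "k2p"), gamma_shape = NULL) {
  model <- match.arg(model)
  n <- length(aln)
  m <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (k in (i + 1L):n) {
        m[i, k] <- m[k, i] <- if (model == "p") {
          p_distance(aln[i], aln[k])
        } else {
          k2p_distance(aln[i], aln[k], gamma_shape)
        }
      }
    }
  }
  m
}

#' Neighbour-joining tree
#'
#' Classical Saitou-Nei agglomeration over the Q-criterion. Tied minimal
#' pairs are broken deterministically by the lexicographically smallest pair
#' of clade labels (a clade is labelled by its smallest member leaf).
#' Negative branch lengths are clamped to zero; the number of clamped edges
#' is recorded in the \code{"negative_branches"} attribute.
#'
#' @param D symmetric distance matrix with unique row/column names
#'   (n >= 3).
#' @return an \code{ape} \code{"phylo"} tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbour joining requires at least 3 taxa")
  if (anyNA(D)) {
    stop("distance matrix contains NA (saturated or non-overlapping pairs)")
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(!anyDuplicated(labels))
  newick <- labels        # newick fragment per active cluster
  key <- labels           # tie-break key: smallest member label
  negatives <- 0L
  clamp <- function(x) {
    if (x < 0) negatives <<- negatives + 1L
    max(0, x)
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3L) {
    r <- rowSums(D)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (k in (i + 1L):n) {
        q <- (n - 2) * D[i, k] - r[i] - r[k]
        pair_key <- sort(c(key[i], key[k]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair_key[1] < best$key[1] ||
              (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
          best <- list(i = i, k = k, q = q, key = pair_key)
        }
      }
    }
    i <- best$i; k <- best$k
    li <- D[i, k] / 2 + (r[i] - r[k]) / (2 * (n - 2))
    lk <- D[i, k] - li
    li <- clamp(li); lk <- clamp(lk)
    merged <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li), newick[k], fmt(lk))
    du <- (D[i, ] + D[k, ] - D[i, k]) / 2
    keep <- setdiff(seq_len(n), c(i, k))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    newick <- c(newick[keep], merged)
    key <- c(key[keep], min(key[c(i, k)]))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], paste0("_u", n))
    D <- D2
    n <- n - 1L
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], fmt(l1),
                 newick[2], fmt(l2), newick[3], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branches") <- negatives
  tree
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and reports, for each internal edge of the original tree, the
#' percentage of replicates containing the same bipartition. Seeded and
#' reproducible.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param n_reps bootstrap replicates (the study convention is 1,000).
#' @param seed RNG seed.
#' @param model distance model passed to \code{\link{distance_matrix}}.
#' @param gamma_shape optional gamma shape for K2P.
#' @return the NJ tree of the full alignment with support percentages as
#'   \code{node.label}.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              model = "p", gamma_shape = NULL) {
  stopifnot(length(aln) >= 3L)
  L <- nchar(aln[1])
  stopifnot(all(nchar(aln) == L))
  ref <- nj_tree(distance_matrix(aln, model, gamma_shape))
  set.seed(seed)
  mats <- vapply(aln, seq_chars, character(L))
  boots <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- apply(mats[cols, , drop = FALSE], 2, paste, collapse = "")
    boots[[r]] <- nj_tree(distance_matrix(res, model, gamma_shape))
  }
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- round(100 * counts / n_reps, 1)
  ref
}

#' Per-column Shannon entropy profile of an alignment
#'
#' Entropy in bits per column over the observed residues, excluding gaps
#' from the distribution. Columns with more than half gaps get consensus
#' symbol \code{"-"}; otherwise the plurality residue if it reaches the
#' plurality threshold, else \code{"?"}.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (nucleotide or amino acid).
#' @param region optional character vector (length = alignment length)
#'   marking regions, e.g. \code{"FR"}/\code{"CDR"}.
#' @param plurality consensus plurality threshold (default 0.5).
#' @return data.frame of class \code{"entropy_profile"}: \code{column},
#'   \code{entropy_bits}, \code{consensus}, \code{gap_fraction},
#'   \code{region}.
#' @export
entropy_profile <- function(aln, region = NULL, plurality = 0.5) {
  if (length(aln) == 0L) stop("empty alignment")
  L <- nchar(aln[1])
  stopifnot(all(nchar(aln) == L))
  if (!is.null(region)) stopifnot(length(region) == L)
  mats <- vapply(aln, seq_chars, character(L))
  if (L == 1L) mats <- matrix(mats, nrow = 1L)
  out <- data.frame(column = seq_len(L), entropy_bits = NA_real_,
                    consensus = NA_character_, gap_fraction = NA_real_,
                    region = if (is.null(region)) NA_character_ else region,
                    stringsAsFactors = FALSE)
  for (p in seq_len(L)) {
    col <- mats[p, ]
    gapf <- mean(col == "-")
    res <- col[col != "-"]
    if (length(res)) {
      f <- table(res) / length(res)
      h <- -sum(f * log2(f))
    } else {
      h <- 0
    }
    cons <- if (gapf > 0.5) {
      "-"
    } else if (length(res) && max(f) >= plurality) {
      names(f)[which.max(f)]
    } else {
      "?"
    }
    out$entropy_bits[p] <- h
    out$consensus[p] <- cons
    out$gap_fraction[p] <- gapf
  }
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Deterministic center-star multiple alignment
#'
#' Chooses the sequence with the highest total pairwise alignment score as
#' the center and merges the pairwise global alignments of all other
#' sequences to it. Deterministic (score ties resolved by input order);
#' every input is recoverable from its aligned row by removing gaps.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @return named character vector of aligned rows (equal length), in input
#'   order.
#' @export
center_star_msa <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_len(n))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  score_pair <- function(a, b) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = submat, gapOpening = 3, gapExtension = 1))
  }
  tot <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      sc <- score_pair(seqs[i], seqs[k])
      tot[i] <- tot[i] + sc
      tot[k] <- tot[k] + sc
    }
  }
  center <- which.max(tot)
  clen <- nchar(seqs[center])
  others <- setdiff(seq_len(n), center)
  # per-alignment gaps inserted into the center, keyed by center boundary
  # (0..clen = before position b+1)
  ins <- matrix(0L, nrow = n, ncol = clen + 1L)
  rows_c <- vector("list", n)
  rows_o <- vector("list", n)
  for (k in others) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[center]), Biostrings::DNAString(seqs[k]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 3, gapExtension = 1)
    pc <- seq_chars(as.character(Biostrings::alignedPattern(al)))
    po <- seq_chars(as.character(Biostrings::alignedSubject(al)))
    b <- 0L
    for (c in seq_along(pc)) {
      if (pc[c] == "-") {
        ins[k, b + 1L] <- ins[k, b + 1L] + 1L
      } else {
        b <- b + 1L
      }
    }
    rows_c[[k]] <- pc
    rows_o[[k]] <- po
  }
  gmax <- apply(ins, 2, max)
  cc <- seq_chars(seqs[center])
  build_center <- function() {
    out <- character(0)
    for (b in 0:clen) {
      out <- c(out, rep("-", gmax[b + 1L]))
      if (b < clen) out <- c(out, cc[b + 1L])
    }
    paste(out, collapse = "")
  }
  build_row <- function(k) {
    pc <- rows_c[[k]]; po <- rows_o[[k]]
    out <- character(0)
    c <- 1L
    for (b in 0:clen) {
      block <- character(0)
      while (c <= length(pc) && pc[c] == "-") {
        block <- c(block, po[c])
        c <- c + 1L
      }
      out <- c(out, block, rep("-", gmax[b + 1L] - length(block)))
      if (b < clen) {
        out <- c(out, po[c])
        c <- c + 1L
      }
    }
    paste(out, collapse = "")
  }
  res <- character(n)
  res[center] <- build_center()
  for (k in others) res[k] <- build_row(k)
  names(res) <- names(seqs)
  res
}
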