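# Repertoire summary statistics over clonotype tables: saturation/
# rarefaction, D50, CDR3 length analyses, gene usage and usage correlations,
# J-group ratios, public-clone sharing partitions and replicate overlap.
# Unless stated otherwise, statistics weight each clonotype once (the unit
# of analysis is the unique receptor, not the read).

#' Rarefaction (saturation) curve
#'
#' Subsamples reads without replacement from the read-expanded clonotype
#' multiset and counts distinct CDR3s at each depth; at full depth the curve
#' equals the observed richness exactly.
#'
#' @param clonotypes AIRR-style clonotype table (\code{junction},
#'   \code{duplicate_count}).
#' @param depths read depths to evaluate (each <= total reads).
#' @param n_reps subsample replicates per depth.
#' @param seed RNG seed.
#' @return data.frame with \code{depth}, \code{mean_unique}, \code{sd}.
#' @export
rarefaction_curve <- function(clonotypes, depths, n_reps = 10L, seed = 1L) {
  counts <- clonotypes$duplicate_count
  total <- sum(counts)
  if (any(depths > total)) stop("depth exceeds total reads (", total, ")")
  stopifnot(all(depths >= 1L))
  set.seed(seed)
  ids <- rep.int(seq_along(counts), counts)
  out <- lapply(depths, function(d) {
    uq <- replicate(n_reps, length(unique(ids[sample.int(total, d)])))
    data.frame(depth = d, mean_unique = mean(uq), sd = stats::sd(uq))
  })
  do.call(rbind, out)
}

# closed-form expectation used as the test oracle for rarefaction:
# E[distinct at depth d] = sum_c 1 - choose(N - n_c, d)/choose(N, d)
expected_distinct <- function(counts, depth) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' D50 repertoire diversity
#'
#' The smallest percentage of clonotypes (ranked by descending read count,
#' ties by CDR3 sequence) whose cumulative read share reaches 50\% of the
#' repertoire. Low values indicate clonal expansion.
#'
#' @param clonotypes clonotype table with \code{junction} and
#'   \code{duplicate_count}.
#' @return percentage in (0, 100].
#' @export
d50 <- function(clonotypes) {
  if (nrow(clonotypes) == 0L || sum(clonotypes$duplicate_count) == 0L) {
    stop("empty repertoire")
  }
  ord <- order(-clonotypes$duplicate_count, clonotypes$junction)
  counts <- clonotypes$duplicate_count[ord]
  k <- which(cumsum(counts) >= 0.5 * sum(counts))[1]
  100 * k / length(counts)
}

#' CDR3 length distribution and mean
#'
#' Lengths are computed over unique clonotypes (unweighted by reads), with
#' all samples pooled.
#'
#' @param samples one clonotype table or a list of them.
#' @param unit \code{"aa"} or \code{"nt"}.
#' @return list with \code{mean}, \code{n} and a \code{distribution}
#'   data.frame (\code{length}, \code{count}).
#' @export
cdr3_length_stats <- function(samples, unit = c("aa", "nt")) {
  unit <- match.arg(unit)
  if (is.data.frame(samples)) samples <- list(samples)
  pooled <- do.call(rbind, lapply(samples, function(s) {
    s[, c("junction", "junction_aa"), drop = FALSE]
  }))
  if (nrow(pooled) == 0L) stop("no clonotypes")
  len <- if (unit == "aa") nchar(pooled$junction_aa) else nchar(pooled$junction)
  tab <- table(len)
  list(mean = mean(len), n = length(len),
       distribution = data.frame(length = as.integer(names(tab)),
                                 count = as.integer(tab)))
}

#' Germline CDR3 length of a V segment
#'
#' The germline contribution to CDR3 in amino acids: CDR3 nucleotides after
#' the 2nd-CYS codon divided by three (may be fractional; reported as is).
#'
#' @param v a V segment row (annotation or germline set) with
#'   \code{germ_cdr3_nt}.
#' @return length in amino acids.
#' @export
germline_cdr3_length <- function(v) {
  g <- v$germ_cdr3_nt
  if (is.null(g) || any(is.na(g))) stop("germ_cdr3_nt not annotated")
  g / 3
}

#' Correlation between germline and expressed CDR3 lengths
#'
#' Pearson correlation between each clonotype's expressed CDR3 length (aa)
#' and the germline CDR3 length of its V call, with the two-sided p-value
#' from the t transform.
#'
#' @param clonotypes clonotype table with \code{v_call} and
#'   \code{junction_aa}.
#' @param germ germline set (provides \code{germ_cdr3_nt} per V name).
#' @return list with \code{r}, \code{p_value}, \code{n};
#'   \code{r} is \code{NA} with a reason when either variable has zero
#'   variance.
#' @export
length_correlation <- function(clonotypes, germ) {
  v <- germ[germ$kind == "V", , drop = FALSE]
  g <- v$germ_cdr3_nt[match(clonotypes$v_call, v$name)] / 3
  y <- nchar(clonotypes$junction_aa)
  ok <- !is.na(g)
  g <- g[ok]; y <- y[ok]
  if (length(g) < 3L) stop("at least 3 clonotypes with V calls required")
  if (stats::sd(g) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(g),
                reason = "zero variance"))
  }
  ct <- stats::cor.test(g, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(g))
}

# family label: the gene name up to the first hyphen, allele suffix removed
# (IGHV3-1-12*01 -> IGHV3, IGIJ4-2*01 -> IGIJ4)
gene_family <- function(names) sub("-.*$", "", sub("\\*\\d+$", "", names))

#' Gene usage frequencies
#'
#' Fraction of clonotypes (unweighted by reads) calling each V gene (or
#' family).
#'
#' @param clonotypes clonotype table.
#' @param level \code{"gene"} or \code{"family"}.
#' @param call column to tabulate (\code{"v_call"} or \code{"j_call"}).
#' @param genes optional gene universe for zero-filling.
#' @return named numeric vector of frequencies summing to 1.
#' @export
gene_usage <- function(clonotypes, level = c("gene", "family"),
                       call = "v_call", genes = NULL) {
  level <- match.arg(level)
  calls <- clonotypes[[call]]
  if (level == "family") {
    calls <- gene_family(calls)
    if (!is.null(genes)) genes <- unique(gene_family(genes))
  }
  tab <- table(calls)
  u <- as.numeric(tab) / sum(tab)
  names(u) <- names(tab)
  if (!is.null(genes)) {
    full <- stats::setNames(numeric(length(genes)), genes)
    full[names(u)[names(u) %in% genes]] <- u[names(u) %in% genes]
    u <- full
  }
  u
}

#' Pairwise usage correlation between samples
#'
#' Pearson correlations of gene-usage vectors over the union of genes
#' (zero-filled), and their mean over distinct unordered pairs. Technical
#' replicates can be excluded by naming the samples and passing
#' \code{exclude}.
#'
#' @param samples named list of clonotype tables (one per sample).
#' @param level,call passed to \code{\link{gene_usage}}.
#' @param exclude sample names dropped before the calculation.
#' @return list with \code{matrix} (pairwise r) and \code{mean}; empty for a
#'   single sample.
#' @export
usage_correlation <- function(samples, level = "gene", call = "v_call",
                              exclude = character(0)) {
  samples <- samples[setdiff(names(samples), exclude)]
  if (length(samples) < 2L) return(list(matrix = NULL, mean = NA_real_))
  us <- lapply(samples, gene_usage, level = level, call = call)
  genes <- sort(unique(unlist(lapply(us, names))))
  mat <- vapply(us, function(u) {
    full <- stats::setNames(numeric(length(genes)), genes)
    full[names(u)] <- u
    full
  }, numeric(length(genes)))
  cm <- stats::cor(mat)
  list(matrix = cm, mean = mean(cm[upper.tri(cm)]))
}

#' Ratio of clonotypes between two J-gene groups
#'
#' @param clonotypes clonotype table.
#' @param group_a,group_b disjoint sets of J gene names (or regular-
#'   expression-free name prefixes, matched after stripping the allele
#'   suffix).
#' @return a/b ratio; \code{Inf} when group b is unused; \code{NA} when both
#'   are empty.
#' @export
j_ratio <- function(clonotypes, group_a, group_b) {
  stopifnot(!length(intersect(group_a, group_b)))
  calls <- sub("\\*\\d+$", "", clonotypes$j_call)
  in_group <- function(g) calls %in% sub("\\*\\d+$", "", g) |
    gene_family(calls) %in% g
  na <- sum(in_group(group_a))
  nb <- sum(in_group(group_b))
  if (na == 0L && nb == 0L) return(NA_real_)
  if (nb == 0L) return(Inf)
  na / nb
}

#' Sharing partition across fish
#'
#' Each distinct CDR3 (amino-acid level by default) gets a prevalence equal
#' to the number of fish carrying it; classes are \code{unique} (1 fish),
#' \code{shared_by_two} (2), \code{widely_shared} (3..n-1) and
#' \code{shared_by_all} (n). Per-fish proportions are over the fish's own
#' distinct CDR3s; only one technical replicate per fish should be supplied.
#'
#' @param samples named list of clonotype tables, one per fish (names =
#'   fish ids).
#' @param level \code{"aa"} or \code{"nt"}.
#' @return list of class \code{"sharing_partition"}: \code{per_fish}
#'   (proportions matrix), \code{shared_by_all_count},
#'   \code{total_distinct}, \code{prevalence} table.
#' @export
sharing_partition <- function(samples, level = c("aa", "nt")) {
  level <- match.arg(level)
  n <- length(samples)
  stopifnot(n >= 2L)
  if (is.null(names(samples)) || anyDuplicated(names(samples))) {
    stop("samples must be uniquely named by fish id")
  }
  col <- if (level == "aa") "junction_aa" else "junction"
  sets <- lapply(samples, function(s) unique(s[[col]]))
  all_cdr3 <- unique(unlist(sets))
  prev <- rowSums(vapply(sets, function(s) all_cdr3 %in% s, logical(length(all_cdr3))))
  names(prev) <- all_cdr3
  classify <- function(p) {
    if (p >= n) "shared_by_all"
    else if (p == 1L) "unique"
    else if (p == 2L) "shared_by_two"
    else "widely_shared"
  }
  cls <- vapply(prev, classify, character(1))
  classes <- c("unique", "shared_by_two", "widely_shared", "shared_by_all")
  per_fish <- t(vapply(sets, function(s) {
    cc <- table(factor(cls[s], levels = classes))
    as.numeric(cc) / length(s)
  }, numeric(4)))
  colnames(per_fish) <- classes
  out <- list(per_fish = per_fish,
              shared_by_all_count = sum(cls == "shared_by_all"),
              total_distinct = length(all_cdr3),
              prevalence = prev)
  class(out) <- "sharing_partition"
  out
}

#' @export
print.sharing_partition <- function(x, ...) {
  cat(sprintf("sharing partition over %d fish: %d distinct CDR3s, %d shared by all\n",
              nrow(x$per_fish), x$total_distinct, x$shared_by_all_count))
  print(round(x$per_fish, 3))
  invisible(x)
}

#' Repertoire overlap between technical replicates
#'
#' Jaccard percentage on the CDR3 sets, with the two per-sample containment
#' percentages also reported (the natural alternative denominator).
#'
#' @param a,b clonotype tables from the same fish.
#' @param level \code{"aa"} or \code{"nt"}.
#' @return list with \code{jaccard}, \code{containment_a},
#'   \code{containment_b} (all percentages).
#' @export
replicate_overlap <- function(a, b, level = c("aa", "nt")) {
  level <- match.arg(level)
  col <- if (level == "aa") "junction_aa" else "junction"
  A <- unique(a[[col]]); B <- unique(b[[col]])
  if (!length(A) && !length(B)) stop("both repertoires empty")
  inter <- length(intersect(A, B))
  list(jaccard = 100 * inter / length(union(A, B)),
       containment_a = if (length(A)) 100 * inter / length(A) else NA_real_,
       containment_b = if (length(B)) 100 * inter / length(B) else NA_real_)
}
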