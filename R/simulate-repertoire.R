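# V(D)J recombination and paired-read simulation. The junction model follows
# the diversification routes available to the Atlantic cod: exonucleolytic
# deletions at every coding end, palindromic (P) additions at untrimmed ends,
# non-templated (N) additions at heavy-chain junctions, and no somatic
# hypermutation. Light-chain mode suppresses N/P additions and most deletion.

#' Recombination simulator parameters
#'
#' Heavy-chain defaults: geometric deletions with mean 3 nt per coding end,
#' Poisson N additions with mean 1.5 per junction, P additions (<= 2 nt) with
#' probability 0.5 at untrimmed ends. Light-chain mode (the default for the
#' light chains) uses mean deletions of 0.5 nt, no N and no P additions,
#' reflecting the near absence of junctional insertions and deletions in
#' light chains. Clonal abundance is lognormal(0, 1.5).
#'
#' @param chain chain type; selects heavy or light defaults.
#' @param n_clones number of clones drawn.
#' @param v_usage,d_usage,j_usage usage probability vectors over the
#'   functional segments of the germline set (default: uniform for V and D;
#'   heavy J usage follows the strong JH1-over-JH2 bias, 7.6:1 between
#'   families; lambda-2 J usage favours the long J gene 2:1).
#' @param del_v,del_d5,del_d3,del_j mean nucleotides deleted at each coding
#'   end (geometric).
#' @param n_ins_lambda mean N nucleotides per junction (Poisson).
#' @param p_nt_prob probability of a palindromic addition at an untrimmed end.
#' @param light_chain_mode suppress N/P additions (single V-J junction).
#' @param error_rate per-base substitution rate applied to reads.
#' @param abundance_meanlog,abundance_sdlog lognormal clone abundance model.
#' @param depth total read pairs to simulate.
#' @param read_length read length (nt).
#' @param c_offset_range read 1 starts this many bases into the C gene
#'   (sampled uniformly per read), mirroring nested C-side priming.
#' @param seed RNG seed.
#' @return list of class \code{"recombination_params"}.
#' @export
recombination_params <- function(chain = "IGH",
                                 n_clones = 1000L,
                                 v_usage = NULL, d_usage = NULL, j_usage = NULL,
                                 del_v = NULL, del_d5 = NULL, del_d3 = NULL,
                                 del_j = NULL,
                                 n_ins_lambda = NULL, p_nt_prob = NULL,
                                 light_chain_mode = NULL,
                                 error_rate = 0,
                                 abundance_meanlog = 0, abundance_sdlog = 1.5,
                                 depth = 50000L, read_length = 150L,
                                 c_offset_range = c(24L, 42L),
                                 seed = 1L) {
  stopifnot(chain %in% ig_chains)
  heavy <- chain == "IGH"
  if (is.null(light_chain_mode)) light_chain_mode <- !heavy
  dflt_del <- if (light_chain_mode) 0.5 else 3
  p <- list(
    chain = chain, heavy = heavy, n_clones = as.integer(n_clones),
    v_usage = v_usage, d_usage = d_usage, j_usage = j_usage,
    del_v = if (is.null(del_v)) dflt_del else del_v,
    del_d5 = if (is.null(del_d5)) dflt_del else del_d5,
    del_d3 = if (is.null(del_d3)) dflt_del else del_d3,
    del_j = if (is.null(del_j)) dflt_del else del_j,
    n_ins_lambda = if (is.null(n_ins_lambda)) {
      if (light_chain_mode) 0 else 1.5
    } else n_ins_lambda,
    p_nt_prob = if (is.null(p_nt_prob)) {
      if (light_chain_mode) 0 else 0.5
    } else p_nt_prob,
    light_chain_mode = light_chain_mode,
    error_rate = error_rate,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    depth = as.integer(depth), read_length = as.integer(read_length),
    c_offset_range = as.integer(c_offset_range),
    seed = as.integer(seed)
  )
  stopifnot(p$del_v >= 0, p$n_ins_lambda >= 0, p$error_rate >= 0,
            p$error_rate <= 1)
  class(p) <- "recombination_params"
  p
}

#' @export
print.recombination_params <- function(x, ...) {
  cat(sprintf("recombination parameters: %s, %d clones, del means %.1f/%.1f/%.1f/%.1f nt, N mean %.1f, P prob %.2f%s\n",
              x$chain, x$n_clones, x$del_v, x$del_d5, x$del_d3, x$del_j,
              x$n_ins_lambda, x$p_nt_prob,
              if (x$light_chain_mode) " (light-chain mode)" else ""))
  invisible(x)
}

# geometric with given mean, redrawn while exceeding cap
rgeom_capped <- function(mean_del, cap) {
  if (mean_del <= 0) return(0L)
  p <- 1 / (1 + mean_del)
  repeat {
    d <- stats::rgeom(1L, p)
    if (d <= cap) return(as.integer(d))
  }
}

p_addition <- function(retained_end, p_prob) {
  if (p_prob <= 0 || nchar(retained_end) == 0L) return("")
  if (stats::runif(1) >= p_prob) return("")
  len <- sample(1:2, 1L)
  len <- min(len, nchar(retained_end))
  revcomp(substr(retained_end, nchar(retained_end) - len + 1L,
                 nchar(retained_end)))
}

n_addition <- function(lambda) {
  n <- if (lambda > 0) stats::rpois(1L, lambda) else 0L
  if (n == 0L) return("")
  random_dna(n)
}

usage_or_uniform <- function(usage, n) {
  if (is.null(usage)) rep(1 / n, n) else usage / sum(usage)
}

default_heavy_j_usage <- function(j) {
  # family 1 : family 2 = 7.6 : 1 overall
  w <- ifelse(j$family == 1L, 7.6 / sum(j$family == 1L),
              1 / sum(j$family == 2L))
  w / sum(w)
}

default_lambda2_j_usage <- function(j) {
  long <- !is.na(j$anchor_nt) & j$anchor_nt == max(j$anchor_nt)
  w <- ifelse(long, 2 / sum(long), 1 / sum(!long))
  w / sum(w)
}

#' Simulate V(D)J recombination
#'
#' Draws clones from a germline set: V/(D)/J chosen by usage, geometric
#' deletions at each coding end (redrawn when exceeding the available
#' sequence), palindromic additions at untrimmed ends, Poisson N additions
#' (suppressed in light-chain mode). The CDR3 junction runs from the
#' conserved 2nd-CYS codon (inclusive) to the J [FW]GxG anchor codon
#' (inclusive of the F/W).
#'
#' @param germ an \code{"ig_germline"} set (functional segments are used).
#' @param params a \code{\link{recombination_params}}.
#' @return data.frame of class \code{"ig_clonotype_truth"}: one row per clone
#'   with junction sequence, provenance (segments, deletions, insertions) and
#'   productivity.
#' @export
simulate_recombination <- function(germ, params) {
  stopifnot(inherits(germ, "ig_germline"), inherits(params, "recombination_params"))
  set.seed(params$seed)
  v <- germ[germ$kind == "V" & germ$functional, , drop = FALSE]
  j <- germ[germ$kind == "J" & germ$functional, , drop = FALSE]
  d <- germ[germ$kind == "D" & germ$functional, , drop = FALSE]
  if (nrow(v) == 0L || nrow(j) == 0L) stop("functional V and J segments required")
  use_d <- params$heavy && nrow(d) > 0L
  v_p <- usage_or_uniform(params$v_usage, nrow(v))
  j_p <- if (!is.null(params$j_usage)) {
    params$j_usage / sum(params$j_usage)
  } else if (params$heavy && length(unique(j$family)) > 1L) {
    default_heavy_j_usage(j)
  } else if (params$chain == "IGI4_lambda2" && length(unique(j$anchor_nt)) > 1L) {
    default_lambda2_j_usage(j)
  } else {
    rep(1 / nrow(j), nrow(j))
  }
  d_p <- if (use_d) usage_or_uniform(params$d_usage, nrow(d)) else NULL

  n <- params$n_clones
  out <- vector("list", n)
  for (i in seq_len(n)) {
    vi <- sample.int(nrow(v), 1L, prob = v_p)
    ji <- sample.int(nrow(j), 1L, prob = j_p)
    vseq <- v$seq[vi]
    tail_nt <- v$germ_cdr3_nt[vi]
    cys <- v$cys_start[vi]
    del_v <- rgeom_capped(params$del_v, tail_nt)
    v_part <- substr(vseq, cys, nchar(vseq) - del_v)
    p_v <- if (del_v == 0L) p_addition(v_part, params$p_nt_prob) else ""
    n1 <- n_addition(params$n_ins_lambda)

    if (use_d) {
      di <- sample.int(nrow(d), 1L, prob = d_p)
      dseq <- d$seq[di]
      del_d5 <- rgeom_capped(params$del_d5, nchar(dseq) - 1L)
      del_d3 <- rgeom_capped(params$del_d3, nchar(dseq) - 1L - del_d5)
      d_part <- substr(dseq, 1L + del_d5, nchar(dseq) - del_d3)
      p_d5 <- if (del_d5 == 0L) {
        # palindrome of the 5' retained end, prepended
        pal <- p_addition(revcomp(d_part), params$p_nt_prob)
        revcomp(pal)
      } else ""
      p_d3 <- if (del_d3 == 0L) p_addition(d_part, params$p_nt_prob) else ""
      n2 <- n_addition(params$n_ins_lambda)
      mid <- paste0(n1, p_d5, d_part, p_d3, n2)
      d_name <- d$name[di]
    } else {
      di <- NA_integer_; del_d5 <- NA_integer_; del_d3 <- NA_integer_
      mid <- n1
      d_name <- NA_character_
    }

    jseq <- j$seq[ji]
    anchor <- j$anchor_nt[ji]
    del_j <- rgeom_capped(params$del_j, anchor - 1L)
    j_part <- substr(jseq, 1L + del_j, anchor + 2L)
    p_j <- if (del_j == 0L) {
      pal <- p_addition(revcomp(j_part), params$p_nt_prob)
      revcomp(pal)
    } else ""

    junction <- paste0(v_part, p_v, mid, p_j, j_part)
    out[[i]] <- data.frame(
      clone_id = sprintf("clone%05d", i),
      v_name = v$name[vi], d_name = d_name, j_name = j$name[ji],
      del_v = del_v, del_d5 = del_d5, del_d3 = del_d3, del_j = del_j,
      n_ins = nchar(n1) + if (use_d) nchar(n2) else 0L,
      p_ins = nchar(p_v) + nchar(p_j) +
        if (use_d) nchar(p_d5) + nchar(p_d3) else 0L,
      junction = junction,
      junction_aa = translate_nt(junction),
      v_germ_cdr3_nt = tail_nt,
      productive = nchar(junction) %% 3L == 0L && !has_internal_stop(junction),
      stringsAsFactors = FALSE
    )
  }
  clones <- do.call(rbind, out)
  attr(clones, "params") <- params
  class(clones) <- c("ig_clonotype_truth", "data.frame")
  clones
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    hits <- which(stats::runif(length(ch)) < rate)
    for (i in hits) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired 5'RACE reads from clonotypes
#'
#' Per-clone read counts are multinomial over lognormal abundances. Read 1
#' starts 24-42 bp into the C gene and sequences back across the junction
#' (3'-5' on the transcript); read 2 sequences the 5' end of the V gene.
#' Substitution errors are applied at the configured flat rate; qualities are
#' emitted as constant Q37.
#'
#' @param clones an \code{"ig_clonotype_truth"} table.
#' @param germ the germline set the clones were drawn from (provides V, J and
#'   C sequences).
#' @param params the \code{\link{recombination_params}} used (depth,
#'   error rate, read geometry, seed).
#' @return list of class \code{"ig_sim_reads"}: \code{read1}, \code{read2}
#'   (data.frames with \code{id}, \code{seq}, \code{qual}), \code{clones}
#'   (with a \code{read_count} column appended) and \code{read_truth}
#'   (read id to clone id).
#' @export
simulate_reads <- function(clones, germ, params) {
  stopifnot(inherits(clones, "ig_clonotype_truth"), inherits(germ, "ig_germline"))
  set.seed(params$seed + 1L)
  stopifnot(params$depth > 0L)
  n <- nrow(clones)
  w <- stats::rlnorm(n, params$abundance_meanlog, params$abundance_sdlog)
  counts <- as.integer(stats::rmultinom(1L, params$depth, w / sum(w)))

  vmap <- germ[germ$kind == "V", , drop = FALSE]
  jmap <- germ[germ$kind == "J", , drop = FALSE]
  cseq <- germ$seq[germ$kind == "C"][1]
  if (is.na(cseq)) stop("germline set lacks a C segment")
  vrow <- match(clones$v_name, vmap$name)
  jrow <- match(clones$j_name, jmap$name)

  pre <- substr(vmap$seq[vrow], 1L, vmap$cys_start[vrow] - 1L)
  j_rest <- substring(jmap$seq[jrow], jmap$anchor_nt[jrow] + 3L)
  transcript <- paste0(pre, clones$junction, j_rest)
  c_break <- nchar(transcript) + 1L
  transcript <- paste0(transcript, substr(cseq, 1L, 60L))

  rl <- params$read_length
  ids <- character(0); r1 <- character(0); r2 <- character(0)
  truth_clone <- character(0)
  for (i in seq_len(n)) {
    k <- counts[i]
    if (k == 0L) next
    off <- sample(params$c_offset_range[1]:params$c_offset_range[2], k,
                  replace = TRUE)
    end1 <- pmin(c_break[i] + off - 1L, nchar(transcript[i]))
    start1 <- pmax(1L, end1 - rl + 1L)
    seq1 <- substring(transcript[i], start1, end1)
    seq2 <- rep(substr(transcript[i], 1L, min(rl, nchar(transcript[i]))), k)
    id <- sprintf("%s_r%04d", clones$clone_id[i], seq_len(k))
    ids <- c(ids, id); r1 <- c(r1, seq1); r2 <- c(r2, seq2)
    truth_clone <- c(truth_clone, rep(clones$clone_id[i], k))
  }
  r1 <- add_read_errors(revcomp_many(r1), params$error_rate)
  r2 <- add_read_errors(r2, params$error_rate)
  qual <- function(s) strrep("F", nchar(s))  # Q37
  clones$read_count <- counts
  out <- list(
    read1 = data.frame(id = ids, seq = r1, qual = vapply(r1, qual, character(1), USE.NAMES = FALSE),
                       stringsAsFactors = FALSE),
    read2 = data.frame(id = ids, seq = r2, qual = vapply(r2, qual, character(1), USE.NAMES = FALSE),
                       stringsAsFactors = FALSE),
    clones = clones,
    read_truth = data.frame(id = ids, clone_id = truth_clone,
                            stringsAsFactors = FALSE)
  )
  class(out) <- "ig_sim_reads"
  out
}

#' @export
print.ig_sim_reads <- function(x, ...) {
  cat(sprintf("simulated reads: %d pairs from %d clones (%d with >=1 read)\n",
              nrow(x$read1), nrow(x$clones), sum(x$clones$read_count > 0)))
  invisible(x)
}
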