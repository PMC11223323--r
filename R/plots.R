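# Base-graphics views of the repertoire statistics, mirroring the standard
# figures: saturation curves, rank-abundance with the D50 mark, and usage
# bars with between-fish standard deviation.

#' Plot a rarefaction curve
#'
#' @param curve output of \code{\link{rarefaction_curve}}.
#' @param add add to an existing plot.
#' @param ... passed to \code{lines}/\code{plot}.
#' @export
plot_rarefaction <- function(curve, add = FALSE, ...) {
  if (!add) {
    plot(curve$depth, curve$mean_unique, type = "l",
         xlab = "reads sampled", ylab = "unique CDR3s", ...)
  } else {
    graphics::lines(curve$depth, curve$mean_unique, ...)
  }
  invisible(curve)
}

#' Rank-abundance plot with the D50 mark
#'
#' @param clonotypes clonotype table.
#' @param ... passed to \code{plot}.
#' @export
plot_rank_abundance <- function(clonotypes, ...) {
  counts <- sort(clonotypes$duplicate_count, decreasing = TRUE)
  frac <- counts / sum(counts)
  plot(seq_along(frac), frac, log = "xy", type = "p", pch = 16, cex = 0.5,
       xlab = "clonotype rank", ylab = "fraction of repertoire", ...)
  dd <- d50(clonotypes)
  graphics::abline(v = dd / 100 * length(frac), lty = 2)
  invisible(dd)
}

#' Gene-usage bar plot with between-sample error bars
#'
#' @param samples named list of clonotype tables.
#' @param call \code{"v_call"} or \code{"j_call"}.
#' @param ... passed to \code{barplot}.
#' @export
plot_gene_usage <- function(samples, call = "v_call", ...) {
  us <- lapply(samples, gene_usage, call = call)
  genes <- sort(unique(unlist(lapply(us, names))))
  mat <- vapply(us, function(u) {
    full <- stats::setNames(numeric(length(genes)), genes)
    full[names(u)] <- u
    full
  }, numeric(length(genes)))
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  bp <- graphics::barplot(m, las = 2, ylab = "usage fraction",
                          ylim = c(0, max(m + s) * 1.1), ...)
  graphics::arrows(bp, m - s, bp, m + s, angle = 90, code = 3, length = 0.03)
  invisible(list(mean = m, sd = s))
}
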