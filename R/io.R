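# Readers and writers for the formats the pipeline touches: FASTA/FASTQ via
# Biostrings, GFF3 via rtracklayer/GenomicRanges, AIRR-style rearrangement
# TSVs, newick via ape, plus sample sheets and run manifests.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip allowed).
#' @return data.frame with \code{id}, \code{seq}, \code{qual} (phred+33
#'   strings).
#' @export
read_fastq <- function(path) {
  # metadata columns (none are written) are dropped by the quality scaling
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with \code{id}, \code{seq}, \code{qual}.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq,
                             "+", reads$qual)), con)
  invisible(path)
}

#' Write an annotation to GFF3
#'
#' Features are \code{V_gene_segment}, \code{D_gene_segment},
#' \code{J_gene_segment} and \code{C_gene_segment} with attributes
#' \code{Name}, \code{Functionality}, \code{Reasons}, \code{RSS_spacer} and
#' \code{Promoter_gap}; coordinates 1-based inclusive with a strand column.
#'
#' @param ann an \code{"ig_annotation"} (or a compatible segment table).
#' @param path output file.
#' @export
write_gff3 <- function(ann, path) {
  s <- if (inherits(ann, "ig_annotation")) ann$segments else ann
  seqid <- if (inherits(ann, "ig_annotation")) ann$genome_id else "genome"
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = s$start, end = s$end),
    strand = s$strand
  )
  S4Vectors::mcols(gr)$type <- paste0(s$kind, "_gene_segment")
  S4Vectors::mcols(gr)$source <- "igloci"
  S4Vectors::mcols(gr)$Name <- if (!is.null(s$name)) s$name else NA
  S4Vectors::mcols(gr)$Functionality <- s$functionality
  S4Vectors::mcols(gr)$Reasons <- if (!is.null(s$reasons)) s$reasons else NA
  S4Vectors::mcols(gr)$RSS_spacer <-
    if (!is.null(s$rss_spacer_class)) as.character(s$rss_spacer_class) else NA
  S4Vectors::mcols(gr)$Promoter_gap <-
    if (!is.null(s$promoter_gap)) as.character(s$promoter_gap) else NA
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a GFF3 file into a segment-like table
#'
#' @param path GFF3 file.
#' @return data.frame with coordinates, strand, type and attributes.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  names(df)[names(df) == "seqnames"] <- "seqid"
  df
}

#' Write an AIRR-style rearrangement table
#'
#' @param tab clonotype table.
#' @param path output TSV.
#' @export
write_airr_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an AIRR-style rearrangement table
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_airr_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' Expected columns: \code{sample_id}, \code{fish_id}, \code{chain},
#' \code{replicate_of} (empty when the sample is the primary replicate).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fish_id", "chain")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"replicate_of" %in% names(sheet)) sheet$replicate_of <- ""
  sheet$replicate_of[is.na(sheet$replicate_of)] <- ""
  sheet
}

#' Write a tree to newick
#'
#' @param tree an ape \code{"phylo"} object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a germline reference FASTA
#'
#' Headers carry key-value tags, e.g.
#' \code{">IGHV1_ref kind=V chain=IGH family=1 cys=238"}; \code{cys} is the
#' 1-based position of the 2nd-CYS codon in a V reference and \code{anchor}
#' the [FW]GxG anchor codon start in a J reference.
#'
#' @param path FASTA file.
#' @return data.frame with \code{name}, \code{kind}, \code{chain},
#'   \code{family}, \code{cys}, \code{anchor}, \code{seq}.
#' @export
read_germline_fasta <- function(path) {
  seqs <- read_fasta(path)
  hdr <- names(seqs)
  tag <- function(h, key) {
    m <- regmatches(h, regexpr(paste0("\\b", key, "=\\S+"), h))
    if (!length(m)) return(NA_character_)
    sub(paste0(key, "="), "", m)
  }
  out <- data.frame(
    name = vapply(strsplit(hdr, "\\s+"), `[`, character(1), 1L),
    kind = vapply(hdr, tag, character(1), "kind", USE.NAMES = FALSE),
    chain = vapply(hdr, tag, character(1), "chain", USE.NAMES = FALSE),
    family = suppressWarnings(as.integer(
      vapply(hdr, tag, character(1), "family", USE.NAMES = FALSE))),
    cys = suppressWarnings(as.integer(
      vapply(hdr, tag, character(1), "cys", USE.NAMES = FALSE))),
    anchor = suppressWarnings(as.integer(
      vapply(hdr, tag, character(1), "anchor", USE.NAMES = FALSE))),
    seq = unname(seqs),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$kind)) stop("germline FASTA headers must carry kind= tags")
  out
}

#' Write a germline reference FASTA with metadata tags
#'
#' @param refs data.frame as returned by \code{\link{read_germline_fasta}}.
#' @param path output file.
#' @export
write_germline_fasta <- function(refs, path) {
  hdr <- sprintf("%s kind=%s chain=%s", refs$name, refs$kind, refs$chain)
  hdr <- ifelse(!is.na(refs$family), paste0(hdr, " family=", refs$family), hdr)
  hdr <- ifelse(!is.na(refs$cys), paste0(hdr, " cys=", refs$cys), hdr)
  hdr <- ifelse(!is.na(refs$anchor), paste0(hdr, " anchor=", refs$anchor), hdr)
  write_fasta(stats::setNames(refs$seq, hdr), path)
}

#' Write a run manifest
#'
#' Records inputs (with md5 checksums), the effective configuration, the
#' seed and the package version for reproducibility.
#'
#' @param dir run output directory.
#' @param inputs character vector of input file paths.
#' @param config a configuration list.
#' @param seed the run seed.
#' @export
write_run_manifest <- function(dir, inputs = character(0), config = list(),
                               seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(
    sprintf("igloci_version: %s",
            as.character(utils::packageVersion("igloci"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %s", seed),
    "inputs:",
    if (length(inputs)) {
      sprintf("  - path: %s\n    md5: %s", inputs,
              unname(tools::md5sum(inputs)))
    } else "  []",
    "config:",
    vapply(names(config), function(k) {
      sprintf("  %s: %s", k, paste(format(config[[k]]), collapse = " "))
    }, character(1))
  )
  writeLines(manifest, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}
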