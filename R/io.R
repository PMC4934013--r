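# Plain-text file formats: FASTQ, FASTA, GMT, RNK, and the package's TSV
# exchange formats for transcript models, alignments, and region counts.
# Gzipped paths (*.gz) are handled transparently.

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write reads as FASTQ
#'
#' @param reads data frame `read_id`, `sequence`. Qualities are constant
#'   (`I`): the protocol uses no quality-based filtering.
#' @param path output path (`.gz` supported).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  con <- open_conn(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    strrep("I", nchar(reads$sequence))), con)
  invisible(path)
}

#' Read a FASTQ file into a read frame
#'
#' @param path FASTQ path (`.gz` supported).
#' @return data frame `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  con <- open_conn(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: line count not 4n")
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  data.frame(read_id = ids, sequence = lines[seq(2, length(lines), by = 4)],
             stringsAsFactors = FALSE)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path (`.gz` supported).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes (the GSEA
#' dialect).
#'
#' @param path GMT path.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  con <- open_conn(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a rank list in RNK format (gene TAB score)
#' @param path RNK path.
#' @return named numeric vector in file order.
#' @export
read_rnk <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "score"))
  stats::setNames(df$score, df$gene)
}

#' Write a rank list in RNK format
#' @param scores named numeric vector.
#' @param path output path.
#' @export
write_rnk <- function(scores, path) {
  stopifnot(!is.null(names(scores)))
  utils::write.table(data.frame(names(scores), unname(scores)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write / read transcript models as TSV
#' @param models a [transcript_models()] table.
#' @param path TSV path.
#' @export
write_models <- function(models, path) {
  utils::write.table(as.data.frame(models), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  transcript_models(df$gene_id, df$transcript_id, df$sequence,
                    df$cds_start, df$cds_end, df$isoform_abundance)
}

#' Write / read alignments as TSV
#' @param alignments alignment data frame (optionally duplicate-flagged).
#' @param path TSV path.
#' @export
write_alignments <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write / read a region count table as long-format TSV
#'
#' Columns: `gene`, `sample`, `assay`, `condition`, `region`, `count`.
#'
#' @param x a [region_counts()] object.
#' @param path TSV path.
#' @export
write_region_counts <- function(x, path) {
  stopifnot(inherits(x, "region_counts"))
  rows <- lapply(REGIONS, function(r) {
    m <- x[[r]]
    data.frame(gene = rep(rownames(m), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               assay = rep(x$samples$assay, each = nrow(m)),
               condition = rep(x$samples$condition, each = nrow(m)),
               region = r, count = as.vector(m), stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_counts
#' @export
read_region_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  genes <- unique(df$gene)
  samples <- unique(df[, c("sample", "assay", "condition")])
  rownames(samples) <- NULL
  grab <- function(r) {
    sub <- df[df$region == r, ]
    m <- matrix(0L, length(genes), nrow(samples),
                dimnames = list(genes, samples$sample))
    m[cbind(match(sub$gene, genes), match(sub$sample, samples$sample))] <-
      as.integer(sub$count)
    m
  }
  region_counts(grab("utr5"), grab("cds"), grab("utr3"), samples)
}
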