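# Core data containers shared across the pipeline.
#
# Transcript coordinates are 0-based half-open throughout, on the sense
# strand of the mature transcript: utr5 = [0, cds_start), cds = [cds_start,
# cds_end), utr3 = [cds_end, length).

REGIONS <- c("utr5", "cds", "utr3")

#' Build a transcript model table
#'
#' A transcript model records, per isoform, the transcript sequence, the
#' 5'UTR/CDS/3'UTR segmentation in 0-based half-open transcript coordinates,
#' and a relative isoform abundance used for abundance-weighted 5' UTR
#' statistics.
#'
#' @param gene_id,transcript_id character vectors, one entry per isoform.
#' @param sequence transcript sequences over A/C/G/T (U is accepted and
#'   converted to T).
#' @param cds_start,cds_end 0-based half-open CDS interval per isoform;
#'   `[0, cds_start)` is the 5' UTR and `[cds_end, nchar(sequence))` the
#'   3' UTR.
#' @param isoform_abundance non-negative relative abundance within the gene.
#' @return a `transcript_models` data frame with columns `gene_id`,
#'   `transcript_id`, `sequence`, `cds_start`, `cds_end`, `length`,
#'   `isoform_abundance`.
#' @export
transcript_models <- function(gene_id, transcript_id, sequence,
                              cds_start, cds_end, isoform_abundance = 1) {
  sequence <- toupper(gsub("U", "T", sequence, fixed = TRUE))
  df <- data.frame(
    gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    sequence = sequence,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    length = nchar(sequence),
    isoform_abundance = as.numeric(isoform_abundance),
    stringsAsFactors = FALSE
  )
  validate_transcript_models(df)
}

#' Validate a transcript model table
#'
#' Checks the interval invariants (regions contiguous, non-overlapping,
#' covering `[0, length)`), positive CDS length, unique transcript ids, and
#' positive per-gene abundance totals.
#'
#' @param models a data frame as produced by [transcript_models()].
#' @return the validated table, classed `transcript_models`.
#' @export
validate_transcript_models <- function(models) {
  need <- c("gene_id", "transcript_id", "sequence", "cds_start", "cds_end",
            "length", "isoform_abundance")
  if (!is.data.frame(models) || !all(need %in% names(models)))
    stop("transcript models need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(models$transcript_id))
    stop("transcript ids must be unique")
  with(models, {
    if (any(nchar(sequence) != length))
      stop("sequence length does not match 'length'")
    if (any(cds_start < 0 | cds_end <= cds_start | cds_end > length))
      stop("CDS interval must satisfy 0 <= cds_start < cds_end <= length")
    if (any(isoform_abundance < 0))
      stop("isoform abundances must be non-negative")
  })
  ab <- tapply(models$isoform_abundance, models$gene_id, sum)
  if (any(ab <= 0))
    stop("per-gene isoform abundances must sum to a positive value")
  class(models) <- unique(c("transcript_models", class(models)))
  models
}

#' Construct a region count table
#'
#' Gene x sample x region (5'UTR/CDS/3'UTR) table of non-negative integer
#' counts plus per-sample metadata. This is the package's exchange container
#' for ribosome-profiling, RNA-seq, and RiboTag IP/homogenate counts.
#'
#' @param utr5,cds,utr3 gene x sample integer matrices with identical
#'   dimnames.
#' @param samples data frame with columns `sample`, `assay` (one of
#'   `ribo`, `rna`, `ip`, `homogenate`) and `condition`; one row per column
#'   of the count matrices.
#' @return an object of class `region_counts`.
#' @export
region_counts <- function(utr5, cds, utr3, samples) {
  mats <- list(utr5 = as.matrix(utr5), cds = as.matrix(cds),
               utr3 = as.matrix(utr3))
  dn <- dimnames(mats$cds)
  for (r in REGIONS) {
    m <- mats[[r]]
    if (!identical(dim(m), dim(mats$cds)) || !identical(dimnames(m), dn))
      stop("region matrices must share dimensions and dimnames")
    if (any(m < 0) || any(m != round(m)))
      stop("counts must be non-negative integers")
    storage.mode(mats[[r]]) <- "integer"
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample", "assay", "condition") %in% names(samples)))
    stop("samples needs columns sample, assay, condition")
  if (!identical(as.character(samples$sample), colnames(mats$cds)))
    stop("samples$sample must match count matrix column names")
  structure(list(utr5 = mats$utr5, cds = mats$cds, utr3 = mats$utr3,
                 samples = samples),
            class = "region_counts")
}

#' Extract one region's gene x sample count matrix
#'
#' @param x a [region_counts()] object.
#' @param region one of `"utr5"`, `"cds"`, `"utr3"`.
#' @return integer matrix, genes x samples.
#' @export
region_matrix <- function(x, region = c("cds", "utr5", "utr3")) {
  stopifnot(inherits(x, "region_counts"))
  region <- match.arg(region)
  x[[region]]
}

#' Combine region count tables by sample
#'
#' Column-binds two or more [region_counts()] tables sharing the same gene
#' universe.
#'
#' @param ... `region_counts` objects.
#' @return a single `region_counts` object.
#' @export
bind_region_counts <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "region_counts")))
  genes <- rownames(xs[[1]]$cds)
  for (x in xs) {
    if (!identical(rownames(x$cds), genes))
      stop("gene universes differ between tables")
  }
  out <- lapply(REGIONS, function(r) do.call(cbind, lapply(xs, `[[`, r)))
  names(out) <- REGIONS
  samples <- do.call(rbind, lapply(xs, `[[`, "samples"))
  if (anyDuplicated(samples$sample)) stop("duplicate sample names")
  region_counts(out$utr5, out$cds, out$utr3, samples)
}

#' @export
print.region_counts <- function(x, ...) {
  cat("region_counts:", nrow(x$cds), "genes x", ncol(x$cds), "samples\n")
  cat("assays:", paste(unique(x$samples$assay), collapse = ", "),
      "| conditions:", paste(unique(x$samples$condition), collapse = ", "),
      "\n")
  invisible(x)
}

# validate an alignment table (AlignedFootprint contract)
validate_alignments <- function(alignments, models = NULL) {
  need <- c("gene_id", "transcript_id", "five_prime_pos", "length")
  if (!is.data.frame(alignments) || !all(need %in% names(alignments)))
    stop("alignments need columns: ", paste(need, collapse = ", "))
  if (any(alignments$five_prime_pos < 0))
    stop("five_prime_pos must be >= 0")
  if (!is.null(models)) {
    i <- match(alignments$transcript_id, models$transcript_id)
    if (anyNA(i)) stop("alignment transcript ids not all present in models")
    if (any(alignments$five_prime_pos + alignments$length > models$length[i]))
      stop("alignment extends past transcript end")
  }
  invisible(alignments)
}

# evaluate code under a fixed RNG seed without clobbering the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# region of a 0-based 5' position given cds bounds (single-assignment rule)
region_of <- function(pos, cds_start, cds_end) {
  ifelse(pos < cds_start, "utr5", ifelse(pos < cds_end, "cds", "utr3"))
}
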