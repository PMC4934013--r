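# Region counting, median-of-ratios normalization, translation efficiency,
# RiboTag enrichment, qPCR abundance conversion.

#' Count alignments per gene and region
#'
#' Assigns each (uniquely mapped) alignment to exactly one region by its 5'
#' end position and sums per gene across that gene's transcripts. Both
#' duplicate-flagged and unflagged alignments are counted. The gene universe
#' is taken from `models`, so genes without alignments appear with zeros.
#'
#' @param alignments alignment data frame.
#' @param models a [transcript_models()] table.
#' @param sample,assay,condition metadata for the single emitted sample.
#' @return a one-sample [region_counts()].
#' @export
count_regions <- function(alignments, models, sample = "sample_1",
                          assay = "ribo", condition = "untreated") {
  models <- validate_transcript_models(models)
  genes <- unique(models$gene_id)
  if (nrow(alignments) > 0) {
    validate_alignments(alignments, models)
    i <- match(alignments$transcript_id, models$transcript_id)
    reg <- region_of(alignments$five_prime_pos, models$cds_start[i],
                     models$cds_end[i])
    tab <- table(factor(alignments$gene_id, levels = genes),
                 factor(reg, levels = REGIONS))
  } else {
    tab <- matrix(0L, length(genes), 3, dimnames = list(genes, REGIONS))
  }
  one <- function(r) {
    m <- matrix(as.integer(tab[, r]), ncol = 1,
                dimnames = list(genes, sample))
    m
  }
  region_counts(one("utr5"), one("cds"), one("utr3"),
                data.frame(sample = sample, assay = assay,
                           condition = condition, stringsAsFactors = FALSE))
}

#' Median-of-ratios size factors
#'
#' The DESeq2 normalization formula, implemented directly: per gene, the
#' geometric mean across samples is the reference (genes with any zero count
#' are excluded); each sample's factor is the median over included genes of
#' `count / reference`.
#'
#' @param counts gene x sample numeric matrix of non-negative counts.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lc <- log(counts)
  gm <- rowMeans(lc)
  use <- is.finite(gm)
  if (!any(use))
    stop("no gene has nonzero counts in all samples; cannot normalize")
  sf <- apply(lc[use, , drop = FALSE], 2,
              function(col) exp(stats::median(col - gm[use])))
  if (is.null(names(sf))) names(sf) <- colnames(counts)
  sf
}

#' Translation efficiency from matched ribosome-profiling and RNA-seq counts
#'
#' Normalizes each assay by its own median-of-ratios size factors and
#' divides normalized footprint counts by normalized RNA counts, CDS counts
#' only. `per_sample` mode computes one TE per matched sample pair and
#' filters genes with fewer than 37 raw counts in either assay;
#' `group` mode averages the per-sample TEs over all samples in the group
#' and raises the raw-count threshold to 75 (required in every sample of
#' both assays). Thresholds apply to raw counts, which guarantees positive
#' denominators without pseudocounts.
#'
#' @param ribo_counts,rna_counts gene x sample matrices of raw CDS counts;
#'   columns are matched pairs (sample j of `ribo_counts` pairs with sample
#'   j of `rna_counts`), or [region_counts()] objects (CDS is extracted).
#' @param mode `"per_sample"` or `"group"`.
#' @param min_count raw-count threshold; defaults to 37 (`per_sample`) or
#'   75 (`group`).
#' @return data frame with columns `gene`, (`sample` in per_sample mode),
#'   `te`, `log2_te`, `passed_threshold`; `te` is `NA` where the threshold
#'   fails.
#' @export
translation_efficiency <- function(ribo_counts, rna_counts,
                                   mode = c("per_sample", "group"),
                                   min_count = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_count)) min_count <- if (mode == "per_sample") 37 else 75
  ribo <- cds_matrix(ribo_counts)
  rna <- cds_matrix(rna_counts)
  if (!identical(rownames(ribo), rownames(rna)))
    stop("gene universes of the two assays must match")
  if (ncol(ribo) != ncol(rna))
    stop("need matched sample pairs across assays")
  sfr <- size_factors(ribo)
  sfn <- size_factors(rna)
  nr <- sweep(ribo, 2, sfr, "/")
  nn <- sweep(rna, 2, sfn, "/")
  te_mat <- nr / nn

  if (mode == "per_sample") {
    passed <- ribo >= min_count & rna >= min_count
    out <- data.frame(
      gene = rep(rownames(ribo), ncol(ribo)),
      sample = rep(colnames(ribo), each = nrow(ribo)),
      te = ifelse(as.vector(passed), as.vector(te_mat), NA_real_),
      stringsAsFactors = FALSE)
    out$log2_te <- log2(out$te)
    out$passed_threshold <- as.vector(passed)
  } else {
    passed <- apply(ribo >= min_count, 1, all) &
      apply(rna >= min_count, 1, all)
    te <- rowMeans(te_mat)
    out <- data.frame(gene = rownames(ribo),
                      te = ifelse(passed, te, NA_real_),
                      stringsAsFactors = FALSE)
    out$log2_te <- log2(out$te)
    out$passed_threshold <- passed
  }
  rownames(out) <- NULL
  out
}

cds_matrix <- function(x) {
  if (inherits(x, "region_counts")) region_matrix(x, "cds") else as.matrix(x)
}

#' RiboTag enrichment score
#'
#' Normalizes IP and homogenate counts jointly by median-of-ratios size
#' factors and scores each gene as mean normalized IP over mean normalized
#' homogenate. Genes with zero normalized homogenate counts are undefined
#' (`NA`, reported via message).
#'
#' @param ip_counts,homogenate_counts gene x replicate matrices of raw CDS
#'   counts (or [region_counts()]; CDS extracted), same gene universe.
#' @return data frame `gene`, `score` (`NA` where undefined).
#' @export
ribotag_enrichment_score <- function(ip_counts, homogenate_counts) {
  ip <- cds_matrix(ip_counts)
  hom <- cds_matrix(homogenate_counts)
  if (!identical(rownames(ip), rownames(hom)))
    stop("gene universes must match")
  joint <- cbind(ip, hom)
  sf <- size_factors(joint)
  norm <- sweep(joint, 2, sf, "/")
  mi <- rowMeans(norm[, seq_len(ncol(ip)), drop = FALSE])
  mh <- rowMeans(norm[, ncol(ip) + seq_len(ncol(hom)), drop = FALSE])
  undef <- mh == 0
  if (any(undef))
    message(sum(undef), " gene(s) with zero homogenate counts excluded")
  data.frame(gene = rownames(ip),
             score = ifelse(undef, NA_real_, mi / mh),
             stringsAsFactors = FALSE)
}

#' Convert qPCR CQ values to max-normalized abundances
#'
#' Applies `abundance = 2^(1 - CQ)` per fraction and divides by the maximum
#' so the most abundant fraction is exactly 1.
#'
#' @param cq_values numeric vector of (triplicate-averaged) CQ values, one
#'   per polysome fraction.
#' @return numeric vector of normalized abundances with max exactly 1.
#' @export
cq_to_abundance <- function(cq_values) {
  if (length(cq_values) == 0) stop("empty CQ vector")
  a <- 2^(1 - cq_values)
  a / max(a)
}
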