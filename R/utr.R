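# 5' UTR feature analysis: ribosomal density flags, uAUG detection,
# abundance-weighted UTR length/GC, binned median TE, Mann-Whitney tests.

#' Flag genes with 5' UTR ribosomal density
#'
#' A gene has 5' UTR ribosomal density iff at least `min_reads` ribosome
#' footprints map to its 5' UTR (ribosome counts only, summed across the
#' supplied ribo samples).
#'
#' @param counts a [region_counts()] (ribo assay) or gene x sample matrix of
#'   5' UTR footprint counts.
#' @param min_reads minimum footprints (default 1).
#' @return named logical vector over genes.
#' @export
utr5_density_flags <- function(counts, min_reads = 1L) {
  m <- if (inherits(counts, "region_counts")) {
    ribo <- counts$samples$assay == "ribo"
    if (!any(ribo)) stop("no ribo samples in counts")
    counts$utr5[, ribo, drop = FALSE]
  } else as.matrix(counts)
  rowSums(m) >= min_reads
}

#' Scan a 5' UTR for upstream AUGs
#'
#' Substring scan for AUG/ATG (T and U equivalent, case-insensitive) in any
#' frame; overlapping occurrences are counted at every start position.
#'
#' @param utr5_sequence character vector of 5' UTR sequences.
#' @return data frame `has_uaug`, `n_uaug`, one row per input sequence.
#' @export
uaug_scan <- function(utr5_sequence) {
  s <- gsub("U", "T", toupper(as.character(utr5_sequence)), fixed = TRUE)
  hits <- gregexpr("(?=ATG)", s, perl = TRUE)
  n <- vapply(hits, function(h) if (h[1] == -1L) 0L else length(h), 0L)
  data.frame(has_uaug = n > 0L, n_uaug = n,
             row.names = names(utr5_sequence))
}

#' Abundance-weighted 5' UTR length and GC content per gene
#'
#' Per gene, the isoform-abundance-weighted mean of 5' UTR length and of
#' the per-isoform 5' UTR GC fraction:
#' `length_g = sum_t a_t len_t / sum_t a_t`. Invariant to rescaling all
#' abundances of a gene by a constant. Genes whose abundances sum to zero,
#' or with no annotated 5' UTR on any isoform, are excluded (message).
#'
#' @param models a [transcript_models()] table.
#' @return data frame `gene`, `utr5_length`, `utr5_gc`.
#' @export
weighted_utr5_stats <- function(models) {
  models <- validate_transcript_models(models)
  ab_tot <- tapply(models$isoform_abundance, models$gene_id, sum)
  zero_ab <- names(ab_tot)[ab_tot == 0]
  if (length(zero_ab))
    message(length(zero_ab), " gene(s) with zero total abundance excluded")
  keep <- !(models$gene_id %in% zero_ab)
  m <- models[keep, , drop = FALSE]
  u5 <- substr(m$sequence, 1L, m$cds_start)
  len <- m$cds_start
  gc <- gc_fraction(u5)
  w <- m$isoform_abundance
  wlen <- tapply(len * w, m$gene_id, sum) / tapply(w, m$gene_id, sum)
  # GC is weighted among isoforms with a non-empty UTR5
  has5 <- len > 0
  wgc <- tapply(ifelse(has5, gc * w, 0), m$gene_id, sum) /
    tapply(ifelse(has5, w, 0), m$gene_id, sum)
  no_utr <- names(wlen)[!is.finite(wgc) | wlen == 0]
  if (length(no_utr))
    message(length(no_utr), " gene(s) without annotated 5' UTR excluded")
  genes <- setdiff(names(wlen), no_utr)
  data.frame(gene = genes,
             utr5_length = as.numeric(wlen[genes]),
             utr5_gc = as.numeric(wgc[genes]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median log2 TE by GC-content and length bins
#'
#' Sorts genes into user-specified GC and 5'UTR-length bins and reports the
#' median CDS log2 TE per marginal bin and per (GC, length) cell; empty
#' bins are `NA`.
#'
#' @param records data frame with columns `utr5_gc`, `utr5_length`,
#'   `cds_log2_te`.
#' @param gc_breaks,length_breaks bin edges passed to [cut()]
#'   (`include.lowest = TRUE`, right-open except the last).
#' @return list with `by_gc`, `by_length` (data frames `bin`, `n`,
#'   `median_te`) and `grid` (GC-bin x length-bin median matrix).
#' @export
binned_median_te <- function(records,
                             gc_breaks = seq(0, 1, by = 0.1),
                             length_breaks = c(0, 50, 100, 200, 400, Inf)) {
  stopifnot(all(c("utr5_gc", "utr5_length", "cds_log2_te") %in%
                names(records)))
  rec <- records[is.finite(records$cds_log2_te), , drop = FALSE]
  gcb <- cut(rec$utr5_gc, gc_breaks, include.lowest = TRUE, right = FALSE)
  lnb <- cut(rec$utr5_length, length_breaks, include.lowest = TRUE,
             right = FALSE)
  marg <- function(f) {
    med <- tapply(rec$cds_log2_te, f, stats::median)
    data.frame(bin = levels(f), n = as.integer(table(f)),
               median_te = as.numeric(med[levels(f)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  grid <- tapply(rec$cds_log2_te, list(gcb, lnb), stats::median)
  list(by_gc = marg(gcb), by_length = marg(lnb), grid = grid)
}

#' Mann-Whitney U test (exact for small samples, midrank ties)
#'
#' Computes U for `group_a` by rank sums with midranks for ties. For
#' `length(a) + length(b) <= exact_limit` the two-sided p value is computed
#' by complete enumeration of group assignments; otherwise by normal
#' approximation with tie correction and continuity correction. The star
#' annotation follows the conventional thresholds (`*` p <= 0.05, `**`
#' p <= 0.01, `***` p <= 0.001).
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param exact_limit largest pooled size for exact enumeration
#'   (default 12).
#' @return list `u`, `p`, `method` (`"exact"`/`"normal"`), `stars`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_limit = 12L) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  na <- length(a)
  nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  tot <- na * nb

  if (na + nb <= exact_limit) {
    sel <- utils::combn(na + nb, na)
    us <- colSums(matrix(r[sel], nrow = na)) - na * (na + 1) / 2
    lo <- min(u, tot - u)
    hi <- max(u, tot - u)
    p <- (sum(us <= lo + 1e-9) + sum(us >= hi - 1e-9)) / ncol(sel)
    p <- min(1, p)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - tot / 2)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  stars <- if (p <= 0.001) "***" else if (p <= 0.01) "**"
           else if (p <= 0.05) "*" else ""
  list(u = u, p = p, method = method, stars = stars)
}

#' Median TE of uAUG-bearing vs uAUG-free genes, by cell-type stratum
#'
#' Among genes with 5' UTR ribosomal density, compares CDS log2 TE between
#' uAUG-bearing and uAUG-free genes with a Mann-Whitney U test, for all
#' genes and within each supplied cell-type-specific gene list. Strata with
#' an empty group are skipped (message).
#'
#' @param records data frame with columns `gene`, `has_density`,
#'   `has_uaug`, `cds_log2_te`.
#' @param cell_type_gene_lists optional named list of gene-id vectors.
#' @return data frame `stratum`, `n_uaug`, `n_no_uaug`, `median_te_uaug`,
#'   `median_te_no_uaug`, `delta_median`, `u`, `p`, `stars`.
#' @export
uaug_te_comparison <- function(records, cell_type_gene_lists = NULL) {
  stopifnot(all(c("gene", "has_density", "has_uaug", "cds_log2_te") %in%
                names(records)))
  rec <- records[records$has_density & is.finite(records$cds_log2_te), ,
                 drop = FALSE]
  strata <- c(list(all = rec$gene), cell_type_gene_lists)
  rows <- lapply(names(strata), function(nm) {
    sub <- rec[rec$gene %in% strata[[nm]], , drop = FALSE]
    g1 <- sub$cds_log2_te[sub$has_uaug]
    g0 <- sub$cds_log2_te[!sub$has_uaug]
    if (length(g1) == 0 || length(g0) == 0) {
      message("stratum '", nm, "' skipped (empty group)")
      return(NULL)
    }
    mw <- mann_whitney_u(g1, g0)
    data.frame(stratum = nm, n_uaug = length(g1), n_no_uaug = length(g0),
               median_te_uaug = stats::median(g1),
               median_te_no_uaug = stats::median(g0),
               delta_median = stats::median(g1) - stats::median(g0),
               u = mw$u, p = mw$p, stars = mw$stars,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
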