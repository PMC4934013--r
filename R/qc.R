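# Library-quality diagnostics: 3-nt periodicity power spectrum, gene-body
# distribution, saturation under downsampling, between-library correlation.

#' Power spectrum of 5' mapping positions (3-nt periodicity)
#'
#' Builds a metagene series of 5'-end counts at offsets `0..window-1` from
#' each CDS start (CDS-mapped alignments only, transcripts shorter than the
#' window contribute their available prefix), subtracts the series mean, and
#' takes the discrete Fourier transform. Ribosome-profiling libraries show a
#' dominant peak at 1/3 nt^-1, reflecting single-codon translocation.
#'
#' Power is scaled as `|X_k|^2 / window^2` so that the total over all
#' `window` bins equals the (population) variance of the mean-subtracted
#' series (Parseval identity).
#'
#' @param alignments alignment data frame.
#' @param models a [transcript_models()] table.
#' @param window metagene window in nt from the CDS start (default 300).
#' @return object of class `spectrum_result`: list with `frequencies`
#'   (nt^-1 grid in `[0, 0.5]`), `power`, `peak_frequency` (argmax over
#'   non-zero frequencies), `total_power` (full-spectrum sum), `series`.
#' @export
periodicity_spectrum <- function(alignments, models, window = 300L) {
  models <- validate_transcript_models(models)
  validate_alignments(alignments, models)
  i <- match(alignments$transcript_id, models$transcript_id)
  d <- alignments$five_prime_pos - models$cds_start[i]
  in_cds <- d >= 0 & alignments$five_prime_pos < models$cds_end[i]
  if (!any(in_cds)) stop("no CDS-mapped alignments")
  d <- d[in_cds]
  d <- d[d < window]
  counts <- tabulate(d + 1L, nbins = window)
  x <- counts - mean(counts)
  pw <- Mod(stats::fft(x))^2 / window^2
  freq <- (seq_len(window) - 1L) / window
  half <- freq <= 0.5 + 1e-12
  nonzero <- half & freq > 0
  peak <- freq[nonzero][which.max(pw[nonzero])]
  structure(list(frequencies = freq[half], power = pw[half],
                 peak_frequency = peak, total_power = sum(pw),
                 series = x),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("periodicity spectrum: peak at", format(x$peak_frequency, digits = 4),
      "nt^-1 over", length(x$series), "nt window\n")
  invisible(x)
}

#' Gene-body distribution of mapped reads
#'
#' Assigns each alignment to exactly one region by its 5' end position
#' (single-assignment rule) and returns the region fractions, which sum
#' to 1. Ribosome-profiling libraries show a strong CDS preference with more
#' 5'UTR than 3'UTR density.
#'
#' @param alignments alignment data frame.
#' @param models a [transcript_models()] table.
#' @return named numeric `c(utr5, cds, utr3)` fractions.
#' @export
gene_body_distribution <- function(alignments, models) {
  if (nrow(alignments) == 0) stop("no alignments")
  models <- validate_transcript_models(models)
  validate_alignments(alignments, models)
  i <- match(alignments$transcript_id, models$transcript_id)
  reg <- region_of(alignments$five_prime_pos, models$cds_start[i],
                   models$cds_end[i])
  tab <- table(factor(reg, levels = REGIONS))
  stats::setNames(as.numeric(tab) / nrow(alignments), REGIONS)
}

#' Saturation analysis by downsampling
#'
#' Samples alignments without replacement at each fraction using a single
#' fixed permutation (nested subsamples), so both curves are monotone by
#' construction, and reports genes detected (>= 1 alignment) and unique
#' fragments (distinct `(transcript_id, five_prime_pos, length)` keys).
#'
#' @param alignments alignment data frame.
#' @param fractions proportions in `[0, 1]`; the value at 1.0 equals the
#'   full-data statistic.
#' @param seed RNG seed for the permutation.
#' @return object of class `saturation_curve`: data frame `fraction`,
#'   `n_reads`, `genes_detected`, `unique_fragments`, with the seed as an
#'   attribute.
#' @export
saturation_analysis <- function(alignments, fractions = seq(0.1, 1, 0.1),
                                seed = 1L) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  n <- nrow(alignments)
  fractions <- sort(fractions)
  perm <- with_seed(seed, sample.int(max(n, 1L)))
  key <- paste(alignments$transcript_id, alignments$five_prime_pos,
               alignments$length, sep = "\r")
  res <- lapply(fractions, function(f) {
    k <- floor(f * n)
    idx <- if (k > 0) perm[seq_len(k)] else integer(0)
    data.frame(fraction = f, n_reads = k,
               genes_detected = length(unique(alignments$gene_id[idx])),
               unique_fragments = length(unique(key[idx])))
  })
  out <- do.call(rbind, res)
  attr(out, "seed") <- seed
  class(out) <- c("saturation_curve", class(out))
  out
}

#' Pearson correlation of log-transformed per-gene counts
#'
#' Restricts to genes present in both tables, applies `log2(count + 1)`,
#' and returns the Pearson correlation, as used to compare libraries made
#' with different protocols.
#'
#' @param table_a,table_b named numeric vectors of per-gene counts.
#' @return Pearson r in `[-1, 1]`.
#' @export
count_correlation <- function(table_a, table_b) {
  stopifnot(!is.null(names(table_a)), !is.null(names(table_b)))
  common <- intersect(names(table_a), names(table_b))
  if (length(common) < 3) stop("need at least 3 shared genes")
  stats::cor(log2(table_a[common] + 1), log2(table_b[common] + 1))
}
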