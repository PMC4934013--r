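# Pre-ranked "classic" GSEA with gene-set permutation NES/p/FDR, TE-binned
# gene-set construction, and the GO cell-type-specificity margin rule.

#' Bin genes into TE gene sets
#'
#' Constructs equal-width bins of `width` log2 TE units with edges anchored
#' at the median (`median + m * width` for integer m) covering the observed
#' range. Bins are half-open `[low, high)` with the topmost bin closed, so
#' each thresholded gene falls in exactly one bin; empty bins are dropped.
#' The bin count is emergent from the data range, not imposed.
#'
#' @param log2_te named numeric vector of log2 TE values (thresholded
#'   genes).
#' @param width bin width in log2 TE units (default 0.75).
#' @return named list of gene-id vectors with attributes `centers` (bin
#'   centers, log2 TE units), `edges`, and `width`.
#' @export
te_bins <- function(log2_te, width = 0.75) {
  stopifnot(width > 0, !is.null(names(log2_te)))
  log2_te <- log2_te[is.finite(log2_te)]
  if (length(log2_te) == 0) stop("no finite TE values")
  med <- stats::median(log2_te)
  if (diff(range(log2_te)) == 0) {
    sets <- list(names(log2_te))
    names(sets) <- sprintf("TE_bin_[%.3g,%.3g]", med - width / 2,
                           med + width / 2)
    attr(sets, "centers") <- med
    attr(sets, "edges") <- med + c(-0.5, 0.5) * width
    attr(sets, "width") <- width
    return(sets)
  }
  m_lo <- floor((min(log2_te) - med) / width)
  m_hi <- ceiling((max(log2_te) - med) / width)
  if (med + m_hi * width < max(log2_te)) m_hi <- m_hi + 1L
  edges <- med + (m_lo:m_hi) * width
  bin <- findInterval(log2_te, edges, rightmost.closed = TRUE)
  sets <- split(names(log2_te), bin)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  keep <- as.integer(names(sets))
  names(sets) <- sprintf("TE_bin_[%.3g,%.3g)", edges[keep],
                         edges[keep + 1])
  attr(sets, "centers") <- centers[keep]
  attr(sets, "edges") <- edges
  attr(sets, "width") <- width
  sets
}

# classic (unweighted) enrichment score from sorted 1-based hit positions.
# Running statistic: +1/N_hit at hits, -1/N_miss at misses; ES is the
# signed maximum deviation from zero. Between hits the statistic decreases
# linearly, so extrema occur just after or just before hits; positive
# candidates are the after-hit values, negative candidates the before-hit
# values (and 0). Ties in magnitude resolve to the positive side.
gsea_es_positions <- function(p, N) {
  nh <- length(p)
  nm <- N - nh
  if (nh == 0L) stop("empty hit set")
  if (nm == 0L) stop("gene set equals the entire rank list")
  i <- seq_len(nh)
  after <- i / nh - (p - i) / nm
  before <- (i - 1) / nh - (p - i) / nm
  mx <- max(after)
  mn <- min(before, 0)
  # ties in magnitude (within float tolerance) resolve to the positive side
  if (mx >= -mn - 1e-12) mx else mn
}

#' Pre-ranked classic GSEA with gene-set permutation
#'
#' Runs unweighted ("classic") pre-ranked GSEA for each gene set against a
#' descending rank list: the running statistic increments `1/N_hit` at set
#' members and decrements `1/N_miss` otherwise, and the enrichment score
#' (ES) is its signed maximum deviation. The null is built from random
#' same-size gene sets drawn from the list (`n_perm` permutations, fixed
#' seed); NES divides ES by the mean of same-sign null ES values; the
#' nominal p value is one-sided within the matching sign; FDR q follows the
#' GSEA procedure (ratio of normalized-null to observed tail fractions,
#' clipped to at most 1).
#'
#' @param rank_list named numeric vector (will be ordered with
#'   [rank_list()]: descending score, ties broken by gene id).
#' @param gene_sets named list of gene-id vectors; each set must intersect
#'   the list (sets with empty intersection are dropped with a warning) and
#'   must not equal the entire list.
#' @param n_perm number of gene-set permutations (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return object of class `gsea_result`: data frame `set`, `size`, `es`,
#'   `nes`, `p`, `fdr`, with `n_perm` and `seed` attributes.
#' @export
preranked_gsea <- function(rank_list, gene_sets, n_perm = 1000L, seed = 1L) {
  rl <- rank_list(rank_list)
  N <- length(rl)
  genes <- names(rl)
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))

  pos_list <- lapply(gene_sets, function(s) which(genes %in% s))
  empty <- vapply(pos_list, length, 1L) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) with empty intersection dropped")
    pos_list <- pos_list[!empty]
  }
  if (length(pos_list) == 0) stop("no usable gene sets")
  sizes <- vapply(pos_list, length, 1L)
  if (any(sizes == N))
    stop("a gene set equals the entire rank list (no misses)")

  es <- vapply(pos_list, gsea_es_positions, numeric(1), N = N)

  null_es <- with_seed(seed, {
    lapply(sizes, function(k)
      vapply(seq_len(n_perm),
             function(b) gsea_es_positions(sort(sample.int(N, k)), N),
             numeric(1)))
  })

  norm_one <- function(e, pos_mean, neg_mean) {
    ifelse(e >= 0,
           if (is.finite(pos_mean) && pos_mean > 0) e / pos_mean else NA_real_,
           if (is.finite(neg_mean) && neg_mean < 0) -e / neg_mean else NA_real_)
  }
  nes <- numeric(length(es))
  pval <- numeric(length(es))
  null_norm <- vector("list", length(es))
  for (s in seq_along(es)) {
    nn <- null_es[[s]]
    pm <- mean(nn[nn > 0])
    nm <- mean(nn[nn < 0])
    nes[s] <- norm_one(es[s], pm, nm)
    if (es[s] >= 0) {
      denom <- sum(nn >= 0)
      pval[s] <- if (denom > 0) sum(nn >= es[s]) / denom else NA_real_
    } else {
      denom <- sum(nn < 0)
      pval[s] <- if (denom > 0) sum(nn <= es[s]) / denom else NA_real_
    }
    null_norm[[s]] <- norm_one(nn, pm, nm)
  }
  pooled <- unlist(null_norm)
  pooled <- pooled[is.finite(pooled)]
  fdr <- vapply(seq_along(nes), function(s) {
    v <- nes[s]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num <- if (any(pooled >= 0)) sum(pooled >= v) / sum(pooled >= 0) else NA
      den <- sum(nes >= v, na.rm = TRUE) / max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      num <- if (any(pooled < 0)) sum(pooled <= v) / sum(pooled < 0) else NA
      den <- sum(nes <= v, na.rm = TRUE) / max(1, sum(nes < 0, na.rm = TRUE))
    }
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(set = names(pos_list), size = sizes, es = es,
                    nes = nes, p = pval, fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("gsea_result", class(out))
  out
}

#' NES matrix of TE bins against cell-type rank lists
#'
#' Runs one pre-ranked GSEA per cell-type rank list against the TE-binned
#' gene sets and collects the NES values into a cell-type x TE-bin matrix
#' (bins ordered by TE), the heatmap summarizing which translation regimes
#' each cell type's specific genes occupy.
#'
#' @param te_bin_sets gene sets from [te_bins()].
#' @param rank_lists named list of named score vectors, one per cell type.
#' @param n_perm,seed passed to [preranked_gsea()].
#' @return list with `nes` (matrix, cell types x bins), `results` (per
#'   cell type [preranked_gsea()] outputs), `bin_centers`.
#' @export
nes_heatmap <- function(te_bin_sets, rank_lists, n_perm = 1000L, seed = 1L) {
  stopifnot(length(te_bin_sets) > 0, length(rank_lists) > 0,
            !is.null(names(rank_lists)))
  res <- lapply(rank_lists, preranked_gsea, gene_sets = te_bin_sets,
                n_perm = n_perm, seed = seed)
  nes <- t(vapply(res, function(r)
    r$nes[match(names(te_bin_sets), r$set)],
    numeric(length(te_bin_sets))))
  dimnames(nes) <- list(names(rank_lists), names(te_bin_sets))
  list(nes = nes, results = res,
       bin_centers = attr(te_bin_sets, "centers"))
}

#' Assign gene ontologies to cell types by NES margin
#'
#' A GO term is assigned to its argmax cell type iff the top NES is at
#' least `margin` units higher than the runner-up NES; otherwise it is
#' unassigned (two equal maxima give margin zero). Optionally reports the
#' median log2 TE of each assigned term's member genes.
#'
#' @param nes_matrix GO x cell-type NES matrix with dimnames.
#' @param margin required NES lead (default 3).
#' @param go_sets optional named list of member genes per GO term.
#' @param log2_te optional named log2 TE vector for the median-TE column.
#' @return data frame `go`, `cell_type` (`NA` if unassigned), `top_nes`,
#'   `runner_up_nes`, `nes_margin`, `assigned`, and `median_te` when
#'   `go_sets` and `log2_te` are supplied.
#' @export
go_cell_type_assignment <- function(nes_matrix, margin = 3,
                                    go_sets = NULL, log2_te = NULL) {
  nes_matrix <- as.matrix(nes_matrix)
  if (ncol(nes_matrix) < 2) stop("need >= 2 cell types")
  top_idx <- apply(nes_matrix, 1, which.max)
  top <- nes_matrix[cbind(seq_len(nrow(nes_matrix)), top_idx)]
  runner <- vapply(seq_len(nrow(nes_matrix)), function(i)
    max(nes_matrix[i, -top_idx[i]]), numeric(1))
  lead <- top - runner
  assigned <- lead >= margin - 1e-12
  out <- data.frame(
    go = rownames(nes_matrix),
    cell_type = ifelse(assigned, colnames(nes_matrix)[top_idx],
                       NA_character_),
    top_nes = top, runner_up_nes = runner, nes_margin = lead,
    assigned = assigned, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(go_sets) && !is.null(log2_te)) {
    out$median_te <- vapply(out$go, function(g) {
      members <- intersect(go_sets[[g]], names(log2_te))
      if (length(members) == 0) NA_real_
      else stats::median(log2_te[members])
    }, numeric(1), USE.NAMES = FALSE)
  }
  out
}
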