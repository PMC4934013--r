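# Differential translation efficiency between conditions, a permutation
# substitute for the external GLM-based differential-TE tool, and TOP-motif
# overlap summaries. Output columns clearly name the substitute statistic.

#' Treated-vs-untreated TE and RNA fold changes
#'
#' Log2 ratios of group TEs (treated over untreated) and, when RNA count
#' matrices are supplied, of size-factor-normalized RNA means. Records are
#' produced only for genes passing the group thresholds in both conditions.
#'
#' @param te_treated,te_untreated group-mode tables from
#'   [translation_efficiency()].
#' @param rna_treated,rna_untreated optional gene x sample matrices (or
#'   [region_counts()]) of raw RNA CDS counts per condition; normalized
#'   jointly.
#' @param top_genes character vector of TOP-motif gene ids (flagging only).
#' @return data frame `gene`, `log2_te_fc`, `log2_rna_fc` (`NA` if RNA not
#'   supplied), `is_top_gene`.
#' @export
te_fold_changes <- function(te_treated, te_untreated,
                            rna_treated = NULL, rna_untreated = NULL,
                            top_genes = character()) {
  stopifnot(all(c("gene", "te", "passed_threshold") %in% names(te_treated)),
            all(c("gene", "te", "passed_threshold") %in% names(te_untreated)))
  tt <- te_treated[te_treated$passed_threshold, c("gene", "te")]
  tu <- te_untreated[te_untreated$passed_threshold, c("gene", "te")]
  genes <- intersect(tt$gene, tu$gene)
  fc <- log2(tt$te[match(genes, tt$gene)] / tu$te[match(genes, tu$gene)])

  rna_fc <- rep(NA_real_, length(genes))
  if (!is.null(rna_treated) && !is.null(rna_untreated)) {
    rt <- cds_matrix(rna_treated)
    ru <- cds_matrix(rna_untreated)
    stopifnot(identical(rownames(rt), rownames(ru)))
    joint <- cbind(rt, ru)
    norm <- sweep(joint, 2, size_factors(joint), "/")
    mt <- rowMeans(norm[, seq_len(ncol(rt)), drop = FALSE])
    mu <- rowMeans(norm[, ncol(rt) + seq_len(ncol(ru)), drop = FALSE])
    i <- match(genes, rownames(rt))
    rna_fc <- ifelse(mu[i] > 0 & mt[i] > 0, log2(mt[i] / mu[i]), NA_real_)
  }
  data.frame(gene = genes, log2_te_fc = fc, log2_rna_fc = rna_fc,
             is_top_gene = genes %in% top_genes,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flag genes with significant differential TE (permutation + BH)
#'
#' Substitute statistic for the external GLM-based tool: per gene, the
#' difference in mean per-sample log2 TE between conditions, with an exact
#' (enumerated) or sampled permutation null over condition labels,
#' Benjamini-Hochberg FDR across genes, and a fold-change requirement. A
#' gene is flagged iff `FDR < alpha` AND `|log2_te_fc| >= fc_cutoff`
#' (amplitude >= 2 by default). With fewer than 2 samples per condition the
#' permutation test is impossible; the function warns prominently and falls
#' back to fold-change-only flagging (p and FDR set to `NA`).
#'
#' @param records output of [te_fold_changes()].
#' @param ribo_counts,rna_counts gene x sample matrices (or
#'   [region_counts()]) of raw CDS counts covering all samples of both
#'   conditions, matched column-for-column across assays.
#' @param conditions character vector (`"treated"`/`"untreated"`) per
#'   sample column.
#' @param n_perm permutations when exhaustive enumeration exceeds
#'   `max_enumeration`.
#' @param seed RNG seed for sampled permutations.
#' @param fc_cutoff required |log2 TE fold change| (default 1).
#' @param alpha FDR level (default 0.05).
#' @param max_enumeration enumerate all label assignments when their number
#'   is at most this (default 20000).
#' @return `records` with added columns `p_permutation`, `fdr`,
#'   `significant`; attribute `method` names the substitute statistic.
#' @export
significance_flags <- function(records, ribo_counts, rna_counts, conditions,
                               n_perm = 2000L, seed = 1L, fc_cutoff = 1,
                               alpha = 0.05, max_enumeration = 20000L) {
  ribo <- cds_matrix(ribo_counts)
  rna <- cds_matrix(rna_counts)
  stopifnot(identical(rownames(ribo), rownames(rna)),
            ncol(ribo) == ncol(rna), length(conditions) == ncol(ribo))
  if (!all(conditions %in% c("treated", "untreated")))
    stop("conditions must be 'treated' or 'untreated'")
  nt <- sum(conditions == "treated")
  nu <- sum(conditions == "untreated")
  genes <- records$gene
  i <- match(genes, rownames(ribo))
  if (anyNA(i)) stop("records contain genes absent from the count matrices")

  if (nt < 2 || nu < 2) {
    warning("fewer than 2 samples per condition: permutation test ",
            "impossible; falling back to fold-change-only flagging",
            call. = FALSE, immediate. = TRUE)
    records$p_permutation <- NA_real_
    records$fdr <- NA_real_
    records$significant <- abs(records$log2_te_fc) >= fc_cutoff
    attr(records, "method") <- "fold-change-only (no replication)"
    return(records)
  }

  norm_r <- sweep(ribo, 2, size_factors(ribo), "/")
  norm_n <- sweep(rna, 2, size_factors(rna), "/")
  L <- log2(norm_r[i, , drop = FALSE] / norm_n[i, , drop = FALSE])
  ok <- apply(is.finite(L), 1, all)

  n <- nt + nu
  w_obs <- ifelse(conditions == "treated", 1 / nt, -1 / nu)
  n_comb <- choose(n, nt)
  if (n_comb <= max_enumeration) {
    sel <- utils::combn(n, nt)
    W <- matrix(-1 / nu, n, ncol(sel))
    W[cbind(as.vector(sel), rep(seq_len(ncol(sel)), each = nt))] <- 1 / nt
    exact <- TRUE
  } else {
    W <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        s <- sample.int(n, nt)
        w <- rep(-1 / nu, n)
        w[s] <- 1 / nt
        w
      }, numeric(n))
    })
    exact <- FALSE
  }
  Lok <- L[ok, , drop = FALSE]
  t_obs <- as.vector(Lok %*% w_obs)
  T_perm <- Lok %*% W
  ge <- abs(T_perm) >= abs(t_obs) - 1e-12
  p_ok <- if (exact) rowMeans(ge) else (1 + rowSums(ge)) / (1 + ncol(W))

  p <- rep(NA_real_, length(genes))
  p[ok] <- p_ok
  fdr <- rep(NA_real_, length(genes))
  fdr[ok] <- stats::p.adjust(p_ok, method = "BH")
  records$p_permutation <- p
  records$fdr <- fdr
  records$significant <- !is.na(fdr) & fdr < alpha &
    abs(records$log2_te_fc) >= fc_cutoff
  attr(records, "method") <- paste0(
    "condition-label permutation of per-sample log2 TE (",
    if (exact) paste0("exact, ", ncol(W), " arrangements")
    else paste0(n_perm, " sampled"), ") + BH FDR; not a GLM")
  records
}

#' Three-way overlap of flagged genes, TOP genes, ribosomal proteins
#'
#' Exclusive and shared counts for the Venn diagram of significantly
#' translationally repressed genes, TOP motif-containing genes, and
#' ribosomal protein genes.
#'
#' @param flagged_down_genes,top_gene_list,ribosomal_protein_list character
#'   vectors of gene ids.
#' @return data frame `region` (membership pattern over
#'   flagged/top/ribosomal), `count`, plus set totals as attributes.
#' @export
top_overlap <- function(flagged_down_genes, top_gene_list,
                        ribosomal_protein_list) {
  a <- unique(flagged_down_genes)
  b <- unique(top_gene_list)
  c_ <- unique(ribosomal_protein_list)
  universe <- unique(c(a, b, c_))
  inA <- universe %in% a
  inB <- universe %in% b
  inC <- universe %in% c_
  pat <- paste0(ifelse(inA, "flagged", ""), ifelse(inA & (inB | inC), "+", ""),
                ifelse(inB, "top", ""), ifelse(inB & inC, "+", ""),
                ifelse(inC, "ribosomal", ""))
  lv <- c("flagged", "top", "ribosomal", "flagged+top",
          "flagged+ribosomal", "top+ribosomal", "flagged+top+ribosomal")
  out <- data.frame(region = lv,
                    count = as.integer(table(factor(pat, levels = lv))),
                    stringsAsFactors = FALSE)
  attr(out, "totals") <- c(flagged = length(a), top = length(b),
                           ribosomal = length(c_))
  out
}
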