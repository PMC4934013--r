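# Cell-type enrichment scores E, comparison scores Es, specific gene lists,
# and rank-list construction.

#' Cell-type enrichment scores
#'
#' For gene i and cell type j with expression `FPKM_ij`, the enrichment
#' score is
#'
#'   `E_ij = FPKM_ij / sum_k FPKM_ik - 1/2`
#'
#' over the retained cell types, giving one score per cell type bounded in
#' `[-0.5, 0.5]`; the bound 0.5 is attained exactly for a gene expressed in
#' a single cell type. Row sums equal `1 - n/2` for `n` retained cell types.
#' Scores can be recalculated excluding cell types (e.g. newly formed
#' oligodendrocytes, whose expression overlaps myelinating ones).
#'
#' @param expr gene x cell-type FPKM matrix (non-negative, >= 2 columns,
#'   row/col names required).
#' @param exclude_cell_types character vector of cell-type columns to drop
#'   before computing scores.
#' @return gene x cell-type matrix of scores; genes with zero total FPKM are
#'   dropped (reported via message).
#' @export
enrichment_scores <- function(expr, exclude_cell_types = NULL) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr)) || is.null(rownames(expr)))
    stop("expr needs gene rownames and cell-type colnames")
  if (any(expr < 0)) stop("FPKM values must be non-negative")
  if (!is.null(exclude_cell_types)) {
    bad <- setdiff(exclude_cell_types, colnames(expr))
    if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "))
    expr <- expr[, setdiff(colnames(expr), exclude_cell_types), drop = FALSE]
  }
  if (ncol(expr) < 2) stop("need at least 2 retained cell types")
  tot <- rowSums(expr)
  drop <- tot == 0
  if (all(drop)) stop("all gene rows have zero total FPKM")
  if (any(drop))
    message(sum(drop), " gene(s) with zero total FPKM dropped")
  expr <- expr[!drop, , drop = FALSE]
  expr / rowSums(expr) - 0.5
}

#' Cell-type-specific gene list
#'
#' Genes whose enrichment score in the given cell type exceeds the cutoff
#' (strictly greater than; the conventional cutoff is 0.2).
#'
#' @param scores matrix from [enrichment_scores()].
#' @param cell_type column to threshold.
#' @param cutoff strict lower bound (default 0.2).
#' @return character vector of gene ids (possibly empty).
#' @export
specific_gene_list <- function(scores, cell_type, cutoff = 0.2) {
  if (!cell_type %in% colnames(scores))
    stop("unknown cell type: ", cell_type)
  rownames(scores)[scores[, cell_type] > cutoff]
}

#' Pairwise comparison scores Es
#'
#' For two cell types k and j, `Es_i = E_ik / E_ij` per gene. Genes with a
#' zero denominator are excluded (reported via message). When both scores
#' are negative the ratio is positive but of ambiguous meaning; such genes
#' are flagged rather than reinterpreted.
#'
#' @param scores matrix from [enrichment_scores()].
#' @param cell_type_k,cell_type_j distinct column names (numerator,
#'   denominator).
#' @return data frame `gene`, `es`, `both_negative`.
#' @export
comparison_scores <- function(scores, cell_type_k, cell_type_j) {
  if (identical(cell_type_k, cell_type_j))
    stop("cell types must differ")
  for (ct in c(cell_type_k, cell_type_j))
    if (!ct %in% colnames(scores)) stop("unknown cell type: ", ct)
  ek <- scores[, cell_type_k]
  ej <- scores[, cell_type_j]
  keep <- ej != 0
  if (any(!keep))
    message(sum(!keep), " gene(s) with zero denominator score excluded")
  data.frame(gene = rownames(scores)[keep],
             es = ek[keep] / ej[keep],
             both_negative = ek[keep] < 0 & ej[keep] < 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a deterministic descending rank list
#'
#' Orders a named score vector (enrichment scores, comparison scores, or
#' RiboTag scores) in descending order, breaking ties lexicographically by
#' gene identifier so downstream GSEA is deterministic.
#'
#' @param scores named numeric vector, or two-column data frame
#'   (gene, score).
#' @return named numeric vector sorted for pre-ranked GSEA.
#' @export
rank_list <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(ncol(scores) >= 2)
    scores <- stats::setNames(as.numeric(scores[[2]]),
                              as.character(scores[[1]]))
  }
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named with unique gene ids")
  scores <- scores[!is.na(scores)]
  scores[order(-scores, names(scores), method = "radix")]
}
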