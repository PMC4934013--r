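# Shared fixtures, built in code.

# small but fully featured simulation config for fast module tests;
# any sim_config() argument can be overridden
small_config <- function(...) {
  defaults <- list(n_genes = 60, cds_length_range = c(150L, 450L),
                   utr5_length_range = c(20L, 120L),
                   utr3_length_range = c(40L, 90L), seed = 7L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built toy transcript models with known sequences
toy_models <- function() {
  set.seed(99)
  u5 <- "CCGGCCGGCC"                                   # 10 nt, no ATG
  cds <- paste0("ATG", paste(rep("GCA", 19), collapse = ""))  # 60 nt
  u3 <- paste(sample(c("C", "G", "T"), 40, replace = TRUE), collapse = "")
  sA <- paste0(u5, cds, u3)
  # second gene: distinct sequence, same layout
  cds2 <- paste0("ATG", paste(rep("TGC", 19), collapse = ""))
  u32 <- paste(sample(c("C", "G", "T"), 40, replace = TRUE), collapse = "")
  sB <- paste0("GGGGGGGGGG", cds2, u32)
  transcript_models(
    gene_id = c("gA", "gB"),
    transcript_id = c("gA.t1", "gB.t1"),
    sequence = c(sA, sB),
    cds_start = c(10L, 10L), cds_end = c(70L, 70L),
    isoform_abundance = c(1, 1))
}

# alignment row builder
aln <- function(gene, tx, pos, len = 30L, read = NULL) {
  data.frame(read_id = if (is.null(read)) sprintf("r%03d", seq_along(pos))
             else read,
             gene_id = rep(gene, length.out = length(pos)),
             transcript_id = rep(tx, length.out = length(pos)),
             five_prime_pos = as.integer(pos),
             length = as.integer(rep(len, length.out = length(pos))),
             stringsAsFactors = FALSE)
}
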