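# Synthetic-data generator.
#
# Emits transcript annotations, sequences, a 7-cell-type FPKM reference,
# footprint reads with the ligation-free read structure, and count tables,
# all with the statistical structure the downstream analysis assumes:
# 3-nt periodic CDS-biased footprints, 5'UTR > 3'UTR density, uAUG-bearing
# UTRs, cell-type-specific expression with bimodal neuronal TE, RiboTag IP
# enrichment, and TOP-gene TE repression under treatment.

#' Default brain cell-type labels
#' @export
brain_cell_types <- function() {
  c("astrocyte", "neuron", "opc", "newly_formed_oligodendrocyte",
    "myelinating_oligodendrocyte", "microglia", "endothelial")
}

default_te_mixtures <- function(cell_types) {
  base <- list(
    astrocyte = list(mean = 0, sd = 0.5, weight = 1),
    # neurons: bimodal, very highly or very lowly translated
    neuron = list(mean = c(-1.5, 1.5), sd = c(0.5, 0.5),
                  weight = c(0.5, 0.5)),
    # oligodendrocyte lineage ordering: OPC > newly formed > myelinating
    opc = list(mean = 0.5, sd = 0.5, weight = 1),
    newly_formed_oligodendrocyte = list(mean = 0, sd = 0.5, weight = 1),
    myelinating_oligodendrocyte = list(mean = -0.5, sd = 0.5, weight = 1),
    microglia = list(mean = -1, sd = 0.5, weight = 1),
    endothelial = list(mean = 0, sd = 0.5, weight = 1)
  )
  out <- lapply(cell_types, function(ct) {
    if (!is.null(base[[ct]])) base[[ct]] else list(mean = 0, sd = 0.5,
                                                   weight = 1)
  })
  names(out) <- cell_types
  out
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic world. Defaults state the
#' conditions the downstream analysis assumes: ~30 nt footprints with strong
#' frame-0 preference, a CDS-dominated gene-body split with more 5'UTR than
#' 3'UTR density, bimodal neuronal log2 TE, low microglial TE, an
#' oligodendrocyte maturation gradient, and -2 log2 TOP-gene repression under
#' treatment.
#'
#' @param n_genes number of genes.
#' @param cell_types cell-type labels; length gives `n_cell_types` (>= 2).
#' @param cds_length_range,utr5_length_range,utr3_length_range integer
#'   length intervals in nt. The 3'UTR minimum must accommodate the longest
#'   footprint.
#' @param utr5_gc_range target GC proportion interval for 5' UTRs.
#' @param frac_uaug_genes fraction of genes whose 5' UTR carries >= 1 AUG.
#' @param te_log2_distribution per-cell-type mixture spec: named list of
#'   `list(mean, sd, weight)` vectors; weights sum to 1 per cell type.
#' @param cds_read_fraction named target gene-body split of footprint 5'
#'   ends, `c(utr5 =, cds =, utr3 =)`, summing to 1.
#' @param periodicity_strength probability in `[0, 1]` that a CDS footprint
#'   5' end is forced onto frame 0 of its codon (otherwise uniform frames).
#' @param footprint_length_probs named discrete footprint-length
#'   distribution (nt).
#' @param top_gene_fraction fraction of genes flagged as TOP (terminal
#'   oligopyrimidine) genes.
#' @param top_repression_log2 log2 TE shift applied to TOP genes in the
#'   `"treated"` condition.
#' @param uaug_te_shift log2 TE shift applied to uAUG-bearing genes.
#' @param utr5_length_te_slope log2 TE shift from shortest to longest
#'   abundance-weighted 5' UTR (linear in scaled length).
#' @param ribotag_target_cell_type cell type whose genes the RiboTag IP
#'   enriches.
#' @param isoforms_per_gene_range integer interval of isoforms per gene.
#' @param read_length fixed raw read length in nt (sequencer cycles).
#' @param noise `"poisson"` or `"nb"`; `nb_dispersion` is the negative
#'   binomial dispersion (1/size) used when `noise = "nb"`.
#' @param nb_dispersion see `noise`.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 500,
                       cell_types = brain_cell_types(),
                       cds_length_range = c(300L, 1800L),
                       utr5_length_range = c(30L, 300L),
                       utr3_length_range = c(60L, 240L),
                       utr5_gc_range = c(0.35, 0.75),
                       frac_uaug_genes = 0.4,
                       te_log2_distribution = NULL,
                       cds_read_fraction = c(utr5 = 0.10, cds = 0.85,
                                             utr3 = 0.05),
                       periodicity_strength = 0.9,
                       footprint_length_probs = c(`28` = 0.2, `29` = 0.3,
                                                  `30` = 0.3, `31` = 0.2),
                       top_gene_fraction = 0.05,
                       top_repression_log2 = -2,
                       uaug_te_shift = -0.5,
                       utr5_length_te_slope = -1,
                       ribotag_target_cell_type = "neuron",
                       isoforms_per_gene_range = c(1L, 2L),
                       read_length = 75L,
                       noise = c("poisson", "nb"),
                       nb_dispersion = 0.1,
                       seed = 1L) {
  if (is.null(te_log2_distribution))
    te_log2_distribution <- default_te_mixtures(cell_types)
  cfg <- list(n_genes = as.integer(n_genes), cell_types = cell_types,
              n_cell_types = length(cell_types),
              cds_length_range = as.integer(cds_length_range),
              utr5_length_range = as.integer(utr5_length_range),
              utr3_length_range = as.integer(utr3_length_range),
              utr5_gc_range = utr5_gc_range,
              frac_uaug_genes = frac_uaug_genes,
              te_log2_distribution = te_log2_distribution,
              cds_read_fraction = cds_read_fraction,
              periodicity_strength = periodicity_strength,
              footprint_length_probs = footprint_length_probs,
              top_gene_fraction = top_gene_fraction,
              top_repression_log2 = top_repression_log2,
              uaug_te_shift = uaug_te_shift,
              utr5_length_te_slope = utr5_length_te_slope,
              ribotag_target_cell_type = ribotag_target_cell_type,
              isoforms_per_gene_range = as.integer(isoforms_per_gene_range),
              read_length = as.integer(read_length),
              noise = match.arg(noise),
              nb_dispersion = nb_dispersion,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2])
      stop("degenerate range for ", nm, " (min > max or wrong length)")
  }
  chk_prop <- function(p, nm) {
    if (any(p < 0 | p > 1)) stop(nm, " must lie in [0, 1]")
  }
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (cfg$n_cell_types < 2) stop("need at least 2 cell types")
  chk_range(cfg$cds_length_range, "cds_length_range")
  chk_range(cfg$utr5_length_range, "utr5_length_range")
  chk_range(cfg$utr3_length_range, "utr3_length_range")
  chk_range(cfg$utr5_gc_range, "utr5_gc_range")
  chk_range(cfg$isoforms_per_gene_range, "isoforms_per_gene_range")
  chk_prop(cfg$utr5_gc_range, "utr5_gc_range")
  chk_prop(cfg$frac_uaug_genes, "frac_uaug_genes")
  chk_prop(cfg$periodicity_strength, "periodicity_strength")
  chk_prop(cfg$top_gene_fraction, "top_gene_fraction")
  chk_prop(cfg$cds_read_fraction, "cds_read_fraction")
  if (abs(sum(cfg$cds_read_fraction) - 1) > 1e-9 ||
      !all(c("utr5", "cds", "utr3") %in% names(cfg$cds_read_fraction)))
    stop("cds_read_fraction must be named (utr5, cds, utr3) and sum to 1")
  fl <- as.integer(names(cfg$footprint_length_probs))
  if (anyNA(fl) || any(cfg$footprint_length_probs < 0) ||
      abs(sum(cfg$footprint_length_probs) - 1) > 1e-9)
    stop("footprint_length_probs must be a named distribution over lengths")
  if (cfg$utr3_length_range[1] < max(fl))
    stop("utr3 minimum length must be >= the longest footprint (",
         max(fl), " nt)")
  if (cfg$utr5_length_range[1] < 10)
    stop("utr5 minimum length must be >= 10 nt")
  for (ct in cfg$cell_types) {
    m <- cfg$te_log2_distribution[[ct]]
    if (is.null(m) || abs(sum(m$weight) - 1) > 1e-9)
      stop("te mixture weights must sum to 1 for cell type ", ct)
  }
  if (!cfg$ribotag_target_cell_type %in% cfg$cell_types)
    stop("ribotag_target_cell_type not among cell_types")
  if (cfg$read_length < 5 + max(fl) + 8)
    stop("read_length too short for prefix + footprint + poly(A) run")
  class(cfg) <- "sim_config"
  cfg
}

# -- sequence construction helpers -------------------------------------------

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) {
  paste(sample(BASES, len, replace = TRUE), collapse = "")
}

# CDS: starts ATG, length divisible by 3
random_cds <- function(len) {
  len <- max(3L, len - len %% 3L)
  paste0("ATG", paste(sample(BASES, len - 3L, replace = TRUE), collapse = ""))
}

# deterministic AUG-free arrangement: with all G/C first, then T, then A,
# no A is ever followed by T, so "ATG" cannot occur
atg_free_arrangement <- function(chars) {
  paste(chars[order(match(chars, c("G", "C", "T", "A")))], collapse = "")
}

# 5' UTR with target GC, with/without at least one AUG
utr5_seq <- function(len, gc_lo, gc_hi, uaug) {
  gc_target <- runif(1, gc_lo, gc_hi)
  n_gc <- round(gc_target * len)
  # clamp achievable GC into the configured range where integer-valued
  lo_n <- ceiling(gc_lo * len - 1e-9)
  hi_n <- floor(gc_hi * len + 1e-9)
  if (lo_n <= hi_n) n_gc <- min(max(n_gc, lo_n), hi_n)
  if (uaug) {
    # reserve an ATG triplet (1 GC, 2 AT)
    if (n_gc - 1L > len - 3L + 1L)
      stop("utr5_gc_range incompatible with frac_uaug_genes: an AUG needs ",
           "two A/T bases")
    n_gc_rest <- min(max(n_gc - 1L, 0L), len - 3L)
    rest <- c(sample(c("G", "C"), n_gc_rest, replace = TRUE),
              sample(c("A", "T"), len - 3L - n_gc_rest, replace = TRUE))
    rest <- sample(rest)
    pos <- sample.int(len - 2L, 1L)
    out <- character(len)
    out[pos:(pos + 2L)] <- c("A", "T", "G")
    out[setdiff(seq_len(len), pos:(pos + 2L))] <- rest
    paste(out, collapse = "")
  } else {
    chars <- c(sample(c("G", "C"), n_gc, replace = TRUE),
               sample(c("A", "T"), len - n_gc, replace = TRUE))
    for (i in 1:30) {
      s <- paste(sample(chars), collapse = "")
      if (!grepl("ATG", s, fixed = TRUE)) return(s)
    }
    atg_free_arrangement(chars)
  }
}

gc_fraction <- function(x) {
  n <- nchar(x)
  ifelse(n == 0, NA_real_, (n - nchar(gsub("[GC]", "", x))) / n)
}

draw_mixture <- function(n, mix) {
  k <- length(mix$weight)
  comp <- sample.int(k, n, replace = TRUE, prob = mix$weight)
  rnorm(n, mean = mix$mean[comp], sd = mix$sd[comp])
}

# -- annotation + truth ------------------------------------------------------

#' Simulate a transcript annotation, sequences, and ground truth
#'
#' Generates the reference world every other generator and analysis stage
#' consumes: per-gene isoform models (5'UTR/CDS/3'UTR segmentation and
#' sequence), a gene x cell-type FPKM matrix with cell-type-specific
#' expression, and per-gene ground truth (cell type of origin, TOP and uAUG
#' flags, true log2 TE per condition).
#'
#' Deterministic for a fixed config seed; uAUG flags are consistent with the
#' generated 5' UTR sequences by construction, and realized 5' UTR GC lies in
#' the configured range.
#'
#' @param config a [sim_config()].
#' @return an object of class `ribosim`: list with elements `models`
#'   ([transcript_models()]), `truth` (per-gene data frame), `fpkm`
#'   (gene x cell type matrix), `config`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    cts <- config$cell_types
    gene_id <- sprintf("gene_%05d", seq_len(n))

    # every cell type present (when n allows), remainder uniform
    cell_type <- c(rep(cts, length.out = min(n, length(cts))),
                   if (n > length(cts))
                     sample(cts, n - length(cts), replace = TRUE))

    is_top <- seq_len(n) %in%
      sample.int(n, round(config$top_gene_fraction * n))
    has_uaug <- seq_len(n) %in%
      sample.int(n, round(config$frac_uaug_genes * n))

    # FPKM reference: strong expression in the home cell type, exponential
    # leakage into the others; many genes end up cell-type specific
    # (enrichment score > 0.2), others broadly expressed.
    home_fpkm <- stats::rlnorm(n, meanlog = log(30), sdlog = 1)
    fpkm <- matrix(0, n, length(cts), dimnames = list(gene_id, cts))
    leak <- matrix(pmin(stats::rexp(n * length(cts), rate = 10), 1),
                   n, length(cts))
    for (j in seq_along(cts)) fpkm[, j] <- home_fpkm * leak[, j]
    fpkm[cbind(seq_len(n), match(cell_type, cts))] <- home_fpkm

    # sequences / isoforms
    ir <- config$isoforms_per_gene_range
    n_iso <- sample(seq(ir[1], ir[2]), n, replace = TRUE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cds_len <- sample(seq(config$cds_length_range[1],
                            config$cds_length_range[2]), 1L)
      cds <- random_cds(cds_len)
      utr3 <- random_seq(sample(seq(config$utr3_length_range[1],
                                    config$utr3_length_range[2]), 1L))
      u5_len <- sample(seq(config$utr5_length_range[1],
                           config$utr5_length_range[2]), n_iso[i],
                       replace = TRUE)
      ab <- stats::rexp(n_iso[i])
      ab <- ab / sum(ab)
      iso <- lapply(seq_len(n_iso[i]), function(k) {
        u5 <- utr5_seq(u5_len[k], config$utr5_gc_range[1],
                       config$utr5_gc_range[2], has_uaug[i])
        data.frame(gene_id = gene_id[i],
                   transcript_id = sprintf("%s.t%d", gene_id[i], k),
                   sequence = paste0(u5, cds, utr3),
                   cds_start = nchar(u5),
                   cds_end = nchar(u5) + nchar(cds),
                   isoform_abundance = ab[k],
                   stringsAsFactors = FALSE)
      })
      rows[[i]] <- do.call(rbind, iso)
    }
    mdf <- do.call(rbind, rows)
    models <- transcript_models(mdf$gene_id, mdf$transcript_id, mdf$sequence,
                                mdf$cds_start, mdf$cds_end,
                                mdf$isoform_abundance)

    # abundance-weighted 5' UTR length drives the configured TE slope
    wlen <- tapply(models$cds_start * models$isoform_abundance,
                   models$gene_id, sum) /
      tapply(models$isoform_abundance, models$gene_id, sum)
    wlen <- as.numeric(wlen[gene_id])
    rng <- range(config$utr5_length_range)
    scaled_len <- if (rng[2] > rng[1]) (wlen - rng[1]) / (rng[2] - rng[1])
                  else rep(0.5, n)

    base_te <- numeric(n)
    for (ct in cts) {
      idx <- which(cell_type == ct)
      if (length(idx))
        base_te[idx] <- draw_mixture(length(idx),
                                     config$te_log2_distribution[[ct]])
    }
    log2_te <- base_te + config$uaug_te_shift * has_uaug +
      config$utr5_length_te_slope * (scaled_len - 0.5)
    log2_te_treated <- log2_te + config$top_repression_log2 * is_top

    truth <- data.frame(
      gene_id = gene_id, cell_type = cell_type,
      is_top = is_top, has_uaug = has_uaug,
      log2_te_untreated = log2_te, log2_te_treated = log2_te_treated,
      utr5_length_weighted = wlen,
      tissue_fpkm = rowMeans(fpkm),  # equal cell-type proportions in tissue
      stringsAsFactors = FALSE
    )
    structure(list(models = models, truth = truth, fpkm = fpkm,
                   config = config),
              class = "ribosim")
  })
}

#' @export
print.ribosim <- function(x, ...) {
  cat("ribosim:", nrow(x$truth), "genes,", nrow(x$models), "isoforms,",
      ncol(x$fpkm), "cell types (seed", x$config$seed, ")\n")
  invisible(x)
}

true_log2_te <- function(sim, condition) {
  switch(condition,
         untreated = sim$truth$log2_te_untreated,
         treated = sim$truth$log2_te_treated,
         stop("condition must be 'untreated' or 'treated'"))
}

count_noise <- function(n, lambda, config) {
  if (config$noise == "poisson") stats::rpois(n, lambda)
  else stats::rnbinom(n, mu = lambda, size = 1 / config$nb_dispersion)
}

# -- footprints --------------------------------------------------------------

#' Simulate ligation-free ribosome footprint reads
#'
#' Draws per-gene footprint counts proportional to tissue FPKM x TE, places
#' 5' ends in regions according to the configured gene-body split, applies
#' the frame-0 codon preference inside the CDS, and (optionally) assembles
#' raw reads with the ligation-free structure: a 5 nt G-rich prefix from
#' terminal transferase activity, the footprint, and a poly(A) run filling
#' the read to the fixed read length.
#'
#' @param sim a `ribosim` from [simulate_annotation()].
#' @param condition `"untreated"` or `"treated"` (the treated condition
#'   applies the configured TOP repression).
#' @param depth expected total number of footprints (> 0).
#' @param seed RNG seed for this call (defaults to `config$seed + 1`).
#' @param emit_reads if `FALSE`, skip raw-read assembly and return only the
#'   truth alignment set (fast path for count-level analyses).
#' @return list with `reads` (data frame `read_id`, `sequence`, or `NULL`),
#'   `alignments` (truth set: `read_id`, `gene_id`, `transcript_id`,
#'   `five_prime_pos`, `length`), and `condition`.
#' @export
simulate_footprints <- function(sim, condition = "untreated", depth = 1e5,
                                seed = sim$config$seed + 1L,
                                emit_reads = TRUE) {
  stopifnot(inherits(sim, "ribosim"))
  config <- sim$config
  if (nrow(sim$models) == 0) stop("empty model collection")
  if (depth <= 0) stop("depth must be positive")
  lte <- true_log2_te(sim, condition)
  with_seed(seed, {
    share <- sim$truth$tissue_fpkm * 2^lte
    p <- share / sum(share)
    n_g <- count_noise(length(p), depth * p, config)
    total <- sum(n_g)
    if (total == 0) stop("no reads drawn; increase depth")

    gidx <- rep.int(seq_along(n_g), n_g)
    # isoform choice by relative abundance, per gene
    tx_of_gene <- split(seq_len(nrow(sim$models)), sim$models$gene_id)
    tx_of_gene <- tx_of_gene[sim$truth$gene_id]  # gene order
    tidx <- integer(total)
    off <- 0L
    for (g in seq_along(n_g)) {
      k <- n_g[g]
      if (k == 0L) next
      txs <- tx_of_gene[[g]]
      tidx[(off + 1L):(off + k)] <- if (length(txs) == 1L) txs
        else sample(txs, k, replace = TRUE,
                    prob = sim$models$isoform_abundance[txs])
      off <- off + k
    }

    m <- sim$models
    cds_start <- m$cds_start[tidx]
    cds_end <- m$cds_end[tidx]
    tx_len <- m$length[tidx]

    fl <- as.integer(names(config$footprint_length_probs))
    len <- sample(fl, total, replace = TRUE,
                  prob = config$footprint_length_probs)
    region <- sample(c("utr5", "cds", "utr3"), total, replace = TRUE,
                     prob = config$cds_read_fraction[c("utr5", "cds",
                                                       "utr3")])
    pos <- integer(total)
    i5 <- region == "utr5"
    pos[i5] <- floor(runif(sum(i5)) * cds_start[i5])
    ic <- region == "cds"
    if (any(ic)) {
      max_p <- pmin(cds_end[ic] - 1L, tx_len[ic] - len[ic])
      n_codon <- pmax(1L, (max_p - 2L - cds_start[ic]) %/% 3L + 1L)
      codon <- floor(runif(sum(ic)) * n_codon)
      frame0 <- runif(sum(ic)) < config$periodicity_strength
      frame <- ifelse(frame0, 0L, floor(runif(sum(ic)) * 3))
      pos[ic] <- cds_start[ic] + 3L * codon + frame
    }
    i3 <- region == "utr3"
    if (any(i3)) {
      width <- pmax(1L, tx_len[i3] - len[i3] - cds_end[i3] + 1L)
      pos[i3] <- cds_end[i3] + floor(runif(sum(i3)) * width)
    }

    read_id <- sprintf("read_%08d", seq_len(total))
    alignments <- data.frame(read_id = read_id,
                             gene_id = m$gene_id[tidx],
                             transcript_id = m$transcript_id[tidx],
                             five_prime_pos = pos, length = len,
                             stringsAsFactors = FALSE)
    validate_alignments(alignments, m)

    reads <- NULL
    if (emit_reads) {
      fp <- substring(m$sequence[tidx], pos + 1L, pos + len)
      pref <- matrix(sample(BASES[c(3, 2, 1, 4)], 5L * total, replace = TRUE,
                            prob = c(0.7, 0.1, 0.1, 0.1)),
                     nrow = total)
      prefix <- do.call(paste0, as.data.frame(pref, stringsAsFactors = FALSE))
      tail_a <- strrep("A", config$read_length - 5L - len)
      reads <- data.frame(read_id = read_id,
                          sequence = paste0(prefix, fp, tail_a),
                          stringsAsFactors = FALSE)
    }
    list(reads = reads, alignments = alignments, condition = condition)
  })
}

# region length shares per gene, abundance-weighted over isoforms (used for
# RNA-seq-like uniform-coverage region splits)
gene_region_shares <- function(models) {
  w <- models$isoform_abundance
  l5 <- tapply(models$cds_start * w, models$gene_id, sum)
  lc <- tapply((models$cds_end - models$cds_start) * w, models$gene_id, sum)
  l3 <- tapply((models$length - models$cds_end) * w, models$gene_id, sum)
  tot <- l5 + lc + l3
  cbind(utr5 = l5 / tot, cds = lc / tot, utr3 = l3 / tot)
}

region_count_draw <- function(lambda, shares, config) {
  n <- length(lambda)
  cbind(utr5 = count_noise(n, lambda * shares[, "utr5"], config),
        cds = count_noise(n, lambda * shares[, "cds"], config),
        utr3 = count_noise(n, lambda * shares[, "utr3"], config))
}

#' Simulate RNA-seq region counts
#'
#' Counts are Poisson (or negative binomial) around FPKM-proportional means;
#' region assignment follows uniform coverage, i.e. region-length shares.
#' The per-sample `library_scale` multiplies the expected library size, so
#' [size_factors()] should recover the configured ratios.
#'
#' @param sim a `ribosim`.
#' @param condition condition label recorded in the sample metadata.
#' @param depth expected reads per (unscaled) sample.
#' @param n_reps number of replicate samples.
#' @param library_scale per-sample library-size scaling factors.
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return a [region_counts()] with assay `"rna"`.
#' @export
simulate_rnaseq_counts <- function(sim, condition = "untreated", depth = 1e6,
                                   n_reps = 1, library_scale = rep(1, n_reps),
                                   seed = sim$config$seed + 2L) {
  stopifnot(inherits(sim, "ribosim"), length(library_scale) == n_reps)
  config <- sim$config
  with_seed(seed, {
    p <- sim$truth$tissue_fpkm
    p <- if (sum(p) > 0) p / sum(p) else p
    shares <- gene_region_shares(sim$models)[sim$truth$gene_id, , drop = FALSE]
    mats <- lapply(seq_len(n_reps), function(s)
      region_count_draw(depth * library_scale[s] * p, shares, config))
    build_region_counts_from_draws(mats, sim$truth$gene_id, "rna", condition,
                                   sprintf("rna_%s_%d", condition,
                                           seq_len(n_reps)))
  })
}

#' Simulate ribosome-profiling region counts directly (count level)
#'
#' Draws per-gene region counts from the same law that aggregating
#' [simulate_footprints()] output by region would follow (FPKM x TE means,
#' configured gene-body split), skipping per-read position sampling. Use for
#' count-level analyses (TE, differential TE) where positions are irrelevant.
#'
#' @inheritParams simulate_rnaseq_counts
#' @return a [region_counts()] with assay `"ribo"`.
#' @export
simulate_ribo_counts <- function(sim, condition = "untreated", depth = 1e6,
                                 n_reps = 1, library_scale = rep(1, n_reps),
                                 seed = sim$config$seed + 3L) {
  stopifnot(inherits(sim, "ribosim"), length(library_scale) == n_reps)
  config <- sim$config
  lte <- true_log2_te(sim, condition)
  with_seed(seed, {
    share <- sim$truth$tissue_fpkm * 2^lte
    p <- share / sum(share)
    shares <- matrix(rep(config$cds_read_fraction[c("utr5", "cds", "utr3")],
                         each = length(p)),
                     ncol = 3, dimnames = list(NULL, c("utr5", "cds", "utr3")))
    mats <- lapply(seq_len(n_reps), function(s)
      region_count_draw(depth * library_scale[s] * p, shares, config))
    build_region_counts_from_draws(mats, sim$truth$gene_id, "ribo", condition,
                                   sprintf("ribo_%s_%d", condition,
                                           seq_len(n_reps)))
  })
}

build_region_counts_from_draws <- function(mats, genes, assay, condition,
                                           sample_names) {
  grab <- function(r) {
    m <- do.call(cbind, lapply(mats, function(x) x[, r]))
    dimnames(m) <- list(genes, sample_names)
    m
  }
  region_counts(grab("utr5"), grab("cds"), grab("utr3"),
                data.frame(sample = sample_names, assay = assay,
                           condition = condition, stringsAsFactors = FALSE))
}

#' Simulate paired RiboTag IP / homogenate counts
#'
#' IP means equal homogenate means multiplied by `enrichment` for genes of
#' the configured target cell type and by `depletion` otherwise. The default
#' `depletion = 1` leaves non-target genes unchanged so that, under
#' median-of-ratios normalization, the absolute enrichment is identifiable
#' and [ribotag_enrichment_score()] recovers `enrichment` in expectation.
#'
#' @param sim a `ribosim`.
#' @param enrichment,depletion multiplicative IP effects (> 0).
#' @param depth expected reads per sample.
#' @param n_reps replicates per arm.
#' @param seed RNG seed (defaults to `config$seed + 4`).
#' @return a [region_counts()] with assays `"ip"` and `"homogenate"`.
#' @export
simulate_ribotag <- function(sim, enrichment = 4, depletion = 1,
                             depth = 2e5, n_reps = 2,
                             seed = sim$config$seed + 4L) {
  stopifnot(inherits(sim, "ribosim"), enrichment > 0, depletion > 0)
  config <- sim$config
  target <- config$ribotag_target_cell_type
  if (!target %in% sim$truth$cell_type)
    stop("ribotag target cell type '", target, "' absent from truth")
  with_seed(seed, {
    p <- sim$truth$tissue_fpkm / sum(sim$truth$tissue_fpkm)
    mult <- ifelse(sim$truth$cell_type == target, enrichment, depletion)
    shares <- gene_region_shares(sim$models)[sim$truth$gene_id, , drop = FALSE]
    hom <- lapply(seq_len(n_reps), function(s)
      region_count_draw(depth * p, shares, config))
    ip <- lapply(seq_len(n_reps), function(s)
      region_count_draw(depth * p * mult, shares, config))
    bind_region_counts(
      build_region_counts_from_draws(ip, sim$truth$gene_id, "ip",
                                     "untreated",
                                     sprintf("ip_%d", seq_len(n_reps))),
      build_region_counts_from_draws(hom, sim$truth$gene_id, "homogenate",
                                     "untreated",
                                     sprintf("homogenate_%d",
                                             seq_len(n_reps))))
  })
}
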