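# synthetic-data generator: determinism, sequence constraints, and the
# statistical laws downstream stages rely on.

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(cds_length_range = c(300, 200)), "degenerate")
  expect_error(sim_config(periodicity_strength = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(cell_types = "neuron"), "at least 2")
  expect_error(sim_config(cds_read_fraction = c(utr5 = 0.5, cds = 0.4,
                                                utr3 = 0.2)), "sum to 1")
  expect_error(sim_config(utr3_length_range = c(10, 20)), "footprint")
  expect_error(sim_config(ribotag_target_cell_type = "hepatocyte"),
               "cell_types")
})

test_that("annotation generation is deterministic and honors constraints", {
  cfg <- small_config()
  sim1 <- simulate_annotation(cfg)
  sim2 <- simulate_annotation(cfg)
  expect_identical(sim1$models, sim2$models)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$fpkm, sim2$fpkm)

  m <- sim1$models
  # interval invariants + start codon + frame
  expect_true(all(m$cds_start > 0 & m$cds_end < m$length))
  expect_true(all((m$cds_end - m$cds_start) %% 3 == 0))
  expect_true(all(substr(m$sequence, m$cds_start + 1, m$cds_start + 3) ==
                    "ATG"))

  # uAUG flags consistent with generated UTR5 sequences
  u5 <- substr(m$sequence, 1, m$cds_start)
  has_atg <- grepl("ATG", u5, fixed = TRUE)
  flagged <- sim1$truth$has_uaug[match(m$gene_id, sim1$truth$gene_id)]
  expect_identical(unname(has_atg), unname(flagged))

  # realized UTR5 GC within the configured range
  gc <- vapply(u5, function(s)
    (nchar(s) - nchar(gsub("[GC]", "", s))) / nchar(s), 1, USE.NAMES = FALSE)
  expect_true(all(gc >= cfg$utr5_gc_range[1] - 1e-9 &
                    gc <= cfg$utr5_gc_range[2] + 1e-9))
})

test_that("uAUG-free and all-GC boundary configs are honored", {
  sim <- simulate_annotation(small_config(frac_uaug_genes = 0))
  u5 <- substr(sim$models$sequence, 1, sim$models$cds_start)
  expect_false(any(grepl("ATG", u5, fixed = TRUE)))

  sim_gc <- simulate_annotation(small_config(frac_uaug_genes = 0,
                                             utr5_gc_range = c(1, 1)))
  u5 <- substr(sim_gc$models$sequence, 1, sim_gc$models$cds_start)
  expect_true(all(grepl("^[GC]+$", u5)))
})

test_that("footprints: determinism, read structure conservation, truth keys", {
  sim <- simulate_annotation(small_config())
  fp1 <- simulate_footprints(sim, depth = 3000, seed = 11)
  fp2 <- simulate_footprints(sim, depth = 3000, seed = 11)
  expect_identical(fp1$reads, fp2$reads)
  expect_identical(fp1$alignments, fp2$alignments)

  # fixed read length: prefix + footprint + poly(A) fill
  expect_true(all(nchar(fp1$reads$sequence) == sim$config$read_length))
  # poly(A) run of >= 8 terminates every read
  expect_true(all(grepl("AAAAAAAA$", fp1$reads$sequence)))
  # bijection between reads and truth alignments
  expect_identical(fp1$reads$read_id, fp1$alignments$read_id)
  # alignments respect transcript bounds
  i <- match(fp1$alignments$transcript_id, sim$models$transcript_id)
  expect_true(all(fp1$alignments$five_prime_pos + fp1$alignments$length <=
                    sim$models$length[i]))
  expect_error(simulate_footprints(sim, depth = 0), "positive")
})

test_that("periodicity_strength = 1 forces frame 0 in the CDS", {
  sim <- simulate_annotation(small_config(periodicity_strength = 1))
  fp <- simulate_footprints(sim, depth = 4000, emit_reads = FALSE)
  i <- match(fp$alignments$transcript_id, sim$models$transcript_id)
  off <- fp$alignments$five_prime_pos - sim$models$cds_start[i]
  in_cds <- off >= 0 & fp$alignments$five_prime_pos < sim$models$cds_end[i]
  expect_true(all(off[in_cds] %% 3 == 0))
})

test_that("frame-0 fraction converges to p + (1-p)/3", {
  p <- 0.9
  sim <- simulate_annotation(small_config(periodicity_strength = p))
  fp <- simulate_footprints(sim, depth = 1e5, emit_reads = FALSE, seed = 3)
  i <- match(fp$alignments$transcript_id, sim$models$transcript_id)
  off <- fp$alignments$five_prime_pos - sim$models$cds_start[i]
  in_cds <- off >= 0 & fp$alignments$five_prime_pos < sim$models$cds_end[i]
  frac0 <- mean(off[in_cds] %% 3 == 0)
  expect_lt(abs(frac0 - (p + (1 - p) / 3)), 0.01)
})

test_that("gene-body split is recovered within 2%", {
  sim <- simulate_annotation(small_config())
  fp <- simulate_footprints(sim, depth = 2e5, emit_reads = FALSE, seed = 5)
  gb <- gene_body_distribution(fp$alignments, sim$models)
  # scaled down from the spec's 1e6-read statement; binomial error at 2e5
  # is ~0.001, well inside the 2% band
  expect_true(all(abs(gb - sim$config$cds_read_fraction[names(gb)]) < 0.02))
})

test_that("TOP repression scales treated footprint counts by 2^shift", {
  sim <- simulate_annotation(small_config(n_genes = 200,
                                          top_gene_fraction = 0.25,
                                          top_repression_log2 = -2))
  un <- simulate_ribo_counts(sim, "untreated", depth = 4e5, seed = 21)
  tr <- simulate_ribo_counts(sim, "treated", depth = 4e5, seed = 22)
  top <- sim$truth$is_top
  # treated library renormalizes total depth; compare TOP/non-TOP ratio of
  # count ratios, which isolates the 2^-2 effect
  r_top <- sum(region_matrix(tr)[top, ]) / sum(region_matrix(un)[top, ])
  r_other <- sum(region_matrix(tr)[!top, ]) / sum(region_matrix(un)[!top, ])
  expect_lt(abs(log2(r_top / r_other) - (-2)), 0.15)
})

test_that("rnaseq counts: determinism, zero-FPKM genes, scale recovery", {
  sim <- simulate_annotation(small_config())
  rc1 <- simulate_rnaseq_counts(sim, depth = 5e4, n_reps = 2, seed = 31)
  rc2 <- simulate_rnaseq_counts(sim, depth = 5e4, n_reps = 2, seed = 31)
  expect_identical(rc1$cds, rc2$cds)

  sim0 <- sim
  sim0$truth$tissue_fpkm[3] <- 0
  rc0 <- simulate_rnaseq_counts(sim0, depth = 5e4, seed = 32)
  expect_true(all(region_matrix(rc0)[3, ] == 0))

  # library_scale = (1, 2) recovered by size factors within 5%
  rcs <- simulate_rnaseq_counts(sim, depth = 2e5, n_reps = 2,
                                library_scale = c(1, 2), seed = 33)
  sf <- size_factors(region_matrix(rcs))
  expect_lt(abs(sf[2] / sf[1] - 2) / 2, 0.05)
})

test_that("ribotag: neutral settings leave IP ~ homogenate; bad target errors", {
  sim <- simulate_annotation(small_config())
  rt <- simulate_ribotag(sim, enrichment = 1, depletion = 1, depth = 1e5,
                         seed = 41)
  sc <- ribotag_enrichment_score(
    region_matrix(rt)[, rt$samples$assay == "ip"],
    region_matrix(rt)[, rt$samples$assay == "homogenate"])
  expect_lt(abs(stats::median(sc$score, na.rm = TRUE) - 1), 0.05)

  sim_no <- sim
  sim_no$truth$cell_type[sim_no$truth$cell_type == "neuron"] <- "astrocyte"
  expect_error(simulate_ribotag(sim_no), "absent from truth")
})
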