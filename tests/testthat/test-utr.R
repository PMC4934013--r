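# 5' UTR features: density flags, uAUG scanning, weighted stats, binned
# medians, Mann-Whitney.

test_that("utr5_density_flags requires at least one footprint", {
  m <- cbind(s1 = c(g1 = 0, g2 = 1, g3 = 5))
  fl <- utr5_density_flags(m)
  expect_identical(unname(fl), c(FALSE, TRUE, TRUE))
})

test_that("uaug_scan counts overlapping AUGs, RNA or DNA, any case", {
  got <- uaug_scan(c("CCAUGCC", "GCGCGC", "AUGCAUGAUG", "ccatgcc", ""))
  expect_identical(got$has_uaug, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(got$n_uaug, c(1L, 0L, 3L, 1L, 0L))
  # overlapping occurrences are counted at every start position
  expect_identical(uaug_scan("ATGATGATG")$n_uaug, 3L)
})

test_that("uaug_scan agrees with the brute-force scanner", {
  set.seed(19)
  seqs <- vapply(1:2000, function(i)
    paste(sample(c("A", "T", "G", "C"), sample(3:40, 1), replace = TRUE),
          collapse = ""), "")
  got <- uaug_scan(seqs)$n_uaug
  want <- vapply(seqs, oracle_uaug_count, 0L, USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("weighted_utr5_stats computes abundance-weighted length and GC", {
  m <- transcript_models(
    gene_id = c("g1", "g2", "g2"),
    transcript_id = c("g1.t1", "g2.t1", "g2.t2"),
    sequence = c(paste0(strrep("G", 100), "ATG", strrep("C", 60)),
                 paste0(strrep("G", 100), "ATG", strrep("C", 60)),
                 paste0(strrep("GA", 100), "ATG", strrep("C", 60))),
    cds_start = c(100, 100, 200),
    cds_end = c(160, 160, 260),
    isoform_abundance = c(1, 1, 1))
  st <- weighted_utr5_stats(m)
  expect_equal(st$utr5_length[st$gene == "g1"], 100)
  expect_equal(st$utr5_gc[st$gene == "g1"], 1)
  # two isoforms, equal abundance, lengths 100/200 -> 150; GC (1 + 0.5)/2
  expect_equal(st$utr5_length[st$gene == "g2"], 150)
  expect_equal(st$utr5_gc[st$gene == "g2"], 0.75)

  # invariant to rescaling a gene's abundances
  m2 <- m
  m2$isoform_abundance[m2$gene_id == "g2"] <- c(10, 10)
  expect_equal(weighted_utr5_stats(m2), st)
})

test_that("binned_median_te: single bin gives the global median", {
  rec <- data.frame(utr5_gc = runif(20, 0.2, 0.8),
                    utr5_length = runif(20, 10, 300),
                    cds_log2_te = rnorm(20))
  out <- binned_median_te(rec, gc_breaks = c(0, 1),
                          length_breaks = c(0, Inf))
  expect_equal(out$by_gc$median_te, median(rec$cds_log2_te))
  expect_equal(out$by_length$median_te, median(rec$cds_log2_te))
  expect_equal(unname(out$grid[1, 1]), median(rec$cds_log2_te))
  # median of a single zero is zero
  out0 <- binned_median_te(data.frame(utr5_gc = 0.5, utr5_length = 50,
                                      cds_log2_te = 0),
                           gc_breaks = c(0, 1), length_breaks = c(0, Inf))
  expect_equal(out0$by_gc$median_te, 0)
})

test_that("longer 5' UTRs carry lower TE in the generator's world", {
  sim <- simulate_annotation(small_config(n_genes = 400,
                                          utr5_length_te_slope = -1))
  st <- weighted_utr5_stats(sim$models)
  rec <- data.frame(
    utr5_gc = st$utr5_gc, utr5_length = st$utr5_length,
    cds_log2_te = sim$truth$log2_te_untreated[match(st$gene,
                                                    sim$truth$gene_id)])
  out <- binned_median_te(rec, gc_breaks = c(0, 1),
                          length_breaks = c(0, 60, 120))
  expect_gt(out$by_length$median_te[1], out$by_length$median_te[2])
})

test_that("mann_whitney_u: exact enumeration, ties, approximation", {
  # U = 0 and exact two-sided p = 1/3 for (1,2) vs (3,4)
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 1 / 3)
  expect_equal(mw$method, "exact")
  expect_equal(mw$stars, "")

  # identical groups -> p = 1
  expect_equal(mann_whitney_u(c(5, 6, 7), c(5, 6, 7))$p, 1)

  # midranks: pooled (1,2,2),(2,3) -> ranks 1, 3,3,3, 5; U_a = 7 - 6 = 1
  expect_equal(mann_whitney_u(c(1, 2, 2), c(2, 3))$u, 1)

  # exact vs normal approximation agree within 0.02 at the boundary
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(6)
    b <- rnorm(6, mean = runif(1, 0, 2))
    pe <- mann_whitney_u(a, b, exact_limit = 12)$p
    pn <- mann_whitney_u(a, b, exact_limit = 0)$p
    expect_lt(abs(pe - pn), 0.02)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("star annotation follows the conventional thresholds", {
  set.seed(29)
  a <- rnorm(40)
  b <- rnorm(40, mean = 3)
  expect_equal(mann_whitney_u(a, b)$stars, "***")
})

test_that("uaug_te_comparison recovers the configured uAUG effect", {
  sim <- simulate_annotation(small_config(n_genes = 600,
                                          uaug_te_shift = -0.5, seed = 99))
  tg <- sim$truth
  set.seed(55)
  rec <- data.frame(gene = tg$gene_id,
                    has_density = runif(nrow(tg)) < 0.8,
                    has_uaug = tg$has_uaug,
                    cds_log2_te = tg$log2_te_untreated)
  lists <- lapply(split(tg$gene_id, tg$cell_type), identity)
  out <- uaug_te_comparison(rec, lists)
  expect_true(all(out$delta_median < 0))
  expect_lt(out$p[out$stratum == "all"], 0.001)

  # null world: no uAUG shift -> no signal at the fixed seed
  sim0 <- simulate_annotation(small_config(n_genes = 600, uaug_te_shift = 0,
                                           utr5_length_te_slope = 0,
                                           seed = 98))
  rec0 <- data.frame(gene = sim0$truth$gene_id,
                     has_density = TRUE,
                     has_uaug = sim0$truth$has_uaug,
                     cds_log2_te = sim0$truth$log2_te_untreated)
  out0 <- uaug_te_comparison(rec0)
  expect_gt(out0$p[out0$stratum == "all"], 0.05)

  # empty stratum skipped with a message
  expect_message(
    uaug_te_comparison(rec, list(empty = character(0))), "skipped")
})
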