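# preprocessing: trimming/clipping rules, rRNA subtraction, toy mapper,
# duplicate marking.

test_that("trim_and_clip applies the fixed rules in order", {
  # 75 nt read, no poly(A) run after trimming -> 50 nt kept
  r75 <- random_read(75)
  r75 <- gsub("AAAAAAAA", "CACGTACG", r75, fixed = TRUE)
  out <- trim_and_clip(r75)
  expect_equal(out$status, "kept")
  expect_equal(nchar(out$sequence), 50)
  expect_equal(out$sequence, substr(r75, 6, 55))

  # 39 nt read -> 14 nt -> discarded (below the 15-base retention boundary)
  r39 <- paste(rep("C", 39), collapse = "")
  out <- trim_and_clip(r39)
  expect_equal(out$status, "too_short")
  expect_equal(out$sequence, "")

  # 40 nt -> exactly 15 nt retained: the boundary is kept
  expect_equal(trim_and_clip(paste(rep("C", 40), collapse = ""))$status,
               "kept")

  # 30 nt footprint + 10 A tail (post-trim): clip removes exactly the run
  fp <- gsub("A", "G", random_read(30))
  raw <- paste0(strrep("G", 5), fp, strrep("A", 10), strrep("T", 20))
  out <- trim_and_clip(raw)
  expect_equal(out$sequence, fp)

  # raw length <= 25 is too_short with empty sequence, not an error
  out <- trim_and_clip(strrep("C", 25))
  expect_equal(out$status, "too_short")
  expect_equal(out$sequence, "")
})

test_that("trim_and_clip with trimming disabled is the identity on clean reads", {
  seqs <- vapply(1:20, function(i) gsub("AAAAAAAA", "CGTACGTA",
                                        random_read(40)), "")
  out <- trim_and_clip(seqs, trim5 = 0, trim3 = 0)
  expect_identical(out$sequence, unname(seqs))
  expect_true(all(out$status == "kept"))
})

test_that("trim_and_clip matches the character-by-character oracle exactly", {
  set.seed(123)
  n <- 1000
  lens <- sample(20:80, n, replace = TRUE)
  reads <- vapply(seq_len(n), function(i) {
    if (runif(1) < 0.5)
      random_read(lens[i], polya_at = sample.int(max(lens[i] - 8, 1), 1),
                  polya_len = sample(6:30, 1))
    else random_read(lens[i])
  }, "")
  got <- trim_and_clip(reads)
  want <- lapply(reads, oracle_trim)
  expect_identical(got$sequence, vapply(want, `[[`, "", "sequence"))
  expect_identical(got$status, vapply(want, `[[`, "", "status"))
})

test_that("filter_rrna labels Hamming<=1 substring matches", {
  set.seed(5)
  ref <- random_read(200)
  exact <- substr(ref, 50, 79)
  one_mm <- exact
  substr(one_mm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(exact, 10, 10))[1]
  two_mm <- one_mm
  substr(two_mm, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                    substr(exact, 20, 20))[1]
  out <- filter_rrna(c(a = exact, b = one_mm, c = two_mm), ref)
  expect_equal(out$status, c("rrna", "rrna", "kept"))
  # agreement with the brute-force Hamming scan oracle
  for (i in seq_len(nrow(out)))
    expect_equal(out$status[i] == "rrna",
                 oracle_rrna_hit(out$sequence[i], ref))

  expect_error(filter_rrna("ACGT", character(0)), "non-empty")
  expect_equal(nrow(filter_rrna(character(0), ref)), 0)
})

test_that("toy mapper implements uniquely-mapped semantics and tie-breaks", {
  m <- toy_models()
  read <- substr(m$sequence[1], 11, 40)
  res <- map_to_transcriptome(c(r1 = read), m)
  expect_equal(res$alignments$five_prime_pos, 10)
  expect_equal(res$alignments$length, 30)
  expect_equal(res$alignments$gene_id, "gA")

  # read present in both genes -> multimapped, excluded
  shared <- "TTTTACGTACGTACGTACGT"
  m2 <- m
  m2$sequence <- paste0(m2$sequence, shared)
  m2$length <- nchar(m2$sequence)
  res <- map_to_transcriptome(c(r1 = shared), m2)
  expect_equal(res$fates$status, "multimapped")
  expect_equal(nrow(res$alignments), 0)

  # unmatched read -> unmapped
  res <- map_to_transcriptome(c(r1 = strrep("ACGTT", 6)), m)
  expect_equal(res$fates$status, "unmapped")

  # tie within one gene (two isoforms sharing the CDS): lowest transcript
  # id, leftmost position wins
  m3 <- transcript_models(
    gene_id = c("g1", "g1"), transcript_id = c("g1.t2", "g1.t1"),
    sequence = c(m$sequence[1], paste0("TTTTTTTTTT", m$sequence[1])),
    cds_start = c(10, 20), cds_end = c(70, 80))
  read <- substr(m$sequence[1], 11, 40)
  res <- map_to_transcriptome(c(r1 = read), m3)
  expect_equal(res$alignments$transcript_id, "g1.t1")
  expect_equal(res$alignments$five_prime_pos, 20)
})

test_that("mark_duplicates keys on (transcript, position, length)", {
  a <- aln("g", "g.t1", pos = c(10, 10, 10), len = 30)
  md <- mark_duplicates(a)
  expect_equal(md$n_unique_fragments, 1)
  expect_equal(md$alignments$duplicate, c(FALSE, TRUE, TRUE))

  b <- aln("g", "g.t1", pos = c(10, 10), len = c(30, 31))
  md <- mark_duplicates(b)
  expect_equal(md$n_unique_fragments, 2)
  expect_false(any(md$alignments$duplicate))

  md <- mark_duplicates(aln("g", "g.t1", pos = integer(0)))
  expect_equal(md$n_unique_fragments, 0)
})

test_that("every read receives exactly one terminal status", {
  sim <- simulate_annotation(small_config())
  fp <- simulate_footprints(sim, depth = 400, seed = 2)
  rrna_ref <- paste(rep("GCGGCTACCACATCCAAGGAA", 4), collapse = "")
  reads <- rbind(fp$reads,
                 data.frame(read_id = c("short", "rrna_read", "junk"),
                            sequence = c(strrep("C", 30),
                                         paste0(strrep("G", 5),
                                                substr(rrna_ref, 1, 30),
                                                strrep("A", 40)),
                                         paste0(strrep("G", 5),
                                                strrep("CT", 15),
                                                strrep("A", 40))),
                            stringsAsFactors = FALSE))
  res <- preprocess_reads(reads, sim$models, rrna_refs = rrna_ref)
  expect_equal(nrow(res$fates), nrow(reads))
  expect_true(all(res$fates$status %in%
                    c("kept", "too_short", "rrna", "unmapped",
                      "multimapped")))
  expect_equal(res$fates$status[res$fates$read_id == "short"], "too_short")
  expect_equal(res$fates$status[res$fates$read_id == "rrna_read"], "rrna")
  expect_equal(res$fates$status[res$fates$read_id == "junk"], "unmapped")
  expect_equal(sum(res$summary$n_reads), nrow(reads))
})
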