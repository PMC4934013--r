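# Independent reference implementations (oracles) used to cross-check the
# package's optimized paths. Deliberately naive: character-by-character,
# brute-force enumeration.

# trimming/clipping oracle: plain loops over characters
oracle_trim <- function(seq, trim5 = 5L, trim3 = 20L, min_len = 15L) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) <= trim5 + trim3)
    return(list(sequence = "", status = "too_short"))
  chars <- chars[(trim5 + 1L):(length(chars) - trim3)]
  # leftmost position where 8 consecutive A's start
  run_start <- NA_integer_
  if (length(chars) >= 8) {
    for (i in 1:(length(chars) - 7L)) {
      if (all(chars[i:(i + 7L)] == "A")) {
        run_start <- i
        break
      }
    }
  }
  if (!is.na(run_start)) chars <- chars[seq_len(run_start - 1L)]
  if (length(chars) < min_len) list(sequence = "", status = "too_short")
  else list(sequence = paste(chars, collapse = ""), status = "kept")
}

# Hamming-substring oracle: does `read` match any window of any reference
# with at most max_mm mismatches?
oracle_rrna_hit <- function(read, refs, max_mm = 1L) {
  rc <- strsplit(read, "")[[1]]
  for (ref in refs) {
    fc <- strsplit(ref, "")[[1]]
    if (length(fc) < length(rc)) next
    for (s in 1:(length(fc) - length(rc) + 1L)) {
      mm <- sum(fc[s:(s + length(rc) - 1L)] != rc)
      if (mm <= max_mm) return(TRUE)
    }
  }
  FALSE
}

# classic GSEA running-sum oracle over the full list; same documented
# tie-break as the package (positive wins on equal magnitude)
oracle_es <- function(ranked_genes, set) {
  hit <- ranked_genes %in% set
  nh <- sum(hit)
  nm <- sum(!hit)
  stopifnot(nh > 0, nm > 0)
  running <- cumsum(ifelse(hit, 1 / nh, -1 / nm))
  mx <- max(running)
  mn <- min(running, 0)
  if (mx >= -mn - 1e-12) mx else mn
}

# position-by-position overlapping AUG scan
oracle_uaug_count <- function(seq) {
  s <- chartr("u", "t", tolower(seq))
  n <- nchar(s)
  if (n < 3) return(0L)
  cnt <- 0L
  for (i in 1:(n - 2L)) if (substr(s, i, i + 2L) == "atg") cnt <- cnt + 1L
  cnt
}

# random read with optional embedded poly(A) run
random_read <- function(len, polya_at = NA, polya_len = 0) {
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.2, 0.3, 0.3, 0.2))
  if (!is.na(polya_at) && polya_len > 0) {
    end <- min(len, polya_at + polya_len - 1L)
    chars[polya_at:end] <- "A"
  }
  paste(chars, collapse = "")
}
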