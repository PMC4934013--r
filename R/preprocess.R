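# Preprocessing of raw ligation-free reads: fixed trimming, poly(A)
# clipping, length filter, rRNA subtraction, transcriptome mapping,
# duplicate marking.

#' Trim and clip raw ligation-free reads
#'
#' Applies the fixed read-structure rules, in order: (1) drop the first
#' `trim5` bases (the G-rich template-switching prefix), (2) drop the last
#' `trim3` bases, (3) if the remaining sequence contains a run of >= 8
#' consecutive A's, clip from the start of the leftmost such run to the 3'
#' end (poly(A) tail removal, fastx_clipper-like: no mismatch tolerated
#' inside the run), (4) mark reads shorter than `min_length` as `too_short`.
#' Reads of raw length `<= trim5 + trim3` become `too_short` with an empty
#' sequence rather than raising an error.
#'
#' @param reads character vector of raw read sequences (names, if any, become
#'   read ids) or a data frame with columns `read_id`, `sequence`.
#' @param trim5,trim3 number of bases removed from the 5'/3' ends.
#' @param min_length minimum retained length after trimming and clipping.
#' @return data frame `read_id`, `sequence` (empty for `too_short`),
#'   `status` (`kept`/`too_short`).
#' @export
trim_and_clip <- function(reads, trim5 = 5L, trim3 = 20L, min_length = 15L) {
  rd <- as_read_frame(reads)
  n <- nchar(rd$sequence)
  core <- ifelse(n > trim5 + trim3,
                 substr(rd$sequence, trim5 + 1L, n - trim3), "")
  m <- regexpr("AAAAAAAA", core, fixed = TRUE)
  clipped <- ifelse(m > 0L, substr(core, 1L, m - 1L), core)
  status <- ifelse(nchar(clipped) >= min_length, "kept", "too_short")
  data.frame(read_id = rd$read_id,
             sequence = ifelse(status == "kept", clipped, ""),
             status = status, stringsAsFactors = FALSE)
}

as_read_frame <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    data.frame(read_id = as.character(reads$read_id),
               sequence = toupper(reads$sequence), stringsAsFactors = FALSE)
  } else {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%08d", seq_along(reads))
    data.frame(read_id = ids, sequence = toupper(as.character(reads)),
               stringsAsFactors = FALSE)
  }
}

#' Partition reads into rRNA contaminants and kept reads
#'
#' A read is labelled `rrna` iff it matches a substring of any reference
#' sequence with Hamming distance `<= max_mismatch` (sense strand only, as
#' reads are sense-stranded after the ligation-free protocol); all other
#' reads pass through as `kept`. Backed by `Biostrings::vcountPattern`.
#'
#' @param reads character vector or data frame (`read_id`, `sequence`).
#' @param rrna_refs non-empty character vector (or `DNAStringSet`) of rRNA
#'   reference sequences.
#' @param max_mismatch maximum Hamming distance (default 1, "allowing for
#'   one error").
#' @return data frame `read_id`, `sequence`, `status` (`rrna`/`kept`).
#' @export
filter_rrna <- function(reads, rrna_refs, max_mismatch = 1L) {
  if (length(rrna_refs) == 0) stop("rrna_refs must be non-empty")
  rd <- as_read_frame(reads)
  if (nrow(rd) == 0)
    return(data.frame(read_id = character(), sequence = character(),
                      status = character(), stringsAsFactors = FALSE))
  subj <- Biostrings::DNAStringSet(as.character(rrna_refs))
  hit <- vapply(rd$sequence, function(s) {
    any(Biostrings::vcountPattern(s, subj, max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE) > 0)
  }, logical(1), USE.NAMES = FALSE)
  data.frame(read_id = rd$read_id, sequence = rd$sequence,
             status = ifelse(hit, "rrna", "kept"), stringsAsFactors = FALSE)
}

#' Map processed reads to a transcriptome (toy exact mapper)
#'
#' Exact-substring search of each read against the transcript sequences
#' (sense strand). Reads matching transcripts of more than one gene are
#' labelled `multimapped` and excluded, implementing "uniquely mapped"
#' semantics; reads with no match are `unmapped`. Within one gene, ties are
#' broken by lowest `transcript_id` then leftmost position. Backed by
#' `Biostrings::PDict`/`matchPDict` over a concatenated subject.
#'
#' @param reads character vector or data frame (`read_id`, `sequence`).
#' @param models a [transcript_models()] table.
#' @param max_mismatch 0 for exact matching (default). Values > 0 use a
#'   slower per-read scan with `Biostrings::vmatchPattern`.
#' @return list with `alignments` (data frame `read_id`, `gene_id`,
#'   `transcript_id`, `five_prime_pos` (0-based), `length`) and `fates`
#'   (data frame `read_id`, `status` in `mapped`/`multimapped`/`unmapped`).
#' @export
map_to_transcriptome <- function(reads, models, max_mismatch = 0L) {
  models <- validate_transcript_models(models)
  rd <- as_read_frame(reads)
  n_reads <- nrow(rd)
  status <- rep("unmapped", n_reads)
  hits <- vector("list", n_reads)

  if (n_reads > 0) {
    sep <- strrep("N", 40L)
    subject <- Biostrings::DNAString(paste(models$sequence, collapse = sep))
    tx_start <- cumsum(c(1L, utils::head(models$length + 40L, -1L)))

    collect <- function(idx, starts_list) {
      for (k in seq_along(idx)) {
        s <- starts_list[[k]]
        if (is.null(s) || length(s) == 0) next
        tx <- findInterval(s, tx_start)
        hits[[idx[k]]] <<- data.frame(tx = tx,
                                      pos = s - tx_start[tx],
                                      stringsAsFactors = FALSE)
      }
    }
    if (max_mismatch == 0L) {
      widths <- nchar(rd$sequence)
      for (w in unique(widths)) {
        idx <- which(widths == w)
        if (w < 1) next
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(rd$sequence[idx]))
        mi <- Biostrings::matchPDict(pd, subject)
        collect(idx, Biostrings::startIndex(mi))
      }
    } else {
      starts_list <- lapply(rd$sequence, function(s) {
        Biostrings::start(Biostrings::matchPattern(
          s, subject, max.mismatch = max_mismatch, with.indels = FALSE))
      })
      collect(seq_len(n_reads), starts_list)
    }
  }

  aln <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    h <- hits[[i]]
    if (is.null(h)) next
    genes <- unique(models$gene_id[h$tx])
    if (length(genes) > 1L) {
      status[i] <- "multimapped"
      next
    }
    status[i] <- "mapped"
    o <- order(models$transcript_id[h$tx], h$pos)[1L]
    aln[[i]] <- data.frame(read_id = rd$read_id[i],
                           gene_id = genes,
                           transcript_id = models$transcript_id[h$tx[o]],
                           five_prime_pos = h$pos[o],
                           length = nchar(rd$sequence[i]),
                           stringsAsFactors = FALSE)
  }
  alignments <- if (any(status == "mapped"))
    do.call(rbind, aln[!vapply(aln, is.null, TRUE)])
  else data.frame(read_id = character(), gene_id = character(),
                  transcript_id = character(), five_prime_pos = integer(),
                  length = integer(), stringsAsFactors = FALSE)
  rownames(alignments) <- NULL
  list(alignments = alignments,
       fates = data.frame(read_id = rd$read_id, status = status,
                          stringsAsFactors = FALSE))
}

#' Mark duplicate footprints and count unique fragments
#'
#' Fragments identical on `(transcript_id, five_prime_pos, length)` beyond
#' the first occurrence are flagged as duplicates; the unique-fragment count
#' is the number of distinct keys (library-complexity metric).
#'
#' @param alignments alignment data frame (see [map_to_transcriptome()]).
#' @return list with `alignments` (input plus logical `duplicate` column)
#'   and `n_unique_fragments`.
#' @export
mark_duplicates <- function(alignments) {
  if (nrow(alignments) == 0) {
    alignments$duplicate <- logical(0)
    return(list(alignments = alignments, n_unique_fragments = 0L))
  }
  validate_alignments(alignments)
  key <- paste(alignments$transcript_id, alignments$five_prime_pos,
               alignments$length, sep = "\r")
  alignments$duplicate <- duplicated(key)
  list(alignments = alignments,
       n_unique_fragments = length(unique(key)))
}

#' Run the full preprocessing chain
#'
#' trim/clip -> rRNA subtraction -> transcriptome mapping -> duplicate
#' marking. Every input read receives exactly one terminal status among
#' `too_short`, `rrna`, `unmapped`, `multimapped`, `kept`.
#'
#' @param reads raw reads (character vector or `read_id`/`sequence` frame).
#' @param models a [transcript_models()] table.
#' @param rrna_refs rRNA reference sequences (may be `NULL` to skip).
#' @param trim5,trim3,min_length see [trim_and_clip()].
#' @param max_mismatch see [map_to_transcriptome()].
#' @return list with `alignments` (duplicate-flagged), `n_unique_fragments`,
#'   `fates` (per-read terminal status) and `summary` (status counts).
#' @export
preprocess_reads <- function(reads, models, rrna_refs = NULL,
                             trim5 = 5L, trim3 = 20L, min_length = 15L,
                             max_mismatch = 0L) {
  tr <- trim_and_clip(reads, trim5 = trim5, trim3 = trim3,
                      min_length = min_length)
  fate <- stats::setNames(tr$status, tr$read_id)
  keep <- tr[tr$status == "kept", c("read_id", "sequence")]
  if (!is.null(rrna_refs) && nrow(keep) > 0) {
    fr <- filter_rrna(keep, rrna_refs)
    fate[fr$read_id[fr$status == "rrna"]] <- "rrna"
    keep <- fr[fr$status == "kept", c("read_id", "sequence")]
  }
  mp <- map_to_transcriptome(keep, models, max_mismatch = max_mismatch)
  fate[mp$fates$read_id] <- ifelse(mp$fates$status == "mapped", "kept",
                                   mp$fates$status)
  dup <- mark_duplicates(mp$alignments)
  summary <- as.data.frame(table(status = factor(
    fate, levels = c("kept", "too_short", "rrna", "unmapped",
                     "multimapped"))), stringsAsFactors = FALSE)
  names(summary) <- c("status", "n_reads")
  list(alignments = dup$alignments,
       n_unique_fragments = dup$n_unique_fragments,
       fates = data.frame(read_id = names(fate), status = unname(fate),
                          stringsAsFactors = FALSE),
       summary = summary)
}
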