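# Strand-aware profiling of small RNAs against reference transcripts:
# sense/antisense accounting, per-base coverage, duplex-partner detection
# among mapped reads, coverage-pattern classification and a position
# frequency matrix for near-identical read families.

#' Map small RNAs onto one transcript, strand-aware
#'
#' Reports every contiguous occurrence of each read (sense) and of its
#' reverse complement (antisense) on the transcript, with at most
#' `max_mismatches` mismatches and no gaps. Multi-occurrence reads yield
#' one mapping per occurrence. With the default `max_mismatches = 0` a
#' read containing `N` only matches a transcript position that also
#' carries `N`.
#'
#' @param cs A `collapsed_set` (or data frame with `id`, `seq`, `count`;
#'   a missing `count` column is treated as all-1).
#' @param transcript_id,transcript_seq Identifier and sequence of the
#'   reference transcript.
#' @param max_mismatches Mismatch tolerance (default 0).
#' @return A data frame with one row per mapping: `read_id`, `transcript`,
#'   `start` (0-based), `strand` (`"sense"`/`"antisense"`), `mismatches`,
#'   `len`, `count`.
#' @export
map_reads <- function(cs, transcript_id, transcript_seq,
                      max_mismatches = 0L) {
  stopifnot(nchar(transcript_seq) >= 1L)
  transcript_seq <- normalize_seq(transcript_seq)
  counts <- if (!is.null(cs$count)) cs$count else rep(1L, nrow(cs))
  subject <- Biostrings::DNAString(transcript_seq)
  rows <- list()
  scan <- function(pattern, strand, i) {
    if (nchar(pattern) > nchar(transcript_seq)) return()
    hits <- Biostrings::matchPattern(pattern, subject,
                                     max.mismatch = max_mismatches,
                                     fixed = TRUE)
    for (h in seq_along(hits)) {
      st <- Biostrings::start(hits)[h]
      mm <- sum(seq_ints(pattern) != seq_ints(
        substr(transcript_seq, st, st + nchar(pattern) - 1L)))
      rows[[length(rows) + 1L]] <<- data.frame(
        read_id = cs$id[i], transcript = transcript_id, start = st - 1L,
        strand = strand, mismatches = mm, len = nchar(pattern),
        count = counts[i], stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(cs))) {
    scan(cs$seq[i], "sense", i)
    scan(revcomp(cs$seq[i]), "antisense", i)
  }
  if (!length(rows)) {
    return(data.frame(read_id = character(), transcript = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), len = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a strand-aware profile of one transcript
#'
#' Aggregates mappings into count-weighted sense/antisense totals,
#' per-base coverage vectors for each strand, and (optionally) the number
#' of antisense mappings starting in a declared 3' UTR.
#'
#' @param mappings Mappings of reads onto this transcript, from
#'   [map_reads()].
#' @param transcript_id,transcript_seq The profiled transcript.
#' @param utr3_start Optional 0-based offset where the 3' UTR begins.
#' @param weighted Weight reads by collapsed copy counts (default `TRUE`);
#'   `FALSE` counts each unique mapped read once.
#' @return A `transcript_profile`: list with `transcript`, `total_reads`,
#'   `antisense_reads`, `sense_coverage`, `antisense_coverage`,
#'   `utr3_antisense` (`NA` when no UTR given), `mappings`.
#' @export
profile_transcript <- function(mappings, transcript_id, transcript_seq,
                               utr3_start = NULL, weighted = TRUE) {
  L <- nchar(transcript_seq)
  if (!is.null(utr3_start) && (utr3_start < 0L || utr3_start > L)) {
    stop("utr3_start outside transcript [0, ", L, "]", call. = FALSE)
  }
  if (nrow(mappings) && !all(mappings$transcript == transcript_id)) {
    stop("mappings refer to a different transcript", call. = FALSE)
  }
  w <- if (weighted) mappings$count else rep(1L, nrow(mappings))
  sense <- mappings$strand == "sense"
  cov <- function(keep) {
    v <- numeric(L)
    for (r in which(keep)) {
      idx <- (mappings$start[r] + 1L):(mappings$start[r] + mappings$len[r])
      v[idx] <- v[idx] + w[r]
    }
    v
  }
  utr3 <- if (is.null(utr3_start)) NA_integer_ else
    sum(w[!sense & mappings$start >= utr3_start])
  structure(list(transcript = transcript_id,
                 total_reads = sum(w),
                 antisense_reads = sum(w[!sense]),
                 sense_coverage = cov(sense),
                 antisense_coverage = cov(!sense),
                 utr3_antisense = utr3,
                 mappings = mappings),
            class = "transcript_profile")
}

#' @export
print.transcript_profile <- function(x, ...) {
  cat(sprintf("<transcript_profile '%s': %d reads (%d antisense)>\n",
              x$transcript, x$total_reads, x$antisense_reads))
  invisible(x)
}

#' Duplex partners between antisense and sense reads on one transcript
#'
#' For every antisense-mapped read, tests every sense-mapped read for
#' Dicer duplex geometry with [pair_duplex()] and returns all valid
#' pairs. This asks whether the antisense reads could be miRNAs whose
#' targets (or precursor complements) are among the sense reads.
#'
#' @param profile A `transcript_profile`.
#' @param cs The `collapsed_set` the mappings were built from (sequence
#'   lookup by read id).
#' @param max_mismatches,max_bulges,overhang Passed to [pair_duplex()].
#' @return Data frame with one row per valid pair: `antisense_id`,
#'   `sense_id`, `mismatches`, `bulges`.
#' @export
find_sense_partners <- function(profile, cs, max_mismatches = 3L,
                                max_bulges = 1L, overhang = 2L) {
  m <- profile$mappings
  anti <- unique(m$read_id[m$strand == "antisense"])
  sens <- unique(m$read_id[m$strand == "sense"])
  seq_of <- stats::setNames(cs$seq, cs$id)
  rows <- list()
  for (ai in anti) {
    for (si in sens) {
      al <- pair_duplex(seq_of[[ai]], seq_of[[si]], max_mismatches,
                        max_bulges, overhang)
      if (!is.null(al)) {
        rows[[length(rows) + 1L]] <- data.frame(
          antisense_id = ai, sense_id = si, mismatches = al$mismatches,
          bulges = nrow(al$bulges), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(antisense_id = character(), sense_id = character(),
                      mismatches = integer(), bulges = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the read-mapping pattern of a transcript
#'
#' Three empirical patterns of stranded coverage: `A` — every read in the
#' same (sense) direction, the signature of mRNA degradation fragments;
#' `B` — a small minority of antisense reads; `C` — a substantial
#' antisense fraction (above `many_threshold`, default 20%), seen e.g.
#' for bidirectionally transcribed or contaminating loci.
#'
#' @param profile A `transcript_profile` with `total_reads > 0`.
#' @param many_threshold Antisense fraction above which the pattern is
#'   `C` (default 0.20).
#' @return `"A"`, `"B"` or `"C"`.
#' @export
classify_pattern <- function(profile, many_threshold = 0.20) {
  if (profile$total_reads == 0L) {
    stop("pattern undefined for a transcript with no mapped reads",
         call. = FALSE)
  }
  frac <- profile$antisense_reads / profile$total_reads
  if (frac == 0) "A" else if (frac > many_threshold) "C" else "B"
}

longest_common_substring <- function(seqs) {
  ref <- seqs[which.min(nchar(seqs))]
  n <- nchar(ref)
  for (len in n:1) {
    for (s in 1:(n - len + 1L)) {
      core <- substr(ref, s, s + len - 1L)
      if (all(vapply(seqs, grepl, logical(1L), pattern = core,
                     fixed = TRUE))) {
        return(core)
      }
    }
  }
  ""
}

#' Position frequency matrix of near-identical sequences
#'
#' Aligns the sequences without gaps by anchoring each on its leftmost
#' occurrence of the longest substring common to the whole set, then
#' counts bases per aligned column. The consensus takes the majority base
#' per column, ties broken alphabetically; columns where a single base
#' has frequency 1.0 are flagged as identities.
#'
#' @param seqs Character vector of sequences (at least one); intended for
#'   families of near-identical small RNAs.
#' @return A `position_frequency_matrix`: list with `counts` (4 x L
#'   matrix, rows A,C,G,T), `n_sequences`, `consensus`, `identity`
#'   (logical per column: one base at frequency 1.0 among covering
#'   sequences).
#' @export
build_pfm <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  seqs <- normalize_seq(seqs)
  core <- longest_common_substring(seqs)
  if (nchar(core) == 0L) {
    stop("sequences share no common substring to anchor on", call. = FALSE)
  }
  anchor <- as.integer(regexpr(core, seqs, fixed = TRUE))  # 1-based
  lead <- max(anchor) - anchor           # left padding per sequence
  width <- max(lead + nchar(seqs))
  counts <- matrix(0L, nrow = 4L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(seqs)) {
    v <- seq_ints(seqs[i])
    pos <- lead[i] + seq_along(v)
    for (j in seq_along(v)) {
      if (v[j] > 0L) counts[v[j], pos[j]] <- counts[v[j], pos[j]] + 1L
    }
  }
  colsum <- colSums(counts)
  top <- apply(counts, 2L, which.max)    # ties -> lowest index = alphabetical
  consensus <- paste(c("A", "C", "G", "T")[top], collapse = "")
  identity <- colsum > 0L & apply(counts, 2L, max) == colsum
  structure(list(counts = counts, n_sequences = length(seqs),
                 consensus = consensus, identity = identity),
            class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, ...) {
  cat(sprintf("<position_frequency_matrix: %d sequences, %d columns>\nconsensus: %s\n",
              x$n_sequences, ncol(x$counts), x$consensus))
  invisible(x)
}
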