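# The cleaning cascade: adapter trim -> rRNA -> tRNA -> polyA -> size
# selection -> second rRNA/tRNA pass -> organelle subtraction, with a
# per-stage accounting report. Subtraction is exact/near-exact substring
# matching against small reference sets; reads are <= ~30 nt so no
# external aligner is needed.

#' Default TruSeq small-RNA 3' adapter
#'
#' The standard Illumina TruSeq small-RNA 3' adapter sequence, used as the
#' documented default when a library's adapter is not stated.
#' @return A length-1 character string.
#' @export
truseq_small_rna_adapter <- function() "TGGAATTCTCGGGTGCCAAGG"

#' Cascade configuration
#'
#' Bundles the cleaning-cascade parameters: adapter sequence, polyA run
#' threshold, size-selection window, subtraction mismatch tolerance and
#' the per-stage reference sets. Stages whose reference set (or adapter)
#' is `NULL` are skipped.
#'
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @param polya_max_run Reads containing a run of consecutive `A` strictly
#'   longer than this are removed (default 6, i.e. ">6 bases").
#' @param size_min,size_max Inclusive length window retained by size
#'   selection (defaults 18 and 26 nt).
#' @param max_mismatches Mismatch tolerance for reference subtraction
#'   (default 0; 1 approximates a tolerant short-read aligner).
#' @param rrna,trna,organelle `reference_set` objects (or `NULL` to skip
#'   the stage).
#' @param second_pass Re-run rRNA/tRNA subtraction after size selection
#'   (default `TRUE`; trimming and selection can expose matches).
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(adapter = truseq_small_rna_adapter(),
                           polya_max_run = 6L,
                           size_min = 18L, size_max = 26L,
                           max_mismatches = 0L,
                           rrna = NULL, trna = NULL, organelle = NULL,
                           second_pass = TRUE) {
  stopifnot(polya_max_run >= 0L, size_min >= 1L, size_min <= size_max,
            max_mismatches >= 0L)
  if (!is.null(adapter)) adapter <- normalize_seq(adapter)
  structure(list(adapter = adapter, polya_max_run = as.integer(polya_max_run),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 max_mismatches = as.integer(max_mismatches),
                 rrna = rrna, trna = trna, organelle = organelle,
                 second_pass = isTRUE(second_pass)),
            class = "cascade_config")
}

#' Trim the 3' sequencing adapter from reads
#'
#' Removes the adapter at the leftmost position where either the full
#' adapter occurs internally, or a prefix of the adapter (of length at
#' least `min_overlap`) ends the read. The 5' remainder is returned; reads
#' whose remainder is empty are rejected (dropped with their rejection
#' recorded), and reads with no adapter occurrence pass unchanged.
#'
#' @param reads Data frame of reads (`id`, `seq`, optional `qual`).
#' @param adapter Adapter sequence (non-empty).
#' @param min_overlap Minimum adapter-prefix length at the 3' end
#'   (default 3).
#' @return A list with `reads` (trimmed survivors, input order preserved)
#'   and `rejected` (number of reads with empty remainder).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 3L) {
  stopifnot(nchar(adapter) >= 1L)
  adapter <- normalize_seq(adapter)
  seqs <- reads$seq
  cut <- nchar(seqs) + 1L  # default: no trim
  # full internal occurrence, leftmost
  hit <- regexpr(adapter, seqs, fixed = TRUE)
  full <- hit > 0L
  cut[full] <- hit[full]
  # else: longest adapter prefix anchored at the 3' end
  todo <- which(!full)
  if (length(todo)) {
    maxk <- min(nchar(adapter) - 1L, max(nchar(seqs[todo]), 0L))
    if (maxk >= min_overlap) {
      for (k in maxk:min_overlap) {
        pref <- substr(adapter, 1L, k)
        isuf <- todo[endsWith(seqs[todo], pref)]
        cut[isuf] <- nchar(seqs[isuf]) - k + 1L
        todo <- setdiff(todo, isuf)
        if (!length(todo)) break
      }
    }
  }
  trimmed <- substr(seqs, 1L, cut - 1L)
  keep <- nchar(trimmed) > 0L
  out <- reads[keep, , drop = FALSE]
  out$seq <- trimmed[keep]
  if (!is.null(out$qual)) out$qual <- substr(reads$qual[keep], 1L, cut[keep] - 1L)
  rownames(out) <- NULL
  list(reads = out, rejected = sum(!keep))
}

#' Test reads for internal polyA runs
#'
#' `TRUE` when the sequence contains a run of consecutive `A` strictly
#' longer than `max_run`, anywhere in the read (not only a 3' tail).
#'
#' @param seq Character vector of sequences.
#' @param max_run Longest permitted A-run (default 6).
#' @return Logical vector.
#' @export
#' @examples
#' has_polya("CCAAAAAAACC")  # run of 7 -> TRUE
#' has_polya("CCAAAAAACC")   # run of 6 -> FALSE
has_polya <- function(seq, max_run = 6L) {
  stopifnot(max_run >= 0L)
  grepl(strrep("A", max_run + 1L), seq, fixed = TRUE)
}

# Does each query sequence occur, on either strand, as a contiguous
# substring of any reference sequence with <= max_mismatches mismatches
# (no gaps)? Vector over queries.
matches_reference <- function(seqs, ref, max_mismatches = 0L) {
  uq <- unique(seqs)
  rc <- revcomp(uq)
  hit <- logical(length(uq))
  if (max_mismatches == 0L) {
    for (rs in ref$seq) {
      todo <- which(!hit)
      if (!length(todo)) break
      hit[todo] <- vapply(todo, function(i) {
        grepl(uq[i], rs, fixed = TRUE) || grepl(rc[i], rs, fixed = TRUE)
      }, logical(1L))
    }
  } else {
    subjects <- lapply(ref$seq, Biostrings::DNAString)
    for (i in seq_along(uq)) {
      for (s in subjects) {
        if (Biostrings::countPattern(uq[i], s,
                                     max.mismatch = max_mismatches,
                                     fixed = TRUE) > 0L ||
            Biostrings::countPattern(rc[i], s,
                                     max.mismatch = max_mismatches,
                                     fixed = TRUE) > 0L) {
          hit[i] <- TRUE
          break
        }
      }
    }
  }
  hit[match(seqs, uq)]
}

#' Subtract reads matching a reference set
#'
#' Removes every read that occurs, on either strand, as a contiguous
#' substring of any reference sequence with at most `max_mismatches`
#' mismatches and no gaps. Surviving reads keep their input order. At
#' `max_mismatches = 0` a read containing `N` can only match a reference
#' that also carries `N` at that position.
#'
#' @param reads Data frame of reads.
#' @param ref A `reference_set`.
#' @param max_mismatches Mismatch tolerance (default 0).
#' @return A list with `reads` (survivors) and `removed` (count).
#' @export
subtract_reference <- function(reads, ref, max_mismatches = 0L) {
  stopifnot(inherits(ref, "reference_set"), length(ref$seq) > 0L)
  if (nrow(reads) == 0L) return(list(reads = reads, removed = 0L))
  hit <- matches_reference(reads$seq, ref, max_mismatches)
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, removed = sum(hit))
}

#' Retain reads within a length window
#'
#' @param reads Data frame of reads.
#' @param size_min,size_max Inclusive bounds (defaults 18 and 26 nt).
#' @return The surviving reads, order preserved.
#' @export
size_select <- function(reads, size_min = 18L, size_max = 26L) {
  stopifnot(size_min >= 1L, size_min <= size_max)
  n <- nchar(reads$seq)
  out <- reads[n >= size_min & n <= size_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent of the initial library, printed-table style
#'
#' One-decimal percentage with half-up rounding, matching the convention
#' of published cascade-accounting tables.
#'
#' @param count Surviving read count (non-negative).
#' @param initial Initial read count (positive).
#' @return `count / initial * 100`, rounded half-up to one decimal.
#' @export
#' @examples
#' percent_of_initial(8599813, 159181068)  # 5.4
percent_of_initial <- function(count, initial) {
  if (any(initial <= 0)) stop("initial count must be positive", call. = FALSE)
  floor(1000 * count / initial + 0.5) / 10
}

#' Run the full cleaning cascade
#'
#' Executes, in order: adapter trimming, rRNA subtraction, tRNA
#' subtraction, polyA-read removal, size selection, a second rRNA/tRNA
#' subtraction pass, and organelle subtraction — skipping any stage whose
#' configuration is absent — and records the surviving count and percent
#' of the initial library after each stage.
#'
#' @param reads Data frame of reads (already quality-filtered upstream).
#' @param config A [cascade_config()].
#' @return A list with `reads` (the survivors) and `report`, a
#'   `cleaning_report` data frame with columns `stage`, `count`,
#'   `percent` and attribute `initial_count`.
#' @export
run_cascade <- function(reads, config) {
  stopifnot(inherits(config, "cascade_config"))
  initial <- nrow(reads)
  pct <- function(n) if (initial > 0L) percent_of_initial(n, initial) else 0.0
  stages <- data.frame(stage = "input", count = initial,
                       percent = pct(initial), stringsAsFactors = FALSE)
  add <- function(name) {
    stages <<- rbind(stages, data.frame(stage = name, count = nrow(reads),
                                        percent = pct(nrow(reads))))
  }
  if (!is.null(config$adapter)) {
    reads <- trim_adapter(reads, config$adapter)$reads
    add("adapter_trim")
  }
  sub_pass <- function(ref) {
    subtract_reference(reads, ref, config$max_mismatches)$reads
  }
  if (!is.null(config$rrna)) { reads <- sub_pass(config$rrna); add("rrna_removal") }
  if (!is.null(config$trna)) { reads <- sub_pass(config$trna); add("trna_removal") }
  reads <- reads[!has_polya(reads$seq, config$polya_max_run), , drop = FALSE]
  rownames(reads) <- NULL
  add("polya_removal")
  reads <- size_select(reads, config$size_min, config$size_max)
  add("size_selection")
  if (config$second_pass && (!is.null(config$rrna) || !is.null(config$trna))) {
    if (!is.null(config$rrna)) reads <- sub_pass(config$rrna)
    if (!is.null(config$trna)) reads <- sub_pass(config$trna)
    add("second_rrna_trna")
  }
  if (!is.null(config$organelle)) {
    reads <- sub_pass(config$organelle)
    add("organelle_removal")
  }
  report <- structure(stages, initial_count = initial,
                      class = c("cleaning_report", "data.frame"))
  list(reads = reads, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}
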