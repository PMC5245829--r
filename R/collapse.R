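# Collapsed-read container: data.frame(id, seq, count) with attribute
# total_input (raw read mass at collapse time). Ordering convention is
# descending count, ties lexicographic by sequence; ids encode rank+count.

new_collapsed_set <- function(seqs, counts, total_input) {
  o <- order(-counts, seqs)
  seqs <- seqs[o]
  counts <- as.integer(counts[o])
  structure(
    data.frame(id = sprintf("seq%d_x%d", seq_along(seqs), counts),
               seq = seqs, count = counts, stringsAsFactors = FALSE),
    total_input = as.integer(total_input),
    class = c("collapsed_set", "data.frame"))
}

sort_collapsed <- function(cs) {
  cs[order(-cs$count, cs$seq), , drop = FALSE]
}

#' Collapse reads to unique sequences with copy counts
#'
#' Each distinct sequence becomes one collapsed read whose count is its
#' multiplicity in the input. Collapsing is strand-literal: a sequence and
#' its reverse complement are distinct, as expected for a directional
#' library. The result is ordered by descending count, ties broken
#' lexicographically, and ids follow the `seq{rank}_x{count}` convention.
#'
#' @param reads Data frame with a `seq` column (e.g. from [read_fastq()]),
#'   or a character vector of sequences.
#' @return A `collapsed_set`: data frame with columns `id`, `seq`, `count`
#'   and attribute `total_input` (the number of input reads).
#' @export
#' @examples
#' collapse_reads(c("ACGT", "ACGT", "GGGG"))
collapse_reads <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (length(seqs) == 0L) {
    return(new_collapsed_set(character(), integer(), 0L))
  }
  tab <- table(seqs)
  new_collapsed_set(names(tab), as.integer(tab), length(seqs))
}

#' Remove low-abundance collapsed reads
#'
#' Drops collapsed reads observed in strictly fewer than `min_copies` raw
#' reads (the boundary is inclusive: `count >= min_copies` survives). The
#' survivors' `total_input` is recomputed as the surviving read mass.
#'
#' @param cs A `collapsed_set`.
#' @param min_copies Minimum copy number to retain (default 5).
#' @return A filtered `collapsed_set`.
#' @export
filter_min_count <- function(cs, min_copies = 5L) {
  stopifnot(min_copies >= 1L)
  keep <- cs$count >= min_copies
  new_collapsed_set(cs$seq[keep], cs$count[keep],
                    total_input = sum(cs$count[keep]))
}

#' @export
print.collapsed_set <- function(x, ...) {
  cat(sprintf("<collapsed_set: %d unique sequences, %d raw reads>\n",
              nrow(x), attr(x, "total_input")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
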