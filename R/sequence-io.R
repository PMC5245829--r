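#' @keywords internal
"_PACKAGE"

#' Normalize a nucleotide sequence to the internal DNA alphabet
#'
#' The package works in DNA space throughout: `U` (RNA input) is converted
#' to `T` and lowercase letters are uppercased. Any character outside
#' `{A,C,G,T,N}` after normalization is an error.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of normalized sequences over `{A,C,G,T,N}`.
#' @export
#' @examples
#' normalize_seq("acgu")  # "ACGT"
normalize_seq <- function(seq) {
  out <- chartr("U", "T", toupper(seq))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("invalid nucleotide character in sequence: ",
         substr(out[bad][1L], 1L, 40L), call. = FALSE)
  }
  out
}

#' Reverse complement
#'
#' Strict Watson-Crick reverse complement over `{A,C,G,T,N}`; `N` maps to
#' `N`. Vectorized over sequences.
#'
#' @param seq Character vector over `{A,C,G,T,N}` (case-insensitive, `U`
#'   accepted and treated as `T`).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACAGATTGCGGCAACCGTGCAG")
revcomp <- function(seq) {
  seq <- normalize_seq(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1L))
}

#' Read a FASTQ file of small-RNA reads
#'
#' Parses 4-line FASTQ records (Sanger/Phred+33 qualities) into a data
#' frame of reads, applying the package's alphabet normalization (U to T,
#' uppercase). Malformed records raise an error naming the 1-based record
#' index.
#'
#' @param path Path to a FASTQ file.
#' @return A data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error: truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("FASTQ format error: missing '@' header at record ", bad[1L],
         call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ format error: missing '+' separator at record ", bad[1L],
         call. = FALSE)
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("FASTQ format error: sequence/quality length mismatch at record ",
         bad[1L], call. = FALSE)
  }
  bad <- which(nchar(seq) == 0L)
  if (length(bad)) {
    stop("FASTQ format error: empty sequence at record ", bad[1L],
         call. = FALSE)
  }
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = normalize_seq(seq), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `id`, `seq` and optionally `qual`
#'   (constant `I` qualities are written when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$qual)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1L))
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that applies the
#' package's alphabet normalization. Multi-line sequences and CRLF line
#' endings are handled; empty records trigger a warning.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("FASTA format error in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    warning("empty sequence for record(s): ",
            paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  seqs[nchar(seqs) > 0L] <- normalize_seq(seqs[nchar(seqs) > 0L])
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param ids Character vector of record identifiers.
#' @param seqs Character vector of sequences, same length as `ids`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}

#' Construct a named reference sequence set
#'
#' A lightweight container for subtraction/mapping references (rRNA, tRNA,
#' organelle, transcriptome ...). Identifiers must be unique and sequences
#' non-empty.
#'
#' @param name Label for the set (e.g. `"rRNA"`).
#' @param ids Character vector of record ids, or a data frame with columns
#'   `id` and `seq` (as returned by [read_fasta()]), in which case `seqs`
#'   is ignored.
#' @param seqs Character vector of sequences.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(name, ids, seqs = NULL) {
  if (is.data.frame(ids)) {
    seqs <- ids$seq
    ids <- ids$id
  }
  if (anyDuplicated(ids)) stop("duplicate ids in reference set '", name, "'",
                               call. = FALSE)
  if (any(nchar(seqs) == 0L)) stop("empty sequence in reference set '", name,
                                   "'", call. = FALSE)
  structure(list(name = name, id = as.character(ids),
                 seq = normalize_seq(seqs)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set '%s': %d sequences, %d total nt>\n",
              x$name, length(x$seq), sum(nchar(x$seq))))
  invisible(x)
}

#' Write a collapsed-read set as FASTA
#'
#' Headers follow the fastx-collapser dialect `seq{rank}_x{count}`, with
#' rank 1..N assigned by descending count, ties broken by sequence
#' lexicographic order. Round-trips losslessly through
#' [read_collapsed_fasta()].
#'
#' @param cs A `collapsed_set` (see [collapse_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(cs, path) {
  cs <- sort_collapsed(cs)
  write_fasta(sprintf("seq%d_x%d", seq_len(nrow(cs)), cs$count), cs$seq, path)
}

#' Read a collapsed-read FASTA file
#'
#' Inverse of [write_collapsed_fasta()]: parses `seq{rank}_x{count}`
#' headers back into a `collapsed_set`.
#'
#' @param path Path to a collapsed FASTA file.
#' @return A `collapsed_set`.
#' @export
read_collapsed_fasta <- function(path) {
  rec <- read_fasta(path)
  m <- regmatches(rec$id, regexec("^seq([0-9]+)_x([0-9]+)$", rec$id))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) {
    stop("not a collapsed-FASTA header: '", rec$id[bad][1L], "'",
         call. = FALSE)
  }
  counts <- as.integer(vapply(m, `[`, character(1L), 3L))
  new_collapsed_set(rec$seq, counts, total_input = sum(counts))
}
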