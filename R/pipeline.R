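# End-to-end orchestration: cleaning cascade -> collapse -> minimum-copy
# filter -> contig filter -> duplex search (-> optional transcript
# profiling), with a run record and table-style summaries.

#' Length histogram of a read set
#'
#' Counts reads per length, both count-weighted (raw read mass) and as
#' unique sequences.
#'
#' @param cs A `collapsed_set`, or data frame with `seq` and optional
#'   `count`.
#' @return Data frame with columns `length`, `n_reads` (count-weighted),
#'   `n_unique`.
#' @export
length_histogram <- function(cs) {
  counts <- if (!is.null(cs$count)) cs$count else rep(1L, nrow(cs))
  if (nrow(cs) == 0L) {
    return(data.frame(length = integer(), n_reads = integer(),
                      n_unique = integer()))
  }
  len <- nchar(cs$seq)
  agg <- stats::aggregate(list(n_reads = counts, n_unique = rep(1L, nrow(cs))),
                          by = list(length = len), FUN = sum)
  agg[order(agg$length), , drop = FALSE]
}

#' Format a cleaning report as a printable accounting table
#'
#' Mirrors the layout of published cascade-accounting tables: stage name,
#' read count with thousands separators, and the percent of the initial
#' library to one decimal. Extra post-collapse rows (which have no
#' meaningful percent of raw reads) can be appended with a blank percent
#' cell.
#'
#' @param report A `cleaning_report` from [run_cascade()].
#' @param extra Optional data frame of (`stage`, `count`) rows appended
#'   with blank percents.
#' @return Data frame of character columns `stage`, `reads`, `percent`.
#' @export
cascade_table <- function(report, extra = NULL) {
  fmt <- function(n) formatC(n, big.mark = ",", format = "d")
  out <- data.frame(stage = report$stage, reads = fmt(report$count),
                    percent = formatC(report$percent, format = "f",
                                      digits = 1L),
                    stringsAsFactors = FALSE)
  out$percent[1L] <- "100"
  if (!is.null(extra)) {
    out <- rbind(out, data.frame(stage = extra$stage,
                                 reads = fmt(extra$count), percent = "",
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Run the full miRNA-candidate discovery pipeline
#'
#' Executes, in order: the cleaning cascade, abundance collapsing, the
#' minimum-copy filter, exact-overlap contig assembly with removal of
#' long unidirectional contigs, the duplex-geometry search, and —
#' when transcripts are supplied — strand-aware profiling of the cleaned
#' reads against each transcript. When `out_dir` is given, stage tables
#' are written as TSV/FASTA artifacts.
#'
#' @param reads Data frame of raw reads (e.g. [read_fastq()] output or a
#'   `sim_library$reads`).
#' @param config A [cascade_config()].
#' @param min_copies Minimum collapsed copy number retained (default 5).
#' @param min_overlap Minimum exact overlap for contig assembly
#'   (default 14).
#' @param length_threshold Contig-length threshold, `"median"` or integer.
#' @param max_mismatches,max_bulges,overhang Duplex-search parameters.
#' @param transcripts Optional `reference_set` of transcripts to profile.
#' @param utr3 Optional data frame (`id`, `utr3_start`) of 3' UTR offsets.
#' @param out_dir Optional output directory for TSV/FASTA artifacts.
#' @return A list of class `pipeline_result`: `report`
#'   (`cleaning_report`), `cleaned` (reads surviving the cascade),
#'   `collapsed`, `filtered`, `contigs`,
#'   `contig_filter`, `candidates` (the retained `collapsed_set`),
#'   `pairs` (`duplex_pairs`), `mirnas` ([candidate_mirnas()] output),
#'   `profiles` (list of `transcript_profile` + `pattern`), `record`
#'   (run metadata).
#' @export
run_pipeline <- function(reads, config,
                         min_copies = 5L, min_overlap = 14L,
                         length_threshold = "median",
                         max_mismatches = 3L, max_bulges = 1L,
                         overhang = 2L,
                         transcripts = NULL, utr3 = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  cleaned <- run_cascade(reads, config)
  collapsed <- collapse_reads(cleaned$reads)
  filtered <- filter_min_count(collapsed, min_copies)
  contigs <- assemble_contigs(filtered, min_overlap)
  cfr <- filter_long_unidirectional(filtered, contigs, length_threshold)
  pairs <- find_duplexes(cfr$retained, max_mismatches, max_bulges, overhang)
  mirnas <- candidate_mirnas(pairs)
  profiles <- NULL
  if (!is.null(transcripts)) {
    # profiling maps the full cleaned, collapsed read set (not just the
    # duplex candidates): degradation fragments are exactly what gives a
    # transcript its sense-only coverage signature
    profiles <- lapply(seq_along(transcripts$seq), function(t) {
      id <- transcripts$id[t]
      mp <- map_reads(collapsed, id, transcripts$seq[t])
      u3 <- if (!is.null(utr3) && id %in% utr3$id)
        utr3$utr3_start[utr3$id == id][1L] else NULL
      pr <- profile_transcript(mp, id, transcripts$seq[t], utr3_start = u3)
      pr$pattern <- if (pr$total_reads > 0L) classify_pattern(pr) else NA
      pr
    })
    names(profiles) <- transcripts$id
  }
  record <- list(
    started = t0, finished = Sys.time(),
    version = as.character(utils::packageVersion("dinomir")),
    params = list(min_copies = min_copies, min_overlap = min_overlap,
                  length_threshold = length_threshold,
                  max_mismatches = max_mismatches, max_bulges = max_bulges,
                  overhang = overhang),
    stage_counts = c(stats::setNames(cleaned$report$count,
                                     cleaned$report$stage),
                     collapsed = nrow(collapsed),
                     min_copy_filtered = nrow(filtered),
                     candidates = nrow(cfr$retained)))
  res <- structure(list(report = cleaned$report, cleaned = cleaned$reads,
                        collapsed = collapsed,
                        filtered = filtered, contigs = contigs,
                        contig_filter = cfr, candidates = cfr$retained,
                        pairs = pairs, mirnas = mirnas,
                        profiles = profiles, record = record),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  extra <- data.frame(
    stage = c("collapsed", "min_copy_filtered", "candidates"),
    count = c(nrow(res$collapsed), nrow(res$filtered),
              nrow(res$candidates)))
  tsv(cascade_table(res$report, extra), "cascade.tsv")
  write_collapsed_fasta(res$filtered, file.path(out_dir, "collapsed.fa"))
  tsv(res$contig_filter$contigs, "contigs.tsv")
  tsv(as.data.frame(res$pairs), "duplexes.tsv")
  tsv(res$mirnas$length_histogram, "candidate_lengths.tsv")
  if (!is.null(res$profiles)) {
    prof <- do.call(rbind, lapply(res$profiles, function(p) {
      data.frame(transcript = p$transcript, total_reads = p$total_reads,
                 antisense_reads = p$antisense_reads,
                 pattern = if (is.null(p$pattern)) NA else p$pattern,
                 utr3_antisense = p$utr3_antisense,
                 stringsAsFactors = FALSE)
    }))
    tsv(prof, "profiles.tsv")
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  cat(sprintf("collapsed: %d unique; >=min-copy: %d; candidates: %d\n",
              nrow(x$collapsed), nrow(x$filtered), nrow(x$candidates)))
  cat(sprintf("duplex pairs: %d (%d unique candidate miRNAs)\n",
              nrow(x$pairs), length(x$mirnas$sequences)))
  invisible(x)
}
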