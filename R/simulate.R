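# Deterministic simulator for a stranded small-RNA library with known
# ground truth: planted miRNA/miRNA* duplex loci with asymmetric strand
# abundance, sense-only mRNA degradation fragments that tile their
# transcript with >=14-nt overlaps, rRNA/tRNA/organelle contaminants,
# polyA-bearing reads, and an appended 3' sequencing adapter. Every read
# is recorded in a truth manifest so pipeline recovery is measurable.

rand_seq <- function(n, len, forbid_polya = TRUE, max_run = 6L) {
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      if (!forbid_polya || !has_polya(s, max_run)) break
    }
    out[i] <- s
  }
  out
}

# Largest-remainder apportionment of `total` into parts proportional to
# `weights`; deterministic, parts sum exactly to total.
largest_remainder <- function(total, weights) {
  if (total == 0L || !length(weights)) return(integer(length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0L) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Simulation configuration
#'
#' Parameters of the synthetic stranded small-RNA library. Defaults give
#' the reference validation scenario: 20 duplex loci at a 50:1
#' guide:star copy ratio (star depth 5, so both strands clear the
#' 5-copy abundance filter), 5000 transcript-tiled degradation fragments,
#' and 20% contaminant reads split across rRNA, tRNA, organelle and
#' polyA classes.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @param n_mirna_loci Number of planted duplex loci (default 20).
#' @param mirna_length_weights Named weights over candidate lengths 18-26
#'   (default: unimodal with mode 22).
#' @param guide_star_ratio Guide:star copy ratio, >= 1 (default 50).
#' @param star_depth Raw copies of each star strand (default 5).
#' @param mirna_mutation_budget Non-complementary substitutions planted
#'   in each duplex pairing region, 0-3 (default 0).
#' @param transcripts Optional `reference_set` of transcripts; by default
#'   the bundled synthetic transcript fixtures are used.
#' @param n_fragments_per_transcript Degradation-fragment reads per
#'   transcript (default 1000; 5 transcripts give the 5000-fragment
#'   default library).
#' @param contaminant_fractions Named fractions of the total library for
#'   classes `rrna`, `trna`, `organelle`, `polya` (default sums to 0.20).
#' @param rrna,trna,organelle `reference_set`s the contaminants are drawn
#'   from; bundled synthetic fixtures by default.
#' @param adapter 3' adapter appended to every read (TruSeq small-RNA
#'   default).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mirna_loci = 20L,
                       mirna_length_weights = c(`18` = 1, `19` = 2, `20` = 4,
                                                `21` = 8, `22` = 16,
                                                `23` = 8, `24` = 4,
                                                `25` = 2, `26` = 1),
                       guide_star_ratio = 50,
                       star_depth = 5L,
                       mirna_mutation_budget = 0L,
                       transcripts = NULL,
                       n_fragments_per_transcript = 1000L,
                       contaminant_fractions = c(rrna = 0.08, trna = 0.05,
                                                 organelle = 0.04,
                                                 polya = 0.03),
                       rrna = NULL, trna = NULL, organelle = NULL,
                       adapter = truseq_small_rna_adapter()) {
  stopifnot(guide_star_ratio >= 1, star_depth >= 1L,
            mirna_mutation_budget >= 0L, mirna_mutation_budget <= 3L,
            all(contaminant_fractions >= 0), sum(contaminant_fractions) <= 1)
  fx <- demo_references()
  structure(list(seed = as.integer(seed), n_mirna_loci = as.integer(n_mirna_loci),
                 mirna_length_weights = mirna_length_weights,
                 guide_star_ratio = guide_star_ratio,
                 star_depth = as.integer(star_depth),
                 mirna_mutation_budget = as.integer(mirna_mutation_budget),
                 transcripts = if (is.null(transcripts)) fx$transcripts else transcripts,
                 n_fragments_per_transcript = as.integer(n_fragments_per_transcript),
                 contaminant_fractions = contaminant_fractions,
                 rrna = if (is.null(rrna)) fx$rrna else rrna,
                 trna = if (is.null(trna)) fx$trna else trna,
                 organelle = if (is.null(organelle)) fx$organelle else organelle,
                 adapter = normalize_seq(adapter)),
            class = "sim_config")
}

#' Bundled synthetic reference fixtures
#'
#' Small synthetic FASTA fixtures shipped with the package (generated, not
#' biological sequences): 3 rRNA-like, 3 tRNA-like and 2 organelle-like
#' entries plus 5 transcripts, one of them "LBP-like" with a declared 3'
#' UTR offset, so every pipeline stage can be exercised offline.
#'
#' @return A list of `reference_set`s (`rrna`, `trna`, `organelle`,
#'   `transcripts`) and `utr3`, a data frame of (`id`, `utr3_start`).
#' @export
demo_references <- function() {
  p <- function(f) system.file("extdata", f, package = "dinomir",
                               mustWork = TRUE)
  list(rrna = reference_set("rRNA", read_fasta(p("synthetic_rrna.fa"))),
       trna = reference_set("tRNA", read_fasta(p("synthetic_trna.fa"))),
       organelle = reference_set("organelle",
                                 read_fasta(p("synthetic_organelle.fa"))),
       transcripts = reference_set("transcriptome",
                                   read_fasta(p("synthetic_transcripts.fa"))),
       utr3 = utils::read.delim(p("synthetic_utr3.tsv"),
                                stringsAsFactors = FALSE))
}

#' Construct one miRNA/miRNA* duplex locus
#'
#' Draws a random guide sequence, builds its perfect Dicer partner
#' (reverse complement of the guide minus its 2-nt 3' overhang, plus a
#' random 2-nt 3' overhang of its own), then plants up to
#' `mutation_budget` non-complementary substitutions in the star's
#' pairing region. The resulting pair always satisfies [pair_duplex()]
#' with at most `mutation_budget` mismatches.
#'
#' @param length Guide length, 18-26.
#' @param mutation_budget Substitutions planted in the pairing region,
#'   0-3 (default 0).
#' @param overhang 3' overhang length (default 2).
#' @return A list with `guide` and `star`.
#' @export
make_duplex_locus <- function(length, mutation_budget = 0L, overhang = 2L) {
  stopifnot(length >= 18L, length <= 26L, mutation_budget <= 3L)
  guide <- rand_seq(1L, length)
  pair_len <- length - overhang
  star_pair <- revcomp(substr(guide, 1L, pair_len))
  if (mutation_budget > 0L) {
    pos <- sample.int(pair_len, mutation_budget)
    chars <- strsplit(star_pair, "", fixed = TRUE)[[1L]]
    for (k in pos) {
      chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1L)
    }
    star_pair <- paste(chars, collapse = "")
  }
  star <- paste0(star_pair,
                 paste(sample(c("A", "C", "G", "T"), overhang,
                              replace = TRUE), collapse = ""))
  if (has_polya(guide) || has_polya(star)) {
    return(make_duplex_locus(length, mutation_budget, overhang))
  }
  list(guide = guide, star = star)
}

# Distinct fragments tiling a transcript left to right with adjacent
# overlaps >= min_overlap; lengths drawn from 18:26.
tile_transcript <- function(seq, min_overlap = 14L) {
  L <- nchar(seq)
  starts <- integer(); lens <- integer()
  pos <- 1L
  repeat {
    len <- sample(18:26, 1L)
    if (pos + len - 1L > L) {
      len <- L - pos + 1L
      if (len < 18L) break
    }
    starts <- c(starts, pos); lens <- c(lens, len)
    if (pos + len - 1L >= L) break
    step <- sample.int(len - min_overlap, 1L)   # 1..len-14: overlap >= 14
    pos <- pos + step
  }
  data.frame(start = starts, len = lens,
             frag = substring(seq, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic stranded small-RNA library
#'
#' Emits reads (with the 3' adapter appended) and a ground-truth manifest
#' for: guide/star reads of each planted duplex locus, sense-strand
#' degradation fragments tiling each transcript with >=14-nt overlaps (so
#' they assemble into long unidirectional contigs), contaminant copies of
#' rRNA/tRNA/organelle reference subsequences, and polyA-bearing reads.
#' Contaminant class counts are a largest-remainder apportionment of the
#' configured fractions of the total library. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_library`: `reads` (data frame `id`,
#'   `seq`, `qual`), `manifest` (per-read: `id`, `class`, `source`,
#'   `offset`, `strand`), `loci` (per-locus: `locus`, `guide`, `star`,
#'   `guide_count`, `star_count`), `config`.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chunks <- list()
  n_emitted <- 0L
  emit <- function(seqs, class, source, offset, strand) {
    n <- length(seqs)
    if (n == 0L) return(invisible())
    ids <- sprintf("%s_%d", class, n_emitted + seq_len(n))
    n_emitted <<- n_emitted + n
    chunks[[length(chunks) + 1L]] <<- list(
      id = ids, insert = seqs, class = rep(class, n),
      source = rep_len(source, n), offset = rep_len(offset, n),
      strand = rep(strand, n))
  }

  # duplex loci: lengths allocated deterministically by largest
  # remainder (same principle as contaminant classes), shuffled across
  # loci, so the planted length distribution is exact at any locus count
  lens <- sample(rep(as.integer(names(config$mirna_length_weights)),
                     largest_remainder(config$n_mirna_loci,
                                       config$mirna_length_weights)))
  guide_count <- as.integer(round(config$star_depth * config$guide_star_ratio))
  loci <- vector("list", config$n_mirna_loci)
  for (l in seq_len(config$n_mirna_loci)) {
    locus <- make_duplex_locus(lens[l], config$mirna_mutation_budget)
    loci[[l]] <- data.frame(locus = sprintf("locus_%d", l),
                            guide = locus$guide, star = locus$star,
                            guide_count = guide_count,
                            star_count = config$star_depth,
                            stringsAsFactors = FALSE)
    emit(rep(locus$guide, guide_count), "mirna_guide",
         sprintf("locus_%d", l), NA_integer_, "+")
    emit(rep(locus$star, config$star_depth), "mirna_star",
         sprintf("locus_%d", l), NA_integer_, "+")
  }
  loci <- do.call(rbind, loci)

  # sense degradation fragments tiling each transcript
  tx <- config$transcripts
  for (t in seq_along(tx$seq)) {
    tiles <- tile_transcript(tx$seq[t])
    copies <- largest_remainder(config$n_fragments_per_transcript,
                                rep(1, nrow(tiles)))
    for (f in seq_len(nrow(tiles))) {
      if (copies[f] == 0L) next
      emit(rep(tiles$frag[f], copies[f]), "mrna_fragment", tx$id[t],
           tiles$start[f] - 1L, "+")
    }
  }

  # contaminants: fractions of the *total* library
  n_base <- n_emitted
  fr <- config$contaminant_fractions
  n_total <- as.integer(round(n_base / (1 - sum(fr))))
  n_contam <- largest_remainder(n_total - n_base, fr)
  names(n_contam) <- names(fr)
  draw_sub <- function(ref, len_range) {
    i <- sample.int(length(ref$seq), 1L)
    len <- sample(len_range, 1L)
    len <- min(len, nchar(ref$seq[i]))
    st <- sample.int(nchar(ref$seq[i]) - len + 1L, 1L)
    list(seq = substr(ref$seq[i], st, st + len - 1L),
         source = ref$id[i], offset = st - 1L)
  }
  for (cls in c("rrna", "trna", "organelle")) {
    ref <- config[[cls]]
    len_range <- if (cls == "organelle") 18:26 else 18:40
    for (q in seq_len(n_contam[[cls]])) {
      repeat {
        d <- draw_sub(ref, len_range)
        if (!has_polya(d$seq)) break   # must not be caught upstream
      }
      emit(d$seq, cls, d$source, d$offset, "+")
    }
  }
  if (n_contam[["polya"]] > 0L) {
    for (q in seq_len(n_contam[["polya"]])) {
      len <- sample(18:26, 1L)
      run <- sample(7:min(10L, len), 1L)
      rest <- rand_seq(1L, len - run)
      at <- sample.int(len - run + 1L, 1L)
      s <- paste0(substr(rest, 1L, at - 1L), strrep("A", run),
                  substr(rest, at, len - run))
      emit(s, "polya", NA_character_, NA_integer_, "+")
    }
  }

  field <- function(f) unlist(lapply(chunks, `[[`, f), use.names = FALSE)
  manifest <- data.frame(id = field("id"), class = field("class"),
                         source = field("source"), offset = field("offset"),
                         strand = field("strand"), insert = field("insert"),
                         stringsAsFactors = FALSE)
  reads <- data.frame(id = manifest$id,
                      seq = paste0(manifest$insert, config$adapter),
                      stringsAsFactors = FALSE)
  reads$qual <- strrep("I", nchar(reads$seq))
  structure(list(reads = reads, manifest = manifest, loci = loci,
                 config = config),
            class = "sim_library")
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library: %d reads (%s)>\n", nrow(x$reads),
              paste(sprintf("%s=%d", names(table(x$manifest$class)),
                            table(x$manifest$class)), collapse = ", ")))
  invisible(x)
}

#' Score pipeline recovery against the truth manifest
#'
#' Compares pipeline outputs with the generator's ground truth: per-stage
#' contaminant-removal recall, degradation-fragment removal recall by the
#' contig filter (scored over the fragments that reach the contig stage),
#' planted duplex reads lost to the contig filter, duplex locus recall,
#' and the error of the recovered guide/star ratio.
#'
#' @param lib A `sim_library`.
#' @param cleaned Reads surviving the cascade (data frame with `id`).
#' @param contig_result A `contig_filter_result` (or `NULL` to skip).
#' @param pairs A `duplex_pairs` data frame (or `NULL` to skip).
#' @param retained_cs The `collapsed_set` entering the duplex search
#'   (needed to trace read ids back to sequences; `NULL` to skip).
#' @return A list of metrics; `NA` where the corresponding output was not
#'   supplied or the denominator is empty.
#' @export
evaluate_recovery <- function(lib, cleaned, contig_result = NULL,
                              pairs = NULL, retained_cs = NULL) {
  man <- lib$manifest
  surv <- man$id %in% cleaned$id
  recall_removed <- function(cls) {
    n <- sum(man$class == cls)
    if (n == 0L) return(NA_real_)
    sum(!surv[man$class == cls]) / n
  }
  out <- list(
    contaminant_removal = c(rrna = recall_removed("rrna"),
                            trna = recall_removed("trna"),
                            organelle = recall_removed("organelle"),
                            polya = recall_removed("polya")),
    mirna_survival = 1 - recall_removed("mirna_guide"))
  if (!is.null(contig_result) && !is.null(retained_cs)) {
    # fragment recall is scored over fragments that actually enter the
    # contig stage (low-copy tiles are dropped earlier, by the abundance
    # filter, and are not the contig filter's to remove)
    frag_seqs <- unique(man$insert[man$class == "mrna_fragment" & surv])
    frag_seqs <- frag_seqs[frag_seqs %in% retained_cs$seq]
    mir_seqs <- unique(man$insert[man$class %in%
                                    c("mirna_guide", "mirna_star")])
    # trace removed ids back to sequences via the pre-filter collapsed set
    seq_of <- stats::setNames(retained_cs$seq, retained_cs$id)
    removed_frag <- sum(frag_seqs %in% seq_of[contig_result$removed_read_ids])
    out$fragment_removal_recall <-
      if (length(frag_seqs)) removed_frag / length(frag_seqs) else NA_real_
    out$duplex_reads_removed_by_contig_filter <-
      sum(mir_seqs %in% seq_of[contig_result$removed_read_ids])
  }
  if (!is.null(pairs)) {
    found <- mapply(function(g, s) {
      any((pairs$seq_a == g & pairs$seq_b == s) |
            (pairs$seq_a == s & pairs$seq_b == g))
    }, lib$loci$guide, lib$loci$star)
    out$duplex_recall <- mean(found)
    hit <- which(found)
    if (length(hit)) {
      ratios <- vapply(hit, function(l) {
        g <- lib$loci$guide[l]; s <- lib$loci$star[l]
        row <- which((pairs$seq_a == g & pairs$seq_b == s) |
                       (pairs$seq_a == s & pairs$seq_b == g))[1L]
        max(pairs$count_a[row], pairs$count_b[row]) /
          min(pairs$count_a[row], pairs$count_b[row])
      }, numeric(1L))
      out$guide_star_ratio_mean <- mean(ratios)
      out$guide_star_ratio_error <-
        mean(abs(ratios - lib$config$guide_star_ratio)) /
        lib$config$guide_star_ratio
    }
  }
  out
}
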