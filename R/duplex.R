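# Dicer-product duplex detection. Two small RNAs form a candidate
# miRNA/miRNA* duplex when, after setting aside exactly 2 unpaired bases
# at each 3' end, the remaining pairing regions align antiparallel with
# at most 3 mismatches and at most 1 single-base bulge. Watson-Crick
# pairs only; G:T wobble counts as a mismatch; N never pairs.

seq_ints <- function(s) {
  # A=1 C=2 G=3 T=4 N=0; integer vector
  match(strsplit(s, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"),
        nomatch = 0L)
}

# mismatches between equal-length integer-coded strands where y is the
# reverse complement target; 0 codes (N) always mismatch
mm_count <- function(x, y) {
  sum(x != y | x == 0L | y == 0L)
}

#' Test two small RNAs for Dicer duplex geometry
#'
#' Sets aside exactly `overhang` (default 2) bases at each sequence's 3'
#' end, reverse-complements one pairing region, and finds the
#' minimum-mismatch gapless-or-one-bulge alignment of the two regions. A
#' bulge is a single unpaired base on either strand strictly inside the
#' pairing region (a terminal gap would change the overhang length), so
#' valid partners differ in length by at most `max_bulges`. When several
#' bulge placements tie on mismatches, the leftmost (in alignment
#' coordinates along `a`'s pairing region) is reported.
#'
#' @param a,b Nucleotide strings over `{A,C,G,T,N}`; `N` pairs with
#'   nothing and always scores a mismatch.
#' @param max_mismatches Maximum tolerated mismatches (default 3).
#' @param max_bulges Maximum single-base bulges, 0 or 1 (default 1).
#' @param overhang Required unpaired 3' overhang length on both strands
#'   (default 2; the Dicer signature).
#' @return `NULL` when the pair cannot form a duplex, otherwise a
#'   `duplex_alignment`: list with `mismatches`, `bulges` (data frame of
#'   `strand` (`"A"`/`"B"`) and 0-based `position` in that strand's
#'   pairing region), `overhang_a`, `overhang_b`.
#' @export
#' @examples
#' a <- "ACAGATTGCGGCAACCGTGCAG"
#' b <- paste0(revcomp(substr(a, 1, 20)), "TT")
#' pair_duplex(a, b)  # perfect duplex: 0 mismatches, 0 bulges
pair_duplex <- function(a, b, max_mismatches = 3L, max_bulges = 1L,
                        overhang = 2L) {
  a <- normalize_seq(a); b <- normalize_seq(b)
  na <- nchar(a); nb <- nchar(b)
  if (na <= overhang || nb <= overhang) return(NULL)
  pa <- seq_ints(substr(a, 1L, na - overhang))
  pb_rc <- rev(5L - seq_ints(substr(b, 1L, nb - overhang)))
  pb_rc[pb_rc == 5L] <- 0L   # N stays N
  m <- length(pa); n <- length(pb_rc)
  if (abs(m - n) > max_bulges) return(NULL)
  no_bulge <- data.frame(strand = character(), position = integer(),
                         stringsAsFactors = FALSE)
  if (m == n) {
    mm <- mm_count(pa, pb_rc)
    if (mm > max_mismatches) return(NULL)
    return(structure(list(mismatches = mm, bulges = no_bulge,
                          overhang_a = overhang, overhang_b = overhang),
                     class = "duplex_alignment"))
  }
  # |m - n| == 1: one interior bulge on the longer pairing region
  if (max_bulges < 1L) return(NULL)
  a_longer <- m > n
  x <- if (a_longer) pa else pb_rc   # longer, carries the bulge
  y <- if (a_longer) pb_rc else pa
  lx <- length(x)
  if (lx < 3L) return(NULL)          # no interior position for a bulge
  best_mm <- NA_integer_; best_k <- NA_integer_
  for (k in 2:(lx - 1L)) {           # 1-based interior deletion position
    mm <- mm_count(x[-k], y)
    if (is.na(best_mm) || mm < best_mm) { best_mm <- mm; best_k <- k }
  }
  if (is.na(best_mm) || best_mm > max_mismatches) return(NULL)
  # map the alignment-coordinate bulge back to its physical strand
  if (a_longer) {
    bulge <- data.frame(strand = "A", position = best_k - 1L,
                        stringsAsFactors = FALSE)
  } else {
    # x is revcomp(b's pairing region): flip the index back onto b
    bulge <- data.frame(strand = "B", position = lx - best_k,
                        stringsAsFactors = FALSE)
  }
  structure(list(mismatches = best_mm, bulges = bulge,
                 overhang_a = overhang, overhang_b = overhang),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment: %d mismatches, %d bulge(s), 2x%d-nt 3' overhangs>\n",
              x$mismatches, nrow(x$bulges), x$overhang_a))
  invisible(x)
}

#' Find all duplex-forming pairs in a candidate set
#'
#' Exhaustively tests candidate pairs for Dicer duplex geometry,
#' restricted by the geometry itself: a sequence of length L can only
#' partner sequences of length L-1, L or L+1 (pairing regions must agree
#' in length up to one bulge). Each unordered pair is reported once;
#' self-pairing is tested rather than excluded a priori.
#'
#' @param cs A `collapsed_set` (or data frame with `id`, `seq`, `count`).
#' @param max_mismatches,max_bulges,overhang Passed to [pair_duplex()].
#' @return A data frame of class `duplex_pairs` with one row per valid
#'   pair: `id_a`, `seq_a`, `count_a`, `id_b`, `seq_b`, `count_b`,
#'   `mismatches`, `bulges`, `ratio` (max count over min count), `guide`
#'   (`"A"`, `"B"` or `"tie"`). Pairs are canonicalised so
#'   `seq_a <= seq_b`.
#' @export
find_duplexes <- function(cs, max_mismatches = 3L, max_bulges = 1L,
                          overhang = 2L) {
  empty <- data.frame(id_a = character(), seq_a = character(),
                      count_a = integer(), id_b = character(),
                      seq_b = character(), count_b = integer(),
                      mismatches = integer(), bulges = integer(),
                      ratio = numeric(), guide = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("duplex_pairs", "data.frame")
  if (nrow(cs) == 0L) return(empty)
  lens <- nchar(cs$seq)
  rows <- list()
  for (L in sort(unique(lens))) {
    ia <- which(lens == L)
    for (dL in 0:min(max_bulges, 1L)) {
      ib <- which(lens == L + dL)
      if (!length(ib)) next
      for (i in ia) {
        js <- if (dL == 0L) ib[ib >= i] else ib
        for (j in js) {
          al <- pair_duplex(cs$seq[i], cs$seq[j], max_mismatches,
                            max_bulges, overhang)
          if (is.null(al)) next
          # canonical order within the pair
          if (cs$seq[i] <= cs$seq[j]) { p <- i; q <- j } else { p <- j; q <- i }
          rows[[length(rows) + 1L]] <- data.frame(
            id_a = cs$id[p], seq_a = cs$seq[p], count_a = cs$count[p],
            id_b = cs$id[q], seq_b = cs$seq[q], count_b = cs$count[q],
            mismatches = al$mismatches, bulges = nrow(al$bulges),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("seq_a", "seq_b")]), , drop = FALSE]
  out <- out[order(out$seq_a, out$seq_b), , drop = FALSE]
  asym <- abundance_asymmetry(out$count_a, out$count_b)
  out$ratio <- asym$ratio
  out$guide <- asym$guide
  rownames(out) <- NULL
  class(out) <- c("duplex_pairs", "data.frame")
  out
}

#' Unique duplex-forming candidate miRNAs and their length histogram
#'
#' @param pairs A `duplex_pairs` data frame from [find_duplexes()].
#' @return A list with `sequences` (unique sequences participating in at
#'   least one duplex, sorted) and `length_histogram` (data frame of
#'   `length`, `n`).
#' @export
candidate_mirnas <- function(pairs) {
  seqs <- sort(unique(c(pairs$seq_a, pairs$seq_b)))
  if (!length(seqs)) {
    hist <- data.frame(length = integer(), n = integer())
  } else {
    tab <- table(nchar(seqs))
    hist <- data.frame(length = as.integer(names(tab)), n = as.integer(tab))
  }
  list(sequences = seqs, length_histogram = hist)
}

#' Guide/star abundance asymmetry of a duplex pair
#'
#' Genuine miRNA loci show a strong copy-number excess of the guide
#' strand over the star strand; this reports that ratio and labels the
#' more abundant strand as the putative guide.
#'
#' @param count_a,count_b Copy counts of the two strands (vectors).
#' @return A list with `ratio` (max/min) and `guide` (`"A"`, `"B"` or
#'   `"tie"`).
#' @export
#' @examples
#' abundance_asymmetry(100, 5)  # ratio 20, guide "A"
abundance_asymmetry <- function(count_a, count_b) {
  stopifnot(all(count_a >= 1L), all(count_b >= 1L))
  ratio <- pmax(count_a, count_b) / pmin(count_a, count_b)
  guide <- ifelse(count_a > count_b, "A",
                  ifelse(count_b > count_a, "B", "tie"))
  list(ratio = ratio, guide = guide)
}
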