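# Independent oracles used to cross-check the implementation. These are
# written in plain string/character-vector style, deliberately sharing no
# code with the package internals.

rdna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = "")
  }, character(1L))
}

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# gapless antiparallel mismatch count between two equal-length pairing
# regions given as character vectors in their own 5'->3' coordinates:
# x[i] pairs with y[n - i + 1]; N (or anything non-WC) is a mismatch
oracle_gapless_mm <- function(x, y) {
  n <- length(x)
  partners <- y[n - seq_len(n) + 1L]
  comp <- unname(ORACLE_COMP[x])
  sum(is.na(comp) | comp != partners)
}

# Exhaustive duplex check: every bulge placement (one interior deletion
# on the longer strand, in that strand's own coordinates) is tried.
# Returns NULL or list(mismatches, bulges).
oracle_duplex <- function(a, b, max_mm = 3L, max_bulge = 1L,
                          overhang = 2L) {
  pa <- strsplit(substr(a, 1L, nchar(a) - overhang), "")[[1L]]
  pb <- strsplit(substr(b, 1L, nchar(b) - overhang), "")[[1L]]
  if (nchar(a) <= overhang || nchar(b) <= overhang) return(NULL)
  la <- length(pa); lb <- length(pb)
  if (abs(la - lb) > max_bulge) return(NULL)
  if (la == lb) {
    mm <- oracle_gapless_mm(pa, pb)
    if (mm <= max_mm) return(list(mismatches = mm, bulges = 0L))
    return(NULL)
  }
  if (max_bulge < 1L) return(NULL)
  long <- if (la > lb) pa else pb
  short <- if (la > lb) pb else pa
  if (length(long) < 3L) return(NULL)
  best <- Inf
  for (j in 2L:(length(long) - 1L)) {    # interior deletions only
    mm <- if (la > lb) oracle_gapless_mm(long[-j], short)
          else oracle_gapless_mm(short, long[-j])
    best <- min(best, mm)
  }
  if (best <= max_mm) list(mismatches = best, bulges = 1L) else NULL
}

# Exhaustive all-pairs duplex enumeration over a set of sequences;
# returns a data frame keyed by the sorted sequence pair.
oracle_find_duplexes <- function(seqs, max_mm = 3L, max_bulge = 1L,
                                 overhang = 2L) {
  rows <- list()
  n <- length(seqs)
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- oracle_duplex(seqs[i], seqs[j], max_mm, max_bulge, overhang)
      if (!is.null(d)) {
        pr <- sort(c(seqs[i], seqs[j]))
        rows[[length(rows) + 1L]] <- data.frame(
          seq_a = pr[1L], seq_b = pr[2L], mismatches = d$mismatches,
          bulges = d$bulges, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_a = character(), seq_b = character(),
                      mismatches = integer(), bulges = integer()))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$seq_a, out$seq_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force longest exact overlap between two sequences, trying every
# overlap length and both orientations of b by direct substring equality
oracle_rc <- function(s) {
  paste(rev(unname(ORACLE_COMP[strsplit(s, "")[[1L]]])), collapse = "")
}

oracle_best_overlap <- function(a, b, min_ov) {
  best <- 0L
  for (bo in c(b, oracle_rc(b))) {
    na <- nchar(a); nb <- nchar(bo)
    for (ov in min(na, nb):min_ov) {
      if (substr(a, na - ov + 1L, na) == substr(bo, 1L, ov) ||
          substr(bo, nb - ov + 1L, nb) == substr(a, 1L, ov)) {
        best <- max(best, ov)
        break
      }
    }
    if (nb <= na && grepl(bo, a, fixed = TRUE)) best <- max(best, nb)
    if (na <= nb && grepl(a, bo, fixed = TRUE)) best <- max(best, na)
  }
  if (best >= min_ov) best else 0L
}

# a perfect Dicer partner for `a`: revcomp of its pairing region plus an
# arbitrary 2-nt 3' overhang
perfect_partner <- function(a, xy = "TT", overhang = 2L) {
  paste0(oracle_rc(substr(a, 1L, nchar(a) - overhang)), xy)
}
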