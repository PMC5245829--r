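# Exact-overlap contig assembly and the long-unidirectional filter.
# mRNA degradation fragments tile their source transcript and so chain
# into long single-direction contigs; genuine miRNA/miRNA* pairs at most
# pair with each other (opposite orientations). Assembly is greedy,
# longest-exact-overlap-first, merging only on 100% identity.

# Longest overlap with suffix of x equal to prefix of y, >= k; 0 if none.
sp_overlap <- function(x, y, k) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx < k || ny < k) return(0L)
  occ <- gregexpr(substr(y, 1L, k), x, fixed = TRUE)[[1L]]
  if (occ[1L] == -1L) return(0L)
  for (p in occ) {               # ascending p = descending candidate ov
    ov <- nx - p + 1L
    if (ov > ny) next
    if (substr(x, p, nx) == substr(y, 1L, ov)) return(ov)
  }
  0L
}

# Leftmost 1-based position of y inside x, or 0.
contain_pos <- function(x, y) {
  p <- regexpr(y, x, fixed = TRUE)
  if (p > 0L) as.integer(p) else 0L
}

# Best merge of two sequences under exact overlap >= min_overlap, trying
# b forward and reverse-complemented and all four arrangements. Returns
# NULL or list(ov, merged, b_rev, a_shift, b_shift) where the shifts are
# the 0-based offsets of a and of oriented b on the merged sequence.
best_merge <- function(a, b, min_overlap) {
  cands <- list()
  for (b_rev in c(FALSE, TRUE)) {
    bo <- if (b_rev) revcomp(b) else b
    na <- nchar(a); nb <- nchar(bo)
    p <- contain_pos(a, bo)
    if (p > 0L && nb >= min_overlap) {
      cands[[length(cands) + 1L]] <- list(ov = nb, merged = a, b_rev = b_rev,
                                          a_shift = 0L, b_shift = p - 1L,
                                          type = "containment")
    }
    p <- contain_pos(bo, a)
    if (p > 0L && na >= min_overlap && na < nb) {
      cands[[length(cands) + 1L]] <- list(ov = na, merged = bo, b_rev = b_rev,
                                          a_shift = p - 1L, b_shift = 0L,
                                          type = "containment")
    }
    ov <- sp_overlap(a, bo, min_overlap)
    if (ov > 0L && ov < min(na, nb)) {
      cands[[length(cands) + 1L]] <- list(
        ov = ov, merged = paste0(a, substr(bo, ov + 1L, nb)), b_rev = b_rev,
        a_shift = 0L, b_shift = na - ov, type = "suffix_prefix")
    }
    ov <- sp_overlap(bo, a, min_overlap)
    if (ov > 0L && ov < min(na, nb)) {
      cands[[length(cands) + 1L]] <- list(
        ov = ov, merged = paste0(bo, substr(a, ov + 1L, na)), b_rev = b_rev,
        a_shift = nb - ov, b_shift = 0L, type = "suffix_prefix")
    }
  }
  if (!length(cands)) return(NULL)
  ovs <- vapply(cands, `[[`, integer(1L), "ov")
  best <- which(ovs == max(ovs))
  if (length(best) > 1L) {
    merged <- vapply(cands[best], `[[`, character(1L), "merged")
    best <- best[order(merged)[1L]]
  }
  cands[[best]]
}

#' Find the best exact overlap between two sequences
#'
#' Reports the longest exact suffix-prefix overlap (of length at least
#' `min_overlap`) or containment between `a` and `b`, considering `b` in
#' both orientations. Used pairwise by the greedy assembler.
#'
#' @param a,b Nucleotide strings.
#' @param min_overlap Minimum accepted overlap length (default 14).
#' @return `NULL` if no qualifying overlap exists, otherwise a list with
#'   `type` (`"suffix_prefix"` or `"containment"`), `length` (overlap
#'   length), `b_orientation` (`"forward"`/`"reverse"`), `merged` (the
#'   merged sequence) and `a_offset`/`b_offset` (0-based positions of `a`
#'   and oriented `b` on `merged`).
#' @export
find_overlap <- function(a, b, min_overlap = 14L) {
  stopifnot(min_overlap >= 1L)
  m <- best_merge(normalize_seq(a), normalize_seq(b), min_overlap)
  if (is.null(m)) return(NULL)
  list(type = m$type, length = m$ov,
       b_orientation = if (m$b_rev) "reverse" else "forward",
       merged = m$merged, a_offset = m$a_shift, b_offset = m$b_shift)
}

flip_members <- function(members, unit_len) {
  members$offset <- unit_len - (members$offset + members$len)
  members$orient <- ifelse(members$orient == "+", "-", "+")
  members
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Assemble collapsed reads into contigs by exact overlap
#'
#' Greedy agglomeration: repeatedly merge the pair of units with the
#' longest exact overlap (suffix-prefix of at least `min_overlap` bases,
#' or containment), in either orientation, until no qualifying overlap
#' remains. Ties are broken by the lexicographically smallest merged
#' sequence. Reads that merge with nothing are not reported as contigs —
#' they remain unassembled candidates.
#'
#' @param cs A `collapsed_set`.
#' @param min_overlap Minimum exact overlap (default 14).
#' @return A list of class `contig_set`; each element is a `contig`: a
#'   list with `seq`, `length` and `members`, a data frame of
#'   (`id`, `offset`, `orient`, `len`) giving each member read's 0-based
#'   start on the contig and its orientation relative to the contig's
#'   forward strand. Attribute `unassembled_ids` lists the reads in no
#'   contig.
#' @export
assemble_contigs <- function(cs, min_overlap = 14L) {
  stopifnot(min_overlap >= 1L)
  n <- nrow(cs)
  units <- vector("list", n)
  for (i in seq_len(n)) {
    units[[i]] <- list(seq = cs$seq[i],
                       members = data.frame(id = cs$id[i], offset = 0L,
                                            orient = "+",
                                            len = nchar(cs$seq[i]),
                                            stringsAsFactors = FALSE))
  }
  active <- rep(TRUE, n)
  # k-mer index over both strands for candidate-pair generation
  index <- new.env(parent = emptyenv())
  add_to_index <- function(i) {
    s <- units[[i]]$seq
    for (km in c(seq_kmers(s, min_overlap), seq_kmers(revcomp(s), min_overlap)))
      assign(km, c(index[[km]], i), envir = index)
  }
  candidates_for <- function(i) {
    s <- units[[i]]$seq
    kms <- seq_kmers(s, min_overlap)   # forward only: partner index holds both strands
    ids <- unlist(lapply(kms, function(km) index[[km]]), use.names = FALSE)
    ids <- unique(ids)
    ids[ids != i & active[ids]]
  }
  for (i in seq_len(n)) add_to_index(i)

  # pair queue: only pairs with a qualifying overlap are stored
  pq <- list()
  push_pair <- function(i, j) {
    m <- best_merge(units[[i]]$seq, units[[j]]$seq, min_overlap)
    if (!is.null(m)) pq[[length(pq) + 1L]] <<- c(list(i = i, j = j), m)
  }
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (j in candidates_for(i)) {
      key <- paste(min(i, j), max(i, j))
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        push_pair(min(i, j), max(i, j))
      }
    }
  }

  merge_units <- function(i, j, m) {
    a <- units[[i]]; b <- units[[j]]
    bm <- b$members
    if (m$b_rev) bm <- flip_members(bm, nchar(b$seq))
    am <- a$members
    am$offset <- am$offset + m$a_shift
    bm$offset <- bm$offset + m$b_shift
    list(seq = m$merged, members = rbind(am, bm))
  }

  while (length(pq)) {
    ovs <- vapply(pq, `[[`, integer(1L), "ov")
    live <- vapply(pq, function(p) active[p$i] && active[p$j], logical(1L))
    ovs[!live] <- -1L
    if (max(ovs) < min_overlap) break
    best <- which(ovs == max(ovs))
    if (length(best) > 1L) {
      merged <- vapply(pq[best], `[[`, character(1L), "merged")
      best <- best[order(merged)[1L]]
    }
    p <- pq[[best]]
    new_unit <- merge_units(p$i, p$j, p)
    active[c(p$i, p$j)] <- FALSE
    units[[length(units) + 1L]] <- new_unit
    k <- length(units)
    active[k] <- TRUE
    add_to_index(k)
    pq <- pq[live & seq_along(pq) != best]
    for (j in candidates_for(k)) push_pair(j, k)
  }

  keep <- which(active)
  multi <- keep[vapply(keep, function(i) nrow(units[[i]]$members) > 1L,
                       logical(1L))]
  contigs <- lapply(units[multi], function(u) {
    u$length <- nchar(u$seq)
    rownames(u$members) <- NULL
    class(u) <- "contig"
    u
  })
  singles <- setdiff(keep, multi)
  unassembled <- unlist(lapply(units[singles],
                               function(u) u$members$id), use.names = FALSE)
  structure(contigs, unassembled_ids = unassembled, class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("<contig_set: %d contigs, %d unassembled reads>\n",
              length(x), length(attr(x, "unassembled_ids"))))
  invisible(x)
}

#' Remove reads in long unidirectional contigs
#'
#' Contigs strictly longer than the length threshold whose member reads
#' all share one orientation carry the signature of mRNA degradation
#' fragments rather than Dicer products; all their member reads are
#' removed from the candidate pool. The threshold defaults to the median
#' length of the (multi-member) contigs. Singleton reads and reads in
#' retained contigs stay in the pool.
#'
#' @param cs The `collapsed_set` the contigs were assembled from.
#' @param contigs A `contig_set` from [assemble_contigs()].
#' @param length_threshold `"median"` (default) or an explicit integer.
#' @return A list of class `contig_filter_result`: `contigs` (annotated
#'   data frame: `contig`, `length`, `n_members`, `unidirectional`,
#'   `removed`), `removed_read_ids`, `retained` (filtered
#'   `collapsed_set`), and `median_contig_length`.
#' @export
filter_long_unidirectional <- function(cs, contigs,
                                       length_threshold = "median") {
  lens <- vapply(contigs, `[[`, integer(1L), "length")
  med <- if (length(lens)) stats::median(lens) else NA_real_
  thr <- if (identical(length_threshold, "median")) med
         else as.numeric(length_threshold)
  unidir <- vapply(contigs, function(ct) {
    length(unique(ct$members$orient)) == 1L
  }, logical(1L))
  flagged <- if (length(lens)) lens > thr & unidir else logical()
  removed_ids <- unique(unlist(lapply(which(flagged), function(i) {
    contigs[[i]]$members$id
  }), use.names = FALSE))
  if (is.null(removed_ids)) removed_ids <- character()
  keep <- !(cs$id %in% removed_ids)
  retained <- cs[keep, , drop = FALSE]
  rownames(retained) <- NULL
  attr(retained, "total_input") <- sum(retained$count)
  class(retained) <- c("collapsed_set", "data.frame")
  tab <- data.frame(contig = seq_along(contigs), length = lens,
                    n_members = vapply(contigs, function(ct)
                      nrow(ct$members), integer(1L)),
                    unidirectional = unidir, removed = flagged,
                    stringsAsFactors = FALSE)
  structure(list(contigs = tab, removed_read_ids = removed_ids,
                 retained = retained, median_contig_length = med,
                 length_threshold = thr),
            class = "contig_filter_result")
}

#' @export
print.contig_filter_result <- function(x, ...) {
  cat(sprintf(paste0("<contig_filter_result: %d contigs (median length %s),",
                     " %d flagged, %d reads removed, %d retained>\n"),
              nrow(x$contigs), format(x$median_contig_length),
              sum(x$contigs$removed), length(x$removed_read_ids),
              nrow(x$retained)))
  invisible(x)
}
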