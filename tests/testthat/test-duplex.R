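test_that("pair_duplex accepts perfect 2-nt-overhang partners", {
  a <- "ACAGATTGCGGCAACCGTGCAG"
  b <- paste0(revcomp(substr(a, 1, 20)), "TT")
  al <- pair_duplex(a, b)
  expect_equal(al$mismatches, 0L)
  expect_equal(nrow(al$bulges), 0L)
  expect_equal(al$overhang_a, 2L)

  # the overhang is unconstrained in sequence
  for (xy in c("AA", "GC", "TG")) {
    al <- pair_duplex(a, paste0(revcomp(substr(a, 1, 20)), xy))
    expect_equal(al$mismatches, 0L)
  }
})

test_that("pair_duplex rejects non-complementary and wrong-geometry pairs", {
  expect_null(pair_duplex(strrep("A", 22), strrep("G", 22)))
  # a sequence facing itself: A:A at every pairing position
  expect_null(pair_duplex(strrep("A", 22), strrep("A", 22)))
  # whereas poly(T) is poly(A)'s perfect antiparallel partner
  expect_equal(pair_duplex(strrep("A", 22), strrep("T", 22))$mismatches, 0L)
  # pairing-region length difference of 2 exceeds one bulge
  set.seed(21)
  expect_null(pair_duplex(rdna(1, 22), rdna(1, 24)))
  # wobble G:T is a mismatch, not a pair: every position pairs G with T
  expect_null(pair_duplex(strrep("G", 22), strrep("T", 22)))
})

test_that("mismatch counting matches the exhaustive oracle at the 3-mismatch edge", {
  set.seed(22)
  for (rep in 1:20) {
    a <- rdna(1, 22)
    perfect <- perfect_partner(a)
    for (k in c(3L, 4L)) {
      mut <- strsplit(perfect, "")[[1]]
      pos <- sample(20, k)                 # only pairing-region positions
      for (p in pos) {
        mut[p] <- setdiff(c("A", "C", "G", "T"),
                          c(mut[p], ORACLE_COMP[[substr(a, 21 - p, 21 - p)]]))[1]
      }
      b <- paste(mut, collapse = "")
      got <- pair_duplex(a, b)
      want <- oracle_duplex(a, b)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got$mismatches, want$mismatches)
        expect_equal(nrow(got$bulges), want$bulges)
      }
    }
  }
})

test_that("a single interior bulge is found on either strand", {
  set.seed(23)
  a <- rdna(1, 22)
  # partner built from a's pairing region with one interior base deleted:
  # a's strand carries the bulge
  pa <- strsplit(substr(a, 1, 20), "")[[1]]
  b <- paste0(oracle_rc(paste(pa[-10], collapse = "")), "GG")
  al <- pair_duplex(a, b)
  expect_equal(al$mismatches, 0L)
  expect_equal(al$bulges$strand, "A")
  # symmetric call reports the same counts, with the bulge on the same
  # physical read (now passed as the second argument)
  al2 <- pair_duplex(b, a)
  expect_equal(al2$mismatches, 0L)
  expect_equal(al2$bulges$strand, "B")
  # disallowing bulges rejects the pair
  expect_null(pair_duplex(a, b, max_bulges = 0))
})

test_that("find_duplexes equals exhaustive enumeration on random sets", {
  set.seed(24)
  seqs <- unique(c(rdna(60, sample(18:26, 60, replace = TRUE)), {
    a <- rdna(1, 22); c(a, perfect_partner(a, "CA"))
  }))
  cs <- collapse_reads(rep(seqs, times = sample(1:5, length(seqs),
                                                replace = TRUE)))
  got <- find_duplexes(cs)
  want <- oracle_find_duplexes(cs$seq)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$seq_a, want$seq_a)
  expect_equal(got$seq_b, want$seq_b)
  expect_equal(got$mismatches, want$mismatches)
  expect_equal(got$bulges, want$bulges)

  expect_equal(nrow(find_duplexes(collapse_reads(character()))), 0L)
})

test_that("candidate enumeration counts unique sequences and lengths", {
  set.seed(25)
  a <- rdna(1, 22); b <- perfect_partner(a, "GT")
  cs <- collapse_reads(c(rep(a, 100), rep(b, 5)))
  pairs <- find_duplexes(cs)
  cm <- candidate_mirnas(pairs)
  expect_length(cm$sequences, 2)
  expect_equal(cm$length_histogram,
               data.frame(length = 22L, n = 2L))

  # a sequence in two pairs is counted once
  b2 <- perfect_partner(a, "CC")
  cs2 <- collapse_reads(c(rep(a, 10), rep(b, 5), rep(b2, 5)))
  cm2 <- candidate_mirnas(find_duplexes(cs2))
  expect_length(cm2$sequences, 3)
})

test_that("abundance asymmetry labels the putative guide strand", {
  r <- abundance_asymmetry(100, 5)
  expect_equal(r$ratio, 20)
  expect_equal(r$guide, "A")
  r <- abundance_asymmetry(7, 7)
  expect_equal(r$ratio, 1)
  expect_equal(r$guide, "tie")
  r <- abundance_asymmetry(5, 100)
  expect_equal(r$guide, "B")
})

test_that("duplex geometry invariants hold on random pairs", {
  set.seed(26)
  n_bad <- 0L
  for (i in 1:300) {
    a <- rdna(1, sample(18:26, 1))
    b <- if (i %% 4 == 0) perfect_partner(a, paste(sample(c("A","C","G","T"),
                                                          2, replace = TRUE),
                                                   collapse = ""))
         else rdna(1, sample(18:26, 1))
    f <- pair_duplex(a, b)
    g <- pair_duplex(b, a)
    if (xor(is.null(f), is.null(g))) n_bad <- n_bad + 1L
    if (!is.null(f) && !is.null(g)) {
      if (f$mismatches != g$mismatches ||
          nrow(f$bulges) != nrow(g$bulges)) n_bad <- n_bad + 1L
      if (abs(nchar(a) - nchar(b)) > 1L) n_bad <- n_bad + 1L
    }
    if (i %% 4 == 0 && (is.null(f) || f$mismatches != 0L)) n_bad <- n_bad + 1L
  }
  expect_equal(n_bad, 0L)
})
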