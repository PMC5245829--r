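test_that("find_overlap reports suffix-prefix overlaps at the 14-base threshold", {
  set.seed(8)
  a <- rdna(1, 20)
  b <- paste0(substr(a, 7, 20), "CCCCCC")     # shares a's last 14 bases
  ov <- find_overlap(a, b, 14)
  expect_equal(ov$type, "suffix_prefix")
  expect_equal(ov$length, 14L)
  expect_equal(ov$b_orientation, "forward")
  expect_equal(ov$merged, paste0(a, "CCCCCC"))

  b13 <- paste0(substr(a, 8, 20), "CCCCCC")   # only 13 shared bases
  expect_null(find_overlap(a, b13, 14))

  # containment reports the contained read's offset
  inner <- substr(a, 3, 18)
  ov <- find_overlap(a, inner, 14)
  expect_equal(ov$type, "containment")
  expect_equal(ov$b_offset, 2L)

  # reverse-orientation overlap is found
  ov <- find_overlap(a, revcomp(b), 14)
  expect_equal(ov$length, 14L)
  expect_equal(ov$b_orientation, "reverse")
})

test_that("find_overlap agrees with a brute-force overlap oracle", {
  set.seed(9)
  for (rep in 1:60) {
    a <- rdna(1, sample(18:30, 1))
    b <- if (rep %% 3 == 0) {
      # planted overlap of random length, possibly reverse-complemented
      ov <- sample(10:18, 1)
      core <- paste0(substr(a, nchar(a) - ov + 1L, nchar(a)), rdna(1, 8))
      if (rep %% 2 == 0) revcomp(core) else core
    } else rdna(1, sample(18:30, 1))
    got <- find_overlap(a, b, 14)
    want <- oracle_best_overlap(a, b, 14)
    expect_equal(if (is.null(got)) 0L else got$length, want,
                 info = paste(a, b))
  }
})

test_that("greedy assembly merges overlapping reads into consistent contigs", {
  set.seed(10)
  a <- rdna(1, 20)
  b <- paste0(substr(a, 7, 20), rdna(1, 6))
  cs <- collapse_reads(c(rep(a, 3), rep(b, 2)))
  contigs <- assemble_contigs(cs, 14)
  expect_length(contigs, 1)
  expect_equal(contigs[[1]]$length, 26L)      # 20 + 20 - 14
  expect_equal(nrow(contigs[[1]]$members), 2L)

  # member consistency: every member substring reproduces its read
  seq_of <- setNames(cs$seq, cs$id)
  for (m in seq_len(nrow(contigs[[1]]$members))) {
    mb <- contigs[[1]]$members[m, ]
    piece <- substr(contigs[[1]]$seq, mb$offset + 1L, mb$offset + mb$len)
    want <- if (mb$orient == "+") seq_of[[mb$id]] else revcomp(seq_of[[mb$id]])
    expect_equal(piece, want)
  }

  # mutually non-overlapping reads produce no contigs
  none <- assemble_contigs(collapse_reads(c("ACGTACGTACGTACGTAC",
                                            "TTGCATGCATGCATGCAA",
                                            "GGATCGATCGATCGATGG")), 14)
  expect_length(none, 0)
  expect_length(attr(none, "unassembled_ids"), 3)
})

test_that("assembly records orientations for reverse-complemented members", {
  set.seed(12)
  a <- rdna(1, 22)
  b <- revcomp(paste0(substr(a, 9, 22), rdna(1, 8)))  # overlaps a only as revcomp
  cs <- collapse_reads(c(a, b))
  contigs <- assemble_contigs(cs, 14)
  expect_length(contigs, 1)
  orients <- sort(contigs[[1]]$members$orient)
  expect_equal(orients, c("+", "-"))
  # and the members still tile the contig exactly
  seq_of <- setNames(cs$seq, cs$id)
  for (m in seq_len(nrow(contigs[[1]]$members))) {
    mb <- contigs[[1]]$members[m, ]
    piece <- substr(contigs[[1]]$seq, mb$offset + 1L, mb$offset + mb$len)
    want <- if (mb$orient == "+") seq_of[[mb$id]] else revcomp(seq_of[[mb$id]])
    expect_equal(piece, want)
  }
})

test_that("tiled fragments chain into one long unidirectional contig", {
  set.seed(13)
  tx <- rdna(1, 120)
  starts <- seq(1, 99, by = 7)
  frags <- substring(tx, starts, starts + 21)
  cs <- collapse_reads(rep(frags, 5))
  contigs <- assemble_contigs(cs, 14)
  expect_length(contigs, 1)
  expect_equal(contigs[[1]]$seq, substr(tx, 1, max(starts) + 21))
  expect_true(all(contigs[[1]]$members$orient == "+"))
  expect_equal(nrow(contigs[[1]]$members), length(starts))
})

test_that("the long-unidirectional filter removes only flagged contig members", {
  set.seed(14)
  # one long unidirectional chain + one short bidirectional pair + singletons
  tx <- rdna(1, 120)
  starts <- seq(1, 99, by = 7)
  frags <- substring(tx, starts, starts + 21)
  a <- rdna(1, 22)
  b <- revcomp(paste0(substr(a, 7, 22), rdna(1, 6)))
  singles <- rdna(3, 22)
  cs <- collapse_reads(c(rep(frags, 5), rep(a, 3), rep(b, 2), singles))
  contigs <- assemble_contigs(cs, 14)
  res <- filter_long_unidirectional(cs, contigs, length_threshold = 26)

  frag_ids <- cs$id[cs$seq %in% frags]
  expect_setequal(res$removed_read_ids, frag_ids)
  # partition invariant: removed + retained tile the input exactly
  expect_setequal(c(res$removed_read_ids, res$retained$id), cs$id)

  # bidirectional contig members and singletons are retained
  expect_true(all(cs$id[cs$seq %in% c(a, b)] %in% res$retained$id))
  expect_true(all(cs$id[cs$seq %in% singles] %in% res$retained$id))
})

test_that("the length threshold is strict and direction-aware", {
  set.seed(15)
  # contig of length exactly 30, all forward
  a <- rdna(1, 22)
  # a 30-base contig from two 22-mers overlapping by 14
  b <- paste0(substr(a, 9, 22), rdna(1, 8))
  cs <- collapse_reads(c(a, b))
  contigs <- assemble_contigs(cs, 14)
  expect_equal(contigs[[1]]$length, 30L)

  res26 <- filter_long_unidirectional(cs, contigs, length_threshold = 26)
  expect_equal(sort(res26$removed_read_ids), sort(cs$id))  # 30 > 26, same direction

  res30 <- filter_long_unidirectional(cs, contigs, length_threshold = 30)
  expect_length(res30$removed_read_ids, 0)                 # strictly greater only

  # same contig with mixed orientations is never removed
  cs2 <- collapse_reads(c(a, revcomp(b)))
  contigs2 <- assemble_contigs(cs2, 14)
  expect_equal(contigs2[[1]]$length, 30L)
  res2 <- filter_long_unidirectional(cs2, contigs2, length_threshold = 26)
  expect_length(res2$removed_read_ids, 0)
})

test_that("the median contig length is the default threshold", {
  set.seed(16)
  tx <- rdna(1, 150)
  starts <- seq(1, 129, by = 7)
  frags <- substring(tx, starts, starts + 21)           # long chain, ~150 nt
  a <- rdna(1, 22)
  b <- paste0(substr(a, 9, 22), rdna(1, 8))             # short 30-nt contig
  c2 <- rdna(1, 22)
  d2 <- paste0(substr(c2, 9, 22), rdna(1, 8))           # another 30-nt contig
  cs <- collapse_reads(c(frags, a, b, c2, d2))
  contigs <- assemble_contigs(cs, 14)
  res <- filter_long_unidirectional(cs, contigs)
  expect_equal(res$median_contig_length, 30)            # lengths {150, 30, 30}
  expect_setequal(res$removed_read_ids, cs$id[cs$seq %in% frags])
})
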