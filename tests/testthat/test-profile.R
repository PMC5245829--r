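make_tx <- function(len = 120) {
  s <- rdna(1, len)
  while (has_polya(s)) s <- rdna(1, len)
  s
}

test_that("map_reads reports sense and antisense occurrences with offsets", {
  set.seed(31)
  tx <- make_tx()
  cs <- collapse_reads(c(substr(tx, 11, 32),          # sense at 0-based 10
                         revcomp(substr(tx, 6, 27)),  # antisense at 5
                         rdna(1, 22)))                # absent
  mp <- map_reads(cs, "tx1", tx)
  sense <- mp[mp$strand == "sense", ]
  anti <- mp[mp$strand == "antisense", ]
  expect_equal(sense$start, 10L)
  expect_equal(anti$start, 5L)
  expect_equal(nrow(mp), 2L)
  # every mapping is sense xor antisense
  expect_true(all(mp$strand %in% c("sense", "antisense")))

  # multi-occurrence reads produce one mapping per occurrence
  tx2 <- paste0(tx, substr(tx, 1, 40))
  mp2 <- map_reads(collapse_reads(substr(tx, 11, 32)), "tx2", tx2)
  expect_equal(sort(mp2$start), c(10L, 130L))
})

test_that("profiles weight reads by collapsed counts and find UTR antisense", {
  set.seed(32)
  tx <- make_tx(200)
  sense_reads <- substring(tx, c(1, 31, 61), c(22, 52, 82))
  anti <- revcomp(substr(tx, 151, 172))   # starts at 150, inside UTR at 140
  cs <- collapse_reads(c(rep(sense_reads[1], 50), rep(sense_reads[2], 30),
                         rep(sense_reads[3], 14), rep(anti, 6)))
  mp <- map_reads(cs, "tx", tx)
  pr <- profile_transcript(mp, "tx", tx, utr3_start = 140)
  expect_equal(pr$total_reads, 100L)
  expect_equal(pr$antisense_reads, 6L)
  expect_equal(pr$utr3_antisense, 6L)
  # coverage mass equals mapped read-length mass
  expect_equal(sum(pr$sense_coverage) + sum(pr$antisense_coverage),
               sum(mp$count * mp$len))

  # unweighted mode counts unique reads
  pr_u <- profile_transcript(mp, "tx", tx, weighted = FALSE)
  expect_equal(pr_u$total_reads, 4L)
  expect_equal(pr_u$antisense_reads, 1L)

  expect_error(profile_transcript(mp, "tx", tx, utr3_start = 500),
               "utr3")
})

test_that("an LBP-like composition recovers its planted antisense count", {
  set.seed(33)
  tx <- make_tx(300)
  starts <- sample(1:250, 100, replace = TRUE)
  sense <- substring(tx, starts, starts + 21)
  anti <- revcomp(substring(tx, c(40, 90, 140, 190, 230, 10),
                            c(61, 111, 161, 211, 251, 31)))
  cs <- collapse_reads(c(sense, anti))
  pr <- profile_transcript(map_reads(cs, "lbp", tx), "lbp", tx)
  expect_equal(pr$total_reads, 106L)
  expect_equal(pr$antisense_reads, 6L)
})

test_that("sense partners of antisense reads are found via duplex geometry", {
  set.seed(34)
  tx <- make_tx(200)
  anti <- revcomp(substr(tx, 51, 72))
  # the sense read shifted 2 nt downstream forms a perfect duplex with
  # anti: both pairing regions cover tx[53..72]
  partner <- substr(tx, 53, 74)
  sense_bg <- substring(tx, c(1, 101), c(22, 122))
  cs <- collapse_reads(c(rep(sense_bg, 3), partner, rep(anti, 2)))
  mp <- map_reads(cs, "tx", tx)
  # the partner maps sense: it is revcomp(anti minus overhang) + 2 nt,
  # i.e. nearly the original transcript substring — map it directly
  pr <- profile_transcript(mp, "tx", tx)
  fp <- find_sense_partners(pr, cs)
  expect_gte(nrow(fp), 1L)
  expect_true(all(fp$antisense_id %in% cs$id[cs$seq == anti]))

  # consistency: every partner pair is also found by the global search
  mapped_ids <- unique(mp$read_id)
  global <- find_duplexes(cs[cs$id %in% mapped_ids, ])
  seq_of <- setNames(cs$seq, cs$id)
  for (r in seq_len(nrow(fp))) {
    pr_seqs <- sort(c(seq_of[[fp$antisense_id[r]]], seq_of[[fp$sense_id[r]]]))
    expect_true(any(global$seq_a == pr_seqs[1] & global$seq_b == pr_seqs[2]))
  }

  # no antisense reads, no partners
  pr0 <- profile_transcript(mp[mp$strand == "sense", ], "tx", tx)
  expect_equal(nrow(find_sense_partners(pr0, cs)), 0L)
})

test_that("coverage patterns classify by antisense fraction", {
  prof <- function(total, anti) {
    structure(list(total_reads = total, antisense_reads = anti),
              class = "transcript_profile")
  }
  expect_equal(classify_pattern(prof(500, 0)), "A")
  expect_equal(classify_pattern(prof(500, 125)), "C")   # 25% > 20%
  expect_equal(classify_pattern(prof(500, 3)), "B")
  expect_equal(classify_pattern(prof(500, 100)), "B")   # 20% is not "over 20%"
  expect_error(classify_pattern(prof(0, 0)), "undefined")
})

test_that("position frequency matrices anchor on the common core", {
  pfm <- build_pfm(rep("ACGT", 3))
  expect_equal(pfm$consensus, "ACGT")
  expect_true(all(pfm$identity))
  expect_equal(unname(pfm$counts["A", 1]), 3L)

  # tie broken alphabetically
  pfm2 <- build_pfm(c("AAAA", "AAAC"))
  expect_equal(pfm2$consensus, "AAAA")
  expect_false(pfm2$identity[4])

  # offset sequences align on the shared core
  pfm3 <- build_pfm(c("GGACGTACGTACGT", "ACGTACGTACGTTT"))
  expect_equal(substr(pfm3$consensus, 3, 14), "ACGTACGTACGT")

  # majority consensus is robust to a minority of mutated copies
  set.seed(35)
  probe <- "ACAGATTGCGGCAACCGTGCAG"
  seqs <- rep(probe, 100)
  for (i in 1:5) {
    p <- sample(22, 1)
    substr(seqs[i], p, p) <- setdiff(c("A", "C", "G", "T"),
                                     substr(probe, p, p))[1]
  }
  pfm4 <- build_pfm(seqs)
  expect_equal(pfm4$consensus, probe)
  expect_equal(pfm4$n_sequences, 100L)
})
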