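# Generates the bundled synthetic reference fixtures under inst/extdata/.
# All sequences are random DNA (no biological provenance), constrained to
# avoid internal polyA runs (>6 A) so degradation fragments tiled from
# the transcripts survive the cleaning cascade, and re-drawn on the
# (unlikely) event of a shared 14-mer between any two entries, so the
# fixture sets cannot cross-match during subtraction or assembly.
# Run from the package root: Rscript data-raw/make_fixtures.R

set.seed(20160817L)

draw <- function(len) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!grepl("AAAAAAA", s, fixed = TRUE)) return(s)
  }
}

revcomp0 <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

kmers <- function(s, k = 14L) {
  n <- nchar(s)
  c(substring(s, 1:(n - k + 1L), k:n),
    substring(revcomp0(s), 1:(n - k + 1L), k:n))
}

draw_disjoint <- function(lens) {
  seqs <- character(0)
  seen <- character(0)
  for (len in lens) {
    repeat {
      s <- draw(len)
      km <- kmers(s)
      if (!any(km %in% seen)) {
        seqs <- c(seqs, s)
        seen <- c(seen, km)
        break
      }
    }
  }
  seqs
}

write_fa <- function(ids, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

rrna <- draw_disjoint(c(160, 140, 120))
trna <- draw_disjoint(c(75, 80, 72))
org <- draw_disjoint(c(200, 180))
tx <- draw_disjoint(c(300, 320, 280, 300, 260))

write_fa(paste0("synthetic_rrna_", 1:3), rrna, "inst/extdata/synthetic_rrna.fa")
write_fa(paste0("synthetic_trna_", 1:3), trna, "inst/extdata/synthetic_trna.fa")
write_fa(paste0("synthetic_organelle_", 1:2), org,
         "inst/extdata/synthetic_organelle.fa")
write_fa(c("synthetic_lbp_like", paste0("synthetic_tx_", 2:5)), tx,
         "inst/extdata/synthetic_transcripts.fa")

# declared 3' UTR offset (0-based) for the LBP-like transcript
writeLines(c("id\tutr3_start", "synthetic_lbp_like\t240"),
           "inst/extdata/synthetic_utr3.tsv")
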