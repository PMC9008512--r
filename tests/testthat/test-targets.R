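rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("site scoring follows the penalty schema with seed doubling", {
  mir <- "TGAAGCTGCCAGCATGATCTA"        # 21 nt
  tx <- paste0("AAAA", rc(mir), "GGGG")
  hit <- scanTargets(mir, tx)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$expectation, 0)
  expect_identical(hit$site_start, 5L)

  # G:U wobble at miRNA position 20 (outside seed): penalty 0.5.
  # miRNA position i pairs site position L - i + 1; make the miRNA carry G
  # and the target T at that spot.
  site <- seq_chars(rc(mir))
  mirv <- seq_chars(mir)
  pos20 <- 21 - 20 + 1
  mirv[20] <- "G"; site[pos20] <- "T"
  h20 <- scanTargets(paste(mirv, collapse = ""),
                     paste0("AAAA", paste(site, collapse = ""), "GGGG"))
  expect_equal(h20$expectation, 0.5)
  # the same wobble at position 5 (seed): doubled to 1.0
  site <- seq_chars(rc(mir)); mirv <- seq_chars(mir)
  pos5 <- 21 - 5 + 1
  mirv[5] <- "G"; site[pos5] <- "T"
  h5 <- scanTargets(paste(mirv, collapse = ""),
                    paste0("AAAA", paste(site, collapse = ""), "GGGG"))
  expect_equal(h5$expectation, 1.0)

  expect_error(scanTargets("ACGTACGTACGT", tx), "18-26")
})

test_that("cutoff is inclusive and suppresses worse sites", {
  mir <- strrep("A", 21)
  # a site at expectation exactly equal to the cutoff is emitted; the
  # mismatch sits mid-site (miRNA position 14, outside the seed, weight 1)
  # so no shifted alignment ties with it
  site <- seq_chars(strrep("T", 21))
  site[8] <- "G"
  tx <- paste0("CC", paste(site, collapse = ""), "CC")
  h <- scanTargets(mir, tx, cutoff = 1.0)
  expect_identical(nrow(h), 1L)
  expect_equal(h$expectation, 1.0)
  expect_identical(nrow(scanTargets(mir, tx, cutoff = 0.99)), 0L)
})

test_that("scan agrees with the brute-force scorer on random pairs", {
  set.seed(6)
  for (i in 1:50) {
    mir <- random_dna(sample(18:26, 1))
    tx <- random_dna(500)
    expect_equal(ceRNAflow:::scan_scores(mir, tx), scan_oracle(mir, tx),
                 tolerance = 1e-12)
  }
})

test_that("cis window rule matches the all-pairs interval oracle", {
  set.seed(13)
  mk <- function(n, pre) {
    gr <- GenomicRanges::GRanges(
      sample(c("chr1", "chr2"), n, TRUE),
      IRanges::IRanges(start = sample(1:200000, n), width = sample(200:3000, n)),
      strand = sample(c("+", "-"), n, TRUE))
    names(gr) <- paste0(pre, seq_len(n))
    gr
  }
  lnc <- mk(100, "L"); gen <- mk(100, "G")
  got <- cisPairs(lnc, gen)
  ora <- cis_oracle(lnc, gen)
  key <- function(d) sort(paste(d$lncrna_id, d$gene_id, d$distance))
  expect_identical(key(got), key(ora))
  # symmetric in which set is the query (distances unchanged)
  swapped <- cisPairs(gen, lnc)
  expect_identical(sort(paste(swapped$gene_id, swapped$lncrna_id,
                              swapped$distance)),
                   key(got))
})

test_that("cis boundary is inclusive at the window and strands set relation", {
  lnc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, 101000), "+")
  names(lnc) <- "L1"
  gene_at <- function(gap) {
    g <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(101000 + gap + 1, width = 1000), "+")
    names(g) <- "G1"
    g
  }
  expect_identical(nrow(cisPairs(lnc, gene_at(10000))), 1L)
  expect_identical(cisPairs(lnc, gene_at(10000))$distance, 10000L)
  expect_identical(nrow(cisPairs(lnc, gene_at(10001))), 0L)
  expect_identical(cisPairs(lnc, gene_at(3999))$distance, 3999L)
  # relation follows the lncRNA's strand
  expect_identical(cisPairs(lnc, gene_at(100))$relation, "downstream")
  GenomicRanges::strand(lnc) <- "-"
  expect_identical(cisPairs(lnc, gene_at(100))$relation, "upstream")
  # disjoint chromosome sets: error
  g2 <- GenomicRanges::GRanges("chr9", IRanges::IRanges(500, 600))
  names(g2) <- "G1"
  expect_error(cisPairs(lnc, g2), "chromosome")
})

test_that("trans pairing energy reproduces hand-computed alignments", {
  # perfect 200-nt G:C duplex: 200 pairs at -3 each
  h <- transPairs(strrep("G", 200), strrep("C", 200))
  expect_equal(h$dg, -600)
  expect_equal(h$ndg, -3)
  expect_identical(h$window_start_lnc, 1L)
  expect_identical(h$window_start_mrna, 1L)
  # zero complementarity is never emitted
  polyA <- strrep("A", 100)
  expect_identical(nrow(transPairs(polyA, polyA)), 0L)
  # boundary: ndg exactly at the threshold is emitted (<= rule)
  # 50-nt A:U duplex inside inert context: dg = -100 over len-100 sequences
  lnc <- paste0(strrep("C", 25), strrep("A", 50), strrep("C", 25))
  mrna <- paste0(strrep("A", 25), strrep("T", 50), strrep("A", 25))
  hb <- transPairs(lnc, mrna, threshold = -1)
  expect_equal(hb$ndg, hb$dg / 100)
  expect_identical(nrow(transPairs(lnc, mrna,
                                   threshold = hb$ndg)), 1L)
  expect_identical(nrow(transPairs(lnc, mrna,
                                   threshold = hb$ndg + 1e-9)), 1L)
  expect_identical(nrow(transPairs(lnc, mrna,
                                   threshold = hb$ndg - 1e-9)), 0L)
  expect_error(transPairs("ACGT", polyA), "window")
})
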