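make_tx <- function(ids, codes, lengths) {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = seq(1, by = 50000, length.out = length(ids)),
                     width = lengths))
  names(gr) <- ids
  S4Vectors::mcols(gr)$class_code <- codes
  S4Vectors::mcols(gr)$tx_length <- lengths
  gr
}

test_that("candidate filter keeps u/i/x/o transcripts strictly over 200 nt", {
  tx <- make_tx(paste0("t", 1:6),
                c("u", "=", "x", "i", "o", "u"),
                c(350, 350, 200, 201, 5000, 150))
  kept <- filterLncrnaCandidates(tx)
  expect_identical(names(kept), c("t1", "t4", "t5"))   # order preserved
  tx2 <- make_tx("t1", NA_character_, 300)
  expect_error(filterLncrnaCandidates(tx2), "class_code")
})

test_that("ORF rule finds the longest in-frame ORF across three frames", {
  # 150-codon ORF -> coding by length
  s <- paste0(strrep("C", 7), "ATG", strrep("GCA", 150), "TAA", strrep("C", 100))
  cp <- codingPotential(s)
  expect_identical(cp$longest_orf_aa, 151L)
  expect_identical(cp$label, "coding")
  # no ATG at all -> no ORF
  cp0 <- codingPotential(strrep("C", 300))
  expect_identical(cp0$longest_orf_aa, 0L)
  expect_identical(cp0$label, "non-coding")
  # ATG AAA TAA embedded in a 240-nt inert context: 2 aa, coverage 9/240
  s2 <- paste0(strrep("C", 120), "ATGAAATAA", strrep("C", 111))
  cp2 <- codingPotential(s2)
  expect_identical(cp2$longest_orf_aa, 2L)
  expect_equal(cp2$orf_coverage, 9 / 240)
  expect_identical(cp2$label, "non-coding")
  # coverage rule alone can call coding
  s3 <- paste0("ATG", strrep("GCA", 60), "TAA", strrep("C", 110))
  expect_identical(codingPotential(s3)$label, "coding")  # 186/296 > 0.5
  expect_identical(codingPotential(s3, min_coverage = 0.7)$label,
                   "non-coding")
  expect_error(codingPotential(""), "non-empty")
  expect_error(codingPotential("ACGTB"), "non-nucleotide")
})

test_that("cascade labels lncRNA vs other and never drops records", {
  fix <- toy_cascade_fixture()
  ann <- rtracklayer::import(fix$gff)
  names(ann) <- S4Vectors::mcols(ann)$ID
  S4Vectors::mcols(ann)$tx_length <-
    as.integer(S4Vectors::mcols(ann)$tx_length)
  seqs <- Biostrings::readDNAStringSet(fix$fasta)
  out <- classifyTranscripts(ann, seqs)
  expect_identical(length(out), length(ann))
  got <- names(out)[S4Vectors::mcols(out)$biotype == "lncRNA"]
  expect_setequal(got, fix$expected_lncrna)
  expect_true(all(S4Vectors::mcols(out)$biotype %in% c("lncRNA", "other")))
})

test_that("cascade thresholds are monotone and agree on the simulation", {
  sim <- small_sim()
  ann <- simAnnotation(sim)
  truth_bio <- setNames(S4Vectors::mcols(ann)$biotype, names(ann))
  out <- classifyTranscripts(ann, simSequences(sim))
  got <- setNames(S4Vectors::mcols(out)$biotype, names(out))
  expect_setequal(names(got)[got == "lncRNA"],
                  names(truth_bio)[truth_bio == "lncRNA"])
  # raising min_orf_aa can only grow the lncRNA set
  lax <- classifyTranscripts(ann, simSequences(sim), min_orf_aa = 30)
  strict <- classifyTranscripts(ann, simSequences(sim), min_orf_aa = 300)
  lnc_of <- function(x) names(x)[S4Vectors::mcols(x)$biotype == "lncRNA"]
  expect_true(all(lnc_of(lax) %in% lnc_of(strict)))
})

test_that("small-RNA catalog matches the exhaustive Hamming oracle", {
  set.seed(5)
  mature <- setNames(replicate(20, random_dna(21)), sprintf("mat_%02d", 1:20))
  reads <- c(
    mature[[3]],                                    # identity, 0 mismatches
    sub("^.", ifelse(substr(mature[[7]], 1, 1) == "A", "C", "A"),
        mature[[7]]),                               # 1 mismatch
    replicate(97, random_dna(sample(c(15:24), 1))))
  got <- catalogSmallRNA(reads, mature)
  expect_true(all(got$length >= 18))
  oracle <- catalog_oracle(reads, as.list(mature))
  expect_identical(nrow(got), length(oracle))
  for (i in seq_along(oracle)) {
    expect_identical(got$matched_mature_id[i], oracle[[i]]$id)
    expect_identical(got$status[i],
                     if (is.na(oracle[[i]]$id)) "unassigned" else "conserved")
  }
  # boundary: a 17-nt read is discarded even if it would match
  expect_identical(nrow(catalogSmallRNA(substr(mature[[1]], 1, 17), mature)),
                   0L)
  expect_error(catalogSmallRNA("ACGTACGTACGTACGTAZ", mature),
               "non-nucleotide")
})

test_that("feature summary reports GC contrast with a Welch t-test", {
  expect_equal(summarizeFeatures("GGCC", "GGCC")$lncRNA$gc, 1.0)
  expect_equal(summarizeFeatures("AATT", "GGCC")$lncRNA$gc, 0.0)
  # identical GC distributions: t = 0, p = 1
  s <- c("GGAA", "GCAT", "GGGA", "ATAT")
  out <- summarizeFeatures(s, s)
  expect_equal(out$gc_test$t, 0)
  expect_equal(out$gc_test$p, 1)
  # clearly separated GC means at n = 500: p below double resolution
  set.seed(9)
  mk <- function(mu) vapply(rnorm(500, mu, 0.02), function(g) {
    g <- min(max(g, 0), 1)
    n_gc <- round(100 * g)
    paste(c(rep("G", n_gc), rep("A", 100 - n_gc)), collapse = "")
  }, character(1))
  out2 <- summarizeFeatures(mk(0.4), mk(0.5))
  expect_lt(out2$gc_test$p, 2.22e-16)
  expect_lt(out2$gc_test$t, 0)
  # single-sequence groups: summary emitted, test undefined
  out3 <- summarizeFeatures("ACGT", c("GGCC", "AACC"))
  expect_true(is.na(out3$gc_test$p))
  expect_equal(out3$lncRNA$mean_length, 4)
})
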