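test_that("NB sampler matches its first two moments, incl. the Poisson limit", {
  set.seed(101)
  for (mu in c(10, 100)) {
    for (phi in c(0, 0.1, 0.5)) {
      x <- simulateCounts(mu, phi, 10000)
      expect_lt(abs(mean(x) - mu) / mu, 0.05)
      expect_lt(abs(var(x) - (mu + phi * mu^2)) / (mu + phi * mu^2), 0.10)
    }
  }
  expect_identical(simulateCounts(0, 0.1, 5), rep(0L, 5))
  expect_error(simulateCounts(-1, 0.1, 5), "mean")
  expect_error(simulateCounts(10, -0.1, 5), "dispersion")
})

test_that("prototype shapes are monotone/unimodal/flat as labelled", {
  p <- prototypeProfiles(4, effect = 4)
  expect_named(p, c("up", "down", "peak2", "peak3", "flat"))
  expect_true(all(diff(p$up) >= 0))
  expect_equal(p$up[1], 1)
  expect_equal(p$up[4], 4)
  expect_true(all(diff(p$down) <= 0))
  expect_equal(which.max(p$peak2), 2)
  expect_equal(which.max(p$peak3), 3)
  expect_equal(p$flat, rep(1, 4))
  expect_true(all(unlist(p) > 0))
  expect_error(prototypeProfiles(1), "n_stages")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- cernaSimConfig(n_mrna = 8, n_lncrna = 4, n_mirna = 2,
                        n_triplets = 1, n_cis_pairs = 1, seed = 3)
  s1 <- simulateCernaDataset(cfg)
  s2 <- simulateCernaDataset(cfg)
  expect_identical(simTruth(s1), simTruth(s2))
  expect_identical(as.character(simSequences(s1)),
                   as.character(simSequences(s2)))
  expect_identical(SummarizedExperiment::assay(simCounts(s1)),
                   SummarizedExperiment::assay(simCounts(s2)))
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- writeSimulation(s1, d1); f2 <- writeSimulation(s2, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("truth tables are consistent with the emitted dataset", {
  sim <- small_sim()
  tr <- simTruth(sim)
  rna_ids <- rownames(simCounts(sim))
  mir_ids <- rownames(simMirna(sim))
  seqs <- as.character(simSequences(sim))
  mature <- as.character(simMature(sim))

  expect_true(all(tr$planted_triplets$lncrna_id %in% rna_ids))
  expect_true(all(tr$planted_triplets$mrna_id %in% rna_ids))
  expect_true(all(tr$planted_triplets$mirna_id %in% mir_ids))
  expect_setequal(names(tr$prototype_of), c(rna_ids, mir_ids))

  # every planted site is re-findable by exact string search, in both sponges
  for (i in seq_len(nrow(tr$planted_triplets))) {
    t <- tr$planted_triplets[i, ]
    site <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(mature[[t$mirna_id]])))
    expect_true(grepl(site, seqs[[t$lncrna_id]], fixed = TRUE))
    expect_true(grepl(site, seqs[[t$mrna_id]], fixed = TRUE))
  }

  # recorded cis distances are exact on the emitted coordinates
  ann <- simAnnotation(sim)
  for (i in seq_len(nrow(tr$cis_pairs))) {
    cp <- tr$cis_pairs[i, ]
    gap <- GenomicRanges::start(ann[cp$gene_id]) -
      GenomicRanges::end(ann[cp$lncrna_id]) - 1L
    expect_identical(unname(gap), cp$distance)
    expect_identical(cp$distance <= 10000, cp$within_window)
  }

  # lncRNA records pass the cascade by construction; mRNAs carry long ORFs
  mc <- S4Vectors::mcols(ann)
  lnc <- names(ann)[mc$biotype == "lncRNA"]
  expect_true(all(mc$class_code[mc$biotype == "lncRNA"] %in%
                    c("u", "i", "x", "o")))
  expect_true(all(mc$tx_length[mc$biotype == "lncRNA"] > 200))
  expect_true(all(vapply(seqs[lnc], function(s)
    codingPotential(s)$label == "non-coding", logical(1))))
  mrna <- names(ann)[mc$biotype == "mRNA"]
  expect_true(all(vapply(seqs[mrna], function(s)
    codingPotential(s)$longest_orf_aa >= 100, logical(1))))
})

test_that("planted triplets satisfy the correlation filter on emitted samples", {
  sim <- small_sim()
  tr <- simTruth(sim)$planted_triplets
  rna <- SummarizedExperiment::assay(simCounts(sim))
  mir <- SummarizedExperiment::assay(simMirna(sim))
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    expect_lt(spearman_oracle(mir[t$mirna_id, ], rna[t$lncrna_id, ]), -0.6)
    expect_lt(spearman_oracle(mir[t$mirna_id, ], rna[t$mrna_id, ]), -0.6)
    expect_gt(pearson_oracle(log2(rna[t$lncrna_id, ] + 1),
                             log2(rna[t$mrna_id, ] + 1)), 0.6)
  }
})

test_that("degenerate configs behave: no triplets, infeasible placement", {
  s0 <- simulateCernaDataset(cernaSimConfig(
    n_mrna = 6, n_lncrna = 3, n_mirna = 1, n_triplets = 0, n_cis_pairs = 1,
    seed = 2))
  expect_identical(nrow(simTruth(s0)$planted_triplets), 0L)
  expect_error(simulateCernaDataset(cernaSimConfig(
    n_mrna = 30, n_lncrna = 10, n_mirna = 2, n_triplets = 1, n_cis_pairs = 2,
    chrom_lengths = c(chr1 = 20000), seed = 2)), "too short")
  expect_error(cernaSimConfig(n_triplets = 5, n_mirna = 2), "miRNA")
  expect_error(cernaSimConfig(dispersion = -1), "dispersion")
})
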