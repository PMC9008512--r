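test_that("correlation agrees with rank-transform and covariance oracles", {
  expect_equal(correlatePair(1:4, c(10, 20, 30, 40), "spearman"), 1.0)
  expect_equal(correlatePair(1:4, c(10, 20, 30, 40), "pearson"), 1.0)
  expect_equal(correlatePair(1:4, c(8, 6, 4, 2), "spearman"), -1.0)
  # ties handled by average ranks
  expect_equal(correlatePair(c(1, 2, 2, 4), c(3, 1, 5, 7), "spearman"),
               spearman_oracle(c(1, 2, 2, 4), c(3, 1, 5, 7)),
               tolerance = 1e-15)
  set.seed(14)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (i %% 3 == 0) x <- round(x)      # induce ties regularly
    expect_equal(correlatePair(x, y, "spearman"), spearman_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(correlatePair(x, y, "pearson"), pearson_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_true(is.na(correlatePair(rep(1, 5), rnorm(5), "pearson")))
  expect_error(correlatePair(1:4, 1:5), "equal length")
  expect_error(correlatePair(1:2, 1:2), ">= 3")
})

test_that("triplet assembly counts products over the shared miRNA", {
  hits <- function(mi, tx) data.frame(mirna_id = mi, transcript_id = tx)
  tri <- assembleTriplets(hits("M", c("L1", "L2", "L2")),
                          hits("M", c("G1", "G2", "G3")))
  expect_identical(nrow(tri), 6L)     # 2 lncRNA x 3 mRNA, dedup first
  expect_setequal(paste(tri$lncrna_id, tri$mrna_id),
                  as.vector(outer(c("L1", "L2"), c("G1", "G2", "G3"), paste)))
  expect_identical(nrow(assembleTriplets(hits("M", "L1"),
                                         hits("M2", "G1"))), 0L)
  expect_identical(nrow(assembleTriplets(hits(character(0), character(0)),
                                         hits(character(0), character(0)))),
                   0L)
})

test_that("pass rule is strict at every threshold and fails on NA", {
  expect_true(tripletPasses(-0.7, -0.65, 0.8))
  expect_false(tripletPasses(-0.5, -0.65, 0.8))
  expect_false(tripletPasses(-0.6, -0.65, 0.8))    # exactly at rho threshold
  expect_false(tripletPasses(-0.7, -0.6, 0.8))
  expect_false(tripletPasses(-0.7, -0.65, 0.6))    # exactly at r threshold
  expect_false(tripletPasses(NA, -0.65, 0.8))
  expect_false(tripletPasses(-0.7, -0.65, NA))
  # relaxing thresholds never removes a passed triplet
  set.seed(15)
  s1 <- runif(200, -1, 1); s2 <- runif(200, -1, 1); p3 <- runif(200, -1, 1)
  tight <- tripletPasses(s1, s2, p3, c(-0.6, -0.6, 0.6))
  loose <- tripletPasses(s1, s2, p3, c(-0.5, -0.5, 0.5))
  expect_true(all(loose[tight]))
})

test_that("filtering planted data passes the truth and fails constants", {
  sim <- small_sim()
  tri_true <- simTruth(sim)$planted_triplets
  cand <- rbind(tri_true,
                data.frame(lncrna_id = tri_true$lncrna_id[1],
                           mirna_id = tri_true$mirna_id[2],
                           mrna_id = tri_true$mrna_id[1]))
  net <- filterTriplets(cand, simMirna(sim), simCounts(sim))
  tab <- netTriplets(net)
  expect_true(all(tab$passed[seq_len(nrow(tri_true))]))
  # members absent from the matrices are skipped with a warning, not fatal
  cand_bad <- rbind(tri_true,
                    data.frame(lncrna_id = "nope", mirna_id = "nada",
                               mrna_id = "zip"))
  expect_warning(net2 <- filterTriplets(cand_bad, simMirna(sim),
                                        simCounts(sim)), "skipped")
  expect_identical(nrow(netTriplets(net2)), nrow(tri_true))
})

test_that("network accounting matches brute-force set construction", {
  # 2 passed triplets sharing one miRNA: 5 nodes, 4 edges
  tab <- data.frame(lncrna_id = c("L1", "L2"), mirna_id = "M",
                    mrna_id = c("G1", "G2"),
                    scc_mir_lnc = -0.9, scc_mir_mrna = -0.9,
                    pcc_lnc_mrna = 0.9, passed = TRUE)
  net <- ceRNAflow:::build_network(tab)
  s <- summarizeNetwork(net)
  expect_identical(s$n_nodes, 5L)
  expect_identical(s$n_edges, 4L)
  expect_identical(s$n_lncrna, 2L)
  expect_identical(s$n_mirna, 1L)
  # single triplet: 3 nodes, 2 edges; empty network: zeros
  s1 <- summarizeNetwork(ceRNAflow:::build_network(tab[1, ]))
  expect_identical(c(s1$n_nodes, s1$n_edges, s1$n_triplets), c(3L, 2L, 1L))
  s0 <- summarizeNetwork(ceRNAflow:::build_network(tab[0, ]))
  expect_identical(c(s0$n_nodes, s0$n_edges, s0$n_triplets), c(0L, 0L, 0L))
  # random triplet lists vs the oracle
  set.seed(16)
  for (i in 1:100) {
    n <- sample(1:30, 1)
    rtab <- data.frame(
      lncrna_id = sample(paste0("L", 1:8), n, TRUE),
      mirna_id = sample(paste0("M", 1:4), n, TRUE),
      mrna_id = sample(paste0("G", 1:8), n, TRUE),
      scc_mir_lnc = -0.9, scc_mir_mrna = -0.9, pcc_lnc_mrna = 0.9,
      passed = TRUE)
    got <- summarizeNetwork(ceRNAflow:::build_network(rtab))
    ora <- network_counts_oracle(rtab)
    expect_identical(got$n_nodes, ora$n_nodes)
    expect_identical(got$n_edges, ora$n_edges)
  }
})

test_that("gene-set subnetworks keep exactly the matching passed triplets", {
  sim <- small_sim()
  tri_true <- simTruth(sim)$planted_triplets
  net <- filterTriplets(tri_true, simMirna(sim), simCounts(sim))
  all_genes <- tri_true$mrna_id
  expect_identical(summarizeNetwork(subnetworkByGenes(net, all_genes)),
                   summarizeNetwork(net))
  sub <- subnetworkByGenes(net, all_genes[1:2])
  expect_identical(summarizeNetwork(sub)$n_triplets, 2L)
  expect_setequal(netTriplets(sub)$mrna_id[netTriplets(sub)$passed],
                  all_genes[1:2])
  none <- subnetworkByGenes(net, "absent_gene")
  expect_identical(summarizeNetwork(none)$n_nodes, 0L)
  expect_error(subnetworkByGenes(net, character(0)), "non-empty")
})

test_that("network export writes SIF and edge list consistently", {
  tab <- data.frame(lncrna_id = c("L1", "L2"), mirna_id = "M",
                    mrna_id = c("G1", "G2"),
                    scc_mir_lnc = -0.9, scc_mir_mrna = -0.9,
                    pcc_lnc_mrna = 0.9, passed = TRUE)
  net <- ceRNAflow:::build_network(tab)
  pre <- tempfile()
  files <- writeNetwork(net, pre)
  expect_true(all(file.exists(files)))
  sif <- read.table(files[["sif"]], sep = "\t")
  expect_identical(nrow(sif), 4L)
  expect_setequal(sif$V2, c("mir-lnc", "mir-mrna"))
})
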