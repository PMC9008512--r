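#' Pipeline configuration
#'
#' Collects every stage threshold of the ceRNA discovery pipeline, each
#' defaulting to the value used throughout the source analysis: lncRNA
#' length > 200 nt and class codes u/i/x/o, |log2FC| > 1 with BH-adjusted
#' p < 0.05, a 10 kb cis window, target-site expectation cutoff 5, and
#' correlation thresholds (-0.6, -0.6, 0.6). Input is either a
#' [cernaSimConfig()] (synthetic run with truth metrics) or an `input_dir`
#' holding files as written by [writeSimulation()].
#'
#' @param sim a [cernaSimConfig()], or `NULL` when `input_dir` is given.
#' @param input_dir directory of input files (annotation.gff3,
#'   transcripts.fa, mature_mirna.fa, counts_rna.tsv, abundance_mirna.tsv,
#'   samples.tsv, term2genes.tsv).
#' @param out_dir output directory.
#' @param lfc,alpha DE thresholds.
#' @param min_lnc_length,min_orf_aa,min_coverage lncRNA cascade thresholds.
#' @param window cis window in bp.
#' @param cutoff target-site expectation cutoff.
#' @param trans_window,trans_threshold,trans_max_pairs trans-screen
#'   parameters ([transPairsSet()]).
#' @param cor_thresholds ceRNA correlation thresholds
#'   `c(scc_mir_lnc, scc_mir_mrna, pcc_lnc_mrna)`.
#' @param k,m fuzzy-clustering cluster count and fuzzifier (`m = NULL`
#'   uses [estimateFuzzifier()]).
#' @param seed seed for clustering initialization (simulation keeps its
#'   own seed).
#' @return classed parameter list for [runCernaPipeline()].
#' @export
cernaPipelineConfig <- function(sim = cernaSimConfig(), input_dir = NULL,
                                out_dir = tempfile("cerna_run_"),
                                lfc = 1, alpha = 0.05,
                                min_lnc_length = 200, min_orf_aa = 100,
                                min_coverage = 0.5, window = 10000,
                                cutoff = 5.0, trans_window = 40,
                                trans_threshold = -0.1, trans_max_pairs = 200,
                                cor_thresholds = c(-0.6, -0.6, 0.6),
                                k = 4, m = 1.25, seed = 1) {
  if (is.null(sim) && is.null(input_dir))
    stopf("either sim or input_dir must be given")
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (lfc < 0) stopf("lfc must be >= 0")
  if (window < 0) stopf("window must be >= 0")
  if (cutoff < 0) stopf("cutoff must be >= 0")
  if (length(cor_thresholds) != 3) stopf("cor_thresholds must have length 3")
  if (!is.null(input_dir)) {
    need <- file.path(input_dir,
                      c("annotation.gff3", "transcripts.fa", "mature_mirna.fa",
                        "counts_rna.tsv", "abundance_mirna.tsv", "samples.tsv",
                        "term2genes.tsv"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stopf("missing input file(s): %s", paste(miss, collapse = ", "))
  }
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 lfc = lfc, alpha = alpha, min_lnc_length = min_lnc_length,
                 min_orf_aa = min_orf_aa, min_coverage = min_coverage,
                 window = window, cutoff = cutoff,
                 trans_window = trans_window,
                 trans_threshold = trans_threshold,
                 trans_max_pairs = trans_max_pairs,
                 cor_thresholds = cor_thresholds, k = k, m = m, seed = seed),
            class = c("cernaPipelineConfig", "list"))
}

read_simulation_files <- function(dir) {
  ann <- rtracklayer::import(file.path(dir, "annotation.gff3"))
  names(ann) <- S4Vectors::mcols(ann)$ID
  S4Vectors::mcols(ann)$tx_length <- as.integer(S4Vectors::mcols(ann)$tx_length)
  S4Vectors::mcols(ann)$exon_count <- as.integer(S4Vectors::mcols(ann)$exon_count)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  mature <- Biostrings::readDNAStringSet(file.path(dir, "mature_mirna.fa"))
  read_mat <- function(f) {
    df <- read.table(file.path(dir, f), header = TRUE, sep = "\t",
                     check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  samp <- read.table(file.path(dir, "samples.tsv"), header = TRUE, sep = "\t")
  cdat <- S4Vectors::DataFrame(stage = samp$stage, replicate = samp$replicate,
                               row.names = samp$sample_id)
  counts <- read_mat("counts_rna.tsv")[, samp$sample_id, drop = FALSE]
  mir <- read_mat("abundance_mirna.tsv")[, samp$sample_id, drop = FALSE]
  list(annotation = ann, transcripts = seqs, mature = mature,
       rna = SummarizedExperiment::SummarizedExperiment(
         assays = list(counts = counts), colData = cdat,
         metadata = list(unit = "counts")),
       mirna = SummarizedExperiment::SummarizedExperiment(
         assays = list(abundance = mir), colData = cdat,
         metadata = list(unit = "RPM")),
       term_map = read.table(file.path(dir, "term2genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE),
       truth = NULL)
}

#' Run the full ceRNA discovery pipeline
#'
#' Stages, in dependency order: data generation (or loading), lncRNA
#' classification, FPKM/RPM normalisation, adjacent-stage NB-Wald DE
#' calling, fuzzy c-means clustering of the DE features' stage means,
#' miRNA target scanning plus cis/trans lncRNA target assignment,
#' correlation-filtered triplet integration, and term enrichment of the
#' network mRNAs. All stage outputs are written under `config$out_dir`
#' and hashed into a manifest; identical configs (and seeds) give
#' byte-identical manifests. When the run is synthetic, truth-recovery
#' metrics (triplet precision/recall, per-comparison DE sensitivity/FDR,
#' cluster ARI) are included in the report.
#'
#' @param config a [cernaPipelineConfig()].
#' @return report list: `counts` (per-stage tallies), `network` (the
#'   [CeRNANetwork-class]), `de_table`, `clustering`, `enrichment`,
#'   `manifest` (file, md5), `truth_metrics` (or `NULL`), `log`.
#' @export
runCernaPipeline <- function(config) {
  if (!inherits(config, "cernaPipelineConfig"))
    stopf("config must come from cernaPipelineConfig()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- data.frame(stage = character(0), seconds = numeric(0))
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    log <<- rbind(log, data.frame(stage = stage,
                                  seconds = proc.time()[["elapsed"]] - t0))
    val
  }

  # -- stage 1: data
  dat <- tick("data", {
    if (!is.null(config$input_dir)) read_simulation_files(config$input_dir)
    else {
      sim <- simulateCernaDataset(config$sim)
      writeSimulation(sim, file.path(config$out_dir, "data"))
      list(annotation = simAnnotation(sim), transcripts = simSequences(sim),
           mature = simMature(sim), rna = simCounts(sim),
           mirna = simMirna(sim), term_map = simTermMap(sim),
           truth = simTruth(sim))
    }
  })
  ann <- dat$annotation
  tx_len <- setNames(S4Vectors::mcols(ann)$tx_length, names(ann))

  # -- stage 2: lncRNA classification
  ann <- tick("txclass", classifyTranscripts(
    ann, dat$transcripts, min_orf_aa = config$min_orf_aa,
    min_coverage = config$min_coverage, min_length = config$min_lnc_length))
  lnc_ids <- names(ann)[S4Vectors::mcols(ann)$biotype == "lncRNA"]
  gene_ids <- setdiff(names(ann), lnc_ids)

  # -- stage 3: normalisation + DE
  fpkm_se <- tick("fpkm", fpkm(dat$rna, tx_len))
  de_tab <- tick("de", deAdjacentStages(dat$rna, lfc_threshold = config$lfc,
                                        alpha = config$alpha))
  mir_counts <- round(extract_counts(dat$mirna))
  de_mir <- tick("de_mirna", deAdjacentStages(
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = mir_counts),
      colData = SummarizedExperiment::colData(dat$mirna)),
    lfc_threshold = config$lfc, alpha = config$alpha))
  de_rna_ids <- unique(de_tab$feature_id[de_tab$significant])
  de_mir_ids <- unique(de_mir$feature_id[de_mir$significant])
  de_lnc <- intersect(de_rna_ids, lnc_ids)
  de_gene <- intersect(de_rna_ids, gene_ids)

  # -- stage 4: temporal clustering of DE features
  clust <- tick("tclust", {
    sm <- stageMeans(fpkm_se)[de_rna_ids, , drop = FALSE]
    Z <- standardizeRows(sm)
    if (nrow(Z) >= config$k)
      fuzzyCMeans(Z, k = config$k, m = config$m, seed = config$seed)
    else NULL
  })

  # -- stage 5: targets
  mir_de_seqs <- as.character(dat$mature)[de_mir_ids]
  tx_seqs <- as.character(dat$transcripts)
  mir2lnc <- tick("targets_lnc",
                  scanTargetsSet(mir_de_seqs, tx_seqs[de_lnc], config$cutoff))
  mir2mrna <- tick("targets_mrna",
                   scanTargetsSet(mir_de_seqs, tx_seqs[de_gene], config$cutoff))
  cis <- tick("cis", cisPairs(ann[intersect(de_lnc, names(ann))],
                              ann[intersect(de_gene, names(ann))],
                              window = config$window))
  trans <- tick("trans", transPairsSet(
    tx_seqs[de_lnc], tx_seqs[de_gene], window = config$trans_window,
    threshold = config$trans_threshold, max_pairs = config$trans_max_pairs))

  # -- stage 6: ceRNA network
  net <- tick("cernanet", {
    cand <- assembleTriplets(mir2lnc, mir2mrna)
    filterTriplets(cand, dat$mirna, fpkm_se,
                   thresholds = config$cor_thresholds)
  })

  # -- stage 7: enrichment of network mRNAs (falls back to DE genes)
  enr <- tick("enrich", {
    study <- netNodes(net)$id[netNodes(net)$type == "mRNA"]
    if (length(study) == 0) study <- de_gene
    if (length(study) == 0) NULL
    else enrichTerms(study, gene_ids, dat$term_map, alpha = config$alpha)
  })

  # -- outputs + manifest
  outp <- function(f) file.path(config$out_dir, f)
  write.table(de_tab, outp("de_rna.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(de_mir, outp("de_mirna.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(clust)) {
    write.table(data.frame(feature_id = rownames(membership(clust)),
                           round(membership(clust), 6)),
                outp("cluster_membership.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(cluster = rownames(clusterCenters(clust)),
                           round(clusterCenters(clust), 6)),
                outp("cluster_centers.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(mir2lnc[, 1:4], outp("mir2lnc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(mir2mrna[, 1:4], outp("mir2mrna.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cis, outp("cis_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(trans, outp("trans_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeNetwork(net, outp("network"))
  if (!is.null(enr))
    write.table(enr, outp("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

  files <- sort(list.files(config$out_dir, recursive = TRUE,
                           full.names = TRUE))
  manifest <- data.frame(
    file = sub(paste0("^", config$out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)), row.names = NULL)

  truth_metrics <- NULL
  if (!is.null(dat$truth))
    truth_metrics <- truth_recovery(dat$truth, net, de_tab, clust)

  ns <- summarizeNetwork(net)
  list(counts = list(
         n_transcripts = length(ann), n_lncrna = length(lnc_ids),
         n_de_rna = length(de_rna_ids), n_de_lncrna = length(de_lnc),
         n_de_gene = length(de_gene), n_de_mirna = length(de_mir_ids),
         n_mir2lnc = nrow(unique(mir2lnc[, 1:2])),
         n_mir2mrna = nrow(unique(mir2mrna[, 1:2])),
         n_cis_pairs = nrow(cis), n_trans_pairs = nrow(trans),
         n_candidate_triplets = nrow(netTriplets(net)),
         n_passed_triplets = ns$n_triplets,
         n_nodes = ns$n_nodes, n_edges = ns$n_edges),
       network = net, de_table = de_tab, de_mirna = de_mir,
       clustering = clust, enrichment = enr, cis = cis, trans = trans,
       manifest = manifest, truth_metrics = truth_metrics, log = log)
}

# Truth-recovery metrics for synthetic runs.
truth_recovery <- function(truth, net, de_tab, clust) {
  tri_true <- truth$planted_triplets
  tri_called <- netTriplets(net)
  tri_called <- tri_called[tri_called$passed %in% TRUE, , drop = FALSE]
  key <- function(d) paste(d$lncrna_id, d$mirna_id, d$mrna_id)
  tp <- sum(key(tri_called) %in% key(tri_true))
  precision <- if (nrow(tri_called)) tp / nrow(tri_called) else NA_real_
  recall <- if (nrow(tri_true)) tp / nrow(tri_true) else NA_real_

  dm <- merge(de_tab, truth$de_status, by = c("feature_id", "comparison"))
  sens <- if (any(dm$true_de)) mean(dm$significant[dm$true_de]) else NA_real_
  fdr <- if (any(dm$significant))
    mean(!dm$true_de[dm$significant]) else 0

  ari <- NA_real_
  if (!is.null(clust)) {
    hard <- assignClusters(clust, min_membership = 0)
    lab <- truth$prototype_of[names(hard)]
    keep <- !is.na(hard) & !is.na(lab)
    if (sum(keep) > 1)
      ari <- mclust::adjustedRandIndex(hard[keep], lab[keep])
  }
  list(triplet_tp = tp, triplet_called = nrow(tri_called),
       triplet_false = nrow(tri_called) - tp,
       triplet_precision = precision, triplet_recall = recall,
       de_sensitivity = sens, de_fdr = fdr, cluster_ari = ari)
}

#' One-call synthetic demonstration run
#'
#' Generates the default synthetic dataset with the given seed and runs the
#' whole pipeline on it.
#'
#' @param seed simulation and clustering seed.
#' @param out_dir output directory.
#' @param ... overrides passed to [cernaPipelineConfig()].
#' @return the [runCernaPipeline()] report.
#' @export
demoPipeline <- function(seed = 7, out_dir = tempfile("cerna_demo_"), ...) {
  cfg <- cernaPipelineConfig(sim = cernaSimConfig(seed = seed),
                             out_dir = out_dir, seed = seed, ...)
  runCernaPipeline(cfg)
}
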