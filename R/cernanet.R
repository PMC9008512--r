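#' Correlation between two expression profiles
#'
#' Spearman (average ranks on ties) or Pearson correlation over paired
#' samples. Returns `NA` when either vector is constant (undefined
#' correlation — downstream filters treat it as a fail, never a pass).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return correlation in `[-1, 1]`, or `NA` for a constant input.
#' @export
correlatePair <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need >= 3 paired samples")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = method)
}

#' Integrate candidate ceRNA triplets from shared-miRNA target hits
#'
#' One candidate triplet per (lncRNA, miRNA, mRNA) combination in which the
#' miRNA targets both the lncRNA and the mRNA; hits are deduplicated to the
#' (miRNA, target) level first, so the number of candidates is, per miRNA,
#' the product of its lncRNA and mRNA target counts.
#'
#' @param mir2lnc,mir2mrna hit tables with columns `mirna_id` and
#'   `transcript_id` (as from [scanTargetsSet()]).
#' @return `data.frame` with columns `lncrna_id`, `mirna_id`, `mrna_id`.
#' @export
assembleTriplets <- function(mir2lnc, mir2mrna) {
  dd <- function(h) unique(h[, c("mirna_id", "transcript_id")])
  a <- dd(mir2lnc); b <- dd(mir2mrna)
  common <- intersect(a$mirna_id, b$mirna_id)
  out <- lapply(common, function(mi) {
    expand.grid(lncrna_id = a$transcript_id[a$mirna_id == mi],
                mirna_id = mi,
                mrna_id = b$transcript_id[b$mirna_id == mi],
                stringsAsFactors = FALSE)[, c("lncrna_id", "mirna_id",
                                              "mrna_id")]
  })
  if (length(out) == 0)
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation-filter candidate triplets into a ceRNA network
#'
#' Per candidate triplet, over the shared sample set: Spearman rho of the
#' miRNA against each sponge and Pearson r between the sponges. A triplet
#' passes when `scc_mir_lnc < thresholds[1]`, `scc_mir_mrna <
#' thresholds[2]` and `pcc_lnc_mrna > thresholds[3]` — all strict, so a
#' correlation exactly at a threshold fails, and an undefined correlation
#' (constant profile) fails. The network is built from passed triplets
#' only.
#'
#' @param triplets candidate table from [assembleTriplets()].
#' @param expr_mirna miRNA abundance (`SummarizedExperiment` or matrix,
#'   RPM scale).
#' @param expr_rna mRNA/lncRNA expression (`SummarizedExperiment` or
#'   matrix, FPKM scale).
#' @param thresholds `c(scc_mir_lnc, scc_mir_mrna, pcc_lnc_mrna)`.
#' @param log_pcc log2(x + 1)-transform the two RNA profiles before the
#'   Pearson correlation (rank-based Spearman is unaffected by monotone
#'   transforms).
#' @param samples optional subset of sample ids to correlate over
#'   (default: all samples shared by the two matrices).
#' @return a [CeRNANetwork-class]; its `triplets` slot keeps all candidates
#'   with their statistics and pass flag.
#' @export
filterTriplets <- function(triplets, expr_mirna, expr_rna,
                           thresholds = c(-0.6, -0.6, 0.6),
                           log_pcc = TRUE, samples = NULL) {
  mm <- extract_counts(expr_mirna)
  mr <- extract_counts(expr_rna)
  shared <- intersect(colnames(mm), colnames(mr))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3) stopf("fewer than 3 shared samples")
  mm <- mm[, shared, drop = FALSE]; mr <- mr[, shared, drop = FALSE]

  ok <- triplets$mirna_id %in% rownames(mm) &
    triplets$lncrna_id %in% rownames(mr) &
    triplets$mrna_id %in% rownames(mr)
  if (any(!ok)) {
    bad <- triplets[!ok, ]
    warning(sprintf("%d triplet(s) skipped: members missing from matrices (e.g. %s/%s/%s)",
                    nrow(bad), bad$lncrna_id[1], bad$mirna_id[1],
                    bad$mrna_id[1]))
    triplets <- triplets[ok, , drop = FALSE]
  }
  n <- nrow(triplets)
  scc1 <- scc2 <- pcc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mi <- mm[triplets$mirna_id[i], ]
    ln <- mr[triplets$lncrna_id[i], ]
    mg <- mr[triplets$mrna_id[i], ]
    scc1[i] <- correlatePair(mi, ln, "spearman")
    scc2[i] <- correlatePair(mi, mg, "spearman")
    if (log_pcc) {
      ln <- log2(ln + 1); mg <- log2(mg + 1)
    }
    pcc[i] <- correlatePair(ln, mg, "pearson")
  }
  passed <- tripletPasses(scc1, scc2, pcc, thresholds)
  tab <- cbind(triplets,
               data.frame(scc_mir_lnc = scc1, scc_mir_mrna = scc2,
                          pcc_lnc_mrna = pcc, passed = passed))
  rownames(tab) <- NULL
  build_network(tab)
}

#' ceRNA pass rule
#'
#' The correlation filter applied to each candidate triplet: all three
#' inequalities are strict (`scc_mir_lnc < thresholds[1]`, `scc_mir_mrna <
#' thresholds[2]`, `pcc_lnc_mrna > thresholds[3]`), so a correlation
#' exactly at a threshold fails, and an undefined (`NA`) correlation fails.
#'
#' @param scc_mir_lnc,scc_mir_mrna,pcc_lnc_mrna correlation statistics
#'   (vectorized).
#' @param thresholds length-3 numeric as in [filterTriplets()].
#' @return logical vector.
#' @export
tripletPasses <- function(scc_mir_lnc, scc_mir_mrna, pcc_lnc_mrna,
                          thresholds = c(-0.6, -0.6, 0.6)) {
  !is.na(scc_mir_lnc) & !is.na(scc_mir_mrna) & !is.na(pcc_lnc_mrna) &
    scc_mir_lnc < thresholds[1] & scc_mir_mrna < thresholds[2] &
    pcc_lnc_mrna > thresholds[3]
}

build_network <- function(triplet_table) {
  ok <- triplet_table[triplet_table$passed %in% TRUE, , drop = FALSE]
  node_df <- function(ids, type)
    data.frame(id = unique(ids), type = rep(type, length(unique(ids))),
               stringsAsFactors = FALSE)
  nodes <- rbind(node_df(ok$lncrna_id, "lncRNA"),
                 node_df(ok$mirna_id, "miRNA"),
                 node_df(ok$mrna_id, "mRNA"))
  edge_df <- function(targets, type)
    data.frame(mirna_id = ok$mirna_id, target_id = targets,
               target_type = rep(type, length(targets)),
               stringsAsFactors = FALSE)
  edges <- unique(rbind(edge_df(ok$lncrna_id, "lncRNA"),
                        edge_df(ok$mrna_id, "mRNA")))
  rownames(nodes) <- rownames(edges) <- NULL
  methods::new("CeRNANetwork", nodes = nodes, edges = edges,
               triplets = triplet_table)
}

#' Node, edge and triplet counts of a ceRNA network
#'
#' Nodes are counted uniquely by type; edges are unique (miRNA, target)
#' pairs pooled over both target types. lncRNA-mRNA co-expression links are
#' not edges.
#'
#' @param net a [CeRNANetwork-class].
#' @return list with `n_triplets`, `n_nodes`, `n_lncrna`, `n_mirna`,
#'   `n_mrna`, `n_edges`.
#' @export
summarizeNetwork <- function(net) {
  nodes <- netNodes(net)
  list(n_triplets = sum(netTriplets(net)$passed %in% TRUE),
       n_nodes = nrow(nodes),
       n_lncrna = sum(nodes$type == "lncRNA"),
       n_mirna = sum(nodes$type == "miRNA"),
       n_mrna = sum(nodes$type == "mRNA"),
       n_edges = nrow(netEdges(net)))
}

#' Sub-network restricted to a gene set
#'
#' Keeps exactly the passed triplets whose mRNA belongs to `gene_set`
#' (e.g. the genes of one enriched functional term), then rebuilds nodes
#' and edges from scratch.
#'
#' @param net a [CeRNANetwork-class].
#' @param gene_set non-empty character vector of mRNA ids.
#' @return a [CeRNANetwork-class].
#' @export
subnetworkByGenes <- function(net, gene_set) {
  if (length(gene_set) == 0) stopf("gene_set must be non-empty")
  tab <- netTriplets(net)
  keep <- tab$passed %in% TRUE & tab$mrna_id %in% gene_set
  build_network(tab[keep, , drop = FALSE])
}

#' Export a ceRNA network as edge-list TSV and SIF
#'
#' Writes `<prefix>_edges.tsv` (mirna_id, target_id, target_type),
#' `<prefix>_triplets.tsv` (all candidates with statistics) and
#' `<prefix>.sif` (`node1<TAB>interaction<TAB>node2`, interaction `mir-lnc`
#' or `mir-mrna`).
#'
#' @param net a [CeRNANetwork-class].
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
writeNetwork <- function(net, prefix) {
  edges <- netEdges(net)
  f_edges <- paste0(prefix, "_edges.tsv")
  f_tri <- paste0(prefix, "_triplets.tsv")
  f_sif <- paste0(prefix, ".sif")
  write.table(edges, f_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(netTriplets(net), f_tri, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sif <- data.frame(node1 = edges$mirna_id,
                    interaction = ifelse(edges$target_type == "lncRNA",
                                         "mir-lnc", "mir-mrna"),
                    node2 = edges$target_id)
  write.table(sif, f_sif, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(edges = f_edges, triplets = f_tri, sif = f_sif))
}
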