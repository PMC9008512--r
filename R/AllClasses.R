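#' @import methods
#' @importFrom stats cor var sd rnorm runif rpois rgamma pnorm p.adjust
#'   phyper t.test quantile setNames median complete.cases
#' @importFrom utils head write.table read.table
NULL

#' Synthetic ceRNA experiment with planted ground truth
#'
#' Container for one simulated staged-transcriptome experiment: a transcript
#' annotation ([GenomicRanges::GRanges] with `class_code`, `biotype` and
#' `exon_count` metadata columns), transcript and mature-miRNA sequences
#' ([Biostrings::DNAStringSet]), an mRNA+lncRNA count matrix and a miRNA
#' abundance matrix (both [SummarizedExperiment::SummarizedExperiment] with
#' `stage` and `replicate` in `colData` and the expression unit in
#' `metadata()$unit`), a term-to-gene annotation map, and the truth tables
#' describing what was planted (temporal prototypes, ceRNA triplets,
#' per-comparison differential-expression status, cis lncRNA-gene pairs).
#'
#' @slot annotation `GRanges` of transcripts, one range per transcript.
#' @slot transcripts `DNAStringSet` of mRNA and lncRNA sequences.
#' @slot matureMirna `DNAStringSet` of mature miRNA sequences.
#' @slot rnaCounts `SummarizedExperiment` of NB counts (unit `"counts"`).
#' @slot mirnaAbundance `SummarizedExperiment` of miRNA abundances
#'   (unit `"RPM"`).
#' @slot termMap `data.frame` with columns `term_id`, `gene_id`.
#' @slot truth `list` with elements `planted_triplets`, `prototype_of`,
#'   `de_status`, `cis_pairs`.
#' @slot config `list`, the [cernaSimConfig()] the object was built from.
#'
#' @seealso [simulateCernaDataset()], [writeSimulation()]
#' @export
setClass("CernaSimulation",
  slots = c(
    annotation     = "GRanges",
    transcripts    = "DNAStringSet",
    matureMirna    = "DNAStringSet",
    rnaCounts      = "SummarizedExperiment",
    mirnaAbundance = "SummarizedExperiment",
    termMap        = "data.frame",
    truth          = "list",
    config         = "list"
  )
)

setValidity("CernaSimulation", function(object) {
  msg <- character()
  ann_ids <- names(object@annotation)
  rna_ids <- rownames(object@rnaCounts)
  mir_ids <- rownames(object@mirnaAbundance)
  if (!all(rna_ids %in% ann_ids))
    msg <- c(msg, "count-matrix features missing from the annotation")
  if (!all(mir_ids %in% names(object@matureMirna)))
    msg <- c(msg, "miRNA abundance features missing from the mature catalog")
  tr <- object@truth$planted_triplets
  if (NROW(tr) > 0) {
    ok <- tr$lncrna_id %in% rna_ids & tr$mrna_id %in% rna_ids &
      tr$mirna_id %in% mir_ids
    if (!all(ok))
      msg <- c(msg, "planted triplet members missing from emitted matrices")
  }
  if (ncol(object@rnaCounts) != ncol(object@mirnaAbundance))
    msg <- c(msg, "RNA and miRNA matrices disagree on sample count")
  if (length(msg)) msg else TRUE
})

#' Fuzzy c-means clustering result
#'
#' Result of [fuzzyCMeans()]: a feature-by-cluster membership matrix whose
#' rows sum to one, the cluster centres (one value per stage), the fuzzifier
#' used, the final objective value and the per-iteration objective trace of
#' the best restart.
#'
#' @slot membership numeric matrix, features x clusters, rows sum to 1.
#' @slot centers numeric matrix, clusters x stages.
#' @slot m numeric(1), fuzzifier (> 1).
#' @slot objective numeric(1), final value of the fuzzy objective.
#' @slot trace numeric, objective after each iteration (non-increasing).
#'
#' @seealso [fuzzyCMeans()], [assignClusters()]
#' @export
setClass("FuzzyClustering",
  slots = c(
    membership = "matrix",
    centers    = "matrix",
    m          = "numeric",
    objective  = "numeric",
    trace      = "numeric"
  )
)

setValidity("FuzzyClustering", function(object) {
  msg <- character()
  u <- object@membership
  if (nrow(u) > 0 && max(abs(rowSums(u) - 1)) > 1e-9)
    msg <- c(msg, "membership rows must sum to 1 (tolerance 1e-9)")
  if (any(u < -1e-12) || any(u > 1 + 1e-12))
    msg <- c(msg, "memberships must lie in [0, 1]")
  if (ncol(u) != nrow(object@centers))
    msg <- c(msg, "number of clusters disagrees between membership and centers")
  if (object@m <= 1) msg <- c(msg, "fuzzifier m must exceed 1")
  if (length(msg)) msg else TRUE
})

#' ceRNA network of correlation-filtered triplets
#'
#' A lncRNA-miRNA-mRNA network assembled from triplets that passed the
#' correlation filter (Spearman rho < -0.6 for both miRNA-target pairs,
#' Pearson r > 0.6 for the lncRNA-mRNA pair, by default). Nodes are typed
#' (`lncRNA`, `miRNA`, `mRNA`); edges are unique (miRNA, target) pairs.
#' Co-expression lncRNA-mRNA links are deliberately not edges.
#'
#' @slot nodes `data.frame` with columns `id`, `type`.
#' @slot edges `data.frame` with columns `mirna_id`, `target_id`,
#'   `target_type`.
#' @slot triplets `data.frame`, the passed triplets with their three
#'   correlation statistics.
#'
#' @seealso [filterTriplets()], [summarizeNetwork()], [writeNetwork()]
#' @export
setClass("CeRNANetwork",
  slots = c(
    nodes    = "data.frame",
    edges    = "data.frame",
    triplets = "data.frame"
  )
)

setValidity("CeRNANetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes$id))
    msg <- c(msg, "duplicated node ids")
  ekey <- paste(object@edges$mirna_id, object@edges$target_id)
  if (anyDuplicated(ekey))
    msg <- c(msg, "duplicated edges")
  tr <- object@triplets
  tr <- tr[tr$passed %in% TRUE, , drop = FALSE]
  if (NROW(tr) > 0) {
    need <- unique(c(paste(tr$mirna_id, tr$lncrna_id),
                     paste(tr$mirna_id, tr$mrna_id)))
    if (!all(need %in% ekey))
      msg <- c(msg, "triplet (miRNA, target) pairs missing from edge set")
  }
  if (length(msg)) msg else TRUE
})
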