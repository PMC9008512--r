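#' @rdname CernaSimulation-class
#' @param object,x a `CernaSimulation`, `FuzzyClustering` or `CeRNANetwork`.
#' @export
setGeneric("simAnnotation", function(x) standardGeneric("simAnnotation"))
#' @rdname CernaSimulation-class
#' @export
setGeneric("simSequences", function(x) standardGeneric("simSequences"))
#' @rdname CernaSimulation-class
#' @export
setGeneric("simMature", function(x) standardGeneric("simMature"))
#' @rdname CernaSimulation-class
#' @export
setGeneric("simCounts", function(x) standardGeneric("simCounts"))
#' @rdname CernaSimulation-class
#' @export
setGeneric("simMirna", function(x) standardGeneric("simMirna"))
#' @rdname CernaSimulation-class
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname CernaSimulation-class
#' @export
setGeneric("simTermMap", function(x) standardGeneric("simTermMap"))

#' @rdname FuzzyClustering-class
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname FuzzyClustering-class
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))
#' @rdname FuzzyClustering-class
#' @export
setGeneric("fuzzifier", function(x) standardGeneric("fuzzifier"))

#' @rdname CeRNANetwork-class
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))
#' @rdname CeRNANetwork-class
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))
#' @rdname CeRNANetwork-class
#' @export
setGeneric("netTriplets", function(x) standardGeneric("netTriplets"))

#' @rdname CernaSimulation-class
#' @export
setMethod("simAnnotation", "CernaSimulation", function(x) x@annotation)
#' @rdname CernaSimulation-class
#' @export
setMethod("simSequences", "CernaSimulation", function(x) x@transcripts)
#' @rdname CernaSimulation-class
#' @export
setMethod("simMature", "CernaSimulation", function(x) x@matureMirna)
#' @rdname CernaSimulation-class
#' @export
setMethod("simCounts", "CernaSimulation", function(x) x@rnaCounts)
#' @rdname CernaSimulation-class
#' @export
setMethod("simMirna", "CernaSimulation", function(x) x@mirnaAbundance)
#' @rdname CernaSimulation-class
#' @export
setMethod("simTruth", "CernaSimulation", function(x) x@truth)
#' @rdname CernaSimulation-class
#' @export
setMethod("simTermMap", "CernaSimulation", function(x) x@termMap)

#' @rdname FuzzyClustering-class
#' @export
setMethod("membership", "FuzzyClustering", function(x) x@membership)
#' @rdname FuzzyClustering-class
#' @export
setMethod("clusterCenters", "FuzzyClustering", function(x) x@centers)
#' @rdname FuzzyClustering-class
#' @export
setMethod("fuzzifier", "FuzzyClustering", function(x) x@m)

#' @rdname CeRNANetwork-class
#' @export
setMethod("netNodes", "CeRNANetwork", function(x) x@nodes)
#' @rdname CeRNANetwork-class
#' @export
setMethod("netEdges", "CeRNANetwork", function(x) x@edges)
#' @rdname CeRNANetwork-class
#' @export
setMethod("netTriplets", "CeRNANetwork", function(x) x@triplets)

#' @rdname CernaSimulation-class
#' @export
setMethod("show", "CernaSimulation", function(object) {
  ann <- object@annotation
  bt <- table(S4Vectors::mcols(ann)$biotype)
  cat("CernaSimulation\n")
  cat("  transcripts:", length(ann),
      sprintf("(%s)", paste(names(bt), as.integer(bt), sep = "=",
                            collapse = ", ")), "\n")
  cat("  miRNAs:     ", nrow(object@mirnaAbundance), "\n")
  cat("  samples:    ", ncol(object@rnaCounts), "\n")
  cat("  planted:    ", NROW(object@truth$planted_triplets), "triplets,",
      NROW(object@truth$cis_pairs), "cis pairs\n")
})

#' @rdname FuzzyClustering-class
#' @export
setMethod("show", "FuzzyClustering", function(object) {
  cat("FuzzyClustering:", nrow(object@membership), "features,",
      nrow(object@centers), "clusters, m =", signif(object@m, 4),
      ", objective =", signif(object@objective, 6), "\n")
})

#' @rdname CeRNANetwork-class
#' @export
setMethod("show", "CeRNANetwork", function(object) {
  s <- summarizeNetwork(object)
  cat("CeRNANetwork:", s$n_triplets, "triplets,", s$n_nodes, "nodes (",
      s$n_lncrna, "lncRNA /", s$n_mirna, "miRNA /", s$n_mrna, "mRNA ),",
      s$n_edges, "edges\n")
})
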