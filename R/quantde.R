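#' FPKM normalisation
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM = counts * 1e9 / (length * libsize)` with per-sample library size
#' taken as the column sum of the count matrix (or supplied).
#'
#' @param counts `SummarizedExperiment` with a `counts` assay, or a plain
#'   count matrix.
#' @param lengths named numeric vector of transcript lengths in nt covering
#'   every feature; when `counts` is a simulation-derived
#'   `SummarizedExperiment` whose annotation carried `tx_length`, pass that.
#' @param lib_sizes optional per-sample library sizes; defaults to column
#'   sums.
#' @return object of the same shape with an `FPKM` assay/matrix
#'   (unit metadata set to `"FPKM"`).
#' @export
fpkm <- function(counts, lengths, lib_sizes = NULL) {
  m <- extract_counts(counts)
  if (!all(rownames(m) %in% names(lengths)))
    stopf("lengths missing for some features")
  len <- lengths[rownames(m)]
  if (any(len <= 0)) stopf("all feature lengths must be positive")
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0))
    stopf("zero library size in sample(s): %s",
          paste(colnames(m)[lib_sizes <= 0], collapse = ", "))
  out <- sweep(m * 1e9 / len, 2, lib_sizes, "/")
  wrap_like(counts, out, assay_name = "FPKM", unit = "FPKM")
}

#' RPM normalisation
#'
#' Reads per million mapped reads: `RPM = counts * 1e6 / libsize`. With
#' library sizes taken as column sums every column of the result sums to
#' one million.
#'
#' @inheritParams fpkm
#' @return object of the same shape with an `RPM` assay/matrix.
#' @export
rpm <- function(counts, lib_sizes = NULL) {
  m <- extract_counts(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0))
    stopf("zero library size in sample(s): %s",
          paste(colnames(m)[lib_sizes <= 0], collapse = ", "))
  out <- sweep(m * 1e6, 2, lib_sizes, "/")
  wrap_like(counts, out, assay_name = "RPM", unit = "RPM")
}

extract_counts <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, 1))
  if (is.matrix(x)) return(x)
  stopf("expected a SummarizedExperiment or a matrix")
}

wrap_like <- function(orig, m, assay_name, unit) {
  if (methods::is(orig, "SummarizedExperiment")) {
    out <- SummarizedExperiment::SummarizedExperiment(
      assays = setNames(list(m), assay_name),
      colData = SummarizedExperiment::colData(orig))
    S4Vectors::metadata(out)$unit <- unit
    return(out)
  }
  m
}

#' Negative-binomial Wald test between two sample groups
#'
#' A self-contained NB Wald test preserving the contract of the usual
#' count-based DE callers (`|log2FC| > 1` and BH-adjusted `p < 0.05`):
#' size factors by median-of-ratios (falling back to column-sum ratios when
#' no feature is positive in all samples), per-feature method-of-moments NB
#' dispersion pooled across the two groups (floored at 1e-8), log2 fold
#' change of pseudocounted normalized group means, and a two-sided p-value
#' for the Wald statistic `log2FC / SE` with a delta-method standard error
#' under NB variance `mu + phi * mu^2`. Features with all-zero counts in
#' both groups are reported with `log2fc = 0`, `p = 1`.
#'
#' Gene lists will not be identical to DESeq2's (no shrinkage, no Cook's
#' filtering, simpler dispersion estimator); the thresholds and the
#' adjustment are the same.
#'
#' @param counts count `SummarizedExperiment` or matrix.
#' @param group_a,group_b disjoint character vectors of sample ids
#'   (>= 2 samples each).
#' @param comparison label stored in the result (default `"A_vs_B"`).
#' @param pseudo pseudocount added to normalized group means for the fold
#'   change.
#' @param lfc_threshold,alpha significance contract: `significant` is
#'   `|log2fc| > lfc_threshold & padj < alpha`.
#' @return `data.frame` with columns `feature_id`, `comparison`, `mean_a`,
#'   `mean_b`, `log2fc`, `p`, `padj`, `significant`.
#' @export
deTest <- function(counts, group_a, group_b, comparison = "A_vs_B",
                   pseudo = 0.5, lfc_threshold = 1, alpha = 0.05) {
  m <- extract_counts(counts)
  all_ids <- colnames(m)
  unknown <- setdiff(c(group_a, group_b), all_ids)
  if (length(unknown))
    stopf("unknown sample id(s): %s", paste(unknown, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    stopf("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("need >= 2 samples per group")
  sub <- m[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  na <- length(group_a); nb <- length(group_b)
  A <- norm[, group_a, drop = FALSE]
  B <- norm[, group_b, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- apply(A, 1, var); vb <- apply(B, 1, var)

  # method-of-moments dispersion per feature, pooled across the two groups,
  # guarded from below by the experiment-wide median estimate: with 2-3
  # replicates the per-feature estimate is noisy, and features whose
  # within-group variance happens to come out small would otherwise get
  # wildly inflated Wald statistics (DESeq1-style "maximum" sharing)
  phi_g <- function(v, mu) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  pa <- phi_g(va, ma); pb <- phi_g(vb, mb)
  phi <- rowMeans(cbind(pa, pb), na.rm = TRUE)
  phi[is.nan(phi)] <- 0
  guard <- median(phi[is.finite(phi)])
  if (is.finite(guard)) phi <- pmax(phi, guard)
  phi <- pmax(phi, 1e-8)

  log2fc <- log2((mb + pseudo) / (ma + pseudo))
  var_mean <- function(mu, n) (mu + phi * mu^2) / n
  se <- sqrt((var_mean(ma, na) / (ma + pseudo)^2 +
              var_mean(mb, nb) / (mb + pseudo)^2)) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  zero <- ma == 0 & mb == 0
  log2fc[zero] <- 0
  p[zero] <- 1
  padj <- adjustBH(p)
  data.frame(feature_id = rownames(sub),
             comparison = comparison,
             mean_a = ma, mean_b = mb,
             log2fc = log2fc, p = p, padj = padj,
             significant = abs(log2fc) > lfc_threshold & padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Median-of-ratios size factors (DESeq-style); falls back to column-sum
# ratios when no feature is positive in every sample.
size_factors <- function(m) {
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (any(use)) {
    sf <- apply(m[use, , drop = FALSE], 2, function(col)
      exp(median(log(col[col > 0]) - loggeo[use][col > 0])))
    if (all(is.finite(sf) & sf > 0)) return(sf)
  }
  cs <- colSums(m)
  if (any(cs == 0)) stopf("cannot compute size factors: empty sample column")
  cs / exp(mean(log(cs)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a raw p-value vector (monotone,
#' order-preserving, values in `[0, 1]`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjustBH <- function(p) {
  check_prob(p, "p")
  p.adjust(p, method = "BH")
}

#' Adjacent-stage DE calling across a staged experiment
#'
#' Runs [deTest()] for each pair of adjacent stages (e.g. ST1 vs ST2,
#' ST2 vs ST3-1, ST3-1 vs ST3-2) and binds the results.
#'
#' @param counts count `SummarizedExperiment` whose `colData` has a `stage`
#'   column, or a matrix plus explicit `stages`.
#' @param stages optional character vector of per-sample stages (matrix
#'   input); stage order follows first appearance.
#' @param ... passed to [deTest()].
#' @return `data.frame` of stacked [deTest()] results.
#' @export
deAdjacentStages <- function(counts, stages = NULL, ...) {
  m <- extract_counts(counts)
  if (is.null(stages)) {
    if (!methods::is(counts, "SummarizedExperiment"))
      stopf("stages must be given for matrix input")
    stages <- as.character(SummarizedExperiment::colData(counts)$stage)
  }
  lev <- unique(stages)
  if (length(lev) < 2) stopf("need >= 2 stages")
  res <- lapply(seq_len(length(lev) - 1), function(k) {
    a <- colnames(m)[stages == lev[k]]
    b <- colnames(m)[stages == lev[k + 1]]
    deTest(m, a, b, comparison = paste0(lev[k], "_vs_", lev[k + 1]), ...)
  })
  do.call(rbind, res)
}
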