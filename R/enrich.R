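#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of at least
#' `k` annotated genes in a study set of size `n` drawn from a background
#' of `N` genes of which `K` carry the term. Computed in a numerically
#' stable way (log-space tail via `phyper`).
#'
#' @param k observed study hits.
#' @param K background genes carrying the term.
#' @param n study-set size.
#' @param N background size.
#' @return upper-tail probability in `(0, 1]`.
#' @examples
#' hypergeomUpper(4, 5, 4, 10)  # 5/210
#' @export
hypergeomUpper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stopf("inconsistent hypergeometric counts (k=%s K=%s n=%s N=%s)",
          k, K, n, N)
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Over-representation analysis of a gene set
#'
#' Hypergeometric upper-tail test of each annotation term against the
#' study set, with BH adjustment across tested terms. Terms are first
#' intersected with the background; one row is reported per term with at
#' least one study hit. Following the source analysis convention, the
#' `significant` flag uses the raw p-value at `alpha`; the BH-adjusted
#' value is reported alongside for stricter use.
#'
#' @param study character vector of study genes (subset of `background`).
#' @param background character vector of background genes.
#' @param term2genes `data.frame` with columns `term_id`, `gene_id`, or a
#'   named list of gene vectors.
#' @param alpha raw-p significance threshold.
#' @return `data.frame` with columns `term_id`, `k`, `K`, `n`, `N`, `p`,
#'   `padj`, `significant`, ordered by `p`.
#' @export
enrichTerms <- function(study, background, term2genes, alpha = 0.05) {
  study <- unique(study); background <- unique(background)
  if (!all(study %in% background))
    stopf("study set must be a subset of the background")
  if (is.data.frame(term2genes))
    term2genes <- split(term2genes$gene_id, term2genes$term_id)
  empty <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      padj = numeric(0), significant = logical(0))
  if (length(study) == 0) {
    warning("empty study set")
    return(empty)
  }
  N <- length(background); n <- length(study)
  rows <- lapply(names(term2genes), function(tm) {
    g <- intersect(unique(term2genes[[tm]]), background)
    k <- length(intersect(g, study))
    if (k == 0) return(NULL)
    data.frame(term_id = tm, k = k, K = length(g), n = n, N = N,
               p = hypergeomUpper(k, length(g), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$padj <- adjustBH(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  out
}
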