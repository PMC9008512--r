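#' Row standardization of stage-mean profiles
#'
#' Centres and scales each feature's stage-mean profile to mean 0 and
#' population SD 1 (divisor `n`, as Mfuzz's standardise does). Zero-variance
#' rows cannot be standardized; they are excluded from the returned matrix
#' and reported in the `excluded` attribute.
#'
#' @param stage_means numeric matrix, features x stages (>= 2 stages).
#' @return standardized matrix with an `excluded` attribute naming the
#'   dropped constant rows.
#' @export
standardizeRows <- function(stage_means) {
  if (!is.matrix(stage_means) || ncol(stage_means) < 2)
    stopf("stage_means must be a matrix with >= 2 stages")
  mu <- rowMeans(stage_means)
  s <- sqrt(rowMeans((stage_means - mu)^2))      # population SD
  keep <- s > 0
  out <- (stage_means[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(out, "excluded") <- rownames(stage_means)[!keep]
  out
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard fuzzy c-means with Euclidean distance:
#' memberships `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))`, centres the
#' `u^m`-weighted means. A point coinciding with one or more centres gets
#' its membership concentrated there. Initialization is k-means++-style
#' seeding from data rows under a fixed RNG seed with `restarts` restarts;
#' the solution with the lowest objective is kept. The objective
#' `sum_ij u_ij^m d_ij^2` is asserted non-increasing at every iteration.
#'
#' @param X numeric matrix, features x stages (rows typically standardized).
#' @param k number of clusters (>= 2, <= number of distinct rows).
#' @param m fuzzifier (> 1); `NULL` uses [estimateFuzzifier()].
#' @param tol convergence threshold on the maximum centre shift.
#' @param max_iter iteration cap per restart.
#' @param restarts independent initializations.
#' @param seed RNG seed for initialization.
#' @return a [FuzzyClustering-class].
#' @export
fuzzyCMeans <- function(X, k = 4, m = NULL, tol = 1e-6, max_iter = 500,
                        restarts = 10, seed = 1) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (k < 2) stopf("k must be >= 2")
  n_distinct <- nrow(unique(X))
  if (k > n_distinct)
    stopf("k (%d) exceeds the number of distinct rows (%d)", k, n_distinct)
  if (is.null(m)) m <- estimateFuzzifier(X)
  if (m <= 1) stopf("fuzzifier m must exceed 1")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- fcm_once(X, k, m, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  methods::new("FuzzyClustering",
               membership = best$u, centers = best$centers,
               m = m, objective = best$objective, trace = best$trace)
}

fcm_once <- function(X, k, m, tol, max_iter) {
  centers <- kpp_init(X, k)
  expo <- 2 / (m - 1)
  trace <- numeric(0)
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    u <- memberships_from_d2(d2, expo)
    obj <- sum(u^m * d2)
    if (obj > obj_prev + 1e-9 * max(1, abs(obj_prev)))
      stopf("internal error: fuzzy c-means objective increased")
    trace <- c(trace, obj)
    um <- u^m
    new_centers <- t(um) %*% X / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    obj_prev <- obj
    if (shift < tol) break
  }
  d2 <- dist2_to_centers(X, centers)
  u <- memberships_from_d2(d2, expo)
  rownames(u) <- rownames(X)
  colnames(u) <- paste0("C", seq_len(k))
  rownames(centers) <- paste0("C", seq_len(k))
  colnames(centers) <- colnames(X)
  list(u = u, centers = centers, objective = sum(u^m * d2), trace = trace)
}

dist2_to_centers <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  pmax(d2, 0)
}

memberships_from_d2 <- function(d2, expo) {
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit))     # coincident with >= 1 centre: all mass there
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  if (any(!hit)) {
    # u_ij = d_ij^(-expo) / sum_l d_il^(-expo), computed from squared d
    w <- d2[!hit, , drop = FALSE]^(-expo / 2)
    u[!hit, ] <- w / rowSums(w)
  }
  u
}

# k-means++ seeding from the data rows
kpp_init <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2min <- apply(dist2_to_centers(X, X[idx, , drop = FALSE]), 1, min)
    d2min[idx] <- 0
    if (sum(d2min) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2min))
    }
  }
  X[idx, , drop = FALSE]
}

#' Fuzzifier estimate for standardized profiles
#'
#' The Schwammle-Jensen rule relating a suitable fuzzifier to the number of
#' features `N` and dimensions `D`:
#' `m = 1 + (1418/N + 22.05) * D^-2 + (12.33/N + 0.243) * D^(-0.0406 ln N - 0.1134)`,
#' clipped to `[1.05, 3]`.
#'
#' @param X standardized numeric matrix, features x stages.
#' @return fuzzifier in `[1.05, 3]`.
#' @export
estimateFuzzifier <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  N <- nrow(X); D <- ncol(X)
  if (N < 2) stopf("need >= 2 features")
  m <- 1 + (1418 / N + 22.05) * D^-2 +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
  min(max(m, 1.05), 3)
}

#' Hard cluster assignment from memberships
#'
#' Argmax membership when it reaches `min_membership`, else `NA`
#' (unassigned). Ties go to the lowest cluster index.
#'
#' @param x a [FuzzyClustering-class] or a membership matrix.
#' @param min_membership assignment threshold in `[0, 1]`.
#' @return named integer vector of cluster indices (`NA` = unassigned).
#' @export
assignClusters <- function(x, min_membership = 0.5) {
  u <- if (methods::is(x, "FuzzyClustering")) membership(x) else x
  check_prob(min_membership, "min_membership")
  best <- apply(u, 1, which.max)              # lowest index on ties
  top <- u[cbind(seq_len(nrow(u)), best)]
  out <- ifelse(top >= min_membership, best, NA_integer_)
  names(out) <- rownames(u)
  out
}

#' Stage-mean matrix from an expression matrix
#'
#' Collapses samples to per-stage means (stage order = first appearance).
#'
#' @param expr `SummarizedExperiment` with `stage` in `colData`, or a
#'   matrix plus `stages`.
#' @param stages optional per-sample stage labels for matrix input.
#' @return numeric matrix, features x stages.
#' @export
stageMeans <- function(expr, stages = NULL) {
  m <- extract_counts(expr)
  if (is.null(stages)) {
    if (!methods::is(expr, "SummarizedExperiment"))
      stopf("stages must be given for matrix input")
    stages <- as.character(SummarizedExperiment::colData(expr)$stage)
  }
  lev <- unique(stages)
  out <- vapply(lev, function(s)
    rowMeans(m[, stages == s, drop = FALSE]), numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), lev)
  out
}
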