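# Independent reference implementations used to cross-check the package.
# These deliberately avoid the code paths they verify.

# Benjamini-Hochberg step-up, written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  scaled <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Pearson correlation from the raw covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - sum(x) / n) * (y - sum(y) / n))
  sxx <- sum((x - sum(x) / n)^2)
  syy <- sum((y - sum(y) / n)^2)
  sxy / sqrt(sxx * syy)
}

# Spearman = Pearson on average ranks.
spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x), rank(y))
}

# Hypergeometric upper tail P(X >= k) by full enumeration of all C(N, n)
# study sets (background 1..N, annotated genes 1..K).
hyper_enum_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= K)
  mean(hits >= k)
}

# Target-site scorer as a plain double loop over offsets and positions.
scan_oracle <- function(mirna, transcript) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(mirna, "")[[1]]
  tx <- strsplit(transcript, "")[[1]]
  L <- length(m)
  n_off <- length(tx) - L + 1
  if (n_off < 1) return(numeric(0))
  vapply(seq_len(n_off), function(s) {
    total <- 0
    for (i in seq_len(L)) {
      tb <- tx[s + L - i]
      pen <- if (identical(tb, unname(comp[m[i]]))) 0
        else if ((m[i] == "G" && tb == "T") || (m[i] == "T" && tb == "G")) 0.5
        else 1
      if (i >= 2 && i <= 13) pen <- 2 * pen
      total <- total + pen
    }
    total
  }, numeric(1))
}

# All-pairs interval oracle for the cis window rule (1-based inclusive;
# gap of [a1,b1] before [a2,b2] is a2 - b1 - 1; 0 when overlapping).
cis_oracle <- function(lnc, genes, window = 10000) {
  out <- list()
  for (i in seq_along(lnc)) for (j in seq_along(genes)) {
    if (as.character(GenomicRanges::seqnames(lnc))[i] !=
        as.character(GenomicRanges::seqnames(genes))[j]) next
    a1 <- GenomicRanges::start(lnc)[i]; b1 <- GenomicRanges::end(lnc)[i]
    a2 <- GenomicRanges::start(genes)[j]; b2 <- GenomicRanges::end(genes)[j]
    gap <- if (a2 > b1) a2 - b1 - 1 else if (a1 > b2) a1 - b2 - 1 else 0
    if (gap <= window)
      out[[length(out) + 1]] <- data.frame(
        lncrna_id = names(lnc)[i], gene_id = names(genes)[j], distance = gap,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  do.call(rbind, out)
}

# Exhaustive Hamming catalog oracle (equal length only, <= 1 mismatch,
# ties by mismatch count then mature id).
catalog_oracle <- function(reads, mature, min_len = 18) {
  lapply(reads[nchar(reads) >= min_len], function(r) {
    best_id <- NA_character_; best_mm <- NA_integer_
    for (id in sort(names(mature))) {
      m <- mature[[id]]
      if (nchar(m) != nchar(r)) next
      mm <- sum(strsplit(r, "")[[1]] != strsplit(m, "")[[1]])
      if (mm <= 1 && (is.na(best_mm) || mm < best_mm)) {
        best_mm <- mm; best_id <- id
      }
    }
    list(id = best_id, mm = best_mm)
  })
}

# Brute-force network accounting from a passed-triplet table.
network_counts_oracle <- function(tab) {
  nodes <- unique(c(tab$lncrna_id, tab$mirna_id, tab$mrna_id))
  edges <- unique(c(paste(tab$mirna_id, tab$lncrna_id),
                    paste(tab$mirna_id, tab$mrna_id)))
  list(n_nodes = length(nodes), n_edges = length(edges))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
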