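COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "X")

# Expectation score at every possible site start (1-based) of `mirna`
# against `transcript`; numeric(0) when the transcript is too short.
scan_scores <- function(mirna, transcript) {
  m <- seq_chars(toupper(mirna))
  tx <- seq_chars(toupper(transcript))
  L <- length(m); n <- length(tx)
  n_off <- n - L + 1L
  if (n_off < 1L) return(numeric(0))
  w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  comp <- unname(COMP[m])
  # target char pairing with miRNA position i at site start s: tx[s + L - i]
  idx <- outer(seq_len(n_off) - 1L, L - seq_len(L), "+") + 1L
  ch <- matrix(tx[idx], n_off, L)
  mm <- matrix(m, n_off, L, byrow = TRUE)
  match_ <- ch == matrix(comp, n_off, L, byrow = TRUE)
  wobble <- (mm == "G" & ch == "T") | (mm == "T" & ch == "G")
  pen <- ifelse(match_, 0, ifelse(wobble, 0.5, 1))
  as.numeric(pen %*% w)
}

#' Scan a transcript for miRNA target sites
#'
#' Plant-style target scoring: the reverse complement of the miRNA is slid
#' (ungapped) along the transcript; each aligned position contributes a
#' penalty of 0 (Watson-Crick match), 0.5 (G:U wobble) or 1 (mismatch),
#' doubled within the seed region (miRNA positions 2-13, 5' to 3'). The
#' expectation score of a site is the total penalty; the best-scoring site
#' (with all ties) is reported when its expectation is at or below
#' `cutoff`. A perfect reverse-complement site scores 0.
#'
#' @param mirna mature miRNA sequence, 18-26 nt (DNA alphabet; U is
#'   accepted and read as T).
#' @param transcript transcript sequence.
#' @param cutoff maximum expectation for a reported hit (inclusive).
#' @param mirna_id,transcript_id identifiers copied into the result.
#' @return `data.frame` with columns `mirna_id`, `transcript_id`,
#'   `site_start`, `expectation`, `alignment` (miRNA 3'->5' / pairing row /
#'   target 5'->3', newline-separated); zero rows when no site passes.
#' @examples
#' scanTargets("TGAAGCTGCCAGCATGATCTA",
#'             paste0("CCC", "TAGATCATGCTGGCAGCTTCA", "GGG"))
#' @export
scanTargets <- function(mirna, transcript, cutoff = 5.0,
                        mirna_id = "miRNA", transcript_id = "transcript") {
  mirna <- gsub("U", "T", toupper(mirna))
  L <- nchar(mirna)
  if (L < 18 || L > 26) stopf("miRNA length must be 18-26 nt (got %d)", L)
  sc <- scan_scores(mirna, transcript)
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), expectation = numeric(0),
                      alignment = character(0), stringsAsFactors = FALSE)
  if (length(sc) == 0) return(empty)
  best <- min(sc)
  if (best > cutoff) return(empty)
  at <- which(sc == best)
  aln <- vapply(at, function(s) site_alignment(mirna, transcript, s),
                character(1))
  data.frame(mirna_id = mirna_id, transcript_id = transcript_id,
             site_start = at, expectation = sc[at], alignment = aln,
             stringsAsFactors = FALSE)
}

site_alignment <- function(mirna, transcript, start) {
  m <- seq_chars(mirna)
  L <- length(m)
  site <- seq_chars(toupper(substr(transcript, start, start + L - 1L)))
  mir_rev <- rev(m)                      # 3' -> 5', aligned with site 5' -> 3'
  pair <- vapply(seq_len(L), function(j) {
    mb <- mir_rev[j]; tb <- site[j]
    if (tb == unname(COMP[mb])) "|"
    else if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) "o"
    else " "
  }, character(1))
  paste(paste(mir_rev, collapse = ""),
        paste(pair, collapse = ""),
        paste(site, collapse = ""), sep = "\n")
}

#' Scan a miRNA catalog against a transcript set
#'
#' [scanTargets()] for every (miRNA, transcript) pair, rows bound together.
#'
#' @param mirnas,transcripts named character vectors or `DNAStringSet`s.
#' @param cutoff expectation cutoff, see [scanTargets()].
#' @return combined hit `data.frame`.
#' @export
scanTargetsSet <- function(mirnas, transcripts, cutoff = 5.0) {
  mirnas <- as_named_chr(mirnas); transcripts <- as_named_chr(transcripts)
  hits <- list()
  for (mi in names(mirnas))
    for (ti in names(transcripts)) {
      h <- scanTargets(mirnas[[mi]], transcripts[[ti]], cutoff, mi, ti)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
  if (length(hits) == 0)
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), expectation = numeric(0),
                      alignment = character(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Cis lncRNA-gene pairs within a genomic window
#'
#' Pairs every lncRNA with every gene on the same chromosome whose genomic
#' interval lies within `window` bp (gap between 1-based inclusive
#' intervals; 0 when they overlap; the boundary is inclusive, so a gap of
#' exactly `window` is a pair). Strand is ignored for the distance;
#' `relation` (upstream/downstream/overlapping) is read from the lncRNA's
#' strand.
#'
#' @param lncrnas,genes named `GRanges`.
#' @param window maximum gap in bp (default 10 kb).
#' @return `data.frame` with columns `lncrna_id`, `gene_id`, `distance`,
#'   `relation`.
#' @export
cisPairs <- function(lncrnas, genes, window = 10000) {
  if (length(lncrnas) == 0 || length(genes) == 0)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), relation = character(0)))
  if (!length(intersect(as.character(GenomicRanges::seqnames(lncrnas)),
                        as.character(GenomicRanges::seqnames(genes)))))
    stopf("lncRNAs and genes share no chromosome: wrong assembly?")
  ov <- GenomicRanges::findOverlaps(lncrnas, genes, maxgap = window,
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi) == 0)
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0), relation = character(0)))
  d <- GenomicRanges::distance(lncrnas[qi], genes[si], ignore.strand = TRUE)
  l_start <- GenomicRanges::start(lncrnas)[qi]
  l_end <- GenomicRanges::end(lncrnas)[qi]
  g_start <- GenomicRanges::start(genes)[si]
  g_end <- GenomicRanges::end(genes)[si]
  l_strand <- as.character(GenomicRanges::strand(lncrnas))[qi]
  overlap <- g_start <= l_end & g_end >= l_start
  before <- g_end < l_start          # gene 5' of lncRNA in genome coordinates
  relation <- ifelse(overlap, "overlapping",
              ifelse(xor(before, l_strand == "-"), "upstream", "downstream"))
  data.frame(lncrna_id = names(lncrnas)[qi], gene_id = names(genes)[si],
             distance = as.integer(d), relation = relation,
             stringsAsFactors = FALSE, row.names = NULL)
}

TRANS_ENERGY <- local({
  e <- matrix(0, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                       c("A", "C", "G", "T", "N")))
  e["G", "C"] <- e["C", "G"] <- -3
  e["A", "T"] <- e["T", "A"] <- -2
  e["G", "T"] <- e["T", "G"] <- -1
  e
})

#' Trans lncRNA-mRNA pairing by a windowed complementarity energy
#'
#' A pairing-energy screen for trans-acting lncRNA targets: the best
#' ungapped antiparallel alignment of the lncRNA against the mRNA over all
#' offsets, under per-pair energies G:C = -3, A:U = -2, G:U = -1, otherwise
#' 0 (arbitrary units); alignments must overlap by at least `window` nt. A
#' 200-nt lncRNA perfectly complementary to a 200-nt mRNA scores
#' `dg = -600`. The raw energy `dg` is normalized by the shorter
#' transcript, `ndg = dg / min(|lnc|, |mrna|)`, and the pair is emitted
#' when `ndg <= threshold` (boundary inclusive).
#'
#' @param lnc_seq,mrna_seq nucleotide strings, both at least `window` nt.
#' @param window minimum alignment overlap in nt.
#' @param threshold maximum normalized energy for an emitted pair.
#' @param lncrna_id,mrna_id identifiers copied into the result.
#' @return one-row `data.frame` (`lncrna_id`, `mrna_id`, `dg`, `ndg`,
#'   `window_start_lnc`, `window_start_mrna`) or zero rows.
#' @export
transPairs <- function(lnc_seq, mrna_seq, window = 40, threshold = -0.1,
                       lncrna_id = "lncRNA", mrna_id = "mRNA") {
  L1 <- nchar(lnc_seq); L2 <- nchar(mrna_seq)
  if (L1 < window || L2 < window)
    stopf("both sequences must be at least window (%d nt) long", window)
  lc <- seq_chars(toupper(lnc_seq))
  mcrev <- rev(seq_chars(toupper(mrna_seq)))
  lc[!lc %in% rownames(TRANS_ENERGY)] <- "N"
  mcrev[!mcrev %in% rownames(TRANS_ENERGY)] <- "N"
  E <- matrix(TRANS_ENERGY[cbind(rep(lc, times = L2),
                                 rep(mcrev, each = L1))], L1, L2)
  # cumulative sums along diagonals: P[i,j] = E[i,j] + P[i-1,j-1]; the full
  # diagonal through a boundary cell is its best alignment (energies <= 0,
  # so extending an overlap never hurts)
  P <- E
  for (i in 2:L1)
    P[i, 2:L2] <- P[i, 2:L2] + P[i - 1, 1:(L2 - 1)]
  ends <- rbind(cbind(L1, seq_len(L2)),
                cbind(seq_len(L1 - 1), L2))
  len <- pmin(ends[, 1], ends[, 2])
  keep <- len >= window
  ends <- ends[keep, , drop = FALSE]
  len <- len[keep]
  sums <- P[ends]
  best <- which.min(sums)
  dg <- sums[best]
  ndg <- dg / min(L1, L2)
  empty <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                      dg = numeric(0), ndg = numeric(0),
                      window_start_lnc = integer(0),
                      window_start_mrna = integer(0))
  if (ndg > threshold) return(empty)
  ie <- ends[best, 1]; je <- ends[best, 2]; lb <- len[best]
  data.frame(lncrna_id = lncrna_id, mrna_id = mrna_id, dg = dg, ndg = ndg,
             window_start_lnc = ie - lb + 1L,
             window_start_mrna = L2 - je + 1L,
             stringsAsFactors = FALSE)
}

#' Trans screening over transcript sets
#'
#' [transPairs()] for each (lncRNA, mRNA) combination, optionally capped at
#' `max_pairs` combinations (taken in order) to bound run time on large
#' sets.
#'
#' @param lnc_seqs,mrna_seqs named character vectors or `DNAStringSet`s.
#' @inheritParams transPairs
#' @param max_pairs cap on scanned combinations (`Inf` = all).
#' @return combined `data.frame` of emitted pairs.
#' @export
transPairsSet <- function(lnc_seqs, mrna_seqs, window = 40, threshold = -0.1,
                          max_pairs = Inf) {
  lnc_seqs <- as_named_chr(lnc_seqs); mrna_seqs <- as_named_chr(mrna_seqs)
  grid <- expand.grid(l = names(lnc_seqs), g = names(mrna_seqs),
                      stringsAsFactors = FALSE)
  if (nrow(grid) > max_pairs) grid <- grid[seq_len(max_pairs), ]
  out <- list()
  for (r in seq_len(nrow(grid))) {
    h <- transPairs(lnc_seqs[[grid$l[r]]], mrna_seqs[[grid$g[r]]],
                    window, threshold, grid$l[r], grid$g[r])
    if (nrow(h)) out[[length(out) + 1L]] <- h
  }
  if (length(out) == 0)
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      dg = numeric(0), ndg = numeric(0),
                      window_start_lnc = integer(0),
                      window_start_mrna = integer(0)))
  do.call(rbind, out)
}
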