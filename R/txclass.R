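#' Filter lncRNA candidates by class code and length
#'
#' First two steps of the lncRNA identification cascade: keep transcripts
#' whose GffCompare class code is one of `u` (intergenic), `i` (intronic),
#' `x` (antisense exonic overlap) or `o` (other same-strand overlap) and
#' whose spliced length strictly exceeds 200 nt. Input order is preserved.
#'
#' @param transcripts `GRanges` with metadata columns `class_code` and
#'   `tx_length` (spliced length in nt), as produced by
#'   [simulateCernaDataset()] or read from a GFF3 with those attributes.
#' @param codes admissible class codes.
#' @param min_length strict lower length bound in nt (a transcript of
#'   exactly `min_length` is rejected).
#' @return the retained subset of `transcripts`.
#' @export
filterLncrnaCandidates <- function(transcripts,
                                   codes = c("u", "i", "x", "o"),
                                   min_length = 200) {
  mc <- S4Vectors::mcols(transcripts)
  cc <- mc$class_code
  if (is.null(cc) || anyNA(cc) || any(cc == "")) {
    bad <- names(transcripts)[is.null(cc) | is.na(cc) | cc == ""]
    stopf("class_code missing for: %s", paste(head(bad, 5), collapse = ", "))
  }
  len <- mc$tx_length
  if (is.null(len)) len <- GenomicRanges::width(transcripts)
  transcripts[cc %in% codes & len > min_length]
}

#' ORF-based coding-potential call
#'
#' A fully specified stand-in for external coding-potential classifiers
#' (CPC/CNCI/Pfam-style): scans the three forward reading frames for the
#' longest open reading frame (in-frame ATG start, in-frame TAA/TAG/TGA
#' stop) and labels the transcript `coding` when the ORF reaches
#' `min_orf_aa` amino acids or covers at least `min_coverage` of the
#' transcript.
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param min_orf_aa coding call threshold on ORF length, in amino acids
#'   (codons between start and stop, excluding the stop).
#' @param min_coverage coding call threshold on the fraction of the
#'   transcript covered by the longest ORF (ATG through stop inclusive).
#' @return list with `longest_orf_aa`, `orf_coverage`, `label`.
#' @examples
#' codingPotential(paste0("ATG", strrep("GCA", 150), "TAA"))$label
#' @export
codingPotential <- function(sequence, min_orf_aa = 100, min_coverage = 0.5) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0)
    stopf("sequence must be a single non-empty string")
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) stopf("sequence contains non-nucleotide characters")
  n <- nchar(s)
  best <- 0L          # aa length of longest ORF
  best_nt <- 0L       # nt span of that ORF incl. stop codon
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0) next
    cod <- substring(s, starts, starts + 2L)
    is_start <- cod == "ATG"
    is_stop <- cod %in% stops
    open_at <- NA_integer_
    for (i in seq_along(cod)) {
      if (is.na(open_at) && is_start[i]) open_at <- i
      if (!is.na(open_at) && is_stop[i]) {
        aa <- i - open_at          # codons before the stop
        if (aa > best) {
          best <- aa
          best_nt <- 3L * (aa + 1L)
        }
        open_at <- NA_integer_
      }
    }
  }
  cov <- if (best > 0) best_nt / n else 0
  list(longest_orf_aa = best,
       orf_coverage = cov,
       label = if (best >= min_orf_aa || cov >= min_coverage)
         "coding" else "non-coding")
}

#' Full lncRNA classification cascade
#'
#' Applies [filterLncrnaCandidates()] then [codingPotential()] to every
#' candidate. Transcripts passing both (admissible class code, length
#' > 200 nt, non-coding call) get `biotype = "lncRNA"`; every other
#' transcript is labelled `"other"` — none are dropped.
#'
#' @inheritParams filterLncrnaCandidates
#' @param sequences named character vector or `DNAStringSet` covering at
#'   least all candidates.
#' @param min_orf_aa,min_coverage passed to [codingPotential()].
#' @return `transcripts` with a recomputed `biotype` metadata column.
#' @export
classifyTranscripts <- function(transcripts, sequences,
                                min_orf_aa = 100, min_coverage = 0.5,
                                codes = c("u", "i", "x", "o"),
                                min_length = 200) {
  if (length(transcripts) == 0) return(transcripts)
  sequences <- as_named_chr(sequences)
  cand <- names(filterLncrnaCandidates(transcripts, codes, min_length))
  missing <- setdiff(cand, names(sequences))
  if (length(missing))
    stopf("no sequence for candidates: %s", paste(head(missing, 5), collapse = ", "))
  noncoding <- vapply(cand, function(id) {
    codingPotential(sequences[[id]], min_orf_aa, min_coverage)$label ==
      "non-coding"
  }, logical(1))
  lnc <- cand[noncoding]
  S4Vectors::mcols(transcripts)$biotype <-
    ifelse(names(transcripts) %in% lnc, "lncRNA", "other")
  transcripts
}

#' Catalog small-RNA reads against known mature miRNAs
#'
#' Reads shorter than `min_len` nt are discarded. A surviving read is
#' `conserved` when it matches a mature miRNA of equal length at Hamming
#' distance <= 1 (ungapped, mirroring one-mismatch short-read matching);
#' ties are broken by lowest mismatch count, then lexicographically
#' smallest mature id. Everything else is `unassigned`.
#'
#' @param sequences character vector of read sequences.
#' @param known_mature named character vector or `DNAStringSet` of mature
#'   miRNA sequences (non-empty).
#' @param min_len minimum read length in nt.
#' @return `data.frame` with columns `sequence`, `length`, `status`,
#'   `matched_mature_id`, `mismatches`.
#' @export
catalogSmallRNA <- function(sequences, known_mature, min_len = 18) {
  known_mature <- as_named_chr(known_mature)
  if (length(known_mature) == 0) stopf("known_mature must be non-empty")
  if (is.null(names(known_mature)))
    stopf("known_mature must be named")
  sequences <- toupper(as_named_chr(sequences))
  if (any(grepl("[^ACGTUN]", c(sequences, toupper(known_mature)))))
    stopf("non-nucleotide characters in reads or mature sequences")
  keep <- nchar(sequences) >= min_len
  reads <- sequences[keep]
  mat_len <- nchar(known_mature)
  mat_chars <- lapply(known_mature, seq_chars)
  res <- lapply(reads, function(r) {
    same <- which(mat_len == nchar(r))
    if (length(same)) {
      rc <- seq_chars(r)
      mm <- vapply(same, function(j) sum(rc != mat_chars[[j]]), integer(1))
      ok <- mm <= 1L
      if (any(ok)) {
        cand_id <- names(known_mature)[same[ok]]
        cand_mm <- mm[ok]
        o <- order(cand_mm, cand_id)
        return(list(status = "conserved", id = cand_id[o[1]],
                    mm = cand_mm[o[1]]))
      }
    }
    list(status = "unassigned", id = NA_character_, mm = NA_integer_)
  })
  data.frame(sequence = reads,
             length = nchar(reads),
             status = vapply(res, `[[`, character(1), "status"),
             matched_mature_id = vapply(res, `[[`, character(1), "id"),
             mismatches = vapply(res, `[[`, integer(1), "mm"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Descriptive lncRNA vs mRNA feature comparison
#'
#' Mean transcript length, exon-count distribution and per-transcript GC
#' content for the two biotypes, with a two-sided Welch two-sample t-test on
#' GC content (lncRNAs typically run GC-poorer than mRNAs, and this is the
#' contrast that shows it). With fewer than two transcripts in either group the t-test is
#' reported as undefined (`NA`) but the summary is still emitted.
#'
#' @param lnc_seqs,mrna_seqs named character vectors or `DNAStringSet`s.
#' @param lnc_exons,mrna_exons optional integer exon counts per transcript.
#' @return list with per-group summaries and `gc_test` (`t`, `df`, `p`).
#' @export
summarizeFeatures <- function(lnc_seqs, mrna_seqs,
                              lnc_exons = NULL, mrna_exons = NULL) {
  lnc_seqs <- as_named_chr(lnc_seqs); mrna_seqs <- as_named_chr(mrna_seqs)
  if (length(lnc_seqs) == 0 || length(mrna_seqs) == 0)
    stopf("both biotype sets must be non-empty")
  grp <- function(seqs, exons) {
    gc <- vapply(seqs, gc_content, numeric(1))
    list(n = length(seqs),
         mean_length = mean(nchar(seqs)),
         gc = unname(gc),
         exon_table = if (is.null(exons)) NULL else table(exons))
  }
  a <- grp(lnc_seqs, lnc_exons)
  b <- grp(mrna_seqs, mrna_exons)
  gc_test <- list(t = NA_real_, df = NA_real_, p = NA_real_)
  if (a$n >= 2 && b$n >= 2 && (sd(a$gc) > 0 || sd(b$gc) > 0)) {
    tt <- t.test(a$gc, b$gc)       # Welch by default
    gc_test <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value)
  } else if (a$n >= 2 && b$n >= 2) {
    # both groups constant and equal -> no evidence of difference
    gc_test <- list(t = 0, df = a$n + b$n - 2, p = 1)
  }
  list(lncRNA = a, mRNA = b, gc_test = gc_test)
}
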