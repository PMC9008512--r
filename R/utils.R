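# Internal sequence and validation helpers.

BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement writeXStringSet
#'   readDNAStringSet
NULL

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

gc_content <- function(x) {
  ch <- seq_chars(toupper(x))
  sum(ch %in% c("G", "C")) / length(ch)
}

# Codon sampler avoiding stop codons (for planting clean ORFs).
non_stop_codons <- function() {
  cod <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(x, nm) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("%s must lie in [0, 1]", nm)
  invisible(x)
}

# Stage labels mirroring the bud-differentiation design: with four stages the
# third timepoint is split (early/late exuberant differentiation).
stage_labels <- function(n_stages) {
  if (n_stages == 4) c("ST1", "ST2", "ST3-1", "ST3-2")
  else paste0("ST", seq_len(n_stages))
}

# as.character() drops names on plain character vectors; keep them.
as_named_chr <- function(x) {
  if (is.character(x)) return(x)
  as.character(x)        # DNAStringSet and friends keep names here
}
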