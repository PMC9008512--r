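# Shared fixtures, built once per test run.

# A small synthetic experiment with planted structure (3 triplets, 2 cis
# pairs, low dispersion), reused across module tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCernaDataset(cernaSimConfig(
        n_mrna = 20, n_lncrna = 10, n_mirna = 4, n_triplets = 3,
        n_cis_pairs = 2, dispersion = 0.02, effect_size = 4, seed = 7))
    cache
  }
})

# Random sequence of the given length, rejected until the ORF rule calls it
# non-coding (so its cascade outcome is known by construction).
noncoding_dna <- function(seed, len) {
  set.seed(seed)
  repeat {
    s <- random_dna(len)
    if (codingPotential(s)$label == "non-coding") return(s)
  }
}

orf_dna <- function(seed, n_codons) {
  cod <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                       paste0), c("A","C","G","T"), paste0)),
                 c("TAA", "TAG", "TGA"))
  set.seed(seed)
  paste0("ATG", paste(sample(cod, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}

# Twelve hand-made transcript records with known class codes, lengths and
# ORF content, written out as GFF3 + FASTA and read back, so the cascade is
# exercised through the file dialect it consumes.
toy_cascade_fixture <- function() {
  seqs <- c(
    t01 = noncoding_dna(1, 300),                  # u, non-coding -> lncRNA
    t02 = noncoding_dna(2, 300),                  # i -> lncRNA
    t03 = noncoding_dna(3, 300),                  # x -> lncRNA
    t04 = noncoding_dna(4, 300),                  # o -> lncRNA
    t05 = noncoding_dna(5, 300),                  # "=" class -> other
    t06 = noncoding_dna(6, 300),                  # "j" class -> other
    t07 = noncoding_dna(7, 200),                  # u but exactly 200 nt -> other
    t08 = noncoding_dna(8, 150),                  # u, short -> other
    t09 = paste0(orf_dna(11, 150),
                 noncoding_dna(9, 300)),          # u, 150 aa ORF -> other
    t10 = paste0(orf_dna(12, 60),
                 noncoding_dna(13, 114)),         # u, ORF covers 186/300 -> other
    t11 = noncoding_dna(10, 201),                 # u, 201 nt -> lncRNA (just over)
    t12 = noncoding_dna(14, 300)                  # u -> lncRNA
  )
  class_code <- c("u", "i", "x", "o", "=", "j", "u", "u", "u", "u", "u", "u")
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = seq(1, by = 20000,
                                          length.out = length(seqs)),
                              width = nchar(seqs)),
    strand = "+")
  names(gr) <- names(seqs)
  S4Vectors::mcols(gr)$class_code <- class_code
  S4Vectors::mcols(gr)$tx_length <- nchar(seqs)
  S4Vectors::mcols(gr)$type <- "transcript"
  S4Vectors::mcols(gr)$ID <- names(gr)

  dir <- tempfile("toy_cascade_")
  dir.create(dir)
  gff <- file.path(dir, "toy.gff3")
  fa <- file.path(dir, "toy.fa")
  rtracklayer::export(gr, gff, format = "gff3")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  list(dir = dir, gff = gff, fasta = fa,
       expected_lncrna = c("t01", "t02", "t03", "t04", "t11", "t12"))
}
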