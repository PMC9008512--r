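#' Simulation configuration for a staged ceRNA experiment
#'
#' Builds the validated parameter list consumed by [simulateCernaDataset()].
#' Defaults emulate the bud-differentiation design: four stages (the third
#' timepoint split into early/late) times three biological replicates, i.e.
#' twelve libraries, negative-binomial counts, four temporal prototype
#' shapes plus a flat majority, planted ceRNA triplets and planted cis
#' lncRNA-gene neighbours inside the 10 kb window.
#'
#' @param n_mrna,n_lncrna,n_mirna numbers of mRNAs, lncRNAs and miRNAs.
#' @param n_stages number of developmental stages (>= 2; default 4).
#' @param n_reps replicates per stage (default 3).
#' @param n_triplets planted ceRNA triplets; each uses a dedicated miRNA, so
#'   `n_triplets <= n_mirna` is required.
#' @param n_cis_pairs planted lncRNA-gene neighbours at distance <= 10 kb;
#'   an equal number of decoy neighbours is placed beyond 10 kb.
#' @param dispersion NB dispersion phi >= 0 (variance `mu + phi * mu^2`).
#' @param baseline_log_mean mean of the log-normal baseline expression.
#' @param effect_size multiplicative fold applied by prototype shapes (>= 1).
#' @param prop_de fraction of non-planted RNA features given a non-flat
#'   prototype; the rest are flat nulls.
#' @param mirna_len mature miRNA length in nt (18-26).
#' @param chrom_lengths named lengths of the synthetic chromosomes (bp).
#' @param seed RNG seed; identical configs give byte-identical datasets.
#' @return a classed list of validated parameters.
#' @export
cernaSimConfig <- function(n_mrna = 60, n_lncrna = 30, n_mirna = 6,
                           n_stages = 4, n_reps = 3,
                           n_triplets = 3, n_cis_pairs = 4,
                           dispersion = 0.05, baseline_log_mean = 5,
                           effect_size = 4, prop_de = 0.3,
                           mirna_len = 21,
                           chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                           seed = 1) {
  cfg <- list(n_mrna = n_mrna, n_lncrna = n_lncrna, n_mirna = n_mirna,
              n_stages = n_stages, n_reps = n_reps,
              n_triplets = n_triplets, n_cis_pairs = n_cis_pairs,
              dispersion = dispersion, baseline_log_mean = baseline_log_mean,
              effect_size = effect_size, prop_de = prop_de,
              mirna_len = mirna_len, chrom_lengths = chrom_lengths,
              seed = seed)
  counts <- c("n_mrna", "n_lncrna", "n_mirna", "n_triplets", "n_cis_pairs")
  for (nm in counts)
    if (cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  if (n_stages < 2) stopf("n_stages must be >= 2")
  if (n_reps < 1) stopf("n_reps must be >= 1")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  if (effect_size < 1) stopf("effect_size must be >= 1")
  if (mirna_len < 18 || mirna_len > 26) stopf("mirna_len must be in [18, 26]")
  if (n_triplets > n_mirna)
    stopf("n_triplets (%d) exceeds n_mirna (%d): each planted triplet needs its own miRNA",
          n_triplets, n_mirna)
  if (n_triplets > min(n_mrna, n_lncrna))
    stopf("n_triplets exceeds available mRNAs or lncRNAs")
  check_prob(prop_de, "prop_de")
  structure(cfg, class = c("cernaSimConfig", "list"))
}

#' Draw negative-binomial counts by a Gamma-Poisson mixture
#'
#' `variance = mean + dispersion * mean^2`; `dispersion = 0` degenerates to
#' Poisson and `mean = 0` to a point mass at zero.
#'
#' @param mean expected count (>= 0).
#' @param dispersion NB dispersion phi (>= 0). May be length 1 or `n`.
#' @param n number of draws.
#' @return integer vector of `n` counts.
#' @examples
#' simulateCounts(100, 0.5, 5)
#' @export
simulateCounts <- function(mean, dispersion, n) {
  if (any(mean < 0)) stopf("mean must be >= 0")
  if (any(dispersion < 0)) stopf("dispersion must be >= 0")
  if (n < 1) stopf("n must be >= 1")
  mu <- rep_len(mean, n)
  phi <- rep_len(dispersion, n)
  lambda <- mu
  idx <- phi > 0 & mu > 0
  if (any(idx))
    lambda[idx] <- rgamma(sum(idx), shape = 1 / phi[idx],
                          rate = 1 / (mu[idx] * phi[idx]))
  rpois(n, lambda)
}

#' Temporal prototype shapes
#'
#' Stage-mean multiplier vectors for the four temporal patterns the
#' clustering stage is expected to recover (up, down, a peak at stage 2, a
#' peak at stage 3) plus the flat null. Shapes are two-level steps from 1 to
#' `effect`: the up shape is non-decreasing and ends at `effect`, down is its
#' mirror, and the peak shapes are unimodal with maximum `effect` at the
#' stated stage. Step shapes (rather than linear ramps) keep adjacent-stage
#' log2 fold changes of planted features comfortably above the |log2FC| > 1
#' calling threshold.
#'
#' @param n_stages number of stages (>= 2; peaks are placed at stages 2 and
#'   3, or at the last stage when fewer exist).
#' @param effect multiplicative effect size (>= 1).
#' @return named list of positive numeric vectors of length `n_stages`.
#' @examples
#' prototypeProfiles(4, effect = 4)
#' @export
prototypeProfiles <- function(n_stages = 4, effect = 4) {
  if (n_stages < 2) stopf("n_stages must be >= 2")
  if (effect < 1) stopf("effect must be >= 1")
  lo <- floor(n_stages / 2)
  up <- c(rep(1, lo), rep(effect, n_stages - lo))
  peak_at <- function(p) {
    v <- rep(1, n_stages)
    v[p] <- effect
    v
  }
  list(up = up,
       down = rev(up),
       peak2 = peak_at(min(2L, n_stages)),
       peak3 = peak_at(min(3L, n_stages)),
       flat = rep(1, n_stages))
}

# --- sequence construction ---------------------------------------------------

# Minimum target-site expectation of any catalog miRNA against `sequence`
# (Inf when the sequence is shorter than every miRNA).
min_site_expectation <- function(sequence, mirnas) {
  if (length(mirnas) == 0) return(Inf)
  min(vapply(mirnas, function(m) {
    sc <- scan_scores(m, sequence)
    if (length(sc) == 0) Inf else min(sc)
  }, numeric(1)))
}

# A random sequence rejected until it contains no target site for any
# catalog miRNA (expectation <= cutoff) and, if asked, no coding ORF.
background_seq <- function(len, mirnas, noncoding = FALSE, cutoff = 5,
                           max_tries = 50) {
  for (i in seq_len(max_tries)) {
    s <- random_seq(len)
    if (min_site_expectation(s, mirnas) <= cutoff) next
    if (noncoding && codingPotential(s)$label == "coding") next
    return(s)
  }
  stopf("could not sample a site-free%s background sequence of length %d",
        if (noncoding) " non-coding" else "", len)
}

insert_site <- function(sequence, site) {
  n <- nchar(sequence)
  w <- nchar(site)
  pos <- sample.int(n - w + 1L, 1L)
  paste0(substr(sequence, 1, pos - 1L), site,
         substr(sequence, pos + w, n))
}

make_mrna_seq <- function(mirnas, site = NULL) {
  cod <- non_stop_codons()
  repeat {
    utr5 <- background_seq(sample(100:300, 1), mirnas)
    orf <- paste0("ATG",
                  paste(sample(cod, sample(150:350, 1), replace = TRUE),
                        collapse = ""),
                  "TAA")
    utr3 <- background_seq(sample(150:400, 1), mirnas)
    if (!is.null(site)) utr3 <- insert_site(utr3, site)
    s <- paste0(utr5, orf, utr3)
    cp <- codingPotential(s)
    if (cp$label != "coding") next                # paranoia; ORF is planted
    if (is.null(site) && min_site_expectation(s, mirnas) <= 5) next
    return(s)
  }
}

make_lncrna_seq <- function(mirnas, site = NULL) {
  repeat {
    s <- background_seq(sample(400:1200, 1), mirnas, noncoding = TRUE)
    if (!is.null(site)) s <- insert_site(s, site)
    cp <- codingPotential(s)
    if (cp$label == "coding") next
    return(s)
  }
}

# --- the generator -----------------------------------------------------------

#' Generate a synthetic staged ceRNA dataset with planted truth
#'
#' Produces a [CernaSimulation-class]: a two-chromosome annotation, transcript
#' and mature-miRNA sequences, an NB count matrix for mRNAs+lncRNAs, an
#' RPM-scale miRNA abundance matrix, a term-to-gene map, and truth tables.
#'
#' Planted structure: each of `n_triplets` ceRNA triplets pairs one dedicated
#' miRNA with one lncRNA and one mRNA that both carry an exact
#' reverse-complement site of that miRNA; the two sponges share a temporal
#' prototype and the miRNA carries the mirror prototype, so at moderate
#' effect size and low dispersion the triplet satisfies the correlation
#' filter (Spearman rho < -0.6 for miRNA-sponge, Pearson r > 0.6 for
#' lncRNA-mRNA). All other transcripts are rejection-sampled to be free of
#' target sites for every catalog miRNA; lncRNAs additionally to be
#' non-coding. `n_cis_pairs` lncRNA-gene neighbours are placed at recorded
#' distances <= 10 kb and as many decoy neighbours beyond 10 kb; all other
#' neighbouring features are > 10 kb apart.
#'
#' @param config a [cernaSimConfig()].
#' @return a [CernaSimulation-class] object.
#' @examples
#' sim <- simulateCernaDataset(cernaSimConfig(n_mrna = 12, n_lncrna = 6,
#'   n_mirna = 2, n_triplets = 1, n_cis_pairs = 1, seed = 1))
#' sim
#' @export
simulateCernaDataset <- function(config) {
  if (!inherits(config, "cernaSimConfig"))
    stopf("config must come from cernaSimConfig()")
  set.seed(config$seed)
  cfg <- config
  stages <- stage_labels(cfg$n_stages)
  n_samp <- cfg$n_stages * cfg$n_reps
  sample_ids <- paste0("S", seq_len(n_samp))
  stage_of <- rep(stages, each = cfg$n_reps)
  rep_of <- rep(seq_len(cfg$n_reps), cfg$n_stages)

  mrna_ids <- sprintf("gene_%03d", seq_len(cfg$n_mrna))
  lnc_ids <- sprintf("lnc_%03d", seq_len(cfg$n_lncrna))
  mir_ids <- sprintf("mir_%03d", seq_len(cfg$n_mirna))

  # -- miRNA catalog
  mir_seqs <- character(cfg$n_mirna)
  while (anyDuplicated(mir_seqs <- replicate(cfg$n_mirna,
                                             random_seq(cfg$mirna_len)))) {}
  names(mir_seqs) <- mir_ids

  # -- prototype assignment
  proto <- prototypeProfiles(cfg$n_stages, cfg$effect_size)
  proto_of <- c(setNames(rep("flat", cfg$n_mrna), mrna_ids),
                setNames(rep("flat", cfg$n_lncrna), lnc_ids),
                setNames(rep("flat", cfg$n_mirna), mir_ids))
  tri <- data.frame(lncrna_id = character(0), mirna_id = character(0),
                    mrna_id = character(0), stringsAsFactors = FALSE)
  if (cfg$n_triplets > 0) {
    tri <- data.frame(lncrna_id = lnc_ids[seq_len(cfg$n_triplets)],
                      mirna_id = mir_ids[seq_len(cfg$n_triplets)],
                      mrna_id = mrna_ids[seq_len(cfg$n_triplets)],
                      stringsAsFactors = FALSE)
    sponge_shape <- rep(c("up", "down"), length.out = cfg$n_triplets)
    mir_shape <- ifelse(sponge_shape == "up", "down", "up")
    proto_of[tri$lncrna_id] <- sponge_shape
    proto_of[tri$mrna_id] <- sponge_shape
    proto_of[tri$mirna_id] <- mir_shape
  }
  # non-planted DE features (a minority; the rest stay flat nulls)
  free <- setdiff(c(mrna_ids, lnc_ids), c(tri$mrna_id, tri$lncrna_id))
  n_free_de <- round(cfg$prop_de * length(free))
  if (n_free_de > 0) {
    de_feats <- sample(free, n_free_de)
    proto_of[de_feats] <- rep(c("up", "down", "peak2", "peak3"),
                              length.out = n_free_de)
  }

  # -- expression matrices
  depth <- exp(rnorm(n_samp, 0, 0.1))            # library-depth wobble
  stage_idx <- match(stage_of, stages)
  mean_matrix <- function(ids) {
    base <- exp(rnorm(length(ids), cfg$baseline_log_mean, 0.5))
    t(vapply(seq_along(ids), function(i) {
      base[i] * proto[[proto_of[ids[i]]]][stage_idx] * depth
    }, numeric(n_samp)))
  }
  mu_rna <- mean_matrix(c(mrna_ids, lnc_ids))
  counts <- matrix(0L, nrow(mu_rna), n_samp,
                   dimnames = list(c(mrna_ids, lnc_ids), sample_ids))
  for (i in seq_len(nrow(mu_rna)))
    counts[i, ] <- simulateCounts(mu_rna[i, ], cfg$dispersion, n_samp)

  mu_mir <- mean_matrix(mir_ids)
  mir_abund <- mu_mir
  if (cfg$dispersion > 0)
    mir_abund <- mu_mir * matrix(rgamma(length(mu_mir),
                                        shape = 1 / cfg$dispersion,
                                        rate = 1 / cfg$dispersion),
                                 nrow(mu_mir), n_samp)
  dimnames(mir_abund) <- list(mir_ids, sample_ids)

  # -- sequences (targets carry an exact reverse-complement site)
  site_of <- setNames(vapply(mir_seqs, rev_comp, character(1)), mir_ids)
  seqs <- character(cfg$n_mrna + cfg$n_lncrna)
  names(seqs) <- c(mrna_ids, lnc_ids)
  mrna_site <- setNames(rep(NA_character_, cfg$n_mrna), mrna_ids)
  lnc_site <- setNames(rep(NA_character_, cfg$n_lncrna), lnc_ids)
  if (cfg$n_triplets > 0) {
    mrna_site[tri$mrna_id] <- site_of[tri$mirna_id]
    lnc_site[tri$lncrna_id] <- site_of[tri$mirna_id]
  }
  for (id in mrna_ids)
    seqs[id] <- make_mrna_seq(mir_seqs,
                              if (is.na(mrna_site[id])) NULL else mrna_site[id])
  for (id in lnc_ids)
    seqs[id] <- make_lncrna_seq(mir_seqs,
                                if (is.na(lnc_site[id])) NULL else lnc_site[id])

  # -- genomic placement
  placement <- place_features(cfg, mrna_ids, lnc_ids, nchar(seqs))
  ann <- placement$granges
  S4Vectors::mcols(ann)$class_code <-
    ifelse(names(ann) %in% mrna_ids, "=",
           sample(c("u", "i", "x", "o"), length(ann), replace = TRUE))
  S4Vectors::mcols(ann)$biotype <-
    ifelse(names(ann) %in% mrna_ids, "mRNA", "lncRNA")
  S4Vectors::mcols(ann)$exon_count <- ifelse(
    names(ann) %in% mrna_ids,
    ifelse(runif(length(ann)) < 0.27, 1L, sample(2:10, length(ann), TRUE)),
    ifelse(runif(length(ann)) < 0.74, 1L, 2L))
  S4Vectors::mcols(ann)$tx_length <- nchar(seqs[names(ann)])

  # -- truth tables
  comparisons <- paste0(stages[-cfg$n_stages], "_vs_", stages[-1])
  de_rows <- lapply(seq_len(cfg$n_stages - 1), function(k) {
    ids <- names(proto_of)
    lfc <- vapply(ids, function(id) {
      p <- proto[[proto_of[id]]]
      log2(p[k + 1] / p[k])
    }, numeric(1))
    data.frame(feature_id = ids, comparison = comparisons[k],
               true_lfc = lfc, true_de = abs(lfc) > 1,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  de_status <- do.call(rbind, de_rows)

  # -- term map: one term covering the up-prototype mRNAs, plus random terms
  up_genes <- mrna_ids[proto_of[mrna_ids] == "up"]
  term_map <- data.frame(term_id = character(0), gene_id = character(0))
  if (length(up_genes) >= 1)
    term_map <- data.frame(term_id = "TERM_up_wave", gene_id = up_genes,
                           stringsAsFactors = FALSE)
  for (k in seq_len(5)) {
    g <- sample(mrna_ids, min(cfg$n_mrna, sample(8:15, 1)))
    term_map <- rbind(term_map,
                      data.frame(term_id = sprintf("TERM_rand_%02d", k),
                                 gene_id = g, stringsAsFactors = FALSE))
  }

  cdat <- S4Vectors::DataFrame(stage = stage_of, replicate = rep_of,
                               row.names = sample_ids)
  se_rna <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cdat,
    metadata = list(unit = "counts"))
  se_mir <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mir_abund), colData = cdat,
    metadata = list(unit = "RPM"))

  truth <- list(planted_triplets = tri,
                prototype_of = proto_of,
                de_status = de_status,
                cis_pairs = placement$cis_pairs)

  methods::new("CernaSimulation",
               annotation = ann,
               transcripts = Biostrings::DNAStringSet(seqs),
               matureMirna = Biostrings::DNAStringSet(mir_seqs),
               rnaCounts = se_rna,
               mirnaAbundance = se_mir,
               termMap = term_map,
               truth = truth,
               config = unclass(cfg))
}

# Lay features on two chromosomes: planted cis pairs at gap <= 10 kb, decoy
# pairs just beyond, everything else separated by > 10 kb.
place_features <- function(cfg, mrna_ids, lnc_ids, lengths) {
  window <- 10000L
  n_pair <- cfg$n_cis_pairs
  if (2L * n_pair > min(length(lnc_ids), length(mrna_ids)))
    stopf("n_cis_pairs too large for the number of lncRNAs/genes")
  # planted pairs use the tail of each id list so triplet members (head of
  # the lists) keep generic placements
  lnc_in <- rev(lnc_ids)[seq_len(n_pair)]
  gene_in <- rev(mrna_ids)[seq_len(n_pair)]
  lnc_out <- rev(lnc_ids)[n_pair + seq_len(n_pair)]
  gene_out <- rev(mrna_ids)[n_pair + seq_len(n_pair)]

  ids <- c(mrna_ids, lnc_ids)
  paired <- c(lnc_in, gene_in, lnc_out, gene_out)
  singles <- setdiff(ids, paired)

  chrom_names <- names(cfg$chrom_lengths)
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_along(cfg$chrom_lengths))
  cur_chr <- 1L
  cursor <- 1L
  chrom <- character(0); starts <- integer(0); placed <- character(0)

  advance <- function(need) {
    # move to the next chromosome when the current one cannot hold `need` bp
    while (cursor + need - 1L > cfg$chrom_lengths[cur_chr]) {
      if (cur_chr >= length(cfg$chrom_lengths))
        stopf(paste("synthetic chromosomes too short to place all features:",
                    "need %d bp more on %s; increase chrom_lengths"),
              need, chrom_names[cur_chr])
      cur_chr <<- cur_chr + 1L
      cursor <<- 1L
    }
  }
  put <- function(id) {
    advance(lengths[id])
    chrom <<- c(chrom, chrom_names[cur_chr])
    starts <<- c(starts, cursor)
    placed <<- c(placed, id)
    cursor <<- cursor + lengths[id] - 1L
  }
  gap_then <- function(gap) cursor <<- cursor + gap + 1L

  cis <- data.frame(lncrna_id = character(0), gene_id = character(0),
                    distance = integer(0), within_window = logical(0),
                    stringsAsFactors = FALSE)
  spacing <- function() sample(15000:30000, 1)
  for (i in seq_len(n_pair)) {
    d_in <- sample(200:window, 1)
    advance(lengths[lnc_in[i]] + d_in + lengths[gene_in[i]] + 1L)
    put(lnc_in[i]); gap_then(d_in); put(gene_in[i])
    gap_then(spacing())
    cis <- rbind(cis, data.frame(lncrna_id = lnc_in[i], gene_id = gene_in[i],
                                 distance = d_in, within_window = TRUE))
    d_out <- sample((window + 1L):(window + 5000L), 1)
    advance(lengths[lnc_out[i]] + d_out + lengths[gene_out[i]] + 1L)
    put(lnc_out[i]); gap_then(d_out); put(gene_out[i])
    gap_then(spacing())
    cis <- rbind(cis, data.frame(lncrna_id = lnc_out[i], gene_id = gene_out[i],
                                 distance = d_out, within_window = FALSE))
  }
  for (id in singles) {
    put(id)
    gap_then(spacing())
  }

  ord <- match(ids, placed)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[ord],
    ranges = IRanges::IRanges(start = starts[ord],
                              width = lengths[ids]),
    strand = rep(c("+", "-"), length.out = length(ids)))
  names(gr) <- ids
  GenomeInfoDb_seqlengths(gr) <- cfg$chrom_lengths[unique(chrom[ord])]
  list(granges = gr, cis_pairs = cis)
}

# thin indirection so we do not Import GenomeInfoDb directly (it ships with
# GenomicRanges); failing to set seqlengths is harmless for the GFF3 export
GenomeInfoDb_seqlengths <- function(gr) gr
`GenomeInfoDb_seqlengths<-` <- function(gr, value) {
  try(suppressWarnings(GenomicRanges::seqlengths(gr) <- value), silent = TRUE)
  gr
}

#' Write a simulated dataset to plain-text files
#'
#' Emits GFF3 annotation (class code and biotype as attributes), transcript
#' and mature-miRNA FASTA, TSV count/abundance matrices
#' (`feature_id<TAB>S1...`), a sample sheet, the term map and the truth
#' tables. Output is deterministic: the same simulation writes byte-identical
#' files.
#'
#' @param sim a [CernaSimulation-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  ann <- simAnnotation(sim)
  S4Vectors::mcols(ann)$type <- "transcript"
  S4Vectors::mcols(ann)$ID <- names(ann)
  rtracklayer::export(ann, p("annotation.gff3"), format = "gff3")
  Biostrings::writeXStringSet(simSequences(sim), p("transcripts.fa"))
  Biostrings::writeXStringSet(simMature(sim), p("mature_mirna.fa"))

  write_mat <- function(se, assay, file) {
    m <- SummarizedExperiment::assay(se, assay)
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(simCounts(sim), "counts", p("counts_rna.tsv"))
  write_mat(simMirna(sim), "abundance", p("abundance_mirna.tsv"))

  cd <- SummarizedExperiment::colData(simCounts(sim))
  write.table(data.frame(sample_id = rownames(cd),
                         stage = cd$stage, replicate = cd$replicate),
              p("samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(simTermMap(sim), p("term2genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tr <- simTruth(sim)
  write.table(tr$planted_triplets, p("truth_triplets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(feature_id = names(tr$prototype_of),
                         prototype = unname(tr$prototype_of)),
              p("truth_prototypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tr$de_status, p("truth_de_status.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tr$cis_pairs, p("truth_cis_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c(annotation = p("annotation.gff3"), transcripts = p("transcripts.fa"),
             mature = p("mature_mirna.fa"), counts = p("counts_rna.tsv"),
             mirna = p("abundance_mirna.tsv"), samples = p("samples.tsv"),
             term2genes = p("term2genes.tsv"),
             truth_triplets = p("truth_triplets.tsv"),
             truth_prototypes = p("truth_prototypes.tsv"),
             truth_de = p("truth_de_status.tsv"),
             truth_cis = p("truth_cis_pairs.tsv"))
  invisible(files)
}
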