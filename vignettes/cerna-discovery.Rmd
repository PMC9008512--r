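---
title: "ceRNA network discovery in staged transcriptomes: models and choices"
author: "ceRNAflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNA network discovery: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAflow)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The running design is a staged bud-development
experiment: four stages (ST1 vegetative, ST2 initial differentiation,
ST3-1/ST3-2 early and late exuberant differentiation), three biological
replicates each, strand-specific RNA-seq for mRNA/lncRNA and small-RNA-seq
for miRNAs.

## The ceRNA model and its filters

A candidate ceRNA triplet is a lncRNA, a miRNA, and an mRNA where the miRNA
has a predicted target site in *both* RNAs. Sequence evidence alone
over-generates candidates, so expression evidence across all samples is
required as well: the miRNA must be anti-correlated with both sponges
(Spearman ρ < −0.6 for each) and the sponges co-expressed (Pearson
r > 0.6). All three inequalities are strict: a correlation exactly at a
threshold fails, and an undefined correlation (a constant profile) fails
rather than passes. `filterTriplets()` computes the statistics per triplet
and `tripletPasses()` is the rule itself; the assembled `CeRNANetwork`
counts unique nodes by type and unique (miRNA, target) edges — the
lncRNA–mRNA co-expression link is deliberately *not* an edge, which is why
a single triplet contributes 3 nodes but only 2 edges.

Two choices here were genuinely open:

- **Which samples enter the correlations.** The source analysis style
  integrates DE features of one stage comparison but does not say whether
  correlations use all libraries or only the compared stages. We default to
  all shared samples (more points stabilise rank correlations; a `samples`
  argument restricts if wanted).
- **Scale for the Pearson correlation.** Spearman is scale-free, but
  Pearson is not; we apply log2(x+1) to the two RNA profiles by default
  (`log_pcc = FALSE` switches to raw), the standard variance-stabilising
  choice for FPKM-scale data.

## The lncRNA cascade

`classifyTranscripts()` keeps a transcript as lncRNA iff (1) its GffCompare
class code is u, i, x or o; (2) its spliced length is strictly greater than
200 nt (a 200-nt transcript is rejected; we read the ">200" rule against
the spliced transcript length, not the genomic span); and (3) an ORF-based
coding-potential rule calls it non-coding. The rule — coding iff the
longest forward-frame ORF (in-frame ATG...stop) reaches `min_orf_aa = 100`
amino acids **or** covers `min_coverage = 0.5` of the transcript — is a
deliberately simple, fully specified stand-in for external
CPC/CNCI/Pfam-style classifiers. It preserves the cascade's logical shape
(intersection of non-coding calls) and is exactly testable; it does not
model hexamer composition or protein domains, so on real data its calls
will differ from those tools. Failing transcripts are labelled `other`,
never dropped.

Small-RNA cataloguing (`catalogSmallRNA()`) discards reads under 18 nt and
calls a read conserved when it matches a known mature miRNA of equal
length at Hamming distance ≤ 1 — ungapped, mirroring one-mismatch
short-read alignment; ties go to the lowest mismatch count, then the
lexicographically smallest mature id. The descriptive lncRNA-vs-mRNA
comparison (`summarizeFeatures()`) uses Welch's two-sample t-test on GC
content rather than the pooled-variance test: group variances are unknown
and Welch is the safe default; on well-separated groups the difference is
immaterial.

## Differential expression

`deTest()` is a self-contained negative-binomial Wald test that preserves
the calling contract |log₂FC| > 1 and BH-adjusted p < 0.05:

- size factors by median-of-ratios, falling back to column-sum ratios when
  no feature is positive in all samples;
- log₂ fold change of normalized group means with a pseudocount of 0.5
  (numerical stability near zero; exposed as `pseudo`);
- per-feature method-of-moments dispersion `(s² − μ)/μ²` pooled across the
  two groups, then **guarded from below by the experiment-wide median**
  estimate and floored at 1e-8;
- Wald statistic log₂FC / SE with a delta-method SE under NB variance
  μ + φμ², two-sided normal p-value; all-zero features report
  log₂FC = 0, p = 1.

The median guard is the package's main numerical choice. With three
replicates the per-feature variance estimate has two degrees of freedom;
features whose within-group variance happens to come out near zero get
enormous Wald statistics, and the raw-p null rate inflates to ~11 %.
Guarding each feature's dispersion by the experiment-wide median (the
"maximum" sharing idea of early DESeq, not an empirical-Bayes shrinkage)
restores calibration to ~5 % without borrowing any between-group signal —
the guard is computed from within-group variances only, so planted effects
do not inflate it. Gene lists will still not match DESeq2's exactly: there
is no trend fitting, no LFC shrinkage, no Cook's filtering, no independent
filtering. The three adjacent-stage comparisons (ST1 vs ST2, ST2 vs ST3-1,
ST3-1 vs ST3-2) are the default; `deTest()` accepts arbitrary groups.

"Adjusted p-value" is read as Benjamini–Hochberg (`adjustBH()`), the only
defensible interpretation for a DESeq2-style workflow.

## Temporal clustering

`fuzzyCMeans()` is standard fuzzy c-means with Euclidean distance on
row-standardized (mean 0, population SD 1) stage means — stage means, not
all twelve samples, because the temporal pattern lives on the four-point
stage axis. Constant rows cannot be standardized and are excluded with a
flag. Details that matter:

- memberships `u_ij = 1/Σ_l (d_ij/d_il)^(2/(m−1))`; a point coinciding
  with a centre takes membership 1 there (split equally over coincident
  centres);
- the objective `Σ u^m d²` is asserted non-increasing at every iteration —
  a violated assertion is a bug, not a warning;
- initialization is k-means++-style seeding from data rows under a fixed
  seed with 10 restarts, best objective kept, making results reproducible
  even though the algorithm itself is only locally convergent;
- convergence when the largest centre shift drops below `tol = 1e-6`.

k = 4 mirrors the four temporal patterns of the motivating analysis and is
exposed, not inferred; `estimateFuzzifier()` implements the
Schwämmle–Jensen rule for the fuzzifier, clipped to [1.05, 3]. The
pipeline default is m = 1.25: the planted prototypes are step-shaped and
well separated after standardization, where a low fuzzifier (near the hard
k-means limit) gives crisp, reproducible assignments; the rule-based m is
available for flatter, noisier data. Hard labels (`assignClusters()`) use
argmax membership with a 0.5 floor, ties to the lowest cluster index.

## Target assignment

`scanTargets()` slides the reverse complement of the miRNA (18–26 nt)
ungapped along the transcript. Penalties per aligned position: 0 for a
Watson–Crick match, 0.5 for a G:U wobble, 1 for a mismatch, doubled at
miRNA positions 2–13 — the seed-weighted schema of plant target predictors.
The expectation score is the total penalty; the best site (plus ties) is
reported when expectation ≤ 5 (inclusive). The ungapped scan trades
psRNATarget's gapped alignment for determinism and exact
brute-force-verifiability; bulges are not modelled.

`cisPairs()` pairs lncRNAs with genes on the same chromosome whose
1-based inclusive intervals are within 10 kb — the gap between [a₁,b₁] and
[a₂,b₂] with b₁ < a₂ is a₂ − b₁ − 1, overlap counts as 0, and the 10 kb
boundary is inclusive. Distances are measured between interval ends (the
motivating text does not say ends or TSS; ends are the symmetric choice),
strand is ignored for distance, and the upstream/downstream relation is
read from the lncRNA's strand.

`transPairs()` scores the best ungapped antiparallel alignment of the two
transcripts over all offsets (overlap at least `window = 40` nt) with
per-pair energies G:C = −3, A:U = −2, G:U = −1 in arbitrary units — a
complementarity screen standing in for lncTar's thermodynamic model, with
`ndg = dg / min(length)` and an inclusive threshold of −0.1. Because
energies are non-positive, the best alignment is always a full diagonal
overlap. This stand-in ranks pairing strength sensibly but is *not* a free
energy; random sequence pairs of typical length routinely pass the default
threshold, so trans hits should be read as a permissive candidate list
(and the pipeline caps the scanned combinations via `trans_max_pairs`).

## Enrichment

`enrichTerms()` is a hypergeometric upper-tail over-representation test
(`hypergeomUpper()`, computed in log space via the stable tail of the
hypergeometric distribution) with BH adjustment across tested terms. The
significance flag follows the source convention of a raw p < 0.05; the
adjusted value is always reported alongside. The background defaults to
all expressed genes.

## What the generator emulates — and what it does not

`simulateCernaDataset()` plants every signal the pipeline is supposed to
find. Counts are Gamma–Poisson (NB) with variance μ + φμ²; per-sample
depth factors (log-normal, σ = 0.1) make size-factor normalisation do real
work; miRNA abundances are emitted directly on RPM scale with matched
multiplicative noise, since the downstream stages consume RPM. Temporal
prototypes are two-level step shapes — up = (1, 1, e, e), down mirrored,
peaks at stages 2 and 3 — rather than linear ramps: a linear 1→4 ramp
never exceeds |log₂FC| = 1 between adjacent stages, so its "DE" features
would be undetectable under the calling contract by construction; step
shapes keep planted truth and the DE contract consistent. Flat features
are the majority class (default 70 % of non-planted features) so null
behaviour is testable. Planted triplets pair two step-up sponges with a
step-down miRNA (or mirrored), which yields stage-driven sample
correlations comfortably past the ±0.6 thresholds at effect 4 and
dispersion ≤ 0.05. Target truth is unambiguous: planted sites are perfect
21-nt reverse complements, and every non-target transcript is
rejection-sampled until it contains no site at expectation ≤ 5 for any
catalog miRNA (lncRNAs additionally until the ORF rule calls them
non-coding). Cis pairs are placed at recorded gaps ≤ 10 kb, decoy
neighbours just beyond, and all other neighbours > 10 kb apart.

Deliberately not emulated: read-level data (FASTQ), splice isoforms,
multi-exon genomic structure (exon counts are bookkeeping for the
descriptive summary; genomic span equals transcript length), sequence
evolution, library-composition biases, and overdispersion heterogeneity
across features (one φ for all). Within-stage biological variance across
trees is unknown in the motivating design, so dispersion is a free
parameter (default 0.05). Passing tests therefore demonstrate the
*logic* of the pipeline — filters, statistics, integration, boundary
semantics — on data matching its assumptions, not performance on real
tissue, where dispersion trends, mapping artefacts and incomplete
annotations dominate.

## Degenerate inputs and tie-breaks

Empty candidate sets propagate as empty (never errors); transcripts
failing the cascade are labelled, not dropped; missing triplet members are
skipped with a warning listing them; all-zero DE features report p = 1;
constant profiles are excluded from clustering and fail the correlation
filter; site-score ties are all reported; assignment ties take the lowest
cluster index; conserved-read ties take the fewest mismatches, then the
smallest mature id; infeasible genomic placement (chromosome too short)
is a generation error naming the bottleneck.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest,
fixed sizes chosen to exercise every code path with stable statistics: the
end-to-end recovery run uses 200 RNA features (140 mRNA, 60 lncRNA), 12
miRNAs and 10 planted triplets at effect 4, dispersion 0.02; the null
calibration uses 2,000 flat NB features at μ = 100, φ = 0.1, 3 vs 3; the
cluster-recovery check uses 400 features, 100 per prototype, at noise SD
0.15 before standardization; oracle-equivalence checks use 50 random
miRNA–transcript pairs, 1,000 random correlation pairs, full
hypergeometric enumeration for all backgrounds up to N = 12, and 1,000
random p-vectors. These sizes are the package's reference conditions; all
of them scale up through the same interfaces.

## Known limitations

The coding-potential rule, the target scorer and the pairing-energy screen
are specified stand-ins, not reimplementations of CPC/CNCI, psRNATarget or
lncTar; on real data their calls will overlap with but not equal those
tools. The DE test is unshrunken and will be less powerful than DESeq2 at
marginal effects. The trans screen is permissive by construction. The
generator's step prototypes make cluster recovery easier than smooth
biological trajectories would be; treat the ARI checks as correctness
tests of the clustering machinery, not benchmarks.
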