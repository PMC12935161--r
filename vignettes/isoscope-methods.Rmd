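---
title: "Models and methods behind isoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind isoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscope)
```

isoscope compares a long-read transcriptome between two sample groups at
isoform resolution. Its inputs are a transcript annotation (GENCODE-dialect
GTF) and a matching transcript-by-sample matrix of raw counts; optionally a
genome FASTA (for ORF prediction) and user-supplied feature tables. This
vignette documents the statistical models, the numerical choices, and what the
synthetic data used for validation does and does not capture.

## Gene models and coordinates

All internal coordinates are 0-based half-open; the GTF boundary converts to
and from the on-disk 1-based inclusive convention. A transcript is an ordered
chain of disjoint exons on one strand, with an optional CDS chain contained in
the exons. Transcript coordinates run 5'→3' along the spliced sequence, so on
the minus strand the largest genomic exonic coordinate is offset 0. Three
primitives do all coordinate work: `genome_to_transcript()` /
`transcript_to_genome()` (mutually inverse bijections between exonic genomic
positions and `[0, spliced length)`), and `project_interval()` (splits a
transcript-space interval at exon junctions; it conserves length and never
emits intronic bases). Transcripts whose CDS length is not a codon multiple
are kept and flagged `cds_incomplete` rather than rejected, since reference
annotations contain such records.

For display, introns are compressed: `build_display_map()` computes, per
locus, a monotone piecewise-linear map in which exonic bases keep length
exactly and every intron collapses to a fixed width (default 100 display
units). The map is built on the **union** of exons across all isoforms of the
locus, not per isoform. This was a genuinely open choice; the union was
chosen because per-isoform compression would misalign isoforms vertically and
make the shared transcription-start-site guide lines meaningless on a common
axis.

## ORF prediction and coding potential

For transcripts lacking CDS annotation, `enumerate_orfs()` lists every
ATG-initiated reading frame per frame, running to the first in-frame stop or
to the transcript end (flagged 3'-incomplete). Only the 5'-most ATG per stop
is reported; the default minimum length is 75 nt. Codon matching is exact, so
`N` never matches ATG or a stop, and hexamers containing `N` are skipped in
scoring.

Coding potential combines four features in a logistic model
(`fit_coding_model()`):

* `log1p(orf_length)` — `log1p` rather than `log` so sequences with no
  candidate ORF (length 0) have finite features;
* ORF coverage (ORF length / transcript length);
* the Fickett TESTCODE statistic, computed with the published position and
  content lookup tables embedded as package constants;
* the mean in-frame hexamer log-odds under a trained table
  (`train_hexamer_table()`: in-frame counts from coding sequence, all-frame
  counts from noncoding, pseudocount 1).

No pre-trained model ships with the package; `run_orf()` trains on the
annotated transcripts of the input itself (CDS sequences feed the hexamer
table; full mRNA sequences feed the logistic model, so feature scales match
prediction-time candidates; transcripts of noncoding biotype, or shuffled
coding sequences when none exist, form the negative class). Under perfect
separation — common on clean training sets — the fit falls back to a lightly
ridge-penalized IRLS solution and says so. `select_orf()` takes the candidate
with the highest coding probability, breaking ties towards the longer and
then the 5'-most candidate, and annotates nothing below a probability
threshold (default 0.5). Written CDS records exclude the stop codon
(GENCODE convention).

Two derived attributes use the annotated or predicted CDS: `detect_uorf()`
reports an upstream ORF only when a complete ATG–stop frame of at least 9 nt
lies **fully** within the 5' UTR (uORFs overlapping the main CDS start are out
of scope, by design); `predict_nmd()` applies the literature-standard 50-nt
rule — the stop lies more than 50 nt upstream of the last exon–exon junction —
with single-exon transcripts never flagged. Where a reference annotation
already carries an NMD biotype, that attribute takes precedence in displays.

## Differential expression

`de_test()` implements a two-group transcript-level test:

1. **TMM normalization** (`tmm_factors()`): the reference sample is the one
   whose upper-quartile CPM is closest to the mean; per sample, the scaling
   factor is 2 to the weighted trimmed mean of gene-wise log2 ratios,
   trimming 30% of each M tail and 5% of each A tail, with inverse asymptotic
   variance weights; zero-containing pairs are excluded and factors are
   rescaled to geometric mean 1. The implementation agrees with an
   independently coded transcription of the formula to 1e-8 (and with edgeR's
   to machine precision in cross-checks).
2. **Filtering**: transcripts with unadjusted CPM > 1 in fewer than
   `min(group sizes)` samples are excluded before dispersion estimation and
   reported separately. The filter keeps dispersion fits stable on sparse
   transcripts.
3. **Dispersion estimation** (`estimate_dispersions()`): per transcript, a
   Cox–Reid-style adjusted profile likelihood is maximized over a fixed grid
   of 41 log-spaced points between 0.001 and 5, then shrunk on the log scale
   with weight 0.5 toward a trend of bin means over 20 abundance bins. The
   grid and weights are fixed so results are deterministic.
4. **Test**: an NB GLM with a group effect and `log(lib_size × factor)`
   offsets; the full-versus-null deviance difference is referred to an F
   distribution after empirical-Bayes moderation of the residual deviance
   variance (`limma::squeezeVar` with an abundance covariate). `log2fc` is
   case minus control, with the control group taken from the design file's
   first row unless overridden. Significance is `BH-adjusted p < 0.05` by
   default.

Validation is by simulation rather than bitwise agreement with any external
tool: under the generator's null (NB dispersion 0.1, 5 + 5 samples, ~2000
transcripts) the fraction of raw p below 0.05 stays within 0.05 ± 0.02 and the
p distribution is near-uniform; a planted four-fold shift is recovered with
median `log2fc` within 2 ± 0.3; swapping group labels negates `log2fc` and
leaves p unchanged to 1e-9. Only unpaired two-group designs are supported;
paired or multi-factor designs are a known limitation.

## Differential isoform usage

Within each gene with at least two expressed transcripts (genes with totals
below `min_gene_count` in more than half the samples are excluded and
reported; samples with zero gene totals are dropped per gene, not imputed),
counts over the k transcripts follow a Dirichlet-multinomial with proportions
π and precision (concentration) φ. `fit_dm()` maximizes the exact DM
log-likelihood by bounded quasi-Newton (L-BFGS-B with analytic gradients) on
logit-transformed proportions and log precision, from the deterministic start
(pooled proportions, φ = 10) with tolerance 1e-8 and bounds φ ∈ [1e-3, 1e8].

The gene-level test (`gene_lrt()`) compares a null with one shared proportion
vector against a full model with per-group proportions; φ is **shared between
groups under both hypotheses**, giving a likelihood-ratio statistic with
k − 1 degrees of freedom. Per-group precision is deliberately out of scope.
The transcript-level test collapses the gene to "this transcript vs the rest"
and applies the same 1-df LRT — the simplest construction that is symmetric
for k = 2 (both transcripts of a 2-isoform gene share one p-value).

`stagewise_correct()` controls the overall FDR in two stages: BH screening
across gene p-values at α, then, within screened genes only, a Holm–Šidák
family-wise adjustment of transcript p-values tested against the adjusted
level α × (screened genes) / (all genes). Transcripts of unscreened genes are
never confirmed and carry `NA` adjusted values. Δusage is the difference of
per-group mean per-sample proportions (case minus control), displayed as
percentage points; per gene it sums to zero by construction.

Simulation results at the documented conditions: gene-level type-I error
within 0.05 ± 0.03 (precision 50, 10 + 10 samples, depth 300, 500 genes); DM
proportion recovery within ±0.05 at 40 samples of depth 200; realized FDR of
the full two-stage procedure ≤ 0.08 over 20 replicate 10%-signal mixtures;
the gatekeeping invariant (confirmed ⇒ screened) holds in every replicate.

## Functional features

Positional features arrive in protein (1-based inclusive amino acids) or
transcript (0-based half-open nt) space. Protein intervals `[a, b]` map to
CDS-relative nucleotides `[3(a−1), 3b)` and then through the CDS chain to the
genome, splitting at junctions and conserving 3 nt per amino acid; features
running past an incomplete CDS are clipped and flagged. Non-positional
attributes are typed binary / categorical / continuous and validated against
their values. Merging writes positional features as extra GTF records (type =
kind, `feature_label`/`feature_source` attributes) and non-positional ones as
`np_<name>` transcript attributes — an encoding of this package's own design,
documented here because no standard exists — and the augmented GTF round-trips
losslessly. External domain/signal-peptide/NLS predictors are consumed only
through this TSV contract; wrapping their binaries is a non-goal.

## Figures

Every figure is first a **structured drawing model**: a tibble of typed
primitives (rectangles, segments, text) carrying roles, data values and
coordinates. Geometry tests read this model back directly — exon box widths
equal display lengths, usage bars sum to one per group, box-plot medians equal
recomputed medians — instead of inspecting pixels. SVG serialization is
deterministic (fixed-precision numbers, fonts by family reference, no
timestamps), so identical inputs give byte-identical files; one golden file
for the toy locus pins the full layout. PNG/PDF go through ggplot2
(`autoplot()`), and every panel's content is exportable as a tidy TSV for
headless use. Lane order is annotated-before-novel, then transcript id,
unless an explicit order is given. Expression box plots use log2 CPM (prior
0.5), stated on the axis; continuous feature bars are max-normalized per
column.

## Synthetic data

`sim_config()` / `simulate_annotation()` / `simulate_counts()` generate the
package's entire test bed; all simulations are bit-reproducible from the
config and seed. Gene loci share a core exon block across isoforms and vary
at the ends (alternative first/last exons, 5' truncation), so TSSs differ
while a planted ORF in the core is carried by every isoform. Coding sequence
is drawn with human-like codon-usage weights; all other exonic sequence is
scrubbed of ATG trinucleotides so the planted start is unambiguous ground
truth for frame-recovery scoring. Counts follow log-normal gene profiles, NB
noise on gene totals (dispersion 0.1 by default), DM isoform splits
(precision 50), planted fold changes of magnitude 2 and usage shifts of 0.3 —
the same conditions quoted in the validation numbers above. Default problem
sizes in the test suite (up to ~800 genes / 2000 transcripts for the DE null,
500 genes for LRT calibration, 20 replicates for FDR) were chosen as the
smallest sizes at which the Monte Carlo tolerances above are meaningful.

What the generator does **not** emulate: positional sequencing biases and ONT
error profiles, read-level uncertainty in transcript assignment,
genuinely novel splice structures (isoforms differ only in documented ways),
correlated library composition shifts, and paired tumor/normal designs.
Passing tests therefore demonstrate correctness of the statistical machinery
under its stated model, not robustness to every artifact of real long-read
data.

## The worked toy locus

`make_toy_locus()` is a fixed four-isoform gene with hand-written
coordinates, counts and domains that mimics a compensatory isoform switch:
usage moves from the long dominant isoform (control mean usage 0.40) to a
short isoform (0.10 → 0.40) while the gene's total output drops. Its every
derived number — Δusage of ±30 percentage points, log2 fold changes of ∓2,
the figure geometry — follows from constants by arithmetic, which makes it
the anchor for the golden-figure test and the README walk-through.
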