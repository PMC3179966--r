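---
title: "Detecting segmental duplications from shotgun read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting segmental duplications from shotgun read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssdr)
```

## The problem

Whole-genome shotgun assemblies systematically collapse recent segmental
duplications (SDs): two copies of a block with more than ~94% sequence
identity are frequently merged into a single assembled locus, while more
divergent copies assemble apart. Assembly-based duplication scans therefore
miss exactly the youngest, most identical duplications — the ones most
relevant for recent copy-number variation and gene-family expansion.

Read depth gives an assembly-independent signal. If the shotgun reads used
to build the assembly are aligned back to it, a locus that collapses `c`
copies into one receives roughly `c` times the expected read density. The
whole-genome shotgun sequence detection (WSSD) strategy exploits this:
count filtered alignment matches in windows over the assembly, calibrate the
single-copy depth distribution on loci known to be single copy, and call as
duplicated the regions whose windows are consistently in the upper tail.
`wssdr` implements this analysis end to end for any assembly + reads +
repeat-annotation triple, with a seeded simulator that generates genomes
with implanted duplications so every stage is testable without external
data.

## Repeat masking: three settings, two tracks

High-copy interspersed and tandem repeats would otherwise dominate the
depth signal, so alignment and windowing operate on a repeat-masked
assembly. Three masking settings are supported and compared:

* `div10_low` — tandem repeats plus interspersed repeats with **< 10%**
  divergence from their consensus, masked to lowercase;
* `nodiv_low` — all annotated repeats, masked to lowercase;
* `nodiv_N` — all annotated repeats, masked to `N`.

The divergence filter is strict: a repeat at exactly 10.0% divergence is
*not* masked under `div10_low`. Lowercase masking excludes masked sequence
from alignment seeding but lets alignments extend through it (matches with
≥ 200 bp of masked overlap are then discarded); `N` masking truncates
alignments outright. The package keeps **assembly gaps** (runs of ≥ 10 `N`
in the input assembly) on a separate track from the mask: windows extend
through masked repeats but are discarded at gaps, so the two must never be
confused — in particular under `nodiv_N`, where masked repeats also become
`N` characters in the emitted FASTA but remain windowable sequence.

The default setting is `nodiv_N`. On a genome rich in divergent repeat
families, leaving > 10%-divergent repeats unmasked (`div10_low`) inflates
depth wherever a family has recent, cross-alignable subfamily copies, and
this shows up as a much larger positive-window share
(`compare_masking_settings()` reproduces the effect on simulated data).

## Windows of unmasked bases (kub)

Depth is counted in windows containing exactly 1,000 **unmasked** bases
(1 kub), built by scanning each gap-delimited run left to right; a window's
genomic span includes any interposed masked bases, so spans lengthen where
masking is denser. A partial window hitting an assembly gap is discarded
and scanning restarts at the first unmasked base after the gap; a trailing
partial window is likewise discarded. Window spans partition each run: a
window's span begins where the previous span ended (at the run start, at
the run's first unmasked base), and masked sequence between two windows is
attributed to the following window's span. Five contiguous 1-kub windows
merge into one 5-kub window, sliding by one, so successive 5-kub windows
share four members; sliding never crosses a gap.

## Read QC, alignment, and depth

Reads are discarded when flagged low-quality/contaminated, when their
per-trace percent error exceeds 6.00, or when the high-quality portion is
shorter than 300 bp; survivors are clipped to the high-quality interval.

Alignment uses either an external aligner's tabular output
(`read_blast_tabular()`) or the built-in deterministic seed-and-extend
mapper (`map_reads()`): exact 32-mer seeds indexed over unmasked genome
positions, ungapped extension in both directions with an X-drop stop
(+1/−2 scoring, X = 20), trimmed to the maximum-scoring extent. Extension
never crosses an `N`; lowercase-masked sequence is extended through and
filtered afterwards by the masked-overlap rule. **All** qualifying matches
of a read are kept — multi-mapping is the signal, since reads from every
collapsed copy pile onto the single assembled locus. Matches must be
longer than 300 bp on the genome and at ≥ 93% identity; the stricter > 94%
identity of called duplications is enforced downstream by the depth
threshold, not by the aligner cutoff. A score cutoff in the style of an
aligner-specific bit-score threshold is deliberately not reimplemented:
the length and identity filters are the operative contract.

Each retained match increments the single 1-kub window whose span contains
its middle nucleotide (`start + floor((length − 1) / 2)`; for even lengths
the left-of-centre base — any fixed convention works, this one is stable
and documented). A 5-kub window's depth is the sum over its five members.

## Calibrating the single-copy depth distribution

Depths of the sliding 5-kub windows lying inside designated single-copy
calibration regions are fitted with a constrained mixture of four
Gaussians, components representing copy numbers 1–4:

$$ p(x) = \sum_{n=1}^{4} f_n\, \mathcal{N}\!\left(x;\; n\,\mu,\; \sqrt{n}\,\sigma\right), \qquad \sum_n f_n = 1 , $$

with only $\mu$ (`avg`), $\sigma$ (`sd`) and the fractions free. The
$\sqrt{n}$ scaling of component SDs reflects the Poisson-like growth of
depth variance with its mean; a `sqrt_scaling = FALSE` switch reverts to
linear $n\,\sigma$ scaling for comparison. The fit maximises the unbinned
log-likelihood directly (`stats::optim`, Nelder–Mead then a BFGS polish)
over log-transformed $\mu,\sigma$ and softmax-parameterised fractions,
multi-started from the histogram mode and the median; initial values are
$\mu_0$ = sample mode, $\sigma_0$ = 1.4826·MAD,
$f_0$ = (0.85, 0.10, 0.04, 0.01). The fit is deterministic given the data,
and `mixture_pulls()` reports binned normalised residuals
((N_data − N_fit)/√N_data, with N_fit an exact bin integral of the fitted
density) for display parity with binned-fit practice: pulls within ±3 mean
fluctuations are statistical. The likelihood treats the overlapping sliding
windows as independent; this is an acknowledged approximation shared with
the original analysis — it biases no parameter but overstates the effective
sample size.

Classification thresholds come from the first component: windows are
**negative** at depth ≤ avg + 2 sd, **borderline** up to avg + 3 sd, and
**positive** at depth ≥ avg + 3 sd. The boundary point avg + 3 sd is
assigned positive (the "greater than or equal" reading; a
`positive_inclusive = FALSE` switch gives the strict alternative — at
realistic depths the boundary set has measure zero, so the choice is
cosmetic, but it is fixed and documented).

The sanity check `implied_sequencing_coverage(read_len, avg, 5000)` ties
the fitted single-copy depth back to fold coverage: with 735-bp reads and
a single-copy 5-kub depth of 79.2, 735 × 79.2 / 5000 = 11.6×.

## Calling duplications: six of seven

Every run of seven consecutive 5-kub windows containing at least six
positives marks all seven as duplicated; the union of marked spans, merged
when overlapping or abutting, yields the called intervals, each reported
with its mean constituent depth. Borderline windows neither count toward
the six nor interrupt a call. Because seven overlapping 5-kub windows span
at least 11 kub of unmasked sequence, calls are ≥ 10 kb by construction and
no extra length filter is applied. Intervals never span an assembly gap,
since sliding stops there.

## What the simulator emulates — and what it does not

`synth_genome()` builds a genome with the statistical structure the
analysis assumes. The default desk-scale study condition is fixed at: a
5 Mb assembly in five sequences (three chromosomes, a `_random` contig and
a `chrUn`, so summary strata are exercised); GC 0.35; 20 duplications with
lognormal sizes (mode near 20 kb, clamped to 10–100 kb), copy number 2–4
with probabilities (0.60, 0.25, 0.15), copy identity uniform on
[94, 99.5]%; ~15% interspersed repeat content in six families with
consensus divergences around (2, 5, 8, 12, 18, 25)% and tight recent
subfamilies (~2% apart, so members of high-divergence families still
cross-align when unmasked — the mechanism that makes `div10_low`
permissive); tandem blocks; three assembly gaps of 5–20 kb; ten organelle
insertions copied from synthetic mitochondrial and plastid sequences; 500
genes; and 25 reserved 30-kb single-copy calibration regions emulating
FISH-validated single loci. Reads are drawn at 12× with truncated-normal
lengths (mean 735, sd 150, range 300–1,447 bp), substitution errors at
0.005/bp, and 1.26% of reads emitted with failing QC metadata — the
discard fraction observed in the reference bookkeeping. Every feature is
recorded in a truth table; all randomness flows from one seed through
named substreams, so stages are independently reproducible.

Deliberate idealisations, which bound what green tests prove about real
data: mutations are substitution-only (no indels), matching the ungapped
mapper; the background is i.i.d. random sequence, so there is no
compositional autocorrelation, GC bias, or unannotated repeat; calibration
regions are repeat-free, whereas real single-copy loci contain repeats;
read starts are uniform (no cloning or chemistry bias) and quality is a
sidecar summary, not per-base; the genome is haploid/homozygous. Real data
add alignment artefacts and annotation incompleteness that the simulator
cannot surface.

## Evaluating recovery

`evaluate_calls()` scores called intervals against the implanted truth at
base level. Sensitivity is the covered fraction of truth. For precision,
the truth is first dilated by the caller's localisation resolution: the
window-of-seven rule marks whole windows, so a call may legitimately
overhang a true edge by up to `k` member windows plus the straddling 1-kub
window — `(k + 1) × unit` **unmasked** bases, which converts to genomic
span as `(k + 1) × unit / (1 − masked fraction)`. With default parameters
and ~20% masking this is ≈ 7.5 kb per side. An explicit `boundary_tol`
overrides the derivation. Precision is scored against all implanted
duplications (a 94–96% identity copy is genuinely duplicated even when the
headline claim concerns ≥ 96%), sensitivity against the ≥ 96% subset.

At the default study condition the pipeline recovers implanted ≥ 96%
duplications with base-level sensitivity and precision well inside the
documented bounds (≥ 0.85 / ≥ 0.90), and single-copy mean 5-kub depth
matches `C × 5000 / L̄` within 5%; the test suite and
`scripts/acceptance.R` recompute these from scratch.

## Downstream summaries

Gene models (GFF3, 1-based inclusive, converted internally to the
package-wide 0-based half-open convention) are classified `full` when
entirely inside the union of merged intervals — a gene spanning two merged
abutting calls is full, since merging precedes the gene overlay —
`partial` on proper overlap, `unique` otherwise. Gene density is genes per
100 kb, over chromosome length or duplicated bp respectively. Genes on
`chrUn` are included by default (flag to exclude): unplaced sequence may
contain misassigned segments, and the tables stratify it separately.

Protein-domain enrichment retains InterProScan-style matches with status
`T` and a real InterPro accession, counts one occurrence per retained
match (a `per_gene` switch counts presence instead), and reports for each
domain the ratio of its fractional abundance among duplicated-peptide
matches to that among unique-peptide matches; domains absent from unique
peptides are listed separately as duplicated-only rather than given an
infinite factor.

Nuclear organelle DNA (NUMTs/NUPTs) is quantified from organelle-vs-
nucleus alignment hits at e-value ≤ 1e-4 as the per-class **union** of hit
intervals — each nucleotide counted once however many hits cover it, read
as "one or more hits" since genomic content is the quantity of interest —
reported per chromosome for the whole sequence and for its duplicated
fraction, the latter as a percentage of duplicated bp (the reading
consistent with per-SD percentage columns).

## Problem sizes and runtime

The shipped tests and the acceptance script use the 5 Mb default study
condition for the end-to-end checks (≈ 82,000 reads, ≈ 30 s for the full
pipeline on one core), 600 kb–1.2 Mb fixtures for the masking comparisons,
20 × 5,000 draws for mixture recovery, and hundreds of randomized small
cases for the oracle-equivalence properties. These sizes were chosen so
the whole suite runs comfortably on a laptop while every stage still
operates far from its trivial regime.

## Known limitations

* Ungapped alignment only; indel-rich duplications would fragment matches
  and lose depth. The BLAST tabular reader is the escape hatch.
* No SAM/BAM ingestion; alignments enter as tabular text or are computed
  internally.
* The mixture models copy numbers 1–4 only; a locus collapsed from many
  more copies is still called (its windows are positive) but its depth is
  not interpreted.
* Calibration quality is bounded by the supplied single-copy regions; the
  package validates only their window count, not their copy-number status.
* The window-of-seven caller's edge resolution (~one 5-kub span per side)
  is inherent to the method; boundaries of called intervals should be read
  with that granularity in mind.
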