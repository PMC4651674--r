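---
title: "Label-free quantification by spectral counting: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification by spectral counting: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spcquant implements a complete label-free quantitative shotgun-proteomics
analysis from peptide-spectrum-match (PSM) tables onward: target-decoy FDR
control, protein grouping, spectral counting, normalized spectral counts,
replicate filtering, differential expression, replicate concordance, GO
enrichment and protein pI/MW profiling. This vignette explains the models
behind each stage, the parameters that matter, and the design decisions
taken where the methodology left genuine freedom.

## The measurement model

Spectral counting treats the number of MS/MS spectra matched to peptides
of a protein (its spectral count, SpC) as a proxy for abundance. Longer
proteins yield more tryptic peptides, so raw counts confound abundance
with length. The normalized spectral count of protein $k$ in one sample is

$$\mathrm{NSpC}_k = \frac{\mathrm{SpC}_k / L_k}{\sum_{i=1}^{n} \mathrm{SpC}_i / L_i},$$

where $L_k$ is the protein (group) length in residues and the sum runs
over all $n$ proteins quantified in that sample. Each sample's NSpC column
is therefore a composition that sums to 1. `compute_nspc()` implements
exactly this, with an optional pseudocount added to every count first.

Compositionality has a consequence worth knowing: when a subset of
proteins genuinely increases, the shared denominator grows and every
other protein's NSpC drifts slightly downward. With strong asymmetric
spike-ins the differential-expression stage therefore tends to call more
proteins in the direction opposite to the dominant spikes than a
count-based model would. This is a property of the NSAF family of
normalizations itself, not of this implementation; tests on null
synthetic data (no spikes) confirm the t-test is calibrated when the
composition is stable.

## Target-decoy FDR

PSMs are ranked by search score; decoy PSMs (matches against reversed
sequences) estimate the number of incorrect target matches above any
threshold. At rank $r$, $\widehat{\mathrm{FDR}}(r) = d(r)/\max(1, t(r))$,
and the q-value of a PSM is the minimum estimated FDR over all ranks at
or below it, which is monotone by construction. Choices made here:

* **Estimator.** The plain $d/t$ ratio is the default; the more
  conservative $(d+1)/t$ variant is available via `estimator = "d1t"`.
* **Ties.** Equal scores rank decoys first — the conservative direction,
  so tied decoys penalize rather than flatter the estimate.
* **Scope.** FDR is controlled at PSM level only, over all pooled PSMs of
  the experiment; peptide- and protein-level error rates are out of scope.

## Protein grouping and counting

Only observed peptides carry inference weight. Accessions with identical
observed peptide sets are indistinguishable and merge; an accession whose
peptide set is a strict subset of another's adds no evidence of its own
and is subsumed. The result is maximal: no group's peptide set is a
strict subset of another group's. The representative is the member with
the most distinct peptides (ties: longer sequence, then lexicographic
accession), and its length serves as the group's $L_k$. When a subset
accession has several incomparable supersets the largest peptide set
wins, with ties broken by the would-be representative's accession — an
arbitrary but deterministic rule for a genuinely ambiguous situation.

Counting is deliberately redundant: a PSM increments every group that
contains any of its candidate accessions. Shared spectra are thus counted
in each matching group, so column totals can exceed the number of PSMs;
with no shared peptides the two are exactly equal (a tested invariant).
A configuration switch (`quantify_by = "accession"`) quantifies each
accession separately instead of by group.

## Replicate filter, concordance and differential expression

A protein enters comparative analysis only if, in at least one condition,
every replicate has at least `min_spc` (default 2) spectra — presence
consistency in *either* arm, so proteins cleanly on/off between
conditions are kept. Raising `min_spc` can only shrink the kept set.

Replicate concordance is summarized as the squared Pearson correlation of
NSpC vectors for every within-condition pair of replicates, on the linear
NSpC scale, averaged over pairs.

Differential expression tests each protein's natural-log NSpC between the
two conditions with a two-sided two-sample t-test. Defaults and why:

* **Pooled-variance (Student) test** by default; with three replicates a
  group, per-protein variance estimates are weak and the pooled form is
  the spreadsheet-era convention this analysis style comes from. Welch is
  one switch away.
* **Pseudocount 0.5** before the DE-stage normalization, so the log is
  defined for proteins absent from one condition (the filter only
  guarantees presence in one arm). Identification-stage NSpC uses
  pseudocount 0 so absent proteins report exactly 0.
* **Expression ratio** is the ratio of linear mean NSpC
  (treatment/control); `ratio_mode = "log"` switches to the geometric
  version. With a pseudocount floor, a protein seen only in treatment
  still yields a finite, large ratio.
* **Raw p-values** drive the increased/decreased calls at `alpha = 0.05`;
  a Benjamini–Hochberg column is always emitted for users who want
  multiplicity control, but does not change the calls.
* **Degenerate rows** (zero variance in both groups) are reported as
  t = 0, p = 1 when means agree, and p = 0 with infinite t when they do
  not, with a log message.

The pipeline normalizes the *filtered* count matrix, so the NSpC
denominator runs over the reproducible proteins being compared;
`compute_nspc()` itself is agnostic and normalizes whatever matrix it is
given, so callers can normalize over all identified proteins instead.

## GO enrichment

Enrichment of a query list against a background uses the one-sided
hypergeometric upper tail (one-sided Fisher test) per term, with BH
correction across terms. Annotations are assumed pre-propagated to
ancestors — the package performs no GO-DAG traversal, which keeps it free
of ontology files but means under-propagated annotation tables will
understate enrichment of general terms. By default the universe is
restricted to annotated background proteins, the convention of common
enrichment servers; `include_unannotated = TRUE` keeps the full
background in the urn. Terms annotating fewer than `min_term_size = 5`
background proteins are not tested.

## Molecular weight and isoelectric point

Molecular weight is the sum of average residue masses plus one water
(monoisotopic masses by flag); modifications are not modeled. The
isoelectric point uses the Henderson–Hasselbalch net-charge model with
the EMBOSS Pepstats default pKa set (N-terminus 8.6, C-terminus 3.6,
side chains C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1). Net
charge is strictly decreasing in pH, so the zero crossing is unique and
is found by bisection on [0, 14] to 1e-4 pH. Two consequences are tested
as oracles: a sequence with no ionizable side chains has
pI = (8.6 + 3.6)/2 = 6.1, and a single lysine gives (8.6 + 10.8)/2 = 9.7.
Cysteine is treated as ionizable even though alkylation in typical
experiments blocks it — that matches the plain Pepstats behaviour this
stage is modeled on, and a custom pKa set can be supplied to change it.
Sequences containing ambiguity codes (B, J, O, U, X, Z) get `NA` for both
quantities rather than a guessed mass.

## The synthetic experiment generator

`generate_experiment()` produces the full input bundle (PSM table, FASTA,
GO annotations, design, truth) from one seed. What it emulates:

* ~2,000 proteins, lengths log-uniform on 60–3,000 residues, random
  sequences with eukaryote-like residue frequencies;
* log-normal(0, 1) protein abundances; expected PSM count per protein
  proportional to abundance × length, scaled to ~30,000 correct PSMs per
  sample; integer counts drawn Poisson (negative-binomial via the
  `dispersion` knob);
* a two-condition × three-replicate design; 5% of proteins spiked at
  8-fold change, direction split evenly;
* tryptic-like peptides (cleaved after K/R, 6–30 residues observable),
  10% of peptides attributed to a second parent protein;
* a two-component score model: correct PSMs ~ Normal(30, 5), incorrect
  and decoy PSMs ~ Normal(15, 5), with 10% incorrect target PSMs and an
  equal expected number of decoy PSMs — the neutral choice under which
  the decoy count is an unbiased estimate of the incorrect-target count,
  as target-decoy theory assumes.

What it does **not** emulate: spectrum-level properties (retention time,
charge, fragmentation), score–peptide-property correlations, shared
peptides arising from true sequence homology (sharing is assigned at
random), batch effects, and the heavy-tailed overdispersion of real
spectral counts unless requested. Passing tests on this generator
therefore demonstrate the pipeline's statistical behaviour under its own
stated model, not performance on any particular instrument's output.

Fold-change recovery in counts is attenuated relative to the programmed
abundance ratio: scaling each sample to fixed depth divides treatment
expectations by the compositional inflation factor
$\sum a_{trt}L / \sum a_{ctrl}L$ (~1.15 under defaults), while ratio-of-
means estimates on Poisson counts carry a small upward bias at moderate
expectations; measured over seeds the spiked count ratio centres near
9 against a programmed 8, comfortably within the ±30% band the
generator's contract promises for well-covered proteins.

## Problem sizes and numerical conventions in the test suite

The validation suite regenerates everything in code. Stochastic
behaviour (realized PSM FDP ≤ 0.02 at q ≤ 0.01; null p ≤ 0.05 fraction in
[0.03, 0.07]; ≥ 80% sensitivity and ≥ 95% direction accuracy for 8-fold
spikes with mean SpC ≥ 10) is averaged over 20 generator seeds at the
default scale, the replication count at which these means are stable to
well within their acceptance bands. Exact oracles use term-by-term
transcriptions (NSpC to 1e-10), textbook formulas (pooled t-test to
1e-10), exact combinatorial enumeration (hypergeometric tails to 1e-12),
brute-force subset enumeration (grouping), and a 1e-6-step grid scan
(pI, to 1e-3 pH). Ties, degenerate inputs and empty cases follow the
conventions stated above; all-zero count columns with pseudocount 0 are
an error rather than a silent NaN.

## Limitations

* Spectral counting saturates for very abundant proteins and is noisy
  below ~5 counts; no saturation correction is applied.
* No protein-level FDR; the identification list inherits PSM-level
  control only.
* The t-test on three replicates has limited power for fold changes
  below ~2 at moderate counts; count-model alternatives (negative
  binomial GLMs, variance moderation) are deliberately out of scope.
* Reported enrichment p-values depend on the annotation snapshot and the
  background convention; with a different universe the same list can
  rank terms differently.
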