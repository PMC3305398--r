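---
title: "Methods: autozygosity mapping, splice-isoform estimation and gene dropping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autozygosity mapping, splice-isoform estimation and gene dropping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stuntscan)
```

## The problem

A recessive juvenile growth-stunting syndrome segregates in a closed,
artificial-insemination-heavy cattle population. Three computational
questions arise once case material is genotyped:

1. **Where is the locus?** Affected animals born to carrier x carrier
   matings are homozygous by descent for a chromosomal segment around the
   causal variant. Runs of homozygosity (ROH) in each case, intersected
   across cases, localize the shared autozygous interval.
2. **What does the variant do?** The causal variant destroys a splice
   acceptor. Mutant transcripts either skip the affected exon or use an
   in-exon cryptic site; the cryptic isoform carries a premature stop and
   is degraded by nonsense-mediated decay (NMD). Relative qPCR levels of
   exon-2- and exon-3-containing transcripts identify the isoform mix.
3. **Why is the allele so common?** If carriers enjoyed a selective
   advantage, the mutant allele would have been transmitted to breeding
   sires more often than the Mendelian 1/2. Gene dropping through the known
   genealogy yields the null distribution of carrier counts among
   descendants, and a transmission-rate scan finds the rate most compatible
   with the observed count.

No individual-level study data are available, so the package ships a
synthetic-data generator that emulates all study materials with known
truth; every pipeline stage is tested against that truth or against
independent oracles (exact enumeration, brute-force window scans,
closed-form identities).

## Synthetic data: what is emulated

`simulate_pedigree()` builds discrete generations. Each generation mates
dams of the previous generation to sires drawn from the previous
generation's males, with a configurable AI-sire skew (by default the top
25% of males serve 75% of matings; the mutation founder is always an AI
sire in generation 1, mirroring the influential-founder structure of
AI-heavy cattle breeds). Sibship sizes are zero-truncated Poisson (mean
parameter 2 by default). Defaults — 5 male and 60 female founders, 6
generations, at most 60 matings per generation — give pedigrees of roughly
900 individuals in which the mutant allele, transmitted at the default
distorted rate `tau_true = 0.6`, reaches a carrier frequency of tens of
percent, and 10-20 animals homozygous for the founder haplotype: the same
order of magnitude as the mapped population (hundreds of genotyped animals,
14 autozygous cases, 26% carrier frequency).

`drop_haplotypes()` places markers at 20 per Mb (a 50K-array-like density)
on a 20 Mb chromosome, draws marker allele frequencies from Uniform(0.05,
0.5) (the spectrum is configurable; no published spectrum exists for this
population), and transmits recombined gametes with Poisson crossovers at
1 cM/Mb (Haldane model; crossover interference is deliberately not
modelled). The causal variant sits at the chromosome midpoint.
Transmission distortion is implemented exactly: the haplotype a
heterozygous parent passes at the variant position is the mutant one with
probability `tau_true`; the crossover mosaic is then anchored to that
choice, so distortion and recombination are consistent. Founder haplotypes
outside the lineage are mutant with probability `q0` each (default 0.01).
The truth table distinguishes mutant-allele dosage from *lineage* dosage
(copies descending identical-by-descent from the tagged founder
haplotype): an animal homozygous for the variant through a `q0` haplotype
is a genuine case but shows no shared ROH, exactly as a phase-unaware
diagnostic would experience. Case selection for interval mapping uses
lineage homozygotes, the analogue of selecting cases homozygous for the
risk haplotype state.

`simulate_cohort()` draws the prospective cohort: genotypes from carrier x
carrier matings (1:2:1 at `tau = 0.5`), an excess death/culling
probability of 1/3 for homozygous mutants by 210 days, a 1% baseline event
rate for all calves (accidents), and linear growth (birth weight
45 +/- 5 kg, 1.1 kg/day; height 85 +/- 4 cm, 0.10 cm/day) with a
multiplicative 15% reduction of the post-onset growth increment in
homozygotes after 180 days. The growth law is deliberately the minimal
smooth divergence model: published evidence is regression lines fitted
separately to affected and unaffected animals, which any smooth divergence
reproduces; nothing in the pipeline depends on the law being linear.

What the generator does **not** emulate: genotyping error, background
linkage disequilibrium beyond the single dropped chromosome, overlapping
generations, selection other than the single transmission-distortion
parameter, and sequence-level detail. Passing tests therefore demonstrate
algorithmic correctness on clean inheritance structure, not robustness to
array artefacts.

## Runs of homozygosity and the shared interval

`detect_roh()` reports maximal marker windows containing at most `max_het`
heterozygous and `max_missing` missing calls, with no adjacent gap above
`max_gap_bp`, at least `min_markers` markers, trimmed to homozygous end
markers; overlapping candidates are resolved greedily (most markers, then
longest, then leftmost), so segments are non-overlapping. Defaults
(`min_markers = 20`, `max_het = 1`, `max_missing = 2`, `max_gap_bp = 1e6`)
are single-error tolerances appropriate for ~50 kb marker spacing; no
published criterion is reproduced and all four are logged in the output.
A two-pointer sweep finds the windows; the test suite checks it against an
exhaustive O(n^2) scan.

`shared_autozygous_interval()` intersects case ROH on the base-pair scale
(closed intervals), so differing missingness across cases cannot shift
marker boundaries. It returns the maximal interval covered by one ROH in
every case, or, failing that, the interval with maximal supporting case
count (ties: longest, then leftmost). Boundaries are the innermost shared
homozygous marker positions; the alternative convention (outermost
positions before the first flanking heterozygote) would widen the interval
by one marker spacing on each side and is not implemented. Coordinates are
1-based closed throughout; BED export (`interval_to_bed()`) converts
explicitly to 0-based half-open.

Across 200 simulated studies under default conditions the shared interval
covers the true variant position in more than 95% of runs (the acceptance
suite recomputes this). The rare misses are boundary effects: a crossover
falling between the variant and the nearest homozygous marker shifts the
innermost boundary tens of kb past the true position.

## qPCR quantification and the two-isoform decay model

Amplification efficiency comes from the standard-curve slope,
`E = 10^(-1/slope)` with Cq regressed on log10 input over a five-point
two-fold dilution series; fits above `E = 2.1` are capped with a warning.
Reference stability is the geNorm measure: `M_g` is the mean over other
genes of the SD across samples of pairwise log2 ratios. Normalized
relative quantities use replicate-mean Cq (arithmetic mean, with replicate
SD reported), per-assay efficiencies, and the geometric mean of all passed
reference genes; the wild-type sample is the calibrator (NRQ = 1).

In the mutant, with `f_skip` the exon-skipping fraction,
`f_cryptic = 1 - f_skip` the cryptic-site fraction and `d_nmrd` the
degraded fraction of exon-retaining transcripts, surviving levels relative
to wild type are

- `rel_exon3 = f_skip + s`, and
- `rel_exon2 = s`, where `s = f_cryptic (1 - d_nmrd)`.

`estimate_splice_fractions()` inverts this: `f_skip = rel_exon3 -
rel_exon2`, `d_nmrd = 1 - rel_exon2 / (1 - f_skip)`. Solving the model at
the published fold reductions gives, for spleen (1.1-fold and 11-fold):
`f_skip = 82%`, `f_cryptic = 18%`, `d_nmrd = 50%`; the published spleen NMD
figure of 55% is not recoverable from the rounded printed folds (the
unrounded assay values would be needed), a gap the package documents
rather than hides. For lymph node (2-fold and 37-fold): `f_skip = 47%`,
`f_cryptic = 53%`, `d_nmrd = 95%`, against published values of ~44%/~56%/
~95%.

Numerical safeguards: NRQs in `(1, 1.2]` are projected to the model
boundary (a mutant cannot exceed the wild-type calibrator; noise can) with
a warning, and `rel_exon3 > 1.2` is a hard model violation, as is
`rel_exon2 > rel_exon3`. After projection all solved fractions lie in
`[0, 1]` by construction.

**Identifiability.** `d_nmrd` divides by `f_cryptic`. When `f_cryptic` is
small (spleen-like truth, `f_skip ~ 0.8`), its estimate is the small
difference of two order-one noisy quantities, and the delta-method SD of
`d_nmrd` at Cq noise SD 0.1 with triplicates is ~0.17: no estimator can
recover it to +-0.05 there. The recovery tests therefore assert +-0.05 at
identified truth points (`f_skip` 0.44 or lower) and +-0.05 for `f_skip`
alone in the spleen-like regime. Uncertainty on real data should come from
the built-in replicate bootstrap (2,000 resamples by default), which makes
the width of this ill-conditioning visible per dataset.

## Gene dropping, exact enumeration and the transmission scan

`gene_drop()` assigns founder genotypes (the designated founder
heterozygous; every other founder haplotype mutant with probability `q0`),
then transmits down the pedigree: a heterozygous parent passes the mutant
allele with probability `tau`, a homozygous mutant with probability 1, a
homozygous wild type with probability 0; an unrecorded parent behaves as a
`q0` founder haplotype. Distortion applies only to heterozygotes — the
hypothesis under test concerns transmission from carriers — while
homozygous mutant parents (possible during dropping) transmit Mendelianly.
Carrier status counts dosage >= 1, matching a carrier/non-carrier
diagnostic. Simulations are vectorized across replicates; a fixed seed
reproduces histograms bit-identically.

`enumerate_exact()` is the oracle: a depth-first sum over all genotype
configurations, feasible when meioses plus stochastic founder haplotypes
number at most 22. The acceptance suite checks the Monte-Carlo histogram
against it by chi-square at 100,000 simulations, verifies that the
distribution's mean equals the sum of exact per-individual carrier
probabilities (computed independently on each individual's ancestor
closure), and confirms that upper-tail probabilities are monotone in both
`tau` and `q0`.

`scan_transmission()` runs one gene-dropping experiment per grid point
(seed offset `seed + i`, so profiles are refinable) and counts simulations
reproducing the observed carrier count exactly; the arg-max (ties to the
smaller rate) is the most compatible transmission rate. On a synthetic
genealogy generated at `tau_true = 0.6`, a 0.01-step scan at 10,000
simulations per point recovers the rate within +-0.05. Descendants are
dropped unconditionally (no ascertainment on the targets having been
born); conditioning on birth would require a reproduction model the data
do not constrain.

## Cohort statistics

Closed forms (`hwe_genotype_freqs`, `prob_no_homozygotes`,
`expected_affected_offspring`, `two_locus_ld`) are implemented directly.
The segregation test defaults to Pearson's chi-square, with a G-test and
an exact multinomial (full enumeration, N <= 200) as alternatives — at the
cohort's printed counts the three give p = 0.727, 0.722 and 0.748, which
is why no single "the" test is asserted. The genotype-by-outcome test is
the two-sided probability-ordering exact test over margin-fixed r x 2
tables, enumerated directly (it reduces to the classical Fisher test for
2 x 2, and is cross-checked against an independent implementation in the
tests). Growth is summarized by per-group ordinary least squares of the
response on age within an age window — the descriptive lines one draws
through the scatter — while the slope-difference test compares
`response ~ calf + age` with `response ~ calf + age:group`: the per-calf
fixed effects absorb animal-level intercept variation, without which the
repeated measures would make the interaction test anti-conservative (the
null-calibration test in the suite verifies uniform p-values under an
identical generating law). Survival is reported as counts and the exact
test only; no hazard model is fitted.

## Problem sizes used by the tests

The suite regenerates everything from seeds: pedigrees of ~900 individuals
(400 markers) for mapping and scanning, 200-study replicates for the
coverage property, 100,000-simulation histograms on the 12-individual
enumeration fixture, 10,000 simulations per grid point for the
transmission scan, and 25-replicate recovery batches for the qPCR
pipeline. These sizes were chosen to keep each statistical assertion's
Monte-Carlo error far below the tolerance it checks.

## Known limitations

- ROH parameters are conventions, not estimates; different array densities
  need different `min_markers`/`max_gap_bp`.
- The shared-interval boundary convention (innermost shared homozygous
  markers) can undercover the true position by up to one marker spacing.
- `d_nmrd` is ill-conditioned when the cryptic fraction is small (above).
- Gene dropping treats the genealogy as known and complete; unrecorded
  ancestry enters only through `q0`.
- The growth model is linear with Gaussian measurement noise; real growth
  curves flatten, so window choice matters on real data.
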