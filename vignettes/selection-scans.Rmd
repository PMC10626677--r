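---
title: "Within-population selection-signature scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-population selection-signature scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sweepstack` implements, as one tested pipeline, the four within-population
selection scans routinely applied to dense livestock SNP-array data —
extreme ROH islands (eROHi), the integrated haplotype score (iHS), the
number-of-segregating-sites-by-length statistic (nSL), and a
SweepFinder-style composite likelihood ratio (CLR) — together with the QC
chain that precedes them (call rates, MAF, exact Hardy–Weinberg test,
method-of-moments relatedness pruning), sliding-window significance calls,
multi-method consensus regions, and QTL-class enrichment.  A forward
Wright–Fisher simulator of neutral and hard-sweep datasets makes the whole
pipeline testable end to end without any external data.

This vignette records the models, the defaults and their units, and the
design decisions taken where a published analysis pipeline typically
leaves choices open.

# The statistics

## Runs of homozygosity and eROHi

ROH are detected per individual by the windowless *consecutive-runs*
method: all maximal stretches of consecutive calls containing at most
`max_het` heterozygous (default 1) and `max_missing_in_run` missing calls
(default 0), broken wherever two adjacent SNPs are more than `max_gap_bp`
(default 1 Mb) apart.  A stretch is retained as a run iff it contains at
least `min_snps` homozygous SNPs (default 15), spans at least
`min_length_bp` (default 1 Mb), and has at least one homozygous SNP per
0.1 Mb.  These are the standard recommendations for high-density arrays.
Two points the usual tool descriptions leave open are fixed here
deterministically:

* the one-heterozygote allowance is applied to *all* runs rather than to
  an unquantified "longer runs" class — the consecutive-runs tools apply
  one global allowance, and no length cut-off for it is published;
* maximality is defined against the run constraints only, so the detector
  is exactly reproducible by brute-force enumeration of maximal
  qualifying intervals (and is tested against such an enumerator on
  thousands of random fixtures).

The eROHi score at a SNP is the number of individuals whose ROH cover its
position.  Counts are z-scored per chromosome (mean *and* standard
deviation — a Gaussian right-tail P value requires a scale, so
"normalising by the chromosome mean" is read as a full z-transform), and
reported as `-log10 P` of the right Gaussian tail.  SNPs at
`-log10 P >= 4` are outliers; at least two *consecutive* outlier SNPs
make a candidate region, which is extended by 100 kb on both sides.
Incidence is computed from retained runs only, and counts (rather than
proportions) are stored — the z-transform is affine-invariant, so the
choice is presentational.

## iHS and nSL

Both statistics compare haplotype homozygosity around the two alleles of
a focal SNP.  EHH for a core allele is the probability that two carrier
haplotypes drawn without replacement are identical at every SNP between
the focal SNP and a flanking SNP; it is computed by outward partition
refinement.  For iHS, the EHH curves of the ancestral and derived carrier
sets are integrated over physical distance (trapezoid rule, both sides,
truncated where EHH < 0.05 or at the chromosome end; the segment reaching
the first sub-cutoff SNP is included) and the raw score is
`ln(iHH_A / iHH_D)`.  For nSL the "distance" unit is one segregating site,
and the per-allele quantity is the mean over carrier pairs of the maximal
interval (in sites, the focal site counted once) over which the pair is
identical; gaps above the gap scale (0.02 Mb) down-weight a step by
`gap_scale / gap` and gaps above 0.2 Mb truncate, the selscan-style
defaults.  The same gap parameters are applied to the iHS integral for
consistency; they are exposed as arguments.  SNPs with minor derived
frequency below 0.05 are skipped.

Raw scores are standardised in 100 equal-width derived-allele-frequency
bins pooled genome-wide, and transformed to `-log10(2 * Phi(-|z|))`.
Sliding windows of 0.5 Mb are advanced in 10 kb steps; the published
phrase "overlap of 0.01 Mb with adjacent windows" is ambiguous between a
10 kb step and a 490 kb step, and the 10 kb-step reading was chosen as
the common sliding-scan convention (the step is configurable, so the
other reading is one argument away).  A window with three or more SNPs at
`-log10 P >= 4` is significant; overlapping or touching significant
windows merge into regions.  Polarisation uses the `AA` tag (or the
simulator truth); when polarity is unknown the major allele is treated as
ancestral and flagged.  Unphased input is rejected for these two scans —
phasing is upstream of this package.

## CLR

The null model is the genome-wide empirical site frequency spectrum
(unfolded when polarity is known, folded otherwise).  At a test position,
the alternative distorts that spectrum by a hitchhiking model: each of
the n sampled lineages escapes the sweep independently with probability
`p_e = 1 - exp(-alpha d)` at distance `d`; escapees carry frequencies
drawn without replacement from the background spectrum, non-escapees
coalesce onto the single sweeping haplotype, and the resulting allele
count distribution is renormalised over segregating outcomes.  The
statistic is `Lambda = 2 (max_alpha l1 - l0)`, clamped at zero (the
factor 2 is the SweepFinder convention and is configurable).  The
escape-model spectrum is implemented by hypergeometric downsampling of
the background spectrum and is verified against exhaustive enumeration
over all escape configurations at small n; the enumeration defines that
model exactly.  In the composite likelihood each site's sweep
probability additionally carries a new-mutation adjustment,
`(1 - w) P_escape + w P_background` with `w = 0.05`
(`new_mutation_weight`): a polymorphism close to the sweep may simply
postdate it, and without this term a single such site can veto the true
sweep position with an arbitrarily large negative log-likelihood.  For
speed the per-site log-probabilities are tabulated over `x = alpha d`
(96 log-spaced knots, linear interpolation; beyond `x = 13.8` the sweep
spectrum is numerically the background, and such sites contribute
nothing to the ratio).

The default alpha grid spans footprint half-widths `ln 2 / alpha` from
10 Mb down to an identifiability floor of ten median inter-SNP spacings,
in 40 log-spaced values plus a full-escape sentinel.  The floor matters:
a "sweep" whose footprint is narrower than a few marker spacings is
indistinguishable from a chance cluster of two or three unusual sites,
and letting the maximisation visit such footprints turns the scan into a
local-noise detector.  The test grid has 10,000 evenly
spaced positions per chromosome by default; the statistic is insensitive
to refinement once grid spacing is ~10 kb or less, which is the property
the tests assert.  Selection signatures are the top 0.1% of grid values
genome-wide (the threshold is the `ceiling(0.001 n)`-th largest value;
contiguous selected grid points merge into regions).

## Consensus and enrichment

Per-method regions are 1-based inclusive intervals; a shared endpoint
counts as overlap.  The consensus table consists of the connected
components of the cross-method overlap graph that contain at least two
distinct methods, with component bounds the *union* of member intervals —
union rather than intersection because published multi-method tables
report lengths (e.g. a 7.79 Mb region) that exceed any single method's
window.  Lengths in Mb are half-up rounded to three decimals, matching
the presentation convention of such tables.

QTL enrichment follows the proportional model of GALLO-style analyses:
for each trait class, observed = distinct QTLs of the class overlapping
any candidate region (a QTL spanning several regions counts once);
expected = class total x (overall overlapping fraction) within the scope
(genome or chromosome); richness = observed / expected; P from the
hypergeometric upper tail; Benjamini–Hochberg FDR across classes.  The
expected-count convention is proportional-to-scope; gene annotation comes
from user-supplied GFF3/BED — there are no network queries.

# Quality control

Filters run in a fixed, logged order: individual call rate (>= 0.90),
SNP call rate (>= 0.95), optional per-SNP GenCall score (>= 0.7, applied
only when a score column is supplied, since intensity scores are absent
from standard formats), minor allele frequency (>= 0.01), exact HWE
(P >= 1e-4; a published "< 0.01%" exclusion threshold is read as
P < 1e-4).  The published pipelines do not state the filter order; fixing
it (individuals first, then SNP-level filters) follows common PLINK
practice and makes reports reproducible.  Relatedness pruning comes after
the SNP filters: PI_HAT is the classic identity-by-state
method-of-moments estimator (without PLINK's small-sample bias-correction
factors, which change nothing at the 0.18 decision boundary for
array-scale SNP counts), and pruning greedily removes the individual with
the most pairs above threshold, breaking ties toward the
lexicographically later ID.

# The simulator

`simulate_neutral()`/`simulate_sweep()` run a discrete-generation
Wright–Fisher diploid population of constant size N with infinite-sites
mutation on a continuous chromosome, crossover recombination, and a
burn-in of 8N generations.  Sweeps add one site under genic selection
(fitness 1, 1+s, 1+2s); trajectories are resampled from the same standing
variation (retry budget 10,000) until the allele reaches the target
frequency, and the sample is drawn at that moment.  The ancestral allele
is the allele of the founding population at burn-in end and is recorded
(`AA` tag / truth sidecar), so downstream polarisation is exact.
Chromosomes are simulated independently and concatenated.

What the simulator emulates: biallelic segregating SNPs with a realistic
frequency spectrum, LD generated by genuine genealogies, hard sweeps with
known truth, missingness, duplicate individuals and parent–child
composites.  What it does not emulate: genotyping-intensity artefacts,
demography (bottlenecks, structure, migration), soft sweeps, and
array ascertainment bias (real arrays under-sample rare alleles).
Passing calibration on these simulations therefore shows the statistics
are correctly computed and calibrated under their own assumptions, not
that array ascertainment leaves the CLR background spectrum unbiased.

## Study conditions

The built-in studies (`calibration_study_haplo()`,
`calibration_study_roh()`, `recovery_study()`) use desk-scale populations
chosen once, by the dimensionless quantities that control the phenomena:

* **Haplotype-score calibration** — 10 neutral chromosomes of 2 Mb,
  N = 200, n = 50 diploids, mu = r = 2.5e-7 per bp: ~20,000 segregating
  sites, >10,000 scored after the frequency filter, enough to populate
  100 standardisation bins.
* **eROHi calibration and power** — N = 100 with livestock-like
  recombination (1–5e-8 per bp) and long (10 Mb) chromosomes, so that
  multi-Mb autozygous segments arise (IBD segment scale ~ 1/(2 N r)); the
  power study uses a strong recent sweep (s = 0.5, 2Ns = 100) whose
  footprint (~1.5 Mb) fits the 1 Mb minimum run length and whose short
  duration keeps new post-sweep heterozygous sites within the one-het
  allowance.
* **Sweep recovery** — one 2 Mb chromosome, N = 1000, n = 50,
  mu = 2.5e-8, r = 1e-7, s = 0.1 at fixation: 2Ns = 200 puts the sweep
  duration at ~0.07 coalescent units (hard sweeps this clean are the
  regime the CLR models), and `r ln(2Ns)/s` gives a ~130 kb footprint,
  interior to the chromosome.  The ROH stage of the consensus run uses
  footprint-scaled run parameters (0.1 Mb / 10 SNPs), since a 130 kb
  swept segment cannot satisfy a 1 Mb minimum designed for real genomes.
  The CLR region call uses the top 2 of 250 grid points per replicate —
  at 250 grid values a literal 0.1% cut is empty.

At smaller 2Ns the recovery degrades honestly: sweeps lasting a
substantial fraction of 2N generations accumulate intermediate-frequency
mutations on the sweeping background, which the star-like escape model
does not describe, and the composite likelihood then prefers the sweep
flanks.  Even at 2Ns = 200 a ring of partially hitchhiked
intermediate-frequency alleles 50–150 kb from the focal site remains the
main cost term at the true position; this is a property of the
instantaneous-escape model class, not of the implementation, and it is
the reason CLR localisation on these simulations sits near (not far
above) the 70% mark that the recovery study asserts.

# Numerical choices

* HWE exact P sums all heterozygote configurations with probability at
  most that of the observed one (with a 1 + 1e-12 relative guard against
  ties lost to floating point); monomorphic sites return P = 1.
* Standardisation bins with fewer than two scores or zero variance yield
  missing standardised values rather than infinities.
* A chromosome with zero incidence variance logs a warning and produces
  no eROHi outliers.
* `Lambda` is clamped at 0; sweep-spectrum probabilities are floored at
  1e-300 before logging.
* Region lengths use half-up rounding (`floor(x * 1000 + 0.5)/1000`), not
  banker's rounding.
* Degenerate threshold grids (all values equal) produce no CLR regions.

# Known limitations

* The consecutive-runs detector returns *all* maximal qualifying
  intervals; overlapping maximal runs (possible with the heterozygote
  allowance) are all reported rather than arbitrarily trimmed.
* iHS integrals are integrated to the chromosome end when EHH never
  falls below the cutoff, rather than discarding the SNP; on short
  simulated chromosomes discarding would lose most of the genome, and
  standardisation absorbs the shared border bias.
* The folded-spectrum CLR applies the escape model to minor-allele
  counts directly; with polarity available the unfolded model is used
  and preferred.
* PI_HAT omits PLINK's finite-sample correction factors; estimates are
  slightly biased for very small reference panels but the pruning
  decision at 0.18 is unaffected at array scale.
* The pipeline consumes phased input; phasing itself is out of scope.
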