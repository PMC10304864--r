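---
title: "Quantifying phage experimental evolution: mutations, parallelism, adsorption and plaques"
author: "phagevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phage experimental evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagevo)
```

## Scope and data model

`phagevo` analyses serial-passage evolution experiments in which replicate
phage populations adapt to a bacterial host. It deliberately starts *after*
read alignment and variant calling: its inputs are mutation tables (one row
per mutation per isolate or population, with optional read-support
frequencies), a reference genome with gene models, adsorption assay plate
counts, plate photographs, and daily titer and cross-streak tallies.
Upstream bioinformatics (alignment, variant calling, assembly, annotation)
is out of scope by design.

Coordinates are 1-based and inclusive throughout, matching how mutation
positions are reported in practice. Mutation alleles are always stated on
the forward genome strand; the annotation layer performs all coding-strand
complementation internally. This split keeps mutation tables
caller-agnostic.

## Mutation annotation

For a position inside a forward-strand gene starting at `s`, the codon
number is `floor((pos - s)/3) + 1` and the within-codon offset
`((pos - s) mod 3) + 1`. For a reverse-strand gene ending at `e`, the
coding-strand nucleotide index is `e - pos + 1` and the same arithmetic
applies to it; the reference codon is read reverse-complemented and the
substituted allele is complemented. A useful internal check is strand
symmetry: annotating position `p` against genome `G` must give the same
codon number, offset and reference codon as annotating `L - p + 1` against
the reverse complement of `G` with all spans flipped — the test suite
asserts this on randomized genomes.

Indels are classified purely by net length: frameshift when `length mod 3
!= 0`, in-frame otherwise. Homopolymer run changes `(B)_n -> m` are
normalised to an indel of `|n - m|` bases, since only the net length
determines the reading-frame consequence. Genes whose length is not a codon
multiple are translated over complete codons only, with a warning for
positions in the trailing 1–2 nt: published ORF lengths are occasionally
internally inconsistent, and silently rounding would hide that.

### Amino-acid property classes

Substitutions are classified by three properties: charge (positive K/R/H,
negative D/E, neutral otherwise), polarity (polar C, D, E, G, H, K, N, Q, R,
S, T, W, Y; nonpolar otherwise) and side-chain volume (small A, C, D, G, N,
P, S, T, V; large otherwise). A substitution that changes none of the three
is "nonsynonymous conserved". This three-way scheme reproduces most
published impact labels of the packaged tables, but not all: published
tables occasionally carry labels inconsistent with any single
charge/polarity/volume partition (for example a glutamine substitution
labelled "small to large" when Q classes as large). The table is therefore
user-overridable via the `table` argument of `classify_property_change()`,
and the round-trip tests assert labels only where the default scheme and
the published label agree — codon pairs, substitution labels and effect
classes are asserted for every row.

### Isolates versus populations

`summarize_isolates()` keys mutation uniqueness on (position, change) and
amino-acid uniqueness on the substitution label, so a substitution shared
by three isolates counts once in each unique tally but three times in the
per-isolate mean — this is the convention needed for the three headline
statistics (unique mutations, unique amino-acid changes, mean mutations per
isolate) to be mutually consistent.

`compare_isolate_to_population()` flags mutations fixed in a population's
read pool (frequency ≥ 1.0 by default) but absent from the isolate sampled
from that population. Matching is on (position, change), so a 1 bp deletion
reported at one end of a homopolymer run does not match a run-contraction
reported at the other end — a deliberate strictness, since variant callers
differ in where they anchor such events and the mismatch is itself
informative.

`filter_preexisting()` removes mutations that match ancestral-stock
polymorphisms at *any* stock frequency: a variant present in the inoculum
cannot count as independent parallel evolution no matter how rare it was.

## Parallelism statistics

The headline statistic is deliberately conservative. With `k` of `k`
populations mutated in a gene of length `L_g` (genome length `L`), the
probability charged is

$$P = (L_g / L)^{k-1},$$

i.e. the first hit is free (conditioned upon) and each additional
population pays the per-population chance that a mutation lands in the
gene. The exponent `k - 1` is the only reading that reproduces both
published example values (exponent 4 with five populations, 2 with three).
Displayed values round to one significant figure in fixed notation
(`format_probability()`), matching how such probabilities are reported.

Two independent nulls check this from below and above:

* `null_parallel_probability_exact()` gives the closed form
  $[1-(1-L_g/L)^m]^k$ for `m` uniform placements per population;
* `null_parallel_probability_mc()` simulates actual placements, optionally
  conditioning on population 1 hitting the gene. With `m = 1` the
  conditional estimate converges to the conservative formula, which ties
  the two together.

One subtlety: the unconditional exact null is *not* always at least the
conservative value (at `m = 1` it is $(L_g/L)^k < (L_g/L)^{k-1}$); the
correct dominance relation is conditional — the per-population hit
probability $1-(1-L_g/L)^m \ge L_g/L$ implies exact-conditional ≥
conservative — and that is what the property tests assert over a parameter
grid.

The uniform-placement null ignores mutational spectrum bias (real phage
data are often enriched for specific transversions) and selection on the
observed mutations; it is a null for *placement*, not for *rate*. This is a
documented limitation, shared with the conservative formula itself.

Monte-Carlo power considerations shaped the test design: with `m = 1` and a
~3.8 kb gene in a ~49 kb genome, a million conditioned simulations yield
only ≈3 expected joint hits across four further populations, so the
convergence check uses a 10 kb gene (≈8,000 expected successes) for its
tight three-standard-error assertion and retains the small-gene case at its
own, necessarily wide, band.

## Adsorption kinetics

Free phage decaying onto cells at density `B` for time `t` satisfy
`T1 = T0 exp(-rate · B · t)`, so `rate = -ln(T1/T0)/(t·B)`. Units follow the
assay sheet: hours and cells/mL, giving mL cell⁻¹ h⁻¹; a `per_minute`
display option divides by 60 for comparison with classical adsorption
constants. The estimator is scale-invariant in the titers (only their ratio
matters) and strictly decreasing in `T1` — both are asserted as properties.

Confidence intervals are t-distribution intervals over replicate rate
estimates (default n = 9), not error propagation from Poisson counts: with
a handful of replicates of ≥30-count plates, replicate-to-replicate
variation dominates counting error, and the replicate CI is the honest
summary. Group comparisons are unpaired Welch t tests; the one-tailed
option tests the directional hypothesis that group A's mean exceeds group
B's. When every observation in both groups is identical the test is
degenerate and p is 1 (equal means) or 0 by convention. Holm–Bonferroni
decisions use the standard step-down rule; adjusted p values are the
monotone Holm adjustment, and rejection at level α is equivalent to the
hand-stepped procedure (the tests verify both hand-stepped cases and the
Bonferroni ⊆ Holm ⊆ uncorrected sandwich).

A no-cell control series can replace `T0` in the ratio when supplied
(`adsorption_rate` applied against control-T1); it is off by default
because the arithmetic of such corrections varies between labs.

## Plaque quantification

The pipeline mirrors a standard ImageJ-style protocol with every constant
exposed:

| parameter | default | meaning |
|---|---|---|
| `plate_diameter_mm` | 86 | physical plate, sets mm/px |
| ROI ellipse | 72.24 × 72.24 mm | centred selection; rim excluded |
| `rolling_ball_radius_px` | 50 | background structuring-element radius |
| thresholds | 180–238 | inclusive 8-bit intensity window |
| area filter | 0.2–64 mm² | plaque size plausibility window |
| circularity filter | 0.20–1.00 | `4πA/P²`, capped at 1 |

Background flattening is grayscale morphological opening with a flat disc
element: it removes any structure wider than the disc (slow illumination
gradients) while bright features smaller than the disc survive subtraction
unchanged. A flat image maps to zero and an oversized radius degenerates to
subtracting the global minimum — both asserted in tests.

Particles are 8-connected components. Perimeters use a corrected
boundary-chain length (0.980 per axial step, 1.406 per diagonal step)
rather than raw staircase length; the raw chain overestimates a circle's
perimeter by ~13–27%, which would push ideal disks' circularity down to
0.6–0.8 and make the 0.20 circularity filter meaningless. With the
correction, rasterised disks of radius ≥ 5 px measure circularity ≥ 0.9.
Components touching the ROI boundary are discarded (they are truncated by
the selection), overlapping plaques are not split (no watershed — the
emulated protocol performs none), and the reported "diameter" is the
equivalent-circle diameter `2·sqrt(A/π)`.

Plaques are assumed *brighter* than the lawn, as under bright-field
transillumination of clearings; the synthetic renderer conforms. Note that
background subtraction shifts absolute intensities: a plaque rendered at
intensity 210 on a lawn of 60 sits near 150 after flattening, so analyses
of synthetic plates use a threshold window bracketing that contrast
(e.g. 110–255), while the printed 180–238 defaults target real photographs
whose absolute levels the generator does not try to reproduce.

## Population dynamics

Titer series classify as extinction-bound when they fall below the
detection limit (default 100 PFU/mL) and never recover through the final
day; the extinction day is the first day of that terminal run, with no
smoothing. A dip-and-recovery is survival — populations can persist at
trace densities below standard enumeration. The classifier is invariant to
rescaling titers and limit together. Cross-streak detection limits are
`(1 - 1/n)·100%` — 95% for n = 20, 97.5% for n = 40 — and rise toward 100%
as the survey deepens.

## Synthetic generators

All generators are seed-deterministic and emit ground-truth sidecars.

* **Fixture genome** (`build_fixture_genome`): a uniform-random 49,223 bp
  background with the packaged tables' reference codons, intergenic bases
  and homopolymer runs embedded at their recorded positions. Gene spans for
  the two tail fiber genes are fixed by the tables (gene 52 forward
  24741–28516, 3,776 bp; gene 57 reverse 31608–33980, 2,373 nt); other
  genes have assumed minimal spans flagged `derived`. An internal oracle
  re-annotates every catalogued mutation after each build and aborts on any
  mismatch, so a fixture that builds is a fixture that is consistent.
  The genome emulates coordinates and codons only: no promoters, no codon
  usage bias, no realistic intergenic structure.
* **Null mutations**: uniform positions, uniform alleles — the placement
  null and nothing more (no mutational spectrum).
* **Adsorption counts**: exponential decay plus Poisson plate counts.
  Defaults (T0 = 10⁶ PFU/mL, 0.5 h, 2×10⁹ cells/mL, n = 9, ~100 and ~37
  expected plaques on T0/T1 plates) describe a well-run assay; the
  estimator recovers the generating rate with |relative bias| below 5%
  under these conditions, which bounds counting-noise bias, not systematic
  assay error.
* **Plate images**: anti-aliased non-overlapping disks (lawn 60, plaque
  210, optional linear gradient of 20 and Gaussian noise of SD 5 on the
  8-bit scale, 0.15 mm/px) inside the ROI with a 1 mm rim gap. Real plates
  additionally have overlapping plaques, lawn aberrations, condensation and
  uneven focus; passing recovery tests on these renders validates the
  measurement chain, not robustness to those artefacts.
* **Dynamics**: rise to ~10⁸ PFU/mL by day 1, then either persistence well
  above detection or log-linear decline crossing the limit around day 4–6
  with no recovery; resistance counts are binomial draws on a 20/40/20
  design over days 1/5/10 with resistance rising to near-fixation.

## Problem sizes in the test suite

The packaged tests run the Monte-Carlo null at 10⁶ replicates where a tight
comparison is claimed and 2×10⁵ elsewhere; adsorption recovery uses 1,000
seeded assays of 9 replicates; plaque recovery uses 20 rendered plates of
40 plaques (plus single-plate unit cases); coverage simulation uses 500
assays. These sizes give the assertions their stated statistical power
while keeping a full run under a minute of compute on one core.

## Known limitations

* The conservative parallelism probability treats gene length as the only
  target-size covariate; hotspots, spectrum bias and selection inflate or
  deflate it in ways the package does not model.
* The property scheme is one defensible partition of residue chemistry;
  others (volume terciles, hydropathy) will re-label some substitutions.
* Circularity at low resolution depends on the perimeter estimator;
  absolute values below ~5 px radius are tool-specific.
* The image pipeline performs no plate localisation or deskewing: inputs
  are assumed already cropped and square to the plate.
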