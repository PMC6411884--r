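---
title: "Quantifying post-mortem integrity: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-mortem integrity: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

paleoQC asks one question three ways: how much of the biology of a long-dead
specimen is still intact? It combines an imaging assay on nuclei transplanted
into live oocytes, a proteomic clock based on collagen deamidation, and the
sequence-level damage signatures of ancient DNA. This vignette explains the
models behind each track, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the design choices made where the
design was genuinely open.

```{r setup}
library(paleoQC)
```

## The DNA damage index (DDI)

A nucleus injected into an oocyte is imaged in two channels: histone H2B
(chromatin amount; also normalizes the injected probe volume) and
gamma-H2A.X (phosphorylated H2A.X, the canonical double-strand-break
marker). For nucleus $j$,

$$ \mathrm{DDI}_j \;=\; \frac{S^{\gamma}_j / S^{H2B}_j}
   {\operatorname{median}_{i \in \mathrm{ref}} \left( S^{\gamma}_i / S^{H2B}_i \right)}, $$

where $S$ are background-subtracted integrated signals and the reference
cohort is undamaged control material (fresh sperm). The reference median is
1 by construction; a DDI strictly above 2 classifies a nucleus as unlikely
to support development (`classify_competence()`, threshold exposed as a
parameter because the boundary is an empirical observation, not a law).

Measurement pipeline choices:

* **Segmentation** runs on the H2B channel only — the structural probe is
  the one guaranteed to mark every nucleus — with Otsu's threshold on the
  3D volume histogram and 26-connected component labelling. Components
  below `min_volume` (default 30 voxels) are discarded as debris.
* **Background** is the median intensity of a 2-voxel dilated shell around
  each mask, excluding voxels of other masks. A local shell is robust to
  the bright metaphase-II chromosomes of the recipient oocyte that sit in
  the same field; a whole-image background is used (with a warning) only
  when the shell is empty.
* **Normalization** divides by the reference median and then re-applies the
  division until the reference median is exactly 1. A single floating-point
  division can leave the even-$n$ interpolated median one ulp away from 1;
  the fixed-point loop (converging in one or two passes) makes "reference
  median equals 1" an identity rather than an approximation.
* **Time courses** re-segment every frame and link nuclei greedily by
  nearest centroid with a 5 um/frame gate; declining series (final DDI
  below initial) are flagged repair-consistent. Whole-nucleus integration
  is used throughout; peripheral damage enrichment is visible in the
  measurements but deliberately plays no role in the index, whose
  definition is a whole-nucleus ratio.

The group comparison uses a Steel-type many-to-one rank test: each
treatment vs the single control by Wilcoxon rank sum (mid-ranks for ties),
with family-wise adjustment from the permutation distribution of the
maximum standardized statistic under joint relabelling. The permutation
formulation was chosen over the classical multivariate-normal tables
because per-group sizes in injection experiments are small (often under
15), where the asymptotic tables are least trustworthy, and because it
needs no tabulated critical values. With one treatment and few
observations the test enumerates all label partitions and is exact.
Sidedness defaults to two-sided (no direction is assumed); 10,000
permutations and an explicit seed are required for the Monte-Carlo path.
Developmental outcome tables (2x2, success/failure by group) are compared
with Fisher's exact test; Shapiro-Wilk and Bartlett checks are provided for
reporting, not gating — the rank test does not require them.

## Collagen deamidation

Asparagine and glutamine deamidate spontaneously after death; the fraction
of collagen peptides observed in deamidated form is a slow molecular clock.
The scoring rule is deliberately coarse and sequence-level: the denominator
is the number of distinct N/Q-containing peptide sequences (after dropping
PSMs under 95% identification confidence, boundary inclusive — only
identifications *below* the threshold are rejected), and a sequence counts
as deamidated if even one of its spectra carries the modification.
Sequence-level counting makes the rate insensitive to how many times a
spectrometer happened to resample the same peptide; the per-protein
grouping is available where per-site resolution is wanted.

Quantifying the *fraction* deamidated for a single peptide needs care: the
deamidated form is +0.984 Da (computed in `deamidation_mass_shift()` from
monoisotopic masses, O − N − H), while the first ¹³C isotopologue of the
non-deamidated form is +1.0034 Da. The ~0.019 Da gap is unresolvable in a
typical XIC window, so the deamidated-form channel is contaminated by
isotope interference. `decompose_xic()` exploits chromatography instead:
the interference must co-elute exactly with the non-deamidated peak, so it
is modelled as a Gaussian pinned to that peak's fitted retention time and
width with free amplitude, plus a free Gaussian for the genuinely
deamidated peptide. The fraction uses only the free component. An
averagine-style M+1/M estimate from the peptide's elemental composition is
reported as a consistency check on the interference amplitude but never
subtracted blindly — the separation argument is chromatographic, not
isotopic, and pinning the quantification to an isotope model would import
that model's error into every sample.

Numerical choices: peaks are Gaussian (a tailing-peak model was considered
and left out; the generator produces symmetric peaks and real tailing
would first need an empirical shape); fitting is Levenberg-Marquardt with
non-negative amplitude bounds through the residual-function interface of
minpack.lm — the `nls`-wrapper interface fails spuriously when an
amplitude converges exactly onto the zero bound, which is the *expected*
solution whenever a sample has no interference. When the free component
lands within one fitted width of the interference the two are declared
chromatographically unresolved and the fraction is reported as bounds
(zero to the value obtained by crediting the whole channel to
deamidation) rather than a point estimate.

## Ancient-DNA damage

Three signatures are profiled from gapless aligned reads:

* **Terminal deamination.** Cytosine deamination in single-stranded
  overhangs produces C→T mismatches at 5' ends and, read on the opposite
  strand, G→A at 3' ends. The profile counts, strand-aware, the frequency
  of each at distance $i$ from the molecule end and fits
  $p(i) = \delta_0 \lambda^i$: two parameters, the terminal damage
  probability and its per-position decay. This is the simplest curve with
  the right shape; it is an intentional summary, not a reimplementation of
  a full Bayesian damage model. The fit is weighted least squares on
  $\log p(i)$ with the observed *event counts* as weights — the
  delta-method variance of a log frequency is $(1-p)/(np)$, so event
  counts are the inverse-variance weights. Weighting by the opportunity
  counts instead was tried and rejected: at deep positions the expected
  frequency is far below $1/n$, only the occasional lucky nonzero count
  survives the log, and those points (upward-biased by construction) then
  carry enough weight to flatten the decay and drag the intercept well
  outside the pipeline's own ±20% recovery target.
* **Fragment lengths.** A 5-bp histogram smoothed with a 3-bin moving
  average; the nucleosome flag fires when the mode falls in 140–180 bp,
  the band expected when histone octamers (146 bp of wrapped DNA per unit)
  protected fragments from nucleases. Chromatin-bearing samples show this
  mode; naked degraded DNA or modern high-molecular-weight extracts do not.
* **Substitutions.** Pileup with plurality consensus
  (`n_common + n_different = depth` is an identity checked site by site),
  and SNV filtering at minimum depth 3 with minimum 2 alternate-supporting
  reads, both bounds inclusive. "Minimum SNP = 2" is read as the
  alternate-read count — the only reading that makes the threshold a
  property of a single site. Consensus ties resolve to the reference base
  when it is among the tied (else alphabetically) and flag the column:
  deterministic and auditable, where IUPAC codes would silently leak
  ambiguity downstream.

Read QC interprets "QV < 20" as a *mean* read quality (strict less-than
removed), since per-base trimming would change fragment lengths and
thereby corrupt the nucleosome analysis; duplicates are collapsed by
(reference, start, strand, length) after quality filtering. Reads
containing N are dropped. Coordinates are 0-based half-open internally;
SAM positions are converted on read and VCF positions on write.

## What the generators emulate — and what they do not

Every input class has a generator with exact ground truth, deterministic
given its seed:

* `sim_nucleus_stack()` renders nuclei as uniform spheres, blurred by a
  Gaussian PSF, over a constant background with additive Gaussian noise
  only. No Poisson term: DDI is a ratio of large integrated signals where
  the noise model is second-order, and a purely additive model keeps the
  truth integrals exact. Nuclei whose support (sphere plus PSF) would
  cross the boundary are rejected so no blur mass is lost. Defaults (2 um
  z-spacing, ~1-voxel PSF, background 10 with noise sd 2 against sphere
  intensities of ~100) are in the working range of spinning-disk confocal
  stacks of oocytes; actual camera noise statistics of an EM-CCD are not
  modelled, so passing recovery tests demonstrates correctness of the
  measurement arithmetic, not robustness to every real-world acquisition
  artifact. Real nuclei are also neither spherical nor uniformly stained,
  and damage foci cluster peripherally; the phantom tests validate signal
  accounting, not morphology handling.
* `sim_ddi_cohort()` draws true damage per group from a gamma distribution
  (cv 0.3), multiplies in lognormal measurement noise, and draws
  development success from a logistic in true damage centred at damage = 2
  — the generator encodes the observation that nuclei above twice the
  reference damage level usually fail.
* `sim_psm_table()` deamidates each N/Q residue independently per
  spectrum, adds proline-oxidation decoys, and draws confidence uniform on
  [80, 100]. Real confidence scores correlate with peptide length and
  spectral quality; the uniform draw only exercises the filter boundary.
* `sim_xic_trace()` renders sums of Gaussians sampled five widths past the
  outermost peaks, so requested and rendered areas agree to well under
  0.5%.
* `sim_ancient_reads()` applies the geometric damage law in molecule
  orientation and stores sequences reference-forward, so minus-strand
  bookkeeping in the profiler is genuinely exercised. The default fragment
  mixture (mean 158 bp, sd 10) sits in the 150–170 bp nucleosomal band;
  terminal damage defaults ($\delta_0 = 0.3$, $\lambda = 0.5$) are in the
  range reported for Pleistocene permafrost material. Sequencing error,
  mappability, and reference bias are not simulated.

## Problem sizes and tolerances

The test suite and the acceptance script use: 10,000 reads on a 20-kb
reference for damage-parameter recovery (±20% over a
$\delta_0 \in \{0.1, 0.3\} \times \lambda \in \{0.3, 0.5, 0.7\}$ grid);
48×48×24-voxel phantoms with 2% noise for imaging recovery (ratios within
5%); 500 null replicates at 10,000 permutations for the Steel type-I check
(family-wise rate within the 99% Monte-Carlo interval of α = 0.05); a
12-fit interference (0–50%) × separation (2–5 widths) sweep for XIC
recovery (fractions within 5%, areas conserved within 2%); and complete
hypergeometric enumeration of every 2×2 table with N ≤ 12 against
`fisher_exact_outcome()`. These sizes keep the whole suite in the
low minutes on a single core while leaving each check enough resolution to
fail loudly if the underlying arithmetic drifts.

## Known limitations

* The DDI is only as good as the segmentation: touching nuclei merge into
  one 26-connected component; no watershed splitting is attempted.
* The geometric decay is a two-parameter summary; it cannot represent
  library-preparation-specific position effects or distinguish
  single-stranded from double-stranded overhang chemistry.
* The XIC decomposition assumes one deamidated species per channel;
  multiply-deamidated peptides with distinct retention times would need
  more components.
* The Steel test's Monte-Carlo p-values have resolution 1/(B+1); at the
  default B = 10,000 that is ample for α = 0.05 but not for
  genome-wide-style thresholds.
* Tracking is greedy nearest-centroid; it is adequate for the few, slow
  nuclei of injection experiments and would not survive dense fields.
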