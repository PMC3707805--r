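---
title: "Methods: detecting and orienting fine-scale genomic clines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and orienting fine-scale genomic clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clinekit)
```

# The problem

Genome-wide SNP data sampled at many closely spaced sites within one
country show, at most, very weak allele-frequency structure: mean pairwise
Weir–Cockerham Fst between subpopulations in the 10⁻⁴–10⁻³ range, with
roughly half of all per-SNP estimates non-positive. The analytical
question is whether, underneath that weak differentiation, genomic
diversity follows a *geographic gradient* (a cline), what compass
orientation it has, and whether such a gradient requires an ancient
demographic explanation — or whether recent events (for example a coastal
strip left uninhabited for a millennium and then recolonized from
neighboring areas) produce an indistinguishable pattern. `clinekit`
implements the full chain of methods for this question, plus the
spatially explicit simulator and a synthetic-data generator that make
every stage testable against known ground truth.

# Quality control

Stages run in a fixed order: individual screening → missingness → exact
HWE → LD pruning.

**Tukey IBS screening.** Within each subpopulation all pairwise IBS
distances are pooled; an individual whose *median* distance to the other
members exceeds Q3 + k·IQR of the pool is a genetic outlier, and a pair
below Q1 − k·IQR is related (the member with more missing genotypes, or
the lexicographically larger id on ties, is dropped). k defaults to 1.5.
The per-individual summary is the median because the criterion in use in
the field ("large distances to the rest") is not formalized; the mean and
minimum are reasonable alternatives and the median is the most robust of
the three. Two properties matter for interpretation: (i) quartile fences
flag ≈0.5–1% of pairs on *any* homogeneous Gaussian-like pool, so a few
exclusions per cohort are expected even without true relatives — which is
also why re-running QC on its own output can flag a few new borderline
pairs (the marker filters, by contrast, are idempotent given a fixed
individual set); and (ii) the power to detect a frequency-shift outlier
grows with the SNP count — an offset of 0.15 on half the SNPs moves an
individual's median distance by ≈0.005, which is invisible against the
fence width at 10³ SNPs and reliably detected from ≈2×10⁴ SNPs up.

**Missingness.** A SNP is dropped when its missing rate is *strictly*
greater than 10% in at least one subpopulation (a 2/20 site is kept).

**Exact HWE.** The conditional exact test enumerates all heterozygote
counts compatible with the observed allele counts; the p-value sums the
probabilities of outcomes no more likely than the observed one.
Monomorphic samples give p = 1. A SNP is removed when any subpopulation
shows p < α/(n_SNPs × n_subpopulations) (Bonferroni; α = 0.05). Note the
Bonferroni denominator depends on the number of SNPs tested, so the filter
is, strictly, defined relative to its input panel.

**LD pruning.** Markers are scanned in map order; a marker is kept iff
|Kendall τ-b| < 0.5 against every already-kept marker within 500 kb on the
same chromosome. τ-b is computed from the 3×3 genotype contingency table
with tie correction in O(n); pairs with a missing genotype are dropped,
and an undefined τ (monomorphic comparison) does not block a marker. Scan
order is map order — deterministic and reproducible; the choice of scan
order is not standardized in the field.

# Relationship matrices

* **IBS distance**: one minus the mean fraction of shared alleles over
  jointly typed SNPs, with allele-count overlap sharing
  (shared = 2 − |gᵢ − gⱼ|, so het–het shares both alleles). This
  convention has to be documented because "IBS distance" is used loosely;
  the alternative (het–het shares 1) changes distances but not orderings.
* **Squared-difference distance**: d²ᵢⱼ = Σₛ(Gᵢₛ−Gⱼₛ)²/nᵢⱼ over jointly
  typed SNPs.
* **Covariance**: double centering, cᵢⱼ = −½(d²ᵢⱼ − d̄²ᵢ. − d̄².ⱼ + d̄²..).
  For complete data this equals the centered genotype Gram matrix divided
  by the SNP count (a tested identity).
* **IBD sharing**: chromosomes are partitioned into elementary intervals
  at the union of segment endpoints; interval s of length lₛ (bp) covered
  by πₛ *pairs* gets weight F(s) = lₛ/πₛ (0 if uncovered);
  W_tot = Σ F(s); Wᵢⱼ sums F over the intervals pair ij covers, divided
  by W_tot; the distance is 1 − Wᵢⱼ. πₛ counts pairs rather than
  individuals to keep F consistent with the pairwise W it weights.
  Lengths are physical bp (a genetic map is not part of the inputs). An
  empty segment table yields all W = 0 (distance 1) rather than a
  division error.

# Ordination

Classical MDS is the eigendecomposition of the double-centered squared
distance matrix (`stats::cmdscale`). When negative eigenvalues occur and
correction is requested, the smallest additive constant making the
configuration Euclidean (Cailliez) is added to the off-diagonal
dissimilarities and reported; axis variance fractions are taken against
the positive part of the corrected spectrum. Procrustes comparisons use
the symmetric convention (both configurations centered and unit-scaled,
reflections allowed) with r = √(1 − m²) and permutation p-values from row
permutations (`vegan::protest`). Ordinations are compared with geography
at the subpopulation level — per-site means of individual coordinates
against (longitude, latitude) pairs without projection; at the ~300 km
extent of the Dutch design the planar distortion is negligible relative
to sampling noise. Gaussian-mixture clustering of MDS coordinates uses
`mclust` with BIC selection over component counts and covariance
parameterizations.

# Differentiation

Per-SNP Weir–Cockerham θ uses the variance-components estimator (a, b, c)
over the included subpopulations; negative per-SNP estimates are *kept*
(they carry the information that about half of all SNPs show no
differentiation). Combined pairwise Fst between two subpopulations is the
ratio of summed a components to summed (a+b+c) across SNPs; SNPs
monomorphic in both members contribute 0/0 and are skipped; negative
combined values are clamped to 0 in the pairwise matrix only. The
pairwise matrix is restricted to subpopulations with at least 10
individuals: on the shipped 54-site table this floor retains exactly 46
subpopulations (a strict "more than 10" reading would retain 45; the
inclusive floor is used and is configurable).

AMOVA partitions squared Euclidean distances on genotype dosages (pairs
rescaled over jointly typed SNPs) into among-group,
among-subpopulation-within-group and within-subpopulation components with
the standard unequal-size coefficients; negative components are reported
with a flag, not clamped. The among-group test permutes sites among
groups — note its attainable p-value floor is set by the number of
distinct site partitions, not by the permutation count; with few sites
per group that floor can be well above 1/(B+1).

# Spatial statistics

**Autocorrelogram.** Pairwise geographic distances (individuals inherit
their site's coordinates; within-site pairs sit at distance 0) are split
into 24 equal-count classes by default — equal-count avoids empty classes
on strongly clustered designs; equal-width binning is available. Class h
gets r_h = (mean codeviation cᵢⱼ over the ordered pairs in h) / (mean
self-codeviation cᵢᵢ over the individuals incident to h); because the
double-centered covariance has zero row sums, the null expectation of
this ratio is −1/(N−1), the familiar small negative offset of
autocorrelation coefficients. The null shuffles individuals among
subpopulations (site sizes
preserved — which also keeps the class occupancies fixed, making the
permutation exact for the design). Per-class p-values are two-sided. The
combined P is Fisher's combination of per-class pseudo p-values,
*calibrated against the same permutation null*: the Fisher statistic is
recomputed for every permutation replicate and the combined P is the rank
of the observed statistic among them. This keeps the combined P uniform
under the null despite the strong dependence between distance classes
(plain Fisher combination across 24 dependent classes is not calibrated;
published descriptions of combined correlogram tests differ, so the
calibrated form is used and recorded).

**Bearing correlogram.** For each angle θ on a 1° grid over [0, 180) the
geographic matrix is weighted as gᵢⱼ(θ) = dᵢⱼ·cos²(αᵢⱼ − θ) (αᵢⱼ the
initial bearing between sites, clockwise from north) and r(θ) is the
Mantel correlation with the genetic matrix; the profile is 180°-periodic
and its argmax orients the cline. One permutation set is shared across
angles. A caution established while validating: r(θ) is flat under
isotropy only when pair distance and pair bearing are independent — true
for symmetric designs (sites on a regular polygon give a spread of ~0.01)
but false for irregular or elongated designs, where spreads above 0.2
occur with purely distance-driven genetic structure. Argmax locations
remain meaningful (rotation-equivariant, a tested property), but the
*amplitude* of the profile should not be read as evidence of anisotropy
on an irregular design.

**Geodesics** use the haversine formula with R = 6371.0088 km.

# Gradient scan and placement

The per-SNP gradient model is binomial-logistic regression of allele
dosage (0–2) on standardized site coordinates, fit by IRLS; the steepness
score is ‖a‖, which is invariant to allele relabeling. This is a fully
specified stand-in for spatial-ancestry gradient estimation: it preserves
the quantity being scanned (how fast a SNP's frequency changes per
standardized km) with a transparent estimator. Separation or
non-convergence caps the slopes and flags the fit; flagged SNPs are
excluded from the scan. Individual placement maximizes the joint binomial
likelihood of an individual's genotypes over the fitted logistic surfaces
(BFGS from the centroid) with a weak Gaussian penalty (sd 5 standardized
units) that pins down directions the fitted gradients barely constrain.
Placement of the *same* individuals used for fitting leaks geography:
under a completely flat model, in-sample placements still correlate with
true sites (Procrustes r ≈ 0.95 in our checks) because each individual's
genotypes contributed to the slopes. Null behavior must therefore be
assessed out-of-sample, and the package's tests do so.

Local Moran's I flags markers whose extreme scores cluster:
Iᵢ = n/((n−1)·S²) · (Zᵢ−Z̄) · Σⱼ wᵢⱼ(Zⱼ−Z̄), with wᵢⱼ = 1 for markers
within 50 kb on the same chromosome, n the neighbor count, and Z̄, S² the
genome-wide mean and sample variance (a window-local variant is available
behind a switch; published forms of this statistic are ambiguous about
which moments are local). Significance
comes from reshuffling scores across all markers, one-sided for positive
local autocorrelation. The default permutation count is 10,000 because
the conventional reporting threshold p < 5×10⁻⁴ is unreachable at 1,000
permutations (minimum attainable p = 1/1001) — a deliberate, documented
deviation from the 1,000 sometimes quoted.

# The synthetic-data generator

`generateClinalDataset()` plants a logistic cline: site frequency
p_s(site) = logistic(α_s + β_s·u(site)), with u the site coordinate
projected onto the unit vector at the cline bearing (clockwise from
north) and rescaled to span 1 across the sampled extent. Site frequencies
are *deterministic* given (α_s, β_s); individual binomial sampling is the
only noise, which keeps parameter-recovery targets sharp. Baseline
frequencies are uniform on (0.1, 0.5); per-SNP frequency ranges are
uniform on (0, clineStrength) with random sign; steep SNPs get twice the
maximum range. The default clineStrength = 0.05 was chosen once so that,
at the shipped table's cleaned sample sizes, the generated cohort sits in
the weak-differentiation regime of the study system: mean pairwise
combined Fst ≈ 9×10⁻⁴, mean clamped per-SNP Fst ≈ 2×10⁻³, and ≈50% of
per-SNP estimates non-positive. Outliers are frequency-shift outliers
(+0.15 on a random half of the SNPs); related pairs copy 75% of one
member's genotypes. What the generator does *not* emulate: linkage
disequilibrium beyond planted duplicates, genotyping batch effects,
admixture from outside the sampled region, and realistic site-frequency
spectra — so green recovery tests demonstrate that the estimators work,
not that real cohorts are this easy.

# The lattice simulator

`runDemography()` is deterministic: per generation, each occupied cell
grows logistically with its layer's parameters (hunter-gatherer wave:
K = 500, r = 0.5, m = 0.4; farming wave: K = 5000, r = 0.8, m = 0.8 —
per-cell capacities quoted at a coarse raster scale),
emits fraction m of its deme split equally among habitable 4-neighbors,
and caps at carrying capacity. When farming migrants reach a
hunter-gatherer cell the deme merges fully into the farming layer (an
assimilation weight of 1; richer layer-interaction schemes exist in
dual-layer simulators but are not identifiable from the published
settings, so full merger is the exposed default). The discontinuity
variant sets K = 0 on the coastal cells for generations 70 down to 36
before present — occupants are removed and immigration blocked — with
natural recolonization from neighbors afterward. `runGenetics()` adds
drift in an Rcpp kernel: each occupied cell redraws its allele
frequencies binomially (2N gametes, N rounded) from the
migration-weighted parental pool; demography is genetics-independent, so
the same history can be re-drifted under any seed. SNPs start uniform
(0.05, 0.95) in the origin deme and are ascertained at pooled sample
MAF ≥ 0.03.

The scaled preset (`toyScenario()`) uses a 40×40 world, both waves
starting in the southeast corner at 135 and 90 generations BP, and 39
sample cells in a mid-latitude block at the western ("coastal") edge, 28
of them coastal. Problem sizes were chosen as the package's desk-scale
study design: the wave front (≈0.6 cells/generation after founder
attenuation) reaches the sample block around generations 50–35 BP, so in
the discontinuity variant the entire coastal strip is founded by
post-window recolonization from inland neighbors at 35 BP, while the
continuity variant's coast is settled by the expansion wave itself — the
two colonization histories the scenario comparison contrasts. Real-valued
deme sizes below 10⁻⁶ are treated as extinct; binomial sampling uses
N ≥ 1.

# Numerical and design notes

* All permutation p-values use the add-one convention (1 + hits)/(B + 1)
  and are therefore bounded below by 1/(B+1).
* Every source of randomness flows from one master seed through named
  substreams, so enabling or disabling a pipeline stage does not perturb
  the others; reruns are bit-identical.
* Dosage coding counts the alternate allele as declared by the source
  file; for PED/MAP the in-file minor allele is the alternate, ties
  broken toward the alphabetically smaller allele. Missing is NA, never
  0. Positions are 1-based bp; coordinates are WGS84 decimal degrees.
* Distance-kind matrices must be symmetric within 1e-9 with a zero
  diagonal; matrices with missing cells are refused by MDS and the
  covariance step with a pointer to QC.
* Known limitations: the AMOVA distance is squared Euclidean on dosages
  (the field's software defaults vary); the combined-P and r_h
  normalizations of the autocorrelogram follow the reconstructions
  documented above because published renderings of these formulas are
  inconsistent; IBD sharing weights physical lengths, not genetic map
  lengths.
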