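---
title: "Methods: nestling gut microbiota dynamics under partial cross-fostering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nestling gut microbiota dynamics under partial cross-fostering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fosterbiome` analyses 16S OTU count tables from a partial cross-fostering
experiment on wild nestling birds sampled at two ages (day 8, just before
the swap, and day 15, one week after).  The experimental unit structure is:
nests, of which some pairs exchange half their nestlings (yielding three
bird-level treatments — `control`, `CFstay` for birds that stayed in a
cross-fostered nest, `CFmove` for birds moved to the partner nest), two
cloacal samples per bird (one per age), and two PCR replicates per sample,
sequenced alongside blank tag combinations and field/reagent negative
controls.

This vignette records the models and their assumptions, the tunable
parameters, the synthetic-data generator's construction, and the numerical
and design choices made where the problem was genuinely open.

## The filtering cascade

The decontamination pipeline (`qc_pipeline()`) runs five fixed stages, in
this order:

1. **Replicate averaging** (`merge_replicates`): the two PCR replicates of
   each biological sample are averaged read-by-read (an OTU absent from one
   replicate contributes a zero), producing fractional counts.
2. **Blank (mistag) subtraction** (`subtract_blank_signal`): blanks are tag
   combinations never assigned to a sample; reads observed there measure
   tag switching.  For every OTU seen in at least one blank, its mean
   abundance across blanks is subtracted from every other sample.  Results
   are floored at zero — negative read counts are not meaningful, and the
   floor is the only defensible truncation.
3. **Contaminant removal** (`identify_contaminants`): an OTU is a reagent
   contaminant when its maximum *and* mean abundance are both strictly
   higher in negative controls than in biological samples (means over all
   samples of the role, zeros included).  Both inequalities are strict, so
   ties are conservatively kept: removal needs positive evidence.
4. **Rare-OTU filtering** (`filter_low_abundance`): OTUs totalling strictly
   less than 0.005% of the table's grand total, and singletons (total ≤ 1
   read), are dropped.  The cutoff is evaluated on the table as it stands
   after stages 2–3, over biological samples only, because the cascade
   lists it last; the audit records per-stage counts so alternative
   orderings can be compared.
5. **Rarefaction** (`rarefy`): counts are rounded half-to-even to integers
   (they are fractional by stage 1), then each sample is subsampled without
   replacement — a multivariate hypergeometric draw — to exactly 1000
   reads.  Samples below the depth are dropped rather than scaled, the
   standard practice; the audit lists them.  One RNG stream, seeded from
   `filter_params(seed = )`, is consumed in column order, making the result
   bit-reproducible.

The audit satisfies `reads_in = reads_out + reads_removed` at every stage,
and stages chain (each stage's input is the previous stage's output).

## Diversity

Alpha diversity per sample: richness is the number of OTUs with abundance
> 0 (no minimum-count presence rule beyond rarefaction itself); Shannon
H′ is computed in nats — the source analyses do not state a base, and
natural log is the common convention; evenness is Pielou's J′ = H′/ln(S),
undefined at S ≤ 1.  Which evenness estimator the original analyses used is
not stated; Pielou is recorded in the run log so alternatives can be
swapped.

Beta diversity is the presence–absence Jaccard dissimilarity,
d(A,B) = 1 − |A∩B|/|A∪B|.  Two empty samples get d = 0 so that matrices
remain total.  Jaccard is a metric but not Euclidean-embeddable, which is
why the ordination machinery below tracks negative eigenvalues explicitly.

## Permutation statistics

All permutation tests use the +1-corrected estimate
p = (#{permutation statistic ≥ observed} + 1)/(B + 1), are seeded, and
default to B = 1000 (the permutation count stated for the distance-based
ANOVA is adopted uniformly).  Tied permutation statistics are counted as
exceedances using a small relative tolerance, so that p-values agree with
exhaustive enumeration on instances small enough to enumerate.

**Mantel** (`mantel`): Pearson correlation of the strictly-lower-triangle
entries of two distance matrices; the null permutes the sample labels of
the second matrix.  The test is one-tailed for positive association,
matching how the matrix correlations are used here.

**PERMANOVA** (`permanova`): the McArdle–Anderson partition of the
Gower-centred inner-product matrix G = −½ J D² J.  Pseudo-F for a term
uses hat matrices of the design's column spans; in the default `margin`
mode each term's sum of squares is the reduction from the full model to
the model without that term (its marginal effect).  The null permutes
sample labels freely.  Restricted permutation for repeated measures is
deliberately not implemented: the workflow runs the two ages separately,
which removes the repeated-measure structure from any one test.  Factor
degrees of freedom are levels − 1 (a 26-level nest factor has 25 df); the
run log records the convention.

**PCoA** (`pcoa`): eigendecomposition of G.  Axes with negative
eigenvalues — expected for Jaccard — are kept as *imaginary* coordinates
rather than discarded or shifted by Lingoes/Cailliez constants, because
the dispersion distances need them: with all axes retained the input
distances are recovered exactly as
(real² difference − imaginary² difference)^½.

**Dispersion** (`dispersion_to_centroid`): each sample's distance to its
group centroid in the PCoA embedding, with the real/imaginary correction
(squared distances on imaginary axes subtract; the difference is floored
at zero before the square root).  Centroids, not spatial medians, are
used.  Homogeneity among groups is an F statistic on these distances with
a null from permuting the distances freely; singleton groups get distance
0 and are excluded from the test.

**Welch + BH** (`welch_bh`): per-feature unequal-variance t tests with
Welch–Satterthwaite degrees of freedom and Benjamini–Hochberg q-values
across features, for comparing feature-table means between two groups.

**SMA regression** (`sma_slope`): the standardized major axis slope
sign(r)·sd(y)/sd(x), symmetric in x and y, appropriate when both variables
carry error — the standard choice for allometry.

## Mixed models

Responses (log richness, Shannon, distances, condition) are analysed with
Gaussian random-intercept linear mixed models, REML-fitted, with
Satterthwaite Wald tests on fixed effects.  Bird and nest-of-rearing
identity are the grouping factors where both ages enter one model.  The
Gaussian choice is deliberate: all responses here are continuous and
roughly symmetric after the stated transforms, and the original analyses
used Gaussian (nlme-style) fits despite a "GLMM" label; link functions are
out of scope.  Optional backward elimination removes the fixed term with
the largest Wald p ≥ 0.05, one per step; random effects are never
eliminated.  Grouping factors reduced to a single level are dropped, and a
model with no grouping factor falls back to OLS, which is also the
documented degenerate-fit fallback.

## Design-specific analyses

* Within-bird change: the Jaccard distance between a bird's day-8 and
  day-15 samples.
* Day-8 OTU retention: the proportion of a bird's day-8 OTUs still present
  at day 15.
* Sibling contrast (day 15, cross-fostered nests only): foster-sibling
  pairs share the nest of rearing but not the nest of origin; separated
  true siblings share the origin but not the rearing nest.  Pair distances
  are averaged per nest before testing — pairs within a nest share birds
  and are pseudo-replicates — and the foster-minus-separated difference is
  tested with nest as a random intercept.  The per-pair table is emitted
  alongside the nest means so a pair-level analysis remains possible.
* Per-treatment Mantel: the day-8 and day-15 Jaccard sub-matrices of each
  treatment group, rows matched by bird.
* Condition: the scaled mass index SMI = mass_D15 × (L0/tarsus)^b with the
  study-wide constants b = 1.87 and L0 = 19.3 mm by default, both
  re-estimable from the data (`estimate_params = TRUE` runs `sma_slope` on
  the data's own log tarsus/log mass and uses its mean tarsus); both paths
  are logged.  Weight gain is day-15 minus day-8 mass, and birds without
  positive gain are excluded from the gain models, mirroring the study's
  exclusion rule.

## The synthetic-data generator

`generate_dataset()` emulates the study so that every analysis runs, with
known truth, without any download.  Defaults reproduce the printed design:
26 nests — 18 cross-fostered in 9 pairs, 8 control — 6 nestlings per nest,
3 of 6 swapped at day 8, two ages, two PCR replicates per sample, 4 blanks,
4 negative controls, allometry constants 1.87 and 19.3 mm.

The community model is Dirichlet-multinomial, the standard overdispersed
count model for OTU tables:

* a log-normal OTU pool (sd 1.4) partitioned into phyla with day-8
  expected shares (Firmicutes 0.30, Actinobacteria 0.28, Proteobacteria
  0.30, Bacteroidetes 0.07, other 0.05);
* nest day-8 profiles ~ Dirichlet(50 × pool); per-bird profiles ~
  Dirichlet(35 × nest profile) at both ages — the two concentrations were
  chosen once so that rarefied richness lands in the ~50 → ~36 range the
  study reports, and are documented as tunable because the real data's
  dispersion is unknown without the deposit;
* the day-15 *target* of a nest mixes the physical nest's profile with the
  current occupants' mean day-8 profile (`nestmate_influence` = 0.3),
  reweights phyla (Firmicutes ×2, Proteobacteria ×0.35), and down-weights
  rare OTUs geometrically (`exp(−tail_exponent × diversity_drop ×
  rank quantile)`, defaults 8 and 0.6) — down-weighting rather than OTU
  deletion keeps retention continuous;
* each bird's day-15 profile is Dirichlet-resampled around
  λᵢ × target(rearing nest) + (1 − λᵢ) × own day-8 profile, with per-bird
  λᵢ ~ Beta(mean 0.7, concentration 12).  The nest-environment term in the
  target is what breaks the symmetry between CFstay and CFmove birds: with
  a pure occupant mixture the two groups would change equally by
  construction, whereas the nest's own contribution makes moved birds
  converge toward a profile their day-8 anchor never matched — the
  mechanism the cross-fostering design is meant to expose;
* contaminant OTUs are Poisson-abundant in negative controls (mean 80
  reads each) and trace-level (mean 0.2) in biological samples, so they
  satisfy the max-and-mean criterion in expectation; blanks carry
  Poisson(50) mistag reads drawn from the pooled community;
* tarsus and mass follow the log-log allometry with latent size driving
  both, and residual errors placed on *both* axes in the slope's
  proportion (log-tarsus error = `mass_noise_sd`/slope).  This is the
  error-in-variables structure SMA regression assumes; putting all noise
  on mass would bias the SMA slope upward by construction.  A bird's
  latent diversity retention (the overlapping mass of its two latent
  profiles) raises both its day-15 log mass (`condition_coupling` = 0.15)
  and its log gain ratio, reproducing the retention–growth association;
  ~2.5% of birds are constructed to lose weight.

All randomness flows from one seed through a single documented stream
order (pool → nest profiles → swaps → bird profiles and λᵢ → targets →
morphometrics → counts in sample order → technical samples).

**What the generator does not emulate:** transient environmental OTUs
(real day-8 communities contain many never-again-seen taxa, so the real
retention, ~25%, is lower than synthetic retention, ~60%), phylogenetic
structure, chimeras and sequence errors, depth heterogeneity beyond
Poisson, and nest-level covariates (habitat, parental effects).  Passing
recovery tests therefore demonstrates that the *estimators* behave
correctly under the study's sampling structure, not that the synthetic
data are distributionally indistinguishable from the field data; headline
field numbers (e.g. Mantel r = 0.37 in controls) are not reproduced at
desk scale, only their ordering and signs.

With λ = 0 the generator is a *null* for convergence: birds keep their
origin profiles, so foster siblings resemble strangers — but separated
true siblings then remain maximally similar, which makes a two-sided
sibling contrast significant in the direction *opposite* to convergence.
Null calibration of the contrast is therefore assessed one-directionally
(foster closer than separated at p < 0.05).

## Numerical choices

* Residual sums of squares in the distance partition can round to small
  negatives when a term explains everything; they are clamped at zero and
  the pseudo-F is then +∞ for a nonzero term SS.
* Permutation exceedance uses a relative tolerance (1e-8 on F, 1e-10 on
  r) so tied relabelings are counted despite floating-point noise.
* PCoA eigenvalues within `max|λ|·1e-9` of zero are treated as null axes.
* Counts are rounded half-to-even (R's `round`) exactly once, immediately
  before rarefaction.
* Double-empty Jaccard pairs are 0; zero-sum samples are rejected at
  normalization with the sample named.

## Problem sizes used by the tests

The test-suite simulations use the full default design (26 nests) where
the design itself is under test — contaminant recovery and the
cross-foster signatures, 20 seeds each — and a reduced design (6 nests, 80
OTUs, depth 3000) where only mechanics are exercised.  Null calibrations
use 500 replicates at n = 10–16 with 199 permutations.  These sizes give
each binomial acceptance band a comfortable margin while keeping the whole
suite in a couple of minutes.

## Known limitations

* Free permutation everywhere: no restricted/nested schemes, so PERMANOVA
  across both ages jointly would be anticonservative (the workflow never
  does this).
* The marginal-SS PERMANOVA assumes the full model is estimable; aliased
  designs are rejected rather than resolved.
* The dispersion F test permutes distances directly rather than residuals
  within groups; with very unbalanced groups a residual-permutation
  variant would be preferable.
* `welch_bh` treats features independently; no hierarchical shrinkage.
* The generator's contaminants are independent Poisson spikes — real
  reagent contamination covaries with extraction batch, which the role
  model here does not represent.
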