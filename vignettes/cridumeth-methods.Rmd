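---
title: "Paired blood methylation analysis with segmental deletions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired blood methylation analysis with segmental deletions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cridumeth` implements a blood DNA-methylation analysis for small paired
patient/control cohorts in which patients carry a segmental chromosome
deletion, modelled on Cri du chat (5p-) syndrome: probe filtering and
beta/M conversion, paired empirical-Bayes moderated t-statistics, deletion
breakpoint calling from total array intensity, two-level preranked
gene-set enrichment (CpG to promoter, promoter score to functional
category), direction-split hypergeometric over-representation of CpG
categories, bivalent-promoter scoring, linear epigenetic clocks,
reference-based cell deconvolution, and PCA quality control. A synthetic
cohort generator with planted deletions and planted gene-set effects
provides fully specified inputs whose truth is known, so every stage can
be validated end to end.

This vignette records the models, the tunable parameters, the numerical
conventions, and the design decisions taken where more than one sensible
choice existed.

# The paired design and the moderated t-statistic

Each *set* pairs one patient with one matched control; a set may carry
several samples on either side (a technical replicate of the patient, or
two age-matched controls). `pair_differences()` averages the M-values
within each side of a set and takes the patient-minus-control difference,
so the design always collapses to one difference column per set. The
statistical model is then one-sample inference on the per-set differences
`ΔM_g` — for this balanced paired layout it is equivalent to a pair-blocked
two-group linear model, but it has testable closed forms.

Per CpG `g`, `ΔM_g ~ 1 (+ covariates)` is fitted by least squares across
sets. The per-CpG residual variances `s²_g` (df `d_g = n − q`) are shrunk
towards a scaled inverse-chi-square prior `σ² = d₀·s₀²/χ²_{d₀}` fitted by
the method of moments on `e_g = log s²_g − ψ(d_g/2) + log(d_g/2)`:

* `trigamma(d₀/2) = var(e) − trigamma(d_g/2)`, solved by Newton iteration
  on the inverse trigamma (strictly monotone, so the root is unique);
* `s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2))`;
* if `var(e) ≤ trigamma(d_g/2)` the spread of variances is fully explained
  by sampling noise and the prior is degenerate: `d₀ = ∞`,
  `s₀² = exp(mean(e))`.

The moderated statistic is `t_g = effect_g / (s̃_g √v₁₁)` with
`s̃²_g = (d₀ s₀² + d_g s²_g)/(d₀ + d_g)` and `v₁₁` the intercept's unscaled
variance; p-values use `d₀ + d_g` df (normal at `d₀ = ∞`). `d₀ = 0`
reproduces the ordinary paired t exactly, `d₀ = ∞` the known-variance
z-statistic; the tests pin both limits and verify agreement with an
independent straight-line implementation of the moment equations and with
`limma::squeezeVar`/`eBayes`, which serve only as cross-check oracles.
Benjamini–Hochberg is used wherever adjusted p-values appear.

**Covariate adjustment** operates at the set level (covariates are
per-set quantities such as the age difference at sampling), keeping the
paired structure. An alternative — adjusting across individual samples
before pairing — was considered and rejected because it breaks the
one-column-per-set contract and confounds within-pair with between-pair
variation.

**Degenerate inputs.** A fully noiseless null input has `s²_g = 0` and
zero effect everywhere; `fit_variance_prior()` alone treats all-zero
variances as an error, but `moderated_t()` recognises the all-degenerate
case and reports `t = 0`, `p = 1`, so a null cohort propagates null
results downstream instead of crashing. p-values are floored at the
smallest positive double so they are never 0.

# Deletion calling from total intensity

A hemizygous deletion halves copy number and therefore the total
(methylated + unmethylated) probe intensity. For each patient the track
`log2(patient total / mean control total)` is computed per CpG along the
deletion chromosome's p-arm (telomere at position 0, arm bounded by the
centromere coordinate in the annotation), smoothed by loess — local
quadratic regression, tricube weights over the `span·N` nearest
neighbours, gaussian family, no robustness iterations, `span = 0.05` — and
evaluated at the observed CpG positions, not a uniform grid. The
breakpoint is the lowest position above `min_pos = 5·10⁶` bp whose
smoothed value exceeds `threshold = −0.25`; the 5 Mb guard exists because
the telomeric end of the arm is noisy.

Two edge regimes are made explicit rather than inherited silently from
the rule:

* a track that never rises above the threshold at an eligible position
  means the deletion extends past the scanned arm — breakpoint "none
  detected";
* a track that never *drops* below the threshold before the first
  eligible position carries no evidence of a deletion; the call is
  flagged `no_deletion` instead of being reported as a ≈5 Mb deletion.
  The rule as stated presumes every subject is a diagnosed patient;
  controls pushed through the caller must not acquire spurious deletions.

Transient later dips (interstitial-loss-like) are logged in
`later_dips`; the first recovery point is still the call. Calls are
invariant to a common intensity rescaling of all samples, and on the
generator's conditions (breakpoints uniform in 6–35 Mb, intensity halving,
lognormal noise σ = 0.2, 2,000 p-arm CpGs) recover the truth within
±1 Mb — the smoothing window (`span`·arm ≈ 2.4 Mb) sets that resolution.

# The preranked GSEA engine

Both enrichment levels use one engine. Items (CpGs, then genes) are
ranked by decreasing statistic, ties broken deterministically by id. The
enrichment score of a member set is the classic weighted
Kolmogorov–Smirnov running sum: members add `|r_i|^p / Σ_members |r_j|^p`
(weight exponent `p = 1` by default), non-members subtract `1/(N − m)`;
the ES is the extremum of largest absolute deviation, with the positive
extremum preferred on exact ties (applied with a 1e-12 tolerance, because
different summation orders differ at machine precision). The leading edge
contains the members at or before a positive extremum, at or after a
negative one. The implementation evaluates the running sum only at the
`2m` candidate extrema (at and just before each hit), which is exact and
makes the permutation null cheap; it is tested exhaustively against the
full running sum on every subset of 8-item lists and against
`fgsea::calcGseaStat`.

The null is random same-size member sets drawn without replacement from
the ranked items (`nperm` per set size, shared between sets of equal
size, seeded). Normalisation and p-values are sign-conditional:
`NES = ES / mean(|null ES| of matching sign)` and
`p = (#{same-sign nulls with |ES_null| ≥ |ES|} + 1)/(#same-sign + 1)` —
the pseudocount keeps p strictly positive. These are one concrete,
testable choice among the null schemes preranked GSEA implementations
hide; the published engines this mirrors do not document theirs to this
level. `nperm` defaults to 1000; the resolution of the smallest
achievable p is roughly `2/nperm`, which matters when an adjusted p must
clear a threshold across many sets.

A ranking whose statistics are all identical carries no order
information (the tie rule would impose an arbitrary one), so every set is
reported with `NES = 0`, `p = 1`. This is what makes a noiseless null
cohort return null enrichment.

**Level 1 (promoters/gene bodies).** Each gene's mapped CpG set
(minimum 5 CpGs) is tested against the full CpG ranking and summarised as
`score = sign(NES) · (−log10 p.adj)`, with `p.adj` floored at 1e-16 so
scores are finite. **Level 2 (categories).** Genes are ranked by that
score and functional categories (GMT gene sets, size filter 10–500 by
default at genome scale; smaller floors are appropriate for the compact
synthetic databases) are tested by the same engine. A negative category
NES therefore means less promoter methylation in patients.

**Region-exclusion reruns** re-run the t-stage on the reduced CpG
universe (not merely drop items from the fixed ranking) and then repeat
both levels — the statistics, the ranking and the null all see the same
universe.

# Direction-split over-representation

Significant CpGs (`p < 0.01`, split by sign of t; "hypo" = less
methylation in patients) are tested against CpG-category databases
(island relation, chromHMM states, transcription-factor and histone
marks) by the upper-tail hypergeometric within the fixed retained-probe
universe, categories intersected with the universe and filtered at
`min_gs = 4`, `max_gs = ∞`. The odds ratio is the 2×2 cross-product with
a Haldane 0.5 correction when any cell is zero — the effect measure is
not standardised in the literature, so the package picks one and labels
it. Note the directionality of universe masking: removing universe
members outside a category and selection *raises* that category's
hypergeometric p (the tail is decreasing in N), so exclusion reruns are
conservative for unaffected categories.

# Signatures, clocks, deconvolution, PCA

**Bivalent scoring** counts membership in the five marks EZH2, SUZ12,
H3K27me3, H3K4me2, H3K4me3 and summarises the fraction of CpGs carrying
at least `k` of 5. **The top-CpG heatmap matrix** takes the genes present
in the leading edge of ≥2 of the chosen categories, picks per gene the
promoter leading-edge CpG with the largest |t| (ties to the lower probe
id), and reports that CpG's per-set ΔM; rows are ordered by |t| (the row
order is otherwise arbitrary and had to be fixed somehow). **External
signature correlation** is the Pearson r over the CpG-id intersection of
the cohort's mean paired differences with a published signature; Δbeta is
the default scale (ΔM is equally supported — the choice matters little
because the two are monotonically related and the correlation is
computed on the same CpGs).

**Clocks** are generic linear predictors on betas with an invertible age
transform; the piecewise "horvath" map (adult age 20) is built in:
`age = 21·exp(m) − 1` for `m < 0`, else `21·m + 20`. Clock CpGs missing
from the matrix are mean-imputed up to 5% missing, an error beyond.
Proprietary coefficient sets are deliberately not shipped; any published
coefficient table loads.

**Cell deconvolution** solves `min ‖b − A·w‖²` subject to `w ≥ 0`,
`Σw ≤ 1` — nonnegative weights of reference cell-type beta profiles. The
NNLS solution is computed by Lawson–Hanson; only if it leaves the simplex
is the sum constraint activated through a heavily weighted normalisation
row (weight 10⁶·max|A|, which pins `Σw` to 1 within ~1e-7, far below the
0.05-scale errors that matter at realistic noise).

**PCA QC** is a column-centred SVD of the samples over the top-variance
CpGs (default cap 20,000), with variance fractions and PC–covariate
screens (Pearson for numeric, rank-sum for two-level covariates).

# What the synthetic cohort emulates — and what it does not

The generator reproduces the statistical structure the analysis relies
on: paired samples with optional multi-sample sets; a bimodal baseline
beta (mirror-image Beta(5,45)/Beta(45,5) modes, weight ½ each) matching
the bimodality of array betas; lognormal total intensities
(mean 10,000, σ = 0.2) split as `meth = T·β`, `unmeth = T·(1−β)`;
hemizygous halving of T on the simulated chr5 p-arm below a per-patient
breakpoint (one lost allele halves copy number, the ≈ −1 log2 drop);
planted promoter hypo-/hyper-methylation (default |Δβ| = 0.2)
concentrated in chosen gene sets, whose CpGs double as the EZH2-anchored
bivalent-mark carriers (co-occurrence 0.8); per-sample additive beta
noise (σ = 0.03); and sporadic detection failures (rate 0.001, one random
sample each). Planted-effect CpGs start at intermediate methylation
(Beta(10,10)) so a ±0.2 shift is realisable without clipping — also the
biologically apt choice, since bivalent promoters sit at intermediate
levels. Planted gene sets may overlap one another (disease categories
share genes) and are kept off chr5 by default so genome-wide effects are
separable from the deleted region. Covariates are generated independent
of effects unless `age_drift > 0`, which plants genuine age-correlated
methylation drift for adjustment and PCA tests. Coordinates are 1-based,
intervals half-open `[start, end)`, everywhere.

Deliberately *not* emulated: type I/II probe chemistry and dye bias
(hence normalisation is an identity pass-through with the plug-in point
where a background/dye correction would sit), detection-p computation
from control probes (detection p is an input), batch structure, genuine
linkage disequilibrium or realistic CpG spacing, and cell-composition
heterogeneity. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model — not robustness
to array chemistry artefacts, which only real data can probe.

Defaults are the study conditions (eight pairs, breakpoints uniform in
6–35 Mb); the validation suite runs at 1,000–6,000 CpGs, 20–120 genes and
100–2,000 permutations, sizes at which every planted effect is
comfortably detectable and the whole suite completes in well under a
minute per stage.

# Known limitations

* The caller reports the first recovery point; a true interstitial
  deletion pattern is only logged, not segmented (CBS/HMM-style
  segmentation is out of scope).
* The random-set GSEA null ignores inter-CpG correlation within
  promoters; on real arrays neighbouring CpGs are correlated, which makes
  the null anti-conservative. The paired design and the second-level
  chaining mitigate but do not remove this — a known property of
  CpG-level preranked GSEA generally.
* `min_gs`, `nperm` and the 1e-16 score floor bound the resolution of
  adjusted p-values; categories whose true p is below the permutation
  resolution are reported at the resolution, not below it.
* The accession-scale probe count (786,010 retained CpGs on the deposited
  cohort) requires the deposited intensity tables plus the published
  cross-reactive/polymorphic probe list and array manifest, which cannot
  be redistributed here; the filter itself is fully exercised on
  constructed fixtures with overlapping removal rules.
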