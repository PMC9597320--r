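---
title: "Methods: JIP-test screening of drought responses in wheat seedlings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: JIP-test screening of drought responses in wheat seedlings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ojipscreen` classifies plant genotypes by their photosynthetic and
biochemical response to osmotic (PEG-induced) drought, using fast
chlorophyll *a* fluorescence induction as the primary phenotype. This
vignette documents the models and procedures the package implements, the
parameters that matter, the synthetic-data generator that makes the whole
pipeline testable, and the numerical and design choices taken where more
than one defensible option existed.

## 1. The fluorescence transient and the JIP-test

A dark-adapted leaf exposed to a saturating light pulse emits a
fluorescence rise from the origin O (read at 50 µs) through the
intermediate steps J (~2 ms) and I (~30 ms) to the peak P (F~M~), the
OJIP curve. The JIP-test treats the cardinal fluorescence values of this
curve as a minimal energy-flux model of photosystem II:

* Quantum yields: φ~P0~ = 1 − F~0~/F~M~ (maximum PSII photochemistry),
  ψ~E0~ = 1 − V~J~ (electron transport past Q~A~⁻), φ~E0~ = φ~P0~ψ~E0~,
  δ~R0~ = (1 − V~I~)/(1 − V~J~) (transfer to PSI end acceptors),
  φ~R0~ = φ~E0~δ~R0~, where V~t~ = (F~t~ − F~0~)/(F~M~ − F~0~).
* Specific fluxes per active reaction centre: TR~0~/RC = M~0~/V~J~ with
  M~0~ = 4(F~300µs~ − F~0~)/(F~M~ − F~0~) the initial relative slope
  (ms⁻¹); ABS/RC = TR~0~/RC ÷ φ~P0~; ET~0~/RC, RE~0~/RC and DI~0~/RC
  follow by the yield chain.
* Phenomenological fluxes per cross-section on two bases, ABS/CS~0~ ≈ F~0~
  and ABS/CS~m~ ≈ F~M~ (the standard "Phi" approximation), each times the
  corresponding yield; RC/CS = φ~P0~(V~J~/M~0~)·ABS/CS on both bases.
* Pool descriptors: S~m~ = (complementary area)/(F~M~ − F~0~) with time in
  ms, N = S~m~M~0~/V~J~, and S~m~/t~FM~.
* Performance indices: PI~ABS~ = [γ~RC~/(1−γ~RC~)]·[φ~P0~/(1−φ~P0~)]·
  [ψ~E0~/(1−ψ~E0~)] with γ~RC~/(1−γ~RC~) = φ~P0~V~J~/M~0~, and
  PI~TOT~ = PI~ABS~·δ~R0~/(1−δ~R0~); driving forces are their log10.

39 parameters are emitted per transient (`jip_parameter_names()`).

**Numerical choices.** Marker fluorescence is interpolated linearly in
log10(time): OJIP grids are log-spaced and linear-in-t interpolation
overshoots the early steps. Default markers are O = 50 µs, L = 150 µs,
K = 300 µs, J = 2 ms, I = 30 ms; only the O marker is fixed by the
measurement convention, the others follow the standard JIP-test usage and
are configurable. F~M~ is the curve maximum with plateau ties resolved to
the earliest time (deterministic); a maximum sitting on the last recorded
sample with positive end slope sets a `truncated_p` flag. The
complementary area is integrated trapezoidally on the recorded grid from
the O marker to t~FM~. The "RC/CS" quantity is computed on both CS bases
and reported as `RC_CSo` and `RC_CSm`; tables default to the CS~0~ basis.
Degenerate transients (F~M~ ≤ F~0~, V~J~ ∈ {0,1}, V~I~ = 1) raise errors
rather than returning silent NaNs; a non-positive PI yields an NaN driving
force with a warning.

## 2. L- and K-bands

Double-normalized curves W~OJ~ = (F~t~−F~0~)/(F~J~−F~0~) and W~OK~ =
(F~t~−F~0~)/(F~K~−F~0~) are built per replicate, averaged per genotype ×
arm (after log-time resampling onto a common grid), and differenced:
ΔW = W~stress~ − W~control~. The K-band is the signed extremum of ΔW~OJ~
inside 200–1000 µs; the L-band the signed extremum of ΔW~OK~ inside
80–300 µs. The windows bracket the nominal 300 µs / 150 µs steps while
excluding the normalization anchors, where ΔW is zero by construction;
both windows are configurable. A positive K-band indicates inhibition of
the oxygen-evolving complex, a positive L-band loss of PSII antenna
connectivity. Because the amplitude of a between-mean difference has no
within-genotype replication of its own, dispersion is reported as the SD
of per-replicate amplitudes obtained by pairing each stress replicate
curve against the control mean curve; the across-genotype one-way ANOVA
with Tukey HSD letters runs on those per-replicate amplitudes. Amplitude
ties resolve to the earliest time.

## 3. Biochemical indices

The printed assay equations are implemented directly: cell membrane
integrity CMI = [(1 − P~int~/P~tot~)/(1 − C~int~/C~tot~)]·100 with
P~int~ the sum of dehydration and rehydration conductivities; relative
water content RWC = (FW−DW)/(TW−DW)·100; electrolyte leakage
EL = (EC~1~/EC~2~)·100; MDA from (A~532~−A~600~) with ε = 155 mM⁻¹cm⁻¹,
expressed in nmol g⁻¹ dry weight; proline from an ordinary-least-squares
standard curve at 520 nm in µmol g⁻¹ DW; pigments from the 470/644.8/661.6
nm acetone-extract equations. Because MDA and proline are extracted from
fresh tissue but reported per dry weight, the conversion is explicit
input (dry mass, or fresh mass plus a dry-matter fraction) rather than a
hidden constant. Out-of-range values are returned with warnings, never
clipped: a negative ΔA or a CMI below zero is information about the assay,
not something the software should repair.

## 4. Effect-size screening

For every genotype × parameter cell the stress and control arms are
summarized and compared by the Hedges standardized mean difference:
d = (x̄₁−x̄₂)/SD~pooled~, SD~pooled~² = [(n₁−1)SD₁² + (n₂−1)SD₂²]/(n₁+n₂−2),
with the small-sample correction g = d·[1 − 3/(4N−9)], N = n₁+n₂. The
95% CI uses the Hedges–Olkin normal-approximation standard error
√(N/(n₁n₂) + g²/2N); the p-value is the two-tailed pooled-variance
Student t-test of the mean difference (df = N−2), consistent with the
pooled-SD framework (not Welch). Both the CI of g and the raw mean
difference are reported; no multiple-testing correction is applied across
the matrix, matching the screening (not confirmatory) intent. Missing
cells are flagged, never imputed; zero pooled SD with unequal means is
reported as an infinite effect rather than an arbitrary large number.

Contract-level ANOVA is provided around the screen: one-way ANOVA with
Tukey–Kramer studentized-range pairwise tests and a greedy insert-absorb
compact letter display, and a two-way genotype × treatment model with
Type III sums of squares under sum-to-zero contrasts (via `car::Anova`)
plus the model R².

## 5. Multivariate classification

* **KMO.** Sampling adequacy from the anti-image partial correlations of
  the inverse correlation matrix; near-singular matrices (unavoidable when
  18 genotypes are described by 39 correlated parameters) are ridged by
  1e-8 with a warning.
* **PCA.** Eigendecomposition of the correlation matrix of standardized
  active variables; supplementary variables are correlated with the score
  vectors post hoc and never influence the axes. Components are retained
  up to 80% cumulative explained variance by default (configurable),
  mirroring the usual practice of keeping the smallest set that explains
  ~80% in this kind of screen. Eigenvector signs are fixed so the
  largest-magnitude coordinate is positive, making results reproducible
  across LAPACK builds.
* **Oblimin rotation.** Direct oblimin at γ = 0 (direct quartimin, the
  common default) by the oblique gradient-projection algorithm, started
  from the identity, tolerance 1e-6 on the projected-gradient norm, at
  most 1000 iterations; non-convergence is an error carrying the
  criterion trace. Variable contributions are squared pattern loadings
  normalized to 100 per factor — pattern rather than structure, because
  contribution tables in the screening literature derive from the rotated
  pattern. Factor signs follow the largest-|loading| rule.
* **Clustering.** Genotypes are clustered on their retained component
  scores by Ward (ward.D2) agglomeration cut at k, whose cluster means
  then seed Lloyd k-means run to convergence — the "hierarchical k-means"
  scheme that removes k-means' dependence on random initialization. With
  k = "auto", k in 2..min(8, n−1) maximizing the mean silhouette width of
  the refined solution is chosen. The procedure is fully deterministic
  for a given input.

The clustering input is the genotype × parameter matrix of stress-minus-
control mean differences, standardized per parameter (an option switches
to bias-corrected effect sizes instead). The mean difference is the
default because the screen's second-stage ordination is defined on the
difference test; the effect-size variant reweights parameters by their
within-genotype noise and is offered for sensitivity analysis.

## 6. The synthetic experiment

The generator exists so that every stage of the pipeline can be tested
against a known truth. One transient is
F(t) = F~0~ + (F~M~−F~0~)·Σ~s~ a~s~/(1 + (τ~s~/t)^h~s~), a sum of four
log-time Hill sigmoids (s ∈ {K, J, I, P}; default τ = 300 µs, 2 ms,
30 ms, 200 ms) whose amplitudes a~s~ sum to one. This reproduces the
O-J-I-P step morphology with seven interpretable parameters; it is a
phenomenological forward model, not an electron-transport simulation.

Four archetypes perturb the control shape:

| archetype | shape deltas | band signature | trait signature |
|---|---|---|---|
| cluster1 | 0.06 amplitude from P to I, F~M~ ×1.05 | K ≈ 0 | traits ≈ control |
| cluster2 | F~0~ ×1.1, F~M~ ×0.9, a~K~ +0.08 | K, L > 0 | proline ×1.5, leaf MDA ×1.4, RWC ×0.88 |
| cluster3 | F~0~, F~M~ ×0.85, a~K~ −0.04 | K, L < 0 | proline ×2, leaf MDA ×1.6, carotenoids ×0.8 |
| cluster4 | 0.06 amplitude from I to P | K ≈ 0, S~m~, N up | proline ×2.5, traits else ≈ control |

The default experiment is 18 genotypes (5/4/6/3 across the archetypes) ×
2 arms × 20 transient replicates (720 transients) and 6 biochemical
replicates per arm. Between-genotype heterogeneity within an archetype is
a lognormal CV of 3% on the shape parameters; replicate-to-replicate
plant variation a CV of 2%; per-point instrument noise a multiplicative
CV of 1% (exposed in config — continuous-excitation fluorometers are
quiet instruments, and 1% is a deliberately conservative placeholder).
Biochemical replicate noise is lognormal with CV 8% on the index targets,
reduced to 0.3× for RWC because a ratio of three weighings has far
smaller replicate error than a colorimetric assay; raw measurements
(weights, conductivities, absorbances) are obtained by inverting the
index equations, so the derived indices hit the targets by construction.
Control-condition targets (RWC 92%, EL 10%, leaf MDA 20 nmol/g DW,
proline 5 µmol/g DW, Chl a 1.2 mg/g FW) are ordinary well-watered wheat
seedling values. All randomness flows from one master seed through named
substreams, so regeneration is byte-identical.

**What the generator does not emulate:** connectivity (sigmoidal O-J
kinetics beyond the Hill shape), instrument saturation and detector
nonlinearity, day/block effects, spatial correlation among replicates,
genotype × assay interactions beyond a multiplicative shift, and any
mechanistic link between the fluorescence and biochemical responses
(they are coupled only through the archetype labels). Passing the
recovery tests therefore shows the pipeline's statistics behave correctly
on data with the designed structure — not that real wheat panels will
separate this cleanly.

## 7. Problem sizes and verification

The test-suite and acceptance checks run at desk scale, chosen to keep a
complete run in minutes while leaving Monte-Carlo margins comfortable:
1000 random transients for the JIP identity sweep, 50 seeded experiments
for cluster recovery and band-sign ordering, 20 for the null pipeline,
5000/2000 draws for t-test type-I and CI coverage. The headline check is
recovery: on the default experiment the pipeline must re-identify the
four archetypes (ARI ≥ 0.9, auto-k = 4) in at least 90% of seeds, while a
null experiment (all genotypes control-like) must show no archetype
signal. Arithmetic-level checks pin each formula to an independent
oracle: a spreadsheet-style transcription for all 39 JIP parameters, hand
arithmetic for CMI/pooled-SD/Hedges, the equicorrelated closed form for
KMO, and a general-purpose optimizer for the oblimin criterion.

## 8. Known limitations

* The JIP-test's CS fluxes use the F~0~/F~M~ approximation of absorbed
  flux per cross-section; no leaf-optics correction is attempted.
* Band amplitudes are window extrema; if a band sits exactly at a window
  edge in unusual material, the window must be widened in config.
* Type III ANOVA requires every genotype × treatment cell occupied; the
  function refuses rather than reparameterizes.
* The oblimin contribution table is pattern-based; packages that report
  structure-based contributions will differ for strongly oblique factors.
* With 39 correlated parameters and 18 genotypes, the second-stage
  correlation matrix is singular by construction; KMO on it is reported
  after ridging and should be read qualitatively.
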