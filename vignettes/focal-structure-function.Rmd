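---
title: "Focal structure–function analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focal structure–function analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic data do and do
not emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## 1. The problem

In glaucoma, retinal ganglion cell axons die; function (light sensitivity,
measured by standard automated perimetry as per-location *total deviation*
in dB) and structure (peripapillary retinal nerve fiber layer thickness,
RNFL-T, and capillary density, CD, of the superficial vascular complex)
decline together, but not linearly. RNFL-T in particular exhibits a *floor*:
residual glial and vascular tissue persists after axons are gone, so at
severe field loss the structural slope flattens. Conventional analyses
relate global or sectoral structure to global function. The focal approach
implemented here relates *each of the 74 analysed 30–2 field locations* to
the specific peripapillary tissue its axons traverse.

## 2. From field location to peripapillary wedge

**Trajectory model.** Nerve fiber bundles are modelled in a disc-centred
polar frame (degrees of visual angle; x nasal, y superior; the fovea sits
temporally near ±180°). A bundle entering the optic disc at angle
`phi0` on the circle `r = r0` follows

    phi(r) = phi0 + b(phi0) · (r − r0)^c(phi0),     r ≥ r0 = 4°,

with `b ≥ 0` superiorly (bundles arc toward the temporal raphe at +180°)
and `b ≤ 0` inferiorly. The hemifield-specific coefficient functions
`b(·)`, `c(·)` are tanh-shaped tables loaded from a versioned JSON config
(`inst/extdata/trajectory_default.json`), so an alternative atlas is a
drop-in replacement. The shipped tables reconstruct the published average
arcuate trajectories for the superior and inferior temporal regions; across
the nasal region (|phi0| < 60°), where bundles run nearly straight and the
package had no printed coefficient table to consume, `b` tapers smoothly to
zero as `b(60°)·(|phi0|/60)²` with `c` frozen at its boundary value. This
taper is a synthetic interpolation — it preserves continuity and the strict
monotonicity of `phi(r; ·)` in `phi0` (verified numerically out to r = 42°),
which is what the inversion below requires — and the config is labelled
"approx" accordingly. All geometry tests are self-consistency and symmetry
oracles, deliberately independent of atlas fidelity.

**Eye fitting.** The model frame is anchored to each eye by a similarity
transform: disc centre to the origin, a y-flip (image rows run downward),
rotation aligning the individual fovea→disc axis with the canonical one
(disc at (15, 2)° nasal/superior of the fovea), and scaling of the
individual fovea–disc distance onto the canonical 15.13°. No
ganglion-cell displacement correction is applied to central field
locations, and field→retina mapping is plain point reflection through
fixation (field superior ↔ retina inferior, field temporal ↔ retina
nasal); left eyes are mirrored into right-eye orientation at ingest so one
convention serves everywhere.

**Wedges and ring arcs.** A field location maps to the unique `phi0` whose
trajectory passes through its retinal position (1-D root finding; the
monotonicity above guarantees uniqueness within a hemifield). The 95% CI
wedge spans `phi0 ± 1.96·s`, where `s = variability_sd_deg` (default 6°) is
the inter-individual spread of disc-entry angles; it is a config value
documented as model-derived, not estimated by this package. The pixel mask
contains every pixel between the two bounding trajectories from `r0` out to
the scan edge (the wedge outer extent follows the scan boundary). The OCT
ring arc is obtained by evaluating the two *bounding trajectories* at the
3.5-mm-ring radius rather than reusing the `phi0` interval, because
trajectories curve between `r0` and the ring; intervals are half-open so
adjacent arcs partition the circle. Wedges are clamped at the temporal
raphe (±180°), the model's genuine discontinuity.

## 3. OCT-A preprocessing

The en-face superficial-slab angiogram is binarized by local adaptive
thresholding (pixel > mean of its 0.1-mm neighbourhood + 0.02 gray levels;
the method is config-exposed because the upstream description of
binarization is method-agnostic). Large vessels are isolated with a
multi-scale Hessian (Frangi) vesselness filter (scales 0.03–0.12 mm,
β = 0.5, structure-sensitivity c set per scale to half the maximal Hessian
norm), and this is the one place where implementation overturned the
original design sketch: a plain threshold at 0.5 of the max-normalized
vesselness produces masks systematically wider than the vessel (the
multi-scale maximum broadens ridge support) and misses vessel stretches
crossed by capillary texture. The final design smooths the vesselness
response (0.03 mm), thresholds at 0.5, and *gates the region by the
binarized bright pixels*, so the mask takes the vessel's true width;
removal additionally dilates the mask by 1 px as a safety margin so
undetected vessel borders do not leak into capillary density. Border bands
where the padded Hessian is unreliable are suppressed. Finally the binary
maps are nearest-neighbour resampled and cropped to the common analysis
frame, exactly 4.11 mm over 960 px centred on the disc; 15° of visual angle
corresponds to 4.11 mm, and the single constant 0.274 mm/deg
(`mm_per_degree()`) is shared between the imaging and trajectory modules.

## 4. Focal metrics

* `focal_cd`: perfused fraction of the wedge. The denominator *excludes*
  large-vessel pixels by default — the quantity is capillary density, not
  total vascular density; `include_large_vessel_area = TRUE` restores the
  literal all-pixels reading. An ROI with an empty denominator yields a
  flagged missing value, never 0 (a zero would masquerade as severe loss).
* `focal_rnflt`: arithmetic mean of the profile samples in the (possibly
  wrapping) half-open ring arc.
* Global CD excludes the large-vessel mask and, by default, a 0.9-mm-radius
  disc mask (configurable; whether the upstream measure excluded the disc is
  not documented, so the choice is explicit).

## 5. Per-location models

At every analysis location, `fVFD` is regressed on `fCD` (Mv), `fRNFL-T`
(Mt), and both plus their interaction (Mvt), by OLS across eyes with
listwise deletion (n reported per location; at least 10 complete records
required). `r_p` is the Pearson correlation between fitted and observed
fVFD — for the univariate models this equals the absolute predictor–response
correlation, for Mvt it is the multiple correlation, hence `r_p ∈ [0, 1]`
and the nesting inequality `r_p(Mvt) ≥ r_p(Mv), r_p(Mt)` holds identically.
The log-likelihood is the Gaussian profile likelihood, AIC counts the error
variance as a parameter, and both nested comparisons (Mvt vs Mv, Mvt vs Mt)
are likelihood-ratio tests with df = 2 (each drops one main effect and the
interaction). Significance is reported raw at α = 0.05 and 0.001 across the
74 locations, with no multiple-testing correction by default (an option
exists), matching how such focal maps are conventionally reported.

## 6. Segmented mixed model and the Davies test

The pooled analysis regresses the *structural* value on fVFD with a random
intercept per eye:

    s_ij = β₀ + u_i + β₁·x_ij + δ·(x_ij − ψ)₊ + ε_ij,   u_i ~ N(0, σ_b²)

where `s` is fCD or fRNFL-T and `x` is fVFD in dB. This orientation is
forced by the units of the quantities the analysis reports: slopes in
structure-per-dB and a breakpoint in dB ("fVFD at BP" is ψ itself). On this
plane the floor effect appears as a *flatter* slope left of ψ.

ψ is estimated by iterative linearization: at the current ψ the working
model adds `U = (x − ψ)₊` and `V = −1[x > ψ]`; the coefficient γ on `V`
measures the gap a wrong ψ leaves at the kink, and ψ is updated by
`γ/δ̂`, with step-halving at the covariate's 5–95% quantile bounds and
damping when updates oscillate; convergence is declared when the update
falls below 1e-4 of the covariate range. `SE(ψ) = SE(γ)/|δ̂|` (delta
method); slope CIs are Wald. The point estimates come from a final refit
without the gap term.

The mixed model itself is a random-intercept LMM fitted by *profiled REML*
written in-package: for fixed λ = σ_b²/σ_e² the GLS solution has closed
form via per-subject whitening, and λ is optimized in one dimension. This
is orders of magnitude faster than a general fitter — the Muggeo loop, the
Davies grid and the simulation-based acceptance criteria need thousands of
fits — and it is validated against `lme4` (coefficients, variance
components, standard errors, ML likelihood) in the test suite; `lme4`
remains the independent oracle, not the production path. With a single
record per subject the random intercept is unidentifiable, λ → 0, and the
fit collapses to segmented least squares (tested against a grid-search
oracle).

The Davies test guards the breakpoint's existence against the
nuisance-parameter-under-the-null problem: variance components are
estimated once from the no-break null model, the slope-change Wald
statistic is computed by GLS at 10 candidate breakpoints between the 5th
and 95th covariate percentiles, and the candidates are combined by Davies'
upper bound for the supremum of a Gaussian process (two-sided, capped at
1, floored above 0). Estimating the variance components once is a
score-type implementation choice that keeps the test inside the time
budget; its empirical size is verified by simulation in the acceptance
suite (the bound is conservative by construction).

## 7. The synthetic cohort: what it is and is not

Damage is parameterized *on the disc-entry angle*: each eye receives a
diffuse component plus 1–3 arcuate Gaussian clusters in `phi0`, scaled so
the mean noiseless fVFD over the analysis locations hits a target MD.
Because the renderer, the profile generator and the field exam all read the
same damage field through the same trajectory mapping the pipeline uses,
structural and functional ground truth are consistent by construction —
this is what makes closed-loop tests meaningful rather than circular at the
*measurement* level: the pipeline must re-derive the wedge geometry,
separate capillaries from vessels, and average the right profile samples to
reproduce the truth table.

Stated-world defaults (chosen once, anchored to the kind of cohort the
method targets): 46 eyes; target MDs stratified in equal thirds over the
early (> −6 dB), moderate (−6 to −12) and advanced (< −12) bands within
−26–0 dB; perimetric floor −35 dB; damage→dB link with breakpoint at
d = 0.45 and 20 dB per unit damage before it vs 48 after, putting the
designed structural breakpoint at −9 dB with the flatter structural slope
on the severe side; capillary density from 0.35 (healthy) to a 0.05 floor;
RNFL from a 90-µm double-hump template to a 55-µm floor; structural noise
σ_b = 0.02/σ_e = 0.02 (density) and 6/5 µm (thickness) — thickness
deliberately noisier relative to its dynamic range, so the designed
correlation ordering is Mvt > Mv > Mt; VF test-retest noise 1.5 dB; four
arcade vessels of width 0.08 mm. The rendered angiogram draws vessels
first, then oriented capillary segments thinned/filled per
(entry-angle × radius) cell to match the density field exactly outside
vessels.

What the generator does **not** emulate: OCT speckle and decorrelation
statistics, projection artifacts, segmentation failures, media opacity,
eye-movement artifacts, longitudinal progression, and realistic perimetric
noise heteroscedasticity (noise grows with defect depth in real SAP). Two
consequences deserve emphasis. First, per-location correlations on
generator output are *cleaner* than published clinical values — a green
ordering test establishes the designed ordering, not clinical effect sizes.
Second, the generator's healthy ceiling (many locations at fVFD ≈ 0 with
structure at base level) plus test-retest noise creates a second, stronger
bend near 0 dB on the structure–function plane; a single-breakpoint
segmented fit on a *noisy* full cohort may lock onto that ceiling bend (and
is then reported non-converged or with a near-zero breakpoint) rather than
the designed −9 dB floor bend. With noise off the ceiling mass lies exactly
on the mild-side line and the designed break is recovered to within
rounding — that invariant is tested. This mirrors a genuine ambiguity of
single-breakpoint models on bounded clinical scales, and is why the
breakpoint-recovery acceptance criterion is run on data drawn from the
segmented model itself.

## 8. Numerical choices

* Wedge masks and the per-pixel entry-angle field use vectorized bisection
  over `phi0` with the coefficient tables pre-tabulated on a 0.05° grid;
  the scalar inversion used for the 74 field locations is exact
  (`uniroot`, tol 1e-9, round-trip residuals ~1e-10°).
* FFT Gaussian convolution uses replicate padding; Hessians are central
  differences of the smoothed image, σ²-normalized.
* REML λ is optimized on log scale over e^±12 with an explicit boundary
  check at λ → 0; singular working designs (degenerate breakpoint
  candidates) yield NA Wald statistics and are dropped from the Davies
  grid.
* Binary maps are resampled nearest-neighbour only — normalization never
  reintroduces gray levels, and normalizing an already-normalized map is
  bit-identical (idempotence is tested).
* The analysis default keeps 74 locations (76 minus the blind-spot pair at
  (+15, ±3)°, indices 36/46 in the package's row-major indexing). A third
  exclusion, when a study requires one, is an explicit config option rather
  than a guess.

## 9. Known limitations

* The nasal trajectory taper is an interpolation, not a published table;
  wedge geometry nasal to the disc inherits it (the config is swappable).
* The Davies bound is conservative; its size is verified empirically but
  p-values near the threshold should be read as upper bounds.
* `SE(ψ)` is a delta-method approximation; coverage is verified by
  simulation at cohort scale but degrades for weak slope changes.
* Large vessels are excluded from capillary density but not from the RNFL
  thickness itself — vascular tissue inside the RNFL remains a known
  confounder of the thickness channel.
* The pipeline consumes device-exported en-face slabs and ring profiles; it
  does not segment volumes, detect the fovea/disc, or undo projection
  artifacts.
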