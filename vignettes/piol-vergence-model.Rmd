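---
title: "Vergence models for phakic supplementary lenses"
author: "piolcalc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vergence models for phakic supplementary lenses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piolcalc)
```

## The problem

Phakic intraocular lenses (PIOLs) — the implantable collamer lens (ICL)
being the canonical example — are thin meniscus lenses implanted in the
posterior chamber of a phakic eye, between the iris and the crystalline
lens, to correct large ametropia without removing the natural lens.  Two
quantities matter clinically when choosing a lens from the labelled power
schedule: the refraction correction **REF** the lens produces at the
spectacle plane, and the relative change in lateral (retinal image)
magnification **ΔM** when the spectacle correction is replaced by the
implanted lens — the driver of aniseikonia symptoms.

`piolcalc` computes both quantities by paraxial vergence propagation
through a model anterior segment, under four scenarios that combine thick
and thin models of the cornea and the PIOL:

| scenario | cornea | PIOL |
|---|---|---|
| A | thick (both radii + thickness, $n_C = 1.376$) | thick (design data) |
| B | thin (keratometric power $PC = (n_K-1)/RC_a$, $n_K = 1.3375$) | thick |
| C | thick | thin (labelled power at SLPOS) |
| D | thin | thin |

The PIOL back surface (thick model) or the thin-lens plane sits at
$\mathrm{SLPOS} = \mathrm{ACD} - \mathrm{vault}$ behind the corneal front
vertex, with a default vault of 0.4 mm (the clearance the haptics maintain
to the crystalline lens).  The spectacle plane sits at the back vertex
distance VD in front of the cornea (12 mm by default; the worked clinical
example in the README uses 14 mm — both appear in practice, so the value
is configuration, not a constant).

## The vergence calculation

All propagation uses reduced vergences $V = n/x$ in dioptres, with the
sign convention: light travels left to right, radii are positive with the
centre of curvature to the right of the vertex, converging wavefronts are
positive.  Refraction adds the surface power, $V' = V + P$ with
$P = 1000\,(n' - n)/r$ for $r$ in mm; transfer over a gap $d$ (mm) in
medium $n$ is $V' = V / (1 - \tfrac{d}{1000\,n} V)$.  Both operations are
exactly invertible, which is what makes the REF solution closed-form:

1. propagate a plane wave ($V = 0$, object at infinity) through the
   postoperative system (cornea, aqueous gap, PIOL) to just behind the
   PIOL: this is $V_\mathrm{SLPOS}$, the vergence a fully corrected eye
   must receive at that plane;
2. invert the preoperative trace (cornea only, no PIOL) from SLPOS back
   through the cornea and the air gap to the spectacle plane; the
   spectacle vergence that lands there is REF.

A ray-transfer-matrix layer (reduced-angle convention, unit determinant)
implements the same physics independently and serves as the oracle in the
test suite: element-by-element vergence propagation and the bilinear
matrix map $(DV - C)/(A - BV)$ agree to $10^{-9}$ dpt on randomly
generated systems, and re-substituting REF forward through the
preoperative system reproduces $V_\mathrm{SLPOS}$ to the same tolerance.

The magnification change multiplies the per-surface lateral
magnifications $V/V'$ over all refracting surfaces of each corrected
state:

$$\Delta M = 100\cdot\left(
  \frac{\prod V_{po}}{\prod V'_{po}}\cdot
  \frac{\prod V'_{pr}}{\prod V_{pr}} - 1\right)$$

with the preoperative state = thin spectacle of power REF + cornea, and
the postoperative state = cornea + PIOL.  For the object at infinity the
incoming vergence at the first surface of both states is zero and the
expression is formally 0/0; since the two zeros are the same object seen
by both states, they are cancelled symbolically (the first-surface
incoming vergence is dropped from both numerator products).  The package
validates this against the finite-distance limit (object at $10^6$ m),
which agrees to $10^{-6}$; everything downstream of SLPOS is common to
both states and cancels identically.  ΔM is undefined (domain error) when
the correction is exactly zero.

## The surrogate design family

Computing scenario A/B requires full thick-lens design data (front and
back radii, central thickness, material index) for every labelled power.
Disclosed ICL design data are incomplete: negative-power designs are fully
listed, positive-power designs lack the back radius, and published
schedules are figures rather than tables.  `piolcalc` therefore ships
two things:

* **completion tools** — `back_calc_index()` solves the Gullstrand
  equation $P = P_1 + P_2 - \tfrac{t}{n}P_1P_2$ for the material index
  (quadratic in the index excess over aqueous; the physical root is
  taken), and `back_calc_back_radius()` solves it for the back-surface
  power and radius.  Applied to complete negative designs the recovered
  index is 1.4490 with zero spread, and that consensus index completes
  the positive designs.  `read_design_csv()` applies exactly this
  procedure to partially specified tables.
* **a surrogate family** — `synth_design_table()` generates all 58 steps
  (−17.0 (0.5) −3.0 and 3.0 (0.5) 17.0 dpt) from parameterized schedules:
  material index 1.4490, front radius decreasing linearly from 12 mm at
  −17 dpt to 6 mm at +17 dpt, thickness 0.2 mm for all negative powers
  and growing affinely from 0.2 mm at +3 dpt to 0.6 mm at +17 dpt, with
  every back radius back-calculated so the labelled equivalent power (in
  aqueous, $n_A = 1.336$, on both sides) is reproduced exactly.

The schedules are the package's own calibration, chosen once to match the
qualitative behaviour of real collamer designs: minus lenses are thin, so
thick and thin PIOL models nearly coincide on the negative branch, while
the growing thickness of plus lenses pushes the image-side principal
plane in front of the front vertex and makes the thin-lens simplification
err by about half a dioptre at +17 dpt.  The family reproduces the
expected principal-plane geometry for every step (behind the back vertex
for minus lenses, in front of the front vertex for plus lenses, receding
from the lens as |power| decreases).  It does **not** reproduce any
manufacturer's actual radii or thicknesses; conclusions about a specific
lens model require loading its real design table via `read_design_csv()`.

## The synthetic cohort

`sample_cohort()` draws (RC_a, RC_p, CCT, AQD, LT) from a multivariate
normal whose marginal means and SDs default to the descriptive statistics
of a 2365-eye clinical anterior-segment OCT cohort (means 7.7633, 6.5751,
0.5434, 3.1256, 3.9217 mm; SDs 0.2854, 0.2473, 0.0366, 0.2381, 0.2024 mm),
truncated componentwise at ±3 SD to exclude non-physical draws, with the
manufacturer's implantability bound AQD ≥ 2.8 mm applied by rejection.
ACD = AQD + CCT holds exactly by construction and PC is derived
keratometrically.  Correlations are not published for the reference
cohort; the defaults couple the two corneal radii (0.9) and AQD with lens
thickness (−0.3) as physiologically plausible values.  The downstream
responses are near-deterministic functions of each eye's predictors, so
the fitted models are insensitive to this choice.

Two deliberate limitations: the AQD rejection acts on a distribution
whose parameters already describe a filtered population, so the realized
AQD mean sits ~0.04 mm above the nominal parameter — marginal-fidelity
checks therefore target the unaffected parameters; and the generator
emits one eye per synthetic subject directly, so the one-eye-per-patient
and repeat-measurement rules (`preprocess_biometry()`) apply only to real
tomographer exports, where those artefacts actually occur.

## The prediction study

`build_grid()` crosses a cohort with the 58-step table (scenarios A and B
only — the thick-PIOL models, since the thin-PIOL scenarios are exactly
what the thick model shows to be inadequate at high plus powers) and
`stepwise_fit()` selects predictors by bidirectional p-value stepwise
regression: start from the constant model, add the eligible excluded term
with the smallest two-sided t-test p-value while $p \le 0.01$, then remove
the worst included term while $p \ge 0.1$, until stable.  Candidates are
RC_a, RC_p, CCT, ACD, LT, PIOLP (scenario A) or PC, ACD, LT, PIOLP
(scenario B); degree 2 adds squares of all candidates, with no
interactions.  Three numerical policies make the selection deterministic
and reproducible: candidates are evaluated in lexicographic order so
p-value ties break deterministically; selection is hierarchical (a square
may enter only while its parent is present, a parent is not removable
while its square remains) — without this, x and x² are so collinear over
the narrow biometry ranges that which of the pair enters first is
seed-dependent; and performance is reported in-sample (n-normalized
residual RMSE, adjusted R², F against the constant model), matching how
such models are reported when R² rounds to 1.000.

On a 1000-eye synthetic cohort (58 000 grid rows) the scenario-A fits
recover the structure of the reference study: the REF model selects
exactly {RC_a, ACD, PIOLP, PIOLP²}; the small biometry coefficients
(≈ −0.08 dpt/mm on RC_a, ≈ +0.08 dpt/mm on ACD) reflect the near-complete
cancellation of the corneal power between the forward and the inverted
trace; the linear REF model leaves ≈ 0.8 dpt of purely structural
residual (the curvature of REF in PIOLP), which the PIOLP² term
(≈ −0.0092 dpt/dpt²) cuts to ≈ 0.2 dpt.  These are the quantities the
acceptance script recomputes; nothing in the package stores them.

## Problem sizes and tolerances

Default problem sizes used by the examples, tests and the acceptance
script: 58-step design table; 1000-eye cohorts for model fitting (the
fitted PIOLP coefficient varies by well under 0.01 across seeds at this
size); 100 random systems/eyes for property checks.  Identity-style
invariants (round trips, oracle agreement, label reproduction) are held
to $10^{-9}$; the symbolic-vs-finite ΔM comparison to $10^{-6}$, limited
by the $10^6$ m reference distance itself.  Degenerate inputs fail
loudly: zero radii without the flat sentinel, translations onto a focal
plane, geometry where the PIOL would intersect the cornea
(SLPOS − PIOLT < CCT), flat-back or non-meniscus solutions of the design
equations, and zero-power ΔM requests are all domain errors, not NaNs.

## Known limitations

Everything is paraxial Gaussian optics: no astigmatic (meridional)
powers beyond averaging the two meridians, no aberrations, no chromatic
dispersion, and no accuracy claims at large ray angles.  The vault is a
fixed configuration value, not predicted from biometry.  The surrogate
design family stands in for undisclosed manufacturer schedules, and the
synthetic cohort reproduces marginal structure only — real-data effects
(measurement noise correlations, age structure, astigmatism) are outside
what passing tests demonstrate.
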