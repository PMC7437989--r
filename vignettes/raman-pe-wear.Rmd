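---
title: "Quantifying polyethylene phase composition and wear from micro-Raman spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polyethylene phase composition and wear from micro-Raman spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanpe)
```

## The physical model

Ultra-high molecular weight polyethylene (UHMWPE) — the bearing material of
acetabular cups in hip prostheses — is a three-phase solid: crystalline
lamellae with orthorhombic packing, an amorphous matrix of mixed
trans/gauche conformers, and an intermediate anisotropic disordered
"third" phase whose chains keep a prevailing trans conformation but have
lost lateral order. Articulating wear changes this microstructure, and the
changes are visible in the Raman spectrum through a handful of marker
bands (all positions in cm^-1):

| band | assignment | role |
|------|------------|------|
| 1416 | CH2 bending, orthorhombic crystal | crystallinity marker |
| 1085 | C–C stretching, amorphous | amorphous marker |
| 1295 + 1305 | CH2 twisting doublet | conformation-independent internal reference |
| 1130 | C–C stretching, all-trans sequences (all phases) | all-trans marker |
| 1065 | C–C stretching, different symmetry from 1130 | orientation reference |
| 1441, 1461 | CH2 bending envelope | strengthen with amorphous content; not quantified |

Five parameters are derived from integrated band areas. The three-phase
mass fractions follow the Strobl–Hagedorn band-ratio formalism,

$$\alpha_o = \frac{A_{1416}}{0.46\,A_{1295+1305}}, \qquad
  \alpha_a = \frac{A_{1085}}{0.79\,A_{1295+1305}}, \qquad
  \alpha_b = 1 - (\alpha_o + \alpha_a),$$

and the conformer contents follow the Lagaron/Naylor equations,

$$\text{all-trans} = \frac{A_{1130}}{0.80\,A_{1295+1305}}, \qquad
  \text{ortho-trans} = 1.78\,\frac{A_{1416}}{A_{1130}}.$$

The calibration constants are stored exactly at their published precision
(`pe_calibration()`); they come from calibration of band ratios against
X-ray and calorimetric crystallinity and are deliberately never
re-derived here. Because every parameter is a ratio of areas from the same
spectrum, all five are invariant under global intensity scaling — an
invariant the test suite enforces to 1e-9.

Two structural facts shape the API. First, $\alpha_b$ is obtained by
difference, so unsuitable band choices can push it negative; the package
returns the negative value with a `negative_alpha_b` flag rather than
clipping, because a negative third phase is diagnostic information.
Second, $A_{1130}$ appears in the numerator of the all-trans equation and
the denominator of the ortho-trans equation, so any wear process that
strengthens the 1130 band moves the two parameters in opposite
directions — the package's trend analysis quantifies exactly this
inverse relation.

## Measuring the band areas

`measure_band_areas()` implements the measurement protocol on a
baseline-corrected spectrum covering 1040–1480:

* **Overlapped regions are deconvolved by curve fitting.** The 1040–1110
  region (1065 + 1085) and the 1395–1500 bending region (1416 + 1441 +
  1461) are fitted with sums of pseudo-Voigt profiles by bounded
  Levenberg–Marquardt least squares (`minpack.lm`), with analytic
  component areas. The bending region must be fitted rather than
  integrated: with realistic widths, roughly 40% of the 1441 band's area
  falls inside any sensible 1416 window, and no local-baseline trick
  separates them.
* **Isolated bands are integrated directly.** The 1130 band (window
  1110–1150) and the twisting reference group (1270–1330) are measured by
  trapezoidal integration with an endpoints-line local baseline, after
  subtracting the fitted models of the neighbouring regions, and the
  result is divided by the closed-form fraction of a reference
  pseudo-Voigt captured by that window under that protocol
  (`pv_window_fraction()`, `effective_capture`). Without this correction
  the slowly decaying Lorentzian tails bias a ±20 window by about
  8% of a pure Lorentzian's area; with it, noiseless recovery of all five
  areas is accurate to well under 1%.
* **Cross-talk is removed by alternating peel-off sweeps.** Each quantity
  is re-measured on the spectrum minus the current model of all other
  bands; two sweeps leave residual cross-talk below 0.5%, which the
  round-trip tests verify.

### Parameterization and constraints

Components are parameterized by (area, center, FWHM, Gaussian fraction).
Bounds: areas nonnegative, centers within ±8 of their initial position,
FWHM within global limits 3–40 and, by default, within 0.6–1.6× the
configured width. The Gaussian/Lorentzian mixing is *fixed* at the
configured value (0.5) by default rather than fitted: at the
photon-noise levels these acquisitions reach, the Lorentzian tail weight
is essentially unidentifiable, and Monte-Carlo measurement on the
synthetic generator showed that freeing it roughly triples the standard
deviation of the overlapped-band areas (cup-level $\alpha_o$ SD 0.077 vs
0.026 at default noise) and introduces a percent-level bias in
$\alpha_a$. `fit_region(..., fix_mixing = FALSE)` restores the fully
free profile for users with high-SNR data. A free linear baseline is
included in each fitted region to absorb residual background and
distant-band tails.

Negative fitted or integrated areas are clipped to zero and flagged, so
the derived fractions stay nonnegative where the physics requires it.

### Baseline correction

The published protocol says only that spectra were baseline-corrected;
the package's default (`baseline_spec()`) is a linear baseline through
two band-free anchor windows, 1020–1035 and 1480–1495, flanking the
analysis range. A polynomial variant (degree ≤ 5) is available for curved
fluorescence backgrounds; it requires at least degree + 1 anchor windows
(the gap at 1180–1260 between the 1130 band and the twisting doublet is
the natural third window). Band measurement is deliberately robust to
the residual of this step: the endpoints-line integrals and the fitted
linear baselines absorb any leftover offset or tilt, which matters
because Lorentzian band tails slightly elevate the anchor windows
themselves.

## The synthetic generator

No instrument data are distributed with the study, so `ramanpe` ships a
generator that emulates it: `invert_composition()` maps phase targets
$(\alpha_o, \alpha_a, \text{all-trans})$ exactly onto band areas
(inverting the equations above), and `render_spectrum()` draws the eight
bands as pseudo-Voigts on a 1000–1500 axis at 1 cm^-1 steps with a
polynomial baseline and additive Gaussian noise of standard deviation
$\text{scale}\cdot\sqrt{\text{signal} + \text{floor}}$ — photon-like
without requiring integer counts. Conventions the equations do not
constrain, chosen once as typical of polymer Raman spectra and never
revisited:

* FWHM 10 for the sharp crystalline/trans bands, 18 for the broad
  amorphous-sensitive ones, Gaussian fraction 0.5;
* $A_{1065} = 0.6\,A_{1085}$, so the orientation ratio is well defined
  and tracks the amorphous pool;
* twisting group split 55/45 between 1295 and 1305 (only the sum is
  consumed downstream);
* bending bands $A_{1441} = 1.2\,\alpha_a A_{1295+1305}$ and
  $A_{1461} = 0.9\,\alpha_a A_{1295+1305}$, rendered but never
  quantified;
* reference area $A_{1295+1305} = 20000$ intensity·cm^-1, giving peak
  signal-to-noise ratios around 20–30 at the default noise scale.

`simulate_study()` adds the cohort structure: per material, cup-level
targets drawn around the group mean, point-level targets within cups,
three loaded (worn) cups and three non-loaded control (unworn) cups that
double as gravimetric soak controls, and twelve points per cup. Loaded
gravimetry rows carry the measured mass loss (true loss minus the cup's
own fluid gain); soak rows carry the measured gain; the analysis adds
the material-matched mean soak gain back
(`correct_mass_loss()`). Everything is reproducible from one seed, and a
scenario serializes to JSON (`write_scenario()`), which is how the
packaged fixtures `fig7_std_unworn` / `fig7_std_worn` are stored.

The default scenario (`default_study_scenario()`) encodes the study's
group structure. The published record prints only a handful of numbers
(the selected standard cup's $\alpha_o$ of 0.59 unworn and 0.62 worn;
mass losses of about 100 mg for standard and vitamin-E cups versus 30–40
mg for the cross-linked ones); the remaining group means were chosen to
reproduce the reported qualitative orderings — standard PE more
crystalline than the 75-kGy cross-linked material, the 50-kGy material
with the highest amorphous and all-trans content and lowest ortho-trans,
vitamin-E cups indistinguishable from standard when unworn — and the two
wear mechanisms: in standard PE the orthorhombic phase grows at the
expense of the amorphous phase, in cross-linked PE the third phase does,
while the all-trans content rises everywhere. Between-cup and
within-cup SDs default to 0.02 and 0.015, consistent with cup-level SDs
of a few hundredths.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: cosmic-ray spikes, detector etaloning or
wavenumber miscalibration, fluorescence with structure beyond a low-order
polynomial, band asymmetry, physical polarization response (polarized
acquisitions are emulated statistically, as independent draws of the same
underlying spectrum), and any chemistry (oxidation) that would change
band positions or widths.

## Cohort statistics

The unit of analysis is the cup: twelve point measurements are averaged
(`summarize_cup()`, flagged points excluded and counted) and groups are
compared on n = 3 cup means. At that size the chi-squared approximation
to the Kruskal–Wallis statistic is poor, so for total N ≤ 12 the p value
is computed by exhaustive enumeration of all assignments of the pooled
mid-ranks to the groups (369,600 for four groups of three; the
distribution is cached for the tie-free case). The test statistic is the
standard tie-corrected H from `stats::kruskal.test`; only the reference
distribution changes. Simulation in the acceptance suite confirms the
exact test holds the 5% level (mildly conservatively, as a discrete test
must) over 2000 null cohorts.

Post hoc, `dunn_bonferroni()` computes Dunn's z on pooled ranks with tie
correction, two-sided normal p values, Bonferroni adjustment
$p_\text{adj} = \min(1, m\,p)$ over the $m = k(k-1)/2$ pairs, and a
compact letter display built from the maximal cliques of the
not-significantly-different graph, so two groups share a letter exactly
when their adjusted p is ≥ α. Comparisons are computed even when the
omnibus test is not significant but flagged `post_hoc_not_licensed`,
mirroring the conditional protocol. Note that at n = 3 per group the
Bonferroni-adjusted Dunn test has little power: even a cohort whose
cross-linked cups lose a third of the mass of the standard cups may earn
a single shared letter. That is a property of the published protocol at
this sample size, not of the implementation.

Percent changes upon wear are computed per group as
$100(\text{worn}-\text{unworn})/\text{unworn}$ on group means, and the
relation between the all-trans and ortho-trans changes is summarized by
an ordinary least-squares line with its correlation
(`trend_fit()`). Under both simulated wear mechanisms the slope is
negative, the inverse relation the equations predict.

## Numerical choices and degenerate inputs

* Optimizer: `minpack.lm::nls.lm`, maximum 500 iterations, `ftol` and
  `ptol` 1e-10; initial areas from the window maxima through the
  pseudo-Voigt peak-height relation.
* Intensities are normalized to their maximum before fitting and areas
  rescaled afterwards, making the whole measurement exactly equivariant
  under intensity scaling (this, not optimizer luck, is why the
  scale-invariance test passes at 1e-9).
* Exact inputs that would divide by zero are flagged, not guessed:
  `ortho_trans` is NA when $A_{1130}=0$, the orientation ratio is NA when
  $A_{1065}=0$, and a nonpositive reference area is an error.
* All-zero fit regions are an error (`degenerate`), as are regions with
  fewer points than 1.5× the parameter count (`underdetermined`). Two
  identical components in one region return a tied solution whose summed
  area is preserved.
* Target draws that leave the valid simplex ($\alpha_o, \alpha_a \ge 0$,
  $\alpha_o + \alpha_a \le 1$, all-trans within $[\alpha_o, 1]$) are
  redrawn, with a bounded retry count so absurd scenarios fail loudly.

## Problem sizes in the test suite

The suite simulates at the study's own scale where the check needs it
(288 spectra for cohort structure; 50-seed Monte-Carlo with 12 points per
cup for bias; 2000 null cohorts for test calibration, fast because the
permutation null is cached) and at reduced scale where it does not
(two-cup, three-point studies for plumbing checks). The full suite and
the acceptance script each run in a couple of minutes on one core.

## Known limitations

* The tail-capture correction and the fixed mixing assume the configured
  band shapes; a real instrument whose bands are substantially more
  Lorentzian than assumed would need the shape table recalibrated (fit a
  few high-SNR spectra with `fix_mixing = FALSE` and update
  `band_config()`).
* The amorphous-band area from the stretch-region fit carries a small
  positive bias (a few percent) at default noise, a known curvature
  effect of nonlinear fitting with a free baseline; $\alpha_o$ and
  all-trans, measured by fit-plus-integration, are unbiased within the
  suite's Monte-Carlo resolution.
* JCAMP-DX support covers the plain AFFN `XYDATA`/`XYPOINTS` tables;
  compressed ordinate encodings (SQZ/DIF/DUP) are not read.
* The polarization comparison is a scalar coincidence metric with a
  conventional 0.05 threshold validated against the noise-only null; it
  is not a physical model of Raman tensor orientation.
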