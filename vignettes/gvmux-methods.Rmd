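---
title: "Pressure-domain multiplexing of acoustic reporter genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-domain multiplexing of acoustic reporter genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvmux)
```

## The problem

Acoustic reporter genes (ARGs) encode gas vesicles (GVs) — air-filled protein
nanostructures that buckle reversibly under the compressional phase of an
ultrasound pulse and thereby scatter nonlinearly, separating them from linear
tissue echoes. Engineering the GvpC shell-stiffening protein shifts the
buckling threshold, so two reporters can coexist in one field of view and be
told apart purely by how their nonlinear signal grows with transmit pressure.
`gvmux` implements the computational side of such two-tone imaging:

1. a forward model of reporter pressure response with irreversible collapse
   and depth-dependent attenuation;
2. seeded generators for every input the pipeline consumes (reference
   curves, 2-D image series, screening plates, variant libraries);
3. pixelwise non-negative least-squares (NNLS) unmixing of pressure spectra
   into per-reporter "acoustic channel" images, flat or depth-corrected;
4. screening analytics (ROI automation, QC filters, threshold/yield/collapse
   estimators, acoustic-map fits, CNR);
5. global protein alignment distances for mutagenesis libraries.

## Forward model of one reporter

A reporter is parameterized by its nonlinear signal threshold `P_o` (kPa),
its maximum nonlinear yield `S_max` (a.u.), and its irreversible collapse
pressure `P_c` (kPa). The noiseless response is a scaled logistic

$$ s(P) = \mathrm{baseline} + S_\max \,\sigma\!\left(\frac{P - p_\mathrm{mid}}{w}\right), $$

attenuated multiplicatively by the collapsed fraction of the population.
The empirical curves this emulates are monotone, saturating, and
threshold-like; the logistic is the minimal form with those properties. Its
two shape parameters are never set by hand: `calibrate_reporter()` solves
them in closed form so that

* the noiseless curve crosses the threshold estimator's detection limit
  exactly at the nominal `P_o` (the calibration invariant that makes
  threshold recovery well-posed), and
* the curve reaches `f_cap = 0.998` of `S_max` at the 1,200-kPa window cap,
  so the windowed-maximum yield estimator sees essentially the full yield.

Collapse is irreversible. With `collapse_width = 0` (the default) it is a
hard step: a population exposed to any pressure above `P_c` is permanently
dark from the next acquisition on — the frame acquired *at* the collapsing
pressure is still recorded intact, because a frame measures the state at
transmit time. A logistic collapse transition of configurable width is
available; the near-field behaviour of soft-shell reporters suggests the
transition is narrow, so the hard step is the default.

### Default reporters

| name | `P_o` (kPa) | `S_max` (a.u.) | `P_c` (kPa) |
|---|---|---|---|
| `bARG560` (soft shell, gvpC-deleted) | 560 | 5,900 | 1,220 |
| `bARG710` (evolved GvpC-L154P)       | 710 | 5,000 | 1,500 |
| `bARGSer` (wild-type parent operon)  | 820 | 1,000 | 1,700 |

Thresholds, the two printed yields and the soft-shell collapse pressure are
the published characterization values. The evolved reporter's yield is
described only as comparable to the soft shell's; 5,000 a.u. encodes
"comparable, slightly below". The stiffer reporters' collapse pressures are
not printed; they are set above the nondestructive window (1,500 and
1,700 kPa), where their exact values are immaterial to every analysis in the
package — only *soft-shell* collapse defines the window.

### Attenuation

Pressure is an amplitude quantity, so attenuation uses the amplitude-decibel
convention throughout:

$$ P(d) = P_0 \cdot 10^{-\alpha f d / 20}, $$

with `alpha` in dB cm⁻¹ MHz⁻¹ (soft-tissue default 0.5), `f` the transmit
frequency (default 15.625 MHz) and `d` the depth in cm. The closed-form
inverse (`attenuation_depth_for()`) locates, for example, the depth above
which a given source amplitude still collapses the soft reporter in situ.

## Synthetic data: what is emulated, and what is not

All generators are pure functions of their parameters and an integer seed
(`withr::with_seed`), so every artifact regenerates byte-identically.

* **Reference replicate curves** (`make_reference_replicates()`): the
  collapse-aware sweep plus i.i.d. zero-mean Gaussian noise of s.d.
  `default_noise_sd()` = 30 a.u., clipped at zero because nonlinear signal
  magnitudes are nonnegative. 30 a.u. places the background two orders of
  magnitude below in-sample peaks, consistent with the ~100 a.u. in vitro
  pixel threshold.
* **GFP control** (`gfp_control_model()`): no gas vesicles, no
  pressure-dependent signal; its curves are pure clipped noise.
* **2-D scenes** (`phantom_scene()`, `render_scene()`): per-reporter
  concentration maps on a depth × lateral grid; per depth row the in-situ
  pressure follows the attenuation model and collapse is tracked per row and
  reporter along the sweep. B-mode is a deliberately simple proxy — affine
  in total concentration with a bright top edge on the sample — because the
  pipeline uses B-mode only for ROI placement and as an expression filter.
  The postcollapse frame is rendered after exposing every pixel to the
  maximum scheduled pressure. **Not** emulated: speckle texture, motion,
  aberration, anatomical structure. Passing tests therefore show estimator
  and unmixing correctness under the stated noise model, not robustness to
  those real-data effects.
* **Noise injection** (`add_noise()`): `I(m) = I0 + m R`, `R` zero-mean
  Gaussian with per-frame s.d. matching the background region (or an
  explicit list). This generator is *not* clipped, preserving the additive
  model exactly; the replicate-curve generator is, per its own contract.
* **Screening plates** (`make_screen_plate()`): traits drawn along a
  negative-log acoustic-map trend `S_max = a + b ln(P_o)` with Gaussian
  scatter (`sample_variant_traits()`); defaults (`b = −5150`,
  `sd(ln P_o) = 0.10`, scatter 152 a.u.) give a theoretical trend
  R² of 0.92 via `trait_trend_theoretical_r2()`. Expression is bimodal:
  ~12% assembly failures around a quarter of nominal expression, successes
  tight (5%) around nominal — solid-phase GV expression mostly saturates,
  and a wide unimodal expression spread would bury the acoustic-map trend
  under multiplicative yield scatter. The truth table records the
  *windowed* operational yield (the noiseless in-window maximum times
  expression): high-threshold variants genuinely cannot express their full
  yield inside the nondestructive window, which is exactly what produces the
  shallow secondary sink of real screens.
* **Variant libraries** (`make_variant_sequences()`): per-sequence mutation
  counts from a negative binomial (a gamma-mixed Poisson, i.e. a wide
  mixture over mutagenesis stringencies) with mean 5.36 and s.d. 13.5;
  substitutions at distinct positions. The bundled parent
  (`synthetic_gvpc_parent()`) is a *synthetic* GvpC-like sequence (charged
  helical 33-mer repeats, ~190 aa), not the natural protein.

## Unmixing

The multiplexing matrix `M` is `N reporters × P pressures`; row `r` is the
mean nonlinear signal of a pure reference of reporter `r` over its sample
ROI at each retained pressure. Acquisitions above the nondestructive cap
(1,200 kPa, the soft reporter's collapse pressure) are trimmed from the tail
before `M` is built — no column of `M` ever corresponds to a pressure above
the cap. Pixels whose nonlinear signal never surpasses the mode-dependent
threshold (100 a.u. in vitro, 200 a.u. in vivo) are zeroed out.

Each retained pixel's pressure spectrum λ is decomposed by NNLS:

$$ \hat c = \arg\min_{c \ge 0} \lVert M^\top c - \lambda \rVert_2 . $$

For two channels the active-set solution is closed-form (the interior
stationary point if nonnegative, else the better single-channel projection);
for more channels the Lawson–Hanson solver of `pracma` is used. Rank-deficient
matrices trigger a degeneracy warning at construction.

**Depth correction.** Under attenuation, a pixel's in-situ pressure depends
on its depth, so a single `M` acquired at the 5-mm calibration depth
misstates the spectra elsewhere; `build_m2d()` evaluates each reporter's
collapse-aware sweep at the attenuated pressures of every image row, and
`unmix_depth_corrected()` unmixes each row against its own `M(d)`. Rows are
matched to the nearest `M2d` depth; a mismatch beyond half a row spacing is
an error — explicit failure beats silent interpolation. At zero attenuation
the method reduces exactly to flat unmixing.

**Normalized difference.** The default bounded contrast between the two
channels is `(S1 − S2)/√(S1² + S2²)` ∈ [−1, 1], antisymmetric under channel
swap. The difference-of-squares radical sometimes quoted for this quantity
is imaginary whenever the second channel dominates; it is retained verbatim
behind `variant = "as_printed"` (NA where the radicand is nonpositive) and
the sum-of-squares form is the default. Stored coefficients are never
rescaled; display scaling is a rendering concern.

## Screening analytics

* **ROI automation**: per lateral column, the first B-mode row above an
  Otsu two-class threshold marks the sample top; a fixed-depth band below it
  is the ROI. All-constant images yield an empty mask with a warning.
* **QC**: keep iff `S_B ≥ 175` a.u. (boundary kept) and postcollapse
  nonlinear signal ≤ 100 a.u. (signals that survive the collapse pulse are
  artifacts, e.g. bubble reflections, not GVs; the cutoff reuses the pixel
  threshold as the least arbitrary constant and is a flag).
* **Threshold `estimate_po()`**: at each scheduled pressure in increasing
  order, a one-sided Welch test (sample > GFP control) at α = 0.05,
  uncorrected — matching the field's uncorrected multiple-t-test
  convention. The detection point is the first pressure that is significant
  *and* whose sample mean reaches the control-derived detection limit
  (pooled control mean + 2 s.d.); without the consistency requirement the
  uncorrected test on few clipped replicates throws spurious low-pressure
  detections at which the limit crossing is undefined. The returned
  threshold interpolates the mean curve's limit crossing between the
  bracketing grid points **linearly in log-signal**: below its midpoint the
  logistic rises exponentially, so the log-domain chord reproduces the
  noiseless crossing essentially exactly, whereas a plain linear chord is
  systematically low by roughly a fifth of the grid spacing (−20 to −30 kPa
  at the default ~100-kPa spacing) — enough to consume most of a ±40 kPa
  recovery tolerance. Where the predecessor mean is nonpositive the
  interpolation falls back to linear.
* **Detection limit**: control curves are clipped zero-mean Gaussians, for
  which mean + 2 s.d. has the closed form
  `noise_sd · (φ(0) + 2√(1/2 − φ(0)²)) ≈ 1.566 · noise_sd`
  (`control_detection_limit()`); calibration targets this level. The
  empirical limit from only 4 control curves has s.d. ≈ 6.5 a.u. (the s.d.
  estimator is noisy on skewed clipped data) and would dominate threshold
  error, so plate characterization and the recovery analyses derive the
  limit from a pooled 16-replicate control strip — a 96-well screen
  routinely dedicates a control strip — while the sample itself keeps the
  published n = 4.
* **Yield `estimate_smax()`**: maximum of the mean curve over scheduled
  pressures at or below the window cap; pressures above the cap are never
  consulted.
* **Collapse `estimate_pc()`**: linear interpolation of the 50%-survival
  crossing of an exposure sweep; on a 10-kPa grid a hard-step truth at
  1,220 kPa is recovered at 1,225 kPa (half a grid step).
* **Acoustic map**: OLS fit of `S_max = a + b ln(P_o)` over kept variants;
  two points give an exact, explicitly flagged degenerate fit. Region
  membership (primary/secondary sink, bridge) is point-in-polygon against
  user-supplied polygons in priority order — the sinks are defined
  visually in practice, and auto-clustering them would invent a method.
* **CNR**: `|S_target − S_background| / σ_background`.
* **dB fold change**: `20 log10(a/b)` (amplitude convention, configurable),
  NA where either curve is nonpositive.

## Sequence distances

`needleman_wunsch()` is a three-state (Gotoh) affine-gap global aligner:
the first residue of a gap run scores `gap_open` (−10), each extension
`gap_extend` (−1); default substitution matrix BLOSUM62, identity scheme
available; `X` is permitted and scored as a mismatch. Traceback ties are
broken deterministically — substitution, then gap-in-second-sequence (up),
then gap-in-first (left) — so alignments are bit-reproducible. The distance
is `D = 1 − matches / alignment length` ∈ [0, 1]; the published per-region
distance normalization is not fully specified, so printed region values are
treated as qualitative anchors, not recovery targets. Scores are verified
against exhaustive enumeration of all global alignments for short pairs.

## Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; generators restore
  the caller's RNG state.
* Pipeline outputs (`run_pipeline()`) regenerate byte-identically from
  (config, seed); logs are JSON-lines without timestamps for that reason.
* Image series serialize as multi-frame 32-bit TIFF normalized to [0, 1]
  with the affine intensity scale in a JSON sidecar (float TIFF storage is
  only defined on [0, 1]); round-trip accuracy ~1e-4 relative.
* Degenerate inputs fail loudly: rank-deficient `M` warns at construction;
  all-zero reference rows yield zero coefficients; empty ROIs, mismatched
  schedules and misaligned depth axes are errors before any computation.
* Tests run at deliberately small problem sizes chosen to exercise every
  code path with comfortable statistical margins: 32×32 to 60×24-pixel
  scenes, 96- and 879-variant plates, 10,000 random NNLS compositions,
  500 enumeration-checked alignments.

## Known limitations

* The threshold estimator's sampling s.d. at the published n = 4 is
  ≈ 20–35 kPa under the default noise model — the same order as the
  published threshold uncertainties. Individual fixed-seed draws can
  therefore fall just outside a ±40 kPa band even though the estimator is
  essentially unbiased (over 30 seeds: means 557/693/810 kPa for the
  560/710/820 reporters). More rarely (a few percent of seeds), a
  sub-threshold grid mean fluctuates over the detection limit with a
  just-significant test, shifting the crossing bracket one grid step early
  and producing a gross underestimate — the known cost of an uncorrected
  per-pressure test on four replicates.
* The acoustic map fitted on *estimated* thresholds is attenuated relative
  to the generating trend (R² ≈ 0.8 versus 0.92 configured) by threshold
  estimation error in the regressor; the generator-truth cloud matches the
  configured R² within ±0.05.
* B-mode realism is intentionally minimal; ROI automation is validated
  against the generator's edge convention, not against clinical B-mode.
* No spatial regularization or joint-pixel priors in unmixing; each pixel
  is independent.
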