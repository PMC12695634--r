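# gvmux — pressure-domain multiplexed ultrasound imaging of acoustic reporter genes

Acoustic reporter genes (ARGs) make engineered cells visible to ultrasound:
they encode gas vesicles (GVs), air-filled protein nanostructures that
buckle reversibly under acoustic pressure and scatter nonlinearly, unlike
tissue. Variants of the GvpC shell protein shift the buckling threshold, so
two reporters — a soft-shell construct that turns on at ~560 kPa and an
evolved stiff-shell variant that turns on at ~710 kPa — can share a field of
view and be separated purely by their pressure-response spectra, without
destroying either population.

`gvmux` implements the analysis stack for this kind of two-tone imaging, for
researchers building or screening ARGs and for anyone unmixing
pressure-sweep ultrasound data:

* **Forward model** — logistic pressure response per reporter
  (threshold `P_o`, yield `S_max`), irreversible collapse at `P_c`,
  amplitude-dB depth attenuation (`reporter_model()`, `sweep_with_collapse()`,
  `attenuated_pressure()`).
* **Synthetic data** — seeded generators for replicate reference curves,
  2-D image series over a pressure sweep (with B-mode and postcollapse
  companions), 96-well screening plates with QC truth tables, structured
  noise `I(m) = I0 + mR`, and mutagenized protein libraries.
* **Unmixing** — reporters × pressures multiplexing matrix `M` (tail-trimmed
  at the 1,200-kPa nondestructive cap), pixelwise NNLS
  `argmin_{c≥0} ‖Mᵀc − λ‖₂` into per-reporter acoustic channel images, a
  depth-corrected variant `M(d)` for attenuating media, normalized
  difference maps, channel means and mixture-linearity fits.
* **Screen analytics** — B-mode ROI automation, expression (`S_B ≥ 175`) and
  postcollapse-artifact QC, threshold/yield/collapse estimators, the
  negative-log acoustic map `S_max = a + b·ln(P_o)`, region assignment, CNR.
* **Sequence distances** — affine-gap Needleman–Wunsch with deterministic
  tie-breaking and the normalized distance `D = 1 − matches/alignment length`.

## Worked example

Estimate the three reporter parameters from synthetic acquisitions, then
unmix a 1:1 mixture scene:

```r
library(gvmux)
sch  <- default_schedule()          # 16 pressures, 330-1840 kPa, cap 1200
mods <- default_reporters()

# threshold of the evolved reporter, n = 4 noisy replicates vs GFP control
ctl <- make_reference_replicates(gfp_control_model(), sch, n = 16, seed = 101)
cur <- make_reference_replicates(mods$bARG710, sch, n = 4, seed = 3)
estimate_po(cur, ctl, sch)$P_o
#> P_o  = 708 kPa (detection limit 42.5 a.u.)

# windowed yield (noiseless curve) and collapse pressure (10-kPa sweep)
estimate_smax(sweep_with_collapse(mods$bARG710, sch)$signals, sch)
#> S_max = 4958 a.u. at 1135 kPa
sw <- collapse_survival_sweep(mods$bARG560, seq(1100, 1350, 10))
estimate_pc(sw$max_pressure_kpa, sw$surviving_fraction)
#> P_c  = 1225 kPa

# unmix a 1:1 mixture of the two reporters
pair <- mods[c("bARG560", "bARG710")]
scn  <- phantom_scene(c(bARG560 = 0.5, bARG710 = 0.5), shape = c(32, 32))
ser  <- render_scene(scn, pair, sch, noise = noise_spec(1, rep(30, 16), seed = 11))
M    <- multiplex_matrix_from_models(pair, sch)
cmap <- unmix_pixelwise(ser, M, threshold_pixels(ser, 100) & scn$rois$sample)
channel_means(cmap, scn$rois$sample & cmap$mask)
#>   reporter      mean          sem   n sem_basis
#> 1  bARG560 0.5014940 0.0007079461 289    pixels
#> 2  bARG710 0.4982149 0.0009551944 289    pixels
```

The estimated threshold (708 kPa), windowed yield (4,958 a.u., i.e. 99% of
the 5,000-a.u. model yield reached inside the nondestructive window) and
collapse pressure (1,225 kPa, half a grid step from the 1,220-kPa truth)
recover the generating parameters, and the 1:1 mixture unmixes to balanced
acoustic channels (0.501 vs 0.498 coefficient means over the sample ROI).

An end-to-end run (scene → matrix → unmixing → normalized difference →
summaries, with a manifest and JSON-lines log) is:

```r
run_pipeline(default_run_config(seed = 1), "demo", "gvmux_out")
```

or from a shell: `Rscript scripts/run_gvmux.R demo --seed 1 --out gvmux_out`.

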