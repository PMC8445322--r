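# retroflux

Quantification of intraluminal vesicle (ILV) retrofusion from live-cell
time-lapses of a protease-cleavable GFP-CD63 reporter.

## The problem

Multivesicular bodies (MVBs) are late endosomes whose limiting membrane (LM)
invaginates to form ILVs. ILVs can be degraded in lysosomes, secreted as
exosomes, or — long speculated and hard to observe — fuse back with the LM
("retrofusion"), re-exposing their membrane proteins to the cytosol.
A chemically tunable reporter makes this measurable: CD63 carries a GFP tag
with a nuclear localization signal behind a TEV-protease cleavage site, and a
split TEV protease is reconstituted on demand with a rapamycin-analog
dimerizer. Once the protease is switched on, only cytosol-exposed reporter
(on the LM and the cell surface) is cleaved; its GFP moves to the nucleus,
and endolysosomal GFP fluorescence decays. Reporter hidden inside ILVs is
protected — unless retrofusion returns it to the LM. The decay of
background-corrected, normalized endolysosomal GFP therefore reads out
retrofusion directly.

`retroflux` implements, as tested and reusable R code, the full quantitative
chain for this assay:

- **Kinetic model** (`kinetic_params()`, `simulate_pools()`,
  `predict_plateau()`, `fit_kinetics()`): a linear six-pool compartment
  model. With L the LM pool, I_dyn / I_inert the retrofusion-competent and
  -inert intraluminal pools, N the nuclear pool, D degraded and S secreted
  (fractions of initial endolysosomal reporter):

      dL/dt       =  k_retro I_dyn − k_cleave L
      dI_dyn/dt   = −(k_retro + k_deg + k_sec) I_dyn
      dI_inert/dt = −(k_deg + k_sec) I_inert
      dN/dt       =  k_cleave L
      dD/dt       =  k_deg (I_dyn + I_inert)
      dS/dt       =  k_sec (I_dyn + I_inert)

  The observable is L + I_dyn + I_inert. With an ILV:LM abundance ratio
  ρ (immunogold: ρ ≈ 2) the intraluminal fraction is f_ilv = ρ/(1+ρ), and in
  the pure-cleavage limit the decay plateaus at f_ilv (no retrofusion) or
  f_ilv(1 − φ_dyn) (a fraction φ_dyn of ILVs retrofuses). At ρ = 2 the
  no-retrofusion plateau is 2/3 — the 66–70% band against which measured
  decay (to ~41% at 6 h) demonstrates retrofusion.

- **Segmentation** (`segment_compartments()`, `measure_intensities()`):
  re-implementation of the image-analysis macro — per-frame masks for
  endolysosomes (lysosome-probe channel), nuclei (red channel), plasma
  membrane (GFP channel) and cytosol, with first/last-frame thresholds
  linearly interpolated across frames and the precedence EL > N > PM > CYTO
  guaranteeing disjoint compartments.

- **Decay readouts** (`background_subtract_normalize()`, `fit_slope_A()`,
  `remaining_fraction()`, `relative_to_control()`): the cytosol-median
  background subtraction, first-frame normalization, slope A over the
  near-linear 90–360 min phase, and condition-versus-control summaries.

- **Fate partition** (`half_life_from_pulse_chase()`,
  `exosome_mvb_fraction()`, `exosome_ratio_change()`,
  `immunogold_ratio_summary()`, `retrofusion_lower_bound()`): pulse-chase
  half-life, the secreted share of the MVB pool, exosome blot ratio changes,
  per-MVB gold-count summaries, and the lower bound on the retrofusing ILV
  fraction.

- **Synthetic data** (`generate_geometry()`, `generate_timelapse()`,
  `generate_pulse_chase_table()`, `generate_immunogold_counts()`,
  `generate_exosome_blot_table()`): seeded generators with exact ground
  truth for every stage, so the whole pipeline is validated end to end
  without any external data.

- **Pipeline** (`read_pipeline_config()`, `run_simulate()`,
  `run_quantify()`, `run_partition()`): YAML-configured batch runs writing
  TIFF/CSV/JSON, plus a thin command-line wrapper in `inst/cli/retroflux.R`.

## Worked example

```r
library(retroflux)

# an unperturbed cell: 2:1 intraluminal ratio, half the ILV pool dynamic
p <- kinetic_params(rho = 2, phi_dynamic = 0.5, k_cleave = 0.03,
                    k_retro = 0.002, half_life_h = 24, k_sec = 3e-4)
sim <- simulate_pools(p, seq(0, 540, by = 3))
curve <- decay_curve(sim$t_min, sim$EL_observable / sim$EL_observable[1])

fit_slope_A(curve)
#>   condition slope_A_per_h slope_magnitude intercept n_points ...
#> 1 control         -0.0482          0.0482     0.659       91

remaining_fraction(curve, 360)  # 0.383
remaining_fraction(curve, 540)  # 0.298

# without retrofusion the decay would stop at the intraluminal fraction
predict_plateau(kinetic_params(rho = 2, phi_dynamic = 0,
                               half_life_h = Inf, k_sec = 0))
#> 0.6666667

# fate arithmetic: 6% of whole-cell reporter secreted, 62% resides in MVBs
exosome_mvb_fraction(0.06, 0.62)
#> 0.0968

retrofusion_lower_bound(0.41, rho = 2, half_life_h = 24,
                        exo_frac_wcl = 0.06, mvb_frac = 0.62, window_h = 6)
#>   frac_secreted_of_mvb frac_degraded_of_ilv frac_retrofused_of_ilv_lower_bound
#> 1           0.0968               0.159                              0.0807
#>   frac_inert_remaining convention
#> 1                0.615   ilv_pool
```

Reading: with these parameters the normalized endolysosomal GFP decays at
0.048 h⁻¹ through the 90–360 min window and 38% of the initial signal
remains at 6 h — the measured-scale behaviour the model was calibrated to.
Since the no-retrofusion plateau is 67%, decay past it requires retrofusion.
The fate partition converts the remaining-fraction, half-life and secretion
measurements into a conservative lower bound on the retrofusing share of the
ILV pool under the documented accounting convention (see the methods
vignette; alternative conventions give materially different bounds).

A full image-level round trip is one call chain away:

```r
cfg <- read_pipeline_config()       # defaults: 512x512, 120 frames, 180 s
sim <- run_simulate(cfg)            # TIFFs + ground truth
cfg$quantify$input_dir <- cfg$out_dir
res <- run_quantify(cfg)            # masks -> intensities -> decay summary
```

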