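# ionquench

Ionization-quenching correction for Al₂O₃:C radioluminescence (RL) fibre
dosimetry in therapeutic proton, helium and carbon ion beams.

Luminescent dosimeters under-respond at high linear energy transfer (LET):
near the Bragg peak of an ion beam, the dense ionization saturates the
recombination centres (Birks saturation) and a raw RL depth scan reads
25–50% low exactly where dose accuracy matters. For helium and carbon
beams, nuclear fragmentation additionally replaces the primary with
lighter fragments (H, He) that dominate the distal fluence at much lower
LET, so a single-species correction is not enough.

`ionquench` is for medical physicists and detector developers who need to

* correct measured RL Bragg curves for quenching in mixed particle fields,
* fit the Birks constant `kB` and scaling `RL0` per species from
  normalized depth scans, with progressive freezing of fragment
  parameters (H → He with frozen H → C with frozen H+He),
* generate the depth-resolved per-species fluence-fraction and
  fluence-averaged-LET profiles the method needs, from an analytic
  Bethe/CSDA beam model with a calibrated fragmentation surrogate (a
  stand-in for Monte Carlo transport), and
* validate the whole chain on synthetic campaigns with known ground truth.

## The model in brief

Light from a voxel crossed by fluence φ of one species with
fluence-averaged LET `L` (MeV/cm) follows the voxelized Birks law

    RL_v = RL0 · L / (1 + kB′·L) · φ,        kB′ = kB / 10⁶  (kB in µg MeV⁻¹ cm⁻²)

and the per-species quenching correction factor — the ratio of deposited
energy to emitted light — is its exact inverse:

    η = (1 + kB′·L) / RL0.

For the mixed field at depth *d* the combined factor is fluence-weighted
over the primary and its fragments,

    η(d) = Σ_i f_di · (1 + kB′_i · L_di) / RL0_i ,

which reduces to the pure-primary form for protons, to the {He, H} form
for helium and to the {C, He, H} form for carbon. A measured curve in the
normalized peak-to-plateau representation is corrected as
`corr(d) = η(d)·y(d)/η(entrance)` and compared with the reference
(ionization-chamber) curve at the peak, in the plateau, and in the distal
falloff.

## Worked example

Stopping-power and range anchors (relativistic Bethe, water, I = 75 eV):

```r
library(ionquench)
stopping_power(154.5)            # 154.5 MeV protons
#> [1] 5.335469                   #   MeV/cm (published: 5.33)
stopping_power(383.2, "C-12")    # 383.2 MeV/u carbon
#> [1] 111.4643                   #   MeV/cm (published: 111.1)
pr <- generate_primary_profile(beam_presets("He150"))
pr$peak_depth_mm
#> [1] 142.65                     #   mm (published peak: 144.91)
```

A synthetic four-beam campaign with 1% signal noise, fitted and corrected
end to end:

```r
cfg    <- experiment_config(beams = c("H160", "H230", "He150", "C290"),
                            seed = 42)
bundle <- synth_experiment(cfg)
report <- run_pipeline(bundle, mode = "full")
report
#> <pipeline_report>
#>   entrance efficiencies: H160=1.022, H230=1.009, He150=0.961, C290=0.715
#>   C-12: kB = 3061, RL0 = 1.016
#>   He-4: kB = 3184, RL0 = 1.028
#>   H-1: kB = 3178, RL0 = 1.026
#>   peak |diff| vs reference (corrected / uncorrected):
#>     H160     0.64% /  21.49%
#>     H230     2.79% /  18.52%
#>     He150    0.75% /  42.98%
#>     C290     2.90% /  37.12%
report$corrections$He150
#> <correction_result>
#>   Bragg peak at 143.85 mm; falloff beyond 145.15 mm
#>   diff vs reference at peak: +0.75% corrected, -42.98% uncorrected
#>   plateau max |diff|: 3.25% corrected, 36.04% uncorrected
#>   falloff max |diff|: 3.08% corrected, 71.82% uncorrected
```

Reading the output: the entrance relative efficiencies reproduce the
measured pattern (≈1 for protons, 0.96 for helium, ≈0.72 for carbon);
the recovered `kB`/`RL0` agree with the generator's ground truth
(3106 µg MeV⁻¹ cm⁻², probe-dependent `RL0`) to ~2%; and the fluence-
weighted correction shrinks the helium peak error from −43% to +0.8%,
mirroring the ~30% → ~5% improvement reported for measured data.

A command-line interface wraps the same pipeline
(`inst/exec/ionquench`): `simulate --config cfg.yaml --out dir/`,
`fit --bundle dir/ --species H|He|C`, `correct`, `report`; see
`cli_config_template()` for the YAML schema with the five reference
beams (H160, H230, He150, C290, C400) as presets.

## What a green test does and does not establish

The synthetic generator emits quenched signals through the method's own
forward model, so the mixed-species correction is exact by construction;
green end-to-end tests certify the internal consistency of the fitting,
freezing, weighting and inversion machinery — not the physical validity
of fluence weighting for carbon beams, which only measured data can
settle. See the methods vignette (`vignettes/quenching-correction.Rmd`)
for the model, the ground-truth calibration, and known limitations.
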