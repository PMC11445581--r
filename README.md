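# fccstools

Quantitative analysis of a spatially regulated protein–protein
interaction in living cells, built around two measurements:

* **Dual-colour fluorescence cross-correlation spectroscopy (FCCS)** —
  from photon-count traces in two detection channels to an in-cell
  dissociation constant. The motivating system is endogenously tagged
  Cyclin B1 (green) binding the APC/C ubiquitin ligase via its APC8
  subunit (red) during mitosis, where the affinity is compartment
  dependent: roughly 80 nM at chromatin versus 180 nM in the cytoplasm,
  with both partners near 100 nM.
* **Single-cell degradation kinetics** — from anaphase-aligned
  fluorescence trajectories to each cell's degradation onset frame and
  maximum degradation speed, plus centrosome-to-centrosome line profiles
  and in/out-of-mask quantification on 2D images.

The package is aimed at microscopists and quantitative cell biologists
who have fluctuation traces or time-lapse intensity tables and want the
full, reproducible chain from raw numbers to physical quantities — with
a seeded synthetic-data generator so every stage can be verified against
ground truth.

## The core quantities

For free 3D diffusion through a Gaussian confocal volume
(lateral radius w_xy, structure parameter κ = w_z/w_xy):

    G(τ) = (1/N) (1 + τ/τ_D)^-1 (1 + τ/(κ² τ_D))^-1/2,
    D = w_xy²/(4 τ_D),   V_eff = π^{3/2} w_xy² w_z,   C = N/(N_A V_eff)

Dual-colour zero-lag amplitudes invert to absolute concentrations
(equal brightness per channel, no cross-talk):

    [gr]     = G×(0) / (N_A V_eff · G_g(0) G_r(0))
    [g]_free = 1/(N_A V_eff G_g(0)) − [gr],   similarly [r]_free
    K_D      = [g]_free [r]_free / [gr]
    q        = max( G×(0)/G_r(0), G×(0)/G_g(0) )

Degradation traces are normalised to a pre-anaphase reference frame,
bleach-corrected (matched cycloheximide+MG132 control, or a straight
line fitted to frames −30..−25), smoothed with a trailing 4-frame
average; the **onset** is the first frame of the first sliding 5-frame
window whose least-squares slope falls strictly below −0.05 per frame,
and the **maximum degradation speed** is the 5-point slope around the
minimum of the first derivative.

## Worked example

Simulate a binding pair at 100 nM totals with ground-truth K_D = 80 nM
in a calibrated 0.22 fL volume, then run the full analysis chain:

```r
library(fccstools)

vol  <- observationVolume(wXY = 0.2, kappa = 5)   # V_eff ~ 0.223 fL
pair <- bindingPairSpecies(kd = 80e-9)            # free green/red + complex
cfg  <- simulationConfig(vol, binWidth = 2e-4, duration = 15, seed = 42)
tr   <- simulatePhotonTraces(pair$species, cfg)
tr$green
#> PhotonCountTrace 'green': 75000 bins of 0.0002 s (15 s), mean rate 57.63 kHz

res <- analyzeDualColour(tr$green, tr$red, vol)
res$interaction
#> InteractionResult: Kd = 79.42 nM, q = 0.441, complex = 42.38 nM (free 62.6 / 53.77 nM)
```

One seed recovers the 80 nM ground truth to within its ~±15% single-run
scatter; the estimator used throughout is the **median over seeds**
(`kdRecoveryExperiment()`), mirroring per-cell medians in dot plots.
`q` is the cross-correlation quotient, the bound fraction of the
limiting species (truth here: 0.42).

Degradation kinetics on a synthetic trace (onset at frame 3, decay
0.1/frame, 1% noise, linear bleaching):

```r
sim <- simulateDegradationTrace(baseline = 1200, bleachRate = 0.002,
                                onsetFrame = 3L, decayRate = 0.1,
                                noiseSd = 12, frameRange = c(-40L, 40L),
                                frameInterval = 30, seed = 7,
                                compartment = "chromatin")
kin <- analyzeDegradation(sim$trace, referenceFrame = -20L,
                          bleachMode = "linear")
kin
#> KineticsResult: onset 3, initial speed -0.05259, max speed -0.07072 /frame at frame 7
```

The detected onset equals the generating truth; the initial speed is the
slope of the triggering window and the maximum speed the steepest
5-point slope of the smoothed trace, both in normalised intensity per
frame.

A command-line wrapper covering the same chains
(`simulate`, `correlate`, `fit`, `kd`, `kinetics`, `profile`,
`run-demo`) is installed at
`system.file("scripts", "fccs", package = "fccstools")`.

## Package layout

* `R/correlate.R` — direct (oracle) and multi-tau correlators, segment
  noise estimates
* `R/models.R`, `R/fit.R`, `R/units.R` — diffusion models, weighted
  fitting, calibration, physical conversions
* `R/interaction.R` — mass-action equilibrium and the amplitude → K_D
  algebra
* `R/kinetics.R`, `R/profiles.R` — degradation pipeline, line profiles,
  compartment means
* `R/synth-fcs.R`, `R/synth-kinetics.R`, `src/simulate.cpp` — seeded
  generators with ground-truth records
* `R/io.R`, `R/config.R`, `R/cli.R` — CSV/JSON formats, validated
  configs, provenance, command-line entry point

See the methods vignette (`vignettes/fccs-methods.Rmd`) for the models,
their assumptions, the generator's scope, and numerical choices.
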