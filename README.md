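# rumpalm

Simulation and analysis of single-molecule localization microscopy
(PALM) of the chytrid zoospore "eye", plus the enzymology of its
photoreceptor.

Chytrid fungal zoospores carry an eyespot-like organelle whose
honeycomb-shaped membrane stack — the rumposome — hosts the natively
fluorescent, bistable rhodopsin photoreceptor NeoR on a roughly
hexagonal lattice (~30 nm in-row pitch). Quantifying that arrangement by
PALM poses three coupled problems that this package implements end to
end:

1. **Forward simulation.** Photoswitching EMCCD movies of lattice
   emitters inside a crescent band of a ~4 µm cell: a discrete-frame
   Markov model (ON/DARK/BLEACHED) with a feedback controller that
   emulates the ramped 405 nm reactivation laser, integrated-Gaussian
   PSF rendering, Poisson background, optional EM gain and read noise.
2. **Localization and quantification.** Matched-scale difference-of-
   Gaussian detection, batched Poisson maximum-likelihood Gaussian
   fitting with neighbour masking, per-localization precision via the
   Thompson formula
   `sigma^2 = (s^2 + a^2/12)/N + 8*pi*s^4*b^2/(a^2*N^2)`,
   temporal-block drift correction, blink-event merging and
   molecule counting, Thompson-blur rendering, intensity profiles,
   rolling-ball background correction, and spatial autocorrelation
   spacing estimation — including the rotated hexagonal-pattern
   projection simulation that explains why a 30 nm lattice yields a
   ~30 nm autocorrelation peak under arbitrary orientation.
3. **Cyclase kinetics.** Hill/Michaelis–Menten fitting
   (`v = Vmax*S^h/(K_M^h + S^h)`) of substrate-saturation data for the
   photoreceptor's guanylyl cyclase partners, nucleotide quantification
   from chromatogram peak areas, linear turnover slopes, and
   fluorescence-based activity normalization, with a seeded synthetic
   data generator for parameter-recovery studies.

The generating conditions of all synthetic fixtures mirror the printed
acquisition: 10,000 frames at 35 ms, ~350 detected photons per ON frame,
background calibrated so the mean localization precision is 32 nm, and
~3,417 emitters per cell.

## Worked example

```r
library(rumpalm)

# per-localization precision at the calibrated fixture
thompson_precision(350, 102, 160, calibrate_background())
#> [1] 32

camera_model()
#> Camera: 128x128 px, 160 nm/px, PSF sigma 102 nm,
#>         background 1139.1 ph/px/frame, EM gain 1, read noise 0

# the rotated hexagonal-pattern forward simulation (30 nm pitch,
# FWHM 30 nm, 200 x 200 distributions, 5-degree steps over 0-360)
rotated_projection_analysis(hex_pattern_params(), seed = 1)
#> Spacing estimate: 31.2 nm (ACF peak 0.005)

# Hill-fit recovery for the soluble homodimeric cyclase domain
d <- generate_kinetics(list(Vmax = 0.96, K_M = 5.53, h = 1),
                       S_mM = hill_grid(5.53), seed = 1)
fit_hill(d, fix_h = 1, weighting = "relative")
#> Hill fit: Vmax = 0.9767 +/- 0.023, K_M = 5.637 +/- 0.22 mM, h = 1 (fixed)
```

The spacing estimate says the rotation-averaged autocorrelation of the
simulated lattice peaks at 31.2 nm — within a lattice constant's
tolerance of the generating 30 nm pitch, which is the core geometric
claim the forward simulation supports. The Hill fit recovers the
generating constants (5.53 mM, 0.96 µmol·min⁻¹·mg⁻¹) within ~2% from 5%
noisy triplicates.

A full counting experiment runs through two calls:

```r
sim <- simulate_zoospore(simulation_config(sensor_px = 48, seed = 1))
res <- analyze_zoospore(sim, fit_sigma = FALSE)
res$count      # blink-event molecule estimate; ground truth is 3417
```

See the methods vignette (`vignettes/methods.Rmd`) for the models, the
calibration of the background to the 32 nm precision, the two
acquisition fixtures (counting vs structural imaging) and the package's
honest account of which quantities the end-to-end pipeline can and
cannot recover at this photon budget.

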