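# ommapol

Analysis of ommatidial alignment in compound eyes and its consequences for
polarization vision.

Butterfly eyes reflect "eyeshine" from a tapetum beneath each rhabdom.
Under crossed polarizers, the *depolarized* component of eyeshine from one
ommatidium waxes and wanes with the eye's roll angle θ as

    I(θ) = background + a + b · sin²(2(θ − Σ)),

a 90°-periodic curve whose minima sit at the microvillar principal axis Σ
of that ommatidium. Measuring stacks of eyeshine images over θ therefore
maps Σ across a whole hexagonal patch of ommatidia at once. The interesting
biology is in the *differences*: adjacent ommatidia with aligned axes
(ΔΣ within ±5°, in runs of 3 or more) support edge and motion detection
(ED), while pairs misaligned by ΔΣ ≥ 20° can drive a second-order neuron
that sums rectified two-channel opponent outputs,

    O(ɸ) = d · (PS−1)/(PS+1) · cos 2(ɸ − α),     S(ɸ) = |O₁| + |O₂|,

whose response is never polarization blind — a robust polarization
detector (PD). `ommapol` implements the full chain for researchers in
visual ecology and compound-eye optics:

- **synthetic data** — seeded generators for Σ fields (including an
  ensemble calibrated so adjacent-pair ΔΣ reproduces the observed
  marginals: 22% exact, 50% ≤ 5°, 30% ≥ 15°, 15% ≥ 20°), rendered
  eyeshine stacks, polarization image pairs, reflectance spectra,
  sensitivity templates and behavioural counts;
- **photometry** — hexagonal grids of circular ROIs over registered
  stacks (TIFF/PNG + JSON sidecar);
- **alignment** — exact Fourier-phase estimation of Σ with a modulation
  QC filter, and the axial difference ΔΣ;
- **hexarray** — neighbour analysis, ED chains, PD pairs, patch metrics
  over interior ommatidia;
- **opponent** — receptor, first-order opponent and second-order summed
  responses, state-space loci, worst-case robustness;
- **wingoptics** — DoP from image pairs, angular-contrast sweeps with
  polynomial trends, spectral peaks, quantum catches and tetrahedral
  colour space;
- **behavior** — site-level approach-count statistics.

## Worked example

Simulate a 12 × 12 patch with the calibrated misalignment ensemble, render
its eyeshine stack, re-estimate every axis from the images and classify
the lattice:

```r
library(ommapol)

res <- runPipeline(pipelineConfig(rows = 12, cols = 12,
                                  mixture = "calibrated", seed = 7))
m <- res$metrics
m$n_interior
#> [1] 100
round(c(ed = m$pct_ed, pd = m$pct_pd,
        ed_only = m$pct_ed_only, pd_only = m$pct_pd_only), 1)
#>      ed      pd ed_only pd_only
#>    74.0    57.0    37.0    20.0
lapply(m$delta_sigma_summary, round, 3)
#> $exact    [1] 0.274
#> $within5  [1] 0.49
#> $ge15     [1] 0.348
#> $ge20     [1] 0.192
```

Of the 100 interior ommatidia (the 10 × 10 core whose six neighbours are
all measured), 74% sit in an aligned run of three or more (ED), 57%
belong to at least one pair misaligned by ≥ 20° (PD), and 37% / 20% are
exclusively one or the other; the pair-level summary shows the ΔΣ bin
fractions for this (finite, seeded) patch. The estimation step is exact
at zero noise — here the largest |Σ̂ − Σ| across all 144 ommatidia is
~1.4 × 10⁻¹⁴ degrees.

The opponent model quantifies why 20° is the robustness threshold:

```r
round(polRobustness(0, 20), 3)   # worst-case response of a 20-deg pair
#> [1] 0.526
```

Behavioural counts aggregate by site and test the polarized-minus-
depolarized difference against zero:

```r
d <- siteDifferences(generateBehaviorCounts(seed = 1), "blue")
d
#> site01 site02 site03 site04 site05 site06 site07
#>     -9     -8     -6      0    -10      0      2
lapply(oneSampleT(d), round, 4)
#> $t [1] -2.3614   $df [1] 6   $p [1] 0.0562   $mean [1] -4.4286
```

## Documentation

The methods vignette (`vignettes/ommatidial-polarization.Rmd`) documents
the intensity model and its assumptions, the estimator and its numerical
choices, the calibration of the synthetic misalignment ensemble, the
classification rules, the opponent model, and known limitations.
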