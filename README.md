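# anisokin

Kinetics and equilibria of fluorescent-nucleotide exchange on actin
monomers, measured by fluorescence anisotropy.

## The problem

Monomeric (G-) actin binds one adenine nucleotide in its central cleft.
Fluorescent ATP analogues carrying a dye on the adenine base (via a long
flexible linker) bind the same site and compete with unlabelled ATP, so the
anisotropy of the dye — low when the small labelled nucleotide tumbles
freely, high when it rides on a 42-kDa protein — reports nucleotide
exchange in real time. `anisokin` provides the complete quantitative
pipeline for this assay, for biochemists characterizing nucleotide
analogues, exchange catalysts (profilin), exchange inhibitors
(ADF/cofilin), or cation/salt effects on G-actin:

1. **Kinetic model.** Deterministic mass-action kinetics of the
   two-ligand competition for the single site,

   ```
   A + T  ⇌  AT      (k_on,T,  k_off,T)
   A + S  ⇌  AS      (k_on,S,  k_off,S)
   ```

   with A free nucleotide-free actin, T unlabelled ATP, S the labelled
   analogue (µM and seconds throughout). An independent analytic solver
   for the competitive equilibrium (root of the coupled binding
   polynomials) serves as the long-time oracle for the ODE integration.

2. **Observation layer.** The standard anisotropy formula
   `r = (I_VV − G·I_VH)/(I_VV + 2·G·I_VH)` with grating factor
   `G = I_HV/I_HH`, and the linear calibration between `r_min` (all label
   free) and `r_max` (all label bound) that converts readings into bound
   fractions and concentrations.

3. **Global fitting.** One shared set of rate constants fit
   simultaneously to association time courses and ATP-chase
   (dissociation) time courses by Levenberg–Marquardt least squares in
   log-parameter space. Exchange kinetics determine the two association
   constants only through their ratio; `identifiability_profile()` makes
   this explicit by rescanning the fit over fixed `k_on,T`.

4. **Titrations.** The exact quadratic binding isotherm (no free-ligand
   approximation) for a labelled actin-binding protein titrated with
   G-actin, fit by nonlinear least squares for `(Kd, r_min, r_max)`, with
   residual-bootstrap confidence intervals.

5. **Synthetic data.** Seeded generators reproducing the statistical
   structure of every assay above, so the whole pipeline is testable
   without instrument data.

## Worked example

Generate the reference noiseless design — four association curves (2 µM
G-actin, labelled ATP at 25–200 nM, sampled every 10 s for 1800 s) plus a
100-µM ATP chase — and refit it globally:

```r
library(anisokin)

bundle <- c(synth_association_bundle(noise_sd = 0),
            list(synth_chase(noise_sd = 0)))
fit <- exchange_fit(bundle)          # k_on,T fixed at 10 /(uM s) by default
print(fit)
#> Global fit of competitive nucleotide-exchange kinetics
#>   5 dataset(s), 1445 points; RSS = 2.023e-21 uM^2; converged in 13 iter.
#>   k_on_T   = 10  (fixed)
#>   k_on_S   = 12  (free)
#>   k_off_T  = 0.0028  (free)
#>   k_off_S  = 0.001  (free)
#>   k_on ratio (label/ATP) = 1.2
```

The fit recovers the generating constants: unlabelled ATP leaves G-actin
at 2.8×10⁻³ s⁻¹, the labelled analogue about three-fold slower at
1×10⁻³ s⁻¹ — the physical reason a chase with excess ATP cleanly strips
the label. Only the ratio of association constants is identifiable:

```r
identifiability_profile(bundle)
#>   k_on_T  k_on_S   k_off_T    k_off_S k_on_ratio        rss        rms
#> 1      2  2.3801 0.0028245 0.00100005     1.1900 1.8785e-08 3.6056e-06
#> 2     10 12.0000 0.0028000 0.00100000     1.2000 2.0229e-21 1.1832e-12
#> 3     50 60.0904 0.0027956 0.00099999     1.2018 7.4717e-10 7.1908e-07
#>   ratio k_on,label/k_on,ATP: 1.197 (spread 0.98%)
```

Anchoring `k_on,T` anywhere across a 25-fold range leaves the fit equally
good (rms residuals orders of magnitude below the 0.2 µM signal) while
the recovered association-rate ratio stays at 1.2.

An equilibrium titration of a labelled actin-binding protein, and a
single-point occupancy reading:

```r
d <- synth_titration(titration_params(Kd = 2.1, r_min = 0.10, r_max = 0.30),
                     ABP_total = 0.5)
titration_fit(d)
#> Quadratic-isotherm titration fit
#>   ABP_total = 0.5 uM, n = 12 points, RSS = 4.776e-32
#>   Kd = 2.1 uM, r_min = 0.1, r_max = 0.3 (5 iterations)

bound_fraction(0.268, cy5_calibration())   # r_EQ against r_min/r_max
#> [1] 0.4905660
```

The last line is the standard steady-state occupancy calculation: an
equilibrium anisotropy of 0.268 on the Cy5 calibration (0.242/0.295)
means 49% of the labelled nucleotide is actin-bound.

A command-line wrapper over the same functions lives in
`inst/cli/anisokin.R`:

```sh
Rscript inst/cli/anisokin.R occupancy --r 0.268 --rmin 0.242 --rmax 0.295
Rscript inst/cli/anisokin.R synth --preset association --seed 1 --out data/
Rscript inst/cli/anisokin.R fit-kinetics --data data/association_S0.025_uM.csv,... --out fit.json
```

## Vignette

`vignettes/nucleotide-exchange.Rmd` documents the model and its
assumptions, the calibration and noise model, the numerical choices
(integration tolerances, starting values, identifiability handling), and
the known limitations of the synthetic designs.
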