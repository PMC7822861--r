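---
title: "Modelling nucleotide exchange on G-actin from fluorescence anisotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nucleotide exchange on G-actin from fluorescence anisotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisokin)
```

## The reaction scheme and its assumptions

G-actin carries a single adenine-nucleotide site. A fluorescent ATP
analogue labelled on the base (S) competes with unlabelled ATP (T) for
that site:

$$A + T \rightleftharpoons AT, \qquad A + S \rightleftharpoons AS$$

with mass-action rate equations

$$\frac{d[AT]}{dt} = k_{on,T}[A][T] - k_{off,T}[AT], \qquad
  \frac{d[AS]}{dt} = k_{on,S}[A][S] - k_{off,S}[AS],$$

and the complementary balances for $A$, $T$ and $S$, so total actin,
total ATP and total analogue are conserved exactly. Units are fixed
package-wide: µM for concentrations, seconds for time, so $k_{on}$ is in
µM⁻¹s⁻¹ and $k_{off}$ in s⁻¹.

The model deliberately excludes everything beyond monomer-level
exchange: no polymerization or depolymerization (assay conditions are
chosen so assembly is negligible on the exchange time scale), no ATP
hydrolysis, no phosphate release, and no stochasticity (concentrations
are nanomolar-to-micromolar in bulk, so the deterministic limit is
appropriate).

### Initial loading

Purified G-actin arrives with one ATP bound per monomer; dilution into
nucleotide-free buffer then sets the remaining *free* ATP. The package's
`"fully loaded"` convention encodes this: $AT(0) = A_{tot}$,
$A(0) = AS(0) = 0$, $T(0) = T_{tot} - A_{tot}$, $S(0) = S_{tot}$. The
default total ATP is $T_{tot} = 3 A_{tot}$, i.e. a two-fold excess of
*free* ATP over actin on top of the bound equivalent, which is the
standard condition for this assay. A custom initial `mixture_state()`
can override the convention; it must agree with the declared totals.

### The ATP chase

Dissociation of the labelled analogue is isolated by adding a large
excess of unlabelled ATP (default 100 µM at $t = 1800$ s): free actin is
then immediately re-occupied by ATP, rebinding of the label is
suppressed, and the anisotropy decays at essentially $k_{off,S}$. The
addition is modelled as an instantaneous step in free ATP; the added
volume is treated as negligible, so no other species is diluted.

### Condition scenarios

Bound divalent cation (Ca²⁺ vs Mg²⁺), salt, and exchange-modulating
ABPs change the *net speed* of exchange; which microscopic constants
they move is not determined by a net fold-change. Because exchange from
fully loaded actin is dissociation-limited, the package applies the
scenario multiplier to both dissociation constants and leaves the
association constants untouched — an interpretive choice, recorded here.
Shipped presets: Mg baseline (×1), Ca²⁺ (×0.2), +50 mM KCl (×2),
saturating profilin (×3.5), ADF/cofilin-inhibited (×0.3).

## The observation layer

Anisotropy is computed from polarized intensities by the standard
formula $r = (I_{VV} - G I_{VH})/(I_{VV} + 2 G I_{VH})$ with grating
factor $G = I_{HV}/I_{HH}$. Binding is read on the linear scale between
two calibration extremes: $r_{min}$ (label fully free) and $r_{max}$
(label fully bound), giving bound fraction
$(r - r_{min})/(r_{max} - r_{min})$ and, multiplied by the total label
concentration, bound/free concentrations.

Two assumptions ride along and are recorded in output metadata rather
than tested: the label's total fluorescence must be
occupancy-independent (otherwise the linear scale needs
intensity-weighting), and no instrument corrections beyond the G factor
are applied (anisotropy is insensitive to photobleaching, one of the
method's advantages). Readings that noise pushes outside
$[r_{min}, r_{max}]$ are clipped to the physical range with a warning
that counts the affected samples: clipping preserves downstream mass
balances while surfacing calibration drift.

The default calibration for synthetic ATTO-488-style data is
$r_{min} = 0.05$, $r_{max} = 0.22$ — plausible for a dye with a ~4 ns
fluorescence lifetime free in solution versus bound to a 42-kDa protein
— and is tagged `"synthetic"`. The published Cy5 calibration pair
(0.242/0.295, F-actin pelleting method) ships as `cy5_calibration()`.
The two experimental routes to $r_{max}$ (pelleting label bound to
F-actin, or stripping free label on ion-exchange resin) differ by a few
percent; the calibration object carries a provenance tag but the package
treats $r_{max}$ as a single user-supplied number.

## Numerical integration and the equilibrium oracle

Trajectories are integrated with `deSolve::lsoda` (stiff-capable) at
relative tolerance $10^{-10}$ and absolute tolerance $10^{-12}$ µM.
These defaults keep all three conservation sums correct to better than
one part in $10^9$ at every sample, and halving them changes no reported
concentration by more than $10^{-6}$ µM.

The long-time limit is computed independently of the ODE path:
at equilibrium $AT = A\,T_{tot}/(K_{d,T} + A)$ and
$AS = A\,S_{tot}/(K_{d,S} + A)$, so free actin solves a scalar
conservation equation whose left side is strictly increasing. The root
is bracketed on $[0, A_{tot}]$ with `uniroot` and then polished with a
few Newton steps — the conservation function is steep near the root when
ligands are in excess, and the polish brings the residual time
derivatives to rounding level (below $10^{-10}$ µM/s) rather than
`uniroot`'s interval tolerance. This analytic state is the oracle the
test suite holds the integrator to.

## Global kinetic fitting

`exchange_fit()` minimizes the summed squared residuals over all
datasets simultaneously with one shared parameter set
(Levenberg–Marquardt, `minpack.lm::nls.lm`). Design choices:

* **Residual space.** Anisotropy traces are converted to
  bound-concentration space through their calibrations before residuals
  are formed, with equal weight per point — the same
  convert-then-fit order used when the assay is analyzed by hand.
* **Positivity.** Optimization runs on log-transformed parameters, so
  rate constants are positive by construction and no active-set logic is
  needed.
* **Anchoring.** Exchange kinetics determine the association constants
  only through their ratio (see below), so $k_{on,T}$ is fixed by
  default at 10 µM⁻¹s⁻¹, a conventional anchor; any subset of the four
  constants can be fixed or freed. Freeing both $k_{on}$ triggers a
  warning that only the ratio is determined; fitting without a chase
  dataset warns that the label's off-rate rests on plateau information
  alone.
* **Starting values.** Defaults are data-driven. From fully loaded
  actin the release of bound ATP is rate-limiting, so $\ln 2 / t_{1/2}$
  of the association rise is a direct estimate of $k_{off,T}$, and the
  half-time of the post-chase decay estimates $k_{off,S}$; $k_{on,S}$
  starts at $k_{on,T}$. Fixed generic guesses (e.g. $10^{-3}$ s⁻¹ for
  both off-rates) were tried first and can leave Levenberg–Marquardt in
  a local minimum several orders of magnitude above the global one when
  the true rates are far from the guess; the half-time seeds place the
  optimizer on the correct branch of the residual surface.
* **Determinism.** Datasets are put into a canonical internal order
  before fitting. The objective is a sum over a *set* of datasets, so
  this makes the estimates bit-identical under permutation of the input
  list, instead of merely equal up to optimizer tolerance.
* **Convergence.** Relative tolerances of $10^{-15}$ on both step and
  residual reduction, up to 500 iterations. A non-converged fit raises
  an error carrying the last parameter vector and residual rather than
  returning estimates.

### Identifiability

With the assay run at $S_{tot} \ll T_{tot}$, the capture fraction of
released actin is $\varphi \approx k_{on,S}S/(k_{on,T}T) \ll 1$: both
the observed rise rate ($\propto k_{off,T}\,k_{on,S}$) and the
equilibrium plateau (set by the $K_d$ ratio) constrain the *product*
$k_{on,S} k_{off,T}$, not its factors. `identifiability_profile()`
exposes this structure: it fixes $k_{on,T}$ at each grid value (default
2, 10, 50 µM⁻¹s⁻¹), refits everything else, and reports the recovered
ratio $k_{on,S}/k_{on,T}$ and the optimum residual per grid point. On
data generated by the model the ratio is stable across the grid while
the rms residual stays negligible relative to the signal — the absolute
$k_{on}$ scale is a convention, the ratio is the measurement. A
continuation pass re-seeds each grid point from the best optimum found
(with $k_{on,S}$ rescaled to preserve the ratio) and keeps the better
fit, which removes cold-start local minima at grid points far from the
data's natural rate scale; the procedure is deterministic.

The flip side of the ridge is a genuine precision limit: at realistic
anisotropy noise, excursions along it (e.g. $k_{off,T}$ up, $k_{on,S}$
down, product fixed) cost far less residual than the noise floor, so the
*individual* $k_{off,T}$ carries substantially more uncertainty than the
product. The test suite asserts recovery of the identifiable
combinations tightly and documents the individual-parameter spread as
what the design supports.

## Equilibrium titrations

For a labelled ABP at fixed total concentration $P$ titrated with
G-actin at total $G$, the exact bound fraction (no free-ligand
approximation) gives the quadratic isotherm

$$r = r_{min} + (r_{max} - r_{min})
  \frac{K_d + G + P - \sqrt{(K_d + G + P)^2 - 4 G P}}{2P},$$

which reduces to the hyperbola $G/(G + K_d)$ when $P \ll K_d$.
`titration_fit()` estimates $(K_d, r_{min}, r_{max})$ by
Levenberg–Marquardt least squares with $K_d$ bounded positive. Starting
values come from the data: $r_{min}$ from the smallest-actin point,
$r_{max}$ from the largest, $K_d$ from the actin concentration nearest
the half-range anisotropy. Flat titrations are rejected as
$K_d$-unidentifiable, and a fitted $K_d$ beyond a third of the titration
range triggers an extrapolation warning.

## Uncertainty

`bootstrap_ci()` implements a residual-resampling bootstrap: centred
residuals are resampled onto fitted values, the model is refit per
replicate starting from the point estimates, and percentile intervals
are taken at the requested level (default 95%, 200 replicates, seed
required). Replicate failures are counted and more than 20% aborts the
procedure. The same seed gives bit-identical intervals. The method makes
no claim of equivalence with any particular fitting software's reported
"±" values; it is simply a stated, reproducible procedure.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure of each assay:
association bundles (default 2 µM actin; label at 25, 50, 100, 200 nM;
10-s sampling over 1800 s), ATP chases (100 µM ATP at 1800 s, followed
to 7200 s), cation/salt/ABP scenarios via the net multipliers, and
titrations (0.5 or 2 µM labelled protein over 0–20 µM actin, 12 points).
Noise is additive Gaussian on anisotropy, i.i.d. per sample, default
sd 0.002 — of the order of twice the precision with which plateau
anisotropy means are typically reported. Every trace's metadata records
the totals, calibration, scenario and seed needed to refit it, and
identical seeds give bit-identical datasets.

What the generators do *not* emulate: photon-counting statistics and
detector gain (noise is not signal-dependent), photobleaching, slow
instrument drift, pipetting/volume errors at the chase, or any
occupancy-dependence of the label's brightness. Passing tests therefore
demonstrate correctness of the estimators under the stated noise model,
not robustness to instrument systematics; real data that violate the
constant-intensity assumption need an intensity-weighted calibration
before these tools apply.

## Problem sizes used by the test suite

The suite runs entirely on generated data: the reference bundle (4 + 1
time courses, 1445 points) for fitting checks, 100-draw random
simulations for the conservation and equilibrium-oracle properties, 20
seeded replicates for noisy-recovery statistics, and 200-replicate
bootstraps. These sizes keep every property statistically meaningful
while the whole suite completes in a few minutes.

## Known limitations

* The individual association constants are conventions, not
  measurements; only their ratio (and everything downstream of it) is
  transferable between labs.
* The scenario multiplier compresses cation, salt and ABP mechanisms
  into a single dissociation-scale factor; it reproduces net exchange
  speeds, not mechanism.
* The linear anisotropy-to-occupancy map assumes state-independent
  quantum yield and lifetime of the label.
* The equilibrium solver assumes both ligands are in thermodynamic
  equilibrium with a single actin site; it does not cover ternary
  complexes or cooperative binding.
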