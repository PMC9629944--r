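---
title: "Moisture sorption isotherms and sorption thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moisture sorption isotherms and sorption thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorptherm)
library(dplyr)
```

## The problem

A hygroscopic food equilibrates with the humidity of the surrounding air:
at a given temperature, its equilibrium moisture content (EMC, expressed in
percent dry basis) is a function of water activity \(a_w\), the relative
vapour pressure of water in the material. That function — the moisture
sorption isotherm — governs drying endpoints, packaging requirements and
microbial stability, and its temperature dependence carries the
thermodynamics of water binding. `sorptherm` implements the complete
analysis chain for multi-temperature sorption experiments: isotherm model
fitting and selection, Clausius–Clapeyron isosteric heats, differential
entropy, Gibbs free energy, enthalpy–entropy compensation, spreading
pressure and sorption surface area. The package ships a reference dataset
of five sweet cherry cultivars measured by the static gravimetric
(saturated salt) method at 30, 40 and 50 °C, with six salt-defined water
activities per isotherm.

## Models

Three isotherm families are supported, each passing through the origin and
fitted over the full water-activity range:

* **GAB** (Guggenheim–Anderson–de Boer):
  \(X = \dfrac{A\,B\,C\,a_w}{(1 - B a_w)(1 - B a_w + C B a_w)}\),
  with monolayer moisture \(A\) (% d.b.), multilayer factor \(B \in (0,1)\)
  and Guggenheim constant \(C > 0\). The monolayer parameter feeds the
  surface-area calculation, and the spreading pressure has a closed form
  under this model.
* **Peleg**: \(X = A a_w^{C} + B a_w^{D}\), a flexible double power law.
* **Enderby**: \(X = \left(\dfrac{A}{1 - B a_w} + \dfrac{C}{1 - D a_w}\right) a_w\),
  a sum of two hyperbolic terms with both poles outside \((0, 1)\).

The GAB expression is typeset ambiguously in parts of the sorption
literature; we adopt the standard form above because it is the one whose
analytic \(\theta/a_w\) integral yields the closed-form spreading pressure,
and the package verifies that closed form against adaptive quadrature to
\(10^{-8}\) relative as a standing test.

### Fitting protocol

Each series is fitted by bounded Levenberg–Marquardt least squares on the
untransformed residuals (no weighting), with a deterministic multi-start
grid: GAB starts at \(A \in \{x_{0.32}, x_{0.32}/2, 2 x_{0.32}\}\) (the
moisture nearest \(a_w = 0.32\)), \(B \in \{0.5, 0.7, 0.9\}\),
\(C \in \{1, 5, 20\}\); Peleg amplitudes from the wet-end moisture with
exponent starts \(C \in \{0.5, 1\}\), \(D \in \{2, 5\}\); Enderby splits
the \(a_w \approx 0.3\) moisture across its two terms with pole factors in
\(\{0.3, 0.7, 0.9\}\). The cost tolerance is \(10^{-10}\); the best
converged start wins, so refits are bit-for-bit reproducible. Fit quality
is summarised by the correlation coefficient
\(r = \sqrt{1 - \mathrm{SSE}/\mathrm{SST}}\) (clipped to \([0, 1]\)) — the
definition used by the common curve-fitting packages in this field, which
also matches the magnitudes reported in published sorption tables better
than the regression-to-total sum-of-squares ratio — and by the mean
relative error \(\mathrm{MRE} = \frac{100}{N} \sum |X_i - \hat X_i| / X_i\)
(percent). A model is acceptable on a series when MRE is below 10%; the
per-series winner maximises \(r\) at reporting precision (3 decimals) with
ties broken by MRE, and the overall winner is the model taking the most
series.

```{r fit-example}
burlat30 <- cherry_sorption() |>
  filter(sample_id == "Burlat", mode == "desorption", temperature_c == 30)
fit <- fit_isotherm(burlat30, "gab")
fit
tidy(fit)
```

## Thermodynamic chain

All physics is computed from the fitted isotherms, not from the six raw
points: with only six observations per series, reading \(a_w\) at constant
moisture across temperatures requires the smooth fitted inverse. Inversion
is bracketed root finding on \([0, 0.95]\) (capped below any model pole),
refined to a residual below \(10^{-10} \max(1, X)\); beyond the last datum
the curve is an extrapolation and the 0.95 cap limits how far it is used.

* **Net isosteric heat and differential entropy.** On a moisture grid
  (default 10–30% d.b. in 1% steps, intersected with the jointly attainable
  range of the three fitted isotherms — a span that covers the
  sharp-variation band of sugar-rich fruit around 14–24% d.b.), ordinary
  least squares of \(\ln a_w\) on \(1/T\) (Kelvin) gives
  \(q_{st} = -R \cdot \mathrm{slope}\) (net of the latent heat of pure
  water; reported in kJ/mol) and \(\Delta S = R \cdot \mathrm{intercept}\)
  (J mol⁻¹ K⁻¹), with \(R = 8.314\) J mol⁻¹ K⁻¹. Grid points unattainable
  at any temperature are dropped with a warning.
* **Gibbs free energy.** \(\Delta G = R T \ln a_w\) at each grid point and
  temperature.
* **Polynomial smooths.** Cubic least-squares summaries of
  \(q_{st}(X)\) and \(\Delta S(X)\) are provided for table-style reporting
  (degree configurable); the downstream regressions always use the grid
  points themselves, never the smooths.
* **Enthalpy–entropy compensation.** Least squares of \(q_{st}\) (J/mol) on
  \(\Delta S\) across the grid: the slope is the isokinetic temperature
  \(T_\beta\) (K), the intercept \(\Delta G_\beta\) (J/mol) whose sign
  classifies the process as spontaneous (negative) or non-spontaneous
  (positive). The compensation is credible only when \(T_\beta\) differs
  from the harmonic mean experimental temperature
  \(T_{hm} = n / \sum 1/T_i\) (312.94 K for 30/40/50 °C); the package
  reports the plain inequality, not a Krug-style confidence band.
* **Spreading pressure and surface area.** The film pressure
  \(\pi(a_w) = \frac{k_B T}{A_m}\ln\frac{1 - B a_w + C B a_w}{1 - B a_w}\)
  (J/m², with \(k_B = 1.380\times10^{-23}\) J/K and water molecule area
  \(A_m = 1.06\times10^{-19}\) m²) is the analytic integral of
  \(\theta / a_w\); a quadrature twin exists purely as its oracle. The
  sorption surface area is \(S_0 = 3.5\times10^3 M_m\) m²/g with \(M_m\)
  the fractional GAB monolayer (\(A/100\)).
* **Optimal storage humidity.** A cubic fitted to one isotherm is read at
  its inflection point \(a_w^{op} = -c_2 / (3 c_3)\), where the curvature
  changes between the two limbs of the sigmoid; the pipeline uses the
  desorption series at the highest temperature. The reading is flagged
  *method-inferred*: it characterises the fitted cubic, not a measured
  optimum, and inflections falling outside \((0, 1)\) — which happens when
  an isotherm's wet-end rise dominates the cubic — are flagged out of
  range rather than silently reported.

```{r thermo-example}
burlat <- cherry_sorption() |> filter(sample_id == "Burlat")
thermo <- burlat |> fit_isotherms(models = "gab") |> isosteric_heat()
head(thermo, 3)
compensation_analysis(thermo)
```

## The synthetic-data generator

`simulate_sorption()` emulates a saturated-salt experiment: GAB-shaped
type-II isotherms, six design activities per temperature (the tabulated
salt values, so synthetic and reference data share a design matrix), three
temperatures, and multiplicative Gaussian noise
\(x = \mu (1 + \varepsilon)\), \(\varepsilon \sim N(0, \sigma^2)\)
truncated at \(\pm 3\sigma\) and floored at 0.1% d.b. The default truth has
the monolayer amplitude falling with temperature (A = 12, 9, 7% d.b. at 30,
40, 50 °C; B = 0.85, C = 8) so moisture decreases with temperature at fixed
\(a_w\), and the default noise is \(\sigma = 0.02\), a realistic
repeatability for gravimetric equilibration. Noise is multiplicative
because sorption balances err in proportion to sample mass, and it keeps
the dry-end values positive.

The generator supports two kinds of oracle test. With \(\sigma = 0\) the
whole chain must reproduce the generating parameters to \(10^{-6}\)
relative. And scaling only \(B\) across temperature as
\(B(T) = B_0 \exp\!\big(\frac{q}{R}(\tfrac{1}{T} - \tfrac{1}{T_0})\big)\)
makes \(B \, a_w\) temperature-invariant at constant moisture, so
\(\ln a_w\) is *exactly* linear in \(1/T\) with slope \(-q/R\) at every
moisture level — the isosteric layer must then return \(q\) to numerical
precision, which it does. `recovery_report()` wraps the Monte-Carlo
version: at \(\sigma = 0.02\) over 200 replicates the median absolute
relative error of the recovered monolayer is about 3–4%, and the
surface-area error is exactly 35 times the monolayer error (the relation
is linear).

What the generator does not emulate: hysteresis (desorption and adsorption
are generated independently), replicate-level weighing noise structure,
solute dissolution above \(a_w \approx 0.9\), and any lack of fit of the
GAB family itself. Passing synthetic tests therefore demonstrates that the
estimation chain is correct, not that GAB is adequate for a given material.

## Numerical choices and edge cases

* Temperatures are stored in °C as measured and converted to Kelvin
  (+273.15) only inside thermodynamic formulas; moisture stays in percent
  dry basis except where a formula needs the fraction (monolayer, Eq. for
  \(S_0\)).
* The fitter's box bounds keep GAB and Enderby poles outside the data
  range; fits that walk to a bound (e.g. \(C\) very large, where GAB
  degenerates to \(A/(1 - B a_w)\)) are legitimate least-squares optima,
  but their monolayer parameter loses physical meaning — a caveat that
  matters when reading surface areas off such series.
* Zero observations are excluded from MRE with a warning; series smaller
  than parameters + 1 are rejected.
* All randomness (generator, Monte-Carlo) flows from an explicit seed;
  everything else is deterministic, and the pipeline's CSV outputs are
  byte-identical across reruns.
* Report problem sizes: the packaged dataset is 30 series of 6 points; the
  default isosteric grid has 21 levels; the bundled Monte-Carlo check uses
  200 replicates.

## Known limitations

* The cherry dataset's published companion tables are not exactly
  reproducible from the printed per-point data: on several series no GAB
  parameter set can reach the published MRE values, and the published
  surface areas imply monolayer values incompatible with the published fit
  quality. The package computes every quantity from the data it ships;
  where the chain is checkable against independent oracles it agrees to
  numerical precision, so differences from the published summary tables
  reflect the source tables, not the implementation.
* At high moisture the fitted isotherms of different temperatures can
  cross (the data themselves cross for one cultivar); the isosteric slope
  then changes sign and the compensation line for that series is
  ill-conditioned. The package reports the result rather than suppressing
  it; users should inspect `r2` in the isosteric table.
* No parameter uncertainty is reported (the multi-start least-squares
  protocol returns point estimates only).
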