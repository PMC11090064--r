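---
title: "Estimating mass density from refractive index: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mass density from refractive index: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridens)
```

## The problem

Quantitative phase imaging and optical diffraction tomography (ODT) deliver
three-dimensional maps of the refractive index (RI) of living matter, but
many downstream questions — buoyancy, molecular crowding, the
interpretation of Brillouin elastography — need the *mass density* (MD).
The two are connected only through the biochemical composition of the
sample: every solute species contributes its own refraction and its own
specific volume. `ridens` implements a mixture model that makes that
connection explicit, propagates the uncertainty that comes from imperfect
knowledge of the composition, and validates the closed forms against a
Monte-Carlo simulator.

## The binary mixture model

For a solute (index 2) dissolved in a solvent (index 1) we assume *volume
additivity*: component volumes add, so the partial specific volume (PSV)
$\theta$ of the solute equals the reciprocal of its pure density,
$\theta = 1/\rho_2$. The solution density is then linear in the solute
concentration $c_2$ (g/mL),

$$\rho = \rho_1\,(1 - c_2\theta) + c_2 .$$

For the RI we adopt the **Biot mixing rule** — the volume-fraction-weighted
arithmetic mean $n = \sum_i \phi_i n_i$ — which together with volume
additivity yields a linear RI contrast $\delta n \equiv n - n_1 = \alpha
c_2$ with RI increment $\alpha = \theta\,(n_2 - n_1)$. Eliminating $c_2$
gives the central estimator implemented in `rho_from_contrast()`:

$$\rho(\delta n) = \frac{\delta n}{\alpha}
  + \rho_1\Bigl(1 - \theta\,\frac{\delta n}{\alpha}\Bigr),
  \qquad
  \frac{\partial \rho}{\partial n} = \frac{1 - \rho_1\theta}{\alpha}.$$

The slope can be positive (protein-like solutes, $\theta < 1/\rho_1$),
negative (lipid-like, $\theta > 1/\rho_1$), or — remarkably — zero. For a
binary protein/lipid solute the effective PSV crosses $1/\rho_1$ at a
specific lipid volume fraction (`decoupling_fraction()`; about 0.80 for
protein with $\theta_p = 0.734$ mL/g and triolein): there the MD is
*decoupled* from the RI and from the water content entirely.

Pure-substance RIs and refractions per gram $R$ interconvert through the
Lorentz–Lorenz relation $R = (1/\rho)(n^2-1)/(n^2+2)$
(`refraction_per_gram()` / `ri_from_material()`). Alternative mixing rules
(Lorentz–Lorenz, Wiener) have no convenient closed-form $\rho(\delta n)$;
`rho_from_contrast_generic()` inverts their $n(c_2)$ numerically by
bracketed root finding on $c_2 \in [0, 1/\theta_{\mathrm{eff}}]$ to a
tolerance of $10^{-12}$, which is safe because $n(c_2)$ is monotone for
physical parameters. Note that the different rules imply different RI
increments for the same material, so their density estimates agree at
$\delta n = 0$ but differ in slope — that is why the package reports
Biot and Lorentz–Lorenz predictions separately.

## Complex solutes: voxels, voxelinos and effective parameters

Real dry mass is a mixture (proteins, lipids, sugars). The model
discretises each imaging voxel into $N_0$ equal-volume "voxelinos", each
occupied by solvent or by one solute constituent with its own
$(\alpha_i, \theta_i)$. A voxelino of PSV $\theta_i$ carries mass
$v_0/\theta_i$, so relative volume fractions $x_j$ convert to mass
fractions $y_j \propto x_j/\theta_j$ (`mass_from_volume_weights()`), and
the voxel obeys the binary-model relations with *mass-averaged effective
parameters*

$$\theta_{\mathrm{eff}} = \sum_i y_i\,\theta_i,\qquad
  \alpha_{\mathrm{eff}} = \sum_i y_i\,\alpha_i .$$

For a binary solute at lipid volume fraction $x$,
$\bar\theta_{\mathrm{eff}}(x)$ reduces to the volume-weighted harmonic
mean (`binary_effective_theta()`).

## Sequence-based protein parameters

Per-protein $(R_p, \theta_p)$ come from molar-mass-weighted averages of
residue constants over the amino-acid sequence (`protein_props()`), the
protein RI from the Lorentz–Lorenz relation at $\rho = 1/\theta_p$, and
the RI increment either from the Biot rule or from the dilute limit of the
Wiener effective-medium rule,

$$\alpha_W = \tfrac{3}{2}\,\theta\,n_1\,
 \frac{n_2^2 - n_1^2}{n_2^2 + 2 n_1^2},$$

which is always below the Biot value $\theta(n_2-n_1)$ — the package
verifies this ordering property and checks $\alpha_W$ against a numerical
derivative of the full Wiener rule.

The bundled residue table stores dehydrated residue masses, consensus
residue volumes (converted to residue PSVs via Avogadro's number) and
literature residue-specific refractive increments; the residue refraction
per gram is *derived* at load time by inverting the Wiener dilute-limit
relation at $n_1 = 1.3330$, so the tabulated increments are reproduced
exactly by construction. These constants are literature stand-ins with
per-entry provenance and can be replaced wholesale via
`residue_table(path)`. Non-standard letters (B, J, O, U, X, Z) are skipped
with a warning and excluded from the weight normalisation — a
deterministic policy that matters only for a tiny fraction of annotated
sequences. No terminal-water correction is applied; for proteome-scale
chains the relative effect is below $10^{-3}$.

## Uncertainty: closed forms

All closed forms live in `propagate_uncertainty()` and its pieces, for a
binary (protein + lipid) solute with component means and SDs
$(\bar\alpha_j \pm \Delta\alpha_j, \bar\theta_j \pm \Delta\theta_j)$:

* **Single-voxelino spread**: the two-moment mixture formula
  (`mixture_spread()`) gives $\Delta\theta^0_{\mathrm{eff}}$,
  $\Delta\alpha^0_{\mathrm{eff}}$; the spread is maximal at $x = 0.5$.
* **Central-limit shrinkage**: averaging $N_s = N_0(1-\bar\phi_1)$
  voxelinos shrinks these by $1/\sqrt{N_s}$ (`delta_eff_single()`).
* **Composition fluctuation**: a voxel-to-voxel spread $\Delta x_{lip}$
  adds $(\partial\bar\theta_{\mathrm{eff}}/\partial x \cdot
  \Delta x_{lip})^2$ in quadrature (`delta_eff_total()`), using the exact
  partial derivatives of the harmonic mean (`binary_partials()`, verified
  against finite differences). This term does not vanish for large $N_0$:
  inhomogeneity sets a floor on the achievable precision.
* **Solvent fraction**: $\phi_1 = 1 - N_s/N_0$ fluctuates with the number
  of solute voxelinos (`delta_phi1()`). Under the equilibrium (binomial)
  model the spread is $\sqrt{\bar\phi_1(1-\bar\phi_1)/N_0}$; under the
  solute-mass bookkeeping model an additional inhomogeneity component
  $\sqrt{(\Delta m_s/\bar m_s)^2 + (\partial\bar\theta_{\mathrm{eff}}/
  \partial x\,\Delta x_{lip}/\bar\theta_{\mathrm{eff}})^2}$ survives at
  large $N_0$.
* **RI and MD**: Gaussian propagation, neglecting correlations, through
  $n = n_1 + (1-\phi_1)\alpha_{\mathrm{eff}}/\theta_{\mathrm{eff}}$
  (`delta_n()`) and through the density relation (`delta_rho()`). At the
  decoupling composition the $\Delta\phi_1$ term of $\Delta\rho$ vanishes
  identically.

Two regimes follow and are asserted as tests: with no inhomogeneity every
propagated SD scales exactly as $N_0^{-1/2}$; with $\Delta m_s > 0$ or
$\Delta x_{lip} > 0$, $\Delta n$ and $\Delta\rho$ plateau at strictly
positive values.

## Uncertainty: the Monte-Carlo simulator

`simulate_voxels()` draws, per voxel: $\phi_1$ and (binary case) $x_{lip}$
from normal distributions truncated to $[0,1]$ (inverse-CDF sampling,
`sample_truncated_normal()`); the number of solute voxelinos $N_s$ from
the chosen `ns_model`; a multinomial split of $N_s$ over components; and
per-voxelino $(\alpha_i, \theta_i)$ from the component distributions. The
voxel MD is the exact mass balance $\phi_1\rho_1 + \frac{1}{N_0}\sum_i
1/\theta_i$ and the RI the Biot average over voxelinos (or the
Lorentz–Lorenz mixture when `rule = "lorentz_lorenz"`). Every voxel
satisfies the density–contrast pairing identity with its *realized*
effective parameters to $10^{-10}$ — a structural invariant of the
implementation, not an approximation.

Design choices worth knowing:

* **`ns_model`**. `"binomial"` (the default; an equilibrium placement
  argument) draws $N_s \sim \mathrm{Bin}(N_0, 1-\phi_1)$;
  `"mass_fluctuation"` multiplies by $(1+\varepsilon_m)$,
  $\varepsilon_m \sim N(0, \Delta m_s/\bar m_s)$; `"fixed"` rounds
  deterministically. $N_s$ is drawn *independently* of the per-voxelino
  $\theta$ draws and of the drawn composition. The closed-form
  propagation neglects exactly those correlations, and the simulator is
  meant to be its like-for-like reference; coupling $N_s$ to the
  $\theta$ draws would cancel part of the density fluctuation (solute
  mass per voxel would become fixed) and change $\Delta n$ by up to a
  factor of two. This is a modelling assumption, documented here as a
  known limitation of both routes.
* **Fast path**. For component counts above 2000 the per-voxelino sums
  are drawn from their matched-moment Gaussian laws (first-order
  deviations, second-order means) instead of explicit draws —
  distributionally equivalent by the central limit theorem, and the
  reason an $N_0 = 10^5$, $N_v = 10^3$ ensemble runs in well under a
  second. The exact path is kept and used as an oracle in the tests;
  both paths agree in means and SDs within sampling error.
* **Truncation**. Composition parameters near the boundary (e.g.
  $\bar x = 0$ with $\Delta x > 0$) produce genuinely truncated
  (half-normal) distributions; the closed forms assume untruncated
  normals, so the analytic/MC comparison is only meaningful away from
  the boundary. At the study's parameter values ($5\sigma$ or more from
  the bounds) truncation is negligible.
* **Contours**. 68%/95% regions of $P(\rho, \delta n)$ use a Gaussian
  KDE (Scott bandwidth, 256×256 grid) with iso-density thresholds chosen
  to enclose the nominal probability mass; on a $10^4$-point Gaussian
  cloud the enclosed empirical mass is correct within ±0.03 (Scott
  smoothing biases it upward by roughly +0.01–0.02 at this sample size).
  Marginals are summarised by the median and the central 68%/95%
  percentile intervals.
* **Determinism**. One top-level seed; all draws happen in a fixed
  vectorised order, so results are bit-reproducible for a given
  (specification, seed). No parallelism.

## Fitting concentration series

Experimental $(\delta n, \rho)$ dilution series (Abbe refractometry +
pycnometry; `pycnometer_volume()`, `density_from_pycnometry()`,
`dilution_concentration()`) are fitted by weighted least squares:
$\delta n = \alpha c$ strictly through the origin (the contrast is zero
at zero concentration by definition), and $\rho = \rho_1 + (1 -
\rho_1\theta)c$ with the intercept *fixed* at the known solvent density —
the solvent is treated as exact throughout the package; a free-intercept
variant exists for diagnostics (`fit_theta(..., fix_intercept =
FALSE)`). With per-point SDs the weights are inverse variances and the
slope SD comes from the weighted normal equations without a dispersion
rescale (the known-variance convention, which is what makes the 68%
intervals calibrated); with no SDs an estimated residual variance is
used. `fit_series()` wraps both fits in a model object with `coef`,
`predict`, `residuals` methods. `compare_mixing_rules()` asks which rule
makes the fitted $(\hat\alpha, \hat\theta)$ consistent with the solute RI
predicted from the known composition, ranking rules by the discrepancy.

The synthetic-series generator (`generate_synthetic_series()`) draws the
model line plus independent Gaussian noise. The defaults emulate a
refractometry/pycnometry bench: 8 concentrations up to 0.08 g/mL, RI
noise $5\times10^{-4}$ (a standard Abbe refractometer's resolution),
density noise $10^{-3}$ g/mL (pycnometry with a precision balance). What
it does *not* emulate: concentration-dependent (heteroscedastic) errors,
volume inadditivity at high concentration, instrument drift — so the
passing coverage tests certify the estimator under the stated noise
model, not those effects.

## Problem sizes used in the validation suite

The test-suite simulations use $N_v = 10^3$–$10^4$ voxels and $N_0 =
10^3$–$10^5$ voxelinos per voxel (the larger values through the fast
path), 500 replicate series for the coverage checks and $10^4$ points for
the contour calibration; these sizes put Monte-Carlo sampling error
(about 1–2% on an ensemble SD) well below the 10% documented agreement
tolerance between the closed forms and the simulator. The analytic
spreads at $x = 0.5$ sit 4–6% above the simulator because the mixture
spread formula is volume-weighted while the realized effective parameters
are mass-weighted ratio statistics — the simulator is the reference where
the two disagree.

## Known limitations

* Volume additivity is assumed everywhere ($\theta = 1/\rho_2$);
  concentration-dependent apparent specific volumes are not modelled.
* Single-wavelength constants; no dispersion or temperature corrections.
* No spatial correlation between voxels; no covariance propagation
  between $\alpha_{\mathrm{eff}}$ and $\theta_{\mathrm{eff}}$ (the MC
  ensemble is the tool of choice when that matters).
* The bundled material and residue constants are literature stand-ins
  with per-entry citations; users with better constants should supply
  their own tables — every API accepts overrides.
* The bundled larval zebrafish trunk configuration represents the tissue
  lipid pool by triolein alone. Its MC medians reproduce published
  trunk-tissue values within their 68% bands, but the Biot RI median
  sits about $10^{-3}$ below the published centre — the expected
  signature of the missing polyunsaturated phospholipid fraction, whose
  composition is not publicly tabulated.
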