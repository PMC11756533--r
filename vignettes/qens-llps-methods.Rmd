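---
title: "Modeling protein short-time diffusion across liquid-liquid phase separation with QENS"
author: "qensllps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling protein short-time diffusion across LLPS with QENS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qensllps)
```

## The scientific problem

Charge-tuned protein solutions (the canonical example: bovine serum albumin
with a trivalent salt such as LaCl3 in D2O) undergo liquid-liquid phase
separation (LLPS): the homogeneous solution demixes into microdroplets of a
protein-rich ("dense") phase suspended in a protein-poor ("dilute") phase.
Quasi-elastic neutron spectroscopy (QENS) on a backscattering spectrometer
measures the incoherent dynamic structure factor $S(q,\omega)$ and thereby
the *short-time self-diffusion* of the proteins and transient protein
clusters on nanosecond time scales — exactly the regime where hydrodynamic
interactions dominate and where both coexisting phases remain visible in a
single spectrum.

This package implements the complete analysis chain for such an experiment:

1. a spectral model for the measured $S(q,\omega)$,
2. a global (all $q$, all $\omega$) weighted least-squares fit with one or
   two diffusing populations and reduced-$\chi^2$ model selection,
3. colloidal hard-sphere theory for the apparent short-time diffusion
   coefficient as a function of volume fraction,
4. an interpretation layer (diffusion-ratio factorization test,
   Flory-Stockmayer cluster statistics, lever rule, unit conversions), and
5. a seeded synthetic-data generator so that every stage is testable against
   known ground truth without access to neutron data.

## The spectral model

The measured spectrum at momentum transfer $q$ is modeled as

$$ S(q,\omega) = \mathcal{R} \otimes \Big\{ \beta(q)\,\big[S_{\rm COM} +
S_{\rm int}\big] + A_0(q)\,\delta(\omega) +
\beta_{\rm D_2O}(q)\, \mathcal{L}(\omega;\gamma_{\rm D_2O}) \Big\}, $$

where $\mathcal{L}(\omega;\gamma)$ is a unit-area Lorentzian of half-width
at half-maximum (HWHM) $\gamma$ and $\mathcal{R}$ the resolution function.

* **Center-of-mass (COM) term.** With one population,
  $S_{\rm COM} = \mathcal{L}(\omega;\gamma)$ with the Fickian law
  $\gamma = \hbar D q^2$.  With two populations,
  $S_{\rm COM} = r\,\mathcal{L}(\gamma_{\rm dil}) +
  (1-r)\,\mathcal{L}(\gamma_{\rm dense})$, with
  $\gamma_{\rm dil} = \hbar D_{\rm dil} q^2$,
  $\gamma_{\rm dense} = \hbar D_{\rm dense} q^2$, the ordering constraint
  $D_{\rm dense} < D_{\rm dil}$ and one global intensity ratio
  $0 \le r \le 1$ — only two parameters more than the single-population
  model.
* **Internal dynamics.** Backbone and side-chain motions are two coupled
  Lorentzians riding on each COM line: convolution of Lorentzians adds
  widths, so $S_{\rm int} = \alpha(q)\,\mathcal{L}(\gamma + \lambda_1) +
  (1-\alpha(q))\,\mathcal{L}(\gamma + \lambda_2)$ with jump-diffusion widths
  $\lambda_i = \hbar D_i q^2 / (1 + D_i q^2 \tau_i)$ (Fickian at small $q$,
  saturating at $\hbar/\tau_i$).  In the two-population case the internal
  mixture is convolved with each COM width at the same ratio $r$, and
  $D_{1,2}$, $\tau_{1,2}$ are shared between the populations.  Since the
  exact amplitude coupling of the underlying switching model is not imposed,
  the weight $\alpha(q) \in [0,1]$ is a free per-$q$ parameter.
* **Elastic line.** $A_0(q)$ collects the elastic incoherent structure
  factor and residual container scattering into one non-negative per-$q$
  amplitude; no parametric confinement model is imposed.
* **Solvent.** The D2O term is fixed: its amplitude scales with the volume
  not occupied by protein, $\beta_0 (1-\varphi)$, and its width comes from a
  solvent table (in the generator, a jump-diffusion law for heavy water).

**A note on the amplitude convention.**  The protein amplitude $\beta(q)$
multiplies the *sum* of the unit-area COM term and the unit-area internal
mixture, so the quasi-elastic protein area is $2\beta(q)$ and the total
spectral area is $2\beta + A_0 + \beta_{\rm D_2O}$.  This convention keeps
the COM and internal contributions locked to a common scale (the fit then
profiles exactly three linear amplitudes per $q$) and reduces exactly to the
single-population form when $r \in \{0, 1\}$.

Units: energies in ueV, diffusion in A$^2$/ns, momentum transfer in 1/A,
through the single constant $\hbar = 0.6582119$ ueV ns (`qens_constants()`).

### Resolution convolution

The resolution function is an area-normalized sum of non-centered Gaussians
per $q$ (the standard analytic description of a backscattering resolution
measured on vanadium).  Convolution is analytic: every Lorentzian becomes a
sum of shifted Voigt profiles, every delta becomes the resolution profile
itself.  The Voigt profile is evaluated through the Faddeeva function
$w(z)$, implemented in compiled code as a 40-term Weideman rational
approximation, switching to a continued fraction for $|\Re z| + \Im z > 15$;
both branches are accurate to ~1e-13 relative error.  A brute-force
trapezoid-quadrature convolution (`convolve_numeric()`) is retained purely
as the independent cross-check; the test suite requires agreement below
1e-5 relative error on the default grid and observes ~1e-9.

## Global fitting strategy

All spectra of a sample enter one weighted least-squares problem (weights
$1/\sigma^2$ from the per-point errors).  Three structural choices make the
fit robust and fast:

* **Profiled linear amplitudes.** For fixed shared parameters the model is
  linear in three per-$q$ amplitudes ($p_1 = \beta\alpha$,
  $p_2 = \beta(1-\alpha)$, $A_0$); they are solved exactly at every
  objective evaluation by a tiny non-negative least-squares step
  (active-set enumeration, exact in $\le 3$ variables).  The outer optimizer
  therefore sees only 5 (single) or 7 (two-population) parameters.
* **Structural ordering.** $D_{\rm dense} = s\,D_{\rm dil}$ with
  $s \in (0,1)$ bounded, so the ordering constraint can never be violated
  and no penalty terms are needed.  Scale-type parameters are optimized on
  the log scale.
* **Global initialization.** A coarse grid over the COM parameters (with
  amplitudes profiled, i.e. scanning the true objective) locates candidate
  basins; Levenberg-Marquardt then refines in stages — internal dynamics
  first with COM frozen, then COM, then everything — because the internal
  jump-diffusion parameters otherwise fall into a Fickian-mimicry local
  minimum ($\tau \to 0$) when moved jointly with badly placed COM
  parameters.  Three seeded multi-starts explore the best *distinct* grid
  basins, and the lowest-deviance solution wins.

Uncertainties come from the full Jacobian (shared parameters *and* per-$q$
amplitudes) at the optimum.  A fit is *flagged* rather than errored when the
optimizer did not converge, the protein carries less than 1% of the fitted
amplitude (a protein-free spectrum leaves $D$ unidentifiable), a diffusion
coefficient sits at its box bound, or a headline parameter has more than
100% relative uncertainty.

**Model selection** between one and two populations follows the reduced
$\chi^2$: the two-population model must improve reduced $\chi^2$ by more
than 1% (relative), otherwise the simpler model is kept.

## Hard-sphere hydrodynamics

Short-time self-diffusion of colloidal hard spheres is reduced by crowding:
$D_t(\varphi) = D_{0,t} f_t(\varphi)$ and
$D_r(\varphi) = D_{0,r} f_r(\varphi)$.  The default polynomials are the
standard short-time virial forms
$f_t(\varphi) = 1 - 1.8315\varphi(1 + 0.12007\varphi - 0.65074\varphi^2)$
and $f_r(\varphi) = 1 - 0.631\varphi - 0.726\varphi^2$; they are
configuration values (reported in the pipeline provenance block), not
hard-coded truths.  An incoherent QENS experiment sees the combination of
translation and rotation: the model spectrum
$\sum_l B_l(qR)\,\mathcal{L}\!\big(\hbar[D_t q^2 + l(l+1)D_r]\big)$ with
$B_l = (2l+1) j_l^2(qR)$, truncated when $\sum_l B_l \ge 1 - 10^{-6}$.  The
*apparent* diffusion coefficient is defined operationally, as in the
experiment: the HWHM of that composite line (found by bisection) divided by
$\hbar q^2$, evaluated at a reference $q$ (default 1.0 1/A; ratios are
insensitive to this choice).  Defaults $R = 30$ A (serum-albumin scale),
$D_{0,t} = 6$ A$^2$/ns and the Stokes-consistent
$D_{0,r} = 3 D_{0,t} / (4R^2)$; all cancel (including any temperature
dependence of $D_0$) in the dense/dilute ratio.

## The factorization test

The interpretation hinges on the hypothesis that at constant temperature the
COM diffusion factorizes as
$D = D_0(T)\, f(\varphi)\, g(c_s/c_p)$ — a crowding factor times a salt
master curve that encodes the cluster statistics.  If $g$ is *the same
function in both coexisting phases* (continuity of cluster statistics at
the phase boundary), then

$$ \frac{D_{\rm dense}}{D_{\rm dil}} =
\frac{f(\varphi_{\rm dense})}{f(\varphi_{\rm dilute})}, $$

with everything else canceling.  `factorization_test()` compares the fitted
ratio with the hard-sphere prediction at the measured volume fractions and
flags agreement at a configurable tolerance (default 5%).  The master curve
itself is represented parametrically as
$g(x) = g_\infty + (1-g_\infty)e^{-x/x_0}$ with the percolation-limit
plateau $g_\infty = 0.4$; only its monotonicity and plateau are used, its
exact shape never enters the ratio test.

Cluster statistics are available through `flory_stockmayer()`: the classical
distribution of $n$-mers for particles with $f$ bonding sites and bond
probability $p$, percolation threshold $p_c = 1/(f-1)$, with the number of
$n$-mers per monomer computed through log-gamma and an adaptively extended
size cutoff (sol mass conservation holds to 1e-8 below $p_c$).

## What the synthetic generator emulates — and what it does not

`default_instrument()` emulates a Si(111) cold-neutron backscattering
spectrometer: energy window $\pm 100$ ueV in 0.4 ueV steps, resolution 3.5
ueV fwhm (composite of non-centered Gaussians, rescaled so the numerically
measured fwhm matches the request within root-finding tolerance), and
$q \in \{0.4, 0.55, \ldots, 1.9\}$ 1/A.  `simulate_spectrum()` adds Gaussian
noise with variance proportional to the model — the counting-statistics
surrogate appropriate for reduced backscattering data — normalized per $q$
so that the peak channel collects `counts_scale` expected counts.

Generator defaults are fixed study conditions, not tuning knobs:

* protein amplitude $\beta = 0.8$ and solvent $\beta_0(1-\varphi) \approx
  0.17$: at 240 mg/mL protein in D2O the protein hydrogens carry the large
  majority of the incoherent signal ($\sigma_{\rm inc}(\mathrm{H}) \approx
  80$ barn vs $\sigma_{\rm inc}(\mathrm{D}) \approx 2$ barn), so roughly
  80-85% protein share is the physically realistic split;
* internal dynamics $D_1 = 5$, $\tau_1 = 0.1$ ns (backbone-like, narrow),
  $D_2 = 30$, $\tau_2 = 0.01$ ns (side-chain-like, broad), $\alpha = 0.4$,
  elastic $A_0 = 0.05$ plus a small residual container line 0.01 — all
  literature-typical magnitudes for serum albumin on a backscattering
  window;
* solvent width from a heavy-water jump-diffusion law
  ($D = 130$ A$^2$/ns, $\tau = 4$ ps).

The generator does **not** emulate detector geometry, event-mode counting,
absorption or multiple scattering, detailed-balance asymmetry, or
coherent-scattering structure factors.  Passing tests therefore demonstrate
the correctness and statistical calibration of the *analysis*, not the
instrument reduction chain upstream of it.

The mock phase diagram is an ellipse-shaped binodal in the $(c_s, c_p)$
plane with tie lines at constant salt concentration — the real binodal of
these systems is known only schematically, and any self-consistent geometry
suffices for testing the lever-rule bookkeeping, which holds exactly by
construction.

## Numerical choices and problem sizes

* Faddeeva/Voigt: Weideman $N = 40$ + continued fraction (see above); the
  quadrature oracle uses 0.02 ueV steps with 400 ueV padding.
* NNLS: exact active-set enumeration in three variables.
* Optimizer: `minpack.lm::nls.lm`, `ftol = 1e-10`, `ptol = 1e-8`, 150
  iterations for the final stage, 50 per alternation stage; 3 multi-starts.
* Reduced $\chi^2$ counts all parameters, shared plus $3 \times n_q$
  profiled amplitudes.
* Study sizes in tests and the acceptance script: the parameter-recovery
  study uses the full default grid (11 $q$ times 501 channels) with 6-10
  seeds; the model-selection and factorization studies use a reduced grid
  (6 $q$, 1.0 ueV steps, single-Gaussian resolution) with 8-20 seeds per
  condition — on that grid the model-discrimination margin (~10% in reduced
  $\chi^2$) is an order of magnitude above the 1% decision threshold, so the
  reduced grid does not weaken the check.  These sizes are the package's
  chosen compromise between statistical resolution and a test suite that
  runs in minutes.
* `counts_scale = 1e4` at the peak channel corresponds to ~1% relative
  error at the peak — conservative relative to several hours of counting on
  a real backscattering instrument.

## Worked example

```{r example, eval = FALSE}
inst <- default_instrument(n_components = 1)
solv <- solvent_table(inst$q_values)
truth <- ground_truth("two_population", D_dil = 5, D_dense = 1, r = 0.5,
                      solvent = solv)
spectra <- simulate_spectrum(inst, truth, counts_scale = 1e4, seed = 1)
fit2 <- fit_two_population(spectra, inst$resolution, solv)
fit1 <- fit_single(spectra, inst$resolution, solv)
select_model(fit1, fit2)
```

### How much counting the ratio comparison needs

The factorization test compares the fitted $D_{\rm dense}/D_{\rm dil}$
(which is exactly the fit parameter $s$) with the hard-sphere prediction.
For a realistic phase split the predicted ratio is around 0.5-0.6, i.e. the
two Lorentzian width scales differ by only a factor of about two while four
free internal-dynamics parameters compete for the same spectral weight.
The package's own sensitivity study (reproduced in the acceptance tests)
shows that a noiseless spectrum set reproduces the predicted ratio exactly
and that at ~$10^6$ expected peak counts per $q$ the fitted ratio agrees
with the prediction to within a few percent, but that at $10^4$ peak counts the
single-spectrum decomposition is too weakly identified for a percent-level
ratio comparison: seeded replicates scatter by tens of percent and the
covariance is frequently singular (which the convergence flag reports).
Percent-level use of the factorization test therefore requires either long
counting times or averaging over repeated measurements; detecting a
qualitative violation (cluster statistics differing between the phases by a
factor of order two) is robust already at $10^4$ counts.

## Known limitations

* The two-population likelihood is multi-modal; the staged multi-start
  machinery makes the global basin the reliably selected one under the
  study conditions, but pathological spectra (vanishing protein amplitude,
  $r$ at its bounds) are flagged, not resolved.
* Covariance-based 1-sigma uncertainties only; no posterior sampling.
* At $r \to 1$ (or $0$) the second population's diffusion coefficient is
  structurally unidentifiable; the flag reports this.
* The internal-dynamics amplitude coupling of the switching model is
  deliberately relaxed to a bounded free weight per $q$.
* Dense/dilute predictions use monomeric hard spheres; cluster-resolved
  hydrodynamics (effective cluster diffusion averaging) is out of scope.
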