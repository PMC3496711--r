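---
title: "Ensemble FRET distributions in dynamic and static orientational regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble FRET distributions in dynamic and static orientational regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretensemble)
```

## The problem

An ensemble FRET measurement — a donor lifetime from FLIM, a sensitized-
emission ratio — reports a single average over a population of donor-acceptor
pairs. Interpreting that average as a distance requires knowing the
*distribution* of microscopic transfer efficiencies underneath it, and that
distribution is shaped by three mechanisms that this package simulates:

1. **Separation heterogeneity.** The transfer rate scales as
   $(R_0/R_{DA})^6$, so even a unimodal Gaussian distribution of separations
   maps to a bimodal efficiency distribution once its width is large: pairs
   much closer than $R_0$ saturate near $E = 1$, pairs much farther pile up
   near $E = 0$.
2. **Acceptor dark states.** Fluorophores (fluorescent proteins especially)
   blink between bright and dark states on timescales much longer than the
   donor excited-state lifetime. A dark acceptor cannot receive transfer, so
   a fraction $f_{dark}$ of pairs contributes an $E = 0$ subpopulation and
   the ensemble mean is attenuated to $(1 - f_{dark})\langle E\rangle$.
3. **Slow rotation (static orientational regime).** The orientation factor
   $\kappa^2 = \cos^2\omega\,(1 + 3\cos^2\theta)$ averages to $2/3$ only when
   dipoles reorient much faster than transfer. Fluorescent proteins rotate
   with 15–20 ns correlation times against 2–4 ns lifetimes, so each pair
   keeps a fixed, isotropically drawn $\kappa^2$ — and the isotropic
   $\kappa^2$ density is heavily skewed toward 0.

All three mechanisms turn a mono-exponential donor decay into a
multi-exponential one *without* any partial binding or aggregation, which is
the confound the simulations are designed to expose.

## Core model

For a fixed pair, $k_T = \tau_{0D}^{-1} (R_0/R_{DA})^6$ and
$E = k_T/(k_T + \tau_{0D}^{-1}) = 1/(1 + (R_{DA}/R_0)^6)$.
$R_0^6 \propto 0.02108\,\kappa^2 Q_D n^{-4} J$ with $J$ the
$\lambda^4$-weighted donor-emission/acceptor-extinction overlap integral
(`overlap_integral()`, trapezoidal quadrature on the union wavelength grid).

In the **static regime** the per-pair rate is
$k_T = \tfrac{3}{2}\kappa^2 \tau_{0D}^{-1} (R_0/R_{DA})^6$, the $3/2$
cancelling the $2/3$ embedded in $R_0$; per-pair efficiency is then
$E = F\kappa^2/(1 + F\kappa^2)$ with the Förster factor
$F = \tfrac{3}{2}(R_0/R_{DA})^6$.

### Closed-form static-regime density

Because $E$ is a monotone function of $\kappa^2$ at fixed $F$, the efficiency
CDF is the isotropic $\kappa^2$ CDF composed with
$g(E) = E/(F(1-E))$. For $x = \cos\theta$, $y = \cos\omega$ uniform on
$[0,1]$, direct integration of $P(y^2(1+3x^2) \le k)$ gives

$$A(k) = \begin{cases}
\sqrt{k/3}\,\ln(2+\sqrt 3), & 0 \le k \le 1,\\[2pt]
\sqrt{(k-1)/3} + \sqrt{k/3}\,\bigl[\ln(2+\sqrt3) - \ln(\sqrt{k-1}+\sqrt k)\bigr], & 1 < k \le 4.
\end{cases}$$

This form was re-derived independently here and is cross-validated against
the Monte-Carlo sampler in the test suite (Kolmogorov–Smirnov distance
< 0.01 at $n = 10^5$) before anything relies on it. Differentiating and
composing gives the efficiency density
$p(E) = A'(g)\,/\,(F(1-E)^2)$ with three phases:
an integrable $E^{-1/2}$ divergence at 0; an interior extremum at
$E = F/(1+F)$; exact 0 at and beyond $E = 4F/(1+4F)$ (the $\kappa^2 = 4$
ceiling). At $R_{DA} = R_0$: $F = 1.5$, boundaries 0.6 and $6/7 \approx 0.86$,
mean 0.379, SD 0.252.

## Monte-Carlo engine

`simulate_distance_heterogeneity()`, `simulate_static_regime()` and
`apply_acceptor_dark_states()` implement the stated world directly:

* **Replicates.** Default $n = 10^5$; tests use smaller populations where a
  tolerance does not assume $10^5$.
* **Separations.** Gaussian draws; non-positive draws are *dropped, not
  resampled*, and all summary statistics use the retained count (the only
  normalization with a probability interpretation after truncation).
* **Orientations.** $x, y \sim U[0,1]$, $\theta = \arccos x$,
  $\omega = \arccos y$ (hemispherical sampling). By the $\cos^2$ symmetry of
  $\kappa^2$ this is distributionally identical to full-sphere sampling on
  $[-1,1]$; `full_sphere = TRUE` exists and the equivalence is tested.
* **Pairing.** Separations and $\kappa^2$ values are associated
  independently at random; $R_{DA}$–$\kappa^2$ correlation is out of scope.
* **Dark states.** Independent Bernoulli masking of rates with probability
  $f_{dark}$; donor dark states are not simulated (they are assumed folded
  into the measured $R_0$; `r0_attenuation()` quantifies that folding as
  $[(1-f_{Dd})(1-f_{Ad})]^{1/6}$, a form inferred from the $R_0$ expression
  rather than printed anywhere — treat it as such).
* **Binning.** Efficiency histograms use 0.01-wide bins over $[0,1]$, final
  bin right-closed; densities normalized to integrate to 1.
* **RNG.** One seed per simulation call; identical parameters and seed give
  bit-identical output. No attempt is made to reproduce any other
  generator's streams — agreement with published numbers is statistical.

## Decay synthesis and fitting

`synthesize_decay()` converts a binned efficiency distribution to
$I(t) = \sum_n w_n e^{-t/\tau_n}$, $\tau_n = \tau_{0D}(1 - E_n)$ at bin
centres. The default grid is 1024 points over $[0, 4\tau_{0D}]$ (covering
> 98% of the intensity decay; no grid is prescribed by the source material).
Curves are noiseless; fits use uniform weights (Poisson $1/\sqrt I$ weights
are available for noisy curves). A bin centred exactly at $E = 1$ would be a
zero-lifetime spike; it is excluded from the sum with its weight recorded —
unreachable with 0.01 bins, but handled for coarse or hand-built histograms.

`fit_exponentials()` fits 1- or 2-component models with amplitudes
constrained non-negative and summing to 1, by **variable projection**: for
fixed lifetimes the amplitude share has a closed-form clipped linear
least-squares solution, leaving a well-conditioned 1- or 2-dimensional
optimisation over log-lifetimes (multi-start Nelder–Mead with BFGS polish).
A naive joint optimisation was found to fail precisely in the interesting
regime of small second-component amplitudes (5% dark acceptors).
Non-convergence is flagged, not thrown.

### Apparent (lifetime-derived) efficiency

`apparent_efficiency()` uses the amplitude-weighted mean lifetime:
$\langle\tau\rangle = \sum_n p_n \tau_n / \sum_n p_n$, apparent
$E = 1 - \langle\tau\rangle/\tau_{0D}$. Algebraically this equals the
binned mean efficiency, so it tracks the microscopic mean to within one bin
width. Three candidate conventions were evaluated for the static population
at $R_{DA} = R_0$ (the tests compute these): amplitude weighting gives
0.379, intensity weighting $\sum p\tau^2/\sum p\tau$ gives 0.277, and
amplitude-weighting a fitted double exponential gives 0.382. Amplitude
weighting is retained as the documented convention; note that the
historically printed value pair (0.37 apparent vs 0.38 microscopic) is
reproduced here as approximately 0.379 vs 0.380 — the two averages agree
more closely than the printed pair suggests, and no convention we tested
separates them by 0.01.

## Numerical choices

* Quadrature of the static density handles the $E^{-1/2}$ endpoint
  singularity by substitution ($u^2$ change of variables); moments are
  integrated in $\kappa^2$ space, an exact change of variables that moves
  the singularity to a form the same substitution removes.
* `distance_from_static_efficiency()` inverts the strictly monotone
  mean-efficiency curve by bracketed root-finding on $R_{DA}/R_0$, initial
  bracket $[0.05, 4]$ expanded geometrically on demand.
* The $\kappa^2$ CDF has unbounded curvature at the $k = 1$ phase seam;
  derivative checks avoid a small neighbourhood of it.
* Convergence of the static mean to 1 as $F \to \infty$ is slow
  ($1 - \langle E\rangle \sim F^{-1/2}$, from the $\kappa^2 \to 0$ pile-up),
  which the limit tests respect.

## What a green test does and does not establish

The generator emulates idealized populations: mono-exponential donors,
noiseless decays, no instrument response function, no photon statistics,
uncorrelated separation and orientation, and exactly two orientational
regimes (the physically continuous range between them is bracketed, not
interpolated). Green tests establish internal consistency of the theory,
the samplers, the closed forms and the fitters under those assumptions —
they do not validate any claim about a real instrument or a real construct.
Known limitations, by design: no Lorentzian or polymer-model separation
distributions, no restricted-cone (anisotropy-informed) $\kappa^2$ ranges,
no donor-dark-state population simulation, no IRF convolution or phasor
analysis.

## Worked example

```{r example, eval = FALSE}
sys <- forster_system(tau0D = 3, R0 = 5.4)

# static vs dynamic regime for the same tight population
sta <- simulate_static_regime(5.4, 1, sys, n = 1e5, seed = 1)
dyn <- simulate_static_regime(5.4, 1, sys, n = 1e5, seed = 1, kappa2 = 2/3)
c(static = sta$mean_E, dynamic = dyn$mean_E)

# closed form agrees with the simulation
static_efficiency_moments(static_factor(5.4, 5.4)$F)

# and inverts a measured mean back to a separation
distance_from_static_efficiency(0.43, R0 = 5.4)
```
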