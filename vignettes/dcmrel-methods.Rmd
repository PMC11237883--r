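---
title: "Models and methods behind dcmrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dcmrel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmrel)
```

# What the package computes

`dcmrel` asks a deceptively simple question: when a biophysical network
model is fitted to resting-state electrophysiological spectra twice — to
two halves of one recording, to two sessions weeks apart, or to two
matched groups — do the fitted models agree? The package answers it at
two levels:

* **model evidence**: are the per-subject free energies (log-evidence
  bounds) from the two measurements correlated beyond chance? This is a
  covariance-component comparison with and without an interclass
  correlation.
* **model parameters**: is there evidence for a session (or group)
  effect on any posterior parameter, once conditional dependencies among
  parameters are accounted for? This is a hierarchical (parametric
  empirical Bayes, PEB) analysis with a third-level session/group
  contrast.

Every stage can be exercised on synthetic cohorts with known ground
truth, which is how the test suite and the acceptance report work.

# The conductance-based microcircuit

Each cortical source contains four populations — spiny stellate cells
(`ss`, layer 4), superficial pyramidal cells (`sp`), one pooled
inhibitory population (`inh`) and deep pyramidal cells (`dp`). Each
population carries a mean depolarisation $V$ (mV) and three channel
conductances $g_\mathrm{AMPA}, g_\mathrm{GABA}, g_\mathrm{NMDA}$
(relative to the fixed leak conductance $g_L = 1$). With time in
milliseconds:

$$\dot V = \frac{1}{C}\Big[g_L (V_L - V) + g_\mathrm{AMPA}(V_\mathrm{AMPA} - V)
 + g_\mathrm{GABA}(V_\mathrm{GABA} - V)
 + g_\mathrm{NMDA}\, m(V) (V_\mathrm{NMDA} - V)\Big] + u$$

$$\dot g_\star = \frac{1}{\tau_\star}\Big(\textstyle\sum_k S_k\,\sigma(V_k) - g_\star\Big)$$

with the magnesium switch $m(V) = 1 / (1 + 0.2\,e^{-\alpha V})$
($\alpha = 0.06\,\mathrm{mV}^{-1}$ by default) gating the NMDA channel,
and a logistic firing-rate function $\sigma(V)$. The endogenous input
$u$ enters the spiny-stellate depolarisation only.

Connection routing follows the laminar microcircuit convention:
excitatory populations (`ss`, `sp`, `dp`) drive AMPA conductances of
their targets (plus a fixed quarter-weight NMDA component, so that NMDA
dynamics are active even in a single isolated region); the inhibitory
pool drives GABA. Between regions, forward connections arise from `sp`
and reach `ss` and `dp` of the target; backward connections arise from
`dp` and reach `sp` and (with double weight) `inh`; every edge carries
an AMPA-mediated strength (`A`) and an NMDA-mediated strength (`AN`),
each parameterised per edge at a base scale of 1/8.

## Parameters and priors

Every unknown is a log-scale deviation $\hat\theta$ with natural value
$\theta_0 e^{\hat\theta}$ and Gaussian prior $N(0, v)$:

| family | meaning | scale $\theta_0$ | prior variance |
|--------|---------|------------------|----------------|
| `T` | channel time constants (ms), per region | 4, 16, 100 | 1/16 |
| `C` | membrane capacitance, per population | (128, 128, 256, 32)/1000 | 1/16 |
| `H` | intrinsic connection gains | template below | 1/32 |
| `A`, `AN` | extrinsic AMPA / NMDA strengths, per edge | 1/8 | 1/8 |
| `L` | sensor gain, per region | 1 | 64 |
| `J` | `ss`/`dp` read-out contributions | 0.2 | 1/16 |
| `a`, `d` | input spectrum amplitude/exponent and cosine shape | 1 | 1/128 |
| `b`, `c` | common / specific noise spectra | 1 | 1/128 |
| `f` | band-edge filter scaling | 1 | 1/128 |
| `D` | intrinsic / extrinsic delays (ms) | 2, 16 | 1/64 |

The intrinsic template (target row, source column, order
`ss, sp, inh, dp`) is a design choice of this package: the printed
source for these gains is typographically corrupted, so a standard
microcircuit using the legible magnitudes was adopted and made
overridable through `prior_table(H_template = ...)`:

```{r}
default_H_template()
```

It encodes a feedforward excitatory chain `ss -> sp -> dp`, excitatory
drive onto the inhibitory pool from all pyramidal populations,
inhibitory self-damping, and GABAergic inhibition of every population.

## The firing-rate sigmoid

The literature names a "sigmoid squashing function" without fixing its
constants. We use $\sigma(V) = 1/(1 + e^{-s (V - V_R)})$ with threshold
$V_R = -40$ mV (the conventional firing threshold of this model family)
and slope $s = 1/4\ \mathrm{mV}^{-1}$. The slope was chosen once, by
scanning a small grid before any acceptance quantity was measured, as
the value at which prior-mean 1-, 2- and 4-region networks possess a
*live* stable equilibrium: steeper sigmoids collapse to a silent fixed
point at $V_L$ (no gain, no identifiable coupling), shallower ones
destabilise the circuit. Both constants sit in `model_constants()` and
can be changed.

## Linearised spectral response

Around the deterministic fixed point $x_0$ (found by damped Newton with
a semi-implicit integration fallback; residual tolerance $10^{-8}$), the
delay-corrected Jacobian is

$$J_\mathrm{eff} = (I + J \circ D)^{-1} J,$$

the first-order Taylor correction for conduction delays ($D$ holds the
intrinsic delay between populations of one region and the extrinsic
delay between regions; the sign follows from
$\dot x = J x(t - D) \approx Jx - (J \circ D)\dot x$ and is checked in
the tests against the dominant root of the scalar delay equation). The
transfer function from the per-region endogenous input to the sensors is
$K(\omega) = W (i\omega I - J_\mathrm{eff})^{-1} B$, with $B$ injecting
input into spiny-stellate depolarisation and $W$ the gain- and
$J$-weighted read-out of depolarisations. The predicted cross-spectral
density is

$$g(\omega) = \mathrm{taper}(\omega)\, K(\omega)\, g_u(\omega)\, K(\omega)^* + g_o(\omega)$$

where $g_u(\omega) = e^{a_1}\,f^{-e^{a_2}}\max(1 + \sum_i d_i
\cos(i\pi\nu), 10^{-8})$ is a power law modulated by a cosine basis on
the band-rescaled frequency $\nu \in [0,1]$; $g_o$ is a common (rank
one) plus source-specific (diagonal) power-law noise; and the taper is a
smooth two-bump band-edge scaling modelling data filtration. Every
predicted slice is Hermitian and clipped to the PSD cone. The default
analysis grid is 1–64 Hz in 1 Hz steps.

# Variational inversion

The likelihood stacks, per frequency, the real upper triangle and
imaginary strict upper triangle of the CSD into a real residual vector,
avoiding Hermitian double counting. Noise precision is diagonal with one
log-precision component per source plus one global component, under a
Gaussian hyperprior ($N(0, 16)$ by default). Optimisation is classic
variational Laplace: Gauss–Newton ascent on the free energy

$$F = \underbrace{-\tfrac12 e^\top \Pi e + \tfrac12 \ln|\Pi|
 - \tfrac{n}{2}\ln 2\pi - \tfrac12\mathrm{tr}(\Sigma_q J^\top \Pi J)}_{\text{expected accuracy}}
 - \mathrm{KL}\big(q \,\|\, \text{prior}\big) + \text{hyper terms}$$

with Levenberg–Marquardt damping, central-difference prediction
derivatives (step $10^{-4}$ on the log scale), precision updates by BFGS
after each accepted step (which can only increase $F$, preserving
monotonicity of accepted iterations), convergence when $\Delta F < 0.01$
for four consecutive iterations, and a cap of 128 iterations. On a
linear-Gaussian model this machinery reproduces the generalised
least-squares posterior and the analytic log evidence to $10^{-6}$,
which the tests assert. CSD data are rescaled by their mean feature
amplitude before fitting (absorbed by the sensor gain; disable with
`normalise = FALSE`).

# Bayesian model reduction and PEB

`reduce_model()` implements the closed-form Gaussian prior swap;
"switching off" a parameter means a reduced prior $N(0, 10^{-8})$,
keeping precisions invertible. `fit_peb()` places the hierarchical model
$\theta_1 = (X \otimes I)\,\theta_2 + \varepsilon_2$,
$\varepsilon_2 \sim N(0, (Q_0 I + e^{-\gamma} Q_1)^{-1})$ over
first-level posteriors, with $Q_0 = 10^{-6}$, $Q_1$ sixteen times the
prior precision of the group mean, and $\gamma \sim N(0,1)$. Because the
first-level evidence enters in information form (posterior precision
minus prior precision), the second level is exactly linear-Gaussian
given $\gamma$; a monotone Newton ascent handles the single
hyperparameter and a Laplace term enters the free energy. First-level
posteriors are re-estimated under the empirical prior by model
reduction. `peb_of_pebs()` feeds per-cohort group-mean posteriors into a
third level with a ones + indicator design; `flag_differences()` calls
a parameter different between cohorts when the model-reduction evidence
for a non-zero indicator effect exceeds posterior probability 0.95 (the
95% interval excluding zero is reported as a secondary criterion).

Note one property worth knowing: with $n$ identical first-level
posteriors the second-level group mean does *not* equal the shared
posterior mean — the hierarchy combines $n$ copies of the data evidence
with a single prior, so it concentrates toward the data. The tests
therefore compare against an exact dense Gaussian oracle of the same
hierarchy rather than against a naive averaging intuition.

# Reliability of model evidences

For paired evidence vectors $k_1, k_2$ (one entry per subject) the
package fits the repeated-measures GLM $y = X\beta + \varepsilon$ with
$y = [k_1; k_2]$, per-measurement intercepts, and covariance built from
log-scaled components $e^{h_1} I_{2n} + e^{h_2} (I_n \otimes 1_2
1_2^\top)$ — a compound-symmetry structure whose interclass correlation
is $\rho = e^{h_2} / (e^{h_1} + e^{h_2})$. $\beta$ is marginalised in
closed form under a vague prior; the $h$ carry a mild shrinkage prior
(variance 4) and a Laplace correction enters the free energy, so that
dropping the second component gives a clean with/without evidence
comparison, reported as $\Delta F$ with the conventional
positive-evidence threshold of 3. A design-matrix argument admits
arbitrary GLMs (e.g. a slope regression of one measurement on the
other). The classical metrics — the pooled-mean "modified Pearson"
correlation and the one-way ANOVA intraclass correlation with negative
between-group components clipped to zero — are provided for comparison.

The literal reading "one $n \times n$ compound-symmetry matrix across
subjects for the residuals of $k_1 = k_2\beta$" was rejected during
design: a single realisation of an exchangeable common component cannot
identify $\rho$ (its estimator does not concentrate with $n$), and it
cannot reproduce the behaviour expected of the test (selection of the
correlated model at $n = 14$, $\rho = 0.9$). The repeated-measures form
is the standard random-intercept equivalent and is what the evidence
comparison operates on.

# The synthetic world

`cohort_spec()` fixes the statistical world the analyses assume:
subjects drawn around the prior mean with a between-subject spread of
one prior standard deviation per family; an optional session effect
added to session 2 on named coordinates (in prior-sd units); complex
Hermitian Gaussian noise added to each epoch's spectrum and PSD
projected; 16 epochs and 2 sessions per subject by default; everything
a pure function of the seed. Two deliberate deviations from a naive
reading of "1 prior sd everywhere":

* the sensor-gain family `L` has prior variance 64 — vagueness about
  units, not biology. Drawing subjects at one prior sd would span ten
  orders of magnitude of gain and produce numerically degenerate
  spectra, so subject gains vary with a realistic 0.5 log-unit sd
  (1/16 of the prior sd). This was fixed when the degeneracy was first
  observed, before any acceptance quantity was measured.
* subjects whose drawn parameters destabilise the fixed point are
  redrawn (rejection counted and reported), so every emitted spectrum is
  defined. This conditions the population on model stability, which is
  also what fitting real data implicitly assumes.

The epoch noise standard deviation defaults to one tenth of the
alpha-band (8–12 Hz) peak of the prior-mean diagonal power — a 10:1
signal-to-noise ratio at the peak, averaging down with epochs.

What a green synthetic test does establish: the estimators are
internally consistent (oracles), the null calibration of the difference
flags is honest, injected effects of the stated size are found, and the
evidence-reliability comparison separates correlated from independent
designs at the study's n. What it cannot establish: robustness to real
MEG artefacts, source-localisation error, head movement, or model
misspecification — none of which the generator emulates.

# Numerical choices and limitations

* Fixed points: Newton with infinity-norm line search; fallback to
  semi-implicit (Rosenbrock–Euler) integration, then a Newton polish;
  everything deterministic, warm-started across the thousands of
  evaluations of an inversion.
* The resolvent is evaluated through the eigendecomposition of the
  Jacobian when the eigenvector basis is well conditioned (checked by a
  cheap reconstruction probe), with per-frequency linear solves as the
  fallback.
* The compiled core (RcppArmadillo) mirrors a pure-R reference
  implementation; both paths are asserted equal to numerical precision
  in the tests.
* Identifiability: single-subject spectra inform only a subset of
  coordinates strongly (gain/amplitude products are degenerate, as in
  any spectral DCM); recovery statements are made over coordinates whose
  posterior variance shrinks below half the prior variance.
* The iteration budget (128) can leave noiseless fits formally
  "unconverged" while the residual is already at machine scale, because
  the estimated noise precision keeps growing; results flag this rather
  than hide it.
* Three hierarchy levels, Gaussian random effects only, no multiplicity
  correction across the three analyses (none is applied by the
  procedure this package re-implements).
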