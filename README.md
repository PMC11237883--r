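# dcmrel

Test–retest reliability analysis for dynamic causal models (DCM) of
resting-state electrophysiology.

## The problem

Biophysical network models fitted to MEG/EEG spectra — here a
conductance-based canonical microcircuit with AMPA, GABA-A and NMDA
channel dynamics in four populations per cortical source — yield
posterior distributions over synaptic parameters and a free-energy bound
on log model evidence. Before such models can track disease progression
or drug effects, one must know whether refitting the same person (split
recordings, or sessions weeks apart) reproduces the same inferences.
Classical reliability statistics (Pearson or intraclass correlation of
point estimates) ignore posterior covariance among parameters, which is
exactly what makes single-parameter estimates of complex models look
unreliable. `dcmrel` implements the Bayesian alternative:

* **Evidence reliability.** Per-subject free energies from two
  measurements are modelled with a GLM whose residual covariance either
  does or does not contain a compound-symmetry (interclass correlation)
  component, estimated by variational Laplace; the free-energy
  difference `ΔF` between the two covariance models is the evidence for
  reliability (`ΔF > 3` is positive evidence, and
  `exp(ΔF)` is the Bayes factor — `ΔF = 20` corresponds to ~5×10⁸).
* **Parameter reliability.** First-level posteriors enter a parametric
  empirical Bayes (PEB) hierarchy per parameter family; the per-session
  (or per-group) PEB results are contrasted in a third-level "PEB of
  PEBs" with a ones + indicator design, and Bayesian model reduction
  scores the evidence for a non-zero difference on every parameter. The
  headline statistic is the fraction of parameters *without* evidence of
  a difference.

The core machinery — spectral forward model (fixed point, delay-corrected
Jacobian, transfer function, structured input and noise spectra),
variational-Laplace inversion, Bayesian model reduction, PEB, the
compound-symmetry evidence test, and seeded synthetic-cohort
generators — is exposed as ordinary R functions. A compiled
(RcppArmadillo) fast path makes whole-cohort inversions practical on a
laptop.

## Worked example

Simulate a small null cohort — four subjects, a two-region network, two
sessions generated from identical subject-level parameters, spectral
noise only — and ask whether anything "differs" between sessions:

```r
library(dcmrel)

spec <- cohort_spec(n_subjects = 4, n_regions = 2, seed = 7)
cfg  <- study_config(cohort = spec,
                     analyses = c("evidence_reliability", "between_session"),
                     seed = 7)
report <- run_reliability_study(cfg)
print(report)
#> Reliability report (seed 7 )
#>   between_session: 0/44 parameters flagged (100.0% without evidence of difference)
#>     evidence reliability dF = 2.40 (rho = 0.91)
```

Reading the output: none of the 44 parameters analysed by the per-family
PEB shows evidence of a between-session difference (the null world is
correctly not rejected), and the free energies of the two sessions carry
an estimated interclass correlation of 0.91; with only four subjects the
evidence for that correlation (`ΔF = 2.40`) sits just below the
conventional threshold of 3 — at realistic cohort sizes (n = 14) the
same comparison is decisive:

```r
pair <- generate_evidence_pairs(14, rho = 0.9, sigma2 = 4, seed = 1)
compare_evidence_reliability(pair)
#> Evidence reliability: dF = 11.85 (favours compound symmetry), rho = 0.93

bayes_factor(20)$bf
#> [1] 485165195
```

Lower-level entry points: `predict_csd()` (forward spectra),
`invert_csd()` / `invert()` (variational Laplace), `reduce_model()` /
`switch_off_prior()` (Bayesian model reduction), `fit_peb()` /
`peb_of_pebs()` / `flag_differences()` (hierarchy and contrasts),
`fit_covariance_components()` (reliability GLM),
`modified_pearson()` / `icc_anova()` (classical metrics). A small CLI
lives at `inst/cli/dcmrel` (`simulate`, `invert`, `reduce`,
`reliability` subcommands). The methods vignette
(`vignettes/dcmrel-methods.Rmd`) documents the model, priors, numerical
choices and the design decisions in detail.

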