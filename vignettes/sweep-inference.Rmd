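---
title: "Inferring the selection regime of a focal variant by two-population ABC"
author: "sweepabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the selection regime of a focal variant by two-population ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepabc)
```

## The question and the model

A biallelic variant segregates in an African and a non-African population,
at moderate frequency in Africa and near fixation outside it, surrounded by
the haplotype and frequency-spectrum signatures of recent positive
selection. Three evolutionary regimes could have produced this pattern:

* **NTR** — neutrality: the derived allele appeared at some time `t_mut`
  and drifted.
* **SDN** — a sweep from a de novo mutation: the allele was beneficial from
  the moment it appeared, with selection coefficient `s_A` in the
  African/ancestral deme, changing to `s_NA` in the non-African deme after
  the out-of-Africa split.
* **SSV** — a sweep from standing variation: a previously neutral allele at
  frequency `f0` became beneficial in the non-African deme only, at time
  `t_mut`.

`sweepabc` decides between these regimes — and estimates their parameters —
by approximate Bayesian computation: simulate many datasets under each
regime with parameters drawn from uniform priors, summarise each simulated
and observed dataset by the same statistic vector, and retain the
simulations closest to the observation. Posterior model probabilities are
retained-set shares; parameter posteriors come from the retained parameter
draws.

The demographic scaffold is a two-deme out-of-Africa history (Gravel et
al. 2011 parameter values, 25-year generations): an ancestral population of
7,310 growing to 14,474 at 148 kya, a split 51 kya with a non-African
bottleneck of 1,861, exponential growth of the non-African deme from 23 kya
(554 at 0.48 %/generation for the East Asian configuration, 1,032 at
0.38 %/generation for the European one), and symmetric migration
(15e-5/generation before 23 kya, then 0.78e-5 or 2.5e-5). Mutation rate
2.36e-8 per bp per generation; constant recombination 1.76 cM/Mb. All of
this is configurable (`gravel_demography()`, `simulator_spec()`, YAML
configs via `load_config()`).

Priors (uniform, conditioned as below): SDN `s_A` ~ U(0, 1.5 %), `s_NA` ~
U(0.5 %, 5 %), `t_mut` ~ U(40, 70) kya; SSV `s_NA` ~ U(0, 5 %], `f0` ~
U(0, 20 %), `t_mut` ~ U(21, 51) kya; NTR `t_mut` ~ U(40, 70) kya.
Dominance `h` is 0.5 by default, with 0 (recessive) and 0.38
(supra-additive) as the alternatives compared by
`dominance_model_choice()`.

## The simulator

Two layers, both behind `simulate_batch()`:

**Allele-frequency trajectories** are forward Wright-Fisher paths: a
deterministic selection step with genotype fitnesses 1 : 1+hs : 1+s, a
symmetric migration exchange, then binomial drift with the epoch's 2N —
per generation, in both demes. For tractability the simulation is rescaled
by a factor `lambda` (default 10): population sizes are divided by
`lambda`, times compressed, and mutation/recombination/migration rates
multiplied by it; selection coefficients are rescaled exactly,
`(1+s)^lambda - 1`, so the growth factor of the selected genotype over
`lambda` real generations is preserved (for the strongest prior draws the
naive `s*lambda` understates selection by ~8 %). Every trajectory is
conditioned, by rejection, on the derived allele segregating in both demes
at present; in `simulate_batch()` the scenario parameters are re-drawn at
every attempt, so accepted draws follow the non-uniform post-conditioning
("effective") prior, whose acceptance rates are logged.

Onset states follow the operational convention of trajectory-conditioned
simulators, which specify the allelic configuration per deme at the moment
selection (or the mutation) starts. SDN/NTR start from one copy in the
ancestral deme when `t_mut` predates the split, and from one copy in
*each* deme otherwise (the alternative — a copy in Africa only, spreading
by migration at ~1e-4/generation — conditions on rare late migrant
establishments and produces the reverse of the observed geographic
pattern; trajectories simulated that way are flagged). SSV imposes `f0` in
each deme at `t_mut`. Pastward of the SSV onset the standing variant has
**no modelled origin**: when the coalescent walks past `t_mut` the allelic
classes simply merge. This matters scientifically: it leaves the ancestry
of the standing variant's carriers unconstrained, so SSV sweeps are
genuinely *soft* (several haplotype backgrounds rise together). Forcing
the standing variant back to a single origin instead makes SSV sweeps
harder than SDN sweeps and inverts the models' separability.

**Haplotypes** are generated by a structured coalescent conditioned on the
trajectory. Sampled lineages carry a deme label and an allelic class at
the focal site (drawn binomially from the final deme frequencies, redrawn
if the pooled sample would be monomorphic). Going backward one rescaled
generation at a time, lineages coalesce within (deme, class) by parent
sampling from the class's copy number (so multiple mergers near the origin
are automatic), recombine at rate r per bp across the span linking their
ancestral material to the focal site (the unlinked side re-draws its class
from the class frequencies of that generation), and migrate with the
class-frequency-weighted backward probability. Neutral mutations fall on
ancestral material under the infinite-sites model. Once no derived
lineages remain and the history is single-deme, a standard continuous-time
ancestral-recombination-graph phase with piecewise-constant epoch sizes
finishes the genealogy. The focal site itself receives no mutation; its
column is the sampled class labels.

The neutral machinery was validated against closed forms: constant-N runs
reproduce Watterson's E[S] = 4 N mu L a_n within Monte-Carlo error and
centre Tajima's D and Fay-Wu's H at zero (`test-acceptance.R` re-runs this
at 2,000 replicates), and the fixation probability of a neutral single
copy matches 1/(2N).

## Summary statistics

The registry (22 entries by default; `default_registry()`) holds pi,
Watterson's theta, Tajima's D and Fay-Wu's H for both populations in a
4 kb symmetric and an 8 kb asymmetric (6 kb upstream / 2 kb downstream)
window around the focal site; the Reynolds (1983) F_ST at the focal site
(gene-copy ANOVA form, appropriate for phased haplotypes); Weir-Cockerham
(1984) F_ST — genotype-based, observed heterozygosity from pairing
consecutive haplotypes — over the 4 kb window and the whole region as
ratios of summed variance components; the raw XP-EHH at the focal site;
and the derived-allele frequency in each population. The source
publications' statistic count does not match any natural decomposition of
that list; the registry is configurable for alternative readings.

Two conventions deserve note. XP-EHH uses the *pooled* site definition
(EHH over all chromosomes of a population, identity including the core
allele, integrated against genetic distance with truncation at EHH < 0.05
and flat extension to the region edge when never truncated — flagged):
this is the statistic's standard operational form and is defined for every
sample, whereas a derived-allele-only core is undefined whenever a
population's sample carries fewer than two derived copies — which happens
in most conditioned neutral simulations. Allele-specific cores remain
available (`ihh()`, and `ihs_raw()` requires them). Second, the 5 %
frequency filters belong to the genome-scan surface (`ihs_raw()`,
`xpehh_raw()` defaults) and are not applied inside the ABC feature space.

Statistics that are mathematically undefined on an input (Tajima's D with
no segregating site; EHH with fewer than two carriers; F_ST at a site
monomorphic in both populations) signal a classed condition; the summary
vector records them as `NA` sentinels and flags the row. In the ABC layer
a flagged simulation row is dropped (and counted); a flagged *observed*
statistic removes that statistic from the run, with the pipeline refitted
on the remaining columns. Distances over partially-defined vectors are
never computed. Under the default settings sentinel rows are < 1 % of
conditioned simulations.

## The ABC layer

Statistics are z-scored across simulations (constant columns dropped), and
reduced to 7 latent components by partial least squares — discriminant
mode (dummy-coded model labels) for model choice, regression mode
(parameter responses) for estimation, mirroring the two-stage usage of the
source analysis. Rejection retains the `retain_fraction` (default 1 %)
closest simulations by Euclidean distance in component space, ties
included. Model posteriors are retained shares with balanced per-model
training sets (downsampled to the smallest model's count, so unequal
simulation budgets do not masquerade as evidence); Bayes factors are
posterior ratios under equal priors, with floor bounds (1/n_retained)
reported when a model is absent from the retained set. We use pure
rejection rather than a post-rejection regression adjustment of model
probabilities: it is assumption-light and reproducible; the optional
local-linear (Beaumont) adjustment with Epanechnikov weights is available
for parameter posteriors. Posterior modes come from a Gaussian kernel
density with Silverman's bandwidth; credible intervals are 2.5/97.5 %
quantiles, clamped to the prior support.

`cross_validate_power()` measures the probability of recovering the true
model: a held-out set of pseudo-observed simulations per model is assigned
by argmax posterior against the remaining training set (the PLS is fitted
once per hold-out split — per-row refits would change nothing at these
training sizes). At the design scale (20,000 training simulations per
model, 200 pseudo-observed per model, `power_experiment()`) the
correct-assignment rates are the quantities compared against the published
values: high for SDN, lower for SSV, near-perfect for NTR, with SSV
mistaken for SDN more often than the reverse — small-`f0` standing sweeps
are intrinsically indistinguishable from de novo sweeps.

## What the generator does and does not emulate

The synthetic data reproduce the study conditions: two demes with the
stated history, a conditioned focal trajectory, linked neutral variation
over 12 kb with the focal site at 8 kb, 100 sampled haplotypes per deme,
and the statistic registry above. Passing tests therefore show that the
*method* behaves as designed under its own model. They do not show
robustness to what real data add: phasing and ancestral-polarization
error, variable recombination along the region, background selection,
sequencing artefacts, or demographic misspecification. The
rescaling (`lambda = 10`) is exact for neutral expectations and very close
for selected ones, but extreme parameter corners (rescaled s near 1) are
represented slightly more coarsely than an unrescaled forward simulation
would.

## Numerical choices and degenerate inputs

* EHH truncation 0.05 and trapezoid integration over genetic distance;
  both configurable. Edge-truncated integrals are kept and flagged —
  simulated and observed regions share a length, so the truncation bias
  cancels in comparisons.
* Empirical p-values with zero exceedances report the floor 1/N as a
  bound, flagged, never 0. Ties count as exceedances.
* iHS standardization bins derived frequency at 1 %; bins with fewer than
  two scores merge into the nearest adequate bin, flagged.
* Genetic maps interpolate piecewise-linearly on the cumulative cM column,
  with edge-rate extrapolation; a single-row map means a constant rate.
* Conditioning rejection has an attempt cap (default 1e6 parameter draws)
  and errors with the implied acceptance rate; acceptance rates are
  first-class outputs since they define the effective prior.
* Missing genotypes are refused, not imputed; unphased genotypes are hard
  errors naming sample and position. Internal coordinates are 0-based
  half-open; the VCF reader is the only 1-based surface.
* `child_seed()` derives per-stage seeds from the top-level seed by a
  fixed multiply-and-add map folded into the 31-bit range, so stages can
  be re-run independently and everything is reproducible byte-for-byte
  from (config, seed).

## Problem sizes used by the shipped validation

The test suite and the acceptance script run the power experiment at
20,000 training + 200 pseudo-observed simulations per model per
demographic configuration, the neutral calibration at 2,000 replicates of
a 4 kb constant-N region, and the parameter-recovery check (SDN,
`s_NA` = 2.5 %, `t_mut` = 55 kya, `s_A` = 0.6 %) at 10,000 training
simulations and 100 pseudo-observed datasets. These sizes were chosen so
the stochastic checks have Monte-Carlo errors a few times smaller than
the tolerances they are compared at.

## Known limitations

* Model-choice probabilities come from rejection counts, not from the
  regression-adjusted marginal-density estimators some ABC toolboxes use;
  absolute posterior probabilities can differ between the two even when
  rankings agree.
* The per-deme onset-state conventions (see above) are operational
  choices; a mutation-and-migration origin model for post-split SDN is
  biologically coherent but incompatible with the geographic pattern this
  analysis is designed around, and is therefore only flagged, not used.
* Parameter posteriors are prior-dominated where the statistics carry
  little information (notably `t_mut`); credible intervals are honest but
  wide.
* The two demes are the model's universe: admixture with, or selection
  in, unmodelled populations is outside scope.

## A worked example

```{r example, eval = FALSE}
library(sweepabc)
set.seed(1)
dem <- gravel_demography("EAS")
spc <- simulator_spec()

# training simulations (scaled down for the vignette)
sims <- do.call(rbind, lapply(c("NTR", "SDN", "SSV"), function(m)
  simulate_batch(m, 2000, dem, spc)))

# a pseudo-observed dataset from a known SDN scenario
sc <- selection_scenario("SDN", s_A = 0.006, s_NA = 0.025, t_mut = 55000)
tr <- simulate_trajectory(sc, dem)
obs <- compute_summary_vector(simulate_haplotypes(tr, dem, spc),
                              map = constant_map(1.76, 12000))

fit <- abc_sweep(obs, sims)
summary(fit)
```
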