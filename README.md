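# sweepabc

Approximate Bayesian computation (ABC) inference of the selection regime
acting on a single focal variant shared by an African and a non-African
population. Motivated by loss-of-function variants that rose to high
frequency outside Africa — the canonical case being a pseudogenizing
variant whose frequency today is ~0.3 in Africa and ~0.95 in East Asia —
the package asks which of three regimes produced the data, and with what
parameters:

* **NTR** — the derived allele appeared at `t_mut` and drifted neutrally;
* **SDN** — selection on a de novo mutation: beneficial from appearance,
  with coefficient `s_A` in the African/ancestral deme, changing to `s_NA`
  in the non-African deme after the out-of-Africa split;
* **SSV** — selection on standing variation: a neutral allele at frequency
  `f0` became beneficial (coefficient `s_NA`) in the non-African deme at
  `t_mut`.

Inference follows the standard rejection-ABC recipe. Simulated datasets are
generated under a two-deme out-of-Africa demography (Gravel et al. 2011
parameter values; split 51 kya at 25 yr/generation; constant recombination
1.76 cM/Mb over a 12 kb region) by a rescaled Wright–Fisher trajectory
simulator (deterministic selection with genotype fitnesses 1 : 1+hs : 1+s,
migration, binomial drift, conditioned on present-day segregation in both
demes) coupled to a trajectory-conditioned structured coalescent for the
linked neutral variation. Each dataset — simulated or observed — is reduced
to a summary vector: π, Watterson's θ, Tajima's D and Fay & Wu's H in 4 kb
and 8 kb windows for both populations, Reynolds F_ST at the focal site,
Weir–Cockerham F_ST for the 4 kb window and the whole region, raw XP-EHH at
the site, and the derived-allele frequency in each population. PLS-DA
compresses the statistics to 7 components, the closest 1 % of simulations
to the observation are retained, and model posteriors P(M | data), Bayes
factors, and per-parameter posterior modes with 95 % credible intervals are
read off the retained set.

The package also provides the surrounding tooling: phased-VCF reading with
ancestral-allele polarization, ms-format round-tripping, HapMap-style
genetic maps, EHH/iHH/iHS scans with 1 %-bin standardization, empirical
p-values against score distributions, demographic-null testing of Fay &
Wu's H with neutral coalescent simulations, cross-validated power
assessment of the model choice, and dominance-model comparison
(h ∈ {0, 0.38, 0.5}).

## A worked example

Simulate training sets under all three regimes, a pseudo-observed dataset
from a known SDN scenario, and fit:

```r
library(sweepabc)
set.seed(1)
dem <- gravel_demography("EAS")
spc <- simulator_spec()

sims <- do.call(rbind, lapply(c("NTR", "SDN", "SSV"), function(m)
  simulate_batch(m, 2000, dem, spc)))

sc  <- selection_scenario("SDN", s_A = 0.006, s_NA = 0.025, t_mut = 55000)
tr  <- simulate_trajectory(sc, dem)
obs <- compute_summary_vector(simulate_haplotypes(tr, dem, spc),
                              map = constant_map(1.76, 12000))
fit <- abc_sweep(obs, sims)
summary(fit)
```

```
P(SDN) = 100.0%; Bayes factor vs next model: > 60
  t_mut: 43.44 (40.98-65.59) kya
  s_A: 0.93 (0.59-1.25) %
  s_NA: 1.48 (0.75-4.71) %
```

Every retained simulation comes from the true model (with 60 retained the
Bayes factor is reported as a floor bound), and the 95 % credible
intervals cover the generating parameters (s_A = 0.6 %, s_NA = 2.5 %,
t_mut = 55 kya); as always with rejection ABC the intervals are wide — the
model choice is more reliable than the point estimates.

`cross_validate_power()` quantifies that reliability: held-out
pseudo-observed simulations are pushed through the full pipeline and the
fraction assigned to their true model is reported per model with binomial
standard errors. At the design scale (20,000 training simulations per
model) the de novo sweep is recovered far more reliably than the
standing-variation sweep, whose small-`f0` corner is intrinsically
confusable with SDN.

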