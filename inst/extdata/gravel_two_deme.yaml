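# Default two-deme out-of-Africa run configuration. Demographic parameter
# values follow the Gravel et al. (2011) low-coverage + exome fit with a
# 25-year generation time: ancestral N = 7,310 until the African expansion
# (148 kya) to N = 14,474; out-of-Africa split 51 kya at bottleneck
# N = 1,861; from 23 kya the non-African deme grows exponentially from
# 1,032 at 0.38%/generation (EUR) or 554 at 0.48%/generation (EAS);
# symmetric migration 15e-5/generation (Africa-bottleneck), then 2.5e-5
# (Africa-Europe) or 0.78e-5 (Africa-East Asia); mutation rate 2.36e-8 per
# bp per generation. These are encoded in gravel_demography(); this file
# only selects between its configurations.
seed: 1
models: [NTR, SDN, SSV]
dominance: 0.5
demography:
  kind: gravel
  nonafrican: EAS        # or EUR
  lambda: 10             # rescaling factor for forward simulation
  generation_years: 25
simulator:
  region_length: 12000   # bp; focal site leaves 6 kb upstream / 2 kb down
  focal_pos: 8000
  mu: 2.36e-8            # per bp per generation
  rec_cM_Mb: 1.76        # constant recombination rate across the region
  n_sample: [100, 100]   # haplotypes per deme
abc:
  n_sims: 10000          # conditioned simulations per model
  retain_fraction: 0.01
  n_components: 7        # PLS components retained
  n_pseudo: 200          # held-out pseudo-observed per model (power)
out_dir: results
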