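# Reduced-scale profile for a single workstation: the full genome and SNP
# chip, but a small pipeline (100 founders, 600 DH per cycle, 60-entry PYT,
# 10-entry AYT), a short burn-in and a short MCMC chain. Capacities keep the
# full-scale stage ratios (PYT ~ 1/10 of the DH cohort, AYT ~ 1/6 of the
# PYT).
program:
  genome: {n_chrom: 7, chrom_length: 1.0, sites_per_chrom: 600}
  founders: {n_founders: 100, n_ancestral_haplotypes: 20, n_drift_generations: 50}
  partition: {snp_per_chrom: 500}
  capacity: {nursery_cap: ~, pyt: 60, ayt: 10}
  mcmc: {iterations: 2000, burn_in: 500, thin: 5, prior_df: 5, R2: 0.5}
  burn_in: {years: 3, n_parents: 10, n_crosses: 15, progeny_per_cross: 40}
  years_post_burnin: 8
grid:
  n_parents: [10]
  crosses_progeny: [[15, 40]]
  methods: [PMV, RandPheno]
n_replicates: 10
master_seed: 1
years: 8
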