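# Full-scale experiment profile: 60 treatments x 50 replicates, 40-year
# programs (10 burn-in + 30 logged). Intended for cluster-scale runs.
program:
  genome: {n_chrom: 7, chrom_length: 1.0, sites_per_chrom: 600}
  founders: {n_founders: 200, n_ancestral_haplotypes: 20, n_drift_generations: 50}
  partition: {snp_per_chrom: 500}
  capacity: {nursery_cap: 4000, pyt: 400, ayt: 40}
  mcmc: {iterations: 40000, burn_in: 10000, thin: 10, prior_df: 5, R2: 0.5}
  burn_in: {years: 10, n_parents: 40, n_crosses: 100, progeny_per_cross: 150}
  years_post_burnin: 30
grid:
  n_parents: [30, 40, 50]
  crosses_progeny: [[50, 300], [100, 150], [150, 100], [200, 75]]
  methods: [UC, PMV, OHV, MeanGEBV, RandPheno]
n_replicates: 50
master_seed: 1
years: 30
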