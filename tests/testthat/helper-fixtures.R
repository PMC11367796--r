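# Small in-code fixtures shared across tests.

tiny_genome <- function(n_chrom = 2, len = 1, sites = 50) {
  build_genome(n_chrom, len, sites)
}

# quick founder population on a small genome
tiny_founders <- function(n = 20, genome = tiny_genome(), drift = 20) {
  generate_founders(genome, n, n_ancestral_haplotypes = 10,
                    n_drift_generations = drift)
}

# a pool of inbred (DH) parents derived from founders
tiny_inbred_parents <- function(n = 10, genome = tiny_genome(), drift = 20) {
  f <- tiny_founders(max(10, ceiling(n / 3)), genome, drift)
  pools <- lapply(seq_len(ceiling(n / 4)), function(k) {
    pa <- sample(n_ind(f), 2)
    make_dh(make_cross(f, pa[1], pa[2], 1), 1, 4,
            ids = sprintf("P%d_%d", k, 1:4))
  })
  pop <- do.call(merge_populations, c(pools, list(generation = "parent")))
  subset_population(pop, seq_len(n), generation = "parent")
}

# hand-built two-individual inbred population from explicit haplotypes
manual_inbred_pair <- function(genome, hap_a, hap_b) {
  haplo <- rbind(hap_a, hap_a, hap_b, hap_b)
  storage.mode(haplo) <- "integer"
  crossel:::new_population(genome, haplo, c("A", "B"), "parent")
}

two_increase_specs <- function() {
  list(trait_spec("t1", 0, 1, "increase"), trait_spec("t2", 0, 1, "increase"))
}

# small config for program-level tests
tiny_program_config <- function(...) {
  program_config(
    genome = list(n_chrom = 2, chrom_length = 1, sites_per_chrom = 60),
    founders = list(n_founders = 30, n_ancestral_haplotypes = 10,
                    n_drift_generations = 20),
    partition = list(qtn_per_chrom = 10, snp_per_chrom = 30),
    capacity = list(nursery_cap = NULL, pyt = 24, ayt = 4),
    mcmc = list(iterations = 400, burn_in = 100, thin = 5, prior_df = 5,
                R2 = 0.5),
    burn_in = list(years = 2, n_parents = 8, n_crosses = 10,
                   progeny_per_cross = 12),
    years_post_burnin = 2,
    ...)
}
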