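# Shared simulated fixtures, built once per test run.

# a small diverged genome pair used by orthology/pipeline tests
shared_sim_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome_pair(sim_config(
        n_genes = 50L, gene_len_codons = 120L, omega = 0.2, kappa = 2,
        t = 0.3, noncoding_fraction = 0.2, seed = 101L))
    }
    cache
  }
})

random_sense_codons <- function(n, seed, code = "11") {
  set.seed(seed)
  sample(oracle_sense_codons(code), n, replace = TRUE)
}

# gapless codon alignment fixture from two codon vectors
gapless_ca <- function(a, b) omegapair:::codon_alignment(a, b)
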