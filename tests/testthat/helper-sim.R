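# Shared simulated fixtures, built once per test run.

# A profile built from an all-intact version of a family, homologous to
# any family simulated with the same seed (the ancestral sequence is a
# deterministic function of the seed).
intact_profile_for_seed <- function(seed, n = 8, seq_length = 120,
                                    base_rate = 0.03) {
  cfg <- family_sim_config(
    n, seq_length = seq_length, base_rate = base_rate,
    triad_state_per_clade = c(invertebrate = "intact", P1 = "intact",
                              P2 = "intact"),
    seed = seed)
  sim <- simulate_family(cfg)
  build_profile(sim$sequences, sim$triad_positions)
}

# plant an insertion of up to max_ins residues at a random position
plant_insertions <- function(seqs, max_ins = 10, seed = 1) {
  set.seed(seed)
  vapply(seqs, function(s) {
    k <- sample(0:max_ins, 1)
    ins <- paste(sample(AA20, k, replace = TRUE), collapse = "")
    pos <- sample(seq_len(nchar(s) - 1), 1)
    paste0(substr(s, 1, pos), ins, substr(s, pos + 1, nchar(s)))
  }, character(1))
}
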