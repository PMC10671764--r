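# The clade-recovery dataset (3 ancestors x 8 descendants, 20 kb, seed 42)
# is expensive to score (576 concatenation transforms of ~40 kb), so it is
# built once per test run and shared by the tests that consume it.
recovery_env <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (is.null(recovery_env$data)) {
    sim <- simulate_phylogeny(evo_config(
      n_ancestors = 3, clade_size = 8, genome_length = 20000, seed = 42))
    D <- ncd_matrix(sim$sequences)
    recovery_env$data <- list(sim = sim, D = D)
  }
  recovery_env$data
}
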