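# Small shared fixtures, generated once per test run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_pops = 3, n_per_pop = 20, L = 500, Fst = 0.1,
                        seed = 42)
      cache <<- c(list(cfg = cfg), simulate_panel(cfg))
    }
    cache
  }
})

# tiny deterministic 3-sample, 4-site panel for parser edge cases
tiny_panel <- function() {
  sites <- tibble::tibble(site_id = paste0("s", 1:4), chrom = "1",
                          pos = c(100L, 200L, 300L, 400L),
                          ref_allele = c("A", "C", "G", "T"),
                          alt_allele = c("G", "T", "A", "C"))
  samples <- tibble::tibble(sample_id = c("r1", "r2", "r3"),
                            population = c("P1", "P1", "P2"),
                            region = "X")
  G <- matrix(c(0L, 1L, 2L, NA, 1L, 1L, 0L, 2L, 2L, 0L, 1L, 0L), 3, 4,
              byrow = TRUE)
  new_ref_panel(G, sites, samples)
}

# the desk-scale study conditions: 3 populations at Fst 0.1, N = 150
# references, L = 2000 unlinked sites
acc_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_pops = 3, n_per_pop = 50, L = 2000, Fst = 0.1,
                        seed = 2024, depth_mean = 5, error_rate = 0.01)
      sim <- simulate_panel(cfg)
      cache <<- c(list(cfg = cfg,
                       space = pca_reference(sim$panel, K = 4)), sim)
    }
    cache
  }
})
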