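test_that("a reference individual replayed as a study sample lands on itself", {
  sim <- small_sim()
  panel <- sim$panel
  space <- pca_reference(panel, K = 4)
  N <- nrow(panel$genotypes)
  # full joint rank: the joint space then contains the reference PCs exactly
  cfg <- placement_config(K = 4, K_prime = N, min_loci = 50)
  normY <- sqrt(sum(space$Y^2))
  for (i in c(1, 25, 60)) {
    study <- new_study_genotypes(panel$genotypes[i, , drop = FALSE],
                                 "copy", seq_len(ncol(panel$genotypes)))
    pl <- place_genotype_sample(panel, space, study, 1, cfg)
    coords <- as.numeric(pl[, paste0("PC", 1:4)])
    expect_lt(sqrt(sum((coords - space$Y[i, ])^2)), 1e-6 * normY)
    expect_gte(pl$t, 0.999)
  }
})

test_that("genotype placement is deterministic and duplicate-stable", {
  sim <- small_sim()
  space <- pca_reference(sim$panel, K = 4)
  st <- simulate_study(sim$freqs, c("POP2", "POP2"), sim$cfg)
  study <- new_study_genotypes(rbind(st$study$genotypes[1, ],
                                     st$study$genotypes[1, ]),
                               c("a", "b"), st$study$site_index)
  cfg <- placement_config(K = 4, K_prime = 10, min_loci = 50)
  p1 <- place_genotype_sample(sim$panel, space, study, 1, cfg)
  p2 <- place_genotype_sample(sim$panel, space, study, 2, cfg)
  expect_equal(p1[, -1], p2[, -1])
  p1b <- place_genotype_sample(sim$panel, space, study, 1, cfg)
  expect_identical(p1, p1b)
})

test_that("placements recover the true population of in-panel individuals", {
  sim <- small_sim()
  space <- pca_reference(sim$panel, K = 4)
  st <- simulate_study(sim$freqs, rep("POP2", 20), sim$cfg)
  cfg <- placement_config(K = 4, K_prime = 10, min_loci = 50, knn_k = 10)
  pl <- place_all(sim$panel, space, st$study, cfg)
  # nearest reference neighbour in the true population for >= 95%
  hits <- vapply(seq_len(nrow(pl)), function(r) {
    nb <- nearest_neighbors(space, as.numeric(pl[r, paste0("PC", 1:4)]), 1)
    sim$panel$samples$population[nb$indices] == "POP2"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_true(all(pl$knn_top_population == "POP2"))
})

test_that("simulated reference reads follow the binomial read model", {
  G <- matrix(c(0L, 2L, 1L), 3, 1)
  set.seed(1)
  d0 <- simulate_reference_reads(G, 10L, 0)
  expect_equal(d0[1, 1], 0)  # g=0, eps=0 -> all reads ref
  expect_equal(d0[2, 1], 2)  # g=2, eps=0 -> all reads alt
  # E[dosage] at g=1, eps=0.01, c=10 is 1.0; Monte Carlo within 3 SE
  set.seed(2)
  n <- 1e4
  draws <- simulate_reference_reads(matrix(1L, 1, n), rep(10L, n),
                                    rep(0.01, n))
  se <- stats::sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - 1), 3 * se)
  # missing genotype and zero depth give missing dosage
  dn <- simulate_reference_reads(matrix(NA_integer_, 1, 1), 5L, 0)
  expect_true(is.na(dn[1, 1]))
  dz <- simulate_reference_reads(matrix(1L, 1, 1), 0L, 0)
  expect_true(is.na(dz[1, 1]))
})

test_that("sequence placement converges to genotype placement at high depth", {
  sim <- small_sim()
  space <- pca_reference(sim$panel, K = 4)
  st <- simulate_study(sim$freqs, c("POP1", "POP2", "POP3"), sim$cfg)
  cfgg <- placement_config(K = 4, K_prime = 10, min_loci = 50)
  cfgs <- placement_config(K = 4, K_prime = 10, min_loci = 50,
                           mode = "sequence", seed = 99)
  pil <- simulate_reads(st$study, sim$cfg, depth_mean = 200,
                        error_rate = 0, seed = 77)
  plg <- place_all(sim$panel, space, st$study, cfgg, diagnostics = FALSE)
  pls <- place_all(sim$panel, space, pil, cfgs, diagnostics = FALSE)
  for (j in 1:4) {
    rng <- diff(range(space$Y[, j]))
    expect_lt(max(abs(plg[[paste0("PC", j)]] - pls[[paste0("PC", j)]])),
              0.05 * rng)
  }
})

test_that("sequence placement is reproducible from the seed", {
  sim <- small_sim()
  space <- pca_reference(sim$panel, K = 4)
  st <- simulate_study(sim$freqs, c("POP1",  "POP3"), sim$cfg)
  pil <- simulate_reads(st$study, sim$cfg, seed = 5)
  cfg <- placement_config(K = 4, K_prime = 10, min_loci = 50,
                          mode = "sequence", reps = 3, seed = 7)
  p1 <- place_all(sim$panel, space, pil, cfg)
  p2 <- place_all(sim$panel, space, pil, cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$t_sd >= 0))
  expect_equal(p1$reps, c(3L, 3L))
})

test_that("place_all is worker-invariant and tolerates per-sample failure", {
  sim <- small_sim()
  space <- pca_reference(sim$panel, K = 4)
  st <- simulate_study(sim$freqs, rep(c("POP1", "POP2"), 5), sim$cfg)
  # knock one sample down below min_loci
  G <- st$study$genotypes
  G[4, 101:500] <- NA
  study <- new_study_genotypes(G, st$study$sample_ids, st$study$site_index)
  cfg <- placement_config(K = 4, K_prime = 10, min_loci = 200)
  p1 <- place_all(sim$panel, space, study, cfg, workers = 1)
  p4 <- place_all(sim$panel, space, study, cfg, workers = 4)
  expect_identical(p1, p4)
  expect_equal(nrow(p1), 9)
  fails <- attr(p1, "failures")
  expect_equal(fails$sample_id, study$sample_ids[4])
  expect_match(fails$error, "usable shared sites")
})

test_that("per-sample seeds are stable hashes of the sample id", {
  sim <- small_sim()
  space <- pca_reference(sim$panel, K = 4)
  st <- simulate_study(sim$freqs, c("POP1", "POP2", "POP3"), sim$cfg)
  pil <- simulate_reads(st$study, sim$cfg, seed = 5)
  cfg <- placement_config(K = 4, K_prime = 10, min_loci = 50,
                          mode = "sequence", seed = 11)
  batch <- place_all(sim$panel, space, pil, cfg, diagnostics = FALSE)
  # placing sample 2 alone reproduces its row from the batch
  solo <- place_sequence_sample(sim$panel, space, pil, 2, cfg)
  expect_equal(solo, batch[2, ], ignore_attr = TRUE)
})
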