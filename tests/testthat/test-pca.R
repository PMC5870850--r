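test_that("standardization centers, scales and imputes as documented", {
  s <- standardize_genotypes(matrix(c(0, 1, 2), 3, 1))
  expect_equal(as.vector(s$X), c(-1, 0, 1))
  expect_equal(s$means, 1)

  # degenerate constant column: zeros, scale forced to 1
  s2 <- standardize_genotypes(matrix(2, 3, 1), mode = "center_scale")
  expect_equal(as.vector(s2$X), c(0, 0, 0))
  expect_equal(s2$scales, 1)

  # missing cells imputed at the column mean -> exactly 0 after centering
  G <- matrix(c(0, 2, NA, 1, NA, 1), 3, 2)
  s3 <- standardize_genotypes(G)
  expect_equal(s3$X[3, 1], 0)
  expect_equal(s3$X[2, 2], 0)

  expect_error(standardize_genotypes(matrix(NA_real_, 3, 1)),
               "entirely missing")
})

test_that("re-standardizing with returned statistics is idempotent", {
  set.seed(7)
  G <- matrix(sample(0:2, 200, replace = TRUE), 10, 20)
  for (mode in c("center_only", "center_scale")) {
    s <- standardize_genotypes(G, mode)
    s2 <- standardize_genotypes(s$X + outer(rep(0, 10), s$means * 0),
                                mode, means = rep(0, 20),
                                scales = rep(1, 20))
    expect_equal(s2$X, s$X)
    # applying the returned stats to the raw matrix reproduces X
    s3 <- standardize_genotypes(G, mode, means = s$means, scales = s$scales)
    expect_equal(s3$X, s$X)
  }
})

test_that("reference PCA matches a dense eigendecomposition oracle", {
  set.seed(11)
  for (rep in 1:3) {
    G <- matrix(sample(0:2, 20 * 50, replace = TRUE), 20, 50)
    sites <- tibble::tibble(site_id = paste0("s", 1:50), chrom = "1",
                            pos = 1:50 * 10L, ref_allele = "A",
                            alt_allele = "G")
    samples <- tibble::tibble(sample_id = paste0("i", 1:20),
                              population = "P")
    panel <- new_ref_panel(G, sites, samples)
    space <- pca_reference(panel, K = 5)
    # oracle: eigendecomposition of the sample covariance of centered data
    Xc <- scale(G, center = TRUE, scale = FALSE)
    ev <- eigen(Xc %*% t(Xc), symmetric = TRUE)
    oracle_scores <- ev$vectors[, 1:5] %*% diag(sqrt(ev$values[1:5]))
    for (j in 1:5)
      expect_equal(abs(space$Y[, j]), abs(oracle_scores[, j]),
                   tolerance = 1e-8)
    expect_equal(space$eigenvalues, ev$values[1:5] / 19, tolerance = 1e-8)
  }
})

test_that("PCA conserves variance and K = N-1 reproduces the full scores", {
  sim <- small_sim()
  panel <- sim$panel
  N <- nrow(panel$genotypes)
  space <- pca_reference(panel, K = N - 1)
  std <- standardize_genotypes(panel$genotypes)
  total <- sum(std$X^2) / (N - 1)
  expect_equal(sum(space$eigenvalues), total, tolerance = 1e-8)
  expect_equal(space$total_var, total, tolerance = 1e-8)
  # score Gram matrix is diagonal (orthogonal columns)
  g <- crossprod(space$Y)
  offdiag <- g - diag(diag(g))
  expect_lt(max(abs(offdiag)), 1e-6 * max(diag(g)))
})

test_that("PCA is equivariant under sample permutation", {
  sim <- small_sim()
  panel <- sim$panel
  set.seed(3)
  perm <- sample(nrow(panel$genotypes))
  panel2 <- new_ref_panel(panel$genotypes[perm, ], panel$sites,
                          panel$samples[perm, ])
  s1 <- pca_reference(panel, K = 4)
  s2 <- pca_reference(panel2, K = 4)
  expect_equal(s2$Y, s1$Y[perm, ], tolerance = 1e-8)
})

test_that("PC1 separates two strongly differentiated populations", {
  cfg <- sim_config(n_pops = 2, n_per_pop = 25, L = 400, Fst = 0.3,
                    seed = 8)
  sim <- simulate_panel(cfg)
  space <- pca_reference(sim$panel, K = 2)
  pop <- sim$panel$samples$population
  pc1 <- space$Y[, 1]
  gap <- abs(mean(pc1[pop == "POP1"]) - mean(pc1[pop == "POP2"]))
  spread <- max(stats::sd(pc1[pop == "POP1"]), stats::sd(pc1[pop == "POP2"]))
  expect_gt(gap, spread)  # silhouette-positive separation
})

test_that("joint PCA gives duplicate rows identical scores", {
  sim <- small_sim()
  G <- sim$panel$genotypes
  jp <- pca_joint(G, G[7, ], K_prime = 10)
  expect_equal(jp$x_study, jp$X_ref[7, ], tolerance = 1e-10)
})

test_that("joint PCA matches a brute-force eigendecomposition on a toy case", {
  set.seed(5)
  panel_rows <- matrix(sample(0:2, 3 * 6, replace = TRUE), 3, 6)
  study <- sample(0:2, 6, replace = TRUE)
  jp <- pca_joint(panel_rows, study, K_prime = 2)
  A <- rbind(panel_rows, study)
  Xc <- scale(A, center = TRUE, scale = FALSE)
  ev <- eigen(Xc %*% t(Xc), symmetric = TRUE)
  oracle <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  got <- rbind(jp$X_ref, jp$x_study)
  for (j in 1:2)
    expect_equal(abs(got[, j]), abs(oracle[, j]), tolerance = 1e-8)
})

test_that("joint PCA coordinates are invariant to site order", {
  sim <- small_sim()
  G <- sim$panel$genotypes[, 1:100]
  study <- sim$panel$genotypes[3, 1:100]
  set.seed(9)
  perm <- sample(100)
  jp1 <- pca_joint(G, study, K_prime = 5)
  jp2 <- pca_joint(G[, perm], study[perm], K_prime = 5)
  # same scores up to per-column sign
  for (j in 1:5)
    expect_equal(abs(jp2$X_ref[, j]), abs(jp1$X_ref[, j]), tolerance = 1e-8)
})

test_that("joint PCA validates inputs and caps K'", {
  sim <- small_sim()
  G <- sim$panel$genotypes[1:10, 1:50]
  expect_error(pca_joint(G, rep(NA_real_, 50), K_prime = 5),
               "entirely missing")
  expect_warning(jp <- pca_joint(G, G[1, ], K_prime = 30), "lowered")
  expect_equal(jp$K_prime, 10L)
})

test_that("ancestry space persists and reloads", {
  sim <- small_sim()
  space <- pca_reference(sim$panel, K = 4)
  prefix <- file.path(withr::local_tempdir(), "sp")
  write_ancestry_space(space, prefix)
  back <- read_ancestry_space(prefix, sim$panel)
  expect_equal(back$Y, unname(space$Y), tolerance = 1e-12)
  expect_equal(back$site_means, space$site_means, tolerance = 1e-12)
  expect_equal(back$eigenvalues, space$eigenvalues, tolerance = 1e-12)
  expect_identical(back$scaling_mode, space$scaling_mode)
})
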