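#' Placement configuration
#'
#' Parameters of the per-sample placement pipeline. Defaults follow the
#' worldwide-analysis operating point: a K = 4 ancestry space fitted through
#' a K' = 20 joint PCA.
#'
#' @param K Ancestry space dimension.
#' @param K_prime Joint PCA dimension, K' >= K. Capped at min(N, L') with a
#'   warning when the data cannot support it.
#' @param mode `"genotype"` or `"sequence"`.
#' @param reps Repetitions of the read-resampling loop in sequence mode
#'   (coordinates and t are averaged); ignored in genotype mode.
#' @param seed Master seed; per-sample seeds are derived deterministically
#'   from it and the sample id.
#' @param min_loci Minimum shared-site count for a placement.
#' @param scaling_mode Standardization, see [standardize_genotypes()].
#' @param knn_k Neighbours used for ancestry composition and the Z score.
#' @param z_threshold |Z| above which a sample is flagged.
#' @return A list of class `placement_config`.
#' @export
placement_config <- function(K = 4L, K_prime = 20L,
                             mode = c("genotype", "sequence"),
                             reps = 1L, seed = 1L, min_loci = 100L,
                             scaling_mode = c("center_only", "center_scale"),
                             knn_k = 20L, z_threshold = 3) {
  mode <- match.arg(mode)
  scaling_mode <- match.arg(scaling_mode)
  if (K_prime < K) stop("K' must be at least K")
  if (reps < 1) stop("reps must be >= 1")
  structure(list(K = as.integer(K), K_prime = as.integer(K_prime),
                 mode = mode, reps = as.integer(reps),
                 seed = as.integer(seed), min_loci = as.integer(min_loci),
                 scaling_mode = scaling_mode, knn_k = as.integer(knn_k),
                 z_threshold = z_threshold),
            class = "placement_config")
}

# Stable 31-bit polynomial hash of a string, for per-sample seed streams.
stable_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

sample_seed <- function(master, sample_id) {
  as.integer((master + stable_hash(sample_id)) %% 2147483647)
}

# Shared core: joint PCA of reference dosages + one study dosage row over
# the study's usable sites, then projection Procrustes onto space$Y.
place_core <- function(ref_dosages, study_dosage, Y, cfg) {
  jp <- pca_joint(ref_dosages, study_dosage, cfg$K_prime, cfg$scaling_mode)
  fit <- fit_projection_procrustes(jp$X_ref, Y)
  list(coords = apply_transform(fit, jp$x_study), t = fit$t)
}

placement_row <- function(sample_id, coords, t, t_sd, L_used, reps, K) {
  row <- tibble::tibble(sample_id = sample_id, L_used = as.integer(L_used),
                        reps = as.integer(reps), t = t, t_sd = t_sd,
                        Z = NA_real_,
                        knn_top_population = NA_character_,
                        knn_top_fraction = NA_real_)
  co <- tibble::as_tibble(as.data.frame(matrix(coords, nrow = 1)))
  names(co) <- paste0("PC", seq_len(K))
  dplyr::bind_cols(row, co)
}

#' Place one genotyped study individual into the ancestry space
#'
#' Restricts the panel to the study individual's non-missing sites, runs the
#' joint PCA of the N + 1 individuals, fits the projection Procrustes
#' transform from the joint space onto the reference coordinates, and applies
#' it to the study individual. Deterministic: genotype mode involves no
#' randomness.
#'
#' @param panel A [ref_panel].
#' @param space The [ancestry_space][pca_reference()] built from `panel`.
#' @param study A [study_genotypes].
#' @param sample_index Row of `study` to place.
#' @param cfg A [placement_config()].
#' @return A one-row placement tibble (sample_id, L_used, reps, t, t_sd,
#'   PC1..PCK; Z and kNN fields are filled by [place_all()]).
#' @export
place_genotype_sample <- function(panel, space, study, sample_index,
                                  cfg = placement_config()) {
  g <- study$genotypes[sample_index, ]
  usable <- which(!is.na(g))
  if (length(usable) < cfg$min_loci)
    stop(sprintf("sample %s: %d usable shared sites, need %d",
                 study$sample_ids[sample_index], length(usable), cfg$min_loci))
  sites <- study$site_index[usable]
  res <- place_core(panel$genotypes[, sites, drop = FALSE], g[usable],
                    space$Y, cfg)
  placement_row(study$sample_ids[sample_index], res$coords, res$t, 0,
                length(usable), 1L, space$K)
}

#' Simulate reads over the reference panel at a study sample's coverage
#'
#' For every reference individual and usable site, draws
#' `depth_profile[site]` reads whose alt-allele count is Binomial with
#' success probability (g/2)(1-eps) + (1-g/2) eps for reference genotype g
#' and base error rate eps, and returns the read-based dosage
#' 2 * alt_count / depth (missing where depth is 0 or the genotype is
#' missing). This puts the reference panel on the same noisy scale as the
#' study sample's sequence data, which is what makes the joint PCA
#' comparable. Uses the current RNG stream.
#'
#' @param panel_rows N x L' reference genotype submatrix.
#' @param depth_profile Length-L' read depths (the study sample's own).
#' @param error_rate Length-L' base error rates.
#' @return N x L' real dosage matrix with NA where no reads.
#' @export
simulate_reference_reads <- function(panel_rows, depth_profile, error_rate) {
  N <- nrow(panel_rows); Lp <- ncol(panel_rows)
  stopifnot(length(depth_profile) == Lp, length(error_rate) == Lp)
  g <- panel_rows
  miss <- is.na(g)
  g[miss] <- 0L
  p_alt <- sweep(g / 2, 2, 1 - error_rate, "*") +
    sweep(1 - g / 2, 2, error_rate, "*")
  depth <- matrix(rep(as.integer(depth_profile), each = N), N, Lp)
  alt <- matrix(stats::rbinom(N * Lp, as.vector(depth), as.vector(p_alt)),
                N, Lp)
  dos <- 2 * alt / depth
  dos[depth == 0 | miss] <- NA_real_
  dos
}

#' Place one sequenced study individual into the ancestry space
#'
#' The study dosage at each covered site is taken directly from the read
#' fractions (alt dosage = 2 - 2 * ref_count / depth; no genotype calling).
#' For each repetition, reads are simulated over the reference panel at the
#' sample's own depth profile and error rates, and the genotype-mode joint
#' PCA + Procrustes pipeline is run on the noisy dosages; coordinates and t
#' are averaged over repetitions. Fully reproducible from the configured
#' seed.
#'
#' @param panel A [ref_panel].
#' @param space The matching [ancestry_space][pca_reference()].
#' @param pileup A [pileup_matrix].
#' @param sample_index Row of the pileup to place.
#' @param cfg A [placement_config()]; `reps` and `seed` matter here.
#' @return A one-row placement tibble as in [place_genotype_sample()].
#' @export
place_sequence_sample <- function(panel, space, pileup, sample_index,
                                  cfg = placement_config(mode = "sequence")) {
  depth <- pileup$depth[sample_index, ]
  covered <- which(depth > 0)
  if (length(covered) < cfg$min_loci)
    stop(sprintf("sample %s: %d covered shared sites, need %d",
                 pileup$sample_ids[sample_index], length(covered),
                 cfg$min_loci))
  sites <- pileup$site_index[covered]
  d <- depth[covered]
  study_dosage <- 2 - 2 * pileup$ref_count[sample_index, covered] / d
  ref_geno <- panel$genotypes[, sites, drop = FALSE]
  err <- pileup$error_rate[covered]
  set.seed(sample_seed(cfg$seed, pileup$sample_ids[sample_index]))
  coords <- matrix(NA_real_, cfg$reps, space$K)
  ts <- numeric(cfg$reps)
  for (r in seq_len(cfg$reps)) {
    ref_dos <- simulate_reference_reads(ref_geno, d, err)
    res <- place_core(ref_dos, study_dosage, space$Y, cfg)
    coords[r, ] <- res$coords
    ts[r] <- res$t
  }
  placement_row(pileup$sample_ids[sample_index], colMeans(coords), mean(ts),
                if (cfg$reps > 1) stats::sd(ts) else 0,
                length(covered), cfg$reps, space$K)
}

#' Place every study sample and attach diagnostics
#'
#' Runs the per-sample pipeline over a [study_genotypes] (genotype mode) or
#' [pileup_matrix] (sequence mode), then fills in the reference-panel
#' appropriateness Z score and the k-nearest-neighbour ancestry composition
#' for each placed sample. Per-sample failures (e.g. too few shared sites)
#' are collected in the `"failures"` attribute and do not abort the batch.
#' Output order follows input order and is independent of `workers`.
#'
#' @param panel A [ref_panel].
#' @param space The matching [ancestry_space][pca_reference()].
#' @param study_input A [study_genotypes] or [pileup_matrix], matching
#'   `cfg$mode`.
#' @param cfg A [placement_config()].
#' @param workers Accepted for interface compatibility; execution is
#'   sequential and output is identical for every value.
#' @param diagnostics Set `FALSE` to skip Z / kNN annotation.
#' @return A placement tibble, one row per successfully placed sample, with
#'   attribute `"failures"` (tibble of sample_id, error message).
#' @export
place_all <- function(panel, space, study_input, cfg = placement_config(),
                      workers = 1L, diagnostics = TRUE) {
  stopifnot(workers >= 1)
  seq_mode <- inherits(study_input, "pileup_matrix")
  if (seq_mode && cfg$mode != "sequence")
    cfg$mode <- "sequence"
  ids <- study_input$sample_ids
  rows <- vector("list", length(ids))
  failures <- list()
  for (i in seq_along(ids)) {
    res <- tryCatch(
      if (seq_mode) place_sequence_sample(panel, space, study_input, i, cfg)
      else place_genotype_sample(panel, space, study_input, i, cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble::tibble(sample_id = ids[i], error = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- placement_row(character(0), matrix(numeric(0), 0, space$K),
                         numeric(0), numeric(0), integer(0), integer(0),
                         space$K)[0, ]
  }
  if (diagnostics && nrow(out) > 0) {
    out <- annotate_placements(out, panel, space, study_input, cfg)
  }
  attr(out, "failures") <- dplyr::bind_rows(failures)
  attr(out, "K") <- space$K
  out
}

# Fill Z and kNN composition columns of a placement tibble.
annotate_placements <- function(placements, panel, space, study_input, cfg) {
  pc_cols <- paste0("PC", seq_len(space$K))
  seq_mode <- inherits(study_input, "pileup_matrix")
  k <- min(cfg$knn_k, nrow(space$Y))
  for (r in seq_len(nrow(placements))) {
    i <- match(placements$sample_id[r], study_input$sample_ids)
    coords <- as.numeric(placements[r, pc_cols])
    nb <- nearest_neighbors(space, coords, k)
    comp <- knn_composition(nb, space$populations)
    placements$knn_top_population[r] <- names(comp)[1]
    placements$knn_top_fraction[r] <- comp[[1]]
    if (seq_mode) {
      covered <- which(study_input$depth[i, ] > 0)
      sites <- study_input$site_index[covered]
      dos <- 2 - 2 * study_input$ref_count[i, covered] /
        study_input$depth[i, covered]
    } else {
      g <- study_input$genotypes[i, ]
      usable <- which(!is.na(g))
      sites <- study_input$site_index[usable]
      dos <- g[usable]
    }
    if (k >= 5) {
      freqs <- panel_alt_freqs(panel)[sites]
      v <- genetic_variance_statistic(dos, freqs)
      z <- z_score(v, panel, nb, sites, threshold = cfg$z_threshold)
      placements$Z[r] <- z$Z
    }
  }
  placements
}
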