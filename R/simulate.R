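#' Simulation configuration
#'
#' Bundles the parameters of the Balding-Nichols synthetic-data generator:
#' structured reference panels, study cohorts and sequencing reads. The
#' defaults describe a small worldwide-style panel: a handful of moderately
#' differentiated populations typed at a few thousand unlinked biallelic SNPs.
#'
#' @param n_pops Number of reference populations.
#' @param n_per_pop Individuals per population; recycled to `n_pops`.
#' @param L Number of biallelic sites.
#' @param Fst Population divergence parameter F in (0, 1); scalar or one
#'   value per population.
#' @param ancestral_freq_range Interval within (0, 1) from which ancestral
#'   alt-allele frequencies are drawn uniformly. The default (0.05, 0.95)
#'   avoids near-monomorphic sites that destabilise variance scaling.
#' @param depth_mean Mean sequencing depth for [simulate_reads()] (Poisson).
#' @param error_rate Per-base sequencing error probability in \[0, 0.5).
#' @param seed Integer seed; every generator is fully deterministic given it.
#' @param outgroup_Fst Divergence of an extra population absent from the
#'   panel, used to simulate out-of-reference study individuals.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 3L, n_per_pop = 50L, L = 2000L, Fst = 0.1,
                       ancestral_freq_range = c(0.05, 0.95),
                       depth_mean = 5, error_rate = 0.01, seed = 1L,
                       outgroup_Fst = 0.2) {
  stopifnot(n_pops >= 1, L >= 1, all(Fst > 0), all(Fst < 1),
            length(ancestral_freq_range) == 2,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] < ancestral_freq_range[2],
            depth_mean > 0, error_rate >= 0, error_rate < 0.5)
  n_per_pop <- as.integer(rep_len(n_per_pop, n_pops))
  Fst <- rep_len(Fst, n_pops)
  structure(list(n_pops = as.integer(n_pops), n_per_pop = n_per_pop,
                 L = as.integer(L), Fst = Fst,
                 ancestral_freq_range = ancestral_freq_range,
                 depth_mean = depth_mean, error_rate = error_rate,
                 seed = as.integer(seed), outgroup_Fst = outgroup_Fst),
            class = "sim_config")
}

# Beta draw around ancestral frequency p with divergence F (Balding-Nichols);
# F -> 0 collapses onto p, F -> 1 pushes mass to fixation.
bn_pop_freq <- function(p, F) {
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  q <- stats::rbeta(length(p), a, b)
  pmin(pmax(q, 1e-6), 1 - 1e-6)
}

#' Simulate a structured reference panel
#'
#' Draws a multi-population reference panel under the Balding-Nichols model:
#' ancestral alt-allele frequencies are uniform on `cfg$ancestral_freq_range`,
#' each population's frequencies are Beta draws around them parameterised by
#' `cfg$Fst`, and genotypes are Binomial(2, q). Sites are unlinked.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `panel` (a [ref_panel]) and `freqs`
#'   (L x n_pops matrix of true per-population alt-allele frequencies) and
#'   `ancestral` (length-L ancestral frequencies).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$L
  p0 <- stats::runif(L, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  freqs <- vapply(seq_len(cfg$n_pops),
                  function(k) bn_pop_freq(p0, cfg$Fst[k]),
                  numeric(L))
  pops <- sprintf("POP%d", seq_len(cfg$n_pops))
  N <- sum(cfg$n_per_pop)
  G <- matrix(NA_integer_, N, L)
  labels <- character(N)
  row <- 1L
  for (k in seq_len(cfg$n_pops)) {
    for (i in seq_len(cfg$n_per_pop[k])) {
      G[row, ] <- stats::rbinom(L, 2L, freqs[, k])
      labels[row] <- pops[k]
      row <- row + 1L
    }
  }
  sites <- tibble::tibble(
    site_id = sprintf("snp%05d", seq_len(L)),
    chrom = "1",
    pos = as.integer(seq_len(L) * 1000L),
    ref_allele = rep_len(c("A", "C"), L),
    alt_allele = rep_len(c("G", "T"), L)
  )
  samples <- tibble::tibble(
    sample_id = sprintf("%s_ref%03d", labels, stats::ave(seq_len(N), labels,
                                                         FUN = seq_along)),
    population = labels,
    region = "SIM"
  )
  panel <- new_ref_panel(G, sites, samples)
  colnames(freqs) <- pops
  list(panel = panel, freqs = freqs, ancestral = p0)
}

#' Simulate study individuals
#'
#' Draws study genotypes from population frequencies simulated by
#' [simulate_panel()]. Individuals may belong to a single population, be
#' admixed (genotype ~ Binomial(2, sum_a alpha_a q_a)), or come from an
#' outgroup population absent from the panel, freshly diverged from the
#' ancestral frequencies at `cfg$outgroup_Fst`.
#'
#' @param freqs L x n_pops matrix of population alt-allele frequencies.
#' @param assignments Character vector of population labels (column names of
#'   `freqs`, or `"OUTGROUP"`), one per study individual. Ignored when
#'   `admixture` is given.
#' @param cfg The [sim_config()] used for the panel.
#' @param admixture Optional M x n_pops matrix of admixture proportions, rows
#'   summing to 1.
#' @param ancestral Length-L ancestral frequencies (required for outgroup
#'   individuals).
#' @param seed Seed for this draw; defaults to `cfg$seed + 1`.
#' @return A list: `study` (a [study_genotypes] covering all panel sites) and
#'   `truth` (tibble with sample_id and true population / proportions).
#' @export
simulate_study <- function(freqs, assignments = NULL, cfg,
                           admixture = NULL, ancestral = NULL,
                           seed = cfg$seed + 1L) {
  set.seed(seed)
  L <- nrow(freqs)
  if (!is.null(admixture)) {
    admixture <- as.matrix(admixture)
    if (any(abs(rowSums(admixture) - 1) > 1e-8))
      stop("admixture proportions must sum to 1 per individual")
    M <- nrow(admixture)
    pm <- freqs %*% t(admixture)  # L x M individual-specific frequencies
    truth <- tibble::tibble(sample_id = sprintf("adm%03d", seq_len(M)),
                            population = "ADMIXED")
  } else {
    stopifnot(!is.null(assignments))
    M <- length(assignments)
    pm <- matrix(NA_real_, L, M)
    for (j in seq_len(M)) {
      if (assignments[j] == "OUTGROUP") {
        if (is.null(ancestral))
          stop("ancestral frequencies required for OUTGROUP individuals")
        pm[, j] <- bn_pop_freq(ancestral, cfg$outgroup_Fst)
      } else {
        pm[, j] <- freqs[, assignments[j]]
      }
    }
    truth <- tibble::tibble(sample_id = sprintf("study%03d", seq_len(M)),
                            population = assignments)
  }
  G <- matrix(stats::rbinom(M * L, 2L, t(pm)), M, L, byrow = FALSE)
  study <- new_study_genotypes(G, truth$sample_id, seq_len(L))
  list(study = study, truth = truth)
}

#' Simulate sequencing reads for study individuals
#'
#' Emulates shallow or deep shotgun sequencing over the study genotypes:
#' depth ~ Poisson(`depth_mean`) per (sample, site); reads carrying the
#' reference allele ~ Binomial(depth, (1-g/2)(1-eps) + (g/2) eps) for
#' genotype g and base-error rate eps. Zero-depth cells are recorded as
#' depth 0 and omitted when the pileup is written to disk.
#'
#' @param study A [study_genotypes].
#' @param cfg A [sim_config()]; `depth_mean` and `error_rate` are used.
#' @param depth_mean,error_rate Overrides of the config values; `depth_mean`
#'   may be a vector with one mean per sample (heterogeneous coverage).
#' @param site_subset Optional integer indices (into the study's sites)
#'   restricting coverage, e.g. an exome-style target set.
#' @param seed Seed; defaults to `cfg$seed + 2`.
#' @return A [pileup_matrix].
#' @export
simulate_reads <- function(study, cfg, depth_mean = cfg$depth_mean,
                           error_rate = cfg$error_rate,
                           site_subset = NULL, seed = cfg$seed + 2L) {
  set.seed(seed)
  G <- study$genotypes
  if (!is.null(site_subset)) {
    G <- G[, site_subset, drop = FALSE]
    site_index <- study$site_index[site_subset]
  } else {
    site_index <- study$site_index
  }
  M <- nrow(G); Lp <- ncol(G)
  depth_mean <- rep_len(depth_mean, M)
  depth <- matrix(stats::rpois(M * Lp, rep(depth_mean, Lp)), M, Lp)
  g <- G
  g[is.na(g)] <- 0L  # uncalled genotype sequenced as hom-ref background
  p_ref <- (1 - g / 2) * (1 - error_rate) + (g / 2) * error_rate
  ref_count <- matrix(stats::rbinom(M * Lp, as.vector(depth), as.vector(p_ref)),
                      M, Lp)
  new_pileup_matrix(depth, ref_count,
                    error_rate = rep(error_rate, Lp),
                    sample_ids = study$sample_ids,
                    site_index = site_index)
}

#' Write a complete synthetic fixture set
#'
#' Generates a reference panel, a study cohort (one third of the individuals
#' per panel population by default), a study VCF, a pileup/site-error pair,
#' and a truth table, and writes them under `dir`. This is what the
#' `simulate` CLI subcommand calls.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @param n_study Number of study individuals.
#' @return Invisibly, a named list of the paths written.
#' @export
write_fixture_set <- function(dir, cfg, n_study = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(cfg)
  pops <- colnames(sim$freqs)
  assignments <- rep_len(pops, n_study)
  st <- simulate_study(sim$freqs, assignments, cfg)
  pil <- simulate_reads(st$study, cfg)
  prefix <- file.path(dir, "panel")
  write_reference_panel(sim$panel, prefix)
  vcf_path <- file.path(dir, "study.vcf")
  write_vcf_genotypes(st$study, sim$panel$sites, vcf_path)
  pileup_path <- file.path(dir, "study.pileup")
  siterr_path <- file.path(dir, "study.siterr")
  write_pileup(pil, sim$panel$sites, pileup_path, siterr_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(st$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(geno = paste0(prefix, ".geno"),
                 site = paste0(prefix, ".site"),
                 sample = paste0(prefix, ".sample"),
                 vcf = vcf_path, pileup = pileup_path,
                 siterr = siterr_path, truth = truth_path))
}

#' Hudson Fst estimator for two populations
#'
#' Ratio-of-averages Hudson estimator from per-population allele counts,
#' used to check that simulated panels realise their configured divergence.
#'
#' @param G Genotype matrix over \{0,1,2\} with missing as NA.
#' @param pop Population label per row; exactly two distinct labels.
#' @return Scalar Fst estimate.
#' @export
hudson_fst <- function(G, pop) {
  labs <- unique(pop)
  stopifnot(length(labs) == 2)
  p <- function(lab) colMeans(G[pop == lab, , drop = FALSE], na.rm = TRUE) / 2
  n <- function(lab) 2 * colSums(!is.na(G[pop == lab, , drop = FALSE]))
  p1 <- p(labs[1]); p2 <- p(labs[2])
  n1 <- n(labs[1]); n2 <- n(labs[2])
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
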