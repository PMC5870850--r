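#' k nearest reference neighbours of a placed sample
#'
#' Finds the k reference individuals of minimal Euclidean distance to a
#' point in the ancestry space. Ties are broken by lower reference index so
#' the result is deterministic.
#'
#' @param space An [ancestry_space][pca_reference()].
#' @param coords Length-K coordinates in the space.
#' @param k Number of neighbours, 1 <= k <= N.
#' @return A list of class `neighbor_set`: `indices`, `distances`, `k`.
#' @export
nearest_neighbors <- function(space, coords, k) {
  N <- nrow(space$Y)
  if (k < 1 || k > N) stop("k must be between 1 and N")
  d <- sqrt(colSums((t(space$Y) - coords)^2))
  ord <- order(d, seq_len(N))  # index tie-break
  idx <- ord[seq_len(k)]
  structure(list(indices = idx, distances = d[idx], k = as.integer(k)),
            class = "neighbor_set")
}

#' Ancestry composition of a neighbour set
#'
#' Fraction of each population label among the k nearest reference
#' neighbours; fractions sum to 1 and are sorted descending (ties by label).
#'
#' @param neighbors A [neighbor_set][nearest_neighbors()].
#' @param populations Population label per reference individual.
#' @return Named numeric vector of fractions.
#' @export
knn_composition <- function(neighbors, populations) {
  stopifnot(inherits(neighbors, "neighbor_set"))
  labs <- populations[neighbors$indices]
  tab <- table(labs) / neighbors$k
  frac <- as.numeric(tab)
  names(frac) <- names(tab)
  frac[order(-frac, names(frac))]
}

# Panel alt-allele frequencies, clipped away from 0/1 so the variance
# standardization cannot blow up at (near-)monomorphic sites.
panel_alt_freqs <- function(panel, clip = c(0.01, 0.99)) {
  p <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  pmin(pmax(p, clip[1]), clip[2])
}

#' Genetic-variance statistic of one individual
#'
#' Frequency-standardized mean squared dosage deviation,
#' v = mean_l (g_l - 2 p_l)^2 / (2 p_l (1 - p_l)), with p the reference
#' panel's alt-allele frequencies at the same sites (clipped to
#' \[0.01, 0.99\]). Under Hardy-Weinberg sampling from the panel's
#' frequencies, E\[v\] = 1, which is what makes it a useful yardstick for
#' panel appropriateness: individuals whose ancestry the panel does not
#' represent show inflated v. Defined identically for study and reference
#' individuals; missing dosages are dropped from the mean.
#'
#' @param dosages Length-L' dosage vector (0/1/2 or real; NA dropped).
#' @param ref_freqs Length-L' panel alt-allele frequencies, already clipped.
#' @return Scalar v >= 0.
#' @export
genetic_variance_statistic <- function(dosages, ref_freqs) {
  stopifnot(length(dosages) == length(ref_freqs))
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing: cannot compute genetic variance")
  g <- dosages[ok]; p <- ref_freqs[ok]
  mean((g - 2 * p)^2 / (2 * p * (1 - p)))
}

#' Reference-panel appropriateness Z score
#'
#' Compares a study individual's genetic-variance statistic with the same
#' statistic computed for its k nearest reference neighbours on the same
#' site set: Z = (v_study - mean(v_neighbors)) / sd(v_neighbors). Large |Z|
#' indicates the reference panel does not represent the individual's
#' ancestry (e.g. a European panel used for non-European samples).
#'
#' @param v_study The study individual's [genetic_variance_statistic()].
#' @param panel A [ref_panel].
#' @param neighbors A [neighbor_set][nearest_neighbors()] with k >= 5 (the
#'   neighbour standard deviation needs support).
#' @param site_index Panel site indices the statistic was computed on.
#' @param threshold |Z| above which the sample is flagged.
#' @return A list of class `z_result`: `Z`, `v_study`, `v_neighbors_mean`,
#'   `v_neighbors_sd`, `flagged`.
#' @export
z_score <- function(v_study, panel, neighbors, site_index, threshold = 3) {
  stopifnot(inherits(neighbors, "neighbor_set"))
  if (neighbors$k < 5) stop("Z score needs at least 5 neighbours")
  freqs <- panel_alt_freqs(panel)[site_index]
  v_nb <- vapply(neighbors$indices, function(i)
    genetic_variance_statistic(panel$genotypes[i, site_index], freqs),
    numeric(1))
  m <- mean(v_nb); s <- stats::sd(v_nb)
  if (s == 0) {
    warning("neighbour variance statistics are constant; Z set to 0")
    Z <- 0
  } else {
    Z <- (v_study - m) / s
  }
  structure(list(Z = Z, v_study = v_study, v_neighbors_mean = m,
                 v_neighbors_sd = s, flagged = abs(Z) > threshold),
            class = "z_result")
}
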