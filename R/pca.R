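#' Standardize a dosage matrix
#'
#' Column-mean imputes missing cells, mean-centres each column and, under
#' `center_scale`, divides by sqrt(p(1-p)) where p = column_mean / 2 — the
#' binomial allele-frequency scaling used in genotype PCA. Zero-variance
#' columns get scale 1. When `means`/`scales` are supplied (study data being
#' mapped into an existing space) they are used instead of being recomputed.
#'
#' @param G Numeric matrix over \{0,1,2,NA\} (or real dosages with NA).
#' @param mode `"center_only"` (default) or `"center_scale"`.
#' @param means,scales Optional per-column statistics to apply.
#' @return List with the standardized matrix `X` and the `means` and
#'   `scales` used.
#' @export
standardize_genotypes <- function(G, mode = c("center_only", "center_scale"),
                                  means = NULL, scales = NULL) {
  mode <- match.arg(mode)
  G <- as.matrix(G) * 1.0
  if (is.null(means)) {
    means <- colMeans(G, na.rm = TRUE)
    if (anyNA(means))
      stop("column entirely missing and no supplied mean")
  }
  if (is.null(scales)) {
    if (mode == "center_scale") {
      p <- means / 2
      scales <- sqrt(p * (1 - p))
      scales[!is.finite(scales) | scales <= 0] <- 1
    } else {
      scales <- rep(1, ncol(G))
    }
  }
  na <- which(is.na(G), arr.ind = TRUE)
  if (nrow(na) > 0) G[na] <- means[na[, 2]]
  X <- sweep(G, 2, means, "-")
  if (any(scales != 1)) X <- sweep(X, 2, scales, "/")
  list(X = X, means = means, scales = scales)
}

# Top-k PCA scores of an already-standardized matrix, with a deterministic
# sign convention: each PC's loading entry of largest absolute value is made
# positive (ties broken by lowest site index). Uses the eigendecomposition of
# the smaller Gram matrix since typically L >> N.
pca_scores <- function(X, k) {
  n <- nrow(X); L <- ncol(X)
  k <- min(k, n, L)
  if (L >= n) {
    ev <- eigen(tcrossprod(X), symmetric = TRUE)
    d2 <- pmax(ev$values[seq_len(k)], 0)
    d <- sqrt(d2)
    U <- ev$vectors[, seq_len(k), drop = FALSE]
    scores <- U * rep(d, each = n)
    # loadings for the sign convention: V = X'U / d
    V <- crossprod(X, U)
    V <- sweep(V, 2, ifelse(d > 0, d, 1), "/")
    all_d2 <- pmax(ev$values, 0)
  } else {
    sv <- svd(X, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    scores <- sv$u * rep(d, each = n)
    V <- sv$v
    all_d2 <- sv$d^2
  }
  for (j in seq_len(k)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) {
      scores[, j] <- -scores[, j]
      V[, j] <- -V[, j]
    }
  }
  list(scores = scores, d2 = pmax(d^2, 0), loadings = V,
       total_var = sum(all_d2))
}

#' Build the reference ancestry space by PCA on the panel
#'
#' Standardizes the panel genotype matrix, runs an exact truncated PCA, and
#' returns the K-dimensional reference coordinate system: the reference
#' coordinates Y (scores = left singular vectors times singular values),
#' eigenvalues (squared singular values / (N-1)), and the per-site
#' standardization statistics that define the space.
#'
#' @param panel A [ref_panel].
#' @param K Dimension of the ancestry space (default 4, suited to
#'   continental-scale panels).
#' @param mode Standardization mode, see [standardize_genotypes()].
#' @return An object of class `ancestry_space`.
#' @export
pca_reference <- function(panel, K = 4L, mode = c("center_only",
                                                  "center_scale")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "ref_panel"))
  N <- nrow(panel$genotypes); L <- ncol(panel$genotypes)
  if (K > min(N - 1, L))
    stop(sprintf("K = %d exceeds min(N-1, L) = %d", K, min(N - 1, L)))
  std <- standardize_genotypes(panel$genotypes, mode)
  pc <- pca_scores(std$X, K)
  structure(list(Y = pc$scores,
                 K = as.integer(K),
                 eigenvalues = pc$d2[seq_len(K)] / (N - 1),
                 site_means = std$means,
                 site_scales = std$scales,
                 scaling_mode = mode,
                 sites = panel$sites,
                 sample_ids = panel$samples$sample_id,
                 populations = panel$samples$population,
                 total_var = pc$total_var / (N - 1)),
            class = "ancestry_space")
}

#' @export
print.ancestry_space <- function(x, ...) {
  cat(sprintf("<ancestry_space> K = %d, N = %d, L = %d (%s)\n",
              x$K, nrow(x$Y), nrow(x$sites), x$scaling_mode))
  cat("  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Joint PCA of the reference panel plus one study individual
#'
#' Stacks the study dosage row under the N reference rows, standardizes the
#' (N+1) x L' matrix jointly (statistics from all N+1 rows), and returns the
#' first K' principal component scores, split into the reference block and
#' the study individual's coordinates. This per-sample joint PCA is what
#' avoids the shrinkage of naive loading-based projection.
#'
#' @param panel_rows N x L' genotype (or real dosage) submatrix.
#' @param study_row Length-L' dosage vector (NA allowed, not all).
#' @param K_prime Dimension K' of the joint space (K' >= K).
#' @param mode Standardization mode.
#' @return List with `X_ref` (N x K'), `x_study` (length K') and `K_prime`.
#' @export
pca_joint <- function(panel_rows, study_row,
                      K_prime = 20L, mode = c("center_only", "center_scale")) {
  mode <- match.arg(mode)
  if (all(is.na(study_row))) stop("study row is entirely missing")
  N <- nrow(panel_rows); Lp <- ncol(panel_rows)
  if (length(study_row) != Lp) stop("study row length mismatch")
  kmax <- min(N, Lp)  # rank of the centered (N+1) x L' matrix is <= min(N, L')
  if (K_prime > kmax) {
    warning(sprintf("K' = %d lowered to achievable rank %d", K_prime, kmax))
    K_prime <- kmax
  }
  A <- rbind(panel_rows, study_row, deparse.level = 0)
  std <- standardize_genotypes(A, mode)
  pc <- pca_scores(std$X, K_prime)
  list(X_ref = pc$scores[seq_len(N), , drop = FALSE],
       x_study = pc$scores[N + 1, ],
       K_prime = as.integer(K_prime))
}

#' Persist an ancestry space
#'
#' Writes `<prefix>.space.tsv` (sample_id, population, PC coordinates) and
#' `<prefix>.space.meta.tsv` (per-site means/scales plus eigenvalues), so
#' reference coordinates can be pre-computed once and reused.
#'
#' @param space An [ancestry_space].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_ancestry_space <- function(space, prefix) {
  coord_path <- paste0(prefix, ".space.tsv")
  meta_path <- paste0(prefix, ".space.meta.tsv")
  co <- data.frame(sample_id = space$sample_ids,
                   population = space$populations,
                   signif(space$Y, 15))
  names(co)[-(1:2)] <- paste0("PC", seq_len(space$K))
  utils::write.table(co, coord_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(site_id = space$sites$site_id,
                     mean = sprintf("%.15g", space$site_means),
                     scale = sprintf("%.15g", space$site_scales))
  hdr <- sprintf("#scaling_mode=%s eigenvalues=%s total_var=%.15g",
                 space$scaling_mode,
                 paste(sprintf("%.15g", space$eigenvalues), collapse = ","),
                 space$total_var)
  writeLines(hdr, meta_path)
  suppressWarnings(
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(c(coords = coord_path, meta = meta_path))
}

#' Load an ancestry space written by [write_ancestry_space()]
#'
#' @param prefix Path prefix used at write time.
#' @param panel The matching [ref_panel] (provides the site table).
#' @return An [ancestry_space].
#' @export
read_ancestry_space <- function(prefix, panel) {
  coord_path <- paste0(prefix, ".space.tsv")
  meta_path <- paste0(prefix, ".space.meta.tsv")
  co <- utils::read.table(coord_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  hdr <- readLines(meta_path, n = 1)
  mode <- sub(".*scaling_mode=([a-z_]+).*", "\\1", hdr)
  eig <- as.numeric(strsplit(sub(".*eigenvalues=([^ ]+).*", "\\1", hdr),
                             ",")[[1]])
  total_var <- as.numeric(sub(".*total_var=([0-9eE.+-]+).*", "\\1", hdr))
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t", skip = 1)
  pc_cols <- grep("^PC", names(co))
  structure(list(Y = unname(as.matrix(co[, pc_cols])),
                 K = length(pc_cols),
                 eigenvalues = eig,
                 site_means = meta$mean,
                 site_scales = meta$scale,
                 scaling_mode = mode,
                 sites = panel$sites,
                 sample_ids = co$sample_id,
                 populations = co$population,
                 total_var = total_var),
            class = "ancestry_space")
}
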