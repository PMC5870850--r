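# Independent projection-Procrustes oracle: best dissimilarity found by
# random Stiefel draws plus derivative-free/quasi-Newton local optimization
# over a polar-decomposition parameterization. Used only to check the
# package's fitter, never as the implementation.
oracle_procrustes_D <- function(X, Y, n_random = 10000) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Kp <- ncol(X); K <- ncol(Y)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  trY <- sum(Yc^2)
  D_of_A <- function(A) {
    M <- Xc %*% A
    num <- sum(M * Yc); den <- sum(M * M)
    if (den <= 0) return(trY)
    rho <- max(num, 0) / den
    trY + rho^2 * den - 2 * rho * num
  }
  polar <- function(M) { sv <- svd(M); sv$u %*% t(sv$v) }
  best <- Inf; bestA <- NULL
  for (i in seq_len(n_random)) {
    A <- polar(matrix(stats::rnorm(Kp * K), Kp))
    d <- D_of_A(A)
    if (d < best) { best <- d; bestA <- A }
  }
  obj <- function(par) D_of_A(polar(matrix(par, Kp, K)))
  for (start in list(as.vector(bestA), stats::rnorm(Kp * K))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    # polish derivative-free (Nelder-Mead warns at a single parameter; the
    # polish is still valid there)
    o2 <- suppressWarnings(
      stats::optim(o$par, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-15)))
    best <- min(best, o$value, o2$value)
  }
  best
}

# random Stiefel matrix (uniform via polar factor of a Gaussian matrix)
random_stiefel <- function(Kp, K) {
  sv <- svd(matrix(stats::rnorm(Kp * K), Kp))
  sv$u %*% t(sv$v)
}
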