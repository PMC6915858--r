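# Rectangle probabilities of low-dimensional multivariate normals.  The
# triplet covariance is block diagonal by event (cross-event covariance is
# fixed at 0), so the trivariate integral always factors into independent
# blocks of dimension <= 3.  Within a block we condition on the leading
# coordinates and integrate with Gauss-Legendre quadrature (the integrands
# are smooth and effectively compactly supported, so convergence is
# spectral; 96 nodes give ~1e-12 on unit-scale probabilities).

.gl_cache <- new.env(parent = emptyenv())

# Golub-Welsch nodes/weights for Gauss-Legendre on [-1, 1]
gauss_legendre <- function(n = 96L) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  out <- list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
  .gl_cache[[key]] <- out
  out
}

# truncate an integration range to the effective support of N(mu, sd)
trunc_range <- function(lower, upper, mu, sd, width = 8.5) {
  c(max(lower, mu - width * sd), min(upper, mu + width * sd))
}

mvn_rect_block <- function(lower, upper, mean, sigma, n_nodes = 96L) {
  d <- length(mean)
  if (d == 1) {
    s <- sqrt(sigma[1, 1])
    return(stats::pnorm(upper, mean, s) - stats::pnorm(lower, mean, s))
  }
  gl <- gauss_legendre(n_nodes)
  s1 <- sqrt(sigma[1, 1])
  r1 <- trunc_range(lower[1], upper[1], mean[1], s1)
  if (r1[1] >= r1[2]) return(0)
  x1 <- (r1[1] + r1[2]) / 2 + (r1[2] - r1[1]) / 2 * gl$nodes
  w1 <- (r1[2] - r1[1]) / 2 * gl$weights
  if (d == 2) {
    b <- sigma[2, 1] / sigma[1, 1]
    v2c <- max(sigma[2, 2] - b * sigma[1, 2], 1e-12)
    s2c <- sqrt(v2c)
    mu2c <- mean[2] + b * (x1 - mean[1])
    return(sum(w1 * stats::dnorm(x1, mean[1], s1) *
                 (stats::pnorm((upper[2] - mu2c) / s2c) -
                    stats::pnorm((lower[2] - mu2c) / s2c))))
  }
  # d == 3: Gauss-Legendre grid over the first two coordinates, closed-form
  # conditional for the third
  s2 <- sqrt(sigma[2, 2])
  r2 <- trunc_range(lower[2], upper[2], mean[2], s2)
  if (r2[1] >= r2[2]) return(0)
  x2 <- (r2[1] + r2[2]) / 2 + (r2[2] - r2[1]) / 2 * gl$nodes
  w2 <- (r2[2] - r2[1]) / 2 * gl$weights
  S12 <- sigma[1:2, 1:2]
  det12 <- S12[1, 1] * S12[2, 2] - S12[1, 2]^2
  if (det12 <= 1e-14) {
    rlang::abort("degenerate leading 2x2 covariance block")
  }
  inv12 <- matrix(c(S12[2, 2], -S12[1, 2], -S12[2, 1], S12[1, 1]), 2) / det12
  b3 <- as.numeric(inv12 %*% sigma[1:2, 3])
  v3c <- max(sigma[3, 3] - sum(sigma[3, 1:2] * b3), 1e-12)
  s3c <- sqrt(v3c)
  X1 <- rep(x1, times = length(x2))
  X2 <- rep(x2, each = length(x1))
  W <- rep(w1, times = length(x2)) * rep(w2, each = length(x1))
  d1 <- X1 - mean[1]
  d2 <- X2 - mean[2]
  quad <- inv12[1, 1] * d1^2 + 2 * inv12[1, 2] * d1 * d2 + inv12[2, 2] * d2^2
  dens2 <- exp(-quad / 2) / (2 * pi * sqrt(det12))
  mu3c <- mean[3] + b3[1] * d1 + b3[2] * d2
  sum(W * dens2 * (stats::pnorm((upper[3] - mu3c) / s3c) -
                     stats::pnorm((lower[3] - mu3c) / s3c)))
}

mvn_rect_mc <- function(lower, upper, mean, sigma, n = 1e6) {
  d <- length(mean)
  ch <- chol(sigma + diag(1e-10, d))
  withr::with_seed(1L, {
    z <- matrix(stats::rnorm(n * d), ncol = d) %*% ch
  })
  x <- sweep(z, 2, mean, `+`)
  inside <- rep(TRUE, n)
  for (j in seq_len(d)) {
    inside <- inside & x[, j] > lower[j] & x[, j] <= upper[j]
  }
  mean(inside)
}

#' Rectangle probability of a multivariate normal (dimension <= 3)
#'
#' \eqn{P(l < X \le u)} for a normal with the given mean and covariance:
#' independent blocks are split off, and each block is integrated by
#' conditioning with Gauss-Legendre quadrature.  Falls back to fixed-seed
#' Monte Carlo (1e6 draws, with a warning) if quadrature fails.
#'
#' @param lower,upper Bounds (may be `-Inf` / `Inf`).
#' @param mean Mean vector.
#' @param sigma Covariance matrix.
#' @return The rectangle probability.
#' @export
mvn_rectangle_prob <- function(lower, upper, mean, sigma) {
  d <- length(mean)
  stopifnot(d >= 1, d <= 3, length(lower) == d, length(upper) == d)
  sigma <- as.matrix(sigma)
  if (any(upper <= lower)) return(0)
  # split into independent blocks (connected components of the
  # off-diagonal pattern)
  adj <- abs(sigma) > 1e-14
  comp <- seq_len(d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (adj[i, j]) comp[comp == comp[j]] <- comp[i]
  }
  prob <- 1
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    p <- tryCatch(
      mvn_rect_block(lower[idx], upper[idx], mean[idx],
                     sigma[idx, idx, drop = FALSE]),
      error = function(e) {
        rlang::warn(paste0(
          "quadrature failed (", conditionMessage(e),
          "); using fixed-seed Monte Carlo"
        ))
        mvn_rect_mc(lower[idx], upper[idx], mean[idx],
                    sigma[idx, idx, drop = FALSE])
      }
    )
    prob <- prob * p
  }
  min(max(prob, 0), 1)
}
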