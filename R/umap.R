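## Compact UMAP: exact kNN, fuzzy simplicial set with per-point bandwidth
## calibration, symmetrization by probabilistic t-conorm, deterministic
## PCA initialization, and negative-sampling SGD layout (C++).

# fit the low-dimensional similarity curve 1/(1 + a x^(2b)) to the ideal
# offset-exponential membership psi(x)
.fitAB <- function(min_dist, spread = 1) {
  x <- seq(0, 3 * spread, length.out = 300)
  y <- ifelse(x <= min_dist, 1, exp(-(x - min_dist) / spread))
  fit <- nls(y ~ 1 / (1 + a * x^(2 * b)), start = list(a = 1.5, b = 1),
             control = list(maxiter = 200, warnOnly = TRUE))
  as.list(coef(fit))
}

.smoothKnnSigma <- function(d, rho, target, iters = 64) {
  lo <- 1e-12; hi <- Inf; mid <- 1
  for (it in seq_len(iters)) {
    val <- sum(exp(-pmax(d - rho, 0) / mid))
    if (abs(val - target) < 1e-5) break
    if (val > target) { hi <- mid; mid <- (lo + hi) / 2 }
    else { lo <- mid; mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2 }
  }
  mid
}

#' 2-D UMAP embedding
#'
#' Uniform manifold approximation and projection of a feature matrix to
#' two dimensions: exact k-nearest-neighbor graph, smoothed-kNN fuzzy
#' membership calibration (each point's bandwidth solves
#' sum(exp(-(d - rho)/sigma)) = log2(k)), fuzzy union symmetrization,
#' deterministic PCA initialization scaled to \[-10, 10\], and
#' negative-sampling SGD with the epochs-per-sample schedule.
#' Bit-reproducible given the seed (single-threaded).
#'
#' @param X numeric matrix (observations x features).
#' @param n_neighbors neighborhood size (default 15).
#' @param min_dist minimum embedding distance parameter (default 0.1).
#' @param n_epochs SGD epochs (default 200).
#' @param seed integer seed for the SGD negative-sampling stream.
#' @param lr initial learning rate.
#' @param n_neg negative samples per positive edge.
#' @return n x 2 matrix of embedding coordinates.
#' @export
umapEmbed <- function(X, n_neighbors = 15, min_dist = 0.1, n_epochs = 200,
                      seed = 1, lr = 1, n_neg = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations")
  k <- max(2, min(n_neighbors, n - 1))
  D <- as.matrix(dist(X))
  A <- matrix(0, n, n)
  target <- log2(k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    d <- D[i, nb]
    rho <- min(d[d > 0], Inf)
    if (!is.finite(rho)) rho <- 0
    sig <- .smoothKnnSigma(d, rho, target)
    A[i, nb] <- exp(-pmax(d - rho, 0) / sig)
  }
  W <- A + t(A) - A * t(A)
  W[lower.tri(W, diag = TRUE)] <- 0
  keepW <- W > max(W) / n_epochs
  ei <- row(W)[keepW]; ej <- col(W)[keepW]; ew <- W[keepW]
  ab <- .fitAB(min_dist)
  init <- if (ncol(X) >= 2) X[, 1:2, drop = FALSE]
          else cbind(X[, 1], 0)
  init <- sweep(init, 2, colMeans(init))
  mx <- max(abs(init))
  if (mx > 0) init <- 10 * init / mx
  umap_sgd_cpp(init, as.integer(ei - 1L), as.integer(ej - 1L), ew,
               as.integer(n_epochs), ab$a, ab$b, lr, as.integer(n_neg),
               as.integer(seed %% 2147483647))
}
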