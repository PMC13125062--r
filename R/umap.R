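# Two-dimensional UMAP embedding, implemented for the few-dozen-point
# problems this package embeds (importance vectors of ~24 white-matter
# regions). The fuzzy k-nearest-neighbour graph construction follows the
# standard UMAP recipe (per-point connectivity rho_i, smooth-kNN bandwidth
# sigma_i solved by bisection, probabilistic t-conorm symmetrization). The
# layout minimizes the usual fuzzy cross-entropy, but by full-batch Adam
# over all pairs rather than edge-sampling SGD: at this scale the full
# gradient is cheap and makes the result deterministic given the seed.

# Fit the (a, b) curve so that (1 + a d^(2b))^-1 approximates the target
# membership exp(-(d - min_dist)) beyond min_dist and 1 below it.
umap_ab <- function(min_dist = 0.1, spread = 1) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d < min_dist, 1, exp(-(d - min_dist) / spread))
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    sum((1 / (1 + a * d^(2 * b)) - target)^2)
  }
  fit <- stats::optim(c(log(1.5), log(1)), obj, method = "Nelder-Mead")
  c(a = exp(fit$par[1]), b = exp(fit$par[2]))
}

# Fuzzy simplicial set membership matrix from a distance matrix.
umap_graph <- function(D, n_neighbors) {
  n <- nrow(D)
  k <- n_neighbors
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    dn <- d[nb]
    pos <- dn[dn > 0]
    rho <- if (length(pos)) min(pos) else 0
    adj <- pmax(dn - rho, 0)
    target <- log2(k)
    # bisection for sigma: sum exp(-adj/sigma) = log2(k)
    lo <- 1e-6; hi <- max(adj) * 10 + 1
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-adj / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    W[i, nb] <- exp(-adj / ((lo + hi) / 2))
  }
  W + t(W) - W * t(W)
}

# Spectral initialization from the symmetric normalized graph Laplacian.
umap_spectral_init <- function(W) {
  n <- nrow(W)
  deg <- pmax(rowSums(W), 1e-12)
  L <- diag(n) - diag(1 / sqrt(deg)) %*% W %*% diag(1 / sqrt(deg))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  Y <- ev$vectors[, c(n - 1, n - 2), drop = FALSE]
  Y <- sweep(Y, 2, apply(abs(Y), 2, max) + 1e-12, "/") * 10
  Y
}

#' Two-dimensional UMAP embedding
#'
#' @param X numeric matrix (rows = points to embed).
#' @param n_neighbors local neighbourhood size (default 5; auto-reduced with
#'   a warning when it reaches the number of rows).
#' @param min_dist minimum separation in the embedding (default 0.1).
#' @param n_epochs optimizer iterations (default 300).
#' @param seed RNG seed (spectral-init jitter).
#' @return n x 2 coordinate matrix.
#' @export
umap_embed <- function(X, n_neighbors = 5, min_dist = 0.1, n_epochs = 300,
                       seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 rows to embed")
  if (n_neighbors >= n) {
    n_neighbors <- n - 1
    warning("n_neighbors reduced to ", n_neighbors)
  }
  D <- as.matrix(stats::dist(X))
  W <- umap_graph(D, n_neighbors)
  ab <- umap_ab(min_dist)
  a <- ab["a"]; b <- ab["b"]
  rng <- local_rng(seed)
  Y <- umap_spectral_init(W) + matrix(stats::rnorm(2 * n, sd = 1e-3), n, 2)
  restore_rng(rng)

  # full-batch Adam on the fuzzy cross-entropy
  m1 <- m2 <- matrix(0, n, 2)
  lr <- 0.15; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (it in seq_len(n_epochs)) {
    dx <- outer(Y[, 1], Y[, 1], "-")
    dy <- outer(Y[, 2], Y[, 2], "-")
    d2 <- dx^2 + dy^2
    v <- 1 / (1 + a * d2^b)
    att <- W * (2 * a * b * d2^(pmax(b - 1, 0))) * v
    rep_ <- (1 - W) * (2 * b) / ((0.001 + d2)) * v
    coef <- att - rep_
    diag(coef) <- 0
    Gx <- rowSums(coef * dx)
    Gy <- rowSums(coef * dy)
    G <- cbind(Gx, Gy)
    G <- pmin(pmax(G, -4), 4)
    m1 <- b1 * m1 + (1 - b1) * G
    m2 <- b2 * m2 + (1 - b2) * G^2
    step <- lr * (1 - it / n_epochs + 0.1)
    Y <- Y - step * (m1 / (1 - b1^it)) / (sqrt(m2 / (1 - b2^it)) + eps)
  }
  dimnames(Y) <- list(rownames(X), c("UMAP1", "UMAP2"))
  Y
}
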