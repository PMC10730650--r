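# Independent reference implementations used as oracles in the tests.
# All are deliberately naive (dense algebra, explicit loops) so they share
# no code path with the package functions they check.

# Brownian covariance by per-pair brute force: shared root-to-MRCA path.
brute_force_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  nd <- ape::node.depth.edgelength(tree)       # root-to-node distances
  mr <- ape::mrca(tree)                        # tip x tip MRCA node ids
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- if (i == j) nd[i] else nd[mr[i, j]]
    }
  }
  C
}

# Dense multivariate-normal log-density with mean mu*1 and covariance
# sigma2 * (lambda-transformed C), via solve() and determinant().
dense_mvn_loglik <- function(y, C, lambda, mu, sigma2) {
  V <- C * lambda
  diag(V) <- diag(C)
  V <- sigma2 * V
  n <- length(y)
  r <- y - mu
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(V, r)))
}

# Mean pairwise absolute difference by the O(k^2) double loop.
brute_force_mpd <- function(x) {
  k <- length(x)
  s <- 0
  for (i in 1:(k - 1)) for (j in (i + 1):k) s <- s + abs(x[i] - x[j])
  s / (k * (k - 1) / 2)
}

# Hierarchical partitioning by explicit enumeration of all k! orderings.
brute_force_hierpart <- function(y, X) {
  X <- as.matrix(X)
  k <- ncol(X)
  r2 <- function(idx) {
    if (length(idx) == 0) return(0)
    f <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  ic <- numeric(k)
  ords <- perms(seq_len(k))
  for (o in ords) {
    prev <- numeric(0)
    for (j in o) {
      ic[j] <- ic[j] + (r2(c(prev, j)) - r2(prev)) / length(ords)
      prev <- c(prev, j)
    }
  }
  stats::setNames(ic, colnames(X))
}

# A random ultrametric tree with labelled tips.
random_tree <- function(n, seed) {
  tr <- froglight:::with_seed(seed, ape::rphylo(n, birth = 1, death = 0))
  tr$tip.label <- sprintf("t%03d", seq_len(n))
  tr
}

# A trait simulated under the lambda model on a tree.
simulate_lambda_trait <- function(tree, lambda, sigma2 = 9, mu = 10,
                                  seed = 1) {
  C <- lambda_transform(vcv_from_tree(tree), lambda)
  froglight:::with_seed(seed, {
    stats::setNames(mu + drop(t(chol(C)) %*% stats::rnorm(ape::Ntip(tree))) *
                      sqrt(sigma2), tree$tip.label)
  })
}

# A small, fast world configuration for pipeline-level tests.
small_config <- function(seed = 11, ...) {
  world_config(seed = seed, grid_nx = 24L, grid_ny = 24L, n_species = 60L,
               water_border_width = 2L, calib_n_species = 30L, ...)
}
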