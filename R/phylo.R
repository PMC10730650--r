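#' Phylogenetic covariance matrix from a tree
#'
#' Builds the Brownian-motion covariance matrix of a rooted tree with branch
#' lengths: `C[i, j]` is the shared path length from the root to the most
#' recent common ancestor of tips i and j, and `C[i, i]` the root-to-tip
#' distance.
#'
#' @param tree An [ape::phylo] tree, rooted, with branch lengths.
#' @return Named covariance matrix in tip-label order of the tree.
#' @export
vcv_from_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance matrix
#' by `lambda`, leaving the diagonal unchanged. `lambda = 1` returns the
#' Brownian covariance; `lambda = 0` removes all phylogenetic covariance.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Signal strength in [0, 1].
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]")
  }
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

# Align a named trait vector with a tree, pruning both sides; messages the
# number of species dropped (mirrors pruning species without trait data).
align_trait_tree <- function(trait, tree, quiet = FALSE) {
  stopifnot(!is.null(names(trait)))
  common <- intersect(names(trait), tree$tip.label)
  drop_trait <- setdiff(names(trait), common)
  drop_tips <- setdiff(tree$tip.label, common)
  if (length(common) < 3) stop("fewer than 3 species shared by trait and tree")
  if (!quiet && (length(drop_trait) || length(drop_tips))) {
    message(sprintf("pruned %d trait value(s) and %d tip(s) without a match",
                    length(drop_trait), length(drop_tips)))
  }
  if (length(drop_tips)) tree <- ape::drop.tip(tree, drop_tips)
  list(y = trait[tree$tip.label], tree = tree,
       n_dropped_trait = length(drop_trait), n_dropped_tips = length(drop_tips))
}

#' Gaussian log-likelihood of a trait under a lambda model
#'
#' Log-density of `y` under a multivariate normal with mean `mu * 1` and
#' covariance `sigma2 * lambda_transform(C, lambda)`. With `mu` and
#' `sigma2` missing, both are profiled analytically at their maximum
#' likelihood values.
#'
#' @param y Trait vector (order matching `C`).
#' @param C Phylogenetic covariance matrix.
#' @param lambda Signal strength in [0, 1].
#' @param mu,sigma2 Optional fixed mean and scale; profiled when `NULL`.
#' @return List with `loglik`, `mu`, `sigma2`.
#' @export
pagel_loglik <- function(y, C, lambda, mu = NULL, sigma2 = NULL) {
  n <- length(y)
  V <- lambda_transform(C, lambda)
  R <- chol(V)
  logdet <- 2 * sum(log(diag(R)))
  ones <- rep(1, n)
  # whitened vectors: solve t(R) x = v
  wy <- backsolve(R, y, transpose = TRUE)
  w1 <- backsolve(R, ones, transpose = TRUE)
  if (is.null(mu)) mu <- sum(w1 * wy) / sum(w1 * w1)
  r <- wy - mu * w1
  q <- sum(r^2)
  if (is.null(sigma2)) sigma2 <- q / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + q / sigma2)
  list(loglik = ll, mu = mu, sigma2 = sigma2)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits the lambda model of phylogenetic signal by maximising the
#' multivariate-normal likelihood with mean `mu * 1` and covariance
#' `sigma2 * lambda_transform(C, lambda)`; `mu` and `sigma2` are profiled
#' analytically and `lambda` is optimised on [0, 1] (boundary optima are
#' compared explicitly). On a star phylogeny the likelihood is flat in
#' `lambda`; the fit is then flagged as unidentifiable and `lambda = 0`
#' reported.
#'
#' @param trait Named numeric vector of per-species trait values.
#' @param tree An [ape::phylo] tree.
#' @param quiet Suppress pruning messages.
#' @return Object of class `lambda_fit`: list with `lambda`, `sigma2`,
#'   `mu`, `loglik`, `identifiable`, `n`.
#' @export
fit_pagel_lambda <- function(trait, tree, quiet = FALSE) {
  al <- align_trait_tree(trait, tree, quiet = quiet)
  y <- al$y
  if (stats::var(y) <= 0) stop("trait is constant")
  C <- vcv_from_tree(al$tree)
  off <- C; diag(off) <- 0
  if (all(off == 0)) {
    f0 <- pagel_loglik(y, C, 0)
    return(structure(list(lambda = 0, sigma2 = f0$sigma2, mu = f0$mu,
                          loglik = f0$loglik, identifiable = FALSE,
                          n = length(y)), class = "lambda_fit"))
  }
  obj <- function(l) pagel_loglik(y, C, l)$loglik
  opt <- stats::optimize(obj, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, obj(0), obj(1))
  best <- which.max(ll)
  fit <- pagel_loglik(y, C, cand[best])
  structure(list(lambda = cand[best], sigma2 = fit$sigma2, mu = fit$mu,
                 loglik = fit$loglik, identifiable = TRUE, n = length(y)),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda fit (n = %d)\n  lambda = %.4f%s\n  mu = %.4f, sigma2 = %.4f, logLik = %.4f\n",
              x$n, x$lambda,
              if (x$identifiable) "" else " (unidentifiable: star tree)",
              x$mu, x$sigma2, x$loglik))
  invisible(x)
}

#' Phylogenetic mixed-model decomposition of a trait
#'
#' Fits the phylogenetic mixed model `y = mu + a + e` with
#' `a ~ N(0, sigma2_phylo * C)` and `e ~ N(0, sigma2_resid * I)` by an EM
#' algorithm on the eigenbasis of `C`, then extracts the best linear
#' unbiased predictors of `a` (the phylogenetically predicted component, P)
#' and `e` (the species-specific component, S). Because
#' `BLUP(a) + BLUP(e) = y - mu_hat` exactly, the additive identity
#' `mu + P_i + S_i = y_i` holds for every species.
#'
#' @param trait Named numeric vector of per-species trait values.
#' @param tree An [ape::phylo] tree.
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   between EM iterations.
#' @param max_iter Maximum EM iterations; non-convergence is flagged, not
#'   fatal.
#' @param quiet Suppress pruning messages.
#' @return Object of class `lynch_fit`: list with `components` (data.frame
#'   `species_id`, `raw`, `P`, `S`), `mu`, `sigma2_phylo`, `sigma2_resid`,
#'   `loglik`, `loglik_trace`, `iterations`, `converged`, `n`.
#' @export
lynch_decompose <- function(trait, tree, tol = 1e-8, max_iter = 10000,
                            quiet = FALSE) {
  al <- align_trait_tree(trait, tree, quiet = quiet)
  y <- al$y
  n <- length(y)
  if (n < 4) stop("need at least 4 species")
  C <- vcv_from_tree(al$tree)
  eg <- eigen(C, symmetric = TRUE)
  d <- eg$values
  if (min(d) <= 1e-10 * max(d)) stop("tree covariance is singular")
  U <- eg$vectors
  z <- drop(crossprod(U, y))
  w <- drop(crossprod(U, rep(1, n)))

  s2a <- stats::var(y) / 2
  s2e <- stats::var(y) / 2
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  mu <- mean(y)
  while (iter < max_iter) {
    iter <- iter + 1
    v <- s2a * d + s2e
    mu <- sum(w * z / v) / sum(w^2 / v)
    r <- z - mu * w
    ll <- -0.5 * sum(log(2 * pi * v) + r^2 / v)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # E-step BLUPs and conditional variances in the eigenbasis, followed by
    # the M-step updates; both use the pre-update components embedded in v.
    az <- s2a * d * r / v
    ez <- s2e * r / v
    s2a_new <- (sum(az^2 / d) + s2a * s2e * sum(1 / v)) / n
    s2e_new <- (sum(ez^2) + s2e * s2a * sum(d / v)) / n
    s2a <- s2a_new
    s2e <- s2e_new
  }
  v <- s2a * d + s2e
  mu <- sum(w * z / v) / sum(w^2 / v)
  r <- z - mu * w
  az <- s2a * d * r / v
  ez <- s2e * r / v
  P <- drop(U %*% az)
  S <- drop(U %*% ez)
  comp <- data.frame(species_id = names(y), raw = as.numeric(y),
                     P = P, S = S, row.names = NULL)
  ll <- -0.5 * sum(log(2 * pi * v) + r^2 / v)
  structure(list(components = comp, mu = mu, sigma2_phylo = s2a,
                 sigma2_resid = s2e, loglik = ll, loglik_trace = ll_trace,
                 iterations = iter, converged = converged, n = n),
            class = "lynch_fit")
}

#' @export
print.lynch_fit <- function(x, ...) {
  cat(sprintf(paste0("Phylogenetic mixed-model decomposition (n = %d)\n",
                     "  mu = %.4f, sigma2_phylo = %.4f, sigma2_resid = %.4f\n",
                     "  logLik = %.4f after %d iteration(s)%s\n"),
              x$n, x$mu, x$sigma2_phylo, x$sigma2_resid, x$loglik,
              x$iterations, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Phylogenetic generalised least squares
#'
#' GLS regression with error covariance `sigma2 * lambda_transform(C,
#' lambda)`. With `lambda = "estimated"` the signal strength is profiled by
#' maximum likelihood jointly with the coefficients. R-squared is reported
#' on the GLS-whitened scale (recorded in the result).
#'
#' @param y Named response vector (names are species ids).
#' @param X Design matrix with named columns, rows aligned to `y` (an
#'   intercept column is added unless `intercept = FALSE`).
#' @param tree An [ape::phylo] tree containing all species in `y`.
#' @param lambda `"estimated"` or a fixed value in [0, 1].
#' @param intercept Add an intercept column (default TRUE).
#' @param quiet Suppress pruning messages.
#' @return Object of class `pgls_fit`: coefficient table (`estimate`, `se`,
#'   `t`, `p`), `lambda`, `r_squared`, `r_squared_scale`, `n`, `df`,
#'   `loglik`, `residuals` (response scale).
#' @export
pgls_fit <- function(y, X, tree, lambda = "estimated", intercept = TRUE,
                     quiet = FALSE) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) == length(y))
  if (is.null(names(y))) stop("y must be named by species id")
  rownames(X) <- names(y)
  al <- align_trait_tree(y, tree, quiet = quiet)
  y <- al$y
  X <- X[names(y), , drop = FALSE]
  if (intercept && !("(Intercept)" %in% colnames(X))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  C <- vcv_from_tree(al$tree)
  n <- length(y)
  p <- ncol(X)

  gls_at <- function(l) {
    V <- lambda_transform(C, l)
    R <- chol(V)
    wy <- backsolve(R, y, transpose = TRUE)
    wX <- backsolve(R, X, transpose = TRUE)
    fit <- stats::lm.fit(wX, wy)
    rss <- sum(fit$residuals^2)
    logdet <- 2 * sum(log(diag(R)))
    s2ml <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2ml) + logdet + n)
    list(fit = fit, rss = rss, ll = ll, R = R, wy = wy, wX = wX)
  }

  if (identical(lambda, "estimated")) {
    opt <- stats::optimize(function(l) gls_at(l)$ll, c(0, 1), maximum = TRUE,
                           tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    ll <- vapply(cand, function(l) gls_at(l)$ll, numeric(1))
    lambda <- cand[which.max(ll)]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
  }
  g <- gls_at(lambda)
  beta <- g$fit$coefficients
  df <- n - p
  sigma2 <- g$rss / df
  XtX_inv <- chol2inv(qr.R(g$fit$qr))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  # whitened-scale R^2 against the GLS intercept-only model
  w1 <- backsolve(g$R, rep(1, n), transpose = TRUE)
  muhat <- sum(w1 * g$wy) / sum(w1^2)
  tss <- sum((g$wy - muhat * w1)^2)
  r2 <- 1 - g$rss / tss
  coef_tab <- data.frame(term = colnames(X), estimate = unname(beta),
                         se = unname(se), t = unname(tval), p = unname(pval),
                         row.names = NULL)
  structure(list(coefficients = coef_tab, lambda = lambda,
                 r_squared = r2, r_squared_scale = "gls-whitened",
                 n = n, df = df, loglik = g$ll,
                 residuals = stats::setNames(drop(y - X %*% beta), names(y))),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d, lambda = %.4f, R2[%s] = %.4f)\n",
              x$n, x$lambda, x$r_squared_scale, x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Graft species missing from a tree at the genus level
#'
#' Attaches each missing species inside the subtree of its genus: a random
#' congeneric tip is chosen (seeded) and the new species is bound to that
#' tip's terminal branch at a fixed fraction of its length, so repeated
#' grafts into one genus resolve randomly and an ultrametric input stays
#' ultrametric. Pruning the grafted tips recovers the original covariance
#' matrix exactly.
#'
#' @param tree An [ape::phylo] tree.
#' @param taxonomy `data.frame` with columns `species_id`, `genus`, covering
#'   the tree's tips and the missing species.
#' @param missing Character vector of species to add.
#' @param seed Integer seed controlling the random resolution.
#' @param stem_fraction Fraction of the chosen terminal branch at which the
#'   new node is inserted (default 0.1).
#' @return The extended tree.
#' @export
graft_missing_species <- function(tree, taxonomy, missing, seed,
                                  stem_fraction = 0.1) {
  if (length(missing) == 0) return(tree)
  stopifnot(all(c("species_id", "genus") %in% names(taxonomy)))
  genus_of <- stats::setNames(as.character(taxonomy$genus),
                              as.character(taxonomy$species_id))
  if (anyNA(genus_of[missing])) {
    stop("taxonomy lacks a genus for: ",
         paste(missing[is.na(genus_of[missing])], collapse = ", "))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  for (sp in missing) {
    gen <- genus_of[[sp]]
    congeners <- tree$tip.label[!is.na(genus_of[tree$tip.label]) &
                                  genus_of[tree$tip.label] == gen]
    if (length(congeners) == 0) stop("genus absent from tree: ", gen)
    target <- if (length(congeners) == 1) congeners else
      sample(congeners, 1)
    tip_idx <- match(target, tree$tip.label)
    edge_len <- tree$edge.length[tree$edge[, 2] == tip_idx]
    h <- stem_fraction * edge_len
    tree <- phytools::bind.tip(tree, sp, edge.length = h,
                               where = tip_idx, position = h)
  }
  tree
}
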