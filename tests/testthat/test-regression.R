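test_that("z-scaling round-trips and records its parameters", {
  set.seed(61)
  df <- data.frame(a = rnorm(20, 5, 2), b = runif(20, 0, 100), g = letters[1:20])
  zs <- zscale(df, c("a", "b"))
  expect_equal(colMeans(zs$data[, c("a", "b")]), c(a = 0, b = 0),
               tolerance = 1e-12)
  expect_equal(apply(zs$data[, c("a", "b")], 2, sd), c(a = 1, b = 1),
               tolerance = 1e-12)
  back <- unzscale(zs$data, zs$center, zs$scale)
  expect_equal(back$a, df$a, tolerance = 1e-12)
  expect_identical(zs$data$g, df$g)
})

test_that("OLS matches the normal equations", {
  set.seed(62)
  X <- cbind(a = rnorm(50), b = runif(50), c = rnorm(50, 2))
  y <- 1 + 2 * X[, "a"] - 0.5 * X[, "c"] + rnorm(50)
  fit <- ols_fit(y, X)
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(fit$coefficients$estimate, drop(beta), tolerance = 1e-10,
               ignore_attr = TRUE)
  rss <- sum((y - Xd %*% beta)^2)
  expect_equal(fit$r_squared, 1 - rss / sum((y - mean(y))^2),
               tolerance = 1e-12)
})

test_that("hierarchical partitioning equals the all-orderings brute force", {
  set.seed(63)
  for (i in 1:5) {
    n <- 40
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, c("w", "x", "y", "z")))
    X[, 2] <- X[, 1] * 0.6 + X[, 2] * 0.8     # induce collinearity
    resp <- X %*% c(1, -2, 0.5, 0) + rnorm(n)
    hp <- hierarchical_partitioning(resp, X)
    ref <- brute_force_hierpart(resp, X)
    expect_equal(hp$independent, ref, tolerance = 1e-10)
    expect_equal(sum(hp$independent), hp$r_squared_full, tolerance = 1e-10)
  }
})

test_that("orthogonal predictors partition into their marginal R-squared", {
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  y <- 2 * x1 + x2
  hp <- hierarchical_partitioning(y, cbind(a = x1, b = x2))
  r2a <- summary(lm(y ~ x1))$r.squared
  r2b <- summary(lm(y ~ x2))$r.squared
  expect_equal(unname(hp$independent), c(r2a, r2b), tolerance = 1e-10)
  expect_equal(hp$r_squared_full, 1, tolerance = 1e-10)
})

test_that("trend surface nests the linear model and absorbs a smooth field", {
  set.seed(64)
  g <- expand.grid(x = 1:18, y = 1:18)
  latent <- sin(g$x / 3) * cos(g$y / 4)          # smooth spatial signal
  a <- rnorm(nrow(g))
  resp <- 2 * a + 5 * latent + rnorm(nrow(g), 0, 0.2)
  lmf <- ols_fit(resp, cbind(a = a))
  gf <- trend_surface_fit(resp, cbind(a = a), g, k = 6)
  expect_gte(gf$r_squared, lmf$r_squared)
  est <- gf$coefficients$estimate[gf$coefficients$term == "a"]
  expect_equal(est, 2, tolerance = 0.1)
  expect_error(trend_surface_fit(resp[1:10], cbind(a = a[1:10]), g[1:10, ],
                                 k = 6), "basis larger")
})

test_that("grouped slopes equal separate per-group regressions", {
  set.seed(65)
  n <- 90
  grp <- rep(c("g1", "g2", "g3"), each = n / 3)
  X <- data.frame(a = rnorm(n), b = runif(n))
  slopes_a <- c(g1 = 1, g2 = -1, g3 = 0.5)
  y <- slopes_a[grp] * X$a + rnorm(n, 0, 0.3)
  fit <- grouped_interaction_fit(y, X, grp)
  zs <- zscale(X)
  for (g in unique(grp)) {
    i <- grp == g
    ref <- coef(lm(y[i] ~ a + b, data = zs$data[i, ]))
    got <- fit$slopes[fit$slopes$group == g, ]
    expect_equal(got$estimate[got$term == "a"], unname(ref["a"]),
                 tolerance = 1e-10)
    expect_equal(got$estimate[got$term == "b"], unname(ref["b"]),
                 tolerance = 1e-10)
  }
  expect_true(all(fit$slopes$ci_lo < fit$slopes$estimate))
  expect_true(all(fit$slopes$ci_hi > fit$slopes$estimate))
})

test_that("group size thresholds drop exactly the configured groups", {
  set.seed(66)
  sizes <- c(gA = 9L, gB = 10L, gC = 25L)
  grp <- rep(names(sizes), times = sizes)
  n <- length(grp)
  X <- data.frame(a = rnorm(n))
  y <- rnorm(n)
  fit <- grouped_interaction_fit(y, X, grp, min_group_size = 10)
  expect_identical(fit$excluded_groups$group, "gA")
  expect_identical(fit$excluded_groups$n, 9L)
  expect_identical(sort(unique(fit$slopes$group)), c("gB", "gC"))
  expect_identical(fit$n, 35L)
  expect_error(grouped_interaction_fit(y, X, grp, min_group_size = 100),
               "no groups left")
})

test_that("severity models apply the family threshold and recover the sign", {
  tr <- random_tree(80, 670)
  sp <- tr$tip.label
  set.seed(67)
  colour <- stats::setNames(rnorm(80, 150, 25), sp)
  evi <- stats::setNames(runif(80, 0.1, 0.9), sp)
  fams <- stats::setNames(rep(c("f1", "f2", "f3"), c(40, 32, 8)), sp)
  inter <- as.numeric(scale(colour)) * as.numeric(scale(evi))
  sev <- stats::setNames(pmax(0, round(2 + 1.5 * inter + rnorm(80, 0, 0.5))),
                         sp)
  out <- severity_models(sev, colour, evi, fams, tr, min_family_size = 9)
  expect_identical(out$excluded_families$family, "f3")
  expect_identical(sort(out$per_family$family), c("f1", "f2"))
  expect_true(all(out$per_family$estimate > 0))
  expect_gt(out$pgls$coefficients$estimate[
    out$pgls$coefficients$term == "colour_x_evi"], 0)
})

test_that("correlogram reproduces ape's Moran's I per distance class", {
  set.seed(68)
  g <- expand.grid(x = 1:10, y = 1:10)
  res <- g$x + rnorm(100, 0, 0.5)                 # strong spatial gradient
  cg <- morans_correlogram(res, g, n_classes = 5)
  D <- as.matrix(dist(g))
  for (i in seq_len(nrow(cg))) {
    W <- (D > cg$lower[i] & D <= cg$upper[i]) * 1
    diag(W) <- 0
    if (sum(W) == 0) next
    ref <- ape::Moran.I(res, W)
    expect_equal(cg$moran_i[i], ref$observed, tolerance = 1e-12)
    expect_equal(cg$p[i], ref$p.value, tolerance = 1e-12)
  }
  expect_gt(cg$moran_i[1], 0.5)                   # gradient: strong lag-1 I
  iid <- rnorm(100)
  cg0 <- morans_correlogram(iid, g, n_classes = 5)
  expect_lt(abs(cg0$moran_i[1]), 0.2)
})

test_that("the permutation band is seeded and brackets iid noise", {
  set.seed(69)
  g <- expand.grid(x = 1:8, y = 1:8)
  v <- rnorm(64)
  b1 <- moran_permutation_band(v, g, 0, 1.5, n_perm = 99, seed = 5)
  b2 <- moran_permutation_band(v, g, 0, 1.5, n_perm = 99, seed = 5)
  expect_identical(b1, b2)
  expect_lt(b1[[1]], 0)
  expect_gt(b1[[2]], 0)
  # iid values themselves fall inside their own null band almost surely
  D <- as.matrix(dist(g)); W <- (D > 0 & D <= 1.5) * 1; diag(W) <- 0
  i1 <- ape::Moran.I(v, W)$observed
  expect_gt(i1, b1[[1]] - 0.1)
  expect_lt(i1, b1[[2]] + 0.1)
})
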