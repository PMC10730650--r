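test_that("covariance matrix matches the per-pair MRCA brute force", {
  for (seed in 1:20) {
    n <- 10 + (seed %% 21)
    tr <- random_tree(n, seed)
    expect_equal(vcv_from_tree(tr), brute_force_vcv(tr), tolerance = 1e-12)
  }
  expect_error(vcv_from_tree(ape::rtree(5, br = NULL)), "branch lengths")
})

test_that("lambda transform hits its endpoints", {
  tr <- random_tree(12, 3)
  C <- vcv_from_tree(tr)
  expect_identical(lambda_transform(C, 1), C)
  V0 <- lambda_transform(C, 0)
  expect_equal(V0, diag(diag(C)), ignore_attr = TRUE)
  V <- lambda_transform(C, 0.3)
  expect_equal(diag(V), diag(C))
  expect_error(lambda_transform(C, 1.2), "lambda")
})

test_that("lambda log-likelihood equals the dense density", {
  for (seed in 1:10) {
    n <- 3 + (seed %% 4)
    tr <- random_tree(n, 100 + seed)
    C <- vcv_from_tree(tr)
    y <- simulate_lambda_trait(tr, 0.5, seed = seed)
    for (lam in c(0, 0.5, 1)) {
      got <- pagel_loglik(unname(y), C, lam, mu = 2, sigma2 = 3)
      ref <- dense_mvn_loglik(unname(y), C, lam, mu = 2, sigma2 = 3)
      expect_equal(got$loglik, ref, tolerance = 1e-8)
      # the profiled mu/sigma2 cannot beat the dense density anywhere else
      prof <- pagel_loglik(unname(y), C, lam)
      expect_gte(prof$loglik + 1e-10,
                 dense_mvn_loglik(unname(y), C, lam, prof$mu, prof$sigma2))
    }
  }
})

test_that("lambda fit is sane at the generating extremes", {
  tr <- random_tree(150, 5)
  y0 <- simulate_lambda_trait(tr, 0, seed = 21)
  y1 <- simulate_lambda_trait(tr, 1, seed = 22)
  f0 <- fit_pagel_lambda(y0, tr, quiet = TRUE)
  f1 <- fit_pagel_lambda(y1, tr, quiet = TRUE)
  expect_lt(f0$lambda, 0.2)
  expect_gt(f1$lambda, 0.8)
  expect_true(f0$identifiable && f1$identifiable)
})

test_that("star phylogeny is flagged unidentifiable", {
  # an effectively star-shaped tree: all internal branches collapsed to 0,
  # so every off-diagonal covariance vanishes
  star <- random_tree(8, 55)
  tip_edge <- star$edge[, 2] <= ape::Ntip(star)
  star$edge.length[!tip_edge] <- 0
  star$edge.length[tip_edge] <- 1
  y <- stats::setNames(rnorm(8), star$tip.label)
  f <- fit_pagel_lambda(y, star, quiet = TRUE)
  expect_false(f$identifiable)
  expect_identical(f$lambda, 0)
})

test_that("trait/tree alignment prunes both sides with a message", {
  tr <- random_tree(10, 9)
  y <- stats::setNames(rnorm(12), c(tr$tip.label[1:8], "x1", "x2",
                                    "x3", "x4"))
  expect_message(al <- froglight:::align_trait_tree(y, tr), "pruned")
  expect_identical(al$n_dropped_trait, 4L)
  expect_identical(al$n_dropped_tips, 2L)
  expect_identical(names(al$y), al$tree$tip.label)
})

test_that("PGLS at lambda = 0 reproduces ordinary least squares", {
  tr <- random_tree(40, 17)
  set.seed(18)
  X <- cbind(a = rnorm(40), b = runif(40))
  y <- stats::setNames(1 + 2 * X[, "a"] - X[, "b"] + rnorm(40),
                       tr$tip.label)
  pg <- pgls_fit(y, X, tr, lambda = 0, quiet = TRUE)
  ols <- summary(lm(unname(y) ~ X))$coefficients
  expect_equal(pg$coefficients$estimate, unname(ols[, 1]), tolerance = 1e-10)
  expect_equal(pg$coefficients$se, unname(ols[, 2]), tolerance = 1e-10)
  expect_equal(pg$coefficients$p, unname(ols[, 4]), tolerance = 1e-10)
})

test_that("PGLS at lambda = 1 reproduces the closed-form GLS", {
  tr <- random_tree(30, 23)
  set.seed(24)
  X <- cbind(a = rnorm(30))
  y <- simulate_lambda_trait(tr, 1, seed = 25) + 0.5 * X[, "a"]
  pg <- pgls_fit(y, X, tr, lambda = 1, quiet = TRUE)
  C <- vcv_from_tree(tr)
  Xd <- cbind(1, X[match(names(pg$residuals), tr$tip.label), , drop = FALSE])
  Ci <- solve(C)
  beta <- solve(t(Xd) %*% Ci %*% Xd, t(Xd) %*% Ci %*% y[rownames(C)])
  expect_equal(pg$coefficients$estimate, drop(beta), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PGLS agrees with nlme::gls under a fixed Pagel correlation", {
  tr <- random_tree(35, 29)
  set.seed(30)
  X <- cbind(a = rnorm(35))
  y <- simulate_lambda_trait(tr, 0.6, seed = 31) + X[, "a"]
  pg <- pgls_fit(y, X, tr, lambda = 0.6, quiet = TRUE)
  dat <- data.frame(y = unname(y[tr$tip.label]), a = X[, "a"],
                    row.names = tr$tip.label)
  gf <- nlme::gls(y ~ a, data = dat,
                  correlation = ape::corPagel(0.6, tr, fixed = TRUE))
  expect_equal(pg$coefficients$estimate, unname(coef(gf)), tolerance = 1e-6)
})

test_that("grafting is seeded, reversible and keeps ultrametricity", {
  tr <- random_tree(20, 33)
  taxonomy <- data.frame(
    species_id = c(tr$tip.label, "new1", "new2"),
    genus = c(rep(c("gA", "gB"), each = 10), "gA", "gB"))
  g1 <- graft_missing_species(tr, taxonomy, c("new1", "new2"), seed = 4)
  g2 <- graft_missing_species(tr, taxonomy, c("new1", "new2"), seed = 4)
  g3 <- graft_missing_species(tr, taxonomy, c("new1", "new2"), seed = 5)
  expect_identical(ape::write.tree(g1), ape::write.tree(g2))
  expect_false(identical(ape::write.tree(g1), ape::write.tree(g3)))
  expect_identical(ape::Ntip(g1), 22L)
  expect_true(ape::is.ultrametric(g1, tol = 1e-8))
  # pruning the grafts recovers the original covariance exactly
  back <- ape::drop.tip(g1, c("new1", "new2"))
  C0 <- vcv_from_tree(tr)
  C1 <- vcv_from_tree(back)[rownames(C0), colnames(C0)]
  expect_equal(C1, C0, tolerance = 1e-9)
  # no-op and error paths
  expect_identical(graft_missing_species(tr, taxonomy, character(0), 1), tr)
  bad_tax <- data.frame(species_id = "new3", genus = "gZ")
  expect_error(graft_missing_species(tr, bad_tax, "new3", 1),
               "genus absent")
})
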