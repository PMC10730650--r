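#' Scale and centre predictor columns
#'
#' z-scales the named columns of a data frame, keeping the means and
#' standard deviations so fits can be back-transformed.
#'
#' @param data `data.frame`.
#' @param cols Columns to scale (default: all numeric columns).
#' @return List with `data` (scaled copy), `center`, `scale` (named
#'   vectors).
#' @export
zscale <- function(data, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  ctr <- vapply(cols, function(v) mean(data[[v]]), numeric(1))
  scl <- vapply(cols, function(v) stats::sd(data[[v]]), numeric(1))
  if (any(scl <= 0 | !is.finite(scl))) {
    stop("constant column(s): ", paste(cols[scl <= 0], collapse = ", "))
  }
  for (v in cols) data[[v]] <- (data[[v]] - ctr[[v]]) / scl[[v]]
  list(data = data, center = ctr, scale = scl)
}

#' Invert a z-scaling
#'
#' @param data Scaled `data.frame` (from [zscale()]).
#' @param center,scale Named vectors stored by [zscale()].
#' @return Data frame on the original scale.
#' @export
unzscale <- function(data, center, scale) {
  for (v in names(center)) data[[v]] <- data[[v]] * scale[[v]] + center[[v]]
  data
}

#' Multiple linear regression with two-sided t tests
#'
#' Ordinary (optionally weighted) least squares with an intercept,
#' reporting slopes, standard errors, two-sided t statistics and P values,
#' and R-squared — the summary used for all assemblage-level linear models.
#'
#' @param y Response vector.
#' @param X Matrix or `data.frame` of predictors with named columns.
#' @param weights Optional observation weights.
#' @return Object of class `froglight_lm`: list with `coefficients`
#'   (data.frame `term`, `estimate`, `se`, `t`, `p`), `r_squared`,
#'   `adj_r_squared`, `n`, `residuals`, `fitted`, and the underlying `fit`.
#' @export
ols_fit <- function(y, X, weights = NULL) {
  X <- as.data.frame(X)
  stopifnot(!is.null(names(X)), nrow(X) == length(y))
  dat <- cbind(data.frame(.y = y), X)
  fml <- stats::reformulate(names(X), response = ".y")
  fit <- if (is.null(weights)) stats::lm(fml, data = dat) else
    stats::lm(fml, data = dat, weights = weights)
  if (fit$rank < ncol(X) + 1) stop("design matrix is rank deficient")
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(ct), estimate = ct[, 1],
                              se = ct[, 2], t = ct[, 3], p = ct[, 4],
                              row.names = NULL),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    n = length(y), residuals = stats::residuals(fit),
    fitted = stats::fitted(fit), fit = fit), class = "froglight_lm")
}

#' @export
print.froglight_lm <- function(x, ...) {
  cat(sprintf("Linear model (n = %d, R2 = %.4f, adj. R2 = %.4f)\n",
              x$n, x$r_squared, x$adj_r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Trend-surface regression
#'
#' Linear environmental terms plus a tensor-product smooth of the
#' geographic coordinates, fitted with [mgcv::gam] and GCV smoothness
#' selection. The smooth absorbs latent spatially autocorrelated variation
#' so the linear terms are interpreted net of broad-scale geographic trend.
#' Because the smooth's penalty null space nests the model without a
#' surface, the trend-surface R-squared is never below the plain linear
#' model's on the same data.
#'
#' @param y Response vector.
#' @param X Matrix or `data.frame` of linear predictors.
#' @param coords Two-column matrix or `data.frame` of coordinates.
#' @param k Basis dimension per coordinate axis. The default of 13 is
#'   chosen so that, on the default 50 x 50 study grid, knot spacing
#'   (about 4 cells) matches the autocorrelation range of the simulated
#'   environmental fields: the surface can then absorb latent structure
#'   down to the finest scale at which the generator produces it.
#' @param bs Spline basis for the marginal smooths (default cubic
#'   regression splines, `"cr"`).
#' @return Object of class `froglight_gam`: `coefficients` (linear terms:
#'   `term`, `estimate`, `se`, `t`, `p`), `edf_surface`, `sp`,
#'   `r_squared` (1 - RSS/TSS on the response scale), `n`, `residuals`,
#'   `fitted`, and the `fit`.
#' @export
trend_surface_fit <- function(y, X, coords, k = 13, bs = "cr") {
  X <- as.data.frame(X)
  coords <- as.data.frame(coords)
  stopifnot(ncol(coords) == 2, nrow(X) == length(y),
            nrow(coords) == length(y))
  names(coords) <- c(".cx", ".cy")
  if (length(y) <= k * k + ncol(X) + 1) stop("basis larger than sample size")
  dat <- cbind(data.frame(.y = y), X, coords)
  fml <- stats::as.formula(paste(
    ".y ~", paste(names(X), collapse = " + "),
    sprintf("+ te(.cx, .cy, k = c(%d, %d), bs = '%s')", k, k, bs)))
  fit <- mgcv::gam(fml, data = dat, method = "GCV.Cp")
  sm <- summary(fit)
  pt <- sm$p.table
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    coefficients = data.frame(term = rownames(pt), estimate = pt[, 1],
                              se = pt[, 2], t = pt[, 3], p = pt[, 4],
                              row.names = NULL),
    edf_surface = sum(sm$edf), sp = unname(fit$sp),
    r_squared = 1 - rss / tss, n = length(y),
    residuals = stats::residuals(fit), fitted = stats::fitted(fit),
    fit = fit), class = "froglight_gam")
}

#' @export
print.froglight_gam <- function(x, ...) {
  cat(sprintf("Trend-surface model (n = %d, R2 = %.4f, surface edf = %.2f)\n",
              x$n, x$r_squared, x$edf_surface))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# R-squared of the OLS of y on the subset of columns in `X` indexed by
# `idx` (with intercept). Empty subset has R-squared 0.
subset_r2 <- function(y, X, idx) {
  if (length(idx) == 0) return(0)
  f <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

#' Hierarchical partitioning of R-squared
#'
#' Decomposes the full-model R-squared into the independent contribution of
#' each predictor: the average, over all orderings of the predictors, of
#' the increase in R-squared when the predictor enters the model
#' (equivalently the level-weighted average over all subsets). The
#' contributions sum exactly to the full-model R-squared.
#'
#' @param y Response vector.
#' @param X Matrix or `data.frame` of predictors (at most `max_k` columns).
#' @param max_k Combinatorial guard on the number of predictors (default 8).
#' @return Object of class `hier_part`: `independent` (named vector of
#'   contributions, R-squared units), `share` (contributions normalised to
#'   sum 1), `r_squared_full`, `n`.
#' @export
hierarchical_partitioning <- function(y, X, max_k = 8) {
  X <- as.matrix(as.data.frame(X))
  k <- ncol(X)
  if (k < 1) stop("need at least one predictor")
  if (k > max_k) stop("more than ", max_k, " predictors; raise max_k if intended")
  subsets <- lapply(0:(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  r2 <- vapply(subsets, function(s) subset_r2(y, X, s), numeric(1))
  names(r2) <- vapply(subsets, function(s) paste(s, collapse = ","), character(1))
  key <- function(s) paste(s, collapse = ",")
  ic <- numeric(k)
  for (j in seq_len(k)) {
    for (i in seq_along(subsets)) {
      s <- subsets[[i]]
      if (j %in% s) next
      size <- length(s)
      w <- factorial(size) * factorial(k - 1 - size) / factorial(k)
      ic[j] <- ic[j] + w * (r2[[key(sort(c(s, j)))]] - r2[[i]])
    }
  }
  names(ic) <- colnames(X)
  full <- r2[[key(seq_len(k))]]
  structure(list(independent = ic, share = ic / sum(ic),
                 r_squared_full = full, n = length(y)),
            class = "hier_part")
}

#' @export
print.hier_part <- function(x, ...) {
  cat(sprintf("Hierarchical partitioning (full R2 = %.4f)\n", x$r_squared_full))
  print(round(rbind(independent = x$independent, share = x$share), 4))
  invisible(x)
}

#' Per-group slopes from a full-interaction model
#'
#' Fits one intercept and one slope per (predictor, group) in a single
#' cell-means parameterisation `y ~ 0 + group + group:predictor...`, after
#' z-scaling the predictors, excluding groups below a size threshold. Used
#' for the realm-level and family-level interaction models.
#'
#' @param y Response vector.
#' @param X Matrix or `data.frame` of predictors.
#' @param groups Group labels (realm or family), same length as `y`.
#' @param min_group_size Groups with fewer observations are excluded and
#'   listed in the result (use `> 50` assemblages for realms, `>= 10`
#'   species for families by passing 51 or 10).
#' @param z Significance multiplier for the confidence limits (default
#'   1.96, the normal approximation).
#' @return Object of class `grouped_fit`: `slopes` (data.frame `group`,
#'   `term`, `estimate`, `se`, `ci_lo`, `ci_hi`, `t`, `p`),
#'   `intercepts`, `r_squared`, `n`, `excluded_groups` (data.frame with
#'   sizes), `scaling` (centres/scales used).
#' @export
grouped_interaction_fit <- function(y, X, groups, min_group_size = 1,
                                    z = 1.96) {
  X <- as.data.frame(X)
  groups <- as.character(groups)
  stopifnot(length(groups) == length(y), nrow(X) == length(y))
  sizes <- table(groups)
  small <- names(sizes)[sizes < min_group_size]
  keep <- !(groups %in% small)
  if (sum(keep) == 0 || length(unique(groups[keep])) == 0) {
    stop("no groups left after size filtering")
  }
  excluded <- data.frame(group = small,
                         n = as.integer(sizes[small]),
                         reason = rep("below min_group_size", length(small)))
  zs <- zscale(X[keep, , drop = FALSE])
  dat <- cbind(data.frame(.y = y[keep],
                          .g = factor(groups[keep])), zs$data)
  terms <- names(X)
  # with a single surviving group the factor parameterisation is
  # degenerate; fall back to a plain regression labelled with that group
  fml <- if (nlevels(dat$.g) == 1) {
    stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  } else {
    stats::as.formula(paste(
      ".y ~ 0 + .g +", paste(sprintf(".g:%s", terms), collapse = " + ")))
  }
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  ct <- sm$coefficients
  rn <- rownames(ct)
  if (nlevels(dat$.g) == 1) {
    is_slope <- rn != "(Intercept)"
    parse_grp <- rep(levels(dat$.g), length(rn))
    parse_term <- rn
  } else {
    is_slope <- grepl(":", rn, fixed = TRUE)
    parse_grp <- sub("^\\.g", "", sub(":.*$", "", rn))
    parse_term <- sub("^.*:", "", rn)
  }
  slopes <- data.frame(group = parse_grp[is_slope],
                       term = parse_term[is_slope],
                       estimate = ct[is_slope, 1], se = ct[is_slope, 2],
                       t = ct[is_slope, 3], p = ct[is_slope, 4],
                       row.names = NULL)
  slopes$ci_lo <- slopes$estimate - z * slopes$se
  slopes$ci_hi <- slopes$estimate + z * slopes$se
  slopes <- slopes[order(slopes$group, slopes$term),
                   c("group", "term", "estimate", "se", "ci_lo", "ci_hi",
                     "t", "p")]
  intercepts <- data.frame(group = parse_grp[!is_slope],
                           estimate = ct[!is_slope, 1],
                           se = ct[!is_slope, 2], row.names = NULL)
  # R2 against the grand mean (the 0-intercept parameterisation still nests it)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((dat$.y - mean(dat$.y))^2)
  structure(list(slopes = slopes, intercepts = intercepts, r_squared = r2,
                 n = sum(keep), excluded_groups = excluded,
                 scaling = list(center = zs$center, scale = zs$scale),
                 fit = fit), class = "grouped_fit")
}

#' @export
print.grouped_fit <- function(x, ...) {
  cat(sprintf("Grouped interaction model (n = %d, R2 = %.4f, %d group(s) excluded)\n",
              x$n, x$r_squared, nrow(x$excluded_groups)))
  print(x$slopes, digits = 4)
  invisible(x)
}

#' Chytridiomycosis severity models
#'
#' Per-family ordinary regressions of infection severity on the interaction
#' of colour lightness and productivity (both z-scaled), plus an overall
#' PGLS with the phylogenetic signal strength estimated by maximum
#' likelihood. Severity is coded numerically with unaffected co-occurring
#' species as 0. Families below the size threshold are excluded.
#'
#' @param severity Named numeric vector (names are species ids).
#' @param colour Named colour-lightness vector covering the same species.
#' @param evi Named productivity (range-mean EVI) vector.
#' @param families Named family labels.
#' @param tree Phylogeny covering the species (for the PGLS).
#' @param min_family_size Families with fewer species are excluded
#'   (default 9, i.e. "fewer than 9" drop).
#' @return List with `per_family` (data.frame `family`, `n`, `estimate`,
#'   `se`, `t`, `p`, `r_squared`), `excluded_families`, and `pgls`
#'   (a [pgls_fit()] result for `severity ~ colour:EVI`).
#' @export
severity_models <- function(severity, colour, evi, families, tree,
                            min_family_size = 9) {
  sp <- names(severity)
  stopifnot(!is.null(sp), all(sp %in% names(colour)),
            all(sp %in% names(evi)), all(sp %in% names(families)))
  zc <- as.numeric(scale(colour[sp]))
  ze <- as.numeric(scale(evi[sp]))
  inter <- zc * ze
  fam <- as.character(families[sp])
  sizes <- table(fam)
  small <- names(sizes)[sizes < min_family_size]
  per_family <- do.call(rbind, lapply(sort(setdiff(names(sizes), small)),
                                      function(f) {
    i <- fam == f
    if (stats::var(inter[i]) == 0) {
      return(data.frame(family = f, n = sum(i), estimate = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        r_squared = NA_real_))
    }
    m <- ols_fit(severity[sp][i], data.frame(colour_x_evi = inter[i]))
    data.frame(family = f, n = sum(i),
               estimate = m$coefficients$estimate[2],
               se = m$coefficients$se[2], t = m$coefficients$t[2],
               p = m$coefficients$p[2], r_squared = m$r_squared)
  }))
  pg <- pgls_fit(severity, cbind(colour_x_evi = inter), tree,
                 lambda = "estimated", quiet = TRUE)
  list(per_family = per_family,
       excluded_families = data.frame(family = small,
                                      n = as.integer(sizes[small]),
                                      reason = "below min_family_size"),
       pgls = pg)
}

# Binary spatial weight matrix for pairs whose distance lies in (lo, hi].
class_weights <- function(D, lo, hi) {
  W <- (D > lo & D <= hi) * 1
  diag(W) <- 0
  W
}

#' Moran's I correlogram of model residuals
#'
#' Moran's I in equal-width distance classes with binary within-class
#' weights; the expected value under no autocorrelation, -1/(n-1), is
#' attached to every class.
#'
#' @param residuals Numeric vector.
#' @param coords Two-column coordinates.
#' @param n_classes Number of equal-width distance classes (default 10).
#' @param max_distance Upper bound of the last class (default: the maximum
#'   pairwise distance).
#' @return `data.frame` with `class`, `lower`, `upper`, `moran_i`,
#'   `expected`, `sd`, `p`, `n_pairs` (classes with no pairs carry NA).
#' @export
morans_correlogram <- function(residuals, coords, n_classes = 10,
                               max_distance = NULL) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  stopifnot(nrow(coords) == n, n >= 2)
  if (stats::var(residuals) == 0) stop("residuals are constant")
  D <- as.matrix(stats::dist(coords))
  if (is.null(max_distance)) max_distance <- max(D)
  breaks <- seq(0, max_distance, length.out = n_classes + 1)
  out <- lapply(seq_len(n_classes), function(i) {
    W <- class_weights(D, breaks[i], breaks[i + 1])
    npairs <- sum(W) / 2
    if (npairs < 1) {
      return(data.frame(class = i, lower = breaks[i], upper = breaks[i + 1],
                        moran_i = NA_real_, expected = -1 / (n - 1),
                        sd = NA_real_, p = NA_real_, n_pairs = 0))
    }
    mi <- ape::Moran.I(residuals, W)
    data.frame(class = i, lower = breaks[i], upper = breaks[i + 1],
               moran_i = mi$observed, expected = mi$expected, sd = mi$sd,
               p = mi$p.value, n_pairs = npairs)
  })
  do.call(rbind, out)
}

#' Permutation null band for first-class Moran's I
#'
#' Empirical quantile band of Moran's I in a given distance class under
#' random permutation of the values across locations.
#'
#' @param values Numeric vector.
#' @param coords Two-column coordinates.
#' @param lower,upper Distance-class bounds (pairs with `lower < d <=
#'   upper`).
#' @param n_perm Number of permutations (default 199).
#' @param seed RNG seed.
#' @param probs Band quantiles (default central 95%).
#' @return Named numeric vector of the band quantiles.
#' @export
moran_permutation_band <- function(values, coords, lower, upper,
                                   n_perm = 199, seed = 1,
                                   probs = c(0.025, 0.975)) {
  D <- as.matrix(stats::dist(as.matrix(coords)))
  W <- class_weights(D, lower, upper)
  n <- length(values)
  xs <- values - mean(values)
  s2 <- sum(xs^2)
  sw <- sum(W)
  stat <- function(x) {
    xc <- x - mean(x)
    (n / sw) * sum(W * tcrossprod(xc)) / sum(xc^2)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sims <- vapply(seq_len(n_perm), function(i) stat(sample(values)),
                 numeric(1))
  stats::quantile(sims, probs)
}
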