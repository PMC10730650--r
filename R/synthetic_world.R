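# Run an expression with a temporary RNG seed, restoring the caller's
# random-number state afterwards.
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stage seed derived from the master seed (kept below
# 2^31 - 1 so it is always a valid integer seed).
stage_seed <- function(seed, stage) {
  as.integer(((seed %% 2147483647) * 7919 + stage * 104729) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

gauss_kernel <- function(range) {
  r <- max(1L, ceiling(3 * range))
  x <- (-r):r
  k <- exp(-0.5 * (x / range)^2)
  k / sum(k)
}

conv1 <- function(v, k) {
  r <- (length(k) - 1) / 2
  n <- length(v)
  vp <- c(rep(v[1], r), v, rep(v[n], r))
  as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
}

# Spatially autocorrelated Gaussian field: white noise smoothed with a
# separable Gaussian kernel, standardised to mean 0 / sd 1. Returns an
# ny x nx matrix; consumes nx*ny normal draws from the current RNG stream.
smooth_field <- function(nx, ny, range) {
  z <- matrix(stats::rnorm(nx * ny), nrow = ny, ncol = nx)
  k <- gauss_kernel(range)
  z <- apply(z, 2, conv1, k = k)
  z <- t(apply(z, 1, conv1, k = k))
  (z - mean(z)) / stats::sd(as.numeric(z))
}

#' Configuration of a synthetic world
#'
#' Returns the default configuration of the synthetic-world generator,
#' optionally overriding entries. The defaults describe the study
#' conditions the rest of the package is exercised under: a 50 x 50
#' planar equal-area grid with a quartic latitudinal temperature profile
#' (flat tropics, steep temperate zone), productivity coupled to
#' temperature with extra tropical variation, UVB peaking at the equator
#' and rising with elevation, four latitudinal realm bands, a 300-tip
#' birth-death phylogeny, a lightness trait built from phylogenetically
#' conserved thermal/productivity/UVB niches plus a lambda-damped Brownian
#' deviation and iid noise, niche-based contiguous ranges, and wheel-coded
#' observations averaging 1.4 individuals per species.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `world_config`.
#' @export
world_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # grid and environment
    grid_nx = 50L, grid_ny = 50L, smooth_range = 4,
    mat_equator = 27, mat_lat_drop = 29, mat_noise_sd = 2,
    elev_mean = 800, elev_sd = 500,
    evi_mean = 0.45, evi_sd = 0.18, evi_mat_cor = 0.5,
    evi_noise_base = 0.3, evi_noise_tropical = 1.2,
    uvb_base = 3200, uvb_equator_gain = 2800, uvb_elev_coef = 0.5,
    uvb_noise_sd = 150,
    n_realm_bands = 4L,
    water_border_width = 3L, water_border_prob = 1,
    water_border_range = c(0.55, 0.95), water_inside_max = 0.25,
    # tree, taxonomy and trait
    n_species = 300L, birth = 1, death = 0,
    genus_height = 0.15, family_height = 0.45,
    base_lightness = 165,
    beta_mat = 20, beta_evi = -10, beta_uvb = -8, beta_elev = 0,
    sigma2_phylo = 100, sigma2_resid = 64, lambda = 0.5,
    uvb_niche_sd = 400,
    # ranges
    breadth_mat = 5, breadth_evi = 0.30, breadth_uvb = 1500,
    range_retries = 3L, breadth_widen = 1.5,
    # observations
    extra_individual_rate = 0.4, observer_noise_sd = 5,
    quantise = TRUE, missingness = 0.1, value_channel = 1,
    tree_missing_fraction = 0.05,
    # observer calibration pairs
    calib_n_species = 100L, calib_slope = 0.6, calib_intercept = 24.45,
    calib_noise_sd = 10,
    # activity and chytrid severity
    activity_classes = c("diurnal", "nocturnal", "both"),
    activity_probs = c(0.15, 0.6, 0.25),
    affected_fraction = 0.25, severity_interaction = 0.8,
    severity_noise_sd = 1, severity_levels = 5L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$lambda >= 0, cfg$lambda <= 1, cfg$sigma2_phylo >= 0,
            cfg$sigma2_resid >= 0, cfg$missingness >= 0, cfg$missingness < 1)
  structure(cfg, class = c("world_config", "list"))
}

# Deterministic (noise-free) environment profiles used to calibrate the
# species niches against the grid without consuming RNG draws.
env_profile <- function(config) {
  ny <- config$grid_ny
  lat <- (seq_len(ny) - (ny + 1) / 2) / ((ny - 1) / 2)
  mat_det <- config$mat_equator - config$mat_lat_drop * lat^4
  list(lat = lat, mat_det = mat_det,
       mat_mean = mean(mat_det), mat_sd = stats::sd(mat_det),
       mat_min = min(mat_det), mat_max = max(mat_det))
}

#' Simulate the environmental grid
#'
#' Generates per-cell mean annual temperature (quartic latitudinal profile
#' plus a smooth field), elevation (independent smooth field), EVI (coupled
#' to temperature at the configured correlation, with stronger independent
#' variation in the tropics), UVB (equatorial peak plus elevation effect),
#' latitudinal realm bands and a border water mask.
#'
#' @param config A [world_config()].
#' @return `data.frame` of grid cells: `cell_id`, `x`, `y`, `lat`,
#'   `water_fraction`, `realm`, `MAT`, `elevation`, `EVI`, `UVB`.
#' @export
simulate_environment <- function(config) {
  nx <- config$grid_nx; ny <- config$grid_ny
  with_seed(stage_seed(config$seed, 1L), {
    g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
    lat <- (g$y - (ny + 1) / 2) / ((ny - 1) / 2)
    G1 <- as.numeric(t(smooth_field(nx, ny, config$smooth_range)))
    G2 <- as.numeric(t(smooth_field(nx, ny, config$smooth_range)))
    G3 <- as.numeric(t(smooth_field(nx, ny, config$smooth_range)))
    G4 <- as.numeric(t(smooth_field(nx, ny, config$smooth_range)))
    # fields are ny x nx (row = y); t() flattens them in x-major order to
    # match expand.grid(x, y)
    MAT <- config$mat_equator - config$mat_lat_drop * lat^4 +
      config$mat_noise_sd * G1
    elevation <- pmax(0, config$elev_mean + config$elev_sd * G2)
    zmat <- as.numeric(scale(MAT))
    amp <- sqrt(config$evi_noise_base^2 +
                  config$evi_noise_tropical^2 * (1 - lat^2))
    z2 <- G3 * amp
    # orthogonalise the independent component against MAT so the realised
    # MAT-EVI correlation equals the configured one (up to clamping)
    z2 <- stats::residuals(stats::lm(z2 ~ zmat))
    z2 <- as.numeric(z2 - mean(z2)) / stats::sd(z2)
    rho <- config$evi_mat_cor
    EVI <- clamp(config$evi_mean +
                   config$evi_sd * (rho * zmat + sqrt(1 - rho^2) * z2),
                 0.01, 0.99)
    UVB <- config$uvb_base + config$uvb_equator_gain * exp(-2 * lat^2) +
      config$uvb_elev_coef * (elevation - config$elev_mean) +
      config$uvb_noise_sd * G4
    band <- ceiling(g$y / (ny / config$n_realm_bands))
    realm <- sprintf("realm%d", pmin(band, config$n_realm_bands))
    w <- config$water_border_width
    border <- g$x <= w | g$x > nx - w | g$y <= w | g$y > ny - w
    is_water <- border & stats::runif(nrow(g)) <= config$water_border_prob
    wf <- stats::runif(nrow(g), 0, config$water_inside_max)
    wf[is_water] <- stats::runif(sum(is_water), config$water_border_range[1],
                                 config$water_border_range[2])
    data.frame(cell_id = sprintf("c%05d", seq_len(nrow(g))),
               x = g$x, y = g$y, lat = lat, water_fraction = wf,
               realm = realm, MAT = MAT, elevation = elevation,
               EVI = EVI, UVB = UVB, stringsAsFactors = FALSE)
  })
}

# Assign tips to clades by slicing an ultrametric tree at a given height
# above the present; tips whose paths coalesce below the slice share a
# group.
slice_groups <- function(tree, height) {
  bt <- ape::branching.times(tree)
  n <- ape::Ntip(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  grp <- integer(n)
  for (i in seq_len(n)) {
    node <- i
    repeat {
      p <- parent[node]
      if (p == 0) break
      if (bt[as.character(p)] > height) break
      node <- p
    }
    grp[i] <- node
  }
  match(grp, unique(grp))
}

#' Simulate the phylogeny, taxonomy and the true colour-lightness trait
#'
#' Grows a birth-death tree rescaled to unit height, derives a genus- and
#' family-level taxonomy by slicing the tree at fixed heights, evolves
#' thermal, productivity and UVB niche centres as (transformed) Brownian
#' motion, and constructs the true lightness as a linear combination of the
#' z-scaled niches plus a lambda-damped Brownian phylogenetic deviation and
#' iid species-specific noise, clipped to the default wheel's lightness
#' span.
#'
#' @param config A [world_config()].
#' @return List with `tree`, `taxonomy` (`species_id`, `genus`, `family`),
#'   `traits` (`species_id`, `true_lightness`, `tniche`, `pniche`,
#'   `uniche`, `clipped`), `clip_fraction`, `lambda_trait_expected` (the
#'   trait-level signal implied by the variance mix; the configured
#'   `lambda` applies to the deviation component alone).
#' @export
simulate_tree_and_traits <- function(config) {
  n <- config$n_species
  if (n < 10) stop("need at least 10 species")
  with_seed(stage_seed(config$seed, 2L), {
    tree <- ape::rphylo(n, birth = config$birth, death = config$death)
    tree$tip.label <- sprintf("sp%04d", seq_len(n))
    h <- max(ape::branching.times(tree))
    tree$edge.length <- tree$edge.length / h
    C <- vcv_from_tree(tree)
    C <- C[tree$tip.label, tree$tip.label]
    R <- chol(C)
    bm <- function() {
      v <- drop(t(R) %*% stats::rnorm(n))
      (v - mean(v)) / stats::sd(v)
    }
    prof <- env_profile(config)
    b1 <- bm(); b2 <- bm(); b3 <- bm(); b4 <- bm()
    tniche <- prof$mat_min + (prof$mat_max - prof$mat_min) * stats::pnorm(b1)
    zmat_sp <- (tniche - prof$mat_mean) / prof$mat_sd
    rho <- config$evi_mat_cor
    pniche <- clamp(config$evi_mean +
                      config$evi_sd * (rho * zmat_sp + sqrt(1 - rho^2) * b2),
                    0.02, 0.98)
    lat_sp <- clamp(((config$mat_equator - tniche) /
                       config$mat_lat_drop)^(1 / 4), 0, 1)
    uniche <- config$uvb_base +
      config$uvb_equator_gain * exp(-2 * lat_sp^2) +
      config$uvb_niche_sd * b3
    env_part <- config$beta_mat * as.numeric(scale(tniche)) +
      config$beta_evi * as.numeric(scale(pniche)) +
      config$beta_uvb * as.numeric(scale(uniche)) +
      config$beta_elev * b4
    a <- if (config$sigma2_phylo > 0) {
      Vl <- lambda_transform(C, config$lambda)
      drop(t(chol(Vl)) %*% stats::rnorm(n)) * sqrt(config$sigma2_phylo)
    } else rep(0, n)
    e <- stats::rnorm(n, 0, sqrt(config$sigma2_resid))
    L <- config$base_lightness + env_part + a + e
    wheel <- build_default_wheel(config$value_channel)
    span <- range(wheel_lightness(wheel))
    clipped <- L < span[1] | L > span[2]
    L <- clamp(L, span[1], span[2])
    v_env <- stats::var(env_part)
    lambda_eff <- (v_env + config$lambda * config$sigma2_phylo) /
      (v_env + config$sigma2_phylo + config$sigma2_resid)
    gidx <- slice_groups(tree, config$genus_height)
    fidx <- slice_groups(tree, config$family_height)
    taxonomy <- data.frame(species_id = tree$tip.label,
                           genus = sprintf("gen%03d", gidx),
                           family = sprintf("fam%02d", fidx),
                           stringsAsFactors = FALSE)
    traits <- data.frame(species_id = tree$tip.label, true_lightness = L,
                         tniche = tniche, pniche = pniche, uniche = uniche,
                         clipped = clipped, stringsAsFactors = FALSE)
    list(tree = tree, taxonomy = taxonomy, traits = traits,
         clip_fraction = mean(clipped),
         lambda_trait_expected = lambda_eff)
  })
}

# Flood fill (4-neighbourhood) of eligible cells starting from `start`;
# cells are rows of `xy`, eligibility a logical vector.
flood_component <- function(xy, eligible, start) {
  key <- paste(xy$x, xy$y)
  idx <- stats::setNames(seq_len(nrow(xy)), key)
  seen <- logical(nrow(xy))
  queue <- start
  seen[start] <- TRUE
  out <- integer(0)
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    out <- c(out, i)
    nb <- c(idx[paste(xy$x[i] + 1, xy$y[i])],
            idx[paste(xy$x[i] - 1, xy$y[i])],
            idx[paste(xy$x[i], xy$y[i] + 1)],
            idx[paste(xy$x[i], xy$y[i] - 1)])
    nb <- nb[!is.na(nb)]
    nb <- nb[eligible[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  out
}

#' Simulate ranges, colour observations and the auxiliary tables
#'
#' Each species occupies the contiguous block of non-water cells whose
#' temperature, productivity and UVB match its niche centres within the
#' configured breadths (breadths widen geometrically on empty matches, and
#' species that still find no cell are dropped with a log entry). Observed
#' individuals (1 + Poisson, mean 1.4 by default) carry observer noise and
#' are expressed as wheel patches with 5%-step coverages; a configured
#' fraction of species lack observations. Also emits observer-calibration
#' pairs, activity classes and a chytridiomycosis severity table generated
#' with a configurable colour-by-productivity interaction (unaffected
#' co-occurring species coded 0).
#'
#' @param config A [world_config()].
#' @param tree,traits From [simulate_tree_and_traits()] (`traits` is the
#'   data.frame of that result).
#' @param cells From [simulate_environment()].
#' @return List with `occupancy`, `observations`, `wheel`, `calibration`,
#'   `activity`, `severity`, `dropped_species`, `missing_species`
#'   (species without observations).
#' @export
simulate_ranges_and_observations <- function(config, tree, traits, cells) {
  with_seed(stage_seed(config$seed, 3L), {
    fc <- filter_cells(cells)
    incl <- fc[fc$included, ]
    n_sp <- nrow(traits)
    occ_list <- vector("list", n_sp)
    dropped <- character(0)
    for (i in seq_len(n_sp)) {
      found <- FALSE
      for (attempt in 0:config$range_retries) {
        wf <- config$breadth_widen^attempt
        el <- abs(incl$MAT - traits$tniche[i]) <= config$breadth_mat * wf &
          abs(incl$EVI - traits$pniche[i]) <= config$breadth_evi * wf &
          abs(incl$UVB - traits$uniche[i]) <= config$breadth_uvb * wf
        if (any(el)) { found <- TRUE; break }
      }
      if (!found) {
        dropped <- c(dropped, traits$species_id[i])
        next
      }
      mm <- ((incl$MAT - traits$tniche[i]) / config$breadth_mat)^2 +
        ((incl$EVI - traits$pniche[i]) / config$breadth_evi)^2 +
        ((incl$UVB - traits$uniche[i]) / config$breadth_uvb)^2
      mm[!el] <- Inf
      comp <- flood_component(incl[, c("x", "y")], el, which.min(mm))
      occ_list[[i]] <- data.frame(cell_id = incl$cell_id[comp],
                                  species_id = traits$species_id[i],
                                  stringsAsFactors = FALSE)
    }
    if (length(dropped)) {
      message(sprintf("%d species with empty ranges dropped", length(dropped)))
    }
    occupancy <- do.call(rbind, occ_list)
    rownames(occupancy) <- NULL

    wheel <- build_default_wheel(config$value_channel)
    span <- range(wheel_lightness(wheel))
    ranged <- setdiff(traits$species_id, dropped)
    missing_species <- if (config$missingness > 0) {
      sort(sample(ranged, size = floor(config$missingness * length(ranged))))
    } else character(0)
    observed <- setdiff(ranged, missing_species)
    tl <- stats::setNames(traits$true_lightness, traits$species_id)
    obs_rows <- vector("list", length(observed))
    ind_means <- list()
    for (j in seq_along(observed)) {
      sp <- observed[j]
      n_ind <- 1L + stats::rpois(1, config$extra_individual_rate)
      li <- clamp(tl[[sp]] + stats::rnorm(n_ind, 0, config$observer_noise_sd),
                  span[1], span[2])
      ind_means[[sp]] <- mean(li)
      rows <- lapply(seq_len(n_ind), function(m) {
        if (config$quantise) {
          p <- lightness_to_patches(li[m], wheel)
          data.frame(species_id = sp,
                     individual_id = sprintf("%s_i%02d", sp, m),
                     observer_id = "obsA", patch_index = seq_len(nrow(p)),
                     colour_id = p$colour_id, R = NA_real_, G = NA_real_,
                     B = NA_real_, coverage = p$coverage,
                     stringsAsFactors = FALSE)
        } else {
          data.frame(species_id = sp,
                     individual_id = sprintf("%s_i%02d", sp, m),
                     observer_id = "obsA", patch_index = 1L,
                     colour_id = NA_integer_, R = li[m], G = li[m],
                     B = li[m], coverage = 1,
                     stringsAsFactors = FALSE)
        }
      })
      obs_rows[[j]] <- do.call(rbind, rows)
    }
    observations <- do.call(rbind, obs_rows)
    rownames(observations) <- NULL

    calib_sp <- sort(sample(observed,
                            min(config$calib_n_species, length(observed))))
    est_a <- unlist(ind_means[calib_sp])
    calibration <- data.frame(
      species_id = calib_sp, estimate_a = unname(est_a),
      estimate_b = config$calib_intercept + config$calib_slope * est_a +
        stats::rnorm(length(est_a), 0, config$calib_noise_sd),
      stringsAsFactors = FALSE)

    activity <- data.frame(
      species_id = traits$species_id,
      activity = sample(config$activity_classes, n_sp, replace = TRUE,
                        prob = config$activity_probs),
      stringsAsFactors = FALSE)

    affected <- sort(sample(observed,
                            floor(config$affected_fraction * length(observed))))
    zl <- as.numeric(scale(tl[affected]))
    pn <- stats::setNames(traits$pniche, traits$species_id)
    zp <- as.numeric(scale(pn[affected]))
    latent <- config$severity_interaction * zl * zp +
      stats::rnorm(length(affected), 0, config$severity_noise_sd)
    sev <- as.integer(cut(latent,
                          breaks = stats::quantile(
                            latent,
                            probs = seq(0, 1, length.out =
                                          config$severity_levels + 1)),
                          include.lowest = TRUE, labels = FALSE))
    cells_of_affected <- unique(occupancy$cell_id[
      occupancy$species_id %in% affected])
    cooccur <- setdiff(unique(occupancy$species_id[
      occupancy$cell_id %in% cells_of_affected]), affected)
    cooccur <- intersect(cooccur, observed)
    severity <- rbind(
      data.frame(species_id = affected, severity = sev, affected = TRUE,
                 stringsAsFactors = FALSE),
      data.frame(species_id = sort(cooccur), severity = 0L, affected = FALSE,
                 stringsAsFactors = FALSE))
    rownames(severity) <- NULL

    list(occupancy = occupancy, observations = observations, wheel = wheel,
         calibration = calibration, activity = activity, severity = severity,
         dropped_species = dropped, missing_species = missing_species)
  })
}

#' Simulate a complete synthetic world
#'
#' Runs [simulate_environment()], [simulate_tree_and_traits()] and
#' [simulate_ranges_and_observations()] and bundles their outputs with a
#' manifest recording the configuration, stage seeds and generator
#' bookkeeping (true parameters, exclusion tallies), for use in recovery
#' tests. A configured fraction of ranged species is withheld from the
#' distributed tree (but kept in the taxonomy) so downstream analyses must
#' graft them back — emulating species added to published phylogenies at
#' the genus level.
#'
#' @param config A [world_config()].
#' @return List of class `synthetic_world` with `cells`, `tree` (withheld
#'   species removed), `tree_full`, `taxonomy`, `traits`, `occupancy`,
#'   `observations`, `wheel`, `calibration`, `activity`, `severity`, and
#'   `manifest`.
#' @export
simulate_world <- function(config = world_config()) {
  cells <- simulate_environment(config)
  tt <- simulate_tree_and_traits(config)
  ro <- simulate_ranges_and_observations(config, tt$tree, tt$traits, cells)
  missing_tree <- with_seed(stage_seed(config$seed, 4L), {
    candidates <- setdiff(tt$tree$tip.label, ro$dropped_species)
    target <- floor(config$tree_missing_fraction * length(candidates))
    genus_of <- stats::setNames(tt$taxonomy$genus, tt$taxonomy$species_id)
    left <- table(genus_of[tt$tree$tip.label])
    picked <- character(0)
    # withhold greedily, never removing a genus's last tip (grafting needs
    # at least one congener to anchor to)
    for (sp in sample(candidates)) {
      if (length(picked) >= target) break
      g <- genus_of[[sp]]
      if (left[[g]] > 1) {
        picked <- c(picked, sp)
        left[[g]] <- left[[g]] - 1
      }
    }
    sort(picked)
  })
  tree_pruned <- if (length(missing_tree)) {
    ape::drop.tip(tt$tree, missing_tree)
  } else tt$tree
  manifest <- list(
    config = unclass(config),
    stage_seeds = vapply(1:4, function(k) stage_seed(config$seed, k),
                         integer(1)),
    n_species = config$n_species,
    n_species_ranged = length(unique(ro$occupancy$species_id)),
    n_species_observed = length(unique(ro$observations$species_id)),
    dropped_species = ro$dropped_species,
    missing_species = ro$missing_species,
    missing_from_tree = missing_tree,
    clip_fraction = tt$clip_fraction,
    lambda_trait_expected = tt$lambda_trait_expected,
    n_cells = nrow(cells),
    n_cells_land = sum(cells$water_fraction <= 0.5)
  )
  structure(list(cells = cells, tree = tree_pruned, tree_full = tt$tree,
                 taxonomy = tt$taxonomy, traits = tt$traits,
                 occupancy = ro$occupancy, observations = ro$observations,
                 wheel = ro$wheel, calibration = ro$calibration,
                 activity = ro$activity, severity = ro$severity,
                 manifest = manifest), class = "synthetic_world")
}

#' Write a synthetic world to disk
#'
#' Writes the full input bundle as plain-text files: CSV tables, a Newick
#' tree and a JSON manifest.
#'
#' @param world A [simulate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cells = file.path(dir, "cells.csv"),
    taxonomy = file.path(dir, "taxonomy.csv"),
    traits = file.path(dir, "traits_true.csv"),
    occupancy = file.path(dir, "occupancy.csv"),
    observations = file.path(dir, "observations.csv"),
    wheel = file.path(dir, "wheel.csv"),
    calibration = file.path(dir, "calibration.csv"),
    activity = file.path(dir, "activity.csv"),
    severity = file.path(dir, "severity.csv"),
    tree = file.path(dir, "tree.nwk"),
    tree_full = file.path(dir, "tree_full.nwk"),
    manifest = file.path(dir, "manifest.json"))
  for (nm in c("cells", "taxonomy", "traits", "occupancy", "observations",
               "calibration", "activity", "severity")) {
    utils::write.csv(world[[if (nm == "traits") "traits" else nm]],
                     paths[[nm]], row.names = FALSE, quote = FALSE)
  }
  write_wheel(world$wheel, paths[["wheel"]])
  ape::write.tree(world$tree, paths[["tree"]])
  ape::write.tree(world$tree_full, paths[["tree_full"]])
  jsonlite::write_json(world$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a synthetic world back from disk
#'
#' Inverse of [write_world()]: reconstructs the world bundle from the
#' plain-text files, so analysis stages can run as separate processes.
#'
#' @param dir Directory written by [write_world()].
#' @return A list of class `synthetic_world` (see [simulate_world()]).
#' @export
read_world <- function(dir) {
  read1 <- function(name) utils::read.csv(file.path(dir, name))
  world <- list(
    cells = read1("cells.csv"),
    tree = ape::read.tree(file.path(dir, "tree.nwk")),
    tree_full = ape::read.tree(file.path(dir, "tree_full.nwk")),
    taxonomy = read1("taxonomy.csv"),
    traits = read1("traits_true.csv"),
    occupancy = read1("occupancy.csv"),
    observations = read1("observations.csv"),
    wheel = read_wheel(file.path(dir, "wheel.csv")),
    calibration = read1("calibration.csv"),
    activity = read1("activity.csv"),
    severity = read1("severity.csv"),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE))
  structure(world, class = "synthetic_world")
}
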