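# ---- mid-level stage functions -------------------------------------------
# These wrap the module operations into the study's analysis stages; the
# numbered scripts under analysis/, run_pipeline() and the acceptance
# script all call them.

#' Score a world's colour observations
#'
#' @param world A [simulate_world()] result (or an equivalent list with
#'   `observations`, `wheel`, `calibration`).
#' @return List with `species_colour` (species_id, lightness,
#'   n_individuals) and `calibration` (an [observer_calibration()] report,
#'   NULL when no pairs are available).
#' @export
score_world <- function(world) {
  sc <- species_lightness(world$observations, world$wheel)
  cal <- if (!is.null(world$calibration) && nrow(world$calibration) >= 3) {
    observer_calibration(world$calibration$estimate_a,
                         world$calibration$estimate_b)
  } else NULL
  list(species_colour = sc, calibration = cal)
}

#' Graft missing species and decompose the colour trait
#'
#' Adds species that have colour data but are absent from the tree at their
#' genus level, prunes species without colour data, then fits Pagel's
#' lambda and the phylogenetic mixed-model decomposition.
#'
#' @param world World bundle (needs `tree`, `taxonomy`).
#' @param species_colour Output of [score_world()]`$species_colour`.
#' @param graft_seed Seed for the random intra-genus resolution.
#' @return List with `tree` (grafted), `lambda` (a `lambda_fit`), `lynch`
#'   (a `lynch_fit`), and `traits` (data.frame `species_id`, `raw`, `P`,
#'   `S`).
#' @export
decompose_world <- function(world, species_colour, graft_seed = 99L) {
  lightness <- stats::setNames(species_colour$lightness,
                               species_colour$species_id)
  missing <- setdiff(names(lightness), world$tree$tip.label)
  tree <- graft_missing_species(world$tree, world$taxonomy, missing,
                                seed = graft_seed)
  lam <- fit_pagel_lambda(lightness, tree, quiet = TRUE)
  ly <- lynch_decompose(lightness, tree, quiet = TRUE)
  traits <- ly$components
  names(traits)[names(traits) == "raw"] <- "raw"
  list(tree = tree, lambda = lam, lynch = ly, traits = traits)
}

#' Build assemblage summaries and species-level range environments
#'
#' @param world World bundle (needs `cells`, `occupancy`).
#' @param traits Decomposition table (`species_id`, `raw`, `P`, `S`).
#' @param coverage_threshold,water_threshold The study's filters.
#' @return List with `cells` (flagged), `summaries` (flagged), and
#'   `species_env` (range means over included cells).
#' @export
assemble_world <- function(world, traits, coverage_threshold = 0.33,
                           water_threshold = 0.5) {
  cells <- filter_cells(world$cells, water_threshold)
  occ_incl <- world$occupancy[world$occupancy$cell_id %in%
                                cells$cell_id[cells$included], ]
  summaries <- assemblage_trait_means(occ_incl, traits)
  summaries <- filter_assemblages(summaries, coverage_threshold)
  species_env <- species_range_environment(world$occupancy, cells,
                                           quiet = TRUE)
  list(cells = cells, summaries = summaries, species_env = species_env)
}

#' Colour-lightness diversity of a world's assemblages
#'
#' @param world World bundle.
#' @param traits Decomposition table (uses `raw`).
#' @param assembled Output of [assemble_world()].
#' @param n_draws,seed,enum_cap Passed to [assemblage_ses()].
#' @return SES `data.frame` (one row per assemblage with richness >= 2).
#' @export
diversity_world <- function(world, traits, assembled, n_draws = 1000,
                            seed = 1, enum_cap = 0) {
  tl <- stats::setNames(traits$raw, traits$species_id)
  incl_cells <- assembled$summaries$cell_id[assembled$summaries$included]
  cells <- assembled$cells[assembled$cells$cell_id %in% incl_cells, ]
  assemblage_ses(world$occupancy, cells, tl, n_draws = n_draws, seed = seed,
                 enum_cap = enum_cap)
}

# Assemblage-level analysis frame: included summaries joined with cell
# environment and coordinates, predictors z-scaled.
assemblage_frame <- function(assembled, ses = NULL,
                             env_vars = c("MAT", "elevation", "EVI", "UVB")) {
  s <- assembled$summaries[assembled$summaries$included, ]
  cells <- assembled$cells
  i <- match(s$cell_id, cells$cell_id)
  df <- cbind(s, cells[i, c("x", "y", "lat", "realm", env_vars)])
  if (!is.null(ses)) {
    df$ses <- ses$ses[match(df$cell_id, ses$cell_id)]
  }
  zs <- zscale(df, env_vars)
  list(data = zs$data, center = zs$center, scale = zs$scale,
       env_vars = env_vars)
}

#' The study's regression battery on one world
#'
#' Runs, at the assemblage level: multiple linear models and trend-surface
#' models of raw colour lightness, its P and S components and (when
#' supplied) colour-lightness diversity against the four z-scaled
#' environmental predictors; hierarchical partitioning overall and per
#' realm; a realm-interaction model; and Moran's I correlograms of the raw
#' LM and trend-surface residuals. At the species level: the
#' family-interaction model, an overall PGLS, Pagel's lambda for colour and
#' each environmental aggregate, an activity-interaction model, and the
#' chytridiomycosis severity models.
#'
#' @param world World bundle.
#' @param scored Output of [score_world()].
#' @param decomposed Output of [decompose_world()].
#' @param assembled Output of [assemble_world()].
#' @param ses Optional output of [diversity_world()].
#' @param realm_min_assemblages Realms with at most this many assemblages
#'   are excluded from realm-level analyses (default 50: "more than 50").
#' @param family_min_species Families with fewer species are excluded from
#'   the family model (default 10).
#' @param severity_min_family Families with fewer species are excluded from
#'   severity models (default 9).
#' @param correlogram_classes,correlogram_fraction Correlogram layout:
#'   number of classes and the fraction of the maximum pairwise distance
#'   covered.
#' @return List of results; see the individual components.
#' @export
regress_world <- function(world, scored, decomposed, assembled, ses = NULL,
                          realm_min_assemblages = 50,
                          family_min_species = 10,
                          severity_min_family = 9,
                          correlogram_classes = 10,
                          correlogram_fraction = 0.5) {
  env_vars <- c("MAT", "elevation", "EVI", "UVB")
  fr <- assemblage_frame(assembled, ses, env_vars)
  d <- fr$data
  X <- d[, env_vars]
  coords <- d[, c("x", "y")]

  responses <- list(raw = d$mean_raw, P = d$mean_P, S = d$mean_S)
  if (!is.null(ses)) responses$diversity <- d$ses
  table1 <- list()
  lm_fits <- list()
  gam_fits <- list()
  for (resp in names(responses)) {
    y <- responses[[resp]]
    ok <- is.finite(y)
    lm_fit <- ols_fit(y[ok], X[ok, ])
    gam_fit <- trend_surface_fit(y[ok], X[ok, ], coords[ok, ])
    lm_fits[[resp]] <- lm_fit
    gam_fits[[resp]] <- gam_fit
    lc <- lm_fit$coefficients[lm_fit$coefficients$term != "(Intercept)", ]
    gc <- gam_fit$coefficients[gam_fit$coefficients$term != "(Intercept)", ]
    table1[[resp]] <- data.frame(
      response = resp, predictor = lc$term,
      lm_slope = lc$estimate, lm_se = lc$se, lm_t = lc$t, lm_p = lc$p,
      lm_r2 = lm_fit$r_squared,
      gam_slope = gc$estimate, gam_se = gc$se, gam_t = gc$t, gam_p = gc$p,
      gam_r2 = gam_fit$r_squared, n = lm_fit$n)
  }
  table1 <- do.call(rbind, table1)
  rownames(table1) <- NULL

  hp_overall <- hierarchical_partitioning(d$mean_raw, X)
  realm_sizes <- table(d$realm)
  realms_kept <- names(realm_sizes)[realm_sizes > realm_min_assemblages]
  hp_realm <- lapply(stats::setNames(realms_kept, realms_kept), function(r) {
    i <- d$realm == r
    hierarchical_partitioning(d$mean_raw[i], X[i, ])
  })
  realm_fit <- grouped_interaction_fit(d$mean_raw, X, d$realm,
                                       min_group_size =
                                         realm_min_assemblages + 1)

  correlograms <- list()
  bands <- list()
  max_d <- correlogram_fraction *
    max(stats::dist(as.matrix(coords[is.finite(d$mean_raw), ])))
  for (m in c("lm", "gam")) {
    res <- if (m == "lm") lm_fits$raw$residuals else gam_fits$raw$residuals
    correlograms[[m]] <- morans_correlogram(res, coords,
                                            n_classes = correlogram_classes,
                                            max_distance = max_d)
  }

  # species level
  se <- assembled$species_env
  sc <- scored$species_colour
  common <- intersect(se$species_id, sc$species_id)
  se <- se[match(common, se$species_id), ]
  colour <- stats::setNames(sc$lightness[match(common, sc$species_id)],
                            common)
  fam <- stats::setNames(
    world$taxonomy$family[match(common, world$taxonomy$species_id)], common)
  Xs <- se[, env_vars]
  family_fit <- grouped_interaction_fit(colour, Xs, fam,
                                        min_group_size = family_min_species)
  zs <- zscale(Xs)
  pgls_overall <- pgls_fit(colour, as.matrix(zs$data), decomposed$tree,
                           lambda = "estimated", quiet = TRUE)
  lambdas <- c(colour = decomposed$lambda$lambda,
               vapply(env_vars, function(v) {
                 fit_pagel_lambda(stats::setNames(se[[v]], common),
                                  decomposed$tree, quiet = TRUE)$lambda
               }, numeric(1)))

  act <- stats::setNames(
    world$activity$activity[match(common, world$activity$species_id)],
    common)
  activity_fit <- grouped_interaction_fit(colour, Xs, act,
                                          min_group_size = 2)
  env_only <- ols_fit(colour, zs$data)
  activity_delta_r2 <- activity_fit$r_squared - env_only$r_squared

  sev <- world$severity[world$severity$species_id %in% common, ]
  severity <- if (nrow(sev) >= 10) {
    severity_models(stats::setNames(as.numeric(sev$severity),
                                    sev$species_id),
                    colour, stats::setNames(se$EVI, common),
                    fam, decomposed$tree,
                    min_family_size = severity_min_family)
  } else NULL

  list(table1 = table1, lm_fits = lm_fits, gam_fits = gam_fits,
       hierpart_overall = hp_overall, hierpart_realm = hp_realm,
       realm_fit = realm_fit, correlograms = correlograms,
       correlogram_max_distance = max_d,
       family_fit = family_fit, pgls_overall = pgls_overall,
       lambdas = lambdas, activity_fit = activity_fit,
       activity_delta_r2 = activity_delta_r2, severity = severity,
       frame = fr)
}

# ---- orchestration --------------------------------------------------------

md5_of <- function(paths) {
  unname(tools::md5sum(paths))
}

#' Run the full pipeline on a synthetic world
#'
#' Simulate, score, decompose, assemble, quantify diversity, regress; write
#' every stage's outputs under `outdir` and return a run manifest with
#' input/output hashes, seeds and exclusion tallies. When `force = FALSE`
#' and a previous manifest shows a stage's inputs and outputs unchanged,
#' the stage is skipped and its outputs reloaded (hash-checked
#' idempotence).
#'
#' @param config A [world_config()].
#' @param outdir Output directory.
#' @param n_draws Null-model draws for the diversity stage.
#' @param force Recompute everything, ignoring an existing manifest.
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `run_manifest.json`.
#' @export
run_pipeline <- function(config = world_config(), outdir, n_draws = 1000,
                         force = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  man_path <- file.path(outdir, "run_manifest.json")
  old_manifest <- if (!force && file.exists(man_path)) {
    tryCatch(jsonlite::read_json(man_path), error = function(e) NULL)
  } else NULL

  stages <- list()
  # manifest entries are keyed by path relative to outdir so they can be
  # resolved again on a later run
  rel <- function(paths) {
    sub("^/+", "", substring(normalizePath(paths, mustWork = FALSE),
                             nchar(normalizePath(outdir)) + 1))
  }
  stage_done <- function(name, inputs, outputs, counts = list()) {
    stages[[name]] <<- list(
      inputs = as.list(stats::setNames(md5_of(inputs), rel(inputs))),
      outputs = as.list(stats::setNames(md5_of(outputs), rel(outputs))),
      counts = counts)
  }
  can_skip <- function(name, inputs) {
    st <- old_manifest$stages[[name]]
    if (is.null(st)) return(FALSE)
    ins <- stats::setNames(md5_of(inputs), rel(inputs))
    if (!identical(as.list(ins), lapply(st$inputs, identity))) return(FALSE)
    outs <- unlist(st$outputs)
    paths <- file.path(outdir, names(outs))
    all(file.exists(paths)) && identical(unname(md5_of(paths)), unname(outs))
  }

  # stage 1: simulate -------------------------------------------------------
  world_dir <- file.path(outdir, "world")
  world_paths <- file.path(world_dir,
                           c("cells.csv", "taxonomy.csv", "traits_true.csv",
                             "occupancy.csv", "observations.csv", "wheel.csv",
                             "calibration.csv", "activity.csv", "severity.csv",
                             "tree.nwk", "tree_full.nwk", "manifest.json"))
  skipped_sim <- can_skip("simulate", cfg_path)
  world <- simulate_world(config)   # cheap enough to rebuild in memory
  if (!skipped_sim) write_world(world, world_dir)
  stage_done("simulate", cfg_path, world_paths,
             list(n_cells = world$manifest$n_cells,
                  n_cells_land = world$manifest$n_cells_land,
                  n_species_ranged = world$manifest$n_species_ranged,
                  n_dropped = length(world$manifest$dropped_species),
                  skipped = skipped_sim))

  # stage 2: score ----------------------------------------------------------
  scored <- score_world(world)
  sc_path <- file.path(outdir, "species_colour.csv")
  cal_path <- file.path(outdir, "calibration_fit.json")
  utils::write.csv(scored$species_colour, sc_path, row.names = FALSE,
                   quote = FALSE)
  cal <- scored$calibration
  jsonlite::write_json(
    list(slope = cal$slope, intercept = cal$intercept,
         r_squared = cal$r_squared, n = cal$n),
    cal_path, auto_unbox = TRUE, digits = NA)
  stage_done("score", world_paths, c(sc_path, cal_path),
             list(n_species_scored = nrow(scored$species_colour)))

  # stage 3: decompose ------------------------------------------------------
  decomposed <- decompose_world(world, scored$species_colour,
                                graft_seed = stage_seed(config$seed, 5L))
  dec_path <- file.path(outdir, "decomposition.csv")
  dec_info <- file.path(outdir, "decomposition_info.json")
  utils::write.csv(decomposed$traits, dec_path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(mu = decomposed$lynch$mu,
         sigma2_phylo = decomposed$lynch$sigma2_phylo,
         sigma2_resid = decomposed$lynch$sigma2_resid,
         iterations = decomposed$lynch$iterations,
         converged = decomposed$lynch$converged,
         lambda_colour = decomposed$lambda$lambda),
    dec_info, auto_unbox = TRUE, digits = NA)
  stage_done("decompose", c(world_paths, sc_path), c(dec_path, dec_info),
             list(n_grafted = length(setdiff(scored$species_colour$species_id,
                                             world$tree$tip.label))))

  # stage 4: assemble -------------------------------------------------------
  assembled <- assemble_world(world, decomposed$traits)
  sum_path <- file.path(outdir, "assemblage_summaries.csv")
  env_path <- file.path(outdir, "species_environment.csv")
  utils::write.csv(assembled$summaries, sum_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(assembled$species_env, env_path, row.names = FALSE,
                   quote = FALSE)
  stage_done("assemble", c(world_paths, dec_path), c(sum_path, env_path),
             list(n_cells_included = sum(assembled$cells$included),
                  n_assemblages_included = sum(assembled$summaries$included),
                  n_excluded_water = sum(!assembled$cells$included),
                  n_excluded_coverage =
                    sum(assembled$summaries$exclusion_reason %in% "coverage")))

  # stage 5: diversity ------------------------------------------------------
  ses <- diversity_world(world, decomposed$traits, assembled,
                         n_draws = n_draws, seed = config$seed)
  ses_path <- file.path(outdir, "ses.csv")
  utils::write.csv(ses, ses_path, row.names = FALSE, quote = FALSE)
  stage_done("diversity", c(world_paths, dec_path, sum_path), ses_path,
             list(n_assemblages_ses = nrow(ses)))

  # stage 6: regressions ----------------------------------------------------
  reg <- regress_world(world, scored, decomposed, assembled, ses)
  res_dir <- file.path(outdir, "results")
  dir.create(res_dir, showWarnings = FALSE)
  out_paths <- c(
    table1 = file.path(res_dir, "table1.csv"),
    hierpart = file.path(res_dir, "hierpart_realms.csv"),
    realm_slopes = file.path(res_dir, "realm_slopes.csv"),
    family_slopes = file.path(res_dir, "family_slopes.csv"),
    correlogram = file.path(res_dir, "correlogram.csv"),
    lambdas = file.path(res_dir, "lambdas.json"))
  utils::write.csv(reg$table1, out_paths[["table1"]], row.names = FALSE,
                   quote = FALSE)
  hp <- do.call(rbind, lapply(names(reg$hierpart_realm), function(r) {
    h <- reg$hierpart_realm[[r]]
    data.frame(realm = r, predictor = names(h$independent),
               independent = unname(h$independent),
               share = unname(h$share), r_squared_full = h$r_squared_full)
  }))
  utils::write.csv(hp, out_paths[["hierpart"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(reg$realm_fit$slopes, out_paths[["realm_slopes"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(reg$family_fit$slopes, out_paths[["family_slopes"]],
                   row.names = FALSE, quote = FALSE)
  cg <- rbind(cbind(model = "lm", reg$correlograms$lm),
              cbind(model = "gam", reg$correlograms$gam))
  utils::write.csv(cg, out_paths[["correlogram"]], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(as.list(reg$lambdas), out_paths[["lambdas"]],
                       auto_unbox = TRUE, digits = NA)
  stage_done("regress", c(world_paths, sc_path, dec_path, sum_path,
                          env_path, ses_path),
             out_paths,
             list(n_realms_kept = length(reg$hierpart_realm),
                  n_families_kept =
                    length(unique(reg$family_fit$slopes$group))))

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("froglight")),
    config_hash = unname(md5_of(cfg_path)),
    seed = config$seed,
    stages = stages,
    world = world$manifest[c("n_species", "n_species_ranged",
                             "n_species_observed", "clip_fraction",
                             "lambda_trait_expected", "n_cells",
                             "n_cells_land")]),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), man_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
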