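test_that("configuration rejects unknown entries and bad values", {
  expect_error(world_config(nonsense = 1), "unknown config")
  expect_error(world_config(lambda = 1.5), "lambda")
  cfg <- world_config(seed = 5, n_species = 40L)
  expect_identical(cfg$n_species, 40L)
  expect_s3_class(cfg, "world_config")
})

test_that("the environment realises its configured structure", {
  cfg <- world_config(seed = 3)
  cells <- simulate_environment(cfg)
  expect_identical(nrow(cells), 2500L)
  expect_identical(length(unique(cells$realm)), 4L)
  # quartic latitude profile: warmest rows in the middle of the grid
  row_means <- tapply(cells$MAT, cells$y, mean)
  expect_gt(mean(row_means[20:30]), mean(row_means[c(1:5, 46:50)]) + 10)
  # MAT-EVI coupling close to the configured correlation
  expect_lt(abs(cor(cells$MAT, cells$EVI) - cfg$evi_mat_cor), 0.05)
  # water concentrates on the border band
  border <- cells$x <= 3 | cells$x > 47 | cells$y <= 3 | cells$y > 47
  expect_true(all(cells$water_fraction[border] > 0.5))
  expect_true(all(cells$water_fraction[!border] <= 0.25))
  expect_true(all(cells$EVI > 0 & cells$EVI < 1))
  expect_true(all(cells$elevation >= 0))
})

test_that("tree, taxonomy and traits respect the generator contract", {
  cfg <- world_config(seed = 3, n_species = 80L)
  tt <- simulate_tree_and_traits(cfg)
  expect_identical(ape::Ntip(tt$tree), 80L)
  expect_equal(max(ape::branching.times(tt$tree)), 1, tolerance = 1e-8)
  expect_true(ape::is.ultrametric(tt$tree, tol = 1e-8))
  # taxonomy is nested: one family per genus
  gf <- unique(tt$taxonomy[, c("genus", "family")])
  expect_false(anyDuplicated(gf$genus) > 0)
  wheel <- build_default_wheel()
  span <- range(wheel_lightness(wheel))
  expect_true(all(tt$traits$true_lightness >= span[1] &
                    tt$traits$true_lightness <= span[2]))
  expect_lt(tt$clip_fraction, 0.05)
  expect_true(tt$lambda_trait_expected >= 0 && tt$lambda_trait_expected <= 1)
})

test_that("trait-level signal tracks the configured generating mix", {
  # no environment, pure lambda-damped deviation: lambda_hat near config
  cfg0 <- world_config(seed = 6, n_species = 150L, beta_mat = 0,
                       beta_evi = 0, beta_uvb = 0, sigma2_resid = 1,
                       lambda = 1)
  tt0 <- simulate_tree_and_traits(cfg0)
  y0 <- stats::setNames(tt0$traits$true_lightness, tt0$traits$species_id)
  expect_gt(fit_pagel_lambda(y0, tt0$tree, quiet = TRUE)$lambda, 0.9)
  cfg1 <- world_config(seed = 6, n_species = 150L, beta_mat = 0,
                       beta_evi = 0, beta_uvb = 0, sigma2_phylo = 0,
                       sigma2_resid = 64)
  tt1 <- simulate_tree_and_traits(cfg1)
  y1 <- stats::setNames(tt1$traits$true_lightness, tt1$traits$species_id)
  expect_lt(fit_pagel_lambda(y1, tt1$tree, quiet = TRUE)$lambda, 0.2)
})

test_that("noise-free unquantised observations reproduce the truth exactly", {
  cfg <- small_config(seed = 8, observer_noise_sd = 0,
                      extra_individual_rate = 0, missingness = 0,
                      quantise = FALSE)
  w <- suppressMessages(simulate_world(cfg))
  sc <- species_lightness(w$observations, w$wheel)
  truth <- stats::setNames(w$traits$true_lightness, w$traits$species_id)
  expect_equal(sc$lightness, unname(truth[sc$species_id]),
               tolerance = 1e-12)
  expect_identical(length(w$manifest$missing_species), 0L)
})

test_that("wheel quantisation keeps scores within the rounding bound", {
  cfg <- small_config(seed = 8, observer_noise_sd = 0,
                      extra_individual_rate = 0, missingness = 0,
                      quantise = TRUE)
  w <- suppressMessages(simulate_world(cfg))
  sc <- species_lightness(w$observations, w$wheel)
  truth <- stats::setNames(w$traits$true_lightness, w$traits$species_id)
  gap <- wheel_max_gap(w$wheel)
  err <- abs(sc$lightness - unname(truth[sc$species_id]))
  expect_true(all(err <= gap * 0.05 / 2 + 1e-9))
})

test_that("worlds are deterministic in the master seed", {
  cfg <- small_config(seed = 21)
  w1 <- suppressMessages(simulate_world(cfg))
  w2 <- suppressMessages(simulate_world(cfg))
  w3 <- suppressMessages(simulate_world(small_config(seed = 22)))
  for (nm in c("cells", "taxonomy", "traits", "occupancy", "observations",
               "calibration", "activity", "severity")) {
    expect_identical(w1[[nm]], w2[[nm]])
  }
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  expect_false(identical(w1$cells, w3$cells))
  expect_false(identical(w1$observations, w3$observations))
})

test_that("generator stages draw from independent seed streams", {
  # changing an observation-stage knob must leave environment and tree
  # untouched
  w1 <- suppressMessages(simulate_world(small_config(seed = 23)))
  w2 <- suppressMessages(simulate_world(small_config(seed = 23,
                                                     missingness = 0)))
  expect_identical(w1$cells, w2$cells)
  expect_identical(w1$traits, w2$traits)
  expect_identical(ape::write.tree(w1$tree_full), ape::write.tree(w2$tree_full))
})

test_that("the manifest's bookkeeping is internally consistent", {
  w <- suppressMessages(simulate_world(small_config(seed = 24)))
  m <- w$manifest
  expect_identical(m$n_cells, nrow(w$cells))
  expect_identical(m$n_cells_land, sum(w$cells$water_fraction <= 0.5))
  expect_identical(m$n_species_ranged,
                   length(unique(w$occupancy$species_id)))
  expect_identical(m$n_species_observed,
                   length(unique(w$observations$species_id)))
  expect_identical(sort(unique(c(m$missing_species, m$dropped_species,
                                 unique(w$observations$species_id)))),
                   sort(w$traits$species_id))
  # withheld-from-tree species remain in the taxonomy and the full tree
  expect_true(all(m$missing_from_tree %in% w$taxonomy$species_id))
  expect_true(all(m$missing_from_tree %in% w$tree_full$tip.label))
  expect_false(any(m$missing_from_tree %in% w$tree$tip.label))
  # every genus withheld from still has a congener left for grafting
  gof <- stats::setNames(w$taxonomy$genus, w$taxonomy$species_id)
  expect_true(all(gof[m$missing_from_tree] %in% gof[w$tree$tip.label]))
})

test_that("ranges are contiguous blocks of included cells", {
  w <- suppressMessages(simulate_world(small_config(seed = 25)))
  fc <- filter_cells(w$cells)
  incl <- fc$cell_id[fc$included]
  expect_true(all(w$occupancy$cell_id %in% incl))
  # check 4-connectivity for a handful of species
  xy <- fc[match(w$occupancy$cell_id, fc$cell_id), c("x", "y")]
  sp <- unique(w$occupancy$species_id)[1:5]
  for (s in sp) {
    pts <- xy[w$occupancy$species_id == s, ]
    if (nrow(pts) == 1) next
    key <- paste(pts$x, pts$y)
    seen <- key[1]
    frontier <- key[1]
    while (length(frontier)) {
      cur <- do.call(rbind, strsplit(frontier, " "))
      cur <- matrix(as.integer(cur), ncol = 2)
      nb <- unique(c(paste(cur[, 1] + 1, cur[, 2]),
                     paste(cur[, 1] - 1, cur[, 2]),
                     paste(cur[, 1], cur[, 2] + 1),
                     paste(cur[, 1], cur[, 2] - 1)))
      frontier <- setdiff(intersect(nb, key), seen)
      seen <- c(seen, frontier)
    }
    expect_identical(sort(seen), sort(key))
  }
})

test_that("worlds write as plain-text files and read back consistently", {
  w <- suppressMessages(simulate_world(small_config(seed = 26)))
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  cells <- read.csv(paths[["cells"]])
  expect_equal(nrow(cells), nrow(w$cells))
  tr <- ape::read.tree(paths[["tree"]])
  expect_identical(sort(tr$tip.label), sort(w$tree$tip.label))
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_identical(man$n_cells, nrow(w$cells))
})

test_that("a written world reads back analysis-equivalent", {
  w <- suppressMessages(simulate_world(small_config(seed = 27)))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  back <- read_world(dir)
  expect_equal(back$cells, w$cells, tolerance = 1e-12)
  expect_identical(back$occupancy, w$occupancy)
  expect_identical(sort(back$tree$tip.label), sort(w$tree$tip.label))
  expect_equal(back$traits$true_lightness, w$traits$true_lightness,
               tolerance = 1e-12)
  # scoring the re-read observations gives identical species estimates
  s1 <- species_lightness(w$observations, w$wheel)
  s2 <- species_lightness(back$observations, back$wheel)
  expect_equal(s1, s2, tolerance = 1e-12)
})
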