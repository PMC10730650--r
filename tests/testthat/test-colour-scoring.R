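test_that("patch lightness is the channel mean and rejects bad input", {
  expect_identical(patch_lightness(c(30, 60, 90)), 60)
  expect_identical(patch_lightness(c(0, 0, 0)), 0)
  expect_identical(patch_lightness(c(255, 255, 255)), 255)
  m <- rbind(c(10, 20, 30), c(200, 100, 0))
  expect_equal(patch_lightness(m), c(20, 100))
  expect_error(patch_lightness(c(-1, 0, 0)), "0, 255")
  expect_error(patch_lightness(c(0, 0, 256)), "0, 255")
  expect_error(patch_lightness(c(0, NA, 0)))
})

test_that("default wheel has the catalog layout and validates", {
  wheel <- build_default_wheel()
  expect_identical(nrow(wheel), 72L)
  expect_identical(sort(unique(wheel$saturation)), c(10, 40, 70, 100))
  expect_identical(length(unique(wheel$hue_index)), 18L)
  expect_silent(validate_wheel(wheel))
  bad <- wheel
  bad$R[1] <- 300
  expect_error(validate_wheel(bad), "0, 255")
  expect_error(validate_wheel(wheel[-1, ]), "72")
  dup <- wheel
  dup$hue_index[2] <- dup$hue_index[1]
  dup$saturation[2] <- dup$saturation[1]
  expect_error(validate_wheel(dup), "duplicate")
  expect_error(build_default_wheel(0), "value_channel")
})

test_that("wheel round-trips through CSV", {
  wheel <- build_default_wheel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_wheel(wheel, path)
  back <- read_wheel(path)
  expect_equal(back, wheel)
})

test_that("coverage invariants are enforced", {
  expect_true(check_coverages(c(0.5, 0.5)))
  expect_true(check_coverages(c(0.05, 0.95)))
  expect_true(check_coverages(1))
  expect_error(check_coverages(c(0.5, 0.4)), "sum to 1")
  expect_error(check_coverages(c(0.52, 0.48)), "multiples of 0.05")
  expect_error(check_coverages(c(-0.5, 1.5)), "positive")
  expect_error(check_coverages(numeric(0)), "at least one")
})

test_that("observation lightness matches the weighted-mean oracle", {
  # the three worked examples
  black <- data.frame(R = 0, G = 0, B = 0, coverage = 1)
  white <- data.frame(R = 255, G = 255, B = 255, coverage = 1)
  mix <- data.frame(R = c(0, 255), G = c(0, 255), B = c(0, 255),
                    coverage = c(0.5, 0.5))
  expect_identical(observation_lightness(black), 0)
  expect_identical(observation_lightness(white), 255)
  expect_identical(observation_lightness(mix), 127.5)
  # arbitrary patches against an explicit loop
  set.seed(31)
  p <- data.frame(R = sample(0:255, 4), G = sample(0:255, 4),
                  B = sample(0:255, 4), coverage = c(0.2, 0.25, 0.5, 0.05))
  manual <- sum(p$coverage * (p$R + p$G + p$B) / 3)
  expect_equal(observation_lightness(p), manual)
})

test_that("colour_id patches resolve against the wheel", {
  wheel <- build_default_wheel()
  p <- data.frame(colour_id = c(5L, 40L), coverage = c(0.3, 0.7))
  wl <- wheel_lightness(wheel)
  expect_equal(observation_lightness(p, wheel),
               unname(0.3 * wl[5] + 0.7 * wl[40]))
  expect_error(observation_lightness(p), "no wheel")
  p$colour_id[1] <- 999L
  expect_error(observation_lightness(p, wheel), "unknown colour_id")
})

test_that("species lightness averages individuals within species", {
  obs <- rbind(
    data.frame(species_id = "a", individual_id = "a1",
               R = 100, G = 100, B = 100, coverage = 1),
    data.frame(species_id = "a", individual_id = "a2",
               R = 200, G = 200, B = 200, coverage = 1),
    data.frame(species_id = "b", individual_id = "b1",
               R = c(0, 255), G = c(0, 255), B = c(0, 255),
               coverage = c(0.25, 0.75))
  )
  sc <- species_lightness(obs)
  expect_identical(sc$species_id, c("a", "b"))
  expect_equal(sc$lightness, c(150, 0.25 * 0 + 0.75 * 255))
  expect_identical(sc$n_individuals, c(2L, 1L))
  empty <- species_lightness(obs[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("quantisation error is bounded by half the wheel's maximum gap", {
  wheel <- build_default_wheel()
  wl <- wheel_lightness(wheel)
  gap <- wheel_max_gap(wheel)
  set.seed(12)
  targets <- runif(200, min(wl), max(wl))
  ids <- quantise_lightness(targets, wheel)
  rescored <- wl[match(ids, wheel$colour_id)]
  expect_true(all(abs(rescored - targets) <= gap / 2 + 1e-12))
})

test_that("two-colour bracketing reproduces a target lightness closely", {
  wheel <- build_default_wheel()
  wl <- wheel_lightness(wheel)
  gap <- wheel_max_gap(wheel)
  set.seed(13)
  targets <- runif(100, min(wl), max(wl))
  for (t in targets) {
    p <- lightness_to_patches(t, wheel)
    expect_true(check_coverages(p$coverage))
    got <- observation_lightness(p, wheel)
    # exact up to the 5% coverage rounding: at most gap * step / 2
    expect_lte(abs(got - t), gap * 0.05 / 2 + 1e-9)
  }
  # out-of-span targets collapse to the extreme colours
  lo <- lightness_to_patches(min(wl) - 10, wheel)
  hi <- lightness_to_patches(max(wl) + 10, wheel)
  expect_equal(observation_lightness(lo, wheel), min(wl))
  expect_equal(observation_lightness(hi, wheel), max(wl))
})

test_that("observer calibration recovers a planted linear map", {
  set.seed(14)
  a <- runif(40, 40, 220)
  b <- 25 + 0.6 * a
  cal <- suppressWarnings(observer_calibration(a, b))  # noiseless: perfect fit
  expect_equal(cal$slope, 0.6, tolerance = 1e-10)
  expect_equal(cal$intercept, 25, tolerance = 1e-8)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(apply_calibration(cal, 100), 25 + 0.6 * 100, tolerance = 1e-8)
  expect_error(observer_calibration(a[1:2], b[1:2]), "at least 3")
  expect_error(observer_calibration(rep(1, 5), b[1:5]), "constant")
})
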