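#' Build the default 72-colour scoring wheel
#'
#' Constructs a colour wheel of 18 equally spaced hues, each at four
#' saturation levels (10, 40, 70 and 100 percent), converted from
#' hue-saturation-value space at a common value channel. This mirrors the
#' layout of the standardised wheels used to score animal colouration from
#' field-guide images; the exact RGB catalog of any particular printed wheel
#' should be supplied as data via [read_wheel()] when available.
#'
#' @param value_channel Value (brightness) channel used for every entry,
#'   in (0, 1]. Default 1 gives the fully bright wheel.
#' @return A `data.frame` with columns `colour_id` (1-72), `hue_index`
#'   (1-18), `saturation` (10, 40, 70, 100), `R`, `G`, `B` (integers 0-255).
#' @examples
#' wheel <- build_default_wheel()
#' range(wheel_lightness(wheel))
#' @export
build_default_wheel <- function(value_channel = 1) {
  stopifnot(is.numeric(value_channel), length(value_channel) == 1,
            value_channel > 0, value_channel <= 1)
  hues <- (seq_len(18) - 1) / 18
  sats <- c(10, 40, 70, 100)
  grid <- expand.grid(saturation = sats, hue_index = seq_len(18))
  cols <- grDevices::hsv(h = hues[grid$hue_index],
                         s = grid$saturation / 100,
                         v = value_channel)
  rgb <- t(grDevices::col2rgb(cols))
  wheel <- data.frame(
    colour_id = seq_len(72L),
    hue_index = grid$hue_index,
    saturation = grid$saturation,
    R = as.integer(rgb[, 1]),
    G = as.integer(rgb[, 2]),
    B = as.integer(rgb[, 3])
  )
  validate_wheel(wheel)
  wheel
}

#' Validate a colour wheel table
#'
#' @param wheel A wheel `data.frame` (see [build_default_wheel()]).
#' @return The wheel, invisibly, after checking the catalog invariants:
#'   72 entries, unique (hue, saturation) pairs, RGB channels in 0-255.
#' @export
validate_wheel <- function(wheel) {
  req <- c("colour_id", "hue_index", "saturation", "R", "G", "B")
  if (!all(req %in% names(wheel))) {
    stop("wheel must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(wheel) != 72L) stop("wheel must have exactly 72 entries")
  if (anyDuplicated(wheel$colour_id)) stop("duplicate colour_id")
  if (anyDuplicated(wheel[, c("hue_index", "saturation")])) {
    stop("duplicate (hue_index, saturation) pair")
  }
  ch <- as.matrix(wheel[, c("R", "G", "B")])
  if (any(ch < 0 | ch > 255)) stop("RGB channels must lie in [0, 255]")
  invisible(wheel)
}

#' @rdname wheel_io
#' @export
write_wheel <- function(wheel, path) {
  validate_wheel(wheel)
  utils::write.csv(wheel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write wheel catalogs
#'
#' Wheels are stored as plain CSV with header
#' `colour_id,hue_index,saturation,R,G,B`.
#'
#' @param wheel A wheel `data.frame`.
#' @param path File path.
#' @return `read_wheel` returns the validated wheel; `write_wheel` the path,
#'   invisibly.
#' @name wheel_io
#' @export
read_wheel <- function(path) {
  wheel <- utils::read.csv(path)
  validate_wheel(wheel)
  wheel
}

#' Lightness of a single colour
#'
#' Colour lightness of an RGB triple is the arithmetic mean of the red,
#' green and blue channels, ranging from 0 (black) to 255 (white).
#'
#' @param rgb Numeric vector of length 3, or a matrix with 3 columns, all
#'   values in [0, 255].
#' @return Lightness value(s) in [0, 255].
#' @examples
#' patch_lightness(c(30, 60, 90))
#' @export
patch_lightness <- function(rgb) {
  if (is.matrix(rgb)) {
    stopifnot(ncol(rgb) == 3)
    m <- rgb
  } else {
    stopifnot(length(rgb) == 3)
    m <- matrix(rgb, ncol = 3)
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 255)) {
    stop("RGB channels must be finite and in [0, 255]")
  }
  out <- rowMeans(m)
  if (!is.matrix(rgb)) out <- unname(out)
  out
}

#' Per-colour lightness of a wheel
#'
#' @param wheel A wheel `data.frame`.
#' @return Numeric vector of lightness values, in `colour_id` order.
#' @export
wheel_lightness <- function(wheel) {
  patch_lightness(as.matrix(wheel[order(wheel$colour_id), c("R", "G", "B")]))
}

# Resolve a patch table (colour_id or explicit R,G,B) to an RGB matrix.
resolve_patch_rgb <- function(patches, wheel = NULL) {
  n <- nrow(patches)
  rgb <- matrix(NA_real_, n, 3)
  has_id <- "colour_id" %in% names(patches) & !is.na(patches$colour_id %||% rep(NA, n))
  if (any(has_id)) {
    if (is.null(wheel)) stop("patches reference colour_id but no wheel given")
    idx <- match(patches$colour_id[has_id], wheel$colour_id)
    if (anyNA(idx)) {
      stop("unknown colour_id: ",
           paste(unique(patches$colour_id[has_id][is.na(idx)]), collapse = ", "))
    }
    rgb[has_id, ] <- as.matrix(wheel[idx, c("R", "G", "B")])
  }
  if (any(!has_id)) {
    if (!all(c("R", "G", "B") %in% names(patches))) {
      stop("patches without colour_id must carry explicit R, G, B")
    }
    rgb[!has_id, ] <- as.matrix(patches[!has_id, c("R", "G", "B")])
  }
  if (anyNA(rgb)) stop("unresolved patch colours")
  rgb
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coverage invariants: positive multiples of 0.05 summing to 1.
check_coverages <- function(coverage, tol = 1e-9) {
  if (length(coverage) < 1) stop("observation needs at least one patch")
  if (any(!is.finite(coverage)) || any(coverage <= 0)) {
    stop("coverages must be positive")
  }
  steps <- coverage / 0.05
  if (any(abs(steps - round(steps)) > 1e-6)) {
    stop("coverages must be multiples of 0.05")
  }
  if (abs(sum(coverage) - 1) > tol) {
    stop("coverages must sum to 1 (got ", format(sum(coverage)), ")")
  }
  invisible(TRUE)
}

#' Colour lightness of one observation
#'
#' Coverage-weighted mean of the patch lightness values of one individual:
#' `sum_i coverage_i * (R_i + G_i + B_i) / 3`.
#'
#' @param patches `data.frame` with a `coverage` column (fractions in 5%
#'   steps summing to 1) and either a `colour_id` column resolved against
#'   `wheel`, or explicit `R`, `G`, `B` columns.
#' @param wheel Optional wheel catalog for `colour_id` lookup.
#' @return Lightness in [0, 255].
#' @examples
#' observation_lightness(data.frame(R = c(0, 255), G = c(0, 255),
#'                                  B = c(0, 255), coverage = c(0.5, 0.5)))
#' @export
observation_lightness <- function(patches, wheel = NULL) {
  check_coverages(patches$coverage)
  rgb <- resolve_patch_rgb(patches, wheel)
  sum(patches$coverage * patch_lightness(rgb))
}

#' Species-level colour lightness
#'
#' Scores every individual with [observation_lightness()] and averages
#' individuals within species, pooling sexes and morphs (unweighted mean).
#'
#' @param observations Long-format `data.frame` with columns `species_id`,
#'   `individual_id`, `coverage` and either `colour_id` or `R`,`G`,`B`;
#'   one row per patch. An `observer_id` column is carried through if
#'   present but not used for weighting.
#' @param wheel Optional wheel catalog for `colour_id` lookup.
#' @return `data.frame` with `species_id`, `lightness`, `n_individuals`.
#'   Species with no observations are absent (never zero-filled).
#' @export
species_lightness <- function(observations, wheel = NULL) {
  if (is.null(observations) || nrow(observations) == 0) {
    return(data.frame(species_id = character(0), lightness = numeric(0),
                      n_individuals = integer(0)))
  }
  key <- interaction(observations$species_id, observations$individual_id,
                     drop = TRUE)
  per_ind <- vapply(split(seq_len(nrow(observations)), key), function(i) {
    observation_lightness(observations[i, , drop = FALSE], wheel)
  }, numeric(1))
  sp_of_ind <- vapply(split(as.character(observations$species_id), key),
                      function(s) s[1], character(1))
  sp_mean <- tapply(per_ind, sp_of_ind, mean)
  out <- data.frame(
    species_id = names(sp_mean),
    lightness = as.numeric(sp_mean),
    n_individuals = as.integer(tapply(per_ind, sp_of_ind, length)),
    row.names = NULL
  )
  out[order(out$species_id), , drop = FALSE]
}

#' Inter-observer calibration of lightness estimates
#'
#' Ordinary least-squares regression of one observer's estimates on
#' another's, used to quantify (and optionally remove) systematic scoring
#' bias when estimates from several observers are combined.
#'
#' @param estimate_a Reference observer's lightness estimates.
#' @param estimate_b Second observer's estimates for the same species.
#' @return List with `slope`, `intercept`, `se_slope`, `se_intercept`,
#'   `r_squared`, `n`, and the fitted `lm` object under `fit`.
#' @export
observer_calibration <- function(estimate_a, estimate_b) {
  stopifnot(length(estimate_a) == length(estimate_b))
  n <- length(estimate_a)
  if (n < 3) stop("need at least 3 paired estimates")
  if (stats::var(estimate_a) <= 0) stop("reference estimates are constant")
  fit <- stats::lm(estimate_b ~ estimate_a)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se_slope = unname(sm$coefficients[2, 2]),
       se_intercept = unname(sm$coefficients[1, 2]),
       r_squared = sm$r.squared,
       n = n,
       fit = fit)
}

#' Apply an observer calibration to new estimates
#'
#' @param calibration Result of [observer_calibration()].
#' @param x Estimates on the reference observer's scale.
#' @return Calibrated values `intercept + slope * x`.
#' @export
apply_calibration <- function(calibration, x) {
  calibration$intercept + calibration$slope * x
}

#' Quantise a lightness value to the nearest wheel colour
#'
#' @param lightness Numeric vector of target lightness values.
#' @param wheel Wheel catalog.
#' @return Integer vector of `colour_id`s whose lightness is nearest each
#'   target (ties broken towards the lower `colour_id`).
#' @export
quantise_lightness <- function(lightness, wheel) {
  wl <- wheel_lightness(wheel)
  ids <- wheel$colour_id[order(wheel$colour_id)]
  ids[vapply(lightness, function(x) which.min(abs(wl - x)), integer(1))]
}

#' Express a target lightness as wheel patches
#'
#' Greedy two-colour bracketing: the wheel colours with lightness just
#' below and just above the target are mixed with coverages rounded to 5%
#' steps so that the re-scored lightness approximates the target. Targets
#' outside the wheel's lightness span collapse to the nearest single
#' colour.
#'
#' @param lightness Scalar target lightness.
#' @param wheel Wheel catalog.
#' @param step Coverage step (default 0.05).
#' @return `data.frame` with columns `colour_id`, `coverage` (1 or 2 rows).
#' @export
lightness_to_patches <- function(lightness, wheel, step = 0.05) {
  wl <- wheel_lightness(wheel)
  ids <- wheel$colour_id[order(wheel$colour_id)]
  o <- order(wl)
  wl <- wl[o]; ids <- ids[o]
  if (lightness <= wl[1]) {
    return(data.frame(colour_id = ids[1], coverage = 1))
  }
  if (lightness >= wl[length(wl)]) {
    return(data.frame(colour_id = ids[length(ids)], coverage = 1))
  }
  hi <- which(wl >= lightness)[1]
  lo <- max(which(wl <= lightness))
  if (lo == hi || wl[hi] == wl[lo]) {
    return(data.frame(colour_id = ids[lo], coverage = 1))
  }
  # coverage on the low colour solving c*wl[lo] + (1-c)*wl[hi] = lightness
  c_lo <- (wl[hi] - lightness) / (wl[hi] - wl[lo])
  c_lo <- round(c_lo / step) * step
  if (c_lo <= 0) return(data.frame(colour_id = ids[hi], coverage = 1))
  if (c_lo >= 1) return(data.frame(colour_id = ids[lo], coverage = 1))
  data.frame(colour_id = c(ids[lo], ids[hi]), coverage = c(c_lo, 1 - c_lo))
}

#' Largest lightness gap of a wheel
#'
#' The maximum difference between adjacent distinct lightness values of the
#' wheel's colours; half this gap bounds the error of nearest-colour
#' quantisation within the wheel's lightness span.
#'
#' @param wheel Wheel catalog.
#' @return Scalar gap in lightness units.
#' @export
wheel_max_gap <- function(wheel) {
  wl <- sort(unique(wheel_lightness(wheel)))
  if (length(wl) < 2) return(0)
  max(diff(wl))
}
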