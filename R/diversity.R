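#' Mean pairwise trait distance
#'
#' Mean of `|x_i - x_j|` over all unordered pairs. Computed via the sorted
#' representation, so it scales to large null-model draws.
#'
#' @param values Numeric vector of trait values (length >= 2).
#' @return Scalar mean pairwise distance.
#' @examples
#' mpd(c(0, 10, 20)) # 40/3
#' @export
mpd <- function(values) {
  k <- length(values)
  if (k < 2) stop("mean pairwise distance needs at least 2 values")
  s <- sort(values)
  sum((2 * seq_len(k) - k - 1) * s) / (k * (k - 1) / 2)
}

# Deterministic per-cell seed from a global seed and the cell id, so that
# SES results are reproducible regardless of the order cells are processed.
cell_seed <- function(global_seed, cell_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(cell_id))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + (global_seed %% 2147483647) * 7919) %% 2147483647)
}

#' Standardised effect size of mean pairwise distance
#'
#' Compares the observed mean pairwise colour-lightness distance of an
#' assemblage with a null model of `n_draws` alternative species sets of
#' the same richness drawn without replacement from the species pool of the
#' assemblage's biogeographical realm:
#' `ses = (observed - null_mean) / null_sd`. When the number of possible
#' subsets does not exceed `enum_cap` the null is enumerated exhaustively
#' instead of sampled.
#'
#' @param species Character vector of species in the assemblage (must all
#'   have trait values).
#' @param pool Character vector of the realm species pool (superset of
#'   `species`).
#' @param traits Named numeric vector of trait values covering the pool.
#' @param n_draws Number of null draws (default 1000).
#' @param seed Global seed; the draw seed is derived from it and `cell_id`.
#' @param cell_id Identifier used for seeding and reporting.
#' @param enum_cap Exhaustive enumeration is used when `choose(|pool|,
#'   richness) <= enum_cap` (default 10000); set to 0 to always sample.
#' @return One-row `data.frame`: `cell_id`, `richness`, `observed_mpd`,
#'   `null_mean`, `null_sd`, `ses` (NA when degenerate), `n_draws`,
#'   `degenerate`, `method`.
#' @export
ses_mpd <- function(species, pool, traits, n_draws = 1000, seed = 1,
                    cell_id = NA_character_, enum_cap = 10000) {
  species <- unique(as.character(species))
  pool <- unique(as.character(pool))
  k <- length(species)
  if (k < 2) stop("assemblage richness must be at least 2")
  if (!all(species %in% pool)) stop("pool must contain the assemblage")
  if (anyNA(traits[pool])) stop("traits missing for some pool species")
  pv <- unname(traits[pool])
  obs <- mpd(unname(traits[species]))
  m <- length(pool)

  if (enum_cap > 0 && choose(m, k) <= enum_cap) {
    subsets <- utils::combn(m, k)
    null_vals <- apply(subsets, 2, function(ix) mpd(pv[ix]))
    method <- "exhaustive"
    nd <- ncol(subsets)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(cell_seed(seed, cell_id))
    null_vals <- vapply(seq_len(n_draws),
                        function(i) mpd(pv[sample.int(m, k)]), numeric(1))
    method <- "sampled"
    nd <- n_draws
  }
  mu <- mean(null_vals)
  sdev <- stats::sd(null_vals)
  degenerate <- !is.finite(sdev) || sdev == 0
  data.frame(cell_id = cell_id, richness = k, observed_mpd = obs,
             null_mean = mu, null_sd = sdev,
             ses = if (degenerate) NA_real_ else (obs - mu) / sdev,
             n_draws = nd, degenerate = degenerate, method = method,
             stringsAsFactors = FALSE)
}

#' Colour-lightness diversity of every assemblage
#'
#' Runs [ses_mpd()] for each included grid cell with at least two species
#' carrying trait data, against the species pool of the cell's realm (all
#' species with trait data occurring in at least one included cell of that
#' realm). Singletons are skipped: their mean pairwise distance is
#' invariant.
#'
#' @param occupancy Long `data.frame` with `cell_id`, `species_id`.
#' @param cells Cell table with `cell_id`, `realm` and (optionally) the
#'   `included` flag from [filter_cells()].
#' @param traits Named numeric vector of species trait values.
#' @param n_draws,seed,enum_cap Passed to [ses_mpd()].
#' @return `data.frame` of per-cell SES results (cells in sorted order).
#' @export
assemblage_ses <- function(occupancy, cells, traits, n_draws = 1000,
                           seed = 1, enum_cap = 10000) {
  if ("included" %in% names(cells)) cells <- cells[cells$included, ]
  occ <- unique(occupancy[, c("cell_id", "species_id")])
  occ <- occ[occ$cell_id %in% cells$cell_id &
               occ$species_id %in% names(traits), ]
  realm_of <- stats::setNames(as.character(cells$realm), cells$cell_id)
  pools <- lapply(split(occ$species_id, realm_of[occ$cell_id]), unique)
  by_cell <- split(occ$species_id, occ$cell_id)
  by_cell <- by_cell[vapply(by_cell, length, integer(1)) >= 2]
  res <- lapply(sort(names(by_cell)), function(cid) {
    ses_mpd(by_cell[[cid]], pools[[realm_of[[cid]]]], traits,
            n_draws = n_draws, seed = seed, cell_id = cid,
            enum_cap = enum_cap)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(cell_id = character(0), richness = integer(0),
                      observed_mpd = numeric(0), null_mean = numeric(0),
                      null_sd = numeric(0), ses = numeric(0),
                      n_draws = integer(0), degenerate = logical(0),
                      method = character(0))
  }
  rownames(out) <- NULL
  out
}
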