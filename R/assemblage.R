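#' Partition grid cells by the water filter
#'
#' Cells containing more than 50% water (strict inequality) are excluded
#' from all assemblage-level analyses.
#'
#' @param cells `data.frame` with at least `cell_id` and `water_fraction`.
#' @param water_threshold Exclusion threshold (default 0.5).
#' @return The cells with logical column `included` and character column
#'   `exclusion_reason` (`NA` or `"water"`).
#' @export
filter_cells <- function(cells, water_threshold = 0.5) {
  stopifnot(all(c("cell_id", "water_fraction") %in% names(cells)))
  wf <- cells$water_fraction
  if (any(!is.finite(wf)) || any(wf < 0 | wf > 1)) {
    stop("water_fraction must be finite and in [0, 1]")
  }
  cells$included <- wf <= water_threshold
  cells$exclusion_reason <- ifelse(cells$included, NA_character_, "water")
  cells
}

#' Per-assemblage trait summaries
#'
#' Unweighted means of the raw trait and, when supplied, its phylogenetic
#' (P) and species-specific (S) components across the species co-occurring
#' in each cell. Species without colour data count towards total richness
#' but not towards the means.
#'
#' @param occupancy Long `data.frame` with columns `cell_id`, `species_id`.
#'   Duplicate records are ignored.
#' @param traits `data.frame` keyed by `species_id` with column `raw` and
#'   optionally `P` and `S`.
#' @return `data.frame` with one row per cell: `cell_id`,
#'   `n_species_total`, `n_species_with_colour`, `coverage`, `mean_raw`,
#'   and `mean_P`/`mean_S` when available (NA when no species has data).
#' @export
assemblage_trait_means <- function(occupancy, traits) {
  stopifnot(all(c("cell_id", "species_id") %in% names(occupancy)),
            "species_id" %in% names(traits), "raw" %in% names(traits))
  occ <- unique(occupancy[, c("cell_id", "species_id")])
  idx <- match(occ$species_id, traits$species_id)
  has <- !is.na(idx)
  comp_cols <- intersect(c("raw", "P", "S"), names(traits))
  cell <- factor(occ$cell_id)
  n_total <- as.integer(table(cell))
  out <- data.frame(cell_id = levels(cell), n_species_total = n_total,
                    stringsAsFactors = FALSE)
  n_with <- tapply(has, cell, sum)
  out$n_species_with_colour <- as.integer(n_with)
  out$coverage <- out$n_species_with_colour / out$n_species_total
  for (cc in comp_cols) {
    vals <- rep(NA_real_, nrow(occ))
    vals[has] <- traits[[cc]][idx[has]]
    m <- tapply(vals, cell, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    })
    out[[paste0("mean_", cc)]] <- as.numeric(m)
  }
  rownames(out) <- NULL
  out
}

#' Partition assemblage summaries by the data-coverage filter
#'
#' Assemblages for which colour data cover less than 33% of species are
#' excluded, as are empty assemblages.
#'
#' @param summaries Output of [assemblage_trait_means()].
#' @param coverage_threshold Minimum fraction of species with colour data
#'   (default 0.33; strict `<` excludes).
#' @return The summaries with columns `included` and `exclusion_reason`
#'   (`NA`, `"coverage"`, or `"empty"`).
#' @export
filter_assemblages <- function(summaries, coverage_threshold = 0.33) {
  stopifnot(all(c("n_species_total", "n_species_with_colour") %in%
                  names(summaries)))
  empty <- summaries$n_species_total == 0 |
    summaries$n_species_with_colour == 0
  low <- !empty & summaries$coverage < coverage_threshold
  summaries$included <- !(empty | low)
  summaries$exclusion_reason <- ifelse(empty, "empty",
                                       ifelse(low, "coverage", NA_character_))
  summaries
}

#' Species-level environmental range means
#'
#' Unweighted means of each environmental variable over the included cells
#' a species occupies, plus range size and a mean absolute latitude proxy
#' when a `lat` column is present.
#'
#' @param occupancy Long `data.frame` with `cell_id`, `species_id`.
#' @param cells Cell table carrying the environment columns; only rows with
#'   `included == TRUE` (see [filter_cells()]) contribute. If no `included`
#'   column is present all cells are used.
#' @param env_vars Environment columns to average.
#' @param quiet Suppress the message listing species with no included cell.
#' @return `data.frame` with `species_id`, one column per variable,
#'   `range_size` (number of cells), and `mean_abs_lat` when available.
#' @export
species_range_environment <- function(occupancy, cells,
                                      env_vars = c("MAT", "elevation",
                                                   "EVI", "UVB"),
                                      quiet = FALSE) {
  stopifnot(all(env_vars %in% names(cells)))
  if ("included" %in% names(cells)) cells <- cells[cells$included, ]
  occ <- unique(occupancy[, c("cell_id", "species_id")])
  keep <- occ$cell_id %in% cells$cell_id
  dropped <- setdiff(unique(occ$species_id), unique(occ$species_id[keep]))
  if (length(dropped) && !quiet) {
    message(sprintf("%d species with no included cell dropped", length(dropped)))
  }
  occ <- occ[keep, ]
  if (nrow(occ) == 0) {
    return(data.frame(species_id = character(0)))
  }
  ci <- match(occ$cell_id, cells$cell_id)
  sp <- factor(occ$species_id)
  out <- data.frame(species_id = levels(sp), stringsAsFactors = FALSE)
  for (v in env_vars) {
    out[[v]] <- as.numeric(tapply(cells[[v]][ci], sp, mean))
  }
  out$range_size <- as.integer(table(sp))
  if ("lat" %in% names(cells)) {
    out$mean_abs_lat <- as.numeric(tapply(abs(cells$lat[ci]), sp, mean))
  }
  rownames(out) <- NULL
  out
}

#' Rasterise rectangular species ranges onto the grid
#'
#' Synthetic stand-in for vector range-map gridding: a species occupies
#' every included cell whose centre lies inside its rectangle (bounds
#' inclusive).
#'
#' @param ranges `data.frame` with columns `species_id`, `xmin`, `xmax`,
#'   `ymin`, `ymax` in grid units.
#' @param cells Cell table with `cell_id`, `x`, `y`; rows with
#'   `included == FALSE` are skipped if the column exists.
#' @param quiet Suppress the message listing species with empty ranges.
#' @return Long occupancy `data.frame` with `cell_id`, `species_id`.
#' @export
rasterize_rect_ranges <- function(ranges, cells, quiet = FALSE) {
  stopifnot(all(c("species_id", "xmin", "xmax", "ymin", "ymax") %in%
                  names(ranges)))
  if ("included" %in% names(cells)) cells <- cells[cells$included, ]
  res <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    hit <- cells$x >= r$xmin & cells$x <= r$xmax &
      cells$y >= r$ymin & cells$y <= r$ymax
    if (!any(hit)) return(NULL)
    data.frame(cell_id = cells$cell_id[hit],
               species_id = r$species_id, stringsAsFactors = FALSE)
  })
  empty <- vapply(res, is.null, logical(1))
  if (any(empty) && !quiet) {
    message(sprintf("%d species with empty rectangles dropped: %s",
                    sum(empty),
                    paste(ranges$species_id[empty], collapse = ", ")))
  }
  out <- do.call(rbind, res[!empty])
  if (is.null(out)) out <- data.frame(cell_id = character(0),
                                      species_id = character(0))
  rownames(out) <- NULL
  out
}
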