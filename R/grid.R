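#' Grid occurrence records onto a half-degree lattice
#'
#' Cells are half-open with the west/south edge inclusive, anchored at
#' (-180, -90): a point maps to its cell by floor division. Duplicate records
#' collapse to presence.
#'
#' @param records data.frame with columns `taxon`, `lon`, `lat`.
#' @param resolution cell size in degrees (default 0.5).
#' @return an `occurrence_grid`: list with `cells` (data.frame: cell, lon,
#'   lat of cell centers), `incidence` (species x cells logical matrix),
#'   `resolution`, and slots `climate` / `biome` (NULL until attached).
#' @export
grid_occurrences <- function(records, resolution = 0.5) {
  stopifnot(all(c("taxon", "lon", "lat") %in% names(records)))
  ok <- is.finite(records$lon) & is.finite(records$lat) &
    records$lon >= -180 & records$lon < 180 &
    records$lat >= -90 & records$lat < 90
  if (any(!ok))
    message(sum(!ok), " records with non-finite or out-of-range coordinates dropped")
  records <- records[ok, , drop = FALSE]
  col <- floor(records$lon / resolution)
  row <- floor(records$lat / resolution)
  cell <- paste0(col, "_", row)
  species <- sort(unique(as.character(records$taxon)))
  cells <- unique(data.frame(cell = cell, col = col, row = row))
  cells <- cells[order(cells$col, cells$row), ]
  cells$lon <- (cells$col + 0.5) * resolution
  cells$lat <- (cells$row + 0.5) * resolution
  inc <- matrix(FALSE, length(species), nrow(cells),
                dimnames = list(species, cells$cell))
  inc[cbind(match(as.character(records$taxon), species), match(cell, cells$cell))] <- TRUE
  structure(list(cells = cells[, c("cell", "lon", "lat")], incidence = inc,
                 resolution = resolution, climate = NULL, biome = NULL),
            class = "occurrence_grid")
}

#' Apply richness and latitude filters to a grid
#'
#' Cells with fewer than `min_taxa` species or with their center beyond
#' `lat_limit` degrees latitude are dropped; cells inside `exempt_region`
#' bypass the latitude filter only (they must still meet `min_taxa`).
#'
#' @param grid an `occurrence_grid`.
#' @param min_taxa minimum species per retained cell (>= 1).
#' @param lat_limit absolute latitude bound in degrees applied to cell
#'   centers (default 33).
#' @param exempt_region optional `c(lon_min, lon_max, lat_min, lat_max)`
#'   bounding box, or a function `(lon, lat) -> logical`.
#' @return filtered `occurrence_grid`.
#' @export
apply_filters <- function(grid, min_taxa, lat_limit = 33, exempt_region = NULL) {
  stopifnot(inherits(grid, "occurrence_grid"), min_taxa >= 1)
  rich <- colSums(grid$incidence)
  in_lat <- abs(grid$cells$lat) <= lat_limit
  if (!is.null(exempt_region)) {
    ex <- if (is.function(exempt_region)) {
      exempt_region(grid$cells$lon, grid$cells$lat)
    } else {
      grid$cells$lon >= exempt_region[1] & grid$cells$lon <= exempt_region[2] &
        grid$cells$lat >= exempt_region[3] & grid$cells$lat <= exempt_region[4]
    }
    in_lat <- in_lat | ex
  }
  keep <- rich >= min_taxa & in_lat
  subset_grid(grid, keep)
}

subset_grid <- function(grid, keep) {
  grid$cells <- grid$cells[keep, , drop = FALSE]
  grid$incidence <- grid$incidence[, keep, drop = FALSE]
  if (!is.null(grid$climate)) grid$climate <- grid$climate[keep, , drop = FALSE]
  if (!is.null(grid$biome)) grid$biome <- grid$biome[keep]
  grid
}

#' Attach per-cell climate predictors to a grid
#'
#' Values are matched by cell: points of `climate_df` are assigned to cells by
#' the same floor rule and averaged within each cell (identity when the input
#' is already at cell resolution). Cells without coverage get `NA`.
#'
#' @param grid an `occurrence_grid`.
#' @param climate_df data.frame with `lon`, `lat`, and predictor columns.
#' @return the grid with a `climate` data.frame (rows match `grid$cells`).
#' @export
attach_climate <- function(grid, climate_df) {
  res <- grid$resolution
  cell <- paste0(floor(climate_df$lon / res), "_", floor(climate_df$lat / res))
  vars <- setdiff(names(climate_df), c("lon", "lat"))
  agg <- stats::aggregate(climate_df[vars], by = list(cell = cell), FUN = mean)
  m <- agg[match(grid$cells$cell, agg$cell), vars, drop = FALSE]
  rownames(m) <- grid$cells$cell
  grid$climate <- m
  grid
}

#' Attach per-cell biome labels
#'
#' @param grid an `occurrence_grid`.
#' @param biome_df data.frame with `lon`, `lat`, `biome`; points assigned to
#'   cells by the floor rule, ties broken by first occurrence.
#' @return grid with a `biome` character vector (NA where uncovered).
#' @export
attach_biome <- function(grid, biome_df) {
  res <- grid$resolution
  cell <- paste0(floor(biome_df$lon / res), "_", floor(biome_df$lat / res))
  first <- !duplicated(cell)
  grid$biome <- as.character(biome_df$biome[first][match(grid$cells$cell, cell[first])])
  grid
}

#' Dry season length
#'
#' The longest run of consecutive months with precipitation below 100 mm,
#' evaluated circularly across the December-January boundary.
#'
#' @param monthly_precip numeric vector of 12 monthly precipitation values (mm).
#' @return integer in 0..12.
#' @export
dry_season_length <- function(monthly_precip) {
  if (length(monthly_precip) != 12L) stop("need exactly 12 monthly values")
  stopifnot(all(monthly_precip >= 0))
  dry <- monthly_precip < 100
  if (all(dry)) return(12L)
  if (!any(dry)) return(0L)
  r <- rle(c(dry, dry))
  as.integer(max(r$lengths[r$values]))
}

#' Per-species medians of climate predictors
#'
#' @param records data.frame with `taxon`, `lon`, `lat`.
#' @param climate_df data.frame with `lon`, `lat` (cell centers or finer) and
#'   predictor columns; records are matched to cells by the floor rule.
#' @param resolution cell size in degrees.
#' @return data.frame: one row per taxon, median of each predictor over its
#'   covered occurrence cells; attribute `n_skipped` counts records without
#'   climate coverage.
#' @export
species_climate_summary <- function(records, climate_df, resolution = 0.5) {
  vars <- setdiff(names(climate_df), c("lon", "lat"))
  key <- function(lon, lat) paste0(floor(lon / resolution), "_", floor(lat / resolution))
  clim_key <- key(climate_df$lon, climate_df$lat)
  idx <- match(key(records$lon, records$lat), clim_key)
  skipped <- sum(is.na(idx))
  if (skipped) message(skipped, " records without climate coverage skipped")
  ok <- !is.na(idx)
  vals <- climate_df[idx[ok], vars, drop = FALSE]
  out <- stats::aggregate(vals, by = list(taxon = as.character(records$taxon[ok])),
                          FUN = stats::median)
  attr(out, "n_skipped") <- skipped
  out
}

#' Pairwise biome distance
#'
#' Same biome: 0; different biomes: 1; pairs of the savanna/succulent overlap
#' class with either savanna or succulent: 0.5.
#'
#' @param biome_i,biome_j biome labels.
#' @param overlap_class label of the intermediate overlap biome.
#' @param overlap_members the two biomes the overlap class intergrades with.
#' @return 0, 0.5 or 1.
#' @export
biome_distance <- function(biome_i, biome_j, overlap_class = "overlap",
                           overlap_members = c("savanna", "succulent")) {
  if (is.na(biome_i) || is.na(biome_j)) stop("both cells must carry a biome label")
  if (biome_i == biome_j) return(0)
  pair <- c(biome_i, biome_j)
  if (overlap_class %in% pair && any(overlap_members %in% pair)) return(0.5)
  1
}
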