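#' Occurrence set
#'
#' A labelled set of presence coordinates (WGS84 lon/lat degrees).
#'
#' @param species_id Species label.
#' @param lon,lat Numeric coordinate vectors of equal length.
#' @param source_tag Free-form provenance label.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species_id, lon, lat, source_tag = "") {
  stopifnot(length(lon) == length(lat))
  structure(list(species_id = species_id,
                 points = data.frame(lon = as.numeric(lon),
                                     lat = as.numeric(lat)),
                 source_tag = source_tag),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set '%s': %d point(s)%s\n", x$species_id,
              nrow(x$points),
              if (nzchar(x$source_tag)) paste0(" [", x$source_tag, "]") else ""))
  invisible(x)
}

#' Read occurrence records from CSV
#'
#' Expects columns `species`, `lon`, `lat` (any order). Rows whose
#' coordinates fail to parse as numbers are excluded and counted, never
#' silently dropped: the per-species malformed counts are attached as the
#' `"malformed"` attribute and reported via a warning.
#'
#' @param path CSV file path.
#' @return Named list of `occurrence_set`, one per species, with attribute
#'   `malformed` (named integer vector of excluded row counts, total under
#'   `"total"`).
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species, lon, lat")
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- is.na(lon) | is.na(lat) | !nzchar(df$species)
  if (all(bad)) stop("no valid occurrence rows in ", path)
  if (any(bad))
    warning(sum(bad), " malformed occurrence row(s) excluded")
  ok <- df[!bad, , drop = FALSE]
  lon <- lon[!bad]; lat <- lat[!bad]
  out <- lapply(split(seq_len(nrow(ok)), ok$species), function(i) {
    occurrence_set(ok$species[i[1]], lon[i], lat[i], source_tag = basename(path))
  })
  mal <- table(factor(df$species[bad], levels = unique(df$species)))
  attr(out, "malformed") <- c(as.integer(mal), total = sum(bad))
  out
}

#' Write an occurrence set (or list of sets) to CSV
#' @param occ An `occurrence_set` or list of them.
#' @param path Output path.
#' @export
write_occurrences <- function(occ, path) {
  if (inherits(occ, "occurrence_set")) occ <- list(occ)
  df <- do.call(rbind, lapply(occ, function(o)
    data.frame(species = o$species_id, lon = o$points$lon, lat = o$points$lat)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

great_circle_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = 6371)
}

#' Spatially thin an occurrence set
#'
#' Greedy order-dependent rarefaction (the SDM-Toolbox algorithm class):
#' points are processed in input order and a point is kept only if its
#' great-circle distance to every already-kept point is at least
#' `min_distance_km`. Pairs at exactly the threshold are both retained.
#' Thinning is idempotent and the retained count is non-increasing in the
#' distance.
#'
#' @param occ An `occurrence_set`.
#' @param min_distance_km Minimum pairwise distance in km (>= 0).
#' @return The thinned `occurrence_set`.
#' @export
thin_occurrences <- function(occ, min_distance_km) {
  stopifnot(min_distance_km >= 0)
  pts <- as.matrix(occ$points)
  n <- nrow(pts)
  if (n <= 1 || min_distance_km == 0) {
    if (min_distance_km == 0) return(occ)
  }
  keep <- logical(n)
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    if (nrow(kept) == 0 ||
        all(great_circle_km(kept, pts[i, ]) >= min_distance_km)) {
      keep[i] <- TRUE
      kept <- rbind(kept, pts[i, ])
    }
  }
  occurrence_set(occ$species_id, pts[keep, 1], pts[keep, 2],
                 source_tag = occ$source_tag)
}

#' Map occurrences to occupied grid cells
#'
#' Cells are half-open `[edge, edge + size)` in longitude and
#' `(edge - size, edge]` descending in latitude, i.e. a coordinate lying
#' exactly on a shared edge belongs to the cell for which it is the left/top
#' bound. Points outside the grid extent are dropped with a warning; occupied
#' cells are deduplicated.
#'
#' @param occ An `occurrence_set`.
#' @param grid A `grid_spec`.
#' @return Integer vector of unique column-major cell indices, with
#'   attributes `rows`, `cols` and `n_dropped`.
#' @export
occurrences_to_cells <- function(occ, grid) {
  s <- grid$cell_size_deg
  col <- floor((occ$points$lon - grid$origin_lon) / s) + 1
  row <- floor((grid$origin_lat - occ$points$lat) / s) + 1
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  if (any(!inside))
    warning(sum(!inside), " occurrence point(s) outside the grid extent dropped")
  col <- col[inside]; row <- row[inside]
  if (length(col) == 0) stop("no occurrence falls inside the grid extent")
  idx <- unique((col - 1) * grid$n_rows + row)
  structure(as.integer(idx),
            rows = as.integer(((idx - 1) %% grid$n_rows) + 1),
            cols = as.integer(((idx - 1) %/% grid$n_rows) + 1),
            n_dropped = sum(!inside))
}
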