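#' Classify a continuous suitability map into four levels
#'
#' Levels: non (0) below `t_low`; low (1) in `[t_low, t_med)`; medium (2) in
#' `[t_med, t_high)`; high (3) at or above `t_high`. NA (nodata) propagates.
#'
#' @param suitability Matrix of values in \[0, 1\].
#' @param grid The `grid_spec` of the map.
#' @param thresholds Increasing numeric vector `(t_low, t_med, t_high)`
#'   strictly inside (0, 1).
#' @return Object of class `classified_map`: list with `grid`, `levels`
#'   (integer matrix, `NA` for nodata) and `thresholds`.
#' @export
classify_suitability <- function(suitability, grid,
                                 thresholds = c(0.1, 0.3, 0.5)) {
  stopifnot(length(thresholds) == 3)
  if (!(0 < thresholds[1] && thresholds[1] < thresholds[2] &&
        thresholds[2] < thresholds[3] && thresholds[3] < 1))
    stop("thresholds must satisfy 0 < t_low < t_med < t_high < 1")
  v <- suitability
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  lv <- matrix(NA_integer_, nrow(v), ncol(v))
  lv[!is.na(v)] <- 0L
  lv[!is.na(v) & v >= thresholds[1]] <- 1L
  lv[!is.na(v) & v >= thresholds[2]] <- 2L
  lv[!is.na(v) & v >= thresholds[3]] <- 3L
  structure(list(grid = grid, levels = lv, thresholds = thresholds),
            class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  tab <- table(factor(x$levels, levels = 0:3,
                      labels = c("non", "low", "medium", "high")))
  cat(sprintf("classified_map (%d x %d), thresholds (%g, %g, %g)\n",
              x$grid$n_rows, x$grid$n_cols,
              x$thresholds[1], x$thresholds[2], x$thresholds[3]))
  print(tab)
  invisible(x)
}

check_shared_grid <- function(maps) {
  g <- if (inherits(maps[[1]], "classified_map")) maps[[1]]$grid else NULL
  for (m in maps[-1]) {
    if (!is.null(g) && !same_grid(m$grid, g)) stop("grids differ across maps")
  }
  invisible(TRUE)
}

#' Average suitability maps across SSP scenarios
#'
#' Cell-wise arithmetic mean of the per-scenario suitability maps of one
#' horizon; a cell is nodata if it is nodata in any input.
#'
#' @param maps List of suitability matrices on a shared grid.
#' @return Matrix of mean suitability.
#' @export
scenario_mean <- function(maps) {
  stopifnot(length(maps) >= 1)
  dims <- vapply(maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("maps have mismatched dimensions")
  out <- Reduce(`+`, maps) / length(maps)
  out
}

#' Equal-weight prey overlay
#'
#' The predator suitability index: the unweighted cell-wise mean of the prey
#' suitability maps, standardized by min-max rescaling to \[0, 1\] over
#' valid cells. A degenerate constant mean maps to 0 everywhere.
#'
#' @param prey_maps List of suitability matrices in \[0, 1\] on a shared
#'   grid.
#' @return Matrix in \[0, 1\].
#' @export
prey_overlay <- function(prey_maps) {
  stopifnot(length(prey_maps) >= 1)
  dims <- vapply(prey_maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("maps have mismatched dimensions")
  for (m in prey_maps)
    if (any(m < 0 | m > 1, na.rm = TRUE)) stop("inputs must lie in [0, 1]")
  mean_map <- Reduce(`+`, prey_maps) / length(prey_maps)
  rng <- range(mean_map, na.rm = TRUE)
  if (diff(rng) == 0) {
    mean_map[!is.na(mean_map)] <- 0
    return(mean_map)
  }
  (mean_map - rng[1]) / (rng[2] - rng[1])
}

#' Temporal stability superposition
#'
#' Superimposes the classified current, 2050 and 2070 maps: a cell's stable
#' level is the minimum of its three period levels, so a cell is "stably
#' high" only if high in every period.
#'
#' @param classified_list List of exactly three `classified_map`s (current,
#'   2050, 2070) sharing grid and thresholds.
#' @return A `classified_map` of stable levels.
#' @export
stability_superposition <- function(classified_list) {
  if (length(classified_list) != 3)
    stop("exactly three classified maps (current, 2050, 2070) are required")
  check_shared_grid(classified_list)
  th <- classified_list[[1]]$thresholds
  for (m in classified_list[-1])
    if (max(abs(m$thresholds - th)) > 1e-12)
      stop("classification thresholds differ across periods")
  lv <- pmin(classified_list[[1]]$levels, classified_list[[2]]$levels,
             classified_list[[3]]$levels)
  structure(list(grid = classified_list[[1]]$grid, levels = lv,
                 thresholds = th),
            class = "classified_map")
}

#' Area of each suitability level
#'
#' Sums the spherical cell areas (radius 6371 km) per level.
#'
#' @param classified A `classified_map`.
#' @return Named numeric vector (`non`, `low`, `medium`, `high`) of km^2.
#' @export
class_areas <- function(classified) {
  A <- cell_area_matrix(classified$grid)
  lv <- classified$levels
  out <- vapply(0:3, function(l) sum(A[!is.na(lv) & lv == l]), numeric(1))
  stats::setNames(out, c("non", "low", "medium", "high"))
}

trunc2 <- function(x) trunc(x * 100) / 100

#' Habitat-change accounting table
#'
#' Combines current and future level areas into a long table with
#' percent-change columns relative to current:
#' `change = (future - current) / current * 100`, reported both at full
#' precision and truncated toward zero to two decimals (the convention used
#' when quoting such tables). Undefined (`NA`) when the current area is 0.
#'
#' @param areas_current Named list/vector: level -> current area (km^2), or
#'   a data frame with columns `species`, `level`, `area_km2`.
#' @param areas_future_list Named list of future-period area sets in the
#'   same shape (names become period labels).
#' @param species Species label used when plain vectors are given.
#' @return Data frame of class `area_table` with columns `species`, `level`,
#'   `period`, `area_km2`, `change_pct` (full precision) and
#'   `change_pct_2dp` (truncated to 2 decimals).
#' @export
change_table <- function(areas_current, areas_future_list, species = "sp") {
  to_df <- function(a, period) {
    if (is.data.frame(a)) {
      a$period <- period
      a
    } else {
      data.frame(species = species, level = names(a),
                 area_km2 = as.numeric(a), period = period,
                 stringsAsFactors = FALSE)
    }
  }
  cur <- to_df(areas_current, "current")
  rows <- list(transform(cur, change_pct = NA_real_,
                         change_pct_2dp = NA_real_))
  for (pd in names(areas_future_list)) {
    fut <- to_df(areas_future_list[[pd]], pd)
    mg <- merge(fut, cur[, c("species", "level", "area_km2")],
                by = c("species", "level"), suffixes = c("", "_current"),
                sort = FALSE)
    mg$change_pct <- ifelse(mg$area_km2_current > 0,
                            (mg$area_km2 - mg$area_km2_current) /
                              mg$area_km2_current * 100, NA_real_)
    mg$change_pct_2dp <- trunc2(mg$change_pct)
    rows[[length(rows) + 1]] <-
      mg[, c("species", "level", "period", "area_km2", "change_pct",
             "change_pct_2dp")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("area_table", "data.frame")
  out
}

#' Summary mean of a group of percent changes
#'
#' Arithmetic mean of signed or absolute percent changes, reported as an
#' integer. Rounding mode `"round"` (half away from zero) is the default;
#' `"trunc"` (toward zero) is available because published tables sometimes
#' truncate rather than round.
#'
#' @param changes Numeric vector of percent changes.
#' @param absolute Average absolute magnitudes instead of signed values.
#' @param report `"round"` or `"trunc"`.
#' @return Integer-valued mean percent, with the exact mean as attribute
#'   `"mean"`.
#' @export
summarize_group_change <- function(changes, absolute = FALSE,
                                   report = c("round", "trunc")) {
  report <- match.arg(report)
  stopifnot(length(changes) >= 1)
  m <- mean(if (absolute) abs(changes) else changes)
  val <- if (report == "round") sign(m) * floor(abs(m) + 0.5) else trunc(m)
  structure(as.integer(val), mean = m)
}
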