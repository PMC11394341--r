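#' Sex-specific tiger density parameters
#'
#' Conservative density estimates per 100 km^2 of habitat: 0.46 males and
#' 1.32 females (the midpoint between the mean and the minimum of published
#' density estimates, taken for conservatism). Male and female ranges are
#' not superimposed: the patch is partitioned between the sexes by
#' `sex_partition_fraction` before either density is applied.
#'
#' @param male_density Males per 100 km^2 (> 0).
#' @param female_density Females per 100 km^2 (> 0).
#' @param sex_partition_fraction Fraction of patch area allotted to each
#'   sex's exclusive range, in (0, 1); default 0.5.
#' @param rounding `"floor"` (default: whole animals only) or `"round"`.
#' @return A `density_params` list.
#' @export
density_params <- function(male_density = 0.46, female_density = 1.32,
                           sex_partition_fraction = 0.5,
                           rounding = c("floor", "round")) {
  rounding <- match.arg(rounding)
  stopifnot(male_density > 0, female_density > 0,
            sex_partition_fraction > 0, sex_partition_fraction < 1)
  structure(list(male_density = male_density,
                 female_density = female_density,
                 sex_partition_fraction = sex_partition_fraction,
                 rounding = rounding),
            class = "density_params")
}

#' Carrying capacity of a patch
#'
#' Number of males and females a patch can support:
#' `floor(area * sex_partition_fraction * density / 100)` for each sex
#' (floor applied last, after the density scaling).
#'
#' @param area_km2 Patch area(s) in km^2 (>= 0); vectorized.
#' @param params A `density_params`.
#' @return Data frame with columns `area_km2`, `n_males`, `n_females`.
#' @export
tiger_capacity <- function(area_km2, params = density_params()) {
  if (any(area_km2 < 0)) stop("patch area must be non-negative")
  rnd <- if (params$rounding == "floor") floor else round
  frac <- params$sex_partition_fraction
  data.frame(
    area_km2 = area_km2,
    n_males = as.integer(rnd(area_km2 * frac * params$male_density / 100)),
    n_females = as.integer(rnd(area_km2 * frac * params$female_density / 100))
  )
}

#' Per-patch capacity table with totals
#'
#' Applies [tiger_capacity()] to each patch and appends a totals row (the
#' sum of the per-patch integer counts, not the capacity of the summed
#' area).
#'
#' @param patches List of `patch` objects (or numeric vector of areas).
#' @param params A `density_params`.
#' @return Data frame: patch_id, area_km2, n_males, n_females; final row
#'   `patch_id = NA` holds the totals.
#' @export
capacity_table <- function(patches, params = density_params()) {
  if (length(patches) == 0)
    return(data.frame(patch_id = NA_integer_, area_km2 = 0,
                      n_males = 0L, n_females = 0L))
  if (is.numeric(patches)) {
    ids <- seq_along(patches)
    areas <- patches
  } else {
    ids <- vapply(patches, `[[`, numeric(1), "patch_id")
    areas <- vapply(patches, `[[`, numeric(1), "area_km2")
  }
  cap <- tiger_capacity(areas, params)
  out <- data.frame(patch_id = as.integer(ids), cap)
  rbind(out, data.frame(patch_id = NA_integer_,
                        area_km2 = sum(out$area_km2),
                        n_males = sum(out$n_males),
                        n_females = sum(out$n_females)))
}
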