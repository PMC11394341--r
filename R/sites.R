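#' Screening configuration for candidate sites
#'
#' @param min_patch_km2 Minimum patch area retained (default 100 km^2).
#' @param hfi_threshold Human-footprint ceiling (default 8.0); cells
#'   strictly above it count against a patch.
#' @param hfi_area_fraction Maximum tolerated fraction of patch area above
#'   the ceiling (default 0.5); strictly more than this rejects the patch.
#' @param connectivity Patch connectivity, 8 (default) or 4.
#' @return A `screening_config` list.
#' @export
screening_config <- function(min_patch_km2 = 100, hfi_threshold = 8.0,
                             hfi_area_fraction = 0.5, connectivity = 8) {
  stopifnot(min_patch_km2 > 0, hfi_threshold > 0,
            hfi_area_fraction > 0, hfi_area_fraction <= 1,
            connectivity %in% c(4, 8))
  structure(list(min_patch_km2 = min_patch_km2,
                 hfi_threshold = hfi_threshold,
                 hfi_area_fraction = hfi_area_fraction,
                 connectivity = connectivity),
            class = "screening_config")
}

# connected-component labeling of a logical matrix by iterative flood fill
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cell - 1L) %% nr) + 1L
      c0 <- ((cell - 1L) %/% nr) + 1L
      nrow_ <- r + dr
      ncol_ <- c0 + dc
      okn <- nrow_ >= 1L & nrow_ <= nr & ncol_ >= 1L & ncol_ <= nc
      nidx <- (ncol_[okn] - 1L) * nr + nrow_[okn]
      nidx <- nidx[mask[nidx] & lab[nidx] == 0L]
      if (length(nidx) > 0) {
        lab[nidx] <- cur
        stack <- c(stack, nidx)
      }
    }
  }
  lab
}

#' Extract connected patches from a high-suitability mask
#'
#' Labels connected components (8-connectivity by default, the region-group
#' convention; 4 by option), computes each patch's spherical area from its
#' cell areas, sorts patches by area descending and assigns ids in that
#' order.
#'
#' @param high_mask Logical matrix (`TRUE` = high-suitability cell); `NA`
#'   treated as `FALSE`.
#' @param grid The `grid_spec` of the mask.
#' @param connectivity 8 (default) or 4.
#' @return List of `patch` objects (fields `patch_id`, `cells`, `area_km2`),
#'   empty when the mask is empty.
#' @export
extract_patches <- function(high_mask, grid, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  mask <- !is.na(high_mask) & high_mask
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0) return(list())
  A <- cell_area_matrix(grid)
  patches <- lapply(seq_len(n), function(i) {
    cells <- which(lab == i)
    list(cells = cells, area_km2 = sum(A[cells]))
  })
  ord <- order(vapply(patches, `[[`, numeric(1), "area_km2"),
               decreasing = TRUE)
  patches <- patches[ord]
  for (i in seq_along(patches)) {
    patches[[i]]$patch_id <- i
    class(patches[[i]]) <- "patch"
  }
  patches
}

#' Derive a human-footprint compatibility threshold from a reference range
#'
#' Takes the given quantile (default the maximum) of footprint values inside
#' a known long-term survival range and rounds it up to one decimal, giving
#' the ceiling below which the focal species is known to persist.
#'
#' @param known_range_mask Logical matrix of the reference range (non-empty).
#' @param hfi Human-footprint matrix.
#' @param quantile Quantile in \[0, 1\] (default 1, the maximum).
#' @return Threshold rounded up to one decimal.
#' @export
derive_hfi_threshold <- function(known_range_mask, hfi, quantile = 1.0) {
  v <- hfi[!is.na(known_range_mask) & known_range_mask]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("reference range mask is empty")
  q <- stats::quantile(v, quantile, names = FALSE)
  ceiling(q * 10) / 10
}

#' Fraction of a patch's area above a footprint threshold
#'
#' Area-weighted fraction of the patch with footprint strictly greater than
#' the threshold. Cells with missing footprint are excluded from both
#' numerator and denominator, with the count recorded as attribute
#' `"n_nodata"`.
#'
#' @param patch A `patch`.
#' @param hfi Human-footprint matrix.
#' @param grid The shared `grid_spec`.
#' @param threshold Footprint threshold.
#' @return Fraction in \[0, 1\].
#' @export
hfi_exceed_fraction <- function(patch, hfi, grid, threshold) {
  A <- cell_area_matrix(grid)
  h <- hfi[patch$cells]
  a <- A[patch$cells]
  nod <- is.na(h)
  h <- h[!nod]; a <- a[!nod]
  if (length(h) == 0) stop("patch has no valid footprint cells")
  structure(sum(a[h > threshold]) / sum(a), n_nodata = sum(nod))
}

#' Screen patches by minimum area and human-footprint rules
#'
#' A patch is kept iff its area is at least `min_patch_km2` AND the fraction
#' of its area with footprint strictly above `hfi_threshold` does not exceed
#' `hfi_area_fraction` (strictly "more than" the fraction rejects; exactly
#' at the boundary is kept). Every rejection is logged with its reason.
#'
#' @param patches List of `patch` objects.
#' @param hfi Human-footprint matrix.
#' @param grid The shared `grid_spec`.
#' @param config A `screening_config`.
#' @return List with `core` (kept patches, each annotated with
#'   `hfi_exceed_fraction`) and `rejections` (data frame: patch_id,
#'   area_km2, hfi_exceed_fraction, reason).
#' @export
screen_patches <- function(patches, hfi, grid, config = screening_config()) {
  core <- list()
  rej <- data.frame(patch_id = integer(0), area_km2 = numeric(0),
                    hfi_exceed_fraction = numeric(0), reason = character(0))
  for (p in patches) {
    fr <- as.numeric(hfi_exceed_fraction(p, hfi, grid, config$hfi_threshold))
    p$hfi_exceed_fraction <- fr
    reason <- NULL
    if (p$area_km2 < config$min_patch_km2) {
      reason <- sprintf("area %.2f km2 < %.2f km2 minimum",
                        p$area_km2, config$min_patch_km2)
    } else if (fr > config$hfi_area_fraction) {
      reason <- sprintf("%.1f%% of area above HFI %.1f (limit %.0f%%)",
                        fr * 100, config$hfi_threshold,
                        config$hfi_area_fraction * 100)
    }
    if (is.null(reason)) {
      core[[length(core) + 1]] <- p
    } else {
      rej <- rbind(rej, data.frame(patch_id = p$patch_id,
                                   area_km2 = p$area_km2,
                                   hfi_exceed_fraction = fr,
                                   reason = reason))
    }
  }
  list(core = core, rejections = rej)
}

#' Protected-area overlap of core patches
#'
#' Annotates each patch with its overlap area against the protected-area
#' mask and the names of the individual protected areas it intersects, and
#' summarizes the total overlap percentage (to one decimal).
#'
#' @param patches List of `patch` objects.
#' @param pa A `protected_areas` object, or a plain logical mask matrix.
#' @param grid The shared `grid_spec`.
#' @return List with `patches` (annotated: `pa_overlap_km2`, `pa_names`) and
#'   `summary` (total_core_km2, overlap_km2, overlap_pct).
#' @export
pa_overlap <- function(patches, pa, grid) {
  if (inherits(pa, "protected_areas")) {
    mask <- pa$mask
    pmasks <- pa$polygon_masks
  } else {
    mask <- pa
    pmasks <- list()
  }
  A <- cell_area_matrix(grid)
  total <- 0; overlap <- 0
  out <- lapply(patches, function(p) {
    inpa <- mask[p$cells]
    p$pa_overlap_km2 <- sum(A[p$cells][inpa])
    p$pa_names <- names(pmasks)[vapply(pmasks, function(m)
      any(m[p$cells]), logical(1))]
    p
  })
  total <- sum(vapply(out, `[[`, numeric(1), "area_km2"))
  overlap <- sum(vapply(out, `[[`, numeric(1), "pa_overlap_km2"))
  pct <- if (total > 0) round(overlap / total * 100, 1) else 0
  list(patches = out,
       summary = list(total_core_km2 = total, overlap_km2 = overlap,
                      overlap_pct = pct))
}

#' Ranked core-site report
#'
#' Top patches by area (descending; ties broken by patch id), with
#' protected-area names and sex-specific carrying capacity.
#'
#' @param core_patches List of (annotated) `patch` objects.
#' @param top_n Number of rows (default 20; fewer if fewer patches).
#' @param density A `density_params` for the capacity columns.
#' @return Data frame: rank, patch_id, area_km2 (2 decimals),
#'   protected_areas, n_males, n_females.
#' @export
rank_report <- function(core_patches, top_n = 20,
                        density = density_params()) {
  if (length(core_patches) == 0)
    return(data.frame(rank = integer(0), patch_id = integer(0),
                      area_km2 = numeric(0), protected_areas = character(0),
                      n_males = integer(0), n_females = integer(0)))
  areas <- vapply(core_patches, `[[`, numeric(1), "area_km2")
  ids <- vapply(core_patches, `[[`, numeric(1), "patch_id")
  ord <- order(-areas, ids)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  cap <- tiger_capacity(areas[ord], density)
  data.frame(
    rank = seq_along(ord),
    patch_id = as.integer(ids[ord]),
    area_km2 = round(areas[ord], 2),
    protected_areas = vapply(core_patches[ord], function(p) {
      if (is.null(p$pa_names) || length(p$pa_names) == 0) ""
      else paste(p$pa_names, collapse = "; ")
    }, character(1)),
    n_males = cap$n_males,
    n_females = cap$n_females,
    stringsAsFactors = FALSE
  )
}
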