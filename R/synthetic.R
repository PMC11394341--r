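#' Synthetic landscape generators
#'
#' These generators produce all inputs the screening pipeline needs —
#' environmental stacks with controlled inter-layer correlation, occurrence
#' points drawn from a known suitability surface, a distance-decay human
#' footprint field, and random protected-area polygons — so that every
#' downstream stage can be exercised against known truth without any
#' external data download.
#'
#' @name synthetic
NULL

# 1-D Gaussian smoothing operator (n x n, rows renormalized at the edges so
# a constant field stays constant).
smoothing_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  idx <- seq_len(n)
  S <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
  S[abs(row(S) - col(S)) > r] <- 0
  S / rowSums(S)
}

#' Generate an environmental stack of correlated Gaussian random fields
#'
#' Each layer is a spatially smoothed white-noise field; cross-layer
#' correlation is imposed by mixing independent standardized fields through
#' the symmetric square root of the target correlation matrix, so the
#' empirical pairwise correlations approach the target as the grid grows.
#'
#' @param grid A `grid_spec`.
#' @param layer_names Character vector of layer names.
#' @param target_correlation Symmetric positive-semidefinite matrix with unit
#'   diagonal, one row per layer. Defaults to the identity (independent
#'   layers).
#' @param smoothness Gaussian smoothing length scale in cells.
#' @param seed Integer seed; output is reproducible given the seed.
#' @return An `env_stack` with standardized (mean ~0, sd ~1) layers.
#' @export
gen_env_stack <- function(grid, layer_names,
                          target_correlation = diag(length(layer_names)),
                          smoothness = 3, seed = 1) {
  k <- length(layer_names)
  stopifnot(k >= 1)
  C <- as.matrix(target_correlation)
  if (nrow(C) != k || ncol(C) != k)
    stop("target_correlation dimension must equal the number of layers")
  if (max(abs(C - t(C))) > 1e-8) stop("target_correlation must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8)
    stop("target_correlation must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("target_correlation is not positive-semidefinite (min eigenvalue ",
         format(min(ev$values)), ")")
  # symmetric matrix square root; handles singular (r = 1) targets
  M <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)

  set.seed(seed)
  Sr <- smoothing_operator(grid$n_rows, smoothness)
  Sc <- smoothing_operator(grid$n_cols, smoothness)
  Z <- matrix(0, grid$n_rows * grid$n_cols, k)
  for (j in seq_len(k)) {
    w <- matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                grid$n_rows, grid$n_cols)
    f <- Sr %*% w %*% t(Sc)
    Z[, j] <- (as.vector(f) - mean(f)) / stats::sd(as.vector(f))
  }
  X <- Z %*% M
  layers <- stats::setNames(lapply(seq_len(k), function(j) {
    matrix(X[, j], grid$n_rows, grid$n_cols)
  }), layer_names)
  env_stack(grid, layers)
}

#' Derive a future-period stack by shifting and scaling layers
#'
#' Emulates a climate anomaly applied to the current stack: each named layer
#' is transformed cell-wise as `value * scale + shift`.
#'
#' @param current An `env_stack`.
#' @param shift Named numeric vector/list of additive deltas (subset of
#'   layer names).
#' @param scale Named numeric vector/list of multipliers (subset of layer
#'   names).
#' @param scenario_tag,period_tag Tags for the output stack.
#' @param seed Unused placeholder kept for interface symmetry with the other
#'   generators (the transform is deterministic).
#' @return An `env_stack` on the same grid.
#' @export
gen_future_stack <- function(current, shift = numeric(), scale = numeric(),
                             scenario_tag = "ssp245", period_tag = "h2050",
                             seed = NULL) {
  shift <- unlist(shift); scale <- unlist(scale)
  unknown <- setdiff(c(names(shift), names(scale)), names(current$layers))
  if (length(unknown) > 0)
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "))
  layers <- current$layers
  for (nm in names(scale)) layers[[nm]] <- layers[[nm]] * scale[[nm]]
  for (nm in names(shift)) layers[[nm]] <- layers[[nm]] + shift[[nm]]
  env_stack(current$grid, layers, period_tag = period_tag,
            scenario_tag = scenario_tag)
}

#' Ground-truth suitability model
#'
#' A known generalized-linear suitability surface used to generate
#' occurrences and to validate parameter recovery: suitability =
#' link(intercept + sum(coef * layer)).
#'
#' @param coefficients Named numeric vector of layer weights (at least one
#'   nonzero). A name of the form `"layer^2"` weights the squared layer,
#'   allowing quadratic response surfaces.
#' @param intercept Intercept.
#' @param link `"logistic"` or `"cloglog"`.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(coefficients, intercept = 0, link = "logistic") {
  link <- match.arg(link, c("logistic", "cloglog"))
  coefficients <- unlist(coefficients)
  if (length(coefficients) == 0 || all(coefficients == 0))
    stop("at least one nonzero coefficient is required")
  structure(list(coefficients = coefficients, intercept = intercept,
                 link = link), class = "truth_model")
}

#' Evaluate a truth model on a stack
#'
#' @param stack An `env_stack` containing every layer the truth model names.
#' @param truth A `truth_model`.
#' @return Matrix of suitability values in \[0, 1\]; `NA` propagated.
#' @export
make_truth_suitability <- function(stack, truth) {
  base_of <- function(nm) sub("\\^2$", "", nm)
  missing <- setdiff(base_of(names(truth$coefficients)), names(stack$layers))
  if (length(missing) > 0)
    stop("truth model references absent layer(s): ",
         paste(missing, collapse = ", "))
  eta <- matrix(truth$intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(truth$coefficients)) {
    v <- stack$layers[[base_of(nm)]]
    if (grepl("\\^2$", nm)) v <- v^2
    eta <- eta + truth$coefficients[[nm]] * v
  }
  if (truth$link == "logistic") 1 / (1 + exp(-eta)) else 1 - exp(-exp(eta))
}

#' Sample presence points from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability (with
#' replacement); each draw is placed at the cell center, so repeated draws of
#' one cell are exact duplicates by design (deduplication is a downstream
#' concern).
#'
#' @param truth_suitability Numeric matrix of non-negative weights.
#' @param grid The `grid_spec` georeferencing the matrix.
#' @param n Number of points (>= 1).
#' @param species_id Label for the resulting set.
#' @param seed Integer seed.
#' @return An `occurrence_set` (see [occurrence_set()]).
#' @export
sample_occurrences <- function(truth_suitability, grid, n, species_id = "sp",
                               seed = 1) {
  stopifnot(n >= 1)
  w <- as.vector(truth_suitability)
  w[is.na(w)] <- 0
  if (all(w <= 0)) stop("suitability surface has no positive cells")
  set.seed(seed)
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  ctr <- cell_centers(grid)
  rows <- ((cells - 1) %% grid$n_rows) + 1
  cols <- ((cells - 1) %/% grid$n_rows) + 1
  occurrence_set(species_id, lon = ctr$lon[cols], lat = ctr$lat[rows],
                 source_tag = "synthetic")
}

#' Generate a distance-decay human footprint field
#'
#' Cell value = sum over centers of `intensity * exp(-d / decay_scale)` plus
#' optional Gaussian noise, clipped at zero; `d` is the great-circle distance
#' in km on a sphere of radius 6371 km.
#'
#' @param grid A `grid_spec`.
#' @param centers Data frame with columns `lon`, `lat`, `intensity`
#'   (intensities >= 0); may have zero rows.
#' @param decay_scale e-folding distance in km.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Matrix of footprint values (>= 0).
#' @export
gen_hfi <- function(grid, centers, decay_scale = 50, noise_sd = 0, seed = 1) {
  if (nrow(centers) > 0 && any(centers$intensity < 0))
    stop("intensities must be non-negative")
  ctr <- cell_centers(grid)
  pts <- cbind(rep(ctr$lon, each = grid$n_rows),
               rep(ctr$lat, times = grid$n_cols))
  v <- numeric(nrow(pts))
  for (i in seq_len(nrow(centers))) {
    d <- geosphere::distHaversine(pts, c(centers$lon[i], centers$lat[i]),
                                  r = 6371)
    v <- v + centers$intensity[i] * exp(-d / decay_scale)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  matrix(pmax(v, 0), grid$n_rows, grid$n_cols)
}

# point-in-polygon by ray casting (planar in lon/lat; adequate at the small
# extents the generators produce). Vertices as two-column matrix, open ring.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# planar polygon area (km^2) via the shoelace formula on a local
# equirectangular projection about the polygon centroid
polygon_area_km2 <- function(vx, vy) {
  R <- 6371
  lat0 <- mean(vy) * pi / 180
  x <- R * cos(lat0) * vx * pi / 180
  y <- R * vy * pi / 180
  i <- seq_along(x)
  j <- c(seq_along(x)[-1], 1)
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

#' Generate random protected-area polygons and their raster mask
#'
#' Polygons are star-convex rings around random interior centers, sized to
#' draw areas from `size_range_km2`; the mask marks cells whose centers fall
#' inside any polygon.
#'
#' @param grid A `grid_spec`.
#' @param n_polygons Number of polygons (>= 0).
#' @param size_range_km2 Length-2 numeric range of target polygon areas.
#' @param seed Integer seed.
#' @return List of class `protected_areas` with `polygons` (named list of
#'   two-column vertex matrices), `areas_km2`, `mask` (logical matrix) and
#'   `polygon_masks` (list of per-polygon logical matrices).
#' @export
gen_protected_areas <- function(grid, n_polygons, size_range_km2 = c(50, 500),
                                seed = 1) {
  stopifnot(n_polygons >= 0)
  set.seed(seed)
  ext <- grid_extent(grid)
  ctr <- cell_centers(grid)
  px <- rep(ctr$lon, each = grid$n_rows)
  py <- rep(ctr$lat, times = grid$n_cols)
  polys <- list(); pmasks <- list(); areas <- numeric(0)
  mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (i in seq_len(n_polygons)) {
    a <- stats::runif(1, size_range_km2[1], size_range_km2[2])
    r_km <- sqrt(a / pi)
    # keep the whole ring inside the grid extent, shrinking if necessary
    R <- 6371
    lat_mid <- (ext$lat_min + ext$lat_max) / 2
    half_h <- (ext$lat_max - ext$lat_min) / 2 * R * pi / 180
    half_w <- (ext$lon_max - ext$lon_min) / 2 * R *
      cos(lat_mid * pi / 180) * pi / 180
    r_km <- min(r_km, 0.45 * min(half_h, half_w) / 1.25 * 2)
    pad_lat <- 1.25 * r_km / R * 180 / pi
    pad_lon <- 1.25 * r_km / (R * cos(lat_mid * pi / 180)) * 180 / pi
    cx <- stats::runif(1, ext$lon_min + pad_lon, ext$lon_max - pad_lon)
    cy <- stats::runif(1, ext$lat_min + pad_lat, ext$lat_max - pad_lat)
    ang <- sort(stats::runif(8, 0, 2 * pi))
    rad <- r_km * stats::runif(8, 0.75, 1.25)
    R <- 6371
    vx <- cx + rad * cos(ang) / (R * cos(cy * pi / 180)) * 180 / pi
    vy <- cy + rad * sin(ang) / R * 180 / pi
    nm <- sprintf("PA%02d", i)
    polys[[nm]] <- cbind(lon = vx, lat = vy)
    areas[nm] <- polygon_area_km2(vx, vy)
    inside <- matrix(points_in_polygon(px, py, vx, vy),
                     grid$n_rows, grid$n_cols)
    pmasks[[nm]] <- inside
    mask <- mask | inside
  }
  structure(list(polygons = polys, areas_km2 = areas, mask = mask,
                 polygon_masks = pmasks, grid = grid),
            class = "protected_areas")
}

#' Write protected-area polygons as GeoJSON
#'
#' @param pa A `protected_areas` object.
#' @param path Output path.
#' @export
write_protected_areas_geojson <- function(pa, path) {
  features <- lapply(names(pa$polygons), function(nm) {
    v <- pa$polygons[[nm]]
    ring <- rbind(v, v[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(name = nm, area_km2 = unname(pa$areas_km2[[nm]])),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) unname(ring[i, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
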