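#' Raster grid geometry
#'
#' A `grid_spec` describes the shared geometry of every raster layer in an
#' analysis: a regular grid of square cells in geographic (WGS84 lon/lat)
#' coordinates, anchored at its top-left corner. All layers bound to the same
#' `grid_spec` are guaranteed to have identical shape and georeferencing.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size_deg Cell edge length in degrees (square cells).
#' @param origin_lon,origin_lat Longitude/latitude of the top-left corner of
#'   the top-left cell, in degrees.
#' @param nodata_value Sentinel used for missing cells in file output.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_deg,
                      origin_lon = 0, origin_lat = 0,
                      nodata_value = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_deg > 0)
  structure(list(
    n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols),
    cell_size_deg = cell_size_deg,
    origin_lon = origin_lon,
    origin_lat = origin_lat,
    nodata_value = nodata_value
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.6g deg resolution\n",
              x$n_rows, x$n_cols, x$cell_size_deg))
  cat(sprintf("  top-left corner: (%.6g, %.6g); nodata %g\n",
              x$origin_lon, x$origin_lat, x$nodata_value))
  invisible(x)
}

#' Cell-center coordinates
#'
#' @param grid A `grid_spec`.
#' @return A list with `lon` (length `n_cols`) and `lat` (length `n_rows`)
#'   vectors of cell-center coordinates; rows run north to south.
#' @export
cell_centers <- function(grid) {
  list(
    lon = grid$origin_lon + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_deg,
    lat = grid$origin_lat - (seq_len(grid$n_rows) - 0.5) * grid$cell_size_deg
  )
}

#' Spherical cell areas by grid row
#'
#' Cell area on a sphere of radius 6371 km:
#' A = R^2 * dlambda * (sin(phi_top) - sin(phi_bottom)), so area depends on
#' the row (latitude band) only.
#'
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `n_rows`: the area in km^2 of one cell in
#'   each row, north to south.
#' @export
cell_area_by_row <- function(grid) {
  R <- 6371
  s <- grid$cell_size_deg
  lat_top <- grid$origin_lat - (seq_len(grid$n_rows) - 1) * s
  lat_bot <- lat_top - s
  R^2 * (s * pi / 180) * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

#' Per-cell area matrix (km^2)
#' @param grid A `grid_spec`.
#' @return Matrix `n_rows x n_cols` of cell areas.
#' @export
cell_area_matrix <- function(grid) {
  matrix(rep(cell_area_by_row(grid), grid$n_cols),
         nrow = grid$n_rows, ncol = grid$n_cols)
}

grid_extent <- function(grid) {
  list(
    lon_min = grid$origin_lon,
    lon_max = grid$origin_lon + grid$n_cols * grid$cell_size_deg,
    lat_max = grid$origin_lat,
    lat_min = grid$origin_lat - grid$n_rows * grid$cell_size_deg
  )
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size_deg - b$cell_size_deg) < tol &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol
}

#' Environmental raster stack
#'
#' Bundles named 2-D layers sharing one `grid_spec`, tagged with the climate
#' period and, for future periods, the shared socioeconomic pathway (SSP)
#' scenario they represent.
#'
#' @param grid A `grid_spec`.
#' @param layers Named list of numeric matrices (`n_rows x n_cols`), `NA` for
#'   missing cells. NA cells must coincide across layers.
#' @param period_tag One of `"current"`, `"h2050"`, `"h2070"`.
#' @param scenario_tag One of `"none"`, `"ssp126"`, `"ssp245"`, `"ssp370"`,
#'   `"ssp585"`. Current stacks must use `"none"`.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, period_tag = "current",
                      scenario_tag = "none") {
  period_tag <- match.arg(period_tag, c("current", "h2050", "h2070"))
  scenario_tag <- match.arg(scenario_tag,
                            c("none", "ssp126", "ssp245", "ssp370", "ssp585"))
  if (period_tag == "current" && scenario_tag != "none")
    stop("current stacks must have scenario_tag 'none'")
  if (length(layers) < 1 || is.null(names(layers)) || any(names(layers) == ""))
    stop("layers must be a non-empty named list")
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop(sprintf("layer '%s' does not conform to the grid", nm))
  }
  na0 <- is.na(layers[[1]])
  for (nm in names(layers)[-1]) {
    if (!identical(unname(is.na(layers[[nm]])), unname(na0)))
      stop(sprintf("nodata cells of layer '%s' do not coincide with '%s'",
                   nm, names(layers)[1]))
  }
  structure(list(grid = grid, layers = layers,
                 period_tag = period_tag, scenario_tag = scenario_tag),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) [%s] on %d x %d grid, period %s%s\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, x$period_tag,
              if (x$scenario_tag == "none") "" else paste0("/", x$scenario_tag)))
  invisible(x)
}

valid_mask <- function(stack) !is.na(stack$layers[[1]])

#' Write a raster matrix as an Esri ASCII grid
#'
#' @param mat Numeric matrix (rows north to south).
#' @param grid The `grid_spec` georeferencing `mat`.
#' @param path Output file path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(mat, grid, path) {
  stopifnot(nrow(mat) == grid$n_rows, ncol(mat) == grid$n_cols)
  ext <- grid_extent(grid)
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", ext$lon_min),
    sprintf("yllcorner %.10g", ext$lat_min),
    sprintf("cellsize %.10g", grid$cell_size_deg),
    sprintf("NODATA_value %.10g", grid$nodata_value)
  )
  m <- mat
  m[is.na(m)] <- grid$nodata_value
  body <- apply(m, 1, function(r) paste(format(r, digits = 10, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path File path.
#' @return List with `grid` (a `grid_spec`) and `values` (matrix, `NA` where
#'   the file holds the nodata value).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed Esri ASCII header")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("cell count does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  g <- grid_spec(nr, nc, hdr$cellsize,
                 origin_lon = xll,
                 origin_lat = yll + nr * hdr$cellsize,
                 nodata_value = nodata)
  list(grid = g, values = m)
}

#' Write every layer of a stack as Esri ASCII grids
#'
#' @param stack An `env_stack`.
#' @param dir Output directory (created if absent); one `<layer>.asc` each.
#' @export
write_stack_ascii <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_ascii_grid(stack$layers[[nm]], stack$grid,
                     file.path(dir, paste0(nm, ".asc")))
  invisible(dir)
}

#' Read a directory of Esri ASCII grids as a stack
#'
#' @param dir Directory holding `<layer>.asc` files.
#' @param period_tag,scenario_tag Tags for the resulting stack.
#' @export
read_stack_ascii <- function(dir, period_tag = "current",
                             scenario_tag = "none") {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0) stop("no .asc layers found in ", dir)
  first <- read_ascii_grid(files[1])
  layers <- list()
  for (f in files) {
    r <- read_ascii_grid(f)
    if (!same_grid(r$grid, first$grid)) stop("layer grids differ in ", dir)
    layers[[sub("\\.asc$", "", basename(f))]] <- r$values
  }
  env_stack(first$grid, layers, period_tag = period_tag,
            scenario_tag = scenario_tag)
}
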