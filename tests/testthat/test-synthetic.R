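test_that("generated fields hit identity, perfect and partial correlation targets", {
  g <- grid_spec(100, 100, 0.05, 103, 31)
  # identity target: independent layers stay nearly uncorrelated over seeds
  for (s in 1:5) {
    st <- gen_env_stack(g, c("a", "b"), diag(2), smoothness = 3, seed = s)
    r <- cor(as.vector(st$layers$a), as.vector(st$layers$b))
    expect_lt(abs(r), 0.2)
  }
  # perfect correlation: identical up to affine transform
  C1 <- matrix(c(1, 1, 1, 1), 2)
  st1 <- gen_env_stack(g, c("a", "b"), C1, smoothness = 3, seed = 1)
  expect_gt(cor(as.vector(st1$layers$a), as.vector(st1$layers$b)), 0.999)
  # r = 0.9 at 200x200 within +-0.05
  g2 <- grid_spec(200, 200, 0.05, 103, 31)
  C9 <- matrix(c(1, 0.9, 0.9, 1), 2)
  st9 <- gen_env_stack(g2, c("a", "b"), C9, smoothness = 3, seed = 3)
  expect_equal(cor(as.vector(st9$layers$a), as.vector(st9$layers$b)), 0.9,
               tolerance = 0.05 / 0.9)
})

test_that("non-PSD or malformed correlation targets are rejected", {
  g <- mini_grid()
  bad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  expect_error(gen_env_stack(g, c("a", "b"), bad), "positive-semidefinite")
  expect_error(gen_env_stack(g, c("a", "b"), matrix(c(1, 0.2, 0.3, 1), 2)),
               "symmetric")
})

test_that("generators are reproducible per seed and differ across seeds", {
  g <- mini_grid(20, 20)
  s1 <- gen_env_stack(g, "a", seed = 11)
  s2 <- gen_env_stack(g, "a", seed = 11)
  s3 <- gen_env_stack(g, "a", seed = 12)
  expect_identical(s1$layers$a, s2$layers$a)
  expect_false(identical(s1$layers$a, s3$layers$a))
  suit <- matrix(1, 20, 20)
  o1 <- sample_occurrences(suit, g, 30, seed = 5)
  o2 <- sample_occurrences(suit, g, 30, seed = 5)
  o3 <- sample_occurrences(suit, g, 30, seed = 6)
  expect_identical(o1$points, o2$points)
  expect_false(identical(o1$points, o3$points))
})

test_that("future stacks apply shift and scale cell-wise", {
  g <- mini_grid(8, 8)
  st <- gen_env_stack(g, c("t", "p"), seed = 2)
  same <- gen_future_stack(st, scenario_tag = "ssp126", period_tag = "h2050")
  expect_equal(same$layers, st$layers)
  shifted <- gen_future_stack(st, shift = c(t = 2), scenario_tag = "ssp245",
                              period_tag = "h2050")
  expect_equal(shifted$layers$t - st$layers$t,
               matrix(2, 8, 8))
  scaled <- gen_future_stack(st, scale = c(p = 1.1), scenario_tag = "ssp585",
                             period_tag = "h2070")
  expect_equal(mean(scaled$layers$p), 1.1 * mean(st$layers$p))
  expect_equal(scaled$period_tag, "h2070")
  expect_error(gen_future_stack(st, shift = c(zz = 1)), "unknown layer")
})

test_that("truth suitability follows the link closed form", {
  g <- mini_grid(3, 3)
  x <- matrix(seq(-2, 2, length.out = 9), 3, 3)
  st <- env_stack(g, list(x = x))
  # all-zero coefficients are rejected; intercept-only via zero-weighted pair
  flat <- make_truth_suitability(st, truth_model(c(x = 0, "x^2" = 1e-12)))
  expect_equal(flat, matrix(0.5, 3, 3), tolerance = 1e-9)
  tm <- truth_model(c(x = 1), intercept = 0)
  suit <- make_truth_suitability(st, tm)
  expect_equal(suit[1, 1], 1 / (1 + exp(2)))      # x = -2
  expect_equal(suit[2, 2], 0.5)                   # x = 0
  expect_equal(suit[3, 3], 1 / (1 + exp(-2)))     # x = 2
  sunk <- make_truth_suitability(st, truth_model(c(x = 1), intercept = -50))
  expect_true(all(sunk < 1e-10))
  cll <- make_truth_suitability(st, truth_model(c(x = 1), link = "cloglog"))
  expect_equal(cll[2, 2], 1 - exp(-1))
  x2 <- x; x2[1, 2] <- NA
  stna <- env_stack(g, list(x = x2))
  expect_true(is.na(make_truth_suitability(stna, tm)[1, 2]))
})

test_that("occurrence sampling follows the suitability distribution", {
  g <- mini_grid(5, 5, size = 0.1)
  one <- matrix(0, 5, 5); one[3, 4] <- 0.7
  occ <- sample_occurrences(one, g, 8, seed = 1)
  ctr <- cell_centers(g)
  expect_true(all(occ$points$lon == ctr$lon[4]))
  expect_true(all(occ$points$lat == ctr$lat[3]))
  expect_error(sample_occurrences(matrix(0, 5, 5), g, 3), "positive")
  # uniform suitability: multinomial uniformity not rejected at alpha 0.01
  u <- sample_occurrences(matrix(1, 5, 5), g, 5000, seed = 7)
  cells <- paste(u$points$lon, u$points$lat)
  counts <- table(factor(cells, levels = unique(paste(
    rep(ctr$lon, each = 5), rep(ctr$lat, 5)))))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
  # 0.9 / 0.1 two-cell surface: observed split inside the binomial 99% band
  two <- matrix(0, 5, 5); two[1, 1] <- 0.9; two[5, 5] <- 0.1
  o2 <- sample_occurrences(two, g, 1000, seed = 9)
  n_first <- sum(o2$points$lat == ctr$lat[1])
  expect_true(n_first >= qbinom(0.005, 1000, 0.9) &&
              n_first <= qbinom(0.995, 1000, 0.9))
})

test_that("human footprint decays from centers as intensity*exp(-d/scale)", {
  g <- mini_grid(21, 21, size = 0.1)
  expect_equal(gen_hfi(g, data.frame(lon = numeric(0), lat = numeric(0),
                                     intensity = numeric(0))),
               matrix(0, 21, 21))
  ctr <- cell_centers(g)
  # center on a cell center; move due south along the meridian
  centers <- data.frame(lon = ctr$lon[11], lat = ctr$lat[3], intensity = 10)
  h <- gen_hfi(g, centers, decay_scale = 50, noise_sd = 0)
  expect_equal(which(h == max(h)), (11 - 1) * 21 + 3)  # max at the center
  d <- haversine_oracle(ctr$lon[11], ctr$lat[3], ctr$lon[11], ctr$lat[12])
  expect_equal(h[12, 11], 10 * exp(-d / 50), tolerance = 1e-9)
  expect_error(gen_hfi(g, data.frame(lon = 0, lat = 0, intensity = -1)),
               "non-negative")
})

test_that("protected-area masks match their polygons", {
  g <- mini_grid(40, 40, size = 0.05)
  expect_equal(sum(gen_protected_areas(g, 0)$mask), 0)
  pa <- gen_protected_areas(g, 3, size_range_km2 = c(3000, 6000), seed = 4)
  A <- cell_area_matrix(g)
  for (nm in names(pa$polygons)) {
    mask_area <- sum(A[pa$polygon_masks[[nm]]])
    poly_area <- pa$areas_km2[[nm]]
    v <- pa$polygons[[nm]]
    # one cell-ring tolerance: boundary length x cell size
    rad <- pi / 180
    seg <- sqrt(diff(c(v[, 1], v[1, 1]) * cos(mean(v[, 2]) * rad))^2 +
                diff(c(v[, 2], v[1, 2]))^2) * 6371 * rad
    ring <- sum(seg) * g$cell_size_deg * 111
    expect_lt(abs(mask_area - poly_area), ring)
  }
  # a polygon covering the whole extent -> mask all true
  ext <- preyhab:::grid_extent(g)
  big <- list(polygons = list(ALL = cbind(
    lon = c(ext$lon_min - 1, ext$lon_max + 1, ext$lon_max + 1, ext$lon_min - 1),
    lat = c(ext$lat_min - 1, ext$lat_min - 1, ext$lat_max + 1, ext$lat_max + 1))))
  inside <- preyhab:::points_in_polygon(
    rep(cell_centers(g)$lon, each = 40), rep(cell_centers(g)$lat, 40),
    big$polygons$ALL[, 1], big$polygons$ALL[, 2])
  expect_true(all(inside))
})

test_that("protected areas survive the GeoJSON round trip", {
  g <- mini_grid(20, 20)
  pa <- gen_protected_areas(g, 2, size_range_km2 = c(500, 1500), seed = 8)
  path <- tempfile(fileext = ".geojson")
  write_protected_areas_geojson(pa, path)
  back <- read_protected_areas_geojson(path, g)
  expect_equal(names(back$polygons), names(pa$polygons))
  expect_equal(back$mask, pa$mask)
  expect_equal(unname(back$areas_km2), unname(pa$areas_km2),
               tolerance = 1e-6)
})
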