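test_that("patch labeling matches the BFS oracle on random masks", {
  g50 <- mini_grid(50, 50)
  set.seed(123)
  for (trial in 1:100) {
    mask <- matrix(runif(2500) < 0.35, 50, 50)
    conn <- if (trial %% 2 == 0) 8 else 4
    got <- preyhab:::label_components(mask, conn)
    want <- bfs_label_oracle(mask, conn)
    expect_equal(component_signature(got), component_signature(want))
  }
})

test_that("patch extraction respects connectivity and area accounting", {
  g <- mini_grid(6, 6, size = 0.5)
  A <- cell_area_matrix(g)
  one <- matrix(FALSE, 6, 6); one[3, 3] <- TRUE
  p1 <- extract_patches(one, g)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$area_km2, A[3, 3])
  # two diagonal cells: one patch under 8-connectivity, two under 4
  diag2 <- matrix(FALSE, 6, 6); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_length(extract_patches(diag2, g, 8), 1)
  expect_length(extract_patches(diag2, g, 4), 2)
  expect_equal(extract_patches(matrix(FALSE, 6, 6), g), list())
  # partition invariant: every true cell in exactly one patch, areas conserved
  set.seed(9)
  mask <- matrix(runif(36) < 0.5, 6, 6)
  ps <- extract_patches(mask, g)
  all_cells <- sort(unlist(lapply(ps, `[[`, "cells")))
  expect_equal(all_cells, which(mask))
  expect_equal(sum(vapply(ps, `[[`, numeric(1), "area_km2")),
               sum(A[mask]), tolerance = 1e-9)
  # ids follow decreasing area
  areas <- vapply(ps, `[[`, numeric(1), "area_km2")
  expect_true(all(diff(areas) <= 0))
  expect_equal(vapply(ps, `[[`, numeric(1), "patch_id"), seq_along(ps))
})

test_that("footprint threshold derivation rounds the mask quantile up", {
  g <- mini_grid(4, 4)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(derive_hfi_threshold(mask, matrix(7.9, 4, 4)), 7.9)
  expect_equal(derive_hfi_threshold(mask, matrix(7.96, 4, 4)), 8.0)
  v <- matrix(c(1:15, 100), 4, 4)
  expect_equal(derive_hfi_threshold(mask, v, quantile = 0.5),
               ceiling(median(v) * 10) / 10)
  expect_error(derive_hfi_threshold(matrix(FALSE, 4, 4), v), "empty")
})

test_that("exceedance fractions are area-weighted with strict inequality", {
  g <- mini_grid(2, 2)
  patch <- structure(list(patch_id = 1L, cells = 1:4,
                          area_km2 = sum(cell_area_matrix(g))),
                     class = "patch")
  expect_equal(as.numeric(hfi_exceed_fraction(patch, matrix(9, 2, 2), g, 8)), 1)
  # boundary: exactly at the threshold does not count as exceeding
  expect_equal(as.numeric(hfi_exceed_fraction(patch, matrix(8, 2, 2), g, 8)), 0)
  half <- matrix(c(9, 9, 1, 1), 2, 2)
  fr <- hfi_exceed_fraction(patch, half, g, 8)
  A <- cell_area_matrix(g)
  expect_equal(as.numeric(fr), sum(A[, 1]) / sum(A))
  # nodata cells leave numerator and denominator, with a count
  hna <- matrix(c(9, NA, 1, 1), 2, 2)
  frna <- hfi_exceed_fraction(patch, hna, g, 8)
  expect_equal(attr(frna, "n_nodata"), 1L)
  expect_equal(as.numeric(frna), A[1, 1] / sum(A[c(1, 3, 4)]))
})

test_that("screening keeps exactly the patches passing both rules", {
  # hand-designed fixture: grid of ~30.2 km2 cells
  g <- mini_grid(12, 12, size = 0.05)
  mask <- matrix(FALSE, 12, 12)
  mask[1, 1:3] <- TRUE          # patch A: 3 cells ~ 82 km2 (too small)
  mask[5:8, 1:4] <- TRUE        # patch B: 16 cells, clean footprint
  mask[10:12, 6:12] <- TRUE     # patch C: 21 cells, footprint-heavy
  hfi <- matrix(0, 12, 12)
  hfi[10:12, 6:12] <- 9         # all of C exceeds
  hfi[5, 1] <- 9                # a corner of B exceeds (1/16 of area)
  patches <- extract_patches(mask, g)
  scr <- screen_patches(patches, hfi, g, screening_config())
  expect_length(scr$core, 1)
  expect_equal(sort(scr$core[[1]]$cells),
               which(row(mask) %in% 5:8 & col(mask) %in% 1:4))
  expect_equal(nrow(scr$rejections), 2)
  expect_match(scr$rejections$reason, "minimum", all = FALSE)
  expect_match(scr$rejections$reason, "HFI", all = FALSE)
  # kept + rejected = input
  expect_equal(length(scr$core) + nrow(scr$rejections), length(patches))
  # boundary: exactly half the area exceeding is kept ("more than" rejects)
  g2 <- mini_grid(2, 4, size = 0.3)
  mask2 <- matrix(TRUE, 2, 4)
  hfi2 <- matrix(0, 2, 4); hfi2[, 1:2] <- 9
  p2 <- extract_patches(mask2, g2)
  fr2 <- as.numeric(hfi_exceed_fraction(p2[[1]], hfi2, g2, 8))
  scr2 <- screen_patches(p2, hfi2, g2, screening_config())
  expect_equal(fr2, 0.5, tolerance = 1e-6)
  expect_length(scr2$core, 1)
})

test_that("lowering the footprint ceiling never keeps more patches", {
  g <- mini_grid(20, 20)
  set.seed(5)
  mask <- matrix(runif(400) < 0.5, 20, 20)
  hfi <- matrix(runif(400, 0, 16), 20, 20)
  patches <- extract_patches(mask, g)
  kept <- vapply(c(12, 8, 4, 1), function(th) {
    cfg <- screening_config(min_patch_km2 = 20, hfi_threshold = th)
    length(screen_patches(patches, hfi, g, cfg)$core)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("protected-area overlap is accounted per patch and in total", {
  g <- mini_grid(6, 6, size = 0.2)
  A <- cell_area_matrix(g)
  mask <- matrix(FALSE, 6, 6); mask[2:4, 2:4] <- TRUE
  patches <- extract_patches(mask, g)
  # PA mask covering the patch entirely
  ov_full <- pa_overlap(patches, matrix(TRUE, 6, 6), g)
  expect_equal(ov_full$patches[[1]]$pa_overlap_km2,
               patches[[1]]$area_km2)
  # no protected areas
  ov_none <- pa_overlap(patches, matrix(FALSE, 6, 6), g)
  expect_equal(ov_none$summary$overlap_km2, 0)
  expect_equal(ov_none$summary$overlap_pct, 0)
  # partial overlap: percent to one decimal
  pa_mask <- matrix(FALSE, 6, 6); pa_mask[2, 2:4] <- TRUE
  ov <- pa_overlap(patches, pa_mask, g)
  want_pct <- round(sum(A[2, 2:4]) / patches[[1]]$area_km2 * 100, 1)
  expect_equal(ov$summary$overlap_pct, want_pct)
})

test_that("ranked reports order by area with stable id tie-breaks", {
  mk <- function(id, a) structure(list(patch_id = id, cells = integer(0),
                                       area_km2 = a), class = "patch")
  ps <- list(mk(1, 5), mk(2, 10), mk(3, 1))
  rep <- rank_report(ps, top_n = 20)
  expect_equal(rep$area_km2, c(10, 5, 1))
  # ties: stable by patch id
  ps2 <- list(mk(2, 7), mk(1, 7), mk(3, 7))
  expect_equal(rank_report(ps2)$patch_id, c(1, 2, 3))
  expect_equal(nrow(rank_report(ps, top_n = 2)), 2)
  expect_equal(nrow(rank_report(list())), 0)
})
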