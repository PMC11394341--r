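# shared small training landscape for the SDM tests
sdm_fixture <- local({
  g <- grid_spec(30, 30, 0.05, 103, 31)
  st <- gen_env_stack(g, c("a", "b"), smoothness = 3, seed = 101)
  suit <- make_truth_suitability(st, truth_model(c(a = 2.5, b = -1.5), -0.5))
  occ <- sample_occurrences(suit, g, 120, seed = 102)
  cells <- occurrences_to_cells(occ, g)
  list(g = g, st = st, suit = suit, cells = cells,
       bg = sample_background(st, 10000, 1))
})

test_that("feature expansion counts and hinge endpoints are exact", {
  st <- sdm_fixture$st
  expect_equal(nrow(build_features(st, c("a", "b"), "L")$defs), 2)
  g3 <- mini_grid(8, 8)
  st3 <- gen_env_stack(g3, c("x", "y", "z"), seed = 1)
  fs <- build_features(st3, c("x", "y", "z"), c("L", "Q", "P"))
  expect_equal(nrow(fs$defs), 9)  # 3 linear + 3 quadratic + 3 products
  # single layer with P: silently no product features, but recorded
  fs1 <- build_features(st3, "x", c("L", "P"))
  expect_equal(nrow(fs1$defs), 1)
  expect_match(fs1$notes, "product", all = FALSE)
  # hinge: 0 at its knot, 1 at the background maximum
  fsh <- build_features(st3, "x", c("L", "H"), n_hinge_knots = 3)
  hf <- which(fsh$defs$kind == "hinge_fwd")[1]
  k <- fsh$defs$knot[hf]
  xmax <- max(st3$layers$x)
  # evaluate through the normalization: raw pmax(0, x - k) scaled by bg range
  at_knot <- (pmax(0, k - k) - fsh$norm$min[hf]) /
    (fsh$norm$max[hf] - fsh$norm$min[hf])
  at_max <- (pmax(0, xmax - k) - fsh$norm$min[hf]) /
    (fsh$norm$max[hf] - fsh$norm$min[hf])
  expect_equal(at_knot, 0)
  expect_equal(at_max, 1)
})

test_that("a featureless or constant-feature model is uniform over background", {
  g <- mini_grid(6, 6)
  st <- env_stack(g, list(flat = matrix(5, 6, 6),
                          x = matrix(rnorm(36, sd = 0.5), 6, 6)))
  fs <- build_features(st, "flat", "L")
  fit <- maxent(1:10, 1:36, fs, reg_multiplier = 1, quiet = TRUE)
  pred <- predict(fit, st, output = "raw")
  expect_equal(as.vector(pred), rep(1 / 36, 36), tolerance = 1e-12)
  # uniform model closed forms: H = log N, cloglog = 1 - exp(-1)
  expect_equal(fit$entropy_H, log(36))
  cl <- predict(fit, st, output = "cloglog")
  expect_equal(cl[1, 1], 1 - exp(-1), tolerance = 1e-12)
})

test_that("unregularized fits match presence feature means (KKT moment matching)", {
  g <- mini_grid(10, 10)
  st <- gen_env_stack(g, c("x", "y"), smoothness = 2, seed = 7)
  suit <- make_truth_suitability(st, truth_model(c(x = 2), -0.5))
  cells <- occurrences_to_cells(sample_occurrences(suit, g, 60, seed = 8), g)
  fs <- build_features(st, c("x", "y"), "L")
  fit <- maxent(cells, 1:100, fs, reg_multiplier = 0, quiet = TRUE)
  Fb <- feature_matrix(fs, 1:100)
  Fp <- feature_matrix(fs, cells)
  q <- exp(drop(Fb %*% coef(fit)) - fit$log_partition)
  expect_lt(max(abs(drop(crossprod(Fb, q)) - colMeans(Fp))), 1e-4)
  expect_lt(abs(sum(q) - 1), 1e-8)
})

test_that("regularized optima satisfy the KKT bound and shrink monotonically", {
  f <- sdm_fixture
  fs <- build_features(f$st, c("a", "b"), c("L", "Q"))
  n_active <- c()
  for (rm in c(0.5, 1, 2, 4, 16, 1e6)) {
    fit <- maxent(f$cells, f$bg, fs, reg_multiplier = rm, quiet = TRUE)
    Fb <- feature_matrix(fs, f$bg)
    Fp <- feature_matrix(fs, f$cells)
    q <- exp(drop(Fb %*% coef(fit)) - fit$log_partition)
    expect_lt(abs(sum(q) - 1), 1e-8)
    gap <- abs(drop(crossprod(Fb, q)) - colMeans(Fp))
    expect_true(all(gap <= fit$beta + 1e-4))
    n_active <- c(n_active, sum(coef(fit) != 0))
  }
  expect_true(all(diff(n_active) <= 0))
  # a very large multiplier shrinks everything to zero
  expect_equal(n_active[length(n_active)], 0)
})

test_that("prediction transforms are monotone and identity on the training stack", {
  f <- sdm_fixture
  fs <- build_features(f$st, c("a", "b"), c("L", "Q"))
  fit <- maxent(f$cells, f$bg, fs, quiet = TRUE)
  raw <- predict(fit, f$st, output = "raw")
  cl <- predict(fit, f$st, output = "cloglog")
  expect_true(all(cl >= 0 & cl <= 1))
  expect_equal(order(as.vector(raw)), order(as.vector(cl)))
  # projecting onto the training stack reproduces training raw values
  raw2 <- predict(fit, f$st, output = "raw")
  expect_identical(raw, raw2)
  # missing layers are rejected
  st_missing <- env_stack(f$g, f$st$layers["a"])
  expect_error(predict(fit, st_missing), "lacks")
})

test_that("AUC equals the pair-counting oracle with tied handling", {
  g <- mini_grid(2, 5)  # 10 cells
  s <- matrix(c(0.9, 0.8, 0.85, 0.7, 0.4, 0.35, 0.3, 0.2, 0.4, 0.1), 2, 5)
  pres <- c(1, 2, 3, 4)
  bg <- 1:10
  # oracle: count presence > background pairs, ties half
  sp <- as.vector(s)[pres]; sb <- as.vector(s)[setdiff(bg, pres)]
  wins <- 0
  for (p in sp) for (b in sb) wins <- wins + (p > b) + 0.5 * (p == b)
  expect_equal(evaluate_auc(s, pres, bg), wins / (length(sp) * length(sb)))
  # complete separation and constant maps
  expect_equal(evaluate_auc(s, c(1, 2, 3), 5:10), 1)
  expect_equal(evaluate_auc(matrix(0.4, 2, 5), pres, bg), 0.5)
})

test_that("AUC bands follow the published breaks with boundary convention", {
  expect_equal(grade_auc(0.95), "excellent")
  expect_equal(grade_auc(0.55), "unqualified")
  expect_equal(grade_auc(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)),
               c("unqualified", "poor", "fair", "good", "excellent",
                 "excellent"))
  expect_equal(grade_auc(0.49), "worse-than-random")
})

test_that("omission rate uses the training percentile threshold", {
  s <- matrix(seq(0.01, 1, length.out = 100), 10, 10)
  train <- 1:10      # suitabilities 0.01 .. 0.1
  # percentile 0: threshold is the training minimum, nothing omitted
  expect_equal(omission_rate(s, train, train, percentile = 0), 0)
  # self-test at the 10th percentile stays within granularity
  expect_lte(omission_rate(s, train, train, percentile = 10), 0.1 + 1 / 10)
  # hand-computed oracle: threshold = sorted train value at ceiling(n*p/100)
  train2 <- c(5, 12, 18, 23, 31, 44, 57, 61, 72, 90)
  test2 <- c(3, 11, 20, 55, 95)
  v <- sort(as.vector(s)[train2])
  th <- v[ceiling(10 * 30 / 100)]
  expect_equal(omission_rate(s, train2, test2, percentile = 30),
               mean(as.vector(s)[test2] < th))
})

test_that("AICc matches its closed forms and counts only active features", {
  g <- mini_grid(6, 6)
  st <- env_stack(g, list(flat = matrix(1, 6, 6)))
  fs <- build_features(st, "flat", "L")
  fit0 <- maxent(1:12, 1:36, fs, reg_multiplier = 1, quiet = TRUE)
  # uniform model: k = 0, -2 LL = 2 n log N
  expect_equal(sum(coef(fit0) != 0), 0)
  expect_equal(aicc(fit0), 2 * 12 * log(36))
  # two-feature fit vs hand-computed formula
  f <- sdm_fixture
  fs2 <- build_features(f$st, c("a", "b"), "L")
  fit2 <- maxent(f$cells, f$bg, fs2, reg_multiplier = 0.5, quiet = TRUE)
  k <- sum(coef(fit2) != 0)
  eta <- drop(feature_matrix(fs2, f$cells) %*% coef(fit2))
  ll <- sum(eta - fit2$log_partition)
  n <- length(f$cells)
  expect_equal(aicc(fit2), 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1))
  # undefined below the sample-size floor
  expect_true(is.na(aicc(fit2, presence_cells = f$cells[1:2])))
})

test_that("calibration applies the omission-then-AICc selection rule", {
  f <- sdm_fixture
  # single candidate: selected
  cal1 <- calibrate(f$cells, f$st, rm_grid = 1, combos = list("L"), seed = 5)
  expect_equal(sum(cal1$selected), 1)
  # the full table is deterministic given the seed
  cal2 <- calibrate(f$cells, f$st, rm_grid = c(0.5, 1), combos = list("L", "LQ"),
                    seed = 5)
  cal3 <- calibrate(f$cells, f$st, rm_grid = c(0.5, 1), combos = list("L", "LQ"),
                    seed = 5)
  expect_equal(cal2, cal3)
  expect_true(any(cal2$selected))
  sel <- cal2[cal2$selected, ]
  expect_true(all(sel$delta_aicc <= 2 | is.na(sel$delta_aicc)))
  # selection rule on synthetic rows: equal omission, AICc apart by 10
  rows <- cal2[1:2, ]
  rows$omission_rate <- c(0.0, 0.0)
  rows$aicc <- c(100, 110)
  rows$delta_aicc <- rows$aicc - min(rows$aicc)
  picked <- rows$omission_rate <= 0.05 & rows$delta_aicc <= 2
  expect_equal(picked, c(TRUE, FALSE))
})

test_that("calibration recovers a quadratic truth response", {
  g <- grid_spec(60, 60, 0.05, 103, 31)
  hits <- 0
  for (s in 1:10) {
    st <- gen_env_stack(g, c("a", "b"), smoothness = 4, seed = 500 + s)
    suit <- make_truth_suitability(
      st, truth_model(c(a = 3, "a^2" = -2, b = 2), -2))
    occ <- sample_occurrences(suit, g, 500, seed = 600 + s)
    cells <- occurrences_to_cells(occ, g)
    cal <- calibrate(cells, st, rm_grid = c(1, 2), combos = list("L", "LQ"),
                     seed = 700 + s)
    best <- cal[cal$selected, ]
    best <- best[order(best$aicc), ][1, ]
    if (grepl("Q", best$feature_combo)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("replicate averaging is bounded by and consistent with its replicates", {
  f <- sdm_fixture
  r1 <- replicate_run(f$cells, f$st, "LQ", 1, n_reps = 1, seed = 4)
  expect_equal(r1$mean_map, predict(r1$models[[1]], f$st))
  # identical sub-seeds force identical splits, hence identical AUCs
  rsame <- replicate_run(f$cells, f$st, "LQ", 1, n_reps = 3,
                         rep_seeds = c(9, 9, 9))
  expect_equal(rsame$rep_aucs, rep(rsame$rep_aucs[1], 3))
  r5 <- replicate_run(f$cells, f$st, "LQ", 1, n_reps = 5, seed = 6)
  expect_equal(r5$mean_auc, mean(r5$rep_aucs))
  per_rep <- vapply(r5$models, function(m) predict(m, f$st)[15, 15],
                    numeric(1))
  expect_gte(r5$mean_map[15, 15], min(per_rep))
  expect_lte(r5$mean_map[15, 15], max(per_rep))
})

test_that("lambdas files round out the model interface", {
  f <- sdm_fixture
  fs <- build_features(f$st, c("a", "b"), "L")
  fit <- maxent(f$cells, f$bg, fs, quiet = TRUE)
  path <- tempfile(fileext = ".lambdas")
  write_lambdas(fit, path)
  lines <- readLines(path)
  expect_match(lines[2], "^a, ")
  expect_match(lines, "regMultiplier", all = FALSE)
  expect_equal(length(lines), 1 + length(coef(fit)) + 4)
})
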