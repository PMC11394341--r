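#' Build a MaxEnt feature set from environmental layers
#'
#' Expands the retained layers of a stack into the classic MaxEnt feature
#' classes: linear (L), quadratic (Q), pairwise product (P), forward and
#' reverse hinge (H) at background quantile knots, and step/threshold (T)
#' features at the same knots. Every feature is min-max normalized to
#' \[0, 1\] over the background (all valid cells of the training stack);
#' the normalization constants are stored so projection stacks are clamped
#' to the training range.
#'
#' @param stack Training `env_stack`.
#' @param retained_layers Character vector of layer names to expand.
#' @param combo Non-empty subset of `c("L", "Q", "P", "H", "T")`.
#' @param n_hinge_knots Number of interior quantile knots per layer for H/T.
#' @return An object of class `feature_set` with elements `defs` (feature
#'   manifest), `norm` (per-feature min/max), `stack` (the training stack)
#'   and `notes` (e.g. a requested class that yielded no features).
#' @export
build_features <- function(stack, retained_layers,
                           combo = c("L", "Q"), n_hinge_knots = 5) {
  combo <- match.arg(combo, c("L", "Q", "P", "H", "T"), several.ok = TRUE)
  stopifnot(length(retained_layers) >= 1)
  missing <- setdiff(retained_layers, names(stack$layers))
  if (length(missing) > 0)
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  valid <- which(as.vector(valid_mask(stack)))
  bg_vals <- lapply(retained_layers,
                    function(nm) as.vector(stack$layers[[nm]])[valid])
  names(bg_vals) <- retained_layers

  defs <- data.frame(kind = character(0), layer1 = character(0),
                     layer2 = character(0), knot = numeric(0),
                     name = character(0), stringsAsFactors = FALSE)
  add <- function(kind, l1, l2 = NA_character_, knot = NA_real_, name) {
    defs <<- rbind(defs, data.frame(kind = kind, layer1 = l1, layer2 = l2,
                                    knot = knot, name = name,
                                    stringsAsFactors = FALSE))
  }
  notes <- character(0)
  for (nm in retained_layers) add("linear", nm, name = nm)
  if ("Q" %in% combo)
    for (nm in retained_layers) add("quadratic", nm, name = paste0(nm, "^2"))
  if ("P" %in% combo) {
    if (length(retained_layers) < 2) {
      notes <- c(notes, "P requested but only one layer: no product features")
    } else {
      prs <- utils::combn(retained_layers, 2)
      for (j in seq_len(ncol(prs)))
        add("product", prs[1, j], prs[2, j],
            name = paste0(prs[1, j], "*", prs[2, j]))
    }
  }
  knots_of <- function(nm) {
    v <- bg_vals[[nm]]
    q <- stats::quantile(v, probs = seq_len(n_hinge_knots) /
                           (n_hinge_knots + 1), names = FALSE)
    unique(q[q > min(v) & q < max(v)])
  }
  if ("H" %in% combo) {
    for (nm in retained_layers) {
      for (k in knots_of(nm)) {
        add("hinge_fwd", nm, knot = k, name = sprintf("h(%s>%.4g)", nm, k))
        add("hinge_rev", nm, knot = k, name = sprintf("h(%s<%.4g)", nm, k))
      }
    }
  }
  if ("T" %in% combo) {
    for (nm in retained_layers)
      for (k in knots_of(nm))
        add("threshold", nm, knot = k, name = sprintf("t(%s>%.4g)", nm, k))
  }

  fs <- structure(list(defs = defs, norm = NULL, stack = stack,
                       combo = combo, notes = notes),
                  class = "feature_set")
  raw <- raw_feature_matrix(fs, valid, stack)
  fs$norm <- data.frame(
    min = apply(raw, 2, min),
    max = apply(raw, 2, max)
  )
  degenerate <- fs$norm$max - fs$norm$min <= 0
  if (any(degenerate))
    fs$notes <- c(fs$notes, sprintf("%d degenerate (constant) feature(s)",
                                    sum(degenerate)))
  fs
}

# un-normalized feature values at the given column-major cell indices
raw_feature_matrix <- function(fs, cells, stack) {
  lay <- function(nm) as.vector(stack$layers[[nm]])[cells]
  d <- fs$defs
  out <- matrix(0, length(cells), nrow(d))
  for (j in seq_len(nrow(d))) {
    x <- lay(d$layer1[j])
    out[, j] <- switch(d$kind[j],
      linear = x,
      quadratic = x^2,
      product = x * lay(d$layer2[j]),
      hinge_fwd = pmax(0, x - d$knot[j]),
      hinge_rev = pmax(0, d$knot[j] - x),
      threshold = as.numeric(x > d$knot[j])
    )
  }
  colnames(out) <- d$name
  out
}

#' Evaluate normalized feature values at cells
#'
#' @param fs A `feature_set`.
#' @param cells Integer column-major cell indices.
#' @param stack Stack to evaluate on (default: the training stack); values
#'   are clamped to the training \[0, 1\] feature range.
#' @return Numeric matrix, one column per feature, values in \[0, 1\].
#' @export
feature_matrix <- function(fs, cells, stack = fs$stack) {
  raw <- raw_feature_matrix(fs, cells, stack)
  rng <- fs$norm$max - fs$norm$min
  rng[rng <= 0] <- 1   # degenerate feature -> constant 0 after centering
  out <- sweep(sweep(raw, 2, fs$norm$min), 2, rng, "/")
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit an L1-regularized maximum-entropy species distribution model
#'
#' Minimizes the regularized negative presence log-likelihood of a Gibbs
#' distribution over the background:
#' \deqn{-\frac{1}{m}\sum_{pres}\eta(x) + \log\sum_{bg} e^{\eta(x)}
#'       + \sum_j \beta_j |\lambda_j|,}
#' with \eqn{\eta = \sum_j \lambda_j f_j} and per-feature penalty
#' \eqn{\beta_j = \mathrm{rm} \cdot w_{class} \cdot s_j/\sqrt{m}} (\eqn{s_j}
#' the presence standard deviation of feature j, class weight 0.5 for hinge
#' features and 1 otherwise). Optimization is FISTA (accelerated proximal
#' gradient with backtracking); convergence is declared when the objective
#' changes by less than `tol` for five consecutive iterations. At the
#' optimum the Karush-Kuhn-Tucker conditions bound the gap between each
#' feature's background expectation and presence mean by its penalty.
#'
#' @param presence_cells Integer cell indices of presences (>= 5).
#' @param background_cells Integer cell indices of background cells.
#' @param features A `feature_set` from [build_features()].
#' @param reg_multiplier Positive global regularization multiplier.
#' @param max_iter Iteration cap; hitting it flags the model non-converged.
#' @param tol Objective-change convergence tolerance.
#' @param quiet Suppress the non-convergence warning.
#' @return An object of class `maxent` with the fitted coefficients
#'   (`lambdas`), penalties (`beta`), `log_partition` (log Z over the
#'   training background), `entropy_H` of the fitted distribution, and
#'   bookkeeping fields.
#' @export
maxent <- function(presence_cells, background_cells, features,
                   reg_multiplier = 1, max_iter = 5000, tol = 1e-6,
                   quiet = FALSE) {
  stopifnot(length(presence_cells) >= 5, reg_multiplier >= 0)
  m <- length(presence_cells)
  Fp <- feature_matrix(features, presence_cells)
  Fb <- feature_matrix(features, background_cells)
  p <- ncol(Fp)
  N <- nrow(Fb)

  class_w <- c(linear = 1, quadratic = 1, product = 1,
               hinge_fwd = 0.5, hinge_rev = 0.5, threshold = 1)
  sd_pres <- if (p > 0) apply(Fp, 2, stats::sd) else numeric(0)
  beta <- reg_multiplier * unname(class_w[features$defs$kind]) *
    pmax(sd_pres, 1e-6) / sqrt(m)

  fbar <- if (p > 0) colMeans(Fp) else numeric(0)
  smooth_obj <- function(l) {
    eta <- if (p > 0) drop(Fb %*% l) else rep(0, N)
    -sum(fbar * l) + logsumexp(eta)
  }
  grad <- function(l) {
    eta <- if (p > 0) drop(Fb %*% l) else rep(0, N)
    q <- exp(eta - logsumexp(eta))
    drop(crossprod(Fb, q)) - fbar
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  lambda <- rep(0, p)
  converged <- TRUE
  iters <- 0L
  if (p > 0) {
    y <- lambda
    tk <- 1
    L <- 1
    obj_old <- smooth_obj(lambda) + sum(beta * abs(lambda))
    stable <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      g <- grad(y)
      fy <- smooth_obj(y)
      repeat {
        cand <- soft(y - g / L, beta / L)
        dlt <- cand - y
        if (smooth_obj(cand) <= fy + sum(g * dlt) + L / 2 * sum(dlt^2) ||
            L > 1e12) break
        L <- L * 2
      }
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      y <- cand + ((tk - 1) / t_new) * (cand - lambda)
      lambda <- cand
      tk <- t_new
      obj <- smooth_obj(lambda) + sum(beta * abs(lambda))
      if (obj > obj_old + tol) {       # FISTA ripple: restart momentum
        y <- lambda
        tk <- 1
      }
      stable <- if (abs(obj - obj_old) < tol) stable + 1L else 0L
      obj_old <- obj
      iters <- it
      if (stable >= 5L) { converged <- TRUE; break }
      L <- max(L / 2, 1e-4)
    }
    if (!converged && !quiet)
      warning(sprintf("maxent fit did not converge in %d iterations (objective %.8g)",
                      max_iter, obj_old))
  }

  eta_b <- if (p > 0) drop(Fb %*% lambda) else rep(0, N)
  logZ <- logsumexp(eta_b)
  q <- exp(eta_b - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))

  structure(list(
    lambdas = stats::setNames(lambda, features$defs$name),
    features = features,
    reg_multiplier = reg_multiplier,
    beta = beta,
    log_partition = logZ,
    entropy_H = H,
    presence_cells = presence_cells,
    background_cells = background_cells,
    m = m, n_background = N,
    converged = converged, n_iter = iters
  ), class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("maxent model: %d feature(s), %d nonzero, rm = %g\n",
              length(x$lambdas), sum(x$lambdas != 0), x$reg_multiplier))
  cat(sprintf("  %d presences, %d background cells; H = %.4f%s\n",
              x$m, x$n_background, x$entropy_H,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambdas

#' @export
logLik.maxent <- function(object, ...) {
  eta <- drop(feature_matrix(object$features, object$presence_cells) %*%
                object$lambdas)
  ll <- sum(eta - object$log_partition)
  structure(ll, df = sum(object$lambdas != 0), class = "logLik")
}

#' @export
summary.maxent <- function(object, ...) {
  nz <- object$lambdas[object$lambdas != 0]
  cat(sprintf("L1-regularized Gibbs SDM (rm = %g)\n", object$reg_multiplier))
  cat(sprintf("presences: %d  background: %d  features: %d (%d active)\n",
              object$m, object$n_background, length(object$lambdas),
              length(nz)))
  cat(sprintf("log Z = %.6f  entropy H = %.6f  training gain = %.6f\n",
              object$log_partition, object$entropy_H, training_gain(object)))
  if (length(nz) > 0) {
    cat("active coefficients:\n")
    print(round(sort(nz, decreasing = TRUE), 6))
  }
  invisible(object)
}

#' Training gain of a fitted model
#'
#' Unpenalized log-likelihood improvement per presence over the uniform
#' background model: `mean_presence(eta) - log Z + log N`.
#'
#' @param fit A `maxent` model.
#' @return Numeric gain (0 for the uniform model).
#' @export
training_gain <- function(fit) {
  eta <- if (length(fit$lambdas) > 0)
    drop(feature_matrix(fit$features, fit$presence_cells) %*% fit$lambdas)
  else rep(0, fit$m)
  mean(eta) - fit$log_partition + log(fit$n_background)
}

#' Predict suitability from a fitted MaxEnt model
#'
#' @param object A `maxent` model.
#' @param stack Stack to project onto (default the training stack); must
#'   provide every source layer. Features are clamped to the training range.
#' @param output `"cloglog"` (default, the 0-1 suitability index
#'   `1 - exp(-e^H * raw)`) or `"raw"` (Gibbs probability `e^eta / Z` with
#'   the training-stack partition function).
#' @param ... Unused.
#' @return Suitability matrix on the projection grid, `NA` outside valid
#'   cells.
#' @export
predict.maxent <- function(object, stack = object$features$stack,
                           output = c("cloglog", "raw"), ...) {
  output <- match.arg(output)
  missing <- setdiff(unique(c(object$features$defs$layer1,
                              stats::na.omit(object$features$defs$layer2))),
                     names(stack$layers))
  if (length(missing) > 0)
    stop("projection stack lacks layer(s): ", paste(missing, collapse = ", "))
  cells <- which(as.vector(valid_mask(stack)))
  Fm <- feature_matrix(object$features, cells, stack)
  eta <- if (length(object$lambdas) > 0) drop(Fm %*% object$lambdas)
         else rep(0, length(cells))
  raw <- exp(eta - object$log_partition)
  vals <- if (output == "raw") raw
          else 1 - exp(-exp(object$entropy_H) * raw)
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[cells] <- vals
  out
}

#' Presence-background AUC
#'
#' Mann-Whitney statistic: the probability that a randomly drawn presence
#' cell scores above a randomly drawn background cell, ties counted 1/2.
#' Presence cells are excluded from the background sample.
#'
#' @param suitability Suitability matrix.
#' @param test_presence_cells Integer cell indices of (test) presences.
#' @param background_cells Integer cell indices of background cells.
#' @return AUC in \[0, 1\] (0.5 for a constant map).
#' @export
evaluate_auc <- function(suitability, test_presence_cells, background_cells) {
  stopifnot(length(test_presence_cells) >= 1)
  bg <- setdiff(background_cells, test_presence_cells)
  sp <- as.vector(suitability)[test_presence_cells]
  sb <- as.vector(suitability)[bg]
  if (anyNA(c(sp, sb))) stop("suitability undefined at evaluation cells")
  if (length(sb) == 0) stop("no background cells left after exclusion")
  r <- rank(c(sp, sb))
  m <- length(sp); n <- length(sb)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Qualitative AUC band
#'
#' Fixed accuracy bands, left-closed right-open except the top:
#' \[0.5, 0.6) unqualified, \[0.6, 0.7) poor, \[0.7, 0.8) fair,
#' \[0.8, 0.9) good, \[0.9, 1.0\] excellent; below 0.5 is
#' "worse-than-random".
#'
#' @param auc AUC value(s) in \[0, 1\].
#' @return Character band label(s).
#' @export
grade_auc <- function(auc) {
  stopifnot(all(auc >= 0 & auc <= 1))
  vapply(auc, function(a) {
    if (a < 0.5) "worse-than-random"
    else if (a < 0.6) "unqualified"
    else if (a < 0.7) "poor"
    else if (a < 0.8) "fair"
    else if (a < 0.9) "good"
    else "excellent"
  }, character(1))
}

#' Omission rate at a training-percentile threshold
#'
#' The threshold is the `percentile`-th percentile of training-presence
#' suitability (inverse empirical CDF: the smallest training value with at
#' least that fraction of mass at or below it); the rate is the fraction of
#' test presences scoring strictly below the threshold.
#'
#' @param suitability Suitability matrix.
#' @param train_presence_cells,test_presence_cells Integer cell indices.
#' @param percentile Percentile in \[0, 100\] (default 10).
#' @return Omission rate in \[0, 1\].
#' @export
omission_rate <- function(suitability, train_presence_cells,
                          test_presence_cells, percentile = 10) {
  stopifnot(length(train_presence_cells) >= 1,
            length(test_presence_cells) >= 1)
  v <- sort(as.vector(suitability)[train_presence_cells])
  th <- if (percentile <= 0) v[1]
        else v[max(1, ceiling(length(v) * percentile / 100))]
  mean(as.vector(suitability)[test_presence_cells] < th)
}

#' Sample-size-corrected AIC of a MaxEnt model
#'
#' Warren-Seifert convention: the likelihood is the product over presences
#' of the raw Gibbs probability (normalized to sum to one over the
#' background); `k` counts nonzero coefficients only. Undefined (`NA`) when
#' the presence count does not exceed `k + 1`.
#'
#' @param fit A `maxent` model.
#' @param presence_cells Presences to score (default: the training set).
#' @return AICc value, or `NA` when undefined.
#' @export
aicc <- function(fit, presence_cells = fit$presence_cells) {
  k <- sum(fit$lambdas != 0)
  n <- length(presence_cells)
  if (n <= k + 1) return(NA_real_)
  eta <- if (length(fit$lambdas) > 0)
    drop(feature_matrix(fit$features, presence_cells) %*% fit$lambdas)
  else rep(0, n)
  ll <- sum(eta - fit$log_partition)
  2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
}

#' Uniform random background sample
#'
#' All valid cells of the stack, downsampled to `max_background` with the
#' given seed when there are more.
#'
#' @param stack An `env_stack`.
#' @param max_background Cap on background size (default 10000).
#' @param seed Integer seed.
#' @return Integer vector of background cell indices.
#' @export
sample_background <- function(stack, max_background = 10000, seed = 1) {
  valid <- which(as.vector(valid_mask(stack)))
  if (length(valid) <= max_background) return(valid)
  set.seed(seed)
  sort(sample(valid, max_background))
}

split_presences <- function(cells, split, seed) {
  set.seed(seed)
  n <- length(cells)
  n_train <- max(1, round(n * split))
  if (n_train >= n) n_train <- n - 1
  train_idx <- sample.int(n, n_train)
  list(train = cells[train_idx], test = cells[-train_idx])
}

combo_label <- function(combo) paste(combo, collapse = "")

parse_combo <- function(label) strsplit(label, "")[[1]]

#' Kuenm-style calibration over regularization multipliers and feature
#' combinations
#'
#' For every `(rm, combo)` candidate: the presences are split once (seeded)
#' into training/test fractions, the model is fitted on the training cells,
#' and test AUC, test omission rate (10th-percentile training threshold) and
#' AICc (over all presences) are computed. Candidate selection follows the
#' omission-then-AICc rule: statistically acceptable rows are those with
#' omission rate at most `omission_max`; among them, rows within
#' `delta_aicc_max` of the minimum AICc are selected. If no row is
#' acceptable, the overall minimum-AICc row is selected as a fallback.
#'
#' @param occ_cells Integer presence cell indices.
#' @param stack Training `env_stack`.
#' @param rm_grid Regularization multipliers to try.
#' @param combos List of feature-class subsets (character vectors or strings
#'   like `"LQH"`).
#' @param split Training fraction (default 0.75).
#' @param seed Integer seed controlling the split and background sample.
#' @param omission_max Acceptability ceiling on the omission rate.
#' @param delta_aicc_max AICc window among acceptable rows.
#' @param n_hinge_knots Knots per layer for hinge/threshold features.
#' @param max_background Background cap.
#' @param retained_layers Layers to use (default: all stack layers).
#' @return A `calibration_result` data frame with one row per candidate and
#'   columns `reg_multiplier`, `feature_combo`, `mean_test_auc`,
#'   `omission_rate`, `aicc`, `delta_aicc`, `selected`, `converged`.
#' @export
calibrate <- function(occ_cells, stack, rm_grid = c(0.5, 1, 2, 4),
                      combos = list("L", "LQ", "LQP", "LQH", "LQPH"),
                      split = 0.75, seed = 1, omission_max = 0.05,
                      delta_aicc_max = 2, n_hinge_knots = 5,
                      max_background = 10000,
                      retained_layers = names(stack$layers)) {
  stopifnot(length(rm_grid) >= 1, length(combos) >= 1)
  bg <- sample_background(stack, max_background, seed)
  sp <- split_presences(occ_cells, split, seed)
  rows <- list()
  for (cb in combos) {
    cb <- if (length(cb) == 1 && nchar(cb) > 1) parse_combo(cb) else cb
    fs <- build_features(stack, retained_layers, combo = cb,
                         n_hinge_knots = n_hinge_knots)
    for (rm in rm_grid) {
      fit <- maxent(sp$train, bg, fs, reg_multiplier = rm, quiet = TRUE)
      suit <- predict(fit, stack, output = "cloglog")
      rows[[length(rows) + 1]] <- data.frame(
        reg_multiplier = rm,
        feature_combo = combo_label(cb),
        mean_test_auc = evaluate_auc(suit, sp$test, bg),
        omission_rate = omission_rate(suit, sp$train, sp$test),
        aicc = aicc(fit, occ_cells),
        converged = fit$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- NA_real_
  tab$selected <- FALSE
  ok <- !is.na(tab$aicc)
  acceptable <- ok & tab$omission_rate <= omission_max
  if (any(acceptable)) {
    tab$delta_aicc[ok] <- tab$aicc[ok] - min(tab$aicc[acceptable])
    tab$selected <- acceptable & tab$delta_aicc <= delta_aicc_max
  } else if (any(ok)) {
    tab$delta_aicc[ok] <- tab$aicc[ok] - min(tab$aicc[ok])
    tab$selected <- ok & tab$delta_aicc == 0
  }
  attr(tab, "seed") <- seed
  attr(tab, "selection") <-
    "omission <= E then deltaAICc <= 2; fallback min AICc (no partial ROC)"
  class(tab) <- c("calibration_result", "data.frame")
  tab
}

#' Replicate-averaged suitability map
#'
#' Runs `n_reps` independent seeded training/test splits with the chosen
#' parameters, predicts the cloglog suitability for each replicate, and
#' averages the maps cell-wise; the suitability index reported downstream is
#' this replicate mean.
#'
#' @param occ_cells Integer presence cell indices.
#' @param stack Training `env_stack`.
#' @param combo Feature-class subset (vector or string).
#' @param reg_multiplier Regularization multiplier.
#' @param n_reps Number of replicates (default 10).
#' @param split Training fraction (default 0.75).
#' @param seed Master seed; per-replicate sub-seeds are drawn from it.
#' @param rep_seeds Optional explicit per-replicate seeds (overrides `seed`
#'   derivation; recycling them forces identical splits).
#' @param n_hinge_knots,max_background,retained_layers As in [calibrate()].
#' @return List of class `replicate_result`: `mean_map`, `mean_auc`,
#'   `rep_aucs`, `models` (the fitted `maxent` objects).
#' @export
replicate_run <- function(occ_cells, stack, combo, reg_multiplier,
                          n_reps = 10, split = 0.75, seed = 1,
                          rep_seeds = NULL, n_hinge_knots = 5,
                          max_background = 10000,
                          retained_layers = names(stack$layers)) {
  stopifnot(n_reps >= 1)
  if (length(combo) == 1 && nchar(combo) > 1) combo <- parse_combo(combo)
  if (is.null(rep_seeds)) {
    set.seed(seed)
    rep_seeds <- sample.int(.Machine$integer.max %/% 2, n_reps)
  }
  stopifnot(length(rep_seeds) == n_reps)
  bg <- sample_background(stack, max_background, seed)
  fs <- build_features(stack, retained_layers, combo = combo,
                       n_hinge_knots = n_hinge_knots)
  maps <- vector("list", n_reps)
  aucs <- numeric(n_reps)
  models <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    sp <- split_presences(occ_cells, split, rep_seeds[i])
    fit <- maxent(sp$train, bg, fs, reg_multiplier = reg_multiplier,
                  quiet = TRUE)
    suit <- predict(fit, stack, output = "cloglog")
    maps[[i]] <- suit
    aucs[i] <- evaluate_auc(suit, sp$test, bg)
    models[[i]] <- fit
  }
  mean_map <- Reduce(`+`, maps) / n_reps
  structure(list(mean_map = mean_map, mean_auc = mean(aucs),
                 rep_aucs = aucs, models = models, rep_seeds = rep_seeds),
            class = "replicate_result")
}

#' Write a fitted model as a plain-text lambdas file
#'
#' One row per feature: name, coefficient, normalization min and max, plus a
#' metadata block (regularization, partition function, entropy).
#'
#' @param fit A `maxent` model.
#' @param path Output path.
#' @export
write_lambdas <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# feature, lambda, min, max", con)
  d <- fit$features$defs
  for (j in seq_along(fit$lambdas))
    writeLines(sprintf("%s, %.10g, %.10g, %.10g", d$name[j],
                       fit$lambdas[j], fit$features$norm$min[j],
                       fit$features$norm$max[j]), con)
  writeLines(sprintf("regMultiplier, %.10g", fit$reg_multiplier), con)
  writeLines(sprintf("logPartition, %.10g", fit$log_partition), con)
  writeLines(sprintf("entropy, %.10g", fit$entropy_H), con)
  writeLines(sprintf("numBackgroundPoints, %d", fit$n_background), con)
  invisible(path)
}
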