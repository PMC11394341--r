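#' Pairwise Pearson correlation between stack layers
#'
#' Correlations are computed over a uniform random sample of valid
#' (non-nodata) cells, or all valid cells when fewer than
#' `max_sample_cells`. Constant layers get `NA` (an explicit
#' undefined-marker) against every other layer, never a silent zero.
#'
#' @param stack An `env_stack` with at least two layers.
#' @param max_sample_cells Cap on the number of cells used.
#' @param seed Integer seed for the cell sample.
#' @return An object of class `correlation_report`: list with `layer_names`,
#'   `r_matrix` and `sample_cells`.
#' @export
pairwise_correlation <- function(stack, max_sample_cells = 10000, seed = 1) {
  nms <- names(stack$layers)
  if (length(nms) < 2) stop("need at least two layers")
  valid <- which(as.vector(valid_mask(stack)))
  if (length(valid) < 3) stop("need at least three valid cells")
  set.seed(seed)
  cells <- if (length(valid) > max_sample_cells)
    sort(sample(valid, max_sample_cells)) else valid
  X <- vapply(stack$layers, function(m) as.vector(m)[cells],
              numeric(length(cells)))
  sds <- apply(X, 2, stats::sd)
  R <- suppressWarnings(stats::cor(X))
  # constant layers: undefined off-diagonal, 1 on the diagonal
  const <- sds == 0
  R[const, ] <- NA
  R[, const] <- NA
  diag(R) <- 1
  dimnames(R) <- list(nms, nms)
  structure(list(layer_names = nms, r_matrix = R,
                 sample_cells = length(cells)),
            class = "correlation_report")
}

#' Univariate contribution scores for stack layers
#'
#' Scores each layer by the training gain of a univariate linear+quadratic
#' maximum-entropy model fitted on that layer alone: the unpenalized
#' log-likelihood improvement of the fitted Gibbs distribution over the
#' uniform background distribution. Degenerate (constant) layers score 0.
#' Used as the "contribution rate" when breaking correlated pairs.
#'
#' @param presence_cells Integer cell indices of presences (>= 5).
#' @param background_cells Integer cell indices of background cells.
#' @param stack An `env_stack`.
#' @param reg_multiplier Regularization multiplier for the univariate fits.
#' @return An object of class `contribution_scores`: named numeric vector of
#'   gains (attribute `method_tag = "univariate_lq_gain"`).
#' @export
variable_contributions <- function(presence_cells, background_cells, stack,
                                   reg_multiplier = 1) {
  if (length(presence_cells) < 5) stop("need at least 5 presence cells")
  scores <- vapply(names(stack$layers), function(nm) {
    sub <- env_stack(stack$grid, stack$layers[nm],
                     period_tag = stack$period_tag,
                     scenario_tag = stack$scenario_tag)
    vals <- as.vector(sub$layers[[1]])[background_cells]
    if (stats::sd(vals, na.rm = TRUE) == 0 ||
        !is.finite(stats::sd(vals, na.rm = TRUE))) return(0)
    fs <- build_features(sub, nm, combo = c("L", "Q"))
    fit <- maxent(presence_cells, background_cells, fs,
                  reg_multiplier = reg_multiplier, quiet = TRUE)
    max(training_gain(fit), 0)
  }, numeric(1))
  structure(scores, method_tag = "univariate_lq_gain",
            class = "contribution_scores")
}

#' Iterative correlation-based variable selection
#'
#' While any retained pair of layers has `|r| >= threshold`, the pair with
#' the largest `|r|` is inspected and its lower-contribution member removed
#' (ties broken by removing the later layer in input order). The result
#' contains no pair at or above the threshold. Undefined (`NA`) correlations
#' never trigger a removal.
#'
#' @param report A `correlation_report`.
#' @param scores A `contribution_scores` (or named numeric vector) covering
#'   every layer in the report.
#' @param threshold Absolute-correlation removal threshold (default 0.8).
#' @return Character vector of retained layer names, in input order, with a
#'   `removed` attribute logging each removal (layer, partner, r, reason).
#' @export
select_variables <- function(report, scores, threshold = 0.8) {
  nms <- report$layer_names
  sc <- unclass(scores)[nms]
  if (any(is.na(sc)))
    stop("a contribution score is required for every layer")
  keep <- nms
  removed <- data.frame(layer = character(0), partner = character(0),
                        r = numeric(0))
  repeat {
    R <- abs(report$r_matrix[keep, keep, drop = FALSE])
    diag(R) <- 0
    R[is.na(R)] <- 0
    if (length(keep) < 2 || max(R) < threshold) break
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    a <- keep[min(ij)]; b <- keep[max(ij)]
    # remove the lower-contribution member; tie -> the later layer in order
    drop_layer <- if (sc[a] < sc[b]) a else b
    partner <- if (drop_layer == a) b else a
    removed <- rbind(removed, data.frame(layer = drop_layer, partner = partner,
                                         r = report$r_matrix[drop_layer, partner]))
    keep <- setdiff(keep, drop_layer)
  }
  structure(keep, removed = removed)
}
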