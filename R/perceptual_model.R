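# Weighted linear gloss/coverage cue-combination model:
#   P' = W * P_coverage + (1 - W) * (1 - P_gloss)
# W is estimated by sweeping a grid of weights and taking the one whose
# model output correlates best (by r^2) with the percepts; the same
# functional form is used for saturation and lightness with independent
# weights.

#' Model prediction from gloss and coverage probabilities
#'
#' `W * p_coverage + (1 - W) * (1 - p_gloss)`, elementwise over conditions.
#' W = 1 weights perceived coverage fully; W = 0 weights perceived gloss
#' fully (through its complement).
#'
#' @param W model weight.
#' @param p_gloss,p_coverage probability estimates in \[0, 1\] (vectors of
#'   equal length).
#' @return Numeric vector of model outputs.
#' @export
predict_percept <- function(W, p_gloss, p_coverage) {
  stopifnot(length(p_gloss) == length(p_coverage),
            all(is.finite(p_gloss)), all(is.finite(p_coverage)),
            all(p_gloss >= 0 & p_gloss <= 1),
            all(p_coverage >= 0 & p_coverage <= 1))
  W * p_coverage + (1 - W) * (1 - p_gloss)
}

# correlation p value by the standard t transform with n - 2 dfs
.cor_p <- function(r, n) {
  if (n < 3 || abs(r) >= 1) return(if (abs(r) >= 1) 0 else NA_real_)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Sweep the model weight
#'
#' Evaluates the Pearson correlation between model output and percepts at
#' every weight on an inclusive grid from -1 to 1 (default step 0.01, 201
#' points) and returns the grid plus the best fit. Best = maximum r^2, with
#' the signed r reported; ties are broken toward smaller `|W|` (then toward
#' the smaller W) for determinism. Weights at which the model output has
#' zero variance are excluded with a warning.
#'
#' @param percepts numeric vector of perceptual estimates (one per
#'   condition), e.g. mean matched saturation.
#' @param p_gloss,p_coverage aligned probability estimates.
#' @param step sweep step (default 0.01).
#' @param pooling,dv labels stored in the fit metadata.
#' @return Object of class `sweep_result`: list with `grid` (data frame W,
#'   r), `best` (a `model_fit` row: W, r, p, n, pooling, dv).
#' @export
sweep_weight <- function(percepts, p_gloss, p_coverage, step = 0.01,
                         pooling = "per-block", dv = "saturation") {
  n <- length(percepts)
  stopifnot(n == length(p_gloss), n == length(p_coverage))
  if (n < 3) stop("need at least 3 conditions to fit", call. = FALSE)
  if (stats::sd(percepts) == 0)
    stop("percepts have zero variance", call. = FALSE)
  W_grid <- seq(-1, 1, by = step)
  r <- vapply(W_grid, function(w) {
    pred <- predict_percept(w, p_gloss, p_coverage)
    if (stats::sd(pred) == 0) NA_real_ else stats::cor(pred, percepts)
  }, numeric(1))
  if (anyNA(r)) {
    if (all(is.na(r)))
      stop("model output has zero variance at every weight", call. = FALSE)
    warning(sum(is.na(r)),
            " weight(s) excluded: model output had zero variance")
  }
  r2 <- ifelse(is.na(r), -Inf, r^2)
  best_idx <- order(-r2, abs(W_grid), W_grid)[1]
  best <- .model_fit(W_grid[best_idx], r[best_idx], n, pooling, dv)
  structure(list(grid = data.frame(W = W_grid, r = r), best = best,
                 step = step),
            class = "sweep_result")
}

.model_fit <- function(W, r, n, pooling, dv) {
  structure(data.frame(W = W, r = r, p = .cor_p(r, n), n = n,
                       pooling = pooling, dv = dv),
            class = c("model_fit", "data.frame"))
}

#' @export
print.sweep_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("weight sweep (%s, %s): best W = %+.2f, r = %+.3f, p = %.3g, n = %d\n",
              b$dv, b$pooling, b$W, b$r, b$p, b$n))
  invisible(x)
}

#' Correlation at a fixed model weight
#'
#' The fit obtained when the weight is forced to a given value (e.g. the
#' pooled-data optimum applied to every subcondition) rather than swept.
#'
#' @param W_fixed the forced weight.
#' @inheritParams sweep_weight
#' @return A `model_fit` row.
#' @export
forced_weight_fit <- function(W_fixed, percepts, p_gloss, p_coverage,
                              pooling = "per-block", dv = "saturation") {
  n <- length(percepts)
  stopifnot(n == length(p_gloss), n == length(p_coverage), n >= 3)
  if (stats::sd(percepts) == 0)
    stop("percepts have zero variance", call. = FALSE)
  pred <- predict_percept(W_fixed, p_gloss, p_coverage)
  if (stats::sd(pred) == 0)
    stop("model output has zero variance at the forced weight", call. = FALSE)
  .model_fit(W_fixed, stats::cor(pred, percepts), n, pooling, dv)
}

#' Pooled fit across blocks
#'
#' Concatenates aligned condition points from several blocks (e.g. all hue
#' by slant subconditions) and runs one weight sweep over the pooled points.
#' Also reports the gloss-coverage inter-correlation on the pooled data.
#'
#' @param tables list of data frames, each with columns `percept`,
#'   `p_gloss`, `p_coverage`.
#' @inheritParams sweep_weight
#' @return A `sweep_result` with an extra element `cue_cor`, the Pearson
#'   correlation between `p_gloss` and `p_coverage` on the pooled points.
#' @export
pooled_fit <- function(tables, step = 0.01, dv = "saturation") {
  stopifnot(length(tables) >= 1)
  pooled <- do.call(rbind, lapply(tables, function(t)
    data.frame(percept = t$percept, p_gloss = t$p_gloss,
               p_coverage = t$p_coverage)))
  out <- sweep_weight(pooled$percept, pooled$p_gloss, pooled$p_coverage,
                      step = step, pooling = "pooled", dv = dv)
  out$cue_cor <- stats::cor(pooled$p_gloss, pooled$p_coverage)
  out
}
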