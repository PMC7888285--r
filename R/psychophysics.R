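# Turning raw responses into perceptual estimates: per-condition matched
# lightness/chroma/saturation, paired-comparison probabilities, and balanced
# repeated-measures ANOVA.

.cond_cols <- c("hue", "relief", "roughness", "slant")

#' Aggregate asymmetric-matching responses
#'
#' Per (observer, condition) means of matched lightness, chroma, and
#' saturation. Saturation aggregation rule:
#' \describe{
#'   \item{`"mean-of-ratios"` (default)}{mean of per-trial C/L — each trial's
#'     saturation is computed first, then averaged (matching per-observer
#'     averaging before any cross-observer average).}
#'   \item{`"ratio-of-means"`}{mean C divided by mean L.}
#' }
#' The two rules differ whenever L varies across trials.
#'
#' @param responses data frame with columns `observer`, `hue`, `relief`,
#'   `roughness`, `slant`, `L`, `C` (one row per trial).
#' @param rule saturation aggregation rule.
#' @param grid optional `matching_grid`; when supplied every response is
#'   validated to be one of the grid's cells.
#' @return Data frame of class `percept_table` with columns observer,
#'   condition fields, `mean_L`, `mean_C`, `mean_S`, `n_trials`.
#' @export
aggregate_matches <- function(responses,
                              rule = c("mean-of-ratios", "ratio-of-means"),
                              grid = NULL) {
  rule <- match.arg(rule)
  need <- c("observer", .cond_cols, "L", "C")
  if (!all(need %in% names(responses)))
    stop("responses must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(grid)) {
    ok <- .on_grid(responses$L, grid$lightness_levels) &
      .on_grid(responses$C, grid$chroma_levels)
    if (!all(ok))
      stop(sprintf("%d responses are not cells of the matching grid",
                   sum(!ok)), call. = FALSE)
  }
  if (any(responses$L <= 0))
    stop("matched lightness must be positive", call. = FALSE)
  key <- responses[, c("observer", .cond_cols)]
  agg <- stats::aggregate(
    cbind(L = responses$L, C = responses$C, S = responses$C / responses$L),
    by = key, FUN = mean)
  names(agg)[names(agg) == "L"] <- "mean_L"
  names(agg)[names(agg) == "C"] <- "mean_C"
  names(agg)[names(agg) == "S"] <- "mean_S"
  if (rule == "ratio-of-means") agg$mean_S <- agg$mean_C / agg$mean_L
  cnt <- stats::aggregate(list(n_trials = responses$L), by = key, FUN = length)
  out <- merge(agg, cnt, by = c("observer", .cond_cols), sort = TRUE)
  class(out) <- c("percept_table", "data.frame")
  out
}

.on_grid <- function(v, levels, tol = 1e-6) {
  vapply(v, function(x) any(abs(x - levels) < tol), logical(1))
}

#' Paired-comparison probability estimates
#'
#' For each condition in a block, the number of trials on which it was
#' chosen divided by the number of times it was presented. Presentations are
#' counted from the trial list itself (every trial presents both members of
#' its pair), never inferred from wins, so unchosen conditions are 0, not
#' missing. Conditions that never appear in the trial list are flagged with
#' `NA`.
#'
#' @param choices data frame with one row per trial: condition fields
#'   suffixed `_1` and `_2` (as produced by [build_pc_trials()]), an
#'   `observer` column, and `chosen` in `{1, 2}` (which side was selected).
#' @param task label stored in the output (`"gloss"` or `"coverage"`).
#' @return Data frame with columns observer, condition fields, `task`,
#'   `wins`, `presentations`, `p`.
#' @export
pc_probability <- function(choices, task = c("gloss", "coverage")) {
  task <- match.arg(task)
  stopifnot(all(choices$chosen %in% c(1, 2)))
  side <- function(s) {
    d <- choices[, c("observer", paste0(.cond_cols, "_", s))]
    names(d) <- c("observer", .cond_cols)
    d$win <- as.integer(choices$chosen == s)
    d
  }
  long <- rbind(side(1), side(2))
  agg <- stats::aggregate(cbind(wins = long$win, presentations = 1 + 0 * long$win),
                          by = long[, c("observer", .cond_cols)], FUN = sum)
  agg$task <- task
  agg$p <- agg$wins / agg$presentations
  agg <- agg[order(agg$observer, agg$hue, agg$slant, agg$relief,
                   agg$roughness), ]
  rownames(agg) <- NULL
  agg
}

#' Balanced repeated-measures ANOVA
#'
#' Classical within-subjects partitioning for a fully crossed balanced
#' design: every main effect and interaction among the within-subject
#' factors is tested against its own effect-by-subject interaction, with no
#' sphericity correction. Sums of squares are computed by
#' inclusion-exclusion on marginal totals, which is exact for balanced
#' designs. Replicated observations within a subject-by-cell combination
#' are averaged first; missing cells are an error (no imputation).
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param factors character vector of within-subject factor columns.
#' @param subject name of the subject identifier column (default
#'   `"observer"`).
#' @return Data frame of class `rm_anova` with columns `effect`, `df1`,
#'   `df2`, `SS_effect`, `SS_error`, `F`, `p`.
#' @export
rm_anova <- function(data, dv, factors, subject = "observer") {
  stopifnot(all(c(dv, factors, subject) %in% names(data)))
  d <- data.frame(y = as.numeric(data[[dv]]),
                  subject = factor(data[[subject]]))
  for (f in factors) d[[f]] <- factor(data[[f]])
  if (nlevels(d$subject) < 2)
    stop("repeated-measures ANOVA needs at least 2 subjects", call. = FALSE)
  # average replicates within subject x cell
  d <- stats::aggregate(y ~ ., data = d, FUN = mean)
  # completeness: one mean per subject x cell
  n_cells <- prod(vapply(factors, function(f) nlevels(d[[f]]), integer(1)))
  tab <- table(d$subject)
  if (any(tab != n_cells) || nrow(d) != n_cells * nlevels(d$subject))
    stop("design is not fully crossed: missing subject-by-cell combinations",
         call. = FALSE)

  # uncorrected sum of squares R(U): totals over the margin U, squared,
  # divided by the number of observations per margin cell
  N <- nrow(d)
  R <- function(cols) {
    if (length(cols) == 0) return(sum(d$y)^2 / N)
    tot <- stats::aggregate(d$y, by = d[cols], FUN = sum)$x
    n_per <- N / length(tot)
    sum(tot^2) / n_per
  }
  ss_term <- function(cols) {
    subsets <- .all_subsets(cols)
    sum(vapply(subsets, function(u)
      (-1)^(length(cols) - length(u)) * R(u), numeric(1)))
  }
  n_subj <- nlevels(d$subject)
  effects <- .all_subsets(factors)
  effects <- effects[lengths(effects) > 0]
  rows <- lapply(effects, function(eff) {
    df1 <- prod(vapply(eff, function(f) nlevels(d[[f]]) - 1L, integer(1)))
    df2 <- df1 * (n_subj - 1)
    ss_e <- ss_term(eff)
    ss_err <- ss_term(c(eff, "subject"))
    Fv <- (ss_e / df1) / (ss_err / df2)
    data.frame(effect = paste(eff, collapse = ":"),
               df1 = df1, df2 = df2, SS_effect = ss_e, SS_error = ss_err,
               F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

.all_subsets <- function(x) {
  out <- list(character(0))
  for (el in x) out <- c(out, lapply(out, function(s) c(s, el)))
  out
}
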