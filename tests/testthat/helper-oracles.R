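# Independent oracles used across the suite.

# Brute-force maximum-chroma scan: exhaustive sweep of C on a fine grid.
scan_max_chroma <- function(L, H, step = 0.25, C_max = 200) {
  Cs <- seq(0, C_max, by = step)
  ok <- chromaglint::in_gamut(rep(L, length(Cs)), Cs, rep(H, length(Cs)))
  if (!any(ok)) return(0)
  max(Cs[ok])
}

# Closed-form continuous optimum of the weight sweep. The model output is
# pred(W) = (1 - g) + W * u with u = c + g - 1; maximizing squared Pearson
# correlation with y over W gives, from d/dW cor^2 = 0,
#   W* = (a * s01 - b * s00) / (b * s01 - a * s11)
# with a = cov(1 - g, y), b = cov(u, y), s00 = var(1 - g),
# s01 = cov(1 - g, u), s11 = var(u).
analytic_best_weight <- function(y, g, cvg) {
  x0 <- 1 - g
  u <- cvg + g - 1
  a <- stats::cov(x0, y); b <- stats::cov(u, y)
  s00 <- stats::var(x0); s01 <- stats::cov(x0, u); s11 <- stats::var(u)
  W <- (a * s01 - b * s00) / (b * s01 - a * s11)
  # the stationary point can be the minimum (zero correlation); make sure we
  # return the r^2 maximizer on [-1, 1]
  cand <- c(max(min(W, 1), -1), -1, 1)
  r2 <- vapply(cand, function(w)
    stats::cor(x0 + w * u, y)^2, numeric(1))
  cand[which.max(r2)]
}

# F statistics from stats::aov with within-subject error strata, keyed by
# effect name in rm_anova's format (A:B etc).
aov_f_table <- function(data, dv, factors, subject = "observer") {
  d <- data
  d[[subject]] <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  rhs <- paste(factors, collapse = "*")
  form <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                    dv, rhs, subject, rhs))
  fit <- summary(stats::aov(form, data = d))
  out <- list()
  for (stratum in fit) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    for (k in seq_along(eff)) {
      if (eff[k] != "Residuals" && !is.na(tab[k, "F value"]))
        out[[eff[k]]] <- tab[k, "F value"]
    }
  }
  out
}

# Small balanced within-subject dataset with random effects.
random_rm_design <- function(seed, n_subj, levels_per_factor) {
  set.seed(seed)
  factors <- LETTERS[seq_along(levels_per_factor)]
  grids <- c(list(observer = paste0("s", seq_len(n_subj))),
             stats::setNames(lapply(levels_per_factor, function(k)
               paste0("l", seq_len(k))), factors))
  d <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$y <- stats::rnorm(nrow(d)) +
    stats::rnorm(n_subj)[match(d$observer, grids$observer)]
  for (f in factors) d$y <- d$y + stats::rnorm(length(unique(d[[f]])))[
    match(d[[f]], unique(d[[f]]))]
  d
}
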