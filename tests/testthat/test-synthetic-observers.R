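test_that("cue templates have the qualitative structure of the percepts", {
  p <- observer_params()
  lv <- default_levels("paired")
  # gloss falls with roughness at mid relief, mid slant
  c1 <- simulate_latent_cues(p, enumerate_conditions(39.999, 0.1,
                                                     c(0.01, 0.4), 30))
  expect_gt(c1$gloss[1], c1$gloss[2])
  # gloss strictly decreasing in roughness everywhere under defaults
  full <- simulate_latent_cues(p, enumerate_conditions(39.999, lv$reliefs,
                                                       lv$roughnesses,
                                                       lv$slants))
  for (h in lv$reliefs) for (s in lv$slants) {
    g <- full$gloss[full$relief == h & full$slant == s]
    expect_true(all(diff(g) < 0))
  }
  # coverage slope in roughness: positive at 15, negative at 45
  cov15 <- full$coverage[full$slant == 15 & full$relief == 0.05]
  cov45 <- full$coverage[full$slant == 45 & full$relief == 0.05]
  expect_true(all(diff(cov15) > 0))
  expect_true(all(diff(cov45) < 0))
  # coverage slope in relief: positive at 15, negative at 45
  rel15 <- full$coverage[full$slant == 15 & full$roughness == 0.1]
  rel45 <- full$coverage[full$slant == 45 & full$roughness == 0.1]
  expect_true(all(diff(rel15) > 0))
  expect_true(all(diff(rel45) < 0))
  # cues bounded in [0, 1] and deterministic
  expect_true(all(full$gloss >= 0 & full$gloss <= 1))
  expect_true(all(full$coverage >= 0 & full$coverage <= 1))
  expect_identical(full, simulate_latent_cues(p, enumerate_conditions(
    39.999, lv$reliefs, lv$roughnesses, lv$slants)))
})

test_that("low-relief inversion flips the gloss-roughness slope only at minimum relief", {
  p <- observer_params(low_relief_inversion = TRUE)
  lv <- default_levels("paired")
  cues <- simulate_latent_cues(p, enumerate_conditions(39.999, lv$reliefs,
                                                       lv$roughnesses, 15))
  low <- cues[cues$relief == 0.025, ]
  expect_true(all(diff(low$gloss) >= 0))
  high <- cues[cues$relief == 0.2, ]
  expect_true(all(diff(high$gloss) < 0))
})

test_that("noise-free matching snaps to the nearest grid cell", {
  p <- observer_params(setting_noise_sd = 0)
  g <- build_matching_grid(306.285, gamut = "flag")
  conds <- enumerate_conditions(306.285, c(0.025, 0.2), c(0.01, 0.4), 15)
  r <- simulate_matching(p, conds, g, seed = 1)
  r2 <- simulate_matching(p, conds, g, seed = 99)
  expect_identical(r[, c("i", "j", "L", "C")], r2[, c("i", "j", "L", "C")])
  expect_true(all(r$L %in% g$lightness_levels))
  expect_true(all(r$C %in% g$chroma_levels))
  # snapped cell is the nearest level to the latent mean, by reconstruction
  cues <- simulate_latent_cues(p, conds)
  blocks <- interaction(conds$hue, conds$slant, drop = TRUE)
  pg <- unlist(tapply(cues$gloss, blocks, expected_choice_probability,
                      sd = p$choice_noise_sd))
  pc <- unlist(tapply(cues$coverage, blocks, expected_choice_probability,
                      sd = p$choice_noise_sd))
  mu_L <- p$light_offset + p$light_gain *
    predict_percept(p$true_W_light, pg, pc)
  nearest <- vapply(mu_L, function(m)
    g$lightness_levels[which.min(abs(g$lightness_levels - m))], numeric(1))
  expect_equal(r$L, unname(nearest))
})

test_that("midpoint settings tie-break to the lower grid index", {
  levels <- seq(18.75, 97.5, by = 3.75)
  snapped <- chromaglint:::.snap_to_levels(18.75 + 3.75 / 2, levels)
  expect_identical(snapped$idx, 1L)
  beyond <- chromaglint:::.snap_to_levels(c(-10, 500), levels)
  expect_identical(beyond$idx, c(1L, length(levels)))
})

test_that("matching noise produces a discretized-Gaussian cell distribution", {
  p <- observer_params(setting_noise_sd = 3.75)
  g <- build_matching_grid(306.285, gamut = "flag")
  cond <- enumerate_conditions(306.285, 0.1, 0.1, 30)
  reps <- cond[rep(1, 10000), ]
  r <- simulate_matching(p, reps, g, seed = 42, cue_scale = "latent")
  # oracle: discretize N(mu, sd) onto the level midpoints
  cues <- simulate_latent_cues(p, cond)
  mu <- p$light_offset + p$light_gain *
    predict_percept(p$true_W_light, cues$gloss, cues$coverage)
  lv <- g$lightness_levels
  cuts <- c(-Inf, lv[-length(lv)] + diff(lv) / 2, Inf)
  probs <- diff(pnorm(cuts, mean = mu, sd = 3.75))
  obs <- tabulate(r$j, nbins = length(lv))
  # lump sparse tail bins (expected < 5) into the nearest kept bin
  keep <- which(probs * sum(obs) >= 5)
  lo <- min(keep); hi <- max(keep)
  obs2 <- obs[lo:hi]
  probs2 <- probs[lo:hi]
  obs2[1] <- sum(obs[1:lo]); obs2[length(obs2)] <- sum(obs[hi:length(obs)])
  probs2[1] <- sum(probs[1:lo])
  probs2[length(probs2)] <- sum(probs[hi:length(probs)])
  chi <- chisq.test(obs2, p = probs2 / sum(probs2))
  expect_gt(chi$p.value, 0.01)
})

test_that("choices follow the Thurstonian rule", {
  conds <- enumerate_conditions(39.999, c(0.025, 0.2), c(0.01, 0.4), 15)
  trials <- build_pc_trials(conds, seed = 4)
  # zero noise: the larger cue always wins; ranking is reproduced exactly
  p0 <- observer_params(choice_noise_sd = 0)
  ch <- simulate_choices(p0, trials, "gloss", seed = 1)
  cues <- simulate_latent_cues(p0, conds)
  won <- ifelse(ch$chosen == 1, ch$first, ch$second)
  lost <- ifelse(ch$chosen == 1, ch$second, ch$first)
  expect_true(all(cues$gloss[won] >= cues$gloss[lost]))
  pp <- pc_probability(ch, task = "gloss")
  key <- paste(pp$relief, pp$roughness)
  ckey <- paste(conds$relief, conds$roughness)
  expect_identical(order(pp$p[match(ckey, key)]), order(cues$gloss))
})

test_that("equal cues with noise choose each side half the time", {
  p <- observer_params(choice_noise_sd = 0.2)
  tr <- data.frame(trial_id = 1:2000,
                   first = 1L, second = 2L,
                   hue_1 = 40, relief_1 = 0.05, roughness_1 = 0.1,
                   slant_1 = 30,
                   hue_2 = 40, relief_2 = 0.05, roughness_2 = 0.1,
                   slant_2 = 30)
  ch <- simulate_choices(p, tr, "gloss", seed = 8)
  rate <- mean(ch$chosen == 1)
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("empirical choice rates converge to the closed-form probability", {
  p <- observer_params(choice_noise_sd = 0.1)
  conds <- enumerate_conditions(39.999, c(0.05, 0.1), 0.1, 30)
  cues <- simulate_latent_cues(p, conds)
  delta <- cues$coverage[1] - cues$coverage[2]
  expected <- pnorm(delta / (sqrt(2) * 0.1))
  tr <- data.frame(trial_id = 1:500, first = 1L, second = 2L,
                   hue_1 = conds$hue[1], relief_1 = conds$relief[1],
                   roughness_1 = conds$roughness[1], slant_1 = conds$slant[1],
                   hue_2 = conds$hue[2], relief_2 = conds$relief[2],
                   roughness_2 = conds$roughness[2], slant_2 = conds$slant[2])
  ch <- simulate_choices(p, tr, "coverage", seed = 10)
  expect_lt(abs(mean(ch$chosen == 1) - expected), 0.03)
})

test_that("datasets are bit-reproducible from seed and parameters", {
  a <- simulate_dataset(seed = 21, n_observers = 2)
  b <- simulate_dataset(seed = 21, n_observers = 2)
  expect_identical(a$matching, b$matching)
  expect_identical(a$choices_gloss, b$choices_gloss)
  expect_identical(a$choices_coverage, b$choices_coverage)
  c_ <- simulate_dataset(seed = 22, n_observers = 2)
  expect_false(identical(a$matching$L, c_$matching$L))
})

test_that("the full pipeline recovers the true weights under default noise", {
  recs <- vapply(1:25, function(s) {
    rep <- run_pipeline(list(seed = s))
    rep$recovery$pooled_W
  }, numeric(2))
  expect_lte(abs(median(recs[1, ]) - 0.41), 0.05)  # saturation
  expect_lte(abs(median(recs[2, ]) - 0.34), 0.05)  # lightness
})

test_that("recovery error grows with setting noise", {
  err_at <- function(sd) {
    e <- vapply(1:6, function(s) {
      rep <- run_pipeline(list(seed = s, observer = list(setting_noise_sd = sd)))
      abs(rep$fits$saturation$pooled$best$W - 0.41)
    }, numeric(1))
    median(e)
  }
  expect_lte(err_at(1), err_at(20))
})
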