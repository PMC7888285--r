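# Synthetic observers with known ground truth. Latent gloss and coverage
# cue surfaces follow the qualitative structure of the psychophysical
# findings (gloss falls with specular roughness; the sign of the coverage
# slope in roughness and relief flips between 15 and 45 degree slants);
# matching settings are generated from the weighted gloss/coverage model
# plus Gaussian setting noise snapped to the matching grid, and pairwise
# choices follow a Thurstonian rule on the latent cues.

#' Synthetic observer parameters
#'
#' @param true_W_sat,true_W_light ground-truth model weights for saturation
#'   and lightness (defaults 0.41 and 0.34, the pooled estimates the model
#'   module is designed around).
#' @param setting_noise_sd Gaussian noise on matched L* and C*, in LCH units
#'   (default 3.75, one grid step).
#' @param choice_noise_sd Gaussian noise on the latent cue difference in the
#'   Thurstonian choice rule (default 0.1 latent units; the default cue
#'   surfaces span about 0.6).
#' @param gloss_coef named numeric: `base`, `roughness` (slope magnitude,
#'   subtracted), `relief` (slope, subtracted).
#' @param coverage_coef named numeric: `base`, `roughness`, `relief`. The
#'   roughness slope carries a factor (1 - 2 s(slant)) that passes through
#'   zero at slant 30; the relief slope carries (0.5 - 1.5 s), reversing
#'   sign between 15 and 45 degrees while staying nonzero at 30.
#' @param low_relief_inversion if `TRUE`, gloss at the lowest relief level
#'   increases with roughness (the inversion reported for flat surfaces
#'   viewed frontally) instead of decreasing.
#' @param hue_W_offset named numeric vector of per-hue additive offsets on
#'   both true weights (names = hue angles as given to the simulator);
#'   default none.
#' @param sat_gain,sat_offset affine map from model output to matched
#'   saturation C*/L* (defaults 0.55 and 0.65: together with the lightness
#'   map they keep the implied chroma C = S * L inside the default grid for
#'   model outputs anywhere in \[0, 1\]).
#' @param light_gain,light_offset affine map from model output to matched
#'   lightness L* (defaults 45 and 35).
#' @return List of class `observer_params`.
#' @export
observer_params <- function(true_W_sat = 0.41, true_W_light = 0.34,
                            setting_noise_sd = 3.75, choice_noise_sd = 0.1,
                            gloss_coef = c(base = 0.88, roughness = 0.60,
                                           relief = 0.12),
                            coverage_coef = c(base = 0.5, roughness = 0.25,
                                              relief = 0.35),
                            low_relief_inversion = FALSE,
                            hue_W_offset = NULL,
                            sat_gain = 0.55, sat_offset = 0.65,
                            light_gain = 45, light_offset = 35) {
  stopifnot(setting_noise_sd >= 0, choice_noise_sd >= 0,
            all(c("base", "roughness", "relief") %in% names(gloss_coef)),
            all(c("base", "roughness", "relief") %in% names(coverage_coef)))
  structure(list(true_W_sat = true_W_sat, true_W_light = true_W_light,
                 setting_noise_sd = setting_noise_sd,
                 choice_noise_sd = choice_noise_sd,
                 gloss_coef = gloss_coef, coverage_coef = coverage_coef,
                 low_relief_inversion = low_relief_inversion,
                 hue_W_offset = hue_W_offset,
                 sat_gain = sat_gain, sat_offset = sat_offset,
                 light_gain = light_gain, light_offset = light_offset),
            class = "observer_params")
}

# normalized predictors on fixed anchors so cue surfaces do not depend on
# which subset of levels a condition table happens to contain
.norm_rough <- function(a) pmin(pmax((a - 0.01) / (0.40 - 0.01), 0), 1)
.norm_relief <- function(h)
  pmin(pmax((log(h) - log(0.025)) / (log(0.200) - log(0.025)), 0), 1)
.norm_slant <- function(s) pmin(pmax((s - 15) / 30, 0), 1)
.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Latent gloss and coverage cue surfaces
#'
#' Deterministic per-condition cues in \[0, 1\]. Gloss decreases with
#' specular roughness (strictly, unless the low-relief inversion flag is set
#' and the condition sits at the lowest relief level) and slightly with
#' relief. The coverage slope in roughness is positive at slant 15, zero at
#' 30 and negative at 45 degrees; the slope in relief is positive at 15 and
#' negative at 30 and 45 degrees.
#'
#' @param params an `observer_params`.
#' @param conditions a `surface_conditions` data frame.
#' @return The conditions with columns `gloss` and `coverage` appended.
#' @export
simulate_latent_cues <- function(params, conditions) {
  stopifnot(inherits(params, "observer_params"))
  a <- .norm_rough(conditions$roughness)
  v <- .norm_relief(conditions$relief)
  s <- .norm_slant(conditions$slant)
  gc <- params$gloss_coef
  gloss <- gc[["base"]] - gc[["roughness"]] * a - gc[["relief"]] * v
  if (params$low_relief_inversion) {
    low <- conditions$relief <= min(conditions$relief) + 1e-12
    gloss[low] <- 0.25 + 0.40 * pmin(a[low] / 0.75, 1)
  }
  cc <- params$coverage_coef
  # roughness slope reverses sign through zero at the middle slant (the
  # roughness effect on coverage vanishes at 30 degrees); the relief slope
  # also reverses between 15 and 45 degrees but stays away from zero at 30,
  # where a relief effect on coverage persists
  coverage <- cc[["base"]] +
    cc[["roughness"]] * (1 - 2 * s) * (a - 0.5) +
    cc[["relief"]] * (0.5 - 1.5 * s) * (v - 0.5)
  out <- as.data.frame(conditions)
  out$gloss <- .clamp01(gloss)
  out$coverage <- .clamp01(coverage)
  out
}

.true_W <- function(params, which, hue) {
  W <- params[[paste0("true_W_", which)]]
  off <- params$hue_W_offset
  if (!is.null(off)) {
    key <- as.character(hue)
    W <- W + ifelse(key %in% names(off), off[key], 0)
  }
  rep_len(W, length(hue))
}

# snap values to the nearest grid level; exact midpoints break toward the
# lower index; values beyond the edges clip to the edge levels
.snap_to_levels <- function(x, levels) {
  step <- levels[2] - levels[1]
  idx <- floor((x - levels[1]) / step + 0.5 - 1e-12) + 1
  idx <- pmin(pmax(idx, 1), length(levels))
  list(idx = as.integer(idx), value = levels[idx])
}

#' Expected round-robin choice probabilities
#'
#' Closed-form expected paired-comparison probability for each condition in
#' a full round robin under the Thurstonian rule: the mean over opponents j
#' of `pnorm((cue_i - cue_j) / (sqrt(2) * sd))`. With `sd = 0` the normal
#' kernel degenerates to a step (ties count 1/2).
#'
#' @param cues numeric vector of latent cue values (one block).
#' @param sd Thurstonian choice noise sd.
#' @return Expected probabilities, same length as `cues`.
#' @export
expected_choice_probability <- function(cues, sd) {
  n <- length(cues)
  stopifnot(n >= 2, sd >= 0)
  d <- outer(cues, cues, "-")
  p <- if (sd > 0) stats::pnorm(d / (sqrt(2) * sd)) else
    (d > 0) + 0.5 * (d == 0)
  diag(p) <- 0
  rowSums(p) / (n - 1)
}

#' Simulate asymmetric-matching responses
#'
#' The latent percept means are affine maps of the model prediction
#' `predict_percept(true_W, cues)` into setting space: matched lightness
#' `L = light_offset + light_gain * P'_light` and matched saturation
#' `S = sat_offset + sat_gain * P'_sat`, with matched chroma `C = S * L`.
#' Gaussian setting noise (sd `setting_noise_sd`, LCH units) is added to L
#' and C independently, then each is snapped to the nearest grid level
#' (midpoint ties to the lower index) and clipped to the grid edges.
#'
#' With `cue_scale = "choice-probability"` (the default) the cues entering
#' the prediction are the expected round-robin choice probabilities of the
#' latent gloss and coverage surfaces within each hue-by-slant block — the
#' same scale on which the paired-comparison analysis estimates them — so
#' the ground-truth weight is recoverable by the downstream sweep without a
#' cue-scale distortion. `"latent"` uses the raw template surfaces instead.
#'
#' @param params an `observer_params`.
#' @param conditions a `surface_conditions` data frame (single hue assumed
#'   per grid; multi-hue tables are allowed when `grid` spans all hues'
#'   levels, since level sets are hue-independent).
#' @param grid a `matching_grid`.
#' @param observer observer identifier stored in the responses.
#' @param seed RNG seed.
#' @param cue_scale `"choice-probability"` (default) or `"latent"`.
#' @return Data frame of matching responses: `observer`, condition fields,
#'   `i`, `j` (chroma/lightness cell indices), `L`, `C`.
#' @export
simulate_matching <- function(params, conditions, grid, observer = "obs1",
                              seed = 1L,
                              cue_scale = c("choice-probability", "latent")) {
  stopifnot(inherits(params, "observer_params"),
            inherits(grid, "matching_grid"))
  cue_scale <- match.arg(cue_scale)
  cues <- simulate_latent_cues(params, conditions)
  if (cue_scale == "choice-probability") {
    block <- interaction(conditions$hue, conditions$slant, drop = TRUE)
    for (b in levels(block)) {
      k <- block == b
      if (sum(k) >= 2) {
        cues$gloss[k] <- expected_choice_probability(cues$gloss[k],
                                                     params$choice_noise_sd)
        cues$coverage[k] <- expected_choice_probability(cues$coverage[k],
                                                        params$choice_noise_sd)
      }
    }
  }
  W_s <- .true_W(params, "sat", conditions$hue)
  W_l <- .true_W(params, "light", conditions$hue)
  P_sat <- W_s * cues$coverage + (1 - W_s) * (1 - cues$gloss)
  P_light <- W_l * cues$coverage + (1 - W_l) * (1 - cues$gloss)
  mu_L <- params$light_offset + params$light_gain * P_light
  mu_S <- params$sat_offset + params$sat_gain * P_sat
  mu_C <- mu_S * mu_L
  Ls <- grid$lightness_levels
  Cs <- grid$chroma_levels
  outside <- mu_L < min(Ls) | mu_L > max(Ls) | mu_C < min(Cs) | mu_C > max(Cs)
  if (mean(outside) > 0.10)
    warning(sprintf(paste0("affine map places %.0f%% of condition means ",
                           "outside the matching grid; settings will pile ",
                           "up at the edges"), 100 * mean(outside)))
  n <- nrow(conditions)
  noise <- with_seed(seed, matrix(stats::rnorm(2 * n,
                                               sd = params$setting_noise_sd),
                                  n, 2))
  sL <- .snap_to_levels(mu_L + noise[, 1], Ls)
  sC <- .snap_to_levels(mu_C + noise[, 2], Cs)
  out <- as.data.frame(conditions)
  out$observer <- observer
  out$i <- sC$idx
  out$j <- sL$idx
  out$L <- sL$value
  out$C <- sC$value
  out[, c("observer", "hue", "relief", "roughness", "slant", "i", "j",
          "L", "C")]
}

#' Simulate paired-comparison choices
#'
#' Thurstonian rule: the first member of the pair is chosen iff
#' `cue(first) - cue(second) + N(0, choice_noise_sd) > 0`. With zero noise
#' the choice is deterministic; exactly tied cues at zero noise go to the
#' second member.
#'
#' @param params an `observer_params`.
#' @param trials a `pc_trials` data frame.
#' @param cue `"gloss"` or `"coverage"`.
#' @param observer observer identifier.
#' @param seed RNG seed.
#' @return The trials with columns `observer`, `task`, `chosen` appended.
#' @export
simulate_choices <- function(params, trials, cue = c("gloss", "coverage"),
                             observer = "obs1", seed = 1L) {
  cue <- match.arg(cue)
  cond1 <- data.frame(hue = trials$hue_1, relief = trials$relief_1,
                      roughness = trials$roughness_1, slant = trials$slant_1)
  cond2 <- data.frame(hue = trials$hue_2, relief = trials$relief_2,
                      roughness = trials$roughness_2, slant = trials$slant_2)
  c1 <- simulate_latent_cues(params, cond1)[[cue]]
  c2 <- simulate_latent_cues(params, cond2)[[cue]]
  eps <- if (params$choice_noise_sd > 0)
    with_seed(seed, stats::rnorm(nrow(trials), sd = params$choice_noise_sd))
  else 0
  out <- as.data.frame(trials)
  out$observer <- observer
  out$task <- cue
  out$chosen <- ifelse(c1 - c2 + eps > 0, 1L, 2L)
  out
}

#' Simulate a complete dataset
#'
#' Conditions default to the paired-comparison design (4 relief x 4
#' roughness per hue x slant block, 3 slants, 3 hues). For each observer,
#' matching responses are simulated for every condition and choice
#' responses for both tasks in every hue-by-slant block. All randomness
#' fans out deterministically from `seed` via labelled substreams, so the
#' dataset is bit-reproducible from (seed, params).
#'
#' @param params an `observer_params`.
#' @param seed top-level seed.
#' @param n_observers number of synthetic observers (default 4).
#' @param levels level sets as from [default_levels()] (default the
#'   paired-comparison design).
#' @param grid_gamut gamut mode for the matching grids (default `"flag"`:
#'   the nominal grid extends beyond the displayable boundary).
#' @return List of class `synthetic_dataset`: `params`, `seed`,
#'   `conditions`, `matching`, `choices_gloss`, `choices_coverage`,
#'   `grids` (one per hue).
#' @export
simulate_dataset <- function(params = observer_params(), seed = 1L,
                             n_observers = 4,
                             levels = default_levels("paired"),
                             grid_gamut = "flag") {
  conditions <- enumerate_conditions(levels$hues, levels$reliefs,
                                     levels$roughnesses, levels$slants)
  grids <- lapply(levels$hues, function(h)
    build_matching_grid(h, gamut = grid_gamut))
  names(grids) <- as.character(levels$hues)
  matching <- list()
  ch_g <- list()
  ch_c <- list()
  obs_ids <- sprintf("obs%d", seq_len(n_observers))
  for (o in seq_len(n_observers)) {
    matching[[o]] <- do.call(rbind, lapply(levels$hues, function(h) {
      sub <- conditions[conditions$hue == h, ]
      simulate_matching(params, sub, grids[[as.character(h)]],
                        observer = obs_ids[o],
                        seed = substream_seed(seed,
                                              sprintf("match/%s/%g",
                                                      obs_ids[o], h)))
    }))
    blocks <- expand.grid(hue = levels$hues, slant = levels$slants)
    for (b in seq_len(nrow(blocks))) {
      sub <- conditions[conditions$hue == blocks$hue[b] &
                          conditions$slant == blocks$slant[b], ]
      trials <- build_pc_trials(sub,
                                seed = substream_seed(seed,
                                                      sprintf("trials/%s/%d",
                                                              obs_ids[o], b)))
      ch_g[[length(ch_g) + 1]] <- simulate_choices(
        params, trials, "gloss", observer = obs_ids[o],
        seed = substream_seed(seed, sprintf("gloss/%s/%d", obs_ids[o], b)))
      ch_c[[length(ch_c) + 1]] <- simulate_choices(
        params, trials, "coverage", observer = obs_ids[o],
        seed = substream_seed(seed, sprintf("cover/%s/%d", obs_ids[o], b)))
    }
  }
  structure(list(params = params, seed = seed, conditions = conditions,
                 matching = do.call(rbind, matching),
                 choices_gloss = do.call(rbind, ch_g),
                 choices_coverage = do.call(rbind, ch_c),
                 grids = grids),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic dataset: %d conditions, %d observers, ",
                     "%d matching trials, %d + %d choice trials (seed %d)\n"),
              nrow(x$conditions),
              length(unique(x$matching$observer)),
              nrow(x$matching), nrow(x$choices_gloss),
              nrow(x$choices_coverage), x$seed))
  invisible(x)
}
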