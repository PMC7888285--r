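# Stimulus design: condition enumeration, asymmetric-matching grids and
# paired-comparison trial lists.

# Default experiment levels. The matching experiment crosses five specular
# roughness levels with four relief heights; the paired-comparison
# experiments drop roughness 0.200 (no nonlinearity between 0.010 and 0.300)
# giving a 4 x 4 design.
#' Default stimulus levels
#'
#' Level sets for the matching experiment (`"matching"`: 4 relief x 5
#' roughness x 3 slants per hue) and the paired-comparison experiments
#' (`"paired"`: 4 relief x 4 roughness, roughness 0.200 dropped).
#'
#' @param design `"matching"` or `"paired"`.
#' @return Named list with `hues`, `reliefs`, `roughnesses`, `slants`.
#' @export
default_levels <- function(design = c("matching", "paired")) {
  design <- match.arg(design)
  list(
    hues = c(39.999, 136.016, 306.285),
    reliefs = c(0.025, 0.050, 0.100, 0.200),
    roughnesses = if (design == "matching")
      c(0.010, 0.100, 0.200, 0.300, 0.400)
    else c(0.010, 0.100, 0.300, 0.400),
    slants = c(15, 30, 45)
  )
}

#' Enumerate surface conditions
#'
#' Cartesian product of the level sets in deterministic lexicographic order
#' (hue slowest, then slant, relief, roughness fastest). A condition's
#' identity is the 4-tuple (hue, relief, roughness, slant).
#'
#' @param hues hue angles (degrees).
#' @param reliefs displacement scales (fraction of tile width).
#' @param roughnesses Beckmann roughness values.
#' @param slants surface slants (degrees from frontoparallel).
#' @return Data frame of class `surface_conditions` with columns
#'   `hue`, `relief`, `roughness`, `slant`.
#' @export
enumerate_conditions <- function(hues, reliefs, roughnesses, slants) {
  if (length(hues) == 0 || length(reliefs) == 0 ||
      length(roughnesses) == 0 || length(slants) == 0) {
    out <- data.frame(hue = numeric(0), relief = numeric(0),
                      roughness = numeric(0), slant = numeric(0))
  } else {
    out <- expand.grid(roughness = roughnesses, relief = reliefs,
                       slant = slants, hue = hues, KEEP.OUT.ATTRS = FALSE)
    out <- out[, c("hue", "slant", "relief", "roughness")]
    rownames(out) <- NULL
  }
  structure(out, class = c("surface_conditions", "data.frame"))
}

#' Build an asymmetric-matching grid
#'
#' Inclusive arithmetic sequences of lightness and chroma at one hue; the
#' observer's match is one cell of this grid. Indexing convention: rows are
#' chroma levels, columns are lightness levels, both ascending.
#'
#' Each cell is validated against the sRGB gamut. The default grid ranges
#' (L* 18.750-97.500, C* 22.500-101.250, step 3.75, 22 levels per axis)
#' extend well beyond the displayable boundary at all three stimulus hues,
#' so with `gamut = "error"` the default grid raises; use `"flag"` to keep
#' nominal LCH values and mark the offending cells, or `"clip"` to validate
#' against clipped colors.
#'
#' @param hue hue angle in degrees.
#' @param L_min,L_max,C_min,C_max inclusive axis ranges.
#' @param step common step size on both axes.
#' @param gamut `"error"` (default), `"flag"`, or `"clip"`.
#' @param white white-point convention passed to the colorimetry layer.
#' @return A list of class `matching_grid`: `hue`, `lightness_levels`,
#'   `chroma_levels`, `cells` (data frame i, j, L, C, H, in_gamut),
#'   `gamut_mode`, `white`.
#' @export
build_matching_grid <- function(hue,
                                L_min = 18.750, L_max = 97.500,
                                C_min = 22.500, C_max = 101.250,
                                step = 3.75,
                                gamut = c("error", "flag", "clip"),
                                white = "D65") {
  gamut <- match.arg(gamut)
  stopifnot(L_min <= L_max, C_min <= C_max, step > 0)
  for (rng in list(c(L_min, L_max), c(C_min, C_max))) {
    k <- (rng[2] - rng[1]) / step
    if (abs(k - round(k)) > 1e-8)
      stop("axis range is not divisible by step", call. = FALSE)
  }
  Ls <- seq(L_min, L_max, by = step)
  Cs <- seq(C_min, C_max, by = step)
  cells <- expand.grid(i = seq_along(Cs), j = seq_along(Ls),
                       KEEP.OUT.ATTRS = FALSE)
  cells$L <- Ls[cells$j]
  cells$C <- Cs[cells$i]
  cells$H <- hue
  cells$in_gamut <- in_gamut(cells$L, cells$C, cells$H, white = white)
  if (gamut == "error" && !all(cells$in_gamut)) {
    bad <- cells[!cells$in_gamut, ]
    stop(sprintf(
      "%d of %d matching-grid cells are out of the sRGB gamut at hue %.3f (first: L=%.3f, C=%.3f)",
      nrow(bad), nrow(cells), hue, bad$L[1], bad$C[1]), call. = FALSE)
  }
  structure(list(hue = hue, lightness_levels = Ls, chroma_levels = Cs,
                 cells = cells, gamut_mode = gamut, white = white),
            class = "matching_grid")
}

#' @export
print.matching_grid <- function(x, ...) {
  cat(sprintf("matching grid: hue %.3f, %d chroma x %d lightness levels, %d/%d cells in gamut (%s mode)\n",
              x$hue, length(x$chroma_levels), length(x$lightness_levels),
              sum(x$cells$in_gamut), nrow(x$cells), x$gamut_mode))
  invisible(x)
}

#' Build a paired-comparison trial list
#'
#' All ordered pairs of distinct conditions (n(n-1) trials for n conditions;
#' pair order encodes left/right screen position), shuffled reproducibly by
#' `seed`. All conditions must share hue and slant: comparisons are never
#' made across blocks.
#'
#' @param conditions a `surface_conditions` data frame (>= 2 rows, one block).
#' @param seed integer seed used for the shuffle (stored in the output).
#' @return Data frame of class `pc_trials` with columns `trial_id`,
#'   `first`, `second` (row indices into `conditions`) plus the condition
#'   fields suffixed `_1`/`_2`; attribute `seed`.
#' @export
build_pc_trials <- function(conditions, seed = 1L) {
  stopifnot(nrow(conditions) >= 2)
  if (length(unique(conditions$hue)) != 1 ||
      length(unique(conditions$slant)) != 1)
    stop("paired-comparison blocks must share hue and slant", call. = FALSE)
  if (anyDuplicated(conditions[, c("relief", "roughness")]))
    stop("duplicate conditions in block", call. = FALSE)
  n <- nrow(conditions)
  pairs <- expand.grid(second = seq_len(n), first = seq_len(n),
                       KEEP.OUT.ATTRS = FALSE)[, c("first", "second")]
  pairs <- pairs[pairs$first != pairs$second, ]
  ord <- with_seed(seed, sample.int(nrow(pairs)))
  pairs <- pairs[ord, ]
  out <- data.frame(trial_id = seq_len(nrow(pairs)),
                    first = pairs$first, second = pairs$second)
  for (f in c("hue", "relief", "roughness", "slant")) {
    out[[paste0(f, "_1")]] <- conditions[[f]][out$first]
    out[[paste0(f, "_2")]] <- conditions[[f]][out$second]
  }
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  class(out) <- c("pc_trials", "data.frame")
  out
}

#' Serialize conditions or trials to CSV
#'
#' @param x a `surface_conditions` or `pc_trials` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
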