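#' @keywords internal
"_PACKAGE"

# Reference whites (CIE 1931 2-degree observer), Y normalised to 1.
.whites <- list(
  D65 = c(X = 0.95047, Y = 1.00000, Z = 1.08883),
  D50 = c(X = 0.96422, Y = 1.00000, Z = 0.82521)
)

# sRGB linear RGB <-> XYZ (D65), derived from the IEC 61966-2-1 primary
# chromaticities so that RGB (1,1,1) maps exactly onto the D65 white (a
# rounded published matrix would leave grays slightly chromatic).
.M_rgb2xyz <- local({
  xy <- rbind(r = c(0.64, 0.33), g = c(0.30, 0.60), b = c(0.15, 0.06))
  P <- apply(xy, 1, function(p) c(p[1] / p[2], 1, (1 - p[1] - p[2]) / p[2]))
  P %*% diag(as.numeric(solve(P, .whites$D65)))
})
.M_xyz2rgb <- solve(.M_rgb2xyz)

# Bradford cone-response matrix, used when Lab is referred to D50 and must be
# adapted to the display's D65 white before entering the sRGB matrix.
.M_bradford <- matrix(c(
  0.8951,  0.2664, -0.1614,
 -0.7502,  1.7135,  0.0367,
  0.0389, -0.0685,  1.0296), 3, 3, byrow = TRUE)

.adapt_d50_d65 <- local({
  src <- .M_bradford %*% .whites$D50
  dst <- .M_bradford %*% .whites$D65
  solve(.M_bradford) %*% diag(as.numeric(dst / src)) %*% .M_bradford
})

.check_white <- function(white) {
  white <- toupper(white)
  if (!white %in% names(.whites))
    stop("unknown white point convention: ", white, call. = FALSE)
  white
}

#' Construct an LCH color
#'
#' A point in CIE LCH (the cylindrical form of CIE Lab): lightness L* in
#' \[0, 100\], chroma C* >= 0 and hue angle H* in degrees, wrapped to
#' \[0, 360). Zero chroma is achromatic; by convention its hue is stored as 0
#' and flagged.
#'
#' @param L lightness L* (0-100).
#' @param C chroma C*ab (>= 0).
#' @param H hue angle in degrees; any real value, wrapped to \[0, 360).
#' @return An object of class `lch_color`: a data frame with columns
#'   `L`, `C`, `H` and logical `achromatic`.
#' @export
lch <- function(L, C, H) {
  n <- max(length(L), length(C), length(H))
  L <- rep_len(as.numeric(L), n)
  C <- rep_len(as.numeric(C), n)
  H <- rep_len(as.numeric(H), n)
  if (any(!is.finite(L)) || any(!is.finite(C)) || any(!is.finite(H)))
    stop("LCH components must be finite", call. = FALSE)
  if (any(L < 0 | L > 100)) stop("L* must lie in [0, 100]", call. = FALSE)
  if (any(C < 0)) stop("C* must be non-negative", call. = FALSE)
  H <- H %% 360
  achrom <- C == 0
  H[achrom] <- 0
  structure(data.frame(L = L, C = C, H = H, achromatic = achrom),
            class = c("lch_color", "data.frame"))
}

#' Construct a companded sRGB color
#'
#' Display-referred sRGB channel values. In-gamut colors have all channels in
#' \[0, 1\]; out-of-range values are permitted in the container (they are how
#' gamut violations are reported) but conversions flag them explicitly.
#'
#' @param r,g,b channel values.
#' @return An object of class `srgb_color`: a data frame with columns
#'   `r`, `g`, `b`.
#' @export
srgb <- function(r, g, b) {
  n <- max(length(r), length(g), length(b))
  structure(data.frame(r = rep_len(as.numeric(r), n),
                       g = rep_len(as.numeric(g), n),
                       b = rep_len(as.numeric(b), n)),
            class = c("srgb_color", "data.frame"))
}

.srgb_compand <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * pmax(v, 0)^(1 / 2.4) - 0.055)
}

.srgb_uncompand <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

# CIE Lab forward/inverse companding of XYZ ratios
.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

.lch_to_linear_rgb <- function(x, white) {
  white <- .check_white(white)
  wp <- .whites[[white]]
  hr <- x$H * pi / 180
  a <- x$C * cos(hr)
  b <- x$C * sin(hr)
  fy <- (x$L + 16) / 116
  xyz <- rbind(X = wp[1] * .lab_finv(fy + a / 500),
               Y = wp[2] * .lab_finv(fy),
               Z = wp[3] * .lab_finv(fy - b / 200))
  if (white == "D50") xyz <- .adapt_d50_d65 %*% xyz
  .M_xyz2rgb %*% xyz
}

#' Convert LCH to companded sRGB
#'
#' Conversion chain LCH -> Lab -> XYZ -> linear RGB -> companded sRGB. The
#' Lab reference white is configurable: `"D65"` (the default, which matches
#' the display's native white and reproduces the stimulus triplets used for
#' rendering) or `"D50"` (Lab referred to D50 with Bradford adaptation to the
#' D65 display white). Conversions never clip silently: out-of-gamut inputs
#' either raise an error carrying the unclipped channel values (default) or,
#' with `clip = TRUE`, are clipped to \[0, 1\] with the clipping magnitude
#' recorded in attributes.
#'
#' @param x an `lch_color` (or anything accepted by [lch()] via a 3-column
#'   data frame / matrix with L, C, H).
#' @param white Lab reference white convention, `"D65"` or `"D50"`.
#' @param clip if `TRUE`, clip out-of-gamut channels to \[0, 1\] and record
#'   per-color clipping magnitude in `attr(, "clip_magnitude")`; if `FALSE`
#'   (default) raise a gamut error.
#' @param tol numeric slack on the \[0, 1\] in-gamut check.
#' @return An `srgb_color` with attributes `white` (the convention used) and,
#'   when `clip = TRUE`, `clip_magnitude` (largest channel excursion per
#'   color, 0 where in gamut).
#' @export
lch_to_srgb <- function(x, white = "D65", clip = FALSE, tol = 1e-9) {
  if (!inherits(x, "lch_color")) x <- lch(x[[1]], x[[2]], x[[3]])
  rgb_lin <- .lch_to_linear_rgb(x, white)
  rgb <- .srgb_compand(rgb_lin)
  # compand is monotone, but linear values can be negative where the companding
  # power is undefined; evaluate gamut on the linear values' sign plus the
  # companded magnitude
  rgb[rgb_lin < 0] <- 12.92 * rgb_lin[rgb_lin < 0]
  excess <- pmax(apply(rgb, 2, max) - 1, 0) + pmax(-apply(rgb, 2, min), 0)
  out_of_gamut <- excess > tol
  if (any(out_of_gamut) && !clip) {
    bad <- which(out_of_gamut)[1]
    stop(sprintf(paste0(
      "out-of-gamut LCH input at row %d (L=%.4g, C=%.4g, H=%.4g): ",
      "unclipped sRGB = (%.4f, %.4f, %.4f)"),
      bad, x$L[bad], x$C[bad], x$H[bad],
      rgb[1, bad], rgb[2, bad], rgb[3, bad]), call. = FALSE)
  }
  if (clip) rgb <- pmin(pmax(rgb, 0), 1)
  out <- srgb(rgb[1, ], rgb[2, ], rgb[3, ])
  attr(out, "white") <- .check_white(white)
  if (clip) attr(out, "clip_magnitude") <- unname(excess)
  out
}

#' Convert companded sRGB to LCH
#'
#' Exact functional inverse of [lch_to_srgb()] (up to floating tolerance)
#' under the same white-point convention.
#'
#' @param x an `srgb_color` (or 3-column object with r, g, b in \[0, 1\]).
#' @param white Lab reference white convention, `"D65"` or `"D50"`.
#' @return An `lch_color`.
#' @export
srgb_to_lch <- function(x, white = "D65") {
  white <- .check_white(white)
  if (!inherits(x, "srgb_color")) x <- srgb(x[[1]], x[[2]], x[[3]])
  xm <- as.matrix(x[, c("r", "g", "b")])
  if (min(xm) < -1e-9 || max(xm) > 1 + 1e-9)
    stop("sRGB channels must lie in [0, 1]", call. = FALSE)
  rgb_lin <- rbind(.srgb_uncompand(x$r), .srgb_uncompand(x$g),
                   .srgb_uncompand(x$b))
  xyz <- .M_rgb2xyz %*% rgb_lin
  if (white == "D50") xyz <- solve(.adapt_d50_d65) %*% xyz
  wp <- .whites[[white]]
  fx <- .lab_f(xyz[1, ] / wp[1])
  fy <- .lab_f(xyz[2, ] / wp[2])
  fz <- .lab_f(xyz[3, ] / wp[3])
  L <- pmin(pmax(116 * fy - 16, 0), 100)
  a <- 500 * (fx - fy)
  b <- 200 * (fy - fz)
  C <- sqrt(a^2 + b^2)
  H <- (atan2(b, a) * 180 / pi) %% 360
  # numerically achromatic inputs: collapse chroma noise below ~1e-10
  C[C < 1e-10] <- 0
  lch(L, C, H)
}

#' Test whether LCH coordinates are inside the sRGB gamut
#'
#' @param L,C,H LCH coordinates (vectorised).
#' @inheritParams lch_to_srgb
#' @return Logical vector.
#' @export
in_gamut <- function(L, C, H, white = "D65", tol = 1e-9) {
  rgb_lin <- .lch_to_linear_rgb(lch(L, C, H), white)
  rgb <- .srgb_compand(pmax(rgb_lin, 0))
  rgb[rgb_lin < 0] <- 12.92 * rgb_lin[rgb_lin < 0]
  apply(rgb >= -tol & rgb <= 1 + tol, 2, all)
}

#' Maximum displayable chroma at a given lightness and hue
#'
#' The largest C* (to within `step`) such that (L*, C*, H*) maps inside the
#' sRGB gamut. For fixed L* and H* the in-gamut chroma range is the interval
#' \[0, Cmax\], so the boundary is located by bisection between an in-gamut
#' lower bound and an out-of-gamut upper bound, refined until the bracket is
#' narrower than `step`.
#'
#' @param L lightness L* (scalar, 0-100).
#' @param H hue angle in degrees (scalar).
#' @param step chroma resolution of the answer (default 0.25).
#' @param C_max upper search limit (default 200, beyond any sRGB chroma).
#' @inheritParams lch_to_srgb
#' @return The boundary chroma (>= 0); 0 when even `C = step` is out of gamut.
#' @export
max_chroma <- function(L, H, step = 0.25, C_max = 200, white = "D65") {
  stopifnot(length(L) == 1, length(H) == 1, step > 0)
  if (L <= 0 || L >= 100) return(0)
  if (!in_gamut(L, step, H, white = white)) return(0)
  lo <- step
  hi <- C_max
  if (in_gamut(L, hi, H, white = white)) return(hi)
  while (hi - lo > step / 2) {
    mid <- (lo + hi) / 2
    if (in_gamut(L, mid, H, white = white)) lo <- mid else hi <- mid
  }
  lo
}

#' Chroma and saturation gamut boundary for one hue
#'
#' For each integer lightness level L* = 0..100, the maximum displayable
#' chroma at hue `H` and the corresponding maximum saturation C*/L*
#' (`NA` at L* = 0, where saturation is undefined).
#'
#' @param H hue angle in degrees.
#' @inheritParams max_chroma
#' @return A data frame of class `gamut_boundary` with columns
#'   `hue`, `L`, `maxC`, `maxS` (101 rows).
#' @export
gamut_boundary <- function(H, step = 0.25, white = "D65") {
  L <- 0:100
  maxC <- vapply(L, function(l) max_chroma(l, H, step = step, white = white),
                 numeric(1))
  maxS <- ifelse(L > 0, maxC / L, NA_real_)
  structure(data.frame(hue = H, L = L, maxC = maxC, maxS = maxS),
            class = c("gamut_boundary", "data.frame"))
}

#' Write a gamut boundary table to CSV
#'
#' Header `hue,L,maxC,maxS`, one row per lightness level.
#'
#' @param x a `gamut_boundary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gamut_boundary <- function(x, path) {
  stopifnot(inherits(x, "gamut_boundary"))
  utils::write.csv(as.data.frame(x)[, c("hue", "L", "maxC", "maxS")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Saturation as the chroma-to-lightness ratio
#'
#' Saturation is colorfulness judged relative to brightness; in LCH it is
#' computed as C*/L*. Undefined (NA) at L* = 0.
#'
#' @param C chroma C* (vectorised).
#' @param L lightness L* (vectorised).
#' @return `C / L`, with `NA` where `L == 0`.
#' @export
saturation <- function(C, L) {
  out <- ifelse(L > 0, C / L, NA_real_)
  if (any(L == 0)) warning("saturation undefined at L* = 0; returning NA")
  out
}
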