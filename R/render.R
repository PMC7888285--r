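# Simplified direct-illumination renderer: displacement-mapped value-noise
# height fields shaded with a Lambertian diffuse term plus a Beckmann
# microfacet specular lobe under an overhead rectangular emitter.
#
# Scene convention (world units = meters, tile width 0.1 m): the tile starts
# in the x-y plane with mean normal +z pointing at the camera (orthographic,
# view direction v = (0, 0, 1)); slanting by theta rotates the tile about the
# horizontal x-axis so the mean normal tilts toward the overhead emitter
# (+y). At theta = 45 degrees the mean normal bisects the viewing and
# lighting directions.

#' Generate a displacement-mapped height field
#'
#' Smooth value noise (random lattice values, smoothstep-interpolated, with
#' optional octaves), averaged by `smoothing_passes` passes of 3x3
#' neighborhood smoothing, min-max normalized to \[0, 1\] and scaled by
#' `relief`. After normalization the peak-to-peak amplitude equals `relief`
#' exactly (heights are in tile-width units, so relief 0.200 means
#' undulations spanning 20% of the tile width).
#'
#' @param n grid resolution per side (>= 8).
#' @param relief displacement scale, fraction of tile width (>= 0).
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   fields.
#' @param smoothing_passes number of 3x3 averaging passes (default 2).
#' @param frequency lattice cells per side (default 8, giving roughly 6-10
#'   undulations across the tile).
#' @param octaves number of noise octaves (default 1); successive octaves
#'   double the frequency at half the amplitude.
#' @return Object of class `height_field`: list with `n`, `z` (n x n matrix),
#'   `relief`, `seed`.
#' @export
generate_height_field <- function(n, relief, seed = 1L, smoothing_passes = 2,
                                  frequency = 8, octaves = 1) {
  stopifnot(n >= 8, relief >= 0, frequency >= 1, octaves >= 1)
  z <- matrix(0, n, n)
  if (relief > 0) {
    z <- with_seed(seed, {
      acc <- matrix(0, n, n)
      amp <- 1
      freq <- frequency
      for (o in seq_len(octaves)) {
        acc <- acc + amp * .value_noise(n, freq)
        amp <- amp / 2
        freq <- freq * 2
      }
      acc
    })
    for (k in seq_len(smoothing_passes)) z <- .smooth3x3(z)
    rng <- range(z)
    if (diff(rng) > 0) z <- (z - rng[1]) / diff(rng) else z[] <- 0
    z <- z * relief
  }
  structure(list(n = n, z = z, relief = relief, seed = seed),
            class = "height_field")
}

# Smoothstep-interpolated lattice noise on an n x n grid, values in [0, 1].
.value_noise <- function(n, freq) {
  lat <- matrix(stats::runif((freq + 1)^2), freq + 1, freq + 1)
  u <- (seq_len(n) - 1) / (n - 1) * freq        # lattice coordinates [0, freq]
  i0 <- pmin(floor(u), freq - 1)
  t <- u - i0
  s <- t * t * (3 - 2 * t)                       # smoothstep weight
  i0 <- i0 + 1                                   # 1-based lattice index
  # bilinear blend: rows = x, cols = y
  a <- lat[i0, i0, drop = FALSE]
  b <- lat[i0 + 1, i0, drop = FALSE]
  cc <- lat[i0, i0 + 1, drop = FALSE]
  d <- lat[i0 + 1, i0 + 1, drop = FALSE]
  sx <- matrix(s, n, n)
  sy <- matrix(s, n, n, byrow = TRUE)
  (a * (1 - sx) + b * sx) * (1 - sy) + (cc * (1 - sx) + d * sx) * sy
}

# One pass of 3x3 neighborhood averaging with clamped (replicated) borders.
.smooth3x3 <- function(z) {
  n <- nrow(z)
  idx <- function(k) pmin(pmax(k, 1), n)
  acc <- matrix(0, n, n)
  for (di in -1:1) for (dj in -1:1)
    acc <- acc + z[idx(seq_len(n) + di), idx(seq_len(n) + dj)]
  acc / 9
}

#' Beckmann microfacet normal distribution function
#'
#' D(theta_m) = exp(-tan^2(theta_m) / alpha^2) / (pi alpha^2 cos^4 theta_m),
#' the density of microfacet normals at angle theta_m from the mean surface
#' normal. Satisfies the projected-solid-angle normalization
#' integral of D cos(theta) d(omega) = 1 over the hemisphere. Returns 0 in
#' the grazing limit theta_m -> pi/2.
#'
#' @param theta_m facet angle in radians, in \[0, pi/2\] (vectorised).
#' @param alpha roughness (> 0); larger alpha spreads the lobe.
#' @return Density values (per steradian).
#' @export
beckmann_ndf <- function(theta_m, alpha) {
  stopifnot(alpha > 0)
  ct <- cos(theta_m)
  out <- numeric(length(theta_m))
  ok <- ct > 1e-12
  tt <- tan(theta_m[ok])
  out[ok] <- exp(-tt^2 / alpha^2) / (pi * alpha^2 * ct[ok]^4)
  out
}

#' Renderer configuration
#'
#' @param specular_amplitude scalar specular gain (default 0.2, the value
#'   used to give common glossy materials a realistic appearance).
#' @param roughness Beckmann roughness alpha (> 0).
#' @param slant surface slant theta in degrees from frontoparallel.
#' @param diffuse_rgb companded sRGB triplet of the base color (uncompanded
#'   internally to linear albedo).
#' @param light_center emitter center, meters, in world coordinates (y up
#'   toward the emitter, z toward the camera).
#' @param light_extent emitter half-plane extents (x and z), meters; the
#'   default 2.5 m x 1.0 m rectangle sits 1.2 m above the tile.
#' @param light_samples number of emitter samples (stratified grid; >= 1).
#' @param tile_width tile width in meters (default 0.1).
#' @return List of class `render_config`.
#' @export
render_config <- function(specular_amplitude = 0.2, roughness = 0.1,
                          slant = 30, diffuse_rgb = c(0.91, 0.42, 0.31),
                          light_center = c(0, 1.2, 0),
                          light_extent = c(2.5, 1.0),
                          light_samples = 32, tile_width = 0.1) {
  stopifnot(specular_amplitude >= 0, roughness > 0, light_samples >= 1,
            length(diffuse_rgb) == 3, all(diffuse_rgb >= 0 & diffuse_rgb <= 1))
  structure(list(specular_amplitude = specular_amplitude,
                 roughness = roughness, slant = slant,
                 diffuse_rgb = diffuse_rgb, light_center = light_center,
                 light_extent = light_extent,
                 light_samples = as.integer(light_samples),
                 tile_width = tile_width),
            class = "render_config")
}

#' Shade a height field
#'
#' Per-pixel direct illumination from the sampled rectangular emitter, with
#' each emitter sample carrying the area-light measure (emitter cosine over
#' squared distance times patch area). The diffuse component is Lambertian,
#' `albedo * sum(w_k (n . l)+)`; the specular component is the Beckmann NDF
#' evaluated at the half-vector angle with cosine foreshortening,
#' `amplitude * sum(w_k D(theta_h) (n . l)+)`. Fresnel and shadow-masking
#' terms are omitted: the stimulus model uses a scalar specular amplitude
#' rather than a physical index of refraction. Components are stored
#' separately and the composite is their exact per-pixel sum (linear
#' radiometric units, pre-companding).
#'
#' @param hf a `height_field`.
#' @param cfg a `render_config`.
#' @return Object of class `rendered_stimulus`: `diffuse` (n x n x 3 array),
#'   `specular` (n x n matrix, achromatic), `composite` (n x n x 3), `config`.
#' @export
shade_surface <- function(hf, cfg) {
  stopifnot(inherits(hf, "height_field"), inherits(cfg, "render_config"))
  n <- hf$n
  w <- cfg$tile_width
  # texel positions and normals in tile coordinates (pre-slant)
  u <- ((seq_len(n) - 1) / (n - 1) - 0.5)          # [-0.5, 0.5] tile units
  px <- matrix(u, n, n) * w
  py <- matrix(u, n, n, byrow = TRUE) * w
  h <- hf$z * w
  step <- w / (n - 1)
  gx <- .central_diff(hf$z * w, 1) / step
  gy <- .central_diff(hf$z * w, 2) / step
  if (any(!is.finite(gx)) || any(!is.finite(gy))) {
    bad <- which(!is.finite(gx) | !is.finite(gy), arr.ind = TRUE)[1, ]
    stop(sprintf("degenerate normal at pixel (%d, %d)", bad[1], bad[2]),
         call. = FALSE)
  }
  # unnormalised normal (-gx, -gy, 1), then rotate by -theta about x so the
  # mean normal tilts toward the overhead light
  th <- cfg$slant * pi / 180
  nx0 <- -gx; ny0 <- -gy; nz0 <- matrix(1, n, n)
  nx <- nx0
  ny <- ny0 * cos(th) + nz0 * sin(th)
  nz <- -ny0 * sin(th) + nz0 * cos(th)
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  nx <- nx / nrm; ny <- ny / nrm; nz <- nz / nrm
  # rotated pixel positions
  qx <- px
  qy <- py * cos(th) + h * sin(th)
  qz <- -py * sin(th) + h * cos(th)
  # stratified emitter samples
  ns <- cfg$light_samples
  k1 <- max(1L, as.integer(round(sqrt(ns * cfg$light_extent[1] /
                                        cfg$light_extent[2]))))
  k2 <- max(1L, as.integer(ceiling(ns / k1)))
  sx <- (seq_len(k1) - 0.5) / k1 - 0.5
  sz <- (seq_len(k2) - 0.5) / k2 - 0.5
  samples <- expand.grid(sx = sx * cfg$light_extent[1],
                         sz = sz * cfg$light_extent[2])
  vx <- 0; vy <- 0; vz <- 1                         # orthographic view dir
  diffuse_acc <- matrix(0, n, n)
  spec_acc <- matrix(0, n, n)
  alpha <- cfg$roughness
  area <- prod(cfg$light_extent)
  for (k in seq_len(nrow(samples))) {
    lx <- cfg$light_center[1] + samples$sx[k] - qx
    ly <- cfg$light_center[2] - qy
    lz <- cfg$light_center[3] + samples$sz[k] - qz
    ln <- sqrt(lx^2 + ly^2 + lz^2)
    lx <- lx / ln; ly <- ly / ln; lz <- lz / ln
    # area-light measure: emitter cosine (emitter faces straight down)
    # over squared distance, times the per-sample patch area
    wk <- pmax(ly, 0) / ln^2 * (area / nrow(samples))
    ndotl <- pmax(nx * lx + ny * ly + nz * lz, 0)
    diffuse_acc <- diffuse_acc + wk * ndotl
    hx <- lx + vx; hy <- ly + vy; hz <- lz + vz
    hn <- sqrt(hx^2 + hy^2 + hz^2)
    ndoth <- pmin(pmax((nx * hx + ny * hy + nz * hz) / hn, -1), 1)
    theta_h <- acos(ndoth)
    D <- matrix(beckmann_ndf(pmin(theta_h, pi / 2), alpha), n, n)
    spec_acc <- spec_acc + wk * D * ndotl
  }
  albedo <- .srgb_uncompand(cfg$diffuse_rgb)
  diffuse <- array(0, c(n, n, 3))
  for (c in 1:3) diffuse[, , c] <- albedo[c] * diffuse_acc
  specular <- cfg$specular_amplitude * spec_acc
  composite <- diffuse
  for (c in 1:3) composite[, , c] <- composite[, , c] + specular
  structure(list(diffuse = diffuse, specular = specular,
                 composite = composite, config = cfg,
                 height_field = list(relief = hf$relief, seed = hf$seed,
                                     n = hf$n)),
            class = "rendered_stimulus")
}

# central differences with one-sided borders, along margin 1 (rows = x) or 2
.central_diff <- function(z, margin) {
  n <- dim(z)[margin]
  ip <- pmin(seq_len(n) + 1, n)
  im <- pmax(seq_len(n) - 1, 1)
  den <- (ip - im)
  if (margin == 1) (z[ip, ] - z[im, ]) / den else
    t((t(z[, ip]) - t(z[, im])) / den)
}

#' Physical specular coverage
#'
#' Fraction of tile pixels whose specular component exceeds
#' `frac_threshold` times the image's maximum specular value — an objective
#' counterpart to judgments of the surface area covered by specular
#' highlights. By convention an identically-zero specular image has
#' coverage 0.
#'
#' @param stim a `rendered_stimulus`.
#' @param frac_threshold fraction of the specular maximum, in (0, 1\]
#'   (default 0.1).
#' @return Coverage fraction in \[0, 1\].
#' @export
physical_specular_coverage <- function(stim, frac_threshold = 0.1) {
  stopifnot(inherits(stim, "rendered_stimulus"),
            frac_threshold > 0, frac_threshold <= 1)
  m <- max(stim$specular)
  if (m <= 0) return(0)
  mean(stim$specular >= frac_threshold * m)
}

#' Coverage sweep over a condition set
#'
#' Renders each (relief, roughness, slant) condition at one hue and returns
#' the physical specular coverage per condition.
#'
#' @param conditions a `surface_conditions` data frame.
#' @param n render resolution (default 64).
#' @param seed height-field seed (one field per relief level, shared across
#'   roughness so coverage differences reflect material, not geometry).
#' @param frac_threshold coverage threshold (default 0.1).
#' @param ... further arguments to [render_config()].
#' @return The conditions data frame with a `coverage` column.
#' @export
coverage_sweep <- function(conditions, n = 64, seed = 1L,
                           frac_threshold = 0.1, ...) {
  hfs <- list()
  cov <- numeric(nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    key <- sprintf("%.6f", conditions$relief[i])
    if (is.null(hfs[[key]]))
      hfs[[key]] <- generate_height_field(n, conditions$relief[i], seed = seed)
    cfg <- render_config(roughness = conditions$roughness[i],
                         slant = conditions$slant[i], ...)
    cov[i] <- physical_specular_coverage(shade_surface(hfs[[key]], cfg),
                                         frac_threshold = frac_threshold)
  }
  out <- as.data.frame(conditions)
  out$coverage <- cov
  out
}
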