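test_that("height fields have exact peak-to-peak amplitude after normalization", {
  for (relief in c(0.025, 0.2)) {
    hf <- generate_height_field(64, relief, seed = 3)
    expect_equal(diff(range(hf$z)), relief, tolerance = 1e-12)
  }
  flat <- generate_height_field(32, 0, seed = 3)
  expect_true(all(flat$z == 0))
})

test_that("height fields are deterministic in seed and parameters", {
  a <- generate_height_field(48, 0.1, seed = 12)
  b <- generate_height_field(48, 0.1, seed = 12)
  expect_identical(a, b)
  c_ <- generate_height_field(48, 0.1, seed = 13)
  expect_false(identical(a$z, c_$z))
})

test_that("more smoothing passes reduce the mean gradient magnitude", {
  grad_mag <- function(hf) {
    gx <- diff(hf$z); gy <- t(diff(t(hf$z)))
    mean(abs(gx)) + mean(abs(gy))
  }
  g <- vapply(c(0, 2, 6), function(p)
    grad_mag(generate_height_field(64, 0.1, seed = 4, smoothing_passes = p)),
    numeric(1))
  expect_true(all(diff(g) <= 0))
})

test_that("Beckmann NDF has the closed form at normal incidence and integrates to one", {
  for (alpha in c(0.01, 0.1, 0.4)) {
    expect_equal(beckmann_ndf(0, alpha), 1 / (pi * alpha^2), tolerance = 1e-12)
    # projected-solid-angle normalization by quadrature
    integrand <- function(t) beckmann_ndf(t, alpha) * cos(t) * sin(t)
    val <- 2 * pi * stats::integrate(integrand, 0, pi / 2,
                                     rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 0.01)
  }
  expect_equal(beckmann_ndf(pi / 2, 0.1), 0)
})

test_that("off-normal NDF density rises then falls as roughness grows", {
  alphas <- seq(0.02, 1, by = 0.02)
  d <- vapply(alphas, function(a) beckmann_ndf(0.3, a), numeric(1))
  peak <- which.max(d)
  expect_gt(peak, 1)
  expect_lt(peak, length(alphas))
  expect_true(all(diff(d[1:peak]) > 0))
  expect_true(all(diff(d[peak:length(d)]) < 0))
})

test_that("components are non-negative and the composite is their exact sum", {
  hf <- generate_height_field(32, 0.1, seed = 5)
  stim <- shade_surface(hf, render_config(roughness = 0.2, slant = 30,
                                          light_samples = 8))
  expect_true(all(stim$diffuse >= 0))
  expect_true(all(stim$specular >= 0))
  for (ch in 1:3)
    expect_equal(stim$composite[, , ch],
                 stim$diffuse[, , ch] + stim$specular, tolerance = 0)
})

test_that("zero specular amplitude gives a purely diffuse image", {
  hf <- generate_height_field(32, 0.05, seed = 5)
  stim <- shade_surface(hf, render_config(specular_amplitude = 0,
                                          roughness = 0.1, light_samples = 4))
  expect_true(all(stim$specular == 0))
  expect_equal(stim$composite, stim$diffuse)
  expect_equal(physical_specular_coverage(stim), 0)
})

test_that("flat-plane highlight sits where the normal bisects view and light", {
  hf <- generate_height_field(64, 0, seed = 1)
  cfg <- render_config(roughness = 0.01, slant = 45,
                       light_extent = c(0.02, 0.02), light_samples = 1)
  stim <- shade_surface(hf, cfg)
  # oracle: per-pixel half-vector angle computed independently for the
  # rotated plane illuminated by the emitter center
  n <- hf$n; w <- cfg$tile_width; th <- 45 * pi / 180
  u <- ((seq_len(n) - 1) / (n - 1) - 0.5) * w
  qx <- matrix(u, n, n); py <- matrix(u, n, n, byrow = TRUE)
  qy <- py * cos(th); qz <- -py * sin(th)
  lx <- -qx; ly <- cfg$light_center[2] - qy; lz <- -qz
  ln <- sqrt(lx^2 + ly^2 + lz^2)
  hx <- lx / ln; hy <- ly / ln; hz <- lz / ln + 1
  hn <- sqrt(hx^2 + hy^2 + hz^2)
  cosang <- (hy * sin(th) + hz * cos(th)) / hn
  got <- arrayInd(which.max(stim$specular), c(n, n))
  want <- arrayInd(which.max(cosang), c(n, n))
  expect_lte(max(abs(got - want)), 1)
})

test_that("rougher lobes have lower specular maxima at fixed geometry", {
  hf <- generate_height_field(48, 0.1, seed = 6)
  maxima <- vapply(c(0.05, 0.1, 0.2, 0.4), function(a)
    max(shade_surface(hf, render_config(roughness = a, slant = 30,
                                        light_samples = 8))$specular),
    numeric(1))
  expect_true(all(diff(maxima) < 0))
})

test_that("coverage statistic counts pixels relative to the specular maximum", {
  fake <- structure(list(specular = matrix(c(1, 0.5, 0.05, 0), 2, 2)),
                    class = "rendered_stimulus")
  expect_equal(physical_specular_coverage(fake, 0.1), 0.5)
  const <- structure(list(specular = matrix(0.3, 4, 4)),
                     class = "rendered_stimulus")
  expect_equal(physical_specular_coverage(const, 1), 1.0)
  none <- structure(list(specular = matrix(0, 4, 4)),
                    class = "rendered_stimulus")
  expect_equal(physical_specular_coverage(none, 0.1), 0)
})

test_that("coverage grows with relief for crisp highlights at 15 deg and shrinks at 45 deg", {
  conds <- enumerate_conditions(39.999, c(0.025, 0.2), c(0.01, 0.1, 0.3, 0.4),
                                c(15, 45))
  cov <- coverage_sweep(conds, n = 64, seed = 2)
  # frontal view, sharp-to-moderate roughness: a flatter tile offers almost
  # no facets that bisect view and light, so relief adds highlight area
  for (a in c(0.01, 0.1)) {
    lo <- cov$coverage[cov$slant == 15 & cov$relief == 0.025 &
                         cov$roughness == a]
    hi <- cov$coverage[cov$slant == 15 & cov$relief == 0.2 &
                         cov$roughness == a]
    expect_gt(hi, lo)
  }
  # oblique view: the flat tile mirrors the emitter everywhere, relief
  # disperses it — holds at every roughness
  m45 <- aggregate(coverage ~ relief, cov[cov$slant == 45, ], mean)
  expect_gt(m45$coverage[m45$relief == 0.025], m45$coverage[m45$relief == 0.2])
})

test_that("renders are deterministic given seed and config", {
  hf <- generate_height_field(32, 0.1, seed = 7)
  cfg <- render_config(roughness = 0.3, slant = 15, light_samples = 4)
  expect_identical(shade_surface(hf, cfg), shade_surface(hf, cfg))
})
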