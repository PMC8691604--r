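# Iso-surface extraction, field projection, sensitivity-curve mapping.

sphere_grid <- function(radius = 10, seed = 1)
  gen_folded_cortex(cortical_shell_spec(radius = radius, fold_amplitude = 0,
                                        seed = seed))

uniform_field_grid <- function(g, ez = 1) {
  d <- g$dim
  g$ef <- list(array(0, d), array(0, d), array(ez, d))
  g
}

test_that("iso-surface of a voxelised sphere has the analytic area", {
  g <- sphere_grid()
  surf <- extract_surface(g)
  expect_gt(nrow(surf$vertices), 1000)
  area <- surface_mesh_area(surf)
  expect_lt(abs(area - 4 * pi * 100) / (4 * pi * 100), 0.05)
  # normals point outward (positive radial component) everywhere
  radial <- surf$vertices / sqrt(rowSums(surf$vertices^2))
  expect_gt(min(rowSums(radial * surf$normals)), 0)
  # isovalue outside the data range errors
  expect_error(extract_surface(g, isovalue = 2), "outside the data range")
})

test_that("nuclei-adjacent vertices are removed from the surface", {
  g <- sphere_grid()
  # craft a second crossing inside the nuclei: carve a hole in the core
  ctr <- (g$dim + 1) / 2
  idx <- as.matrix(expand.grid(i = -2:2, j = -2:2, k = -2:2))
  hole <- sweep(idx, 2, ctr, "+")
  g2 <- g
  g2$field[hole] <- 0
  s_keep <- extract_surface(g2, drop_nuclei = FALSE)
  s_drop <- extract_surface(g2, drop_nuclei = TRUE)
  expect_lt(nrow(s_drop$vertices), nrow(s_keep$vertices))
  # remaining vertices all sit on the outer (cortex) surface
  r <- sqrt(rowSums(s_drop$vertices^2))
  expect_gt(min(r), 5)
})

test_that("field projection follows the sign convention", {
  g <- uniform_field_grid(sphere_grid())
  surf <- extract_surface(g)
  proj <- project_field(surf, g)
  # at the north pole the normal is +z, the axis -z; field +z points toward
  # the dendrites there: theta = 180, E_proj = +|E| (cathodal)
  top <- which.max(surf$vertices[, 3])
  expect_gt(proj$theta[top], 175)
  expect_equal(proj$e_proj[top], 1, tolerance = 0.05)
  # at the south pole the field points toward the axonal terminal: anodal
  bot <- which.min(surf$vertices[, 3])
  expect_lt(proj$theta[bot], 5)
  expect_equal(proj$e_proj[bot], -1, tolerance = 0.05)
  # on the equator the field is perpendicular: E_proj ~ 0
  eq <- which(abs(surf$vertices[, 3]) < 0.2)
  expect_lt(max(abs(proj$e_proj[eq])), 0.1)
  # consistency: |E_proj| = |E| |cos theta|
  expect_equal(abs(proj$e_proj),
               proj$intensity * abs(cos(proj$theta * pi / 180)),
               tolerance = 1e-6)
})

test_that("a uniform field over a sphere splits anodal/cathodal 50/50 and has the sin-theta law", {
  g <- uniform_field_grid(sphere_grid())
  surf <- extract_surface(g)
  expect_gt(nrow(surf$vertices), 1e4)
  proj <- project_field(surf, g)
  an <- mean(proj$e_proj < 0)
  expect_lt(abs(an - 0.5), 0.02)
  # theta distribution matches the analytic sin density
  th <- proj$theta[!is.na(proj$theta)] * pi / 180
  ks <- suppressWarnings(stats::ks.test(th, function(q) (1 - cos(q)) / 2))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("zero field vectors yield an undefined angle and zero projection", {
  g <- uniform_field_grid(sphere_grid(), ez = 0)
  surf <- extract_surface(g)
  proj <- project_field(surf, g)
  expect_true(all(is.na(proj$theta)))
  expect_true(all(proj$e_proj == 0))
})

test_that("metric mapping interpolates piecewise-linearly with clamping", {
  cv <- sensitivity_curve(seq(-1.5, 1.5, by = 0.25),
                          seq(-1.5, 1.5, by = 0.25) * 10 + 30, "demo")
  pr <- data.frame(e_proj = c(0, 0.25, 0.125, 2.5, -2.5),
                   theta = rep(90, 5), intensity = abs(c(0, .25, .125, 2.5, 2.5)))
  mp <- map_metric(pr, cv)
  expect_equal(mp$value[1], 30)                      # baseline at E = 0
  expect_equal(mp$pct_change[1], 0)
  expect_equal(mp$value[2], 32.5)                    # exact grid point
  expect_equal(mp$value[3], mean(c(30, 32.5)))       # midpoint = mean
  expect_equal(mp$value[4], 45)                      # clamped above
  expect_equal(mp$value[5], 15)                      # clamped below
  # all-zero projections reproduce the baseline with 0 % change
  pr0 <- data.frame(e_proj = rep(0, 4), theta = 90, intensity = 0)
  mp0 <- map_metric(pr0, cv)
  expect_true(all(mp0$value == 30 & mp0$pct_change == 0))
})

test_that("mapping flags vertices next to undefined curve points", {
  vals <- seq(-1.5, 1.5, by = 0.25) * 10 + 30
  vals[3] <- NA  # undefined at E = -1
  cv <- sensitivity_curve(seq(-1.5, 1.5, by = 0.25), vals, "demo")
  pr <- data.frame(e_proj = c(-1.1, 0.5), theta = 90, intensity = c(1.1, .5))
  mp <- map_metric(pr, cv)
  expect_true(is.na(mp$value[1]))
  expect_false(is.na(mp$value[2]))
})

test_that("mapping preserves monotonicity of a monotone curve", {
  cv <- sensitivity_curve(seq(-1.5, 1.5, length.out = 13),
                          cumsum(runif(13, 0.1, 1)) + 20, "mono")
  x <- sort(runif(500, -1.6, 1.6))
  mp <- map_metric(data.frame(e_proj = x, theta = 90, intensity = abs(x)), cv)
  expect_true(all(diff(mp$value) >= -1e-12))
})

test_that("map summaries have coherent fractions and histograms", {
  g <- uniform_field_grid(sphere_grid())
  surf <- extract_surface(g)
  proj <- project_field(surf, g)
  cv <- sensitivity_curve(seq(-1.5, 1.5, length.out = 13),
                          seq(25, 35, length.out = 13), "rate")
  mp <- map_metric(proj, cv)
  sm <- summarize_map(mp)
  expect_equal(sm$anodal_fraction + sm$cathodal_fraction + sm$zero_fraction, 1)
  expect_equal(sum(sm$theta_hist$count), sum(!is.na(mp$theta)))
  # |E| = 1 V/m everywhere: nothing beyond +-1.5
  expect_equal(sm$intensity_fractions$anodal_beyond[2], 0)
  expect_equal(sm$intensity_fractions$cathodal_beyond[2], 0)
  # thresholds above max projection give zero fractions
  sm2 <- summarize_map(mp, thresholds = c(5))
  expect_equal(sm2$intensity_fractions$anodal_beyond, 0)
  # change fractions are monotone in the threshold
  expect_true(all(diff(sm$change_fractions) <= 0))
})

test_that("summaries are invariant under rigid rotation of geometry plus field", {
  g <- sphere_grid()
  # rotating a sphere plus a uniform field by 90 degrees about y maps
  # +z fields onto +x; the summary statistics must agree
  gz <- uniform_field_grid(g, 1)
  gx <- g
  d <- g$dim
  gx$ef <- list(array(1, d), array(0, d), array(0, d))
  sz <- summarize_map(map_metric(project_field(extract_surface(gz), gz),
                                 sensitivity_curve(seq(-1.5, 1.5, 0.5),
                                                   seq(0, 60, 10), "m")))
  sx <- summarize_map(map_metric(project_field(extract_surface(gx), gx),
                                 sensitivity_curve(seq(-1.5, 1.5, 0.5),
                                                   seq(0, 60, 10), "m")))
  expect_lt(abs(sz$anodal_fraction - sx$anodal_fraction), 0.02)
  expect_lt(max(abs(sz$theta_hist$density - sx$theta_hist$density)), 0.02)
})

test_that("surfaces export as valid OBJ", {
  g <- sphere_grid(radius = 5)
  surf <- extract_surface(g)
  f <- file.path(tempdir(), "surf.obj")
  write_surface_obj(surf, f)
  ln <- readLines(f)
  expect_equal(sum(startsWith(ln, "v ")), nrow(surf$vertices))
  expect_equal(sum(startsWith(ln, "f ")), nrow(surf$faces))
})
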