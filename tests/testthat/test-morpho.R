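test_that("point grids have exactly n points and deterministic offsets", {
  mask <- matrix(1L, 300, 300)
  g <- overlay_grid(mask, 82, seed = 1)
  expect_equal(g$n_points, 82)
  expect_length(g$labels, 82)
  expect_true(all(g$labels == 1L))
  g2 <- overlay_grid(mask, 82, seed = 1)
  expect_identical(g$x, g2$x)
  expect_error(overlay_grid(matrix(0L, 3, 3), 82), "more test points")
})

test_that("point counts on a half-and-half field are binomial around 50 %", {
  mask <- cbind(matrix(1L, 400, 200), matrix(0L, 400, 200))
  hits <- vapply(1:40, function(s)
    sum(overlay_grid(mask, 200, seed = s)$labels == 1L), numeric(1))
  expect_true(abs(mean(hits) - 100) < 5)      # binomial(200, .5), SE ~ 1.1
  expect_true(all(hits > 70 & hits < 130))
})

test_that("volume density is 100 * PP / PT", {
  expect_equal(volume_density(41, total = 82), 50)
  expect_equal(volume_density(0, total = 82), 0)
  mask <- matrix(c(1L, 0L), 100, 100)
  g <- overlay_grid(mask, 140, seed = 2)
  expect_equal(volume_density(g, 1),
               100 * sum(g$labels == 1) / 140)
  expect_error(volume_density(10, total = 0), "> 0")
})

test_that("Vv point counting is unbiased with binomial sampling error", {
  res <- vapply(1:30, function(s) {
    f <- sim_tissue_field(600, 600, fractions = c(cf = 13.7), seed = s)
    c(volume_density(overlay_grid(f, 140, seed = 1000 + s), 1),
      attr(f, "truth")$achieved_fractions[["cf"]])
  }, numeric(2))
  expect_true(abs(mean(res[1, ]) - mean(res[2, ])) < 2)
  se_emp <- sd(res[1, ] / 100)
  se_bin <- sqrt(0.137 * 0.863 / 140)
  expect_true(se_emp / se_bin > 0.6 && se_emp / se_bin < 1.6)
})

test_that("numerical density divides counts by the reference space", {
  expect_equal(numerical_density(10, 2)$density, 5)
  expect_equal(numerical_density(0, 2)$density, 0)
  nd <- numerical_density(c(4, 6), c(2, 2))
  expect_equal(nd$density, 2.5)
  expect_equal(nd$per_field, c(2, 3))
  expect_error(numerical_density(5, 0), "> 0")
})

test_that("granule morphometry measures counts, areas and diameters", {
  # one synthetic circular granule of radius 20 px at 10 nm/px
  mask <- matrix(0L, 200, 200)
  off <- expand.grid(dy = -25:25, dx = -25:25)
  off <- off[off$dy^2 + off$dx^2 <= 20^2, ]
  mask[cbind(100 + off$dy, 100 + off$dx)] <- 1L
  gs <- granule_stats(list(mask), seed = 1)
  expect_equal(gs$counts, 1L)
  expect_equal(gs$diameters_nm, 2 * sqrt(gs$areas_nm2 / pi))
  expect_equal(gs$diameters_nm, 400, tolerance = 0.02)   # 2 x 20 px x 10 nm
  # two identical granules: mean area equals the individual area
  mask2 <- mask
  mask2[cbind(30 + off$dy, 60 + off$dx)] <- 1L
  gs2 <- granule_stats(list(mask2), seed = 1)
  expect_equal(gs2$counts, 2L)
  expect_equal(gs2$mean_area_nm2, gs$areas_nm2)
  # an equivalent-circle diameter at the atrial granule scale
  expect_equal(2 * sqrt(1785 / pi), 47.7, tolerance = 1e-3)
  empty <- granule_stats(list(matrix(0L, 50, 50)), seed = 1)
  expect_equal(empty$granules_per_field, 0)
  expect_length(empty$diameters_nm, 0)
})

test_that("lumen diameter inverts the disc area", {
  expect_equal(lumen_diameter(pi), 2)
  expect_equal(lumen_diameter(0), 0)
  expect_equal(lumen_diameter(0.709), 0.950, tolerance = 1e-3)
  d <- 1.37
  expect_equal(lumen_diameter(pi * (d / 2)^2), d)
  expect_error(lumen_diameter(-1), "non-negative")
})

test_that("intima-media geometry and shrinkage correction are exact", {
  im <- intima_media(rep(177.3, 4), 1.15)
  expect_equal(im$imt_um, 177.3)
  expect_equal(im$ima_raw_mm2, 0.739, tolerance = 1e-3)
  expect_equal(im$ima_mm2, 0.946, tolerance = 1e-3)
  # degenerate lumen: annulus becomes a disc
  disc <- intima_media(rep(100, 4), 0)
  expect_equal(disc$ima_mm2, 1.28 * pi * 0.1^2)
  # thin wall limit
  expect_lt(intima_media(rep(0.1, 4), 1)$ima_mm2, 1e-3)
  expect_error(intima_media(rep(1500, 4), 1.15), "check units")
})

test_that("IMA matches the pixel-counted wall area of a synthetic ring", {
  ring <- sim_aorta_ring(0.95, 158, 5, px_per_um = 1, seed = 4)
  wall_px <- sum(ring != 0L)
  wall_mm2 <- wall_px / (1 * 1000)^2
  im <- intima_media(rep(158, 4), 0.95)
  expect_equal(im$ima_raw_mm2, wall_mm2, tolerance = 0.02)
})

test_that("lamellae counting is exact, also under pixel noise", {
  expect_equal(count_lamellae(sim_aorta_ring(0.95, 158, 13, seed = 1))$count,
               13L)
  expect_equal(count_lamellae(sim_aorta_ring(0.95, 158, 1, seed = 2))$count,
               1L)
  expect_equal(count_lamellae(sim_aorta_ring(0.95, 158, 10,
                                             noise_prob = 0.05,
                                             seed = 3))$count, 10L)
  expect_error(count_lamellae(matrix(0L, 50, 50)), "no lamellae")
})

test_that("wall tension is Laplace's law and bilinear", {
  expect_equal(wall_tension(142, 0.86)$cwt_mmHg_mm, 61.06)
  expect_equal(round(wall_tension(142, 0.86)$cwt_mmHg_mm), 61)
  expect_equal(wall_tension(0, 1)$cwt_mmHg_mm, 0)
  expect_equal(wall_tension(100, 1)$cwt_mmHg_mm, 50)
  expect_equal(wall_tension(200, 0.86)$cwt_mmHg_mm,
               2 * wall_tension(100, 0.86)$cwt_mmHg_mm)
  expect_equal(wall_tension(142, 1.72)$cwt_mmHg_mm,
               2 * wall_tension(142, 0.86)$cwt_mmHg_mm)
  expect_equal(wall_tension(100, 1)$cwt_dyne_cm, 50 * 133.322)
})

test_that("percent change honours the denominator conventions", {
  expect_equal(percent_change(240, 160, "reference"), -33.33, tolerance = 1e-3)
  expect_equal(percent_change(3.9, 5.2, "value"), 25, tolerance = 1e-3)
  expect_equal(percent_change(5, 5), 0)
  # auto: decreases on the reference, increases on the value
  expect_equal(percent_change(240, 160), percent_change(240, 160, "reference"))
  expect_equal(percent_change(3.9, 5.2), percent_change(3.9, 5.2, "value"))
  expect_error(percent_change(0, 5, "reference"), "zero denominator")
})
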