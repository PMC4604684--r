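test_that("centre finding is exact, equivariant, and rejects blanks", {
  ri <- generate_ring_image(ring_image_params(size = 256))
  ctr <- find_center(ri$image)
  expect_equal(unname(ctr), c(128.5, 128.5), tolerance = 0.5)

  shifted <- generate_ring_image(ring_image_params(size = 256,
                                                   center = c(138.5, 123.5)))
  ctr2 <- find_center(shifted$image)
  expect_equal(unname(ctr2 - ctr), c(10, -5), tolerance = 0.2)

  expect_error(find_center(matrix(0.2, 64, 64)), "blank")
})

test_that("ray casting produces the 16 standard angles (and generalises)", {
  ri <- generate_ring_image(ring_image_params())
  rays <- cast_rays(ri$image, find_center(ri$image))
  expect_length(rays, 16)
  expect_equal(vapply(rays, `[[`, numeric(1), "angle"), seq(0, 337.5, 22.5))

  rays4 <- cast_rays(ri$image, find_center(ri$image), n_lines = 4)
  expect_length(rays4, 8)
  expect_equal(vapply(rays4, `[[`, numeric(1), "angle"), seq(0, 315, 45))

  expect_error(cast_rays(ri$image, c(-5, 10)), "outside")
})

test_that("rotational symmetry: all 16 profiles of a circular ring agree", {
  ri <- generate_ring_image(ring_image_params())
  m <- measure_ring(ri$image)
  expect_lt(diff(range(m$thickness_px)), 0.5)
  expect_equal(unique(m$laminae), 4L)
})

test_that("circular annulus thickness is 20 px on every ray", {
  ri <- generate_ring_image(ring_image_params(inner_radius = 40,
                                              outer_radius = 60))
  m <- measure_ring(ri$image, scale = 0.65)
  expect_equal(nrow(m), 16)
  expect_true(all(!m$excluded))
  expect_true(all(abs(m$thickness_px - 20) <= 0.5))
  expect_equal(m$thickness_um, m$thickness_px * 0.65)
})

test_that("elliptical annulus matches the radial geometric oracle", {
  ri <- generate_ring_image(ring_image_params(size = 220, axis_ratio = 0.8))
  m <- measure_ring(ri$image)
  expect_true(all(abs(m$thickness_px - ri$truth$thickness) <= 1))
})

test_that("rays through a branch gap are excluded with a reason", {
  ri <- generate_ring_image(ring_image_params(branch_angles = c(45, 8)))
  expect_true(ri$truth$in_gap[ri$truth$angle == 45])
  m <- measure_ring(ri$image)
  bad <- m[m$angle == 45, ]
  expect_true(bad$excluded)
  expect_match(bad$reason, "no wall")
  expect_true(all(!m$excluded[m$angle %in% c(0, 90, 180, 270)]))
})

test_that("user angle masks exclude rays", {
  ri <- generate_ring_image(ring_image_params())
  m <- measure_ring(ri$image, exclude_angles = c(40, 50))
  expect_true(m$excluded[m$angle == 45])
  expect_match(m$reason[m$angle == 45], "user-masked")
})

test_that("laminae counts are exact noise-free and robust to noise", {
  for (nl in c(0, 2, 4, 6)) {
    ri <- generate_ring_image(ring_image_params(n_laminae = nl))
    expect_equal(unique(measure_ring(ri$image)$laminae), nl)
  }
  hits <- 0
  total <- 0
  for (s in 1:40) {
    ri <- generate_ring_image(ring_image_params(noise_sd = 0.02), seed = s)
    m <- measure_ring(ri$image)
    hits <- hits + sum(m$laminae == 4, na.rm = TRUE)
    total <- total + sum(!m$excluded)
  }
  expect_gte(hits / total, 0.95)
})

test_that("measurements are invariant under linear intensity rescaling", {
  ri <- generate_ring_image(ring_image_params())
  m1 <- measure_ring(ri$image)
  m2 <- measure_ring(0.25 + 2.2 * ri$image)
  expect_identical(m1$laminae, m2$laminae)
  expect_equal(m1$thickness_px, m2$thickness_px, tolerance = 1e-9)
})

test_that("quarter-turn rotation leaves the circular summary unchanged", {
  ri <- generate_ring_image(ring_image_params())
  rot <- t(ri$image)[ncol(ri$image):1, ] # 90-degree rotation
  s1 <- summarize_rings(list(measure_ring(ri$image)))
  s2 <- summarize_rings(list(measure_ring(rot)))
  expect_equal(s1$mean_thickness_px, s2$mean_thickness_px, tolerance = 0.1)
})

test_that("ring summaries average included points then sections", {
  mk <- function(th, excl = 0) {
    df <- data.frame(angle = seq(0, 337.5, 22.5), inner = 40, outer = 40 + th,
                     thickness_px = th, thickness_um = NA_real_,
                     laminae = 4L, excluded = FALSE, reason = "")
    if (excl > 0) {
      df$excluded[seq_len(excl)] <- TRUE
      df$thickness_px[seq_len(excl)] <- 99
    }
    df
  }
  s <- summarize_rings(list(mk(20), mk(20), mk(20)))
  expect_equal(s$mean_thickness_px, 20)
  expect_equal(s$mean_laminae, 4)

  s2 <- summarize_rings(list(mk(20, excl = 2)))
  expect_equal(s2$mean_thickness_px, 20)
  expect_equal(s2$n_included, 14)

  s3 <- summarize_rings(list(mk(18), mk(20), mk(22)))
  expect_equal(s3$mean_thickness_px, 20)

  all_excl <- mk(20)
  all_excl$excluded <- TRUE
  expect_error(summarize_rings(list(all_excl)), "all rays excluded")
})

test_that("image parameter validation", {
  expect_error(ring_image_params(inner_radius = 70, outer_radius = 60), "inner")
  expect_error(ring_image_params(outer_radius = 120, size = 192), "fit")
  expect_error(ring_image_params(size = 32), "at least 64")
  expect_error(ring_image_params(n_laminae = -1), "n_laminae")
})
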