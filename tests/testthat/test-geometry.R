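test_that("pixel/degree conversions follow the display scale", {
  geom <- display_geometry(600, 19.15)
  expect_equal(round(px_to_deg(100, geom), 2), 3.19)
  expect_equal(round(px_to_deg(25, geom), 2), 0.80)
  expect_identical(px_to_deg(0, geom), 0)
  x <- c(0, 1, 37, 100, 599)
  expect_equal(deg_to_px(px_to_deg(x, geom), geom), x, tolerance = 1e-12)
  expect_error(px_to_deg(-1, geom), "non-negative")
  expect_error(deg_to_px(-0.5, geom), "non-negative")
  expect_error(display_geometry(0, 19.15), "positive")
})

test_that("annulus conventions give equal-area stimuli; naive reading is impossible", {
  # diameter_diff: the small/thick and large/thin annuli share their area
  st <- annulus_spec(100, 75, "diameter_diff")
  lt <- annulus_spec(200, 25, "diameter_diff")
  expect_equal(shape_area_px(st), shape_area_px(lt))
  expect_equal(st$outer_r, 50)
  expect_equal(st$inner_r, 12.5)
  expect_equal(lt$inner_r, 87.5)
  # all four annuli fit the central 300 x 300 px under diameter_diff
  expect_lte(annulus_spec(200, 75, "diameter_diff")$outer_r, 150)

  # radius_width also satisfies equal area
  st2 <- annulus_spec(100, 75, "radius_width")
  lt2 <- annulus_spec(200, 25, "radius_width")
  expect_equal(shape_area_px(st2), shape_area_px(lt2))

  # the naive diameter + printed-ring-width reading cannot be constructed
  expect_error(annulus_spec(100, 75, "diameter_width"), "impossible")
  # and rasterised masks agree in pixel count within 2%
  m_st <- shape_mask(st); m_lt <- shape_mask(lt)
  expect_lt(abs(sum(m_st) - sum(m_lt)) / sum(m_st), 0.02)
})

test_that("shape masks follow the half-open pixel-centre rule", {
  geom <- display_geometry(600, 19.15)
  # an annulus with inner radius zero is exactly a disk of the same radius
  ann0 <- annulus_spec(100, 100, "diameter_diff")
  expect_equal(ann0$inner_r, 0)
  dk <- disk_spec(diameter_deg = px_to_deg(100, geom))
  expect_identical(shape_mask(ann0, geom), shape_mask(dk, geom))

  # pixel count approximates the continuous area within 2% for R >= 25 px
  for (spec in list(annulus_spec(100, 25), annulus_spec(100, 75),
                    annulus_spec(200, 25), annulus_spec(200, 75),
                    disk_spec(px_to_deg(50, geom)),
                    disk_spec(px_to_deg(400, geom)))) {
    m <- shape_mask(spec, geom)
    a <- shape_area_px(spec, geom)
    expect_lt(abs(sum(m) - a) / a, 0.02)
  }

  # centred masks are invariant under 90-degree rotation and mirror flips
  m <- shape_mask(annulus_spec(200, 75), geom)
  n <- nrow(m)
  expect_identical(m, t(m)[n:1, ])          # rotate 90
  expect_identical(m, m[n:1, ])             # vertical mirror
  expect_identical(m, m[, n:1])             # horizontal mirror

  # pixel count strictly increases with outer radius at fixed inner radius
  counts <- vapply(c(120, 160, 200, 240), function(sz)
    sum(shape_mask(annulus_spec(sz, sz - 100), geom)), 0)
  expect_true(all(diff(counts) > 0))

  # shapes leaving the matrix raise an error naming the overflow
  expect_error(shape_mask(annulus_spec(700, 50), geom), "px beyond")
  expect_error(shape_mask(disk_spec(6, eccentricity_deg = 8), geom),
               "px beyond")
})

test_that("filling-in features implement contour length and fill distance", {
  geom <- display_geometry(600, 19.15)
  dk <- disk_spec(diameter_deg = px_to_deg(94, geom))
  f <- fillin_features(dk, geom)
  expect_equal(f$contour_len_px, 2 * pi * 47)
  expect_equal(f$fill_dist_px, 47)

  ann <- annulus_spec(200, 25, "diameter_diff")
  fa <- fillin_features(ann, geom)
  expect_equal(fa$contour_len_px, 2 * pi * 187.5)
  expect_equal(fa$fill_dist_px, 12.5)
  expect_equal(fillin_features(ann, geom, fill_dist = "printed")$fill_dist_px,
               25)

  tiny <- fillin_features(disk_spec(1e-9), geom)
  expect_lt(tiny$contour_len_px, 1e-6)
  expect_lt(tiny$fill_dist_px, 1e-6)
})
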