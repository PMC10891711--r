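test_that("MCV from hematocrit and count, with explicit unit handling", {
  expect_equal(round_half_up(mcv_from_count(0.45, 5.5), 1), 81.8)
  expect_equal(mcv_from_count(45, 5.5, hct_unit = "percent"),
               mcv_from_count(0.45, 5.5))
  expect_equal(mcv_from_count(0.40, 5.0), 80)
  expect_error(mcv_from_count(1.2, 5), "fraction")
  expect_error(mcv_from_count(110, 5, hct_unit = "percent"), "percent")
  expect_error(mcv_from_count(-0.4, 5))
  expect_error(mcv_from_count(0.4, 0))
})

test_that("thickness inversion reproduces worked cases and inverts the cylinder exactly", {
  expect_equal(round_half_up(thickness_from_mcv(7.2, 90), 1), 2.2)
  expect_equal(round_half_up(thickness_from_mcv(4.0, 90), 1), 7.2)
  smp <- generate_rbc_sample(200, seed = 3)
  expect_equal(thickness_from_mcv(smp$d_um, cylinder_volume(smp$d_um, smp$t_um)),
               smp$t_um)
  expect_equal(cylinder_volume(smp$d_um, thickness_from_mcv(smp$d_um, smp$mcv_fl)),
               smp$mcv_fl)
  expect_error(thickness_from_mcv(0, 90))
})

test_that("validity screen applies the pallor and ratio rules", {
  s <- screen_validity(7.2, thickness_from_mcv(7.2, 90))
  expect_true(s$valid)
  expect_equal(round_half_up(s$ratio, 1), 0.3)
  expect_length(s$reasons, 0)

  s <- screen_validity(2.2, 1.473)
  expect_false(s$valid)
  expect_equal(s$ratio_used, 0.7)

  # borderline case: raw ratio 0.496 rounds to 0.5 and fails the default
  # rule, but passes under the unrounded rule
  s <- screen_validity(5.9, 2.926)
  expect_false(s$valid)
  expect_equal(s$ratio_used, 0.5)
  expect_true(screen_validity(5.9, 2.926, ratio_rule = "unrounded")$valid)

  s <- screen_validity(7.2, 2.2, central_pallor = FALSE)
  expect_false(s$valid)
  expect_match(s$reasons, "pallor", all = FALSE)
})

test_that("validity verdicts are monotone in the thickness:diameter ratio", {
  d <- 6
  ratios <- seq(0.1, 1.2, by = 0.05)
  fired <- vapply(ratios, function(r) !screen_validity(d, r * d)$valid, logical(1))
  # once the ratio rule fires it keeps firing for every larger ratio
  expect_true(all(diff(fired) >= 0))
})

test_that("protocol picks the biconcave model for a valid discocyte", {
  res <- surface_area_protocol(7.2, 90)
  expect_equal(res$model_used, "biconcave_spheroid")
  expect_true(res$valid)
  expect_equal(round_half_up(res$thickness, 1), 2.2)
  expect_equal(res$volume, 90)
  expect_equal(res$surface_area, biconcave_surface(7.2, res$thickness))
  expect_match(res$notes, "assumed present", all = FALSE)
})

test_that("protocol falls back to the sphere for spherical cells", {
  # spherocyte: ratio 1.8, eccentricity imaginary, biconcave n.c.
  res <- surface_area_protocol(4.0, 90)
  expect_false(res$valid)
  expect_equal(round_half_up(res$ratio, 1), 1.8)
  expect_false(res$biconcave_computable)
  expect_true(is.na(res$biconcave_sa))
  expect_equal(res$model_used, "sphere")
  expect_equal(res$surface_area, sphere_surface(4.0))

  # small spherical cells: sphere surface from the MEASURED diameter
  res <- surface_area_protocol(2.2, 5.6)
  expect_equal(res$model_used, "sphere")
  expect_equal(round_half_up(res$surface_area, 1), 15.2)

  # optional MCV-equivalent sphere diameter for cross-checking
  res <- surface_area_protocol(2.2, 5.6, sphere_diameter = "mcv_equivalent")
  expect_equal(res$surface_area, sphere_surface((6 * 5.6 / pi)^(1 / 3)))

  # absent pallor forces the fallback even at discocyte proportions
  res <- surface_area_protocol(7.2, 90, central_pallor = FALSE)
  expect_equal(res$model_used, "sphere")

  res <- surface_area_protocol(7.2, 90, shape_hint = "spherical")
  expect_equal(res$model_used, "sphere")
})

test_that("protocol handles the camelid elliptical path", {
  res <- surface_area_protocol(8, 50, shape_hint = "elliptical",
                               major = 8, minor = 4)
  expect_equal(res$model_used, "elliptical_cylinder")
  expect_equal(res$thickness, 4 * 50 / (pi * 8 * 4))
  expect_equal(res$surface_area,
               elliptical_cylinder_surface(8, 4, res$thickness))
  expect_equal(elliptical_cylinder_volume(8, 4, res$thickness), 50)
  expect_error(surface_area_protocol(8, 50, shape_hint = "elliptical"),
               "major")
})

test_that("protocol never reports a biconcave surface on an invalid verdict", {
  smp <- generate_rbc_sample(100, seed = 9)
  for (i in seq_len(nrow(smp))) {
    res <- surface_area_protocol(smp$d_um[i], smp$mcv_fl[i])
    if (!res$valid) expect_equal(res$model_used, "sphere")
    if (res$valid) {
      expect_equal(res$model_used, "biconcave_spheroid")
      expect_false(is.na(res$surface_area))
    }
    # cylinder-inversion identity holds for every record
    expect_equal(cylinder_volume(smp$d_um[i], res$thickness), smp$mcv_fl[i])
  }
})
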