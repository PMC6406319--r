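test_that("distance field obeys pythagorean geometry and edge cases", {
  m <- matrix(0L, 20, 20); m[5, 5] <- 1L
  d <- distance_field(m, pixel_size_um = 1)
  expect_equal(d[8, 9], 5)         # offset (3, 4)
  expect_equal(d[5, 5], 0)
  d2 <- distance_field(m, pixel_size_um = 0.5)
  expect_equal(d2[8, 9], 2.5)

  everywhere <- matrix(1L, 12, 12)
  expect_true(all(distance_field(everywhere, 1) == 0))
  expect_error(distance_field(matrix(0L, 5, 5), 1), "empty source")
})

test_that("distance field matches the exhaustive oracle on random masks", {
  for (s in c(101, 202)) {
    set.seed(s)
    m <- matrix(0L, 64, 64)
    m[sample(64 * 64, 30)] <- 1L
    expect_equal(distance_field(m, 0.8), brute_force_distance(m, 0.8),
                 tolerance = 1e-6)
  }
})

test_that("constant intensity over the full depth integrates to depth x intensity", {
  # distances increase along columns: one vessel column at the left edge
  m <- matrix(0L, 40, 130); m[, 1] <- 1L
  d <- distance_field(m, 1)
  img <- matrix(7, 40, 130)
  pr <- intensity_profile(img, d, bin_width_um = 1, max_depth_um = 80,
                          exclude_source = FALSE)
  expect_equal(profile_auc(pr), 80 * 7, tolerance = 1e-9)
  expect_equal(nrow(pr), 80)
})

test_that("auc of a zero-noise exponential phantom matches the closed form", {
  sp <- synthetic_spec(rng_seed = 5, n_vessels = 1, noise_sd = 0, n_nuclei = 0,
                       decay_length_um = 20, antibody_amplitude = 100)
  g <- generate_section(sp)
  dm <- distance_field(g$truth$vessel_mask, sp$pixel_size_um)
  pr <- suppressWarnings(intensity_profile(g$section, dm, bin_width_um = 1))
  closed <- 100 * 20 * (1 - exp(-80 / 20))
  expect_lt(abs(profile_auc(pr) - closed) / closed, 0.02)
  # refinement stability: halving the bin width moves the AUC by < 2%
  pr_half <- suppressWarnings(intensity_profile(g$section, dm,
                                                bin_width_um = 0.5))
  expect_lt(abs(profile_auc(pr_half) - profile_auc(pr)) / profile_auc(pr),
            0.02)
})

test_that("auc increases with the generator decay length", {
  aucs <- vapply(c(10, 15, 25), function(lam) {
    sp <- synthetic_spec(rng_seed = 5, n_vessels = 1, noise_sd = 0,
                         n_nuclei = 0, decay_length_um = lam)
    g <- generate_section(sp)
    dm <- distance_field(g$truth$vessel_mask, sp$pixel_size_um)
    profile_auc(intensity_profile(g$section, dm))
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("profile of an isotropic phantom is rotation invariant", {
  n <- 201
  m <- matrix(0L, n, n); m[101, 101] <- 1L
  d <- distance_field(m, 1)
  img <- 50 * exp(-d / 25)
  pr <- intensity_profile(img, d, bin_width_um = 2)
  # quarter rotation of the field leaves the profile unchanged
  rot <- function(x) t(x[nrow(x):1, ])
  pr_rot <- intensity_profile(rot(img), rot(d), bin_width_um = 2)
  expect_equal(pr$mean_intensity, pr_rot$mean_intensity, tolerance = 1e-12)
  expect_equal(profile_auc(pr), profile_auc(pr_rot))
})

test_that("peak depth lands on the ground-truth maximum", {
  sp <- synthetic_spec(rng_seed = 5, n_vessels = 1, noise_sd = 0, n_nuclei = 0)
  g <- generate_section(sp)
  tr <- g$truth
  # non-monotone phantom peaking at 27 um, the depth shift seen under
  # combination treatment
  I <- 100 * (tr$distance_um / 27) * exp(1 - tr$distance_um / 27)
  I[tr$tumor_mask == 0] <- 0
  s <- section_image(g$section$nuclei, g$section$vessels, I,
                     sp$pixel_size_um, tumor_mask = tr$tumor_mask)
  dm <- distance_field(tr$vessel_mask, sp$pixel_size_um)
  pr <- intensity_profile(s, dm, bin_width_um = 1)
  expect_lte(abs(profile_peak_depth(pr) - 27), 1)
  expect_lte(abs(profile_peak_depth(pr, smoothed = FALSE) - 27), 1)
})

test_that("empty distance bins are flagged and handled per config", {
  m <- matrix(0L, 30, 30); m[15, 15] <- 1L
  d <- distance_field(m, 10)            # coarse pixels: sparse depth coverage
  img <- matrix(5, 30, 30)
  expect_warning(pr <- intensity_profile(img, d, bin_width_um = 1),
                 "interpolated")
  expect_true(any(pr$interpolated))
  pr2 <- intensity_profile(img, d, bin_width_um = 1, empty_bins = "drop")
  expect_true(all(!pr2$interpolated))
  expect_true(all(pr2$n_pixels > 0))
})

test_that("accumulation density is total intensity over tumor area", {
  mask <- matrix(1L, 10, 10)
  s <- section_image(matrix(0, 10, 10), matrix(0, 10, 10),
                     matrix(3, 10, 10), pixel_size_um = 0.5,
                     tumor_mask = mask)
  acc <- accumulation(s)
  expect_equal(acc$tumor_area_um2, 100 * 0.25)
  expect_equal(acc$accumulation_density, 3 / 0.25)

  zero <- section_image(matrix(0, 10, 10), matrix(0, 10, 10),
                        matrix(0, 10, 10), 0.5, tumor_mask = mask)
  expect_equal(accumulation(zero)$accumulation_density, 0)

  # homogeneity and monotonicity
  s2 <- section_image(s$nuclei, s$vessels, 2 * s$antibody, 0.5,
                      tumor_mask = mask)
  expect_equal(accumulation(s2)$accumulation_density,
               2 * acc$accumulation_density)
  part <- matrix(0L, 10, 10); part[1:5, ] <- 1L
  hot <- matrix(0, 10, 10); hot[1:5, ] <- 3
  sp_ <- section_image(matrix(0, 10, 10), matrix(0, 10, 10), hot, 0.5)
  expect_gt(accumulation(sp_, tumor_mask = part)$accumulation_density,
            accumulation(sp_, tumor_mask = matrix(1L, 10, 10))$accumulation_density)
  expect_error(accumulation(sp_, tumor_mask = matrix(0L, 10, 10)), "empty")
})

test_that("percent change reproduces the reported treatment contrasts", {
  expect_equal(percent_change(3.10, 1.72, digits = 0), 80)
  expect_equal(percent_change(2.76, 1.72, digits = 0), 60)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "positive")
  expect_error(percent_change(1, -2), "positive")
})
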