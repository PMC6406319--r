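test_that("circularity matches analytic shapes", {
  expect_lt(abs(shape_circularity(make_disk(50)) - 1), 0.02)
  expect_lt(abs(shape_circularity(make_square(100)) - pi / 4), 0.02)
  expect_error(shape_circularity({m <- matrix(0L, 5, 5); m[3, 3] <- 1L; m}),
               "degenerate")
  expect_error(shape_circularity(matrix(0L, 5, 5)), "empty")
})

test_that("circularity is stable under rotation and uniform scaling", {
  sq0 <- shape_circularity(make_square(100))
  for (th in c(20, 45) * pi / 180) {
    expect_lt(abs(shape_circularity(make_square(100, theta = th)) - sq0) / sq0,
              0.02)
  }
  d20 <- shape_circularity(make_disk(20))
  d50 <- shape_circularity(make_disk(50))
  expect_lt(abs(d20 - d50) / d50, 0.02)
})

test_that("fractal dimension recovers known dimensions", {
  line <- cbind(seq(0, 200, by = 0.4), seq(0, 100, by = 0.2))
  fl <- fractal_dimension(line)
  expect_lt(abs(fl$fd - 1), 0.05)
  expect_gt(fl$r2, 0.99)

  koch <- koch_prefractal()
  fk <- fractal_dimension(koch)
  expect_lt(abs(fk$fd - log(4) / log(3)), 0.05)
})

test_that("box counting equals the exhaustive oracle", {
  set.seed(8)
  pts <- matrix(runif(120, 0, 60), ncol = 2)
  sizes <- c(2, 4, 8, 16)
  f <- fractal_dimension(pts, box_sizes = sizes, n_offsets = 4)
  for (k in seq_along(sizes)) {
    oracle <- mean(vapply(1:4, function(o)
      brute_force_box_count(pts, sizes[k], (o - 1) / 4 * sizes[k]),
      numeric(1)))
    expect_equal(f$counts[k], oracle)
  }
  expect_equal(f$fd, brute_force_fd(pts, sizes), tolerance = 1e-12)
})

test_that("fd is invariant to point order and stable across grid offsets", {
  koch <- koch_prefractal()
  f1 <- fractal_dimension(koch)
  f2 <- fractal_dimension(koch[sample(nrow(koch)), ])
  expect_equal(f1$fd, f2$fd, tolerance = 1e-12)

  singles <- vapply(1:4, function(o) {
    shifted <- koch + (o - 1) / 4 * 2
    fractal_dimension(shifted, n_offsets = 1)$fd
  }, numeric(1))
  expect_lt(max(singles) - min(singles), 0.1)
  expect_gte(f1$fd, min(singles) - 0.05)
  expect_lte(f1$fd, max(singles) + 0.05)
})

test_that("fd errors on degenerate input", {
  expect_error(fractal_dimension(matrix(1:10, ncol = 2)), "too few")
  expect_error(fractal_dimension(cbind(1:20, 1), box_sizes = 4), "two box")
})

test_that("all intact nuclei are recovered from a clean section", {
  sp <- synthetic_spec(rng_seed = 11, n_nuclei = 50, n_vessels = 2,
                       noise_sd = 0)
  g <- generate_section(sp)
  ns <- extract_nuclei(g$section)
  expect_length(ns, 50)
  df <- as.data.frame(ns)
  expect_true(all(df$circularity > 0.9))
  expect_true(all(df$n_components == 1))
  # centroids match the ground-truth placement (within a couple of pixels)
  truth <- g$truth$nuclei[order(g$truth$nuclei$row, g$truth$nuclei$col), ]
  found <- df[order(df$row, df$col), ]
  expect_lt(max(abs(truth$row - found$row)), 2)
  expect_lt(max(abs(truth$col - found$col)), 2)
})

test_that("blank images yield an empty nucleus set with a warning", {
  expect_warning(ns <- extract_nuclei(matrix(0, 32, 32)), "blank")
  expect_length(ns, 0)
  expect_equal(nrow(as.data.frame(ns)), 0)
})

test_that("fragments are separate objects unless merged by config", {
  m <- NULL
  for (sd in 1:60) {
    cand <- render_nucleus("fragmented", severity = 4, seed = sd,
                           radius_px = 14)
    lab <- EBImage::bwlabel(EBImage::Image(cand))
    if (max(lab) == 3) { m <- cand; break }
  }
  expect_false(is.null(m))
  img <- matrix(0, 90, 90)
  img[25:(24 + nrow(m)), 25:(24 + ncol(m))] <- 150 * m
  expect_length(extract_nuclei(img, min_size_px = 5), 3)
  merged <- extract_nuclei(img, min_size_px = 5, merge_radius_px = 30)
  expect_length(merged, 1)
  expect_equal(merged[[1]]$n_components, 3)
})

test_that("proximal filter keeps nuclei within the distance band", {
  # distance grows one micrometre per column: objects at 79 and 81 um
  dist_um <- matrix(rep(0:99, each = 50), 50, 100)
  img <- matrix(0, 50, 100)
  stamp <- render_nucleus("intact", radius_px = 4)
  img[21:(20 + nrow(stamp)), 76:(75 + ncol(stamp))] <- 150 * stamp
  ns <- extract_nuclei(img, min_size_px = 10, distance_um = dist_um)
  expect_length(ns, 1)
  d_obj <- ns[[1]]$distance_to_vessel_um
  keep <- proximal_filter(ns, max_dist_um = d_obj)
  drop <- proximal_filter(ns, max_dist_um = d_obj - 1)
  expect_length(keep, 1)    # boundary is inclusive
  expect_length(drop, 0)
  expect_length(proximal_filter(ns, max_dist_um = Inf), 1)
})

test_that("proximal filter retains exactly the ground-truth band population", {
  sp <- synthetic_spec(rng_seed = 31, n_nuclei = 40, n_vessels = 1,
                       noise_sd = 0)
  g <- generate_section(sp)
  dm <- distance_field(g$truth$vessel_mask, sp$pixel_size_um)
  ns <- extract_nuclei(g$section, distance_um = dm)
  expect_length(ns, 40)
  d_all <- vapply(ns, function(o) o$distance_to_vessel_um, numeric(1))
  for (cut in c(40, 80)) {
    expect_length(proximal_filter(ns, max_dist_um = cut), sum(d_all <= cut))
  }
})

test_that("severity drives circularity down and fractal dimension up", {
  sevs <- c(0.5, 1, 1.5, 2, 2.5, 3)
  res <- vapply(sevs, function(s) {
    mm <- vapply(seq_len(200), function(i) {
      m <- render_nucleus("fragmented", severity = s, seed = 7000 + i,
                          radius_px = 12)
      mo <- nucleus_morphometrics(m)
      c(mo$circularity, mo$fractal_dimension)
    }, numeric(2))
    rowMeans(mm)
  }, numeric(2))
  expect_lte(stats::cor(sevs, res[1, ], method = "spearman"), -0.9)
  expect_gte(stats::cor(sevs, res[2, ], method = "spearman"), 0.9)
})
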