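test_that("substack projection tiling follows the 10/20 um rule", {
  arr <- array(rep(1:100, 4), dim = c(100, 2, 2))
  projs <- project_substacks(arr, thickness_um = 10, spacing_um = 20, z_step_um = 1)
  expect_length(projs, 4L)
  expect_equal(attr(projs[[1]], "planes"), 1:10)
  expect_equal(attr(projs[[2]], "planes"), 31:40)
  expect_equal(attr(projs[[4]], "planes"), 91:100)
  expect_equal(projs[[1]][1, 1], mean(1:10))

  projs1 <- project_substacks(array(7, dim = c(10, 4, 4)), 10, 20, 1)
  expect_length(projs1, 1L)
  expect_equal(projs1[[1]][2, 2], 7)

  expect_warning(p0 <- project_substacks(array(0, dim = c(5, 4, 4)), 10, 20, 1),
                 "shallower")
  expect_length(p0, 0L)
})

test_that("seed detection finds somas and nothing on blank images", {
  expect_equal(nrow(detect_seeds(matrix(10, 64, 64))), 0L)

  sp <- cell_spec(c(72, 72), 5, 3, 12, 0.04, 0.3, seed = 12)
  ci <- generate_cell_image(sp, c(144, 144), 1)
  img <- corrupt_image(ci$image, 31)
  seeds <- detect_seeds(img, calibration = 1)
  expect_equal(nrow(seeds), 1L)
  expect_true(ci$truth$soma_mask[seeds[1, 1], seeds[1, 2]])

  # two cells 60 um apart give two seeds
  s1 <- cell_spec(c(60, 60), 4, 4, 15, 0.05, 0.3, 5)
  s2 <- cell_spec(c(120, 60), 4, 4, 15, 0.05, 0.3, 6)
  i1 <- generate_cell_image(s1, c(176, 176), 1)$image
  i2 <- generate_cell_image(s2, c(176, 176), 1)$image
  im <- corrupt_image(pmax(i1, i2), 9)
  expect_equal(nrow(detect_seeds(im, calibration = 1)), 2L)
})

test_that("grow_mask is the seed's connected supra-threshold component", {
  set.seed(2)
  roi <- matrix(runif(400, 10, 20), 20, 20)
  roi[5:8, 5:8] <- 100
  roi[14:16, 14:16] <- 100  # second blob, not connected to the seed
  m_all <- grow_mask(roi, threshold = min(roi) - 1, seed = c(6, 6))
  expect_true(all(m_all))
  m_none <- grow_mask(roi, threshold = max(roi) + 1, seed = c(6, 6))
  expect_false(any(m_none))
  m <- grow_mask(roi, threshold = 50, seed = c(6, 6))
  expect_equal(sum(m), 16)
  expect_false(m[15, 15])
})

test_that("next_threshold matches hand evaluation and is monotone", {
  expect_equal(next_threshold(100, 500, 400, 1), 125)
  expect_equal(next_threshold(100, 200, 400, 2), 75)
  expect_equal(next_threshold(80, 400, 400, 5), 80)  # fixed point at A = MS
  expect_error(next_threshold(100, 200, 0, 1), "positive")
  # property: direction and 1/n shrinkage
  set.seed(7)
  for (i in 1:50) {
    T_I <- runif(1, 10, 200)
    MS <- runif(1, 100, 800)
    A <- runif(1, 0, 1600)
    n <- sample(1:20, 1)
    nt <- next_threshold(T_I, A, MS, n)
    if (A > MS) expect_gt(nt, T_I) else if (A < MS) expect_lt(nt, T_I)
    step1 <- abs(next_threshold(T_I, A, MS, 1) - T_I)
    expect_equal(abs(nt - T_I), step1 / n, tolerance = 1e-9)
  }
})

test_that("segment_cell converges to the target area and applies edge rules", {
  # cell with true area near MS: accepted within the limit
  sp <- cell_spec(c(72, 72), 3.5, 6, 30, 0.1, 0.3, seed = 11)
  ci <- generate_cell_image(sp, c(144, 144), 1)
  img <- corrupt_image(ci$image, 41)
  seeds <- detect_seeds(img, calibration = 1)
  er <- extract_roi(img, seeds[1, ], 1)
  MS <- sum(ci$truth$mask)
  cm <- segment_cell(er$roi, er$seed, MS = MS, limit = 100, calibration = 1)
  expect_s3_class(cm, "cell_mask")
  expect_equal(cm$status, "accepted")
  expect_lte(abs(cm$area - MS), 100)
  expect_lte(nrow(cm$history), 25)

  # convergence from perturbed starting thresholds (+-50% around Otsu)
  t_otsu <- otsu_threshold(er$roi)
  for (fac in c(0.5, 0.75, 1.25, 1.5)) {
    cmf <- segment_cell(er$roi, er$seed, MS = MS, limit = 100,
                        calibration = 1, t0 = fac * t_otsu)
    expect_equal(cmf$status, "accepted")
    expect_lte(abs(cmf$area - MS), 100)
    expect_lte(nrow(cmf$history), 25)
  }

  # accepted masks never touch the ROI edge
  expect_false(any(cm$mask[1, ]), any(cm$mask[, 1]))

  # cell close to the ROI edge is rejected
  sp_edge <- cell_spec(c(6, 72), 5, 0, seed = 2)
  ce <- generate_cell_image(sp_edge, c(144, 144), 1)
  imge <- corrupt_image(ce$image, 5)
  ere <- extract_roi(imge, c(6, 72), 1)
  cme <- segment_cell(ere$roi, ere$seed, MS = 80, limit = 100, calibration = 1)
  expect_equal(cme$status, "rejected_edge")

  # uniform ROI cannot be segmented
  cmu <- segment_cell(matrix(10, 120, 120), c(60, 60), MS = 400, limit = 100)
  expect_match(cmu$status, "rejected")
})

test_that("soma detection applies the area/circularity rules with fallback", {
  # disc soma radius 4 um (area ~ 50 um^2) on clean background: automatic
  spd <- cell_spec(c(60, 60), 4, 0, seed = 3)
  cd <- generate_cell_image(spd, c(120, 120), 1)
  img <- corrupt_image(cd$image, 17, noise_sd = 4)
  soma <- detect_soma(img, cd$truth$mask, 1)
  expect_equal(soma$origin, "automatic")
  expect_gt(soma$area, 20)
  expect_gte(soma$circularity, 0.6)

  # thin line only: circularity below 0.6, fallback disc inside the line
  line <- matrix(10, 60, 60)
  line[30:31, 10:50] <- 200
  lm <- line > 100
  sl <- detect_soma(line, lm, 1)
  expect_equal(sl$origin, "fallback")

  # two qualifying blobs: ambiguous, fallback
  two <- matrix(10, 80, 80)
  for (c0 in c(20, 60)) {
    for (y in 1:80) for (x in 1:80) {
      if ((y - 40)^2 + (x - c0)^2 <= 16) two[y, x] <- 200
    }
  }
  mask2 <- two > 100
  s2 <- detect_soma(two, mask2, 1)
  expect_equal(s2$origin, "fallback")
})

test_that("mask review rejects engulfing masks and honours accept lists", {
  # one mask containing pixels nearer to another seed: rejected under auto
  m1 <- matrix(FALSE, 40, 40); m1[18:22, 5:35] <- TRUE  # spans both seeds
  m2 <- matrix(FALSE, 40, 40); m2[18:22, 28:34] <- TRUE
  cm1 <- structure(list(mask = m1, seed = c(20, 8), status = "accepted"),
                   class = "cell_mask")
  cm2 <- structure(list(mask = m2, seed = c(20, 31), status = "accepted"),
                   class = "cell_mask")
  seeds <- rbind(c(20, 8), c(20, 31))
  out <- review_masks(list(cm1, cm2), seeds, policy = "auto")
  expect_equal(out[[1]]$status, "rejected_overlap")
  expect_equal(out[[2]]$status, "accepted")

  # single-cell frame: untouched
  out1 <- review_masks(list(cm1), seeds[1, , drop = FALSE], policy = "auto")
  expect_equal(out1[[1]]$status, "accepted")

  # empty accept list rejects everything
  outl <- review_masks(list(cm1, cm2), policy = "list", accept = integer(0))
  expect_true(all(vapply(outl, function(m) m$status, "") == "rejected_overlap"))
  expect_error(review_masks(list(cm1), policy = "bogus"))
})
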