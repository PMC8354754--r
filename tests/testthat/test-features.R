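test_that("shape descriptors match analytic fixtures", {
  # centred disc
  n <- 61
  disc <- matrix(FALSE, n, n)
  ys <- matrix(seq_len(n), n, n); xs <- t(ys)
  disc[(ys - 31)^2 + (xs - 31)^2 <= 15^2] <- TRUE
  f <- shape_descriptors(disc, disc, 1)
  expect_equal(f[["eccentricity"]], 1, tolerance = 0.02)
  expect_equal(f[["roundness"]], 1, tolerance = 0.02)
  expect_equal(f[["cell spread"]], 15, tolerance = 0.05)
  expect_equal(f[["mask area"]], sum(disc))
  expect_equal(f[["perimeter"]], 2 * pi * 15, tolerance = 0.06 * 2 * pi * 15)

  # 2:1 rectangle: second-moment eccentricity = side ratio
  rect <- matrix(FALSE, 60, 60)
  rect[21:40, 11:50] <- TRUE
  fr <- shape_descriptors(rect, rect, 1)
  expect_equal(fr[["eccentricity"]], 2, tolerance = 0.03)
  expect_error(shape_descriptors(matrix(FALSE, 5, 5), NULL), "empty")
})

test_that("Sholl profile counts the arms of parametric stars", {
  for (arms in c(3, 5, 8)) {
    ci <- make_star(arms)
    prof <- sholl_profile(ci$truth$mask, as_soma(ci$truth$soma_mask), 1, 2)
    # counts equal the arm count for radii between soma and the arm length
    mid <- prof$radii > prof$soma_radius + 3 & prof$radii < 0.7 * 0.8 * 30
    expect_true(all(prof$counts[mid] == arms))
    sk <- skeleton_descriptors(ci$truth$mask)
    sd <- sholl_descriptors(prof, sk$skeleton, 1)
    expect_equal(sd[["primary branches"]], arms)
    expect_equal(sd[["maximum number of intersections"]], arms)
    expect_equal(sd[["ramification index (sampled)"]], 1)
  }
})

test_that("Sholl fit and regressions behave on constructed profiles", {
  # constant profile: low-degree fit with value ~ 5
  radii <- seq(5, 25, 2)
  fit <- mgmorph:::.fit_sholl_poly(radii, rep(5, length(radii)))
  expect_lte(fit$degree, 1)
  expect_equal(fit$fitted, rep(5, length(radii)), tolerance = 1e-6)

  # exponential decay: semi-log slope = -log10(e), log-log well defined
  r <- seq(1, 10, 0.5)
  cnt <- 100 * exp(-r)
  sl <- mgmorph:::.sholl_regression(r, cnt, loglog = FALSE)
  expect_equal(sl[1], -log10(exp(1)), tolerance = 1e-9)

  # symmetric triangular profile: sampled skewness ~ 0 (the counts-based
  # convention of the reference plugin leaves a small finite-sample residual)
  tri <- c(1:5, 4:1)
  expect_equal(mgmorph:::skewness_g1(tri), 0, tolerance = 0.15)

  # bare disc: profile empty, Sholl features all zero
  sp0 <- cell_spec(c(40, 40), 6, 0, seed = 1)
  c0 <- generate_cell_image(sp0, c(80, 80), 1)
  prof0 <- sholl_profile(c0$truth$mask, as_soma(c0$truth$soma_mask), 1)
  expect_length(prof0$radii, 0)
  sd0 <- sholl_descriptors(prof0, skeletonize(c0$truth$mask), 1)
  expect_true(all(sd0 == 0))
})

test_that("hull metrics match exact geometry", {
  sq <- matrix(FALSE, 30, 30)
  sq[10:20, 10:20] <- TRUE  # 11 x 11 px square, pixel-centre hull side 10
  h <- hull_descriptors(sq, 1)
  expect_equal(h[["maximum span across hull"]], 10 * sqrt(2), tolerance = 1e-9)
  expect_equal(h[["diameter of bounding circle"]], 10 * sqrt(2), tolerance = 1e-9)
  expect_equal(h[["convex hull area"]], 100, tolerance = 1e-9)
  expect_equal(h[["convex hull perimeter"]], 40, tolerance = 1e-9)
  expect_equal(h[["density"]], 1, tolerance = 0.25)  # 121 px over area 100
  expect_equal(h[["span ratio"]], 1, tolerance = 1e-9)
  expect_equal(h[["mean radius"]],
               mean(c(rep(sqrt(50), 4), rep(5, 4))), tolerance = 0.6)

  # star: concave, density < 1
  ci <- make_star(5)
  hs <- hull_descriptors(ci$truth$mask, 1)
  expect_lt(hs[["density"]], 0.5)
  expect_lt(hs[["convex hull circularity"]], 1)

  # disc: near-circular hull
  n <- 61; disc <- matrix(FALSE, n, n)
  ys <- matrix(seq_len(n), n, n); xs <- t(ys)
  disc[(ys - 31)^2 + (xs - 31)^2 <= 15^2] <- TRUE
  hd <- hull_descriptors(disc, 1)
  expect_gt(hd[["convex hull circularity"]], 0.97)
  expect_equal(hd[["span ratio"]], 1, tolerance = 0.05)
  expect_equal(hd[["max/min radii"]], 1, tolerance = 0.05)
})

test_that("fractal dimension and lacunarity behave on canonical masks", {
  ln <- matrix(FALSE, 64, 64); ln[32, 5:60] <- TRUE
  f <- fractal_descriptors(ln)
  expect_equal(f[["fractal dimension"]], 1, tolerance = 0.1)

  fsq <- matrix(FALSE, 64, 64); fsq[10:50, 10:50] <- TRUE
  fs <- fractal_descriptors(fsq)
  expect_equal(fs[["fractal dimension"]], 1, tolerance = 0.1)

  # a gappy branched mask is more lacunar than a filled square
  ci <- make_star(6)
  fstar <- fractal_descriptors(ci$truth$mask)
  expect_gt(fstar[["lacunarity"]], fs[["lacunarity"]])

  # translation invariance is exact (grids anchored at the bounding box)
  shifted <- mgmorph:::shift_mat(ci$truth$mask, 7, -9, fill = FALSE)
  ft <- fractal_descriptors(shifted)
  expect_equal(ft, fstar, tolerance = 1e-12)
})

test_that("extract_features returns exactly 62 stable, named features", {
  sp <- cell_spec(c(61, 61), 4, 5, 22, 0.08, 0.3, seed = 13)
  ci <- generate_cell_image(sp, c(121, 121), 1)
  soma <- as_soma(ci$truth$soma_mask)
  fv <- extract_features(ci$truth$mask, soma, 1)
  expect_length(fv, 62L)
  expect_identical(names(fv), feature_names())
  expect_false(anyNA(fv))
  expect_length(attr(fv, "errors"), 0L)
  fv2 <- extract_features(ci$truth$mask, soma, 1)
  expect_identical(as.numeric(fv), as.numeric(fv2))

  # bare disc: no branches, density ~ 1, Sholl zeros
  sp0 <- cell_spec(c(40, 40), 6, 0, seed = 1)
  c0 <- generate_cell_image(sp0, c(80, 80), 1)
  f0 <- extract_features(c0$truth$mask, as_soma(c0$truth$soma_mask), 1)
  expect_equal(f0[["branches"]], 0)
  expect_equal(f0[["density"]], 1, tolerance = 0.05)
  expect_equal(f0[["sum of intersections"]], 0)
})

test_that("features are translation invariant and scale by dimension", {
  sp <- cell_spec(c(50, 50), 4, 5, 20, 0.05, 0.3, seed = 23)
  ci <- generate_cell_image(sp, c(121, 121), 1)
  soma <- as_soma(ci$truth$soma_mask)
  fv <- extract_features(ci$truth$mask, soma, 1)

  msk_t <- mgmorph:::shift_mat(ci$truth$mask, 6, 11, fill = FALSE)
  som_t <- as_soma(mgmorph:::shift_mat(ci$truth$soma_mask, 6, 11, fill = FALSE))
  fv_t <- extract_features(msk_t, som_t, 1)
  expect_equal(as.numeric(fv_t), as.numeric(fv), tolerance = 1e-9)

  # calibration doubled: linear x2, areas x4, dimensionless unchanged
  fv2 <- extract_features(ci$truth$mask, soma, 2)
  linear <- c("perimeter", "cell spread", "maximum branch length",
              "longest shortest path", "maximum span across hull",
              "convex hull perimeter", "diameter of bounding circle",
              "mean radius", "average branch length")
  areal <- c("mask area", "soma area", "skeleton area", "convex hull area")
  dimless <- c("eccentricity", "roundness", "density", "span ratio",
               "convex hull circularity", "max/min radii", "CV for all radii",
               "fractal dimension", "lacunarity", "branching density",
               "branches", "junctions", "triple points")
  for (nm in linear) expect_equal(fv2[[nm]], 2 * fv[[nm]], tolerance = 1e-9)
  for (nm in areal) expect_equal(fv2[[nm]], 4 * fv[[nm]], tolerance = 1e-9)
  for (nm in dimless) expect_equal(fv2[[nm]], fv[[nm]], tolerance = 0.05 * max(1, abs(fv[[nm]])))
})
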