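test_that("contrast normalisation matches frames to the reference statistics", {
  set.seed(1)
  base <- matrix(runif(32 * 32, 0, 200), 32, 32)
  d <- array(0, dim = c(2, 3, 32, 32))
  for (z in 1:3) {
    d[1, z, , ] <- base
    d[2, z, , ] <- 2 * base  # doubled contrast
  }
  st <- raw_stack(d, range = c(0, 1e6))  # wide range: no clipping effects
  ns <- normalize_contrast(st, reference_plane = 1)
  m_ref <- mean(ns$data[1, 1, , ])
  for (z in 1:3) for (f in 1:2) {
    expect_lt(abs(mean(ns$data[f, z, , ]) - m_ref) / m_ref, 0.01)
    expect_lt(abs(sd(ns$data[f, z, , ]) - sd(ns$data[1, 1, , ])) /
                sd(ns$data[1, 1, , ]), 0.01)
  }

  # constant frame left unscaled, flagged
  d[2, 2, , ] <- 0
  st2 <- raw_stack(d)
  expect_warning(ns2 <- normalize_contrast(st2, 1), "constant")
  expect_true(attr(ns2, "constant_frames")[2, 2])
  expect_equal(ns2$data[2, 2, , ], matrix(0, 32, 32))
})

test_that("blur score: offset invariant, decreasing under blur, zero when flat", {
  expect_equal(blur_score(matrix(5, 16, 16)), 0)
  set.seed(3)
  f <- mgmorph:::blur_gaussian(matrix(runif(64 * 64, 0, 255), 64, 64), 1)
  expect_equal(blur_score(f), blur_score(f + 37), tolerance = 1e-10)
  expect_gt(blur_score(f), blur_score(mgmorph:::blur_gaussian(f, 2)))
  # strictly decreasing under repeated blurring
  cur <- f
  prev_score <- blur_score(cur)
  for (i in 1:5) {
    cur <- mgmorph:::blur_gaussian(cur, 1)
    s <- blur_score(cur)
    expect_lt(s, prev_score)
    prev_score <- s
  }
})

test_that("translation registration recovers shifts and is inverse-consistent", {
  set.seed(4)
  f0 <- mgmorph:::blur_gaussian(matrix(runif(80 * 80, 0, 255), 80, 80), 1.5)
  expect_equal(register_translation(f0, f0)$shift, c(0, 0))
  for (sh in list(c(3, -2), c(-5, 4), c(0, 7))) {
    mv <- mgmorph:::shift_mat(f0, sh[1], sh[2], fill = min(f0))
    r <- register_translation(mv, f0)
    expect_equal(r$shift, sh)
    # inverse consistency
    r_back <- register_translation(f0, mv)
    expect_equal(r_back$shift, -sh)
  }
  # pure noise: shift bounded by the search radius
  n1 <- matrix(rnorm(64 * 64), 64, 64)
  n2 <- matrix(rnorm(64 * 64), 64, 64)
  r <- register_translation(n1, n2, max_shift = 10)
  expect_true(all(abs(r$shift) <= 10))
})

test_that("reference frames favour sharp frames; clean_plane drops artefacts", {
  set.seed(5)
  sharp <- mgmorph:::blur_gaussian(matrix(runif(64 * 64, 0, 255), 64, 64), 1)
  frames_same <- list(sharp, sharp, sharp)
  expect_equal(build_reference_frame(frames_same, 3), sharp)

  blurred <- lapply(c(2, 3, 4, 5, 6), function(s) mgmorph:::blur_gaussian(sharp, s))
  ref1 <- build_reference_frame(c(list(sharp), blurred), k_sharp = 1)
  expect_equal(ref1, sharp)
  expect_error(build_reference_frame(frames_same, 0), "k_sharp")

  # k_sharp=3 on jittered copies: reference at least as sharp as the mean frame
  jit <- lapply(1:6, function(i) {
    mgmorph:::shift_mat(sharp, sample(-2:2, 1), sample(-2:2, 1), fill = min(sharp))
  })
  ref <- build_reference_frame(jit, 3)
  mean_frame <- Reduce(`+`, jit) / length(jit)
  expect_gte(blur_score(ref), blur_score(mean_frame))

  # artefact frame excluded by difference ranking
  art <- sharp
  art[10:30, 10:30] <- 255
  sub <- list(sharp, sharp, art)
  cleaned <- clean_plane(sub, reference = sharp, k_keep = 2)
  expect_false(3 %in% attr(cleaned, "kept"))
  expect_equal(unclass(cleaned), sharp, ignore_attr = TRUE)
})

test_that("reorder_z matches brute force on 3 planes and recovers shuffles", {
  sp <- cell_spec(c(48, 48), 4, 5, 20, 0.05, 0.3, seed = 3)
  # brute force over all 6 orderings of 3 planes: maximise adjacent NCC sum
  for (s in 1:3) {
    g <- generate_raw_stack(sp, stack_corruption(z_permutation = c(2, 1, 3)),
                            1, 3, shape = c(64, 64), seed = s)
    arr <- array(0, dim = c(3, 64, 64))
    for (z in 1:3) arr[z, , ] <- g$stack$data[1, z, , ]
    ro <- reorder_z(arr)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    score <- vapply(perms, function(p) {
      mgmorph:::ncc(arr[p[1], , ], arr[p[2], , ]) +
        mgmorph:::ncc(arr[p[2], , ], arr[p[3], , ])
    }, 0)
    best <- perms[[which.max(score)]]
    same <- all(ro$permutation == best) || all(ro$permutation == rev(best))
    expect_true(same)
    # and the truth: the middle-swap is undone (up to reversal)
    rec <- g$truth$z_order[ro$permutation]
    expect_true(all(rec == 1:3) || all(rec == 3:1))
  }

  # shuffled smooth volumes recovered with Kendall |tau| >= 0.9
  for (s in 1:3) {
    set.seed(s)
    zp <- sample(10)
    g <- generate_raw_stack(sp, stack_corruption(noise_sd = 4, z_permutation = zp),
                            2, 10, shape = c(80, 80), seed = s + 20)
    cs <- clean_stack(g$stack)
    rec <- zp[cs$provenance$z_order]
    expect_gte(abs(cor(rec, 1:10, method = "kendall")), 0.9)
  }

  expect_error(reorder_z(array(0, dim = c(2, 8, 8))), "3 planes")
  expect_warning(ro <- reorder_z(array(1, dim = c(3, 8, 8))), "identical")
  expect_equal(ro$permutation, 1:3)
})

test_that("clean_stack cleans corruption-free stacks and flags ruined planes", {
  sp <- cell_spec(c(40, 40), 4, 4, 15, 0, 0.2, seed = 6)
  g <- generate_raw_stack(sp, stack_corruption(), 3, 5, shape = c(80, 80), seed = 2)
  cs <- clean_stack(g$stack)
  expect_true(all(cs$qc))
  expect_equal(dim(cs$data), c(5, 80, 80))
  # with no corruption each plane equals its truth projection up to rescaling
  cor_truth <- cor(as.numeric(cs$data[1, , ]),
                   as.numeric(g$truth$planes[[cs$provenance$z_order[1]]]))
  expect_gt(cor_truth, 0.98)

  # one irrecoverably corrupted plane gets flagged, others pass
  bad <- g$stack$data
  set.seed(9)
  for (f in 1:3) bad[f, 3, , ] <- matrix(sample(0:255, 80 * 80, TRUE), 80, 80)
  csb <- clean_stack(raw_stack(bad, g$stack$calibration))
  flagged_original <- csb$provenance$z_order[!csb$qc]
  expect_true(3 %in% flagged_original)
  expect_equal(sum(!csb$qc), 1L)
})
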