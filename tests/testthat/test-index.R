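test_that("rank-based AUC equals exhaustive pair counting", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    v <- sample(1:6, n, TRUE)
    lab <- factor(sample(c("a", "b"), n, TRUE))
    if (length(unique(lab)) < 2) next
    r <- roc_auc(v, lab)
    expect_equal(r$auc, brute_auc(v, lab), tolerance = 1e-12)
    expect_equal(r$folded, max(r$auc, 1 - r$auc))
  }
  # frozen oracle value for A = {1,2,3}, B = {2,3,4}
  expect_equal(roc_auc(c(1, 2, 3, 2, 3, 4),
                       factor(rep(c("A", "B"), each = 3)))$auc, 7 / 9)
  # perfect separation and identity
  expect_equal(roc_auc(c(1, 2, 9, 10), factor(c("A", "A", "B", "B")))$folded, 1)
  expect_equal(roc_auc(rep(3, 8), factor(rep(c("A", "B"), 4)))$auc, 0.5)
  expect_error(roc_auc(1:4, factor(rep("A", 4))), "both classes")
})

test_that("feature selection prunes copies, variants and correlated pairs", {
  set.seed(11)
  tab <- as.data.frame(matrix(rnorm(60 * 6), 60, 6))
  names(tab) <- paste0("f", 1:6)
  lab <- factor(rep(c("r", "a"), 30), levels = c("r", "a"))
  tab$f1 <- tab$f1 + ifelse(lab == "a", 2, 0)
  tab$copy <- tab$f1  # r = 1 duplicate
  sel <- select_discriminators(tab, lab, top_n = 4)
  expect_false(all(c("f1", "copy") %in% sel))
  expect_true("f1" %in% sel || "copy" %in% sel)

  # variant family: only the better semi-log variant survives
  tab2 <- tab[, c("f2", "f3")]
  tab2[["regression coefficient (semi-log)"]] <- tab$f1 + rnorm(60, 0, 2)
  tab2[["regression coefficient (semi-log)[P10-P90]"]] <- tab$f1 + rnorm(60, 0, 2)
  expect_warning(sel2 <- select_discriminators(tab2, lab, top_n = 4),
                 "survive")
  fams <- mgmorph:::.variant_family(sel2)
  expect_false(any(duplicated(fams)))

  # constructed effect: selection lands on the informative columns
  set.seed(12)
  tab3 <- as.data.frame(matrix(rnorm(80 * 10), 80, 10))
  names(tab3) <- paste0("g", 1:10)
  lab3 <- factor(rep(c("r", "a"), 40), levels = c("r", "a"))
  for (j in 1:3) tab3[[j]] <- tab3[[j]] + ifelse(lab3 == "a", 1.5, 0)
  sel3 <- select_discriminators(tab3, lab3, top_n = 3)
  expect_true(all(sel3 %in% paste0("g", 1:3)))
})

test_that("fit_index reproduces an independent eigendecomposition", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(20:60, 1); p <- sample(3:8, 1)
    tab <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(tab) <- paste0("f", seq_len(p))
    lab <- factor(rep_len(c("r", "a"), n), levels = c("r", "a"))
    m <- fit_index(tab, lab, names(tab))
    idx <- apply_index(m, tab)
    ev <- eigen(stats::cor(as.matrix(tab)), symmetric = TRUE)
    sc <- scale(as.matrix(tab)) %*% ev$vectors[, 1]
    expect_lt(max(abs(abs(idx) - abs(as.numeric(sc)))), 1e-8)
  }

  # two perfectly correlated features: PC1 explains everything
  x <- rnorm(30)
  tab2 <- data.frame(a = x, b = 2 * x + 3)
  lab2 <- factor(rep_len(c("r", "a"), 30), levels = c("r", "a"))
  m2 <- fit_index(tab2, lab2, c("a", "b"))
  expect_equal(m2$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(as.numeric(m2$loadings)), rep(1 / sqrt(2), 2), tolerance = 1e-12)

  # orientation contract: activated mean is never below resting mean
  set.seed(14)
  tab3 <- data.frame(f = c(rnorm(20, 0), rnorm(20, 3)), g = rnorm(40))
  lab3 <- factor(rep(c("resting", "activated"), each = 20),
                 levels = c("resting", "activated"))
  m3 <- fit_index(tab3, lab3, c("f", "g"))
  idx3 <- apply_index(m3, tab3)
  expect_gte(mean(idx3[lab3 == "activated"]), mean(idx3[lab3 == "resting"]))

  # zero-variance feature dropped with a warning
  tab4 <- data.frame(f = rnorm(30), z = rep(1, 30))
  expect_warning(m4 <- fit_index(tab4, lab2, c("f", "z")), "zero-variance")
  expect_equal(m4$features, "f")
})

test_that("apply_index standardises with training statistics", {
  set.seed(15)
  tab <- as.data.frame(matrix(rnorm(40 * 3), 40, 3))
  names(tab) <- c("a", "b", "c")
  lab <- factor(rep_len(c("r", "x"), 40), levels = c("r", "x"))
  m <- fit_index(tab, lab, names(tab), mask_size = 400)
  # idempotence on training data
  expect_equal(apply_index(m, tab), apply_index(m, tab))
  # linearity: shifting one input column shifts scores along its loading
  tab_s <- tab; tab_s$b <- tab_s$b + 5
  delta <- apply_index(m, tab_s) - apply_index(m, tab)
  expect_equal(delta, rep(m$orientation * m$loadings[["b"]] * 5 / m$scale[["b"]], 40),
               tolerance = 1e-12)
  expect_error(apply_index(m, tab[, 1:2]), "lacks selected")
  expect_warning(apply_index(m, tab, mask_size = 200), "differs")

  # invariance to affine rescaling of a training feature column
  tab_r <- tab; tab_r$a <- 10 * tab_r$a - 7
  m_r <- fit_index(tab_r, lab, names(tab_r))
  expect_equal(abs(apply_index(m_r, tab_r)), abs(apply_index(m, tab)),
               tolerance = 1e-9)
})

test_that("mask-size and feature-count optimisation pick the signal", {
  set.seed(16)
  lab <- factor(rep(c("r", "a"), each = 30), levels = c("r", "a"))
  mk_tab <- function(effect) {
    tab <- as.data.frame(matrix(rnorm(60 * 8), 60, 8))
    names(tab) <- paste0("f", 1:8)
    for (j in 1:3) tab[[j]] <- tab[[j]] + ifelse(lab == "a", effect, 0)
    tab
  }
  tabs <- list(`200` = mk_tab(0), `300` = mk_tab(2), `400` = mk_tab(0))
  ms <- choose_mask_size(tabs, lab, method = "auc", top_n = 3)
  expect_equal(as.numeric(ms), 300)
  # single mask size returned unchanged
  expect_equal(as.numeric(choose_mask_size(tabs["400"], lab)), 400)

  # two informative features: small n chosen, informative pair included
  set.seed(17)
  tab <- as.data.frame(matrix(rnorm(80 * 12), 80, 12))
  names(tab) <- paste0("f", 1:12)
  lab2 <- factor(rep(c("r", "a"), 40), levels = c("r", "a"))
  tab$f1 <- tab$f1 + ifelse(lab2 == "a", 2.5, 0)
  tab$f2 <- tab$f2 + ifelse(lab2 == "a", 2.5, 0)
  m <- optimize_feature_count(tab, lab2, N_max = 8)
  expect_lte(attr(m, "n_selected"), 4)
  expect_true(all(c("f1", "f2") %in% select_discriminators(tab, lab2, 2)))
  # argmax contract
  scores <- attr(m, "scores")
  expect_gte(scores[attr(m, "n_selected")], max(scores) - 1e-12)
  # N_max = 1: single best discriminator
  m1 <- optimize_feature_count(tab, lab2, N_max = 1)
  expect_equal(m1$n_features, 1L)
})

test_that("condition comparison respects animal clustering", {
  # identical values in both conditions: zero effect, p = 1
  v <- rep(c(1.2, 3.4, 2.2, 5.1, 0.7), 4)
  cond <- factor(rep(c("r", "a"), each = 10), levels = c("r", "a"))
  an <- factor(rep(rep(c("m1", "m2"), each = 5), 2))
  cc <- compare_conditions(v, cond, an)
  expect_equal(cc$estimate, 0, tolerance = 1e-6)
  expect_equal(cc$effect_size, 0, tolerance = 1e-12)
  expect_gt(cc$p_value, 0.99)

  # animal-level clustering without condition effect: the mixed model is more
  # conservative than the animal-ignoring t-test
  set.seed(18)
  n_per <- 12
  animals <- factor(rep(paste0("m", 1:6), each = n_per))
  cond2 <- factor(rep(rep(c("r", "a"), each = 3 * n_per)), levels = c("r", "a"))
  intercepts <- rnorm(6, 0, 2)
  vals <- intercepts[as.integer(animals)] + rnorm(6 * n_per, 0, 0.5)
  cc2 <- compare_conditions(vals, cond2, animals)
  naive_p <- stats::t.test(vals ~ cond2)$p.value
  expect_equal(cc2$method, "lmm")
  expect_gt(cc2$p_value, naive_p)

  # hand-computed Cohen's d on a 4-point table
  v4 <- c(1, 3, 2, 6)
  c4 <- factor(c("r", "r", "a", "a"), levels = c("r", "a"))
  d_hand <- (mean(c(2, 6)) - mean(c(1, 3))) /
    sqrt((stats::var(c(1, 3)) + stats::var(c(2, 6))) / 2)
  cc4 <- compare_conditions(v4, c4, NULL)
  expect_equal(cc4$effect_size, d_hand, tolerance = 1e-12)
  expect_equal(cc4$method, "t_test")
})

test_that("index models serialise to JSON and back", {
  set.seed(19)
  tab <- as.data.frame(matrix(rnorm(30 * 4), 30, 4))
  names(tab) <- paste0("f", 1:4)
  lab <- factor(rep_len(c("r", "a"), 30), levels = c("r", "a"))
  m <- fit_index(tab, lab, names(tab), mask_size = 400)
  path <- withr::local_tempfile(fileext = ".json")
  write_index_model(m, path)
  m2 <- read_index_model(path)
  expect_equal(apply_index(m2, tab), apply_index(m, tab), tolerance = 1e-12)
  expect_equal(m2$mask_size, 400)
})
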