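# Shared fixtures: all synthetic, built in code at test time.

# Emulate acquisition corruption of a rendered cell image: optical blur plus
# additive Gaussian noise, clipped to the 8-bit range.
corrupt_image <- function(img, seed, noise_sd = 8, blur = 1) {
  set.seed(seed)
  b <- mgmorph:::blur_gaussian(img, blur)
  pmax(pmin(b + matrix(rnorm(length(img), 0, noise_sd), nrow(img)), 255), 0)
}

# A noiseless star cell (straight arms, no secondary branching).
make_star <- function(arms, soma_r = 5, arm_len = 30, n = 121, seed = arms * 7) {
  sp <- cell_spec(c((n + 1) / 2, (n + 1) / 2), soma_r, arms, arm_len,
                  branch_prob = 0, tortuosity = 0, seed = seed)
  generate_cell_image(sp, c(n, n), 1)
}

as_soma <- function(mask) {
  structure(list(mask = mask, area = sum(mask), circularity = 1,
                 origin = "automatic"), class = "soma_mask")
}

# Exhaustive pair-counting AUC oracle (ties at 1/2).
brute_auc <- function(values, labels) {
  labels <- as.factor(labels)
  pos <- values[labels == levels(labels)[2L]]
  neg <- values[labels == levels(labels)[1L]]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Feature table with latent correlation structure but exchangeable rows
# (used for the zero-effect null control).
null_feature_table <- function(n, seed, k = 6) {
  set.seed(seed)
  L <- matrix(rnorm(62 * k, 0, 0.6), 62, k)
  f <- matrix(rnorm(n * k), n, k)
  x <- f %*% t(L) + matrix(rnorm(n * 62), n, 62)
  df <- as.data.frame(x)
  names(df) <- feature_names()
  df
}

# Render, segment and measure every cell of a condition dataset; returns a
# data frame of the 62 features plus a `cond` column (accepted cells only).
measure_dataset <- function(ds, base_seed, MS = 300, shape = c(144L, 144L)) {
  rows <- list()
  for (i in seq_along(ds$specs)) {
    ci <- generate_cell_image(ds$specs[[i]], shape, 1)
    img <- corrupt_image(ci$image, base_seed + i)
    seeds <- detect_seeds(img, calibration = 1)
    if (!nrow(seeds)) next
    er <- extract_roi(img, seeds[1L, ], 1)
    cm <- segment_cell(er$roi, er$seed, MS = MS, limit = 100, calibration = 1)
    if (cm$status != "accepted") next
    soma <- detect_soma(er$roi, cm$mask, 1)
    if (is.null(soma)) next
    fv <- extract_features(cm$mask, soma, 1)
    rows[[length(rows) + 1L]] <- c(list(cond = as.character(ds$condition[i]),
                                        animal = as.character(ds$animal[i])),
                                   as.list(fv))
  }
  nm <- names(rows[[1L]])
  do.call(rbind, lapply(rows, function(r) as.data.frame(r[nm], check.names = FALSE)))
}
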