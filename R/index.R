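# The inflammation index: rank morphology features by their ability to
# discriminate a training condition pair (ROC-AUC), drop redundant variants
# and highly correlated features, run a centred/scaled PCA on the survivors,
# and use the first principal component -- oriented so activated cells score
# higher -- as a single morphology index that can be applied to novel data.

#' Rank-based ROC AUC
#'
#' Computes the probability that a random value from the positive class
#' exceeds one from the negative class, ties counted 1/2 (Mann-Whitney).
#'
#' @param values numeric vector.
#' @param labels factor (or coercible) with exactly two levels; the second
#'   level is the positive class.
#' @return list with `auc`, `folded` = max(auc, 1 - auc), and `direction`
#'   (+1 when larger values favour the positive class).
#' @export
roc_auc <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L || length(unique(labels)) != 2L) {
    stop("need both classes present for ROC analysis")
  }
  pos <- labels == levels(labels)[2L]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, folded = max(auc, 1 - auc),
       direction = if (auc >= 0.5) 1 else -1)
}

# Variant families of Table-style feature names: within a family only the
# best discriminator is kept. Unlisted features are their own family.
.variant_family <- function(feature) {
  fam <- sub("\\[P10-P90\\]$", "", feature)
  fam <- sub(" \\(sampled\\)$| \\(fit\\)$", "", fam)
  fam <- sub(" from circle's centre$", "", fam)
  fam <- sub(" from hull's centre of mass$", "", fam)
  fam
}

#' Select the best discriminating features
#'
#' Ranks all features by folded AUC, keeps the best member of each variant
#' family (percentile-window, sampled/fit, hull-centre/circle-centre
#' duplicates), then greedily drops the lower-ranked member of any remaining
#' pair with |Pearson r| >= `r_max`, and returns the top `top_n` survivors
#' in rank order.
#'
#' @param table data frame of feature columns (cells x features).
#' @param labels two-level factor, one entry per row.
#' @param top_n number of features to return.
#' @param r_max correlation-pruning threshold (default 0.9).
#' @param prune run variant/correlation pruning before taking the top n
#'   (default TRUE; FALSE reproduces a plain AUC ranking cut).
#' @return character vector of feature names (warns when fewer than `top_n`
#'   survive); attribute `auc` carries the folded AUCs.
#' @export
select_discriminators <- function(table, labels, top_n = 5L, r_max = 0.9,
                                  prune = TRUE) {
  stopifnot(top_n >= 1L)
  feats <- colnames(table)
  ok <- vapply(feats, function(f) {
    v <- table[[f]]
    all(is.finite(v)) && stats::sd(v) > 0
  }, TRUE)
  feats <- feats[ok]
  aucs <- vapply(feats, function(f) roc_auc(table[[f]], labels)$folded, 0)
  ord <- order(-aucs)  # stable: ties keep column order
  ranked <- feats[ord]
  if (prune) {
    # variant families: keep the best-ranked member of each
    fams <- .variant_family(ranked)
    ranked <- ranked[!duplicated(fams)]
    # greedy correlation pruning from the top
    kept <- character(0)
    for (f in ranked) {
      if (!length(kept)) { kept <- f; next }
      r <- vapply(kept, function(k) {
        suppressWarnings(abs(stats::cor(table[[f]], table[[k]])))
      }, 0)
      if (all(is.na(r) | r < r_max)) kept <- c(kept, f)
    }
    ranked <- kept
  }
  if (length(ranked) < top_n) {
    warning("only ", length(ranked), " features survive selection")
  }
  out <- utils::head(ranked, top_n)
  attr(out, "auc") <- aucs[out]
  out
}

#' Fit the PCA index on selected features
#'
#' Standardises the selected columns by their training mean/SD, takes the
#' first principal component, and fixes the orientation so that the mean
#' score of the activated condition (second factor level) is at least that
#' of the resting condition.
#'
#' @param table data frame of features.
#' @param labels two-level factor (second level = activated).
#' @param features character vector of feature names to combine.
#' @param mask_size mask size the features were extracted at (metadata).
#' @return object of class `index_model`: `features`, `center`, `scale`,
#'   `loadings` (unit norm), `orientation` (+-1), `mask_size`, `n_features`,
#'   `var_explained`.
#' @export
fit_index <- function(table, labels, features, mask_size = NA_real_) {
  stopifnot(length(features) >= 1L, nrow(table) >= 3L)
  labels <- as.factor(labels)
  x <- as.matrix(table[, features, drop = FALSE])
  if (any(!is.finite(x))) stop("non-finite feature values in training data")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  drop <- scl == 0
  if (any(drop)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[drop], collapse = ", "))
    features <- features[!drop]
    x <- x[, !drop, drop = FALSE]
    ctr <- ctr[!drop]; scl <- scl[!drop]
    if (!length(features)) stop("no features left after dropping")
  }
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  if (length(features) == 1L) {
    loadings <- 1
    scores <- z[, 1L]
    ve <- 1
  } else {
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    loadings <- pc$rotation[, 1L]
    scores <- z %*% loadings
    ve <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  }
  orientation <- if (mean(scores[labels == levels(labels)[2L]]) >=
                     mean(scores[labels == levels(labels)[1L]])) 1 else -1
  structure(list(features = features,
                 center = stats::setNames(as.numeric(ctr), features),
                 scale = stats::setNames(as.numeric(scl), features),
                 loadings = stats::setNames(as.numeric(loadings), features),
                 orientation = orientation,
                 mask_size = mask_size,
                 n_features = length(features),
                 var_explained = ve),
            class = "index_model")
}

#' Apply a fitted index to (novel) data
#'
#' Standardises with the model's training centre/scale -- never the new
#' data's -- projects on the stored loadings and applies the orientation.
#' Rows with missing selected features get `NA`.
#'
#' @param model an `index_model`.
#' @param table data frame containing all the model's feature columns.
#' @param mask_size optional mask size of `table`, checked against the model.
#' @return numeric vector of per-cell index values.
#' @export
apply_index <- function(model, table, mask_size = NULL) {
  missing_cols <- setdiff(model$features, colnames(table))
  if (length(missing_cols)) {
    stop("table lacks selected feature(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(mask_size) && !is.na(model$mask_size) &&
      mask_size != model$mask_size) {
    warning("mask size ", mask_size, " differs from the model's ",
            model$mask_size)
  }
  x <- as.matrix(table[, model$features, drop = FALSE])
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  as.numeric(z %*% model$loadings) * model$orientation
}

#' Choose the mask size whose index best separates the training conditions
#'
#' For every mask size a preliminary index (top `top_n` pruned
#' discriminators) is built and scored: by its ROC AUC (`method = "auc"`) or
#' by the random-intercept-model p-value of the condition effect
#' (`method = "lmm_p"`, needs `animal`). Ties go to the smaller mask size.
#'
#' @param tables named list, mask size -> feature data frame.
#' @param labels_list list of label factors matching `tables` rows (or one
#'   factor shared by all).
#' @param method "auc" or "lmm_p".
#' @param top_n discriminators per preliminary index.
#' @param animal_list per-table animal factors (for `lmm_p`).
#' @return chosen mask size (numeric), with attribute `scores`.
#' @export
choose_mask_size <- function(tables, labels_list, method = c("auc", "lmm_p"),
                             top_n = 5L, animal_list = NULL) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 1L)
  sizes <- as.numeric(names(tables))
  if (!is.list(labels_list) || is.factor(labels_list)) {
    labels_list <- rep(list(labels_list), length(tables))
  }
  scores <- vapply(seq_along(tables), function(i) {
    tab <- tables[[i]]; lab <- as.factor(labels_list[[i]])
    feats <- select_discriminators(tab, lab, top_n = top_n)
    m <- fit_index(tab, lab, feats, mask_size = sizes[i])
    idx <- apply_index(m, tab)
    if (method == "auc") {
      roc_auc(idx, lab)$folded
    } else {
      an <- animal_list[[i]]
      -log10(compare_conditions(idx, lab, an)$p_value)
    }
  }, 0)
  ord <- order(-scores, sizes)
  out <- sizes[ord[1L]]
  attr(out, "scores") <- stats::setNames(scores, names(tables))
  out
}

#' Optimise the number of features in the index
#'
#' Rebuilds the index from the best 1..`N_max` pruned discriminators and
#' keeps the count whose index separates the training conditions best
#' (largest AUC or smallest mixed-model p-value); ties go to fewer features.
#'
#' @param table feature data frame at the chosen mask size.
#' @param labels two-level factor.
#' @param N_max maximum number of discriminators (default 15).
#' @param method "auc" or "lmm_p".
#' @param animal animal factor for `lmm_p`.
#' @param mask_size stored in the returned model.
#' @return the selected `index_model`, with attributes `scores` (per n) and
#'   `n_selected`.
#' @export
optimize_feature_count <- function(table, labels, N_max = 15L,
                                   method = c("auc", "lmm_p"), animal = NULL,
                                   mask_size = NA_real_) {
  method <- match.arg(method)
  stopifnot(N_max >= 1L)
  labels <- as.factor(labels)
  ranked <- suppressWarnings(select_discriminators(table, labels, top_n = N_max))
  scores <- numeric(0)
  models <- list()
  for (n in seq_len(min(N_max, length(ranked)))) {
    m <- fit_index(table, labels, ranked[seq_len(n)], mask_size = mask_size)
    idx <- apply_index(m, table)
    s <- if (method == "auc") roc_auc(idx, labels)$folded else
      -log10(compare_conditions(idx, labels, animal)$p_value)
    scores <- c(scores, s)
    models[[n]] <- m
  }
  best <- which.max(scores)  # first max: ties go to fewer features
  out <- models[[best]]
  attr(out, "scores") <- scores
  attr(out, "n_selected") <- best
  out
}

#' Compare conditions with a random-intercept model
#'
#' Fits `index ~ condition + (1 | animal)` and reports the condition
#' coefficient, a likelihood-ratio p-value (ML refit against the
#' intercept-only model), and Cohen's d with pooled SD. With fewer than two
#' animals per condition it falls back to a Welch t-test (flagged).
#'
#' @param index numeric per-cell index values.
#' @param condition two-level factor.
#' @param animal factor of animal identifiers.
#' @return list: `estimate`, `p_value`, `effect_size`, `method`.
#' @export
compare_conditions <- function(index, condition, animal) {
  condition <- as.factor(condition)
  g1 <- index[condition == levels(condition)[1L]]
  g2 <- index[condition == levels(condition)[2L]]
  n1 <- length(g1); n2 <- length(g2)
  sp <- sqrt(((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
               (n1 + n2 - 2))
  d <- if (sp > 0) (mean(g2) - mean(g1)) / sp else 0
  enough_animals <- !is.null(animal) &&
    all(tapply(animal, condition, function(a) length(unique(a))) >= 2L)
  if (enough_animals) {
    df <- data.frame(index = index, condition = condition,
                     animal = as.factor(animal))
    m1 <- lme4::lmer(index ~ condition + (1 | animal), data = df, REML = FALSE)
    m0 <- lme4::lmer(index ~ 1 + (1 | animal), data = df, REML = FALSE)
    a <- stats::anova(m0, m1)
    p <- a$`Pr(>Chisq)`[2L]
    est <- lme4::fixef(m1)[[2L]]
    list(estimate = est, p_value = p, effect_size = d, method = "lmm")
  } else {
    tt <- stats::t.test(g2, g1)
    list(estimate = mean(g2) - mean(g1),
         p_value = tt$p.value, effect_size = d, method = "t_test")
  }
}

#' Serialise / restore an index model as JSON
#' @param model an `index_model`.
#' @param path file path.
#' @return `path` invisibly; `read_index_model` returns the model.
#' @export
write_index_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index_model
#' @export
read_index_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$center <- unlist(m$center); m$scale <- unlist(m$scale)
  m$loadings <- unlist(m$loadings)
  structure(m, class = "index_model")
}
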