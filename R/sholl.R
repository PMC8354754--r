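# Sholl analysis: intersection counts of the cell's processes with
# concentric circles around the soma centroid, a best-fit polynomial chosen
# by BIC, and the 27 profile descriptors (sampled statistics, fit statistics,
# and semi-log / log-log regressions, each also restricted to the 10th-90th
# radius percentiles).

# Count distinct crossings of `mask` with the circle of radius r_px around
# (cy, cx): mask pixels inside the annulus |d - r| <= band are clustered by
# angle; each angular cluster is one crossing.
.circle_crossings <- function(mask, cy, cx, r_px, band = 0.75) {
  idx <- which(mask)
  if (!length(idx) || r_px <= 0) return(0L)
  nr <- nrow(mask)
  ys <- ((idx - 1L) %% nr) + 1L
  xs <- ((idx - 1L) %/% nr) + 1L
  d <- sqrt((ys - cy)^2 + (xs - cx)^2)
  sel <- abs(d - r_px) <= band
  if (!any(sel)) return(0L)
  ang <- sort(atan2(ys[sel] - cy, xs[sel] - cx))
  if (length(ang) == 1L) return(1L)
  gap_thresh <- max(0.07, 3.2 / r_px)
  gaps <- diff(ang)
  wrap_gap <- 2 * pi - (ang[length(ang)] - ang[1L])
  n_splits <- sum(gaps > gap_thresh)
  if (wrap_gap > gap_thresh) n_splits + 1L else max(1L, n_splits)
}

#' Sholl intersection profile of a cell mask
#'
#' Circles are centred on the soma centroid, starting at the soma equivalent
#' radius and stepping by `step_um`. The best-fit polynomial degree is chosen
#' by BIC among degrees 1..min(30, n - 2).
#'
#' @param mask logical cell mask.
#' @param soma `soma_mask` object (or logical matrix).
#' @param calibration micrometres per pixel.
#' @param step_um radius step (default 2 um).
#' @return object of class `sholl_profile`: `radii` (um), `counts`, `fit`
#'   (list with degree, coefficients, fitted values at the sampled radii),
#'   `center` (y, x pixels), `soma_radius` (um). Empty profile (0 radii) when
#'   no mask pixel lies beyond the soma radius.
#' @export
sholl_profile <- function(mask, soma, calibration = 1, step_um = 2) {
  soma_mask <- if (inherits(soma, "soma_mask")) soma$mask else soma
  idx <- which(soma_mask)
  stopifnot(length(idx) > 0)
  nr <- nrow(mask)
  cy <- mean(((idx - 1L) %% nr) + 1L)
  cx <- mean(((idx - 1L) %/% nr) + 1L)
  r0_px <- sqrt(sum(soma_mask) / pi)
  midx <- which(mask)
  d <- sqrt(((((midx - 1L) %% nr) + 1L) - cy)^2 +
            ((((midx - 1L) %/% nr) + 1L) - cx)^2)
  rmax_px <- max(d)
  step_px <- step_um / calibration
  if (rmax_px <= r0_px + step_px / 2) {
    return(structure(list(radii = numeric(0), counts = integer(0),
                          fit = NULL, center = c(cy, cx),
                          soma_radius = r0_px * calibration),
                     class = "sholl_profile"))
  }
  radii_px <- seq(r0_px, rmax_px + step_px, by = step_px)
  counts <- vapply(radii_px, function(r) .circle_crossings(mask, cy, cx, r), 0L)
  radii <- radii_px * calibration
  fit <- .fit_sholl_poly(radii, counts)
  structure(list(radii = radii, counts = counts, fit = fit,
                 center = c(cy, cx), soma_radius = r0_px * calibration),
            class = "sholl_profile")
}

# Best polynomial by BIC; returns degree, coefficients and fitted values.
.fit_sholl_poly <- function(radii, counts) {
  n <- length(radii)
  if (n < 3L) {
    return(list(degree = 0L, coefficients = mean(counts),
                fitted = rep(mean(counts), n)))
  }
  max_deg <- min(30L, n - 2L)
  best <- NULL; best_bic <- Inf
  tiny_rss <- 1e-10 * max(1, sum(counts^2))
  for (deg in seq_len(max_deg)) {
    fit <- tryCatch(stats::lm(counts ~ stats::poly(radii, deg, raw = TRUE)),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) next
    cand <- list(degree = deg, coefficients = unname(stats::coef(fit)),
                 fitted = unname(stats::fitted(fit)))
    if (sum(stats::resid(fit)^2) < tiny_rss) {
      # numerically perfect fit: keep the lowest such degree
      if (is.null(best) || best_bic > -Inf) best <- cand
      best_bic <- -Inf
      break
    }
    bic <- stats::BIC(fit)
    if (is.finite(bic) && bic < best_bic - 1e-9) {
      best_bic <- bic
      best <- cand
    }
  }
  if (is.null(best)) {
    best <- list(degree = 0L, coefficients = mean(counts),
                 fitted = rep(mean(counts), n))
  }
  best
}

.poly_eval <- function(coefficients, x) {
  out <- 0
  for (i in seq_along(coefficients)) out <- out + coefficients[i] * x^(i - 1L)
  out
}

# log10 regression of counts on radius (semi-log) or log10 radius (log-log);
# zero counts excluded. Returns c(slope, intercept), zeros when degenerate.
.sholl_regression <- function(radii, counts, loglog = FALSE) {
  sel <- counts > 0 & radii > 0
  if (sum(sel) < 2L) return(c(0, 0))
  x <- if (loglog) log10(radii[sel]) else radii[sel]
  y <- log10(counts[sel])
  if (stats::sd(x) == 0) return(c(0, 0))
  fit <- stats::lm(y ~ x)
  c(unname(stats::coef(fit)[2L]), unname(stats::coef(fit)[1L]))
}

.SHOLL_NAMES <- c(
  "primary branches", "intersecting radii", "sum of intersections",
  "mean of intersections", "median of intersections",
  "skewness (sampled)", "skewness (fit)", "kurtosis (sampled)",
  "kurtosis (fit)", "maximum number of intersections",
  "max intersection radius", "ramification index (sampled)",
  "ramification index (fit)", "centroid radius", "centroid value",
  "enclosing radius", "critical radius", "mean value", "polynomial degree",
  "regression coefficient (semi-log)",
  "regression coefficient (semi-log)[P10-P90]",
  "regression coefficient (log-log)",
  "regression coefficient (log-log)[P10-P90]",
  "regression intercept (semi-log)",
  "regression intercept (semi-log)[P10-P90]",
  "regression intercept (log-log)",
  "regression intercept (log-log)[P10-P90]")

#' The 27 Sholl descriptors
#'
#' Sampled statistics come from the raw intersection counts, fit statistics
#' from the polynomial evaluated at the sampled radii, and the four
#' regressions from log10 of the positive counts (whole profile and within
#' the 10th-90th percentile radius window). Primary branches are counted as
#' skeleton crossings of a circle one pixel outside the soma equivalent
#' radius.
#'
#' @param profile a [sholl_profile()].
#' @param skeleton logical skeleton matrix (for primary branches).
#' @param calibration micrometres per pixel.
#' @return named numeric vector of 27 features; an empty profile yields
#'   all zeros except primary branches.
#' @export
sholl_descriptors <- function(profile, skeleton, calibration = 1) {
  out <- stats::setNames(numeric(length(.SHOLL_NAMES)), .SHOLL_NAMES)
  r0_px <- profile$soma_radius / calibration
  primary <- .circle_crossings(skeleton, profile$center[1L], profile$center[2L],
                               r0_px + 1, band = 0.8)
  out["primary branches"] <- primary
  r <- profile$radii; cnt <- as.numeric(profile$counts)
  if (!length(r) || all(cnt == 0)) return(out)
  fitv <- profile$fit$fitted
  out["intersecting radii"] <- sum(cnt > 0)
  out["sum of intersections"] <- sum(cnt)
  out["mean of intersections"] <- mean(cnt)
  out["median of intersections"] <- stats::median(cnt)
  out["skewness (sampled)"] <- skewness_g1(cnt)
  out["skewness (fit)"] <- skewness_g1(fitv)
  out["kurtosis (sampled)"] <- kurtosis_m4(cnt)
  out["kurtosis (fit)"] <- kurtosis_m4(fitv)
  out["maximum number of intersections"] <- max(cnt)
  out["max intersection radius"] <- r[which.max(cnt)]
  out["ramification index (sampled)"] <- if (primary > 0) max(cnt) / primary else 0
  out["ramification index (fit)"] <- if (primary > 0) max(fitv) / primary else 0
  # area centroid of the linear profile (piecewise-constant convention)
  out["centroid radius"] <- sum(r * cnt) / sum(cnt)
  out["centroid value"] <- sum(cnt^2) / (2 * sum(cnt))
  out["enclosing radius"] <- max(r[cnt > 0])
  # critical radius / mean value from the fit on a dense grid
  grid <- seq(min(r), max(r), length.out = 256L)
  gv <- .poly_eval(profile$fit$coefficients, grid)
  if (length(grid) > 2L) {
    dg <- diff(gv)
    locmax <- which(dg[-length(dg)] > 0 & dg[-1L] <= 0) + 1L
    out["critical radius"] <- if (length(locmax)) grid[locmax[which.max(gv[locmax])]]
                              else grid[which.max(gv)]
  } else {
    out["critical radius"] <- grid[which.max(gv)]
  }
  out["mean value"] <- mean(gv)
  out["polynomial degree"] <- profile$fit$degree
  sl <- .sholl_regression(r, cnt, loglog = FALSE)
  ll <- .sholl_regression(r, cnt, loglog = TRUE)
  qs <- stats::quantile(r, c(0.1, 0.9), names = FALSE)
  win <- r >= qs[1L] & r <= qs[2L]
  slw <- .sholl_regression(r[win], cnt[win], loglog = FALSE)
  llw <- .sholl_regression(r[win], cnt[win], loglog = TRUE)
  out["regression coefficient (semi-log)"] <- sl[1L]
  out["regression coefficient (semi-log)[P10-P90]"] <- slw[1L]
  out["regression coefficient (log-log)"] <- ll[1L]
  out["regression coefficient (log-log)[P10-P90]"] <- llw[1L]
  out["regression intercept (semi-log)"] <- sl[2L]
  out["regression intercept (semi-log)[P10-P90]"] <- slw[2L]
  out["regression intercept (log-log)"] <- ll[2L]
  out["regression intercept (log-log)[P10-P90]"] <- llw[2L]
  out
}
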