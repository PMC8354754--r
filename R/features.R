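# Morphology descriptors: simple shape, convex hull / circularity
# morphometrics, box-counting fractal dimension and lacunarity, and the
# assembler producing the full 62-feature vector per cell.

.SIMPLE_NAMES <- c("perimeter", "cell spread", "eccentricity", "roundness",
                   "soma area", "mask area")

.HULL_NAMES <- c(
  "density", "span ratio", "maximum span across hull", "convex hull area",
  "convex hull perimeter", "convex hull circularity",
  "maximum radius from hull's centre of mass", "max/min radii",
  "CV for all radii", "mean radius", "diameter of bounding circle",
  "maximum radius from circle's centre", "max/min radii from circle's centre",
  "CV for all radii from circle's centre", "mean radius from circle's centre")

#' All 62 feature names, in canonical order
#' @return character vector of length 62.
#' @export
feature_names <- function() {
  c(.SIMPLE_NAMES,
    c("branches", "junctions", "endpoint voxels", "junction voxels",
      "slab voxels", "average branch length", "triple points",
      "quadruple points", "maximum branch length", "longest shortest path",
      "skeleton area"),
    .SHOLL_NAMES,
    .HULL_NAMES,
    c("fractal dimension", "lacunarity"),
    "branching density")
}

.mask_coords <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  cbind(y = ((idx - 1L) %% nr) + 1L, x = ((idx - 1L) %/% nr) + 1L)
}

#' Simple shape descriptors
#'
#' Perimeter from the traced boundary; cell spread = mean distance from the
#' mask centre of mass to its four extremities (left/right/top/bottom-most
#' pixels); eccentricity = major/minor axis ratio of the second-moment
#' ellipse; roundness = its inverse.
#'
#' @param mask logical cell mask (non-empty).
#' @param soma `soma_mask` or logical matrix.
#' @param calibration micrometres per pixel.
#' @return named numeric vector of 6 features.
#' @export
shape_descriptors <- function(mask, soma, calibration = 1) {
  if (!any(mask)) stop("empty mask")
  soma_mask <- if (inherits(soma, "soma_mask")) soma$mask else soma
  co <- .mask_coords(mask)
  per <- trace_boundary(mask)$perimeter * calibration
  cy <- mean(co[, "y"]); cx <- mean(co[, "x"])
  ext <- rbind(co[which.min(co[, "x"]), ], co[which.max(co[, "x"]), ],
               co[which.min(co[, "y"]), ], co[which.max(co[, "y"]), ])
  spread <- mean(sqrt((ext[, "y"] - cy)^2 + (ext[, "x"] - cx)^2)) * calibration
  if (nrow(co) > 2L) {
    cv <- stats::cov(co)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ecc <- if (ev[2L] > 1e-12) sqrt(ev[1L] / ev[2L]) else Inf
  } else ecc <- 1
  c("perimeter" = per, "cell spread" = spread,
    "eccentricity" = ecc, "roundness" = if (is.finite(ecc)) 1 / ecc else 0,
    "soma area" = sum(soma_mask) * calibration^2,
    "mask area" = sum(mask) * calibration^2)
}

# Exact minimum enclosing circle of a small point set (brute force over
# pairs and triples; the input is a convex hull, so this stays tiny).
.min_enclosing_circle <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1L, ], radius = 0))
  contains_all <- function(c, r) all((pts[, 1L] - c[1L])^2 + (pts[, 2L] - c[2L])^2 <= r^2 + 1e-9)
  best_r <- Inf; best_c <- pts[1L, ]
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    c <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - c)^2))
    if (r < best_r && contains_all(c, r)) { best_r <- r; best_c <- c }
  }
  if (n >= 3L) for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    d <- 2 * (a[1L] * (b[2L] - cc[2L]) + b[1L] * (cc[2L] - a[2L]) + cc[1L] * (a[2L] - b[2L]))
    if (abs(d) < 1e-12) next
    ux <- (sum(a^2) * (b[2L] - cc[2L]) + sum(b^2) * (cc[2L] - a[2L]) +
             sum(cc^2) * (a[2L] - b[2L])) / d
    uy <- (sum(a^2) * (cc[1L] - b[1L]) + sum(b^2) * (a[1L] - cc[1L]) +
             sum(cc^2) * (b[1L] - a[1L])) / d
    c0 <- c(ux, uy)
    r <- sqrt(sum((a - c0)^2))
    if (r < best_r && contains_all(c0, r)) { best_r <- r; best_c <- c0 }
  }
  list(center = best_c, radius = best_r)
}

# Area and centroid of a simple polygon (shoelace); vertices as (x, y) rows.
.polygon_area_centroid <- function(v) {
  n <- nrow(v)
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    return(list(area = 0, centroid = c(mean(x), mean(y))))
  }
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  list(area = abs(a), centroid = c(cx, cy))
}

#' Convex hull and circularity morphometrics (15 features)
#'
#' Hull of the mask pixel centres; radii are measured from both the hull's
#' centre of mass and the centre of the exact minimum bounding circle to the
#' hull vertices.
#'
#' @param mask logical mask with at least 3 pixels.
#' @param calibration micrometres per pixel.
#' @return named numeric vector of 15 features.
#' @export
hull_descriptors <- function(mask, calibration = 1) {
  co <- .mask_coords(mask)
  pts <- cbind(co[, "x"], co[, "y"])  # (x, y)
  h <- grDevices::chull(pts)
  hv <- pts[h, , drop = FALSE]
  out <- stats::setNames(numeric(length(.HULL_NAMES)), .HULL_NAMES)
  pac <- .polygon_area_centroid(hv)
  degenerate <- nrow(hv) < 3L || pac$area == 0
  # pairwise spans between hull vertices
  dmat <- as.matrix(stats::dist(hv))
  max_span <- max(dmat)
  # minor extent: largest spread perpendicular to the max-span direction
  ij <- which(dmat == max_span, arr.ind = TRUE)[1L, ]
  dir <- hv[ij[2L], ] - hv[ij[1L], ]
  nrm <- sqrt(sum(dir^2))
  minor <- if (nrm > 0) {
    perp <- c(-dir[2L], dir[1L]) / nrm
    proj <- hv %*% perp
    diff(range(proj))
  } else 0
  hull_per <- sum(sqrt(rowSums((hv - hv[c(2:nrow(hv), 1L), , drop = FALSE])^2)))
  mbc <- .min_enclosing_circle(hv)
  radii_h <- sqrt((hv[, 1L] - pac$centroid[1L])^2 + (hv[, 2L] - pac$centroid[2L])^2)
  radii_c <- sqrt((hv[, 1L] - mbc$center[1L])^2 + (hv[, 2L] - mbc$center[2L])^2)
  cv <- function(x) if (mean(x) > 0) stats::sd(x) / mean(x) else 0
  ratio <- function(x) if (min(x) > 1e-9) max(x) / min(x) else 0
  out["density"] <- if (degenerate) 0 else nrow(co) / (pac$area / 1)  # px/px
  out["span ratio"] <- if (minor > 1e-9) max_span / minor else 0
  out["maximum span across hull"] <- max_span * calibration
  out["convex hull area"] <- pac$area * calibration^2
  out["convex hull perimeter"] <- hull_per * calibration
  out["convex hull circularity"] <- if (degenerate || hull_per == 0) 0 else
    min(1, 4 * pi * pac$area / hull_per^2)
  out["maximum radius from hull's centre of mass"] <- max(radii_h) * calibration
  out["max/min radii"] <- ratio(radii_h)
  out["CV for all radii"] <- cv(radii_h)
  out["mean radius"] <- mean(radii_h) * calibration
  out["diameter of bounding circle"] <- 2 * mbc$radius * calibration
  out["maximum radius from circle's centre"] <- max(radii_c) * calibration
  out["max/min radii from circle's centre"] <- ratio(radii_c)
  out["CV for all radii from circle's centre"] <- cv(radii_c)
  out["mean radius from circle's centre"] <- mean(radii_c) * calibration
  # density uses calibrated areas (both scale alike, so this is px-based)
  out["density"] <- if (degenerate) 0 else min(1, nrow(co) / pac$area)
  out
}

#' Box-counting fractal dimension and lacunarity
#'
#' Fractal dimension: minus the slope of log(box count) vs log(box size)
#' over dyadic box sizes, counts averaged over 4 grid offsets, computed on
#' the mask outline. Lacunarity: mean over box sizes and offsets of
#' (sigma/mu)^2 of per-box foreground pixel counts on the filled mask. Grids
#' are anchored at the mask bounding box, so both are translation invariant.
#'
#' @param mask logical mask.
#' @param calibration micrometres per pixel (unused: both are dimensionless).
#' @return named numeric vector: `fractal dimension`, `lacunarity`.
#' @export
fractal_descriptors <- function(mask, calibration = 1) {
  co <- .mask_coords(mask)
  if (nrow(co) == 0L) stop("empty mask")
  outline <- mask & !erode3(mask)
  oc <- .mask_coords(outline)
  y0 <- min(co[, "y"]); x0 <- min(co[, "x"])
  extent <- max(max(co[, "y"]) - y0, max(co[, "x"]) - x0) + 1L
  max_size <- min(dim(mask)) %/% 4L
  sizes <- 2^(1:12)
  sizes <- sizes[sizes <= max(2L, max_size)]
  if (!length(sizes)) stop("mask smaller than the smallest box grid")
  counts <- numeric(length(sizes))
  lac_terms <- numeric(0)
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    offs <- unique(rbind(c(0L, 0L), c(s %/% 2L, 0L), c(0L, s %/% 2L),
                         c(s %/% 2L, s %/% 2L)))
    cnt_o <- numeric(nrow(offs))
    for (oi in seq_len(nrow(offs))) {
      oy <- offs[oi, 1L]; ox <- offs[oi, 2L]
      # boxes on the outline (fractal dimension)
      by <- (oc[, "y"] - y0 + oy) %/% s
      bx <- (oc[, "x"] - x0 + ox) %/% s
      cnt_o[oi] <- length(unique(by * 100000 + bx))
      # box masses on the filled mask (lacunarity), over the grid covering
      # the bounding box
      fy <- (co[, "y"] - y0 + oy) %/% s
      fx <- (co[, "x"] - x0 + ox) %/% s
      masses <- table(fy * 100000 + fx)
      n_boxes_y <- (extent + oy + s - 1L) %/% s
      n_boxes_x <- (extent + ox + s - 1L) %/% s
      all_masses <- c(as.numeric(masses),
                      rep(0, max(0L, n_boxes_y * n_boxes_x - length(masses))))
      mu <- mean(all_masses)
      if (mu > 0) lac_terms <- c(lac_terms, (stats::sd(all_masses) / mu)^2)
    }
    counts[si] <- mean(cnt_o)
  }
  fd <- if (length(sizes) >= 2L) {
    -unname(stats::coef(stats::lm(log(counts) ~ log(sizes)))[2L])
  } else 1
  c("fractal dimension" = fd,
    "lacunarity" = mean(lac_terms))
}

#' Assemble the full 62-feature vector for one cell
#'
#' Runs all five descriptor domains on an accepted cell mask and its soma
#' mask. Any failing sub-computation sets its features to `NA` and records
#' the reason in the `errors` attribute.
#'
#' @param mask logical cell mask or `cell_mask` object.
#' @param soma `soma_mask` object or logical matrix.
#' @param calibration micrometres per pixel.
#' @param sholl_step_um Sholl radius step.
#' @return named numeric vector of exactly 62 features (see
#'   [feature_names()]), with attribute `errors` (named character, possibly
#'   empty).
#' @export
extract_features <- function(mask, soma, calibration = 1, sholl_step_um = 2) {
  if (inherits(mask, "cell_mask")) mask <- mask$mask
  out <- stats::setNames(rep(NA_real_, 62L), feature_names())
  errors <- character(0)
  put <- function(vals) out[names(vals)] <<- vals
  try_domain <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(v)) put(v)
    v
  }
  try_domain("shape", shape_descriptors(mask, soma, calibration))
  sk <- try_domain("skeleton", {
    sd <- skeleton_descriptors(mask, calibration)
    attr(sd$features, "payload") <- sd
    sd$features
  })
  skel <- if (!is.null(sk)) attr(sk, "payload")$skeleton else
    matrix(FALSE, nrow(mask), ncol(mask))
  try_domain("sholl", {
    prof <- sholl_profile(mask, soma, calibration, sholl_step_um)
    sholl_descriptors(prof, skel, calibration)
  })
  hull <- try_domain("hull", hull_descriptors(mask, calibration))
  try_domain("fractal", fractal_descriptors(mask, calibration))
  if (!is.null(hull) && !is.null(sk) && hull[["convex hull area"]] > 0) {
    out["branching density"] <- sk[["skeleton area"]] / hull[["convex hull area"]]
  } else if (is.na(out["branching density"])) {
    out["branching density"] <- NA_real_
    errors[["branching density"]] <- "hull area unavailable or zero"
  }
  attr(out, "errors") <- errors
  out
}
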