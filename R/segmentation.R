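# Seeded segmentation: detect cell seed points on averaged substack
# projections, then grow one mask per seed by iterative thresholding until
# the mask area reaches a user-defined target (the "mask size", MS), using
# the update
#     T_{I+1} = T_I + T_I * (A_I - MS) / (n * MS)
# starting from Otsu's threshold on the 120 x 120 um ROI. The soma is found
# by Otsu thresholding plus particle filtering (area >= 20 um^2,
# circularity >= 0.6).

ROI_UM <- 120      # ROI side length, micrometres
EDGE_UM <- 5       # rejection margin from the ROI edge, micrometres

#' Mean projections of depth substacks
#'
#' Splits a cleaned stack into substacks of `thickness_um` separated by
#' `spacing_um` gaps (so cells are not sampled twice) and mean-projects each.
#'
#' @param stack a `clean_stack` or 3-D array (z, y, x).
#' @param thickness_um substack thickness in micrometres.
#' @param spacing_um gap between consecutive substacks in micrometres.
#' @param z_step_um plane spacing; taken from the stack calibration when
#'   available.
#' @return list of 2-D projections with attribute `planes` (plane indices
#'   used); empty list (with a warning) when the stack is too shallow.
#' @export
project_substacks <- function(stack, thickness_um = 10, spacing_um = 20,
                              z_step_um = NULL) {
  arr <- if (inherits(stack, "clean_stack")) stack$data else stack
  if (is.null(z_step_um)) {
    z_step_um <- if (inherits(stack, "clean_stack")) stack$calibration[3L] else 1
  }
  nz <- dim(arr)[1L]
  n_thick <- max(1L, round(thickness_um / z_step_um))
  n_gap <- round(spacing_um / z_step_um)
  if (nz < n_thick) {
    warning("stack shallower than substack thickness; no projections")
    return(list())
  }
  starts <- as.integer(seq(1L, nz - n_thick + 1L, by = n_thick + n_gap))
  lapply(starts, function(s) {
    pl <- s:(s + n_thick - 1L)
    proj <- apply(arr[pl, , , drop = FALSE], c(2L, 3L), mean)
    attr(proj, "planes") <- pl
    proj
  })
}

#' Detect cell seed points on a projection
#'
#' Local maxima of the lightly smoothed projection whose prominence over the
#' local background exceeds a threshold, with a minimum mutual separation
#' (greedy, brightest first).
#'
#' @param projection 2-D numeric matrix.
#' @param prominence required height above the local background; default 10%
#'   of the projection's dynamic range.
#' @param min_sep_um minimum seed separation in micrometres.
#' @param calibration micrometres per pixel.
#' @return integer matrix with columns `y`, `x` (pixel indices), possibly
#'   zero rows.
#' @export
detect_seeds <- function(projection, prominence = NULL, min_sep_um = 20,
                         calibration = 1) {
  rng <- diff(range(projection))
  if (rng == 0) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("y", "x"))))
  if (is.null(prominence)) prominence <- 0.1 * rng
  # smooth at roughly soma scale so thin processes do not produce maxima
  sm <- blur_gaussian(projection, 3)
  nr <- nrow(sm); nc <- ncol(sm)
  p <- pad_replicate(sm, 1L)
  is_max <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    is_max <- is_max & (sm >= p[(2 + dy):(nr + 1L + dy), (2 + dx):(nc + 1L + dx)])
  }
  bg <- stats::median(sm)
  cand <- which(is_max & (sm - bg >= prominence))
  if (!length(cand)) return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("y", "x"))))
  ys <- ((cand - 1L) %% nr) + 1L
  xs <- ((cand - 1L) %/% nr) + 1L
  vals <- sm[cand]
  ord <- order(vals, decreasing = TRUE)
  min_sep <- min_sep_um / calibration
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all((ys[i] - ys[keep])^2 + (xs[i] - xs[keep])^2 >= min_sep^2)) {
      keep <- c(keep, i)
    }
  }
  cbind(y = ys[keep], x = xs[keep])
}

#' Grow a mask from a seed at a fixed threshold
#'
#' The 8-connected component of pixels above the threshold that contains the
#' seed; empty when the seed pixel itself is below the threshold.
#'
#' @param roi 2-D numeric matrix.
#' @param threshold intensity threshold.
#' @param seed c(y, x) pixel position of the seed inside the ROI.
#' @return logical matrix.
#' @export
grow_mask <- function(roi, threshold, seed) {
  stopifnot(seed[1L] >= 1L, seed[1L] <= nrow(roi),
            seed[2L] >= 1L, seed[2L] <= ncol(roi))
  above <- roi > threshold
  idx <- (seed[2L] - 1L) * nrow(roi) + seed[1L]
  flood_from(above, idx)
}

#' Threshold update of the iterative mask-growing loop
#'
#' Returns `T_I + T_I * (A_I - MS) / (n * MS)`: the threshold rises when the
#' mask is too large, falls when too small, with corrections shrinking as
#' 1/n.
#'
#' @param T_I current threshold.
#' @param A_I current mask area (um^2).
#' @param MS target mask size (um^2), > 0.
#' @param n iteration number (>= 1).
#' @return next threshold.
#' @export
next_threshold <- function(T_I, A_I, MS, n) {
  if (MS <= 0) stop("mask size MS must be positive")
  stopifnot(n >= 1)
  T_I + T_I * (A_I - MS) / (n * MS)
}

#' Segment one cell by iterative thresholding to a target area
#'
#' Starting from Otsu's threshold on the ROI, the mask is regrown and the
#' threshold updated by [next_threshold()] until the area lands within
#' `limit` of `MS`, the area stabilises for three consecutive iterations
#' (relative change < 0.5%), or `max_iter` is reached. Accepted masks must
#' stay more than 5 um away from the ROI edge.
#'
#' @param roi 2-D numeric matrix (the 120 x 120 um window around the seed).
#' @param seed c(y, x) pixel position of the seed in the ROI.
#' @param MS target mask size, um^2.
#' @param limit acceptance half-width, um^2 (paper default 100).
#' @param max_iter iteration cap.
#' @param calibration micrometres per pixel.
#' @param t0 optional starting threshold (default: ROI Otsu).
#' @return object of class `cell_mask`: list with `mask`, `seed`,
#'   `final_threshold`, `history` (data frame of T, area, n), `status` in
#'   accepted / rejected_edge / rejected_unstable, and `area` (um^2).
#' @export
segment_cell <- function(roi, seed, MS = 400, limit = 100, max_iter = 25L,
                         calibration = 1, t0 = NULL) {
  stopifnot(limit > 0, MS > 0)
  px_area <- calibration^2
  T_I <- if (is.null(t0)) otsu_threshold(roi) else t0
  roi_max <- max(roi)
  hist_T <- hist_A <- numeric(0)
  mask <- NULL
  status <- "rejected_unstable"
  for (n in seq_len(max_iter)) {
    T_I <- min(T_I, roi_max)  # clamp: beyond the ROI maximum nothing survives
    mask <- grow_mask(roi, T_I, seed)
    A_I <- sum(mask) * px_area
    hist_T <- c(hist_T, T_I); hist_A <- c(hist_A, A_I)
    if (abs(A_I - MS) <= limit && A_I > 0) {
      status <- "accepted"
      break
    }
    if (n >= 3L) {
      a3 <- hist_A[(n - 2L):n]
      if (all(a3 > 0) && max(abs(diff(a3))) / mean(a3) < 0.005) {
        status <- "rejected_unstable"  # stabilised outside the target band
        break
      }
      if (all(a3 == 0)) break
    }
    T_next <- next_threshold(T_I, A_I, MS, n)
    if (T_next >= roi_max && T_I >= roi_max) break
    if (T_next <= 0) T_next <- T_I / 2
    T_I <- T_next
  }
  area <- sum(mask) * px_area
  if (status == "accepted") {
    edge_px <- max(1L, ceiling(EDGE_UM / calibration))
    nr <- nrow(mask); nc <- ncol(mask)
    border <- mask
    border[(edge_px + 1L):(nr - edge_px), (edge_px + 1L):(nc - edge_px)] <- FALSE
    if (any(border)) status <- "rejected_edge"
  }
  structure(list(mask = mask, seed = seed,
                 final_threshold = T_I,
                 history = data.frame(n = seq_along(hist_T), threshold = hist_T,
                                      area = hist_A),
                 status = status, area = area,
                 MS = MS, limit = limit, calibration = calibration),
            class = "cell_mask")
}

#' Detect the soma within an accepted cell mask
#'
#' Otsu-thresholds the ROI and keeps 8-connected particles that intersect
#' the cell mask with area >= 20 um^2 and circularity (4 pi A / P^2) >= 0.6.
#' Exactly one survivor is the soma; otherwise the largest disc inscribed in
#' the cell mask is used as a fallback (origin flagged).
#'
#' @param roi 2-D numeric matrix.
#' @param cell_mask logical matrix (accepted mask).
#' @param calibration micrometres per pixel.
#' @return object of class `soma_mask` (list with `mask`, `area`,
#'   `circularity`, `origin` = "automatic" or "fallback"), or `NULL` when
#'   even the fallback fails.
#' @export
detect_soma <- function(roi, cell_mask, calibration = 1) {
  px_area <- calibration^2
  th <- otsu_threshold(roi)
  lab <- label_components(roi > th)
  n <- attr(lab, "n")
  survivors <- list()
  if (n > 0L) {
    for (k in seq_len(n)) {
      part <- lab == k
      if (!any(part & cell_mask)) next
      area <- sum(part) * px_area
      if (area < 20) next
      per <- trace_boundary(part)$perimeter * calibration
      circ <- min(1, 4 * pi * area / per^2)
      if (circ < 0.6) next
      survivors[[length(survivors) + 1L]] <- list(mask = part, area = area,
                                                  circularity = circ)
    }
  }
  if (length(survivors) == 1L) {
    s <- survivors[[1L]]
    return(structure(list(mask = s$mask, area = s$area,
                          circularity = s$circularity, origin = "automatic"),
                     class = "soma_mask"))
  }
  # fallback: largest inscribed disc of the cell mask
  if (!any(cell_mask)) return(NULL)
  dt <- distance_transform(cell_mask)
  i <- which.max(dt)
  r <- dt[i]
  if (r < 1) return(NULL)
  nr <- nrow(cell_mask); nc <- ncol(cell_mask)
  cy <- ((i - 1L) %% nr) + 1L
  cx <- ((i - 1L) %/% nr) + 1L
  ys <- matrix(seq_len(nr), nr, nc)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  disc <- (ys - cy)^2 + (xs - cx)^2 <= r^2
  structure(list(mask = disc, area = sum(disc) * px_area,
                 circularity = 1, origin = "fallback"),
            class = "soma_mask")
}

#' Review cell masks for cross-cell contamination
#'
#' Automated stand-in for visual mask approval. Under `policy = "auto"` a
#' mask is rejected when it contains pixels strictly closer to another
#' accepted cell's seed than to its own (it has engulfed a neighbour); under
#' `policy = "list"` only masks whose index appears in `accept` survive.
#'
#' @param cell_masks list of `cell_mask` objects sharing one image frame
#'   (seeds in frame coordinates, see `offset` attribute set by callers).
#' @param seeds matrix of all accepted seed positions (y, x), frame coords.
#' @param policy "auto" or "list".
#' @param accept integer indices for `policy = "list"`.
#' @return the input list with statuses updated (`rejected_overlap`).
#' @export
review_masks <- function(cell_masks, seeds = NULL, policy = c("auto", "list"),
                         accept = integer(0)) {
  policy <- match.arg(policy)
  if (policy == "list") {
    for (i in seq_along(cell_masks)) {
      if (!(i %in% accept) && cell_masks[[i]]$status == "accepted") {
        cell_masks[[i]]$status <- "rejected_overlap"
      }
    }
    return(cell_masks)
  }
  if (is.null(seeds) || nrow(seeds) < 2L) return(cell_masks)
  for (i in seq_along(cell_masks)) {
    cm <- cell_masks[[i]]
    if (cm$status != "accepted") next
    off <- attr(cm, "offset")
    if (is.null(off)) off <- c(0L, 0L)
    idx <- which(cm$mask)
    ys <- ((idx - 1L) %% nrow(cm$mask)) + off[1L]
    xs <- ((idx - 1L) %/% nrow(cm$mask)) + off[2L]
    own <- cm$seed + off  # frame coordinates of this cell's seed
    d_own <- (ys - own[1L])^2 + (xs - own[2L])^2
    for (j in seq_len(nrow(seeds))) {
      sj <- seeds[j, ]
      if (all(sj == own)) next
      d_other <- (ys - sj[1L])^2 + (xs - sj[2L])^2
      if (any(d_other < d_own)) {
        cell_masks[[i]]$status <- "rejected_overlap"
        break
      }
    }
  }
  cell_masks
}

#' Extract the 120 x 120 um ROI around a seed
#'
#' @param frame 2-D image.
#' @param seed c(y, x) seed pixel in frame coordinates.
#' @param calibration micrometres per pixel.
#' @return list with `roi`, `seed` (ROI coordinates) and `offset` (frame
#'   coords of ROI pixel (1,1) minus one).
#' @export
extract_roi <- function(frame, seed, calibration = 1) {
  half <- round(ROI_UM / 2 / calibration)
  y0 <- max(1L, seed[1L] - half); y1 <- min(nrow(frame), seed[1L] + half - 1L)
  x0 <- max(1L, seed[2L] - half); x1 <- min(ncol(frame), seed[2L] + half - 1L)
  list(roi = frame[y0:y1, x0:x1, drop = FALSE],
       seed = c(seed[1L] - y0 + 1L, seed[2L] - x0 + 1L),
       offset = c(y0 - 1L, x0 - 1L))
}
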