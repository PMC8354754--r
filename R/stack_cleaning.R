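# Stack cleaning: turn a noisy, motion- and blur-contaminated 4-D two-photon
# acquisition (multiple frames per Z plane, F-within-Z order) into one clean
# 2-D frame per plane, in the correct Z order. Per plane: score frame blur
# with a Laplacian-of-Gaussian filter, average the sharpest frames into a
# reference, register every frame to it, keep the least-different frames, and
# average those. Planes are then reordered by similarity seriation.

#' Construct a raw (4-D) acquisition stack
#'
#' @param data 4-D numeric array indexed (frame, z, y, x).
#' @param calibration numeric length-3: micrometres per pixel in x and y, and
#'   micrometres per Z step. All strictly positive.
#' @param range intensity range of the source dtype (default 8-bit).
#' @return object of class `raw_stack`.
#' @export
raw_stack <- function(data, calibration = c(1, 1, 1), range = c(0, 255)) {
  stopifnot(length(dim(data)) == 4L, dim(data)[1L] >= 1L,
            length(calibration) == 3L, all(calibration > 0))
  structure(list(data = data, calibration = as.numeric(calibration),
                 range = range),
            class = "raw_stack")
}

#' Construct a cleaned (one frame per plane) stack
#'
#' @param data 3-D numeric array indexed (z, y, x).
#' @param calibration as in [raw_stack()].
#' @param provenance list with per-plane retained frame indices, applied
#'   shifts and the applied `z_order` permutation.
#' @param qc logical vector, per-plane pass flag.
#' @return object of class `clean_stack`.
#' @export
clean_stack_obj <- function(data, calibration = c(1, 1, 1),
                            provenance = list(), qc = rep(TRUE, dim(data)[1L])) {
  stopifnot(length(dim(data)) == 3L)
  structure(list(data = data, calibration = as.numeric(calibration),
                 provenance = provenance, qc = qc),
            class = "clean_stack")
}

#' Normalise contrast across a raw stack
#'
#' Each frame is linearly rescaled so that its mean and standard deviation
#' match those of the reference plane's mean frame; output is clipped to the
#' stack's intensity range. Constant frames are left unscaled and flagged.
#'
#' @param stack a [raw_stack()].
#' @param reference_plane plane index whose mean frame supplies the target
#'   statistics; default the middle plane.
#' @return a `raw_stack` with attribute `constant_frames` (matrix of flags).
#' @export
normalize_contrast <- function(stack, reference_plane = NULL) {
  stopifnot(inherits(stack, "raw_stack"))
  d <- stack$data
  nf <- dim(d)[1L]; nz <- dim(d)[2L]
  if (is.null(reference_plane)) reference_plane <- (nz + 1L) %/% 2L
  ref <- apply(d[, reference_plane, , , drop = FALSE], c(3L, 4L), mean)
  m0 <- mean(ref); s0 <- stats::sd(ref)
  flags <- matrix(FALSE, nf, nz)
  for (z in seq_len(nz)) for (f in seq_len(nf)) {
    fr <- d[f, z, , ]
    s <- stats::sd(fr)
    if (s == 0) {
      flags[f, z] <- TRUE
      next
    }
    out <- (fr - mean(fr)) / s * s0 + m0
    d[f, z, , ] <- pmax(stack$range[1L], pmin(stack$range[2L], out))
  }
  if (any(flags)) warning("constant frame(s) left unscaled")
  out <- raw_stack(d, stack$calibration, stack$range)
  attr(out, "constant_frames") <- flags
  out
}

#' Blur score of a frame (LoG filter response spread)
#'
#' The frame is filtered with a Laplacian of Gaussian and the standard
#' deviation of the filtered image is returned; sharper frames score higher.
#' `method = "max"` instead returns the maximum filtered value, the inferior
#' alternative blur statistic.
#'
#' @param frame 2-D numeric matrix, at least 8 x 8.
#' @param sigma_log Gaussian scale of the LoG filter in pixels.
#' @param method `"sd"` (default) or `"max"`.
#' @return non-negative scalar.
#' @export
blur_score <- function(frame, sigma_log = 1.5, method = c("sd", "max")) {
  method <- match.arg(method)
  stopifnot(nrow(frame) >= 8L, ncol(frame) >= 8L)
  log_img <- laplacian4(blur_gaussian(frame, sigma_log))
  if (method == "sd") stats::sd(log_img) else max(log_img)
}

#' Integer-pixel translation registration by cross-correlation
#'
#' Finds the integer shift of `moving` relative to `fixed` that maximises
#' their cross-correlation (FFT-based, mean-removed). Ties are broken by the
#' smallest shift magnitude. The registered image is `moving` shifted back,
#' exposed edges filled with the image minimum.
#'
#' @param moving,fixed equally sized numeric matrices.
#' @param max_shift search radius in pixels.
#' @return list with `shift` (dy, dx) and `registered`.
#' @export
register_translation <- function(moving, fixed, max_shift = 20L) {
  stopifnot(all(dim(moving) == dim(fixed)))
  nr <- nrow(fixed); nc <- ncol(fixed)
  a <- moving - mean(moving)
  b <- fixed - mean(fixed)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  # cc[dy+1, dx+1] (wrapped) = sum_x moving(x) fixed(x - s): max at s = shift
  dy_axis <- c(0:(nr - 1L)); dy_axis[dy_axis > nr / 2] <- dy_axis[dy_axis > nr / 2] - nr
  dx_axis <- c(0:(nc - 1L)); dx_axis[dx_axis > nc / 2] <- dx_axis[dx_axis > nc / 2] - nc
  ok <- outer(abs(dy_axis) <= max_shift, abs(dx_axis) <= max_shift)
  ccv <- ifelse(ok, cc, -Inf)
  mx <- max(ccv)
  cand <- which(ccv >= mx - 1e-6 * max(1, abs(mx)), arr.ind = TRUE)
  dys <- dy_axis[cand[, 1L]]; dxs <- dx_axis[cand[, 2L]]
  ord <- order(dys^2 + dxs^2, dys, dxs)
  shift <- c(dys[ord[1L]], dxs[ord[1L]])
  registered <- shift_mat(moving, -shift[1L], -shift[2L], fill = min(moving))
  list(shift = shift, registered = registered)
}

#' Build the reference frame of one plane's substack
#'
#' The `k_sharp` frames with the highest [blur_score()] are mutually
#' registered to the sharpest one and averaged.
#'
#' @param substack 3-D array (frame, y, x) or list of matrices.
#' @param k_sharp number of sharpest frames to average (>= 1).
#' @param sigma_log LoG scale for blur scoring.
#' @return 2-D reference image.
#' @export
build_reference_frame <- function(substack, k_sharp = 3L, sigma_log = 1.5) {
  frames <- .as_frame_list(substack)
  if (k_sharp < 1L) stop("k_sharp must be >= 1")
  k_sharp <- min(k_sharp, length(frames))
  scores <- vapply(frames, blur_score, 0, sigma_log = sigma_log)
  ord <- order(scores, decreasing = TRUE)
  keep <- ord[seq_len(k_sharp)]
  anchor <- frames[[keep[1L]]]
  regs <- lapply(keep, function(i) {
    if (i == keep[1L]) anchor else register_translation(frames[[i]], anchor)$registered
  })
  Reduce(`+`, regs) / length(regs)
}

.as_frame_list <- function(substack) {
  if (is.list(substack)) return(substack)
  stopifnot(length(dim(substack)) == 3L)
  lapply(seq_len(dim(substack)[1L]), function(i) substack[i, , ])
}

# Mean absolute difference over the overlap region implied by a shift; the
# fill introduced at the edges by registration must not dominate the score.
.mad_overlap <- function(a, b, shift) {
  nr <- nrow(a); nc <- ncol(a)
  dy <- shift[1L]; dx <- shift[2L]
  ys <- max(1L, 1L + dy):min(nr, nr + dy)
  xs <- max(1L, 1L + dx):min(nc, nc + dx)
  if (!length(ys) || !length(xs)) return(Inf)
  mean(abs(a[ys, xs] - b[ys, xs]))
}

#' Clean a single plane's substack
#'
#' Registers every frame to the reference, ranks frames by mean absolute
#' difference to the reference over the registered overlap, and averages the
#' `k_keep` least-different frames (after mutual registration).
#'
#' @param substack 3-D array (frame, y, x) or list of matrices.
#' @param reference 2-D reference image for the plane.
#' @param k_keep number of frames retained (paper default 2).
#' @return 2-D cleaned frame with attributes `kept` (frame indices) and
#'   `residual` (mean abs difference of kept frames to the reference).
#' @export
clean_plane <- function(substack, reference, k_keep = 2L) {
  frames <- .as_frame_list(substack)
  stopifnot(k_keep >= 1L, k_keep <= length(frames))
  regs <- lapply(frames, register_translation, fixed = reference)
  diffs <- vapply(seq_along(frames), function(i) {
    .mad_overlap(regs[[i]]$registered, reference, regs[[i]]$shift)
  }, 0)
  keep <- order(diffs)[seq_len(k_keep)]
  anchor <- regs[[keep[1L]]]$registered
  imgs <- lapply(keep, function(i) {
    if (i == keep[1L]) anchor
    else register_translation(regs[[i]]$registered, anchor)$registered
  })
  out <- Reduce(`+`, imgs) / length(imgs)
  attr(out, "kept") <- keep
  attr(out, "residual") <- mean(diffs[keep])
  attr(out, "shifts") <- t(vapply(regs, function(r) r$shift, c(0, 0)))
  out
}

#' Recover the Z order of a cleaned stack
#'
#' Builds the matrix of pairwise normalised cross-correlations between planes
#' and chains planes greedily from the least-similar plane (a path endpoint),
#' always appending the nearest unused neighbour. A globally reversed order
#' is equivalent.
#'
#' @param stack a `clean_stack` (or 3-D array (z, y, x)).
#' @return list with `permutation` (new order, indices into the input) and
#'   `stack` (reordered `clean_stack` or array).
#' @export
reorder_z <- function(stack) {
  arr <- if (inherits(stack, "clean_stack")) stack$data else stack
  stopifnot(length(dim(arr)) == 3L)
  nz <- dim(arr)[1L]
  if (nz < 3L) stop("need at least 3 planes to reorder")
  planes <- lapply(seq_len(nz), function(i) arr[i, , ])
  # translation-invariant similarity: peak normalised cross-correlation over
  # integer shifts (cleaned planes can carry a residual common shift from the
  # anchor frame they were registered to)
  npix <- prod(dim(arr)[2:3])
  fts <- lapply(planes, function(p) stats::fft(p - mean(p)))
  ss <- vapply(planes, function(p) sum((p - mean(p))^2), 0)
  sim <- matrix(1, nz, nz)
  for (i in seq_len(nz - 1L)) for (j in (i + 1L):nz) {
    if (ss[i] == 0 || ss[j] == 0) { sim[i, j] <- sim[j, i] <- 0; next }
    cc <- Re(stats::fft(fts[[i]] * Conj(fts[[j]]), inverse = TRUE)) / npix
    sim[i, j] <- sim[j, i] <- max(cc) / sqrt(ss[i] * ss[j])
  }
  identical_planes <- all(vapply(planes[-1L], function(p) {
    isTRUE(all.equal(p, planes[[1L]], tolerance = 1e-12))
  }, TRUE))
  if (identical_planes) {
    warning("all planes identical; keeping input order")
    perm <- seq_len(nz)
  } else {
    tot <- rowSums(sim) - 1
    perm <- integer(nz)
    perm[1L] <- which.min(tot)
    used <- rep(FALSE, nz)
    used[perm[1L]] <- TRUE
    for (k in 2:nz) {
      s <- sim[perm[k - 1L], ]
      s[used] <- -Inf
      perm[k] <- which.max(s)
      used[perm[k]] <- TRUE
    }
  }
  out <- arr[perm, , , drop = FALSE]
  if (inherits(stack, "clean_stack")) {
    stack$data <- out
    stack$qc <- stack$qc[perm]
    stack$provenance$z_order <- perm
    out <- stack
  }
  list(permutation = perm, stack = out)
}

#' Clean a raw 4-D stack end to end
#'
#' Contrast normalisation, per-plane reference building and frame selection,
#' Z reordering, and automated QC: a plane is flagged when the residual mean
#' absolute difference of its retained frames exceeds `qc_factor` times the
#' median residual across planes.
#'
#' @param raw a [raw_stack()].
#' @param k_sharp frames averaged into the reference (default 3).
#' @param k_keep frames retained per plane (default 2).
#' @param sigma_log LoG scale for blur scoring (pixels).
#' @param qc_factor residual-threshold multiplier for plane QC.
#' @param normalize run contrast normalisation first (default TRUE).
#' @return a `clean_stack`; errors if every plane fails QC.
#' @export
clean_stack <- function(raw, k_sharp = 3L, k_keep = 2L, sigma_log = 1.5,
                        qc_factor = 3, normalize = TRUE) {
  stopifnot(inherits(raw, "raw_stack"))
  if (normalize) raw <- normalize_contrast(raw)
  d <- raw$data
  nf <- dim(d)[1L]; nz <- dim(d)[2L]
  cleaned <- vector("list", nz)
  residuals <- numeric(nz)
  kept <- vector("list", nz)
  for (z in seq_len(nz)) {
    sub <- lapply(seq_len(nf), function(f) d[f, z, , ])
    ref <- build_reference_frame(sub, k_sharp, sigma_log)
    cp <- clean_plane(sub, ref, k_keep)
    cleaned[[z]] <- cp
    residuals[z] <- attr(cp, "residual")
    kept[[z]] <- attr(cp, "kept")
  }
  qc <- residuals <= qc_factor * pmax(stats::median(residuals), 1e-9)
  if (!any(qc)) stop("every plane failed QC; stack rejected")
  arr <- array(0, dim = c(nz, dim(d)[3L], dim(d)[4L]))
  for (z in seq_len(nz)) arr[z, , ] <- cleaned[[z]]
  cs <- clean_stack_obj(arr, raw$calibration,
                        provenance = list(kept_frames = kept,
                                          residuals = residuals),
                        qc = qc)
  if (nz >= 3L) {
    ro <- reorder_z(cs)
    cs <- ro$stack
  } else {
    cs$provenance$z_order <- seq_len(nz)
  }
  cs
}
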