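# Low-level image primitives shared by the cleaning, segmentation and
# morphology stages. Everything operates on plain numeric matrices indexed
# [y, x]; calibrated quantities are handled by the callers.

#' Shift a matrix by an integer offset
#'
#' Content moves down by `dy` rows and right by `dx` columns; exposed pixels
#' are filled with `fill`.
#'
#' @param m numeric matrix.
#' @param dy,dx integer offsets (may be negative).
#' @param fill fill value for exposed pixels (default: matrix minimum).
#' @return matrix of the same dimension.
#' @keywords internal
shift_mat <- function(m, dy, dx, fill = min(m)) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy  # source rows
  xs <- seq_len(nc) - dx
  oky <- ys >= 1L & ys <= nr
  okx <- xs >= 1L & xs <= nc
  if (any(oky) && any(okx)) {
    out[which(oky), which(okx)] <- m[ys[oky], xs[okx], drop = FALSE]
  }
  out
}

# Replicate-pad a matrix by r rows/cols on every side.
pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(rep(1L, r), seq_len(nr), rep(nr, r)),
    c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur (separable, replicate edges)
#' @param img numeric matrix.
#' @param sigma Gaussian width in pixels; `sigma <= 0` returns `img`.
#' @return blurred matrix.
#' @keywords internal
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # along x
  p <- img[, c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) out <- out + k[i] * p[, i:(i + nc - 1L), drop = FALSE]
  # along y
  p <- out[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) out <- out + k[i] * p[i:(i + nr - 1L), , drop = FALSE]
  out
}

# 4-neighbour Laplacian with replicate edges.
laplacian4 <- function(img) {
  p <- pad_replicate(img, 1L)
  nr <- nrow(img); nc <- ncol(img)
  p[1:nr, 2:(nc + 1L)] + p[3:(nr + 2L), 2:(nc + 1L)] +
    p[2:(nr + 1L), 1:nc] + p[2:(nr + 1L), 3:(nc + 2L)] - 4 * img
}

#' Otsu's threshold
#'
#' Histogram-based threshold minimising intra-class intensity variance,
#' computed on 256 bins spanning the image range. Returns an intensity value;
#' the foreground is `img > threshold`.
#'
#' @param img numeric matrix or vector.
#' @return scalar threshold.
#' @export
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  bins <- pmin(nb, 1L + floor((v - lo) / (hi - lo) * nb))
  h <- tabulate(bins, nbins = nb)
  w <- h / sum(h)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  w1 <- cumsum(w)
  mu1 <- cumsum(w * mids)
  mu_t <- mu1[nb]
  # between-class variance for a cut after each bin
  denom <- w1 * (1 - w1)
  bc <- (mu_t * w1 - mu1)^2 / ifelse(denom > 0, denom, Inf)
  bc <- bc[-nb]
  # the maximum is a plateau when the histogram has an empty gap between
  # classes; take the plateau midpoint (ImageJ behaviour)
  ks <- which(bc >= max(bc) - 1e-12 * max(bc))
  k <- round(mean(range(ks)))
  lo + k * (hi - lo) / nb
}

# Neighbour index offsets for a matrix stored column-major, 8-connectivity.
.nbr_offsets8 <- function(nr) c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)

# Expand a set of linear indices to their valid 8-neighbours.
.neighbours8 <- function(idx, nr, nc) {
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  out <- integer(0)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
    r2 <- row + d[1L]; c2 <- col + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, (c2[ok] - 1L) * nr + r2[ok])
  }
  unique(out)
}

#' Connected-component labelling (8-connectivity)
#' @param mask logical matrix.
#' @return integer matrix of labels (0 = background), attribute `n` = number
#'   of components.
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  unvisited <- rep(FALSE, nr * nc)
  unvisited[todo] <- TRUE
  k <- 0L
  for (s in todo) {
    if (!unvisited[s]) next
    k <- k + 1L
    frontier <- s
    unvisited[s] <- FALSE
    lab[s] <- k
    while (length(frontier)) {
      nb <- .neighbours8(frontier, nr, nc)
      nb <- nb[unvisited[nb]]
      unvisited[nb] <- FALSE
      lab[nb] <- k
      frontier <- nb
    }
  }
  attr(lab, "n") <- k
  lab
}

# Flood fill the component of `mask` containing linear index `seed_idx`.
flood_from <- function(mask, seed_idx) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  if (!mask[seed_idx]) return(out)
  inmask <- as.logical(mask)
  frontier <- seed_idx
  out[seed_idx] <- TRUE
  while (length(frontier)) {
    nb <- .neighbours8(frontier, nr, nc)
    nb <- nb[inmask[nb] & !out[nb]]
    out[nb] <- TRUE
    frontier <- nb
  }
  out
}

# 3x3 binary erosion / dilation (8-neighbourhood), edges treated as background
# for erosion and as-is for dilation.
erode3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- p[2:(nr + 1L), 2:(nc + 1L)]
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    out <- out & p[(2 + dy):(nr + 1L + dy), (2 + dx):(nc + 1L + dx)]
  }
  out
}

dilate3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- p[2:(nr + 1L), 2:(nc + 1L)]
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    out <- out | p[(2 + dy):(nr + 1L + dy), (2 + dx):(nc + 1L + dx)]
  }
  out
}

# Chamfer 3-4 distance to background, in pixels (divided by 3).
distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- 3L * (nr + nc)
  d <- matrix(ifelse(mask, big, 0L), nr, nc)
  # forward pass
  for (x in seq_len(nc)) for (y in seq_len(nr)) {
    if (d[y, x] == 0L) next
    v <- d[y, x]
    if (y > 1L) v <- min(v, d[y - 1L, x] + 3L)
    if (x > 1L) v <- min(v, d[y, x - 1L] + 3L)
    if (y > 1L && x > 1L) v <- min(v, d[y - 1L, x - 1L] + 4L)
    if (y > 1L && x < nc) v <- min(v, d[y - 1L, x + 1L] + 4L)
    d[y, x] <- v
  }
  # backward pass
  for (x in rev(seq_len(nc))) for (y in rev(seq_len(nr))) {
    if (d[y, x] == 0L) next
    v <- d[y, x]
    if (y < nr) v <- min(v, d[y + 1L, x] + 3L)
    if (x < nc) v <- min(v, d[y, x + 1L] + 3L)
    if (y < nr && x < nc) v <- min(v, d[y + 1L, x + 1L] + 4L)
    if (y < nr && x > 1L) v <- min(v, d[y + 1L, x - 1L] + 4L)
    d[y, x] <- v
  }
  d / 3
}

#' Trace the outer boundary of the largest component and estimate perimeter
#'
#' Moore-neighbour tracing; the perimeter uses corner-corrected step weights
#' (0.948 for axial, 1.340 for diagonal steps) so digitised smooth shapes are
#' estimated close to their true contour length.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return list with `perimeter` (pixels) and `boundary` (n x 2 matrix of
#'   y, x pixel coordinates).
#' @keywords internal
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  if (!length(fg)) stop("empty mask")
  if (length(fg) == 1L) {
    yx <- c(((fg - 1L) %% nr) + 1L, ((fg - 1L) %/% nr) + 1L)
    return(list(perimeter = 4 * 0.948, boundary = matrix(yx, 1L)))
  }
  # start: leftmost pixel of topmost row
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  ord <- order(rows, cols)
  sy <- rows[ord[1L]]; sx <- cols[ord[1L]]
  # Moore tracing, clockwise; directions indexed 1..8:
  dirs <- matrix(c(0L, 1L,  1L, 1L,  1L, 0L,  1L, -1L,
                   0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L),
                 ncol = 2L, byrow = TRUE)  # (dy,dx): E,SE,S,SW,W,NW,N,NE
  inside <- function(y, x) y >= 1L && y <= nr && x >= 1L && x <= nc && mask[y, x]
  bpts <- matrix(0L, 0L, 2L)
  cy <- sy; cx <- sx
  prev_dir <- 7L  # came from "north" search direction
  steps <- numeric(0)
  maxit <- 8L * length(fg) + 8L
  it <- 0L
  first_move <- NULL
  repeat {
    it <- it + 1L
    if (it > maxit) break
    bpts <- rbind(bpts, c(cy, cx))
    # search neighbours clockwise starting after the backtrack direction
    start <- (prev_dir + 6L) %% 8L  # turn back then clockwise
    found <- FALSE
    for (j in 0:7) {
      d <- (start + j) %% 8L
      dy <- dirs[d + 1L, 1L]; dx <- dirs[d + 1L, 2L]
      ny <- cy + dy; nx <- cx + dx
      if (inside(ny, nx)) {
        steps <- c(steps, if (dy != 0L && dx != 0L) 1.340 else 0.948)
        cy <- ny; cx <- nx
        prev_dir <- d
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel cluster
    if (is.null(first_move)) {
      first_move <- prev_dir
    } else if (cy == sy && cx == sx && nrow(bpts) > 1L) {
      break
    }
  }
  list(perimeter = sum(steps), boundary = unique(bpts))
}

# Normalised cross-correlation of two equally sized matrices.
ncc <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  sa <- stats::sd(av); sb <- stats::sd(bv)
  if (sa == 0 || sb == 0) return(0)
  mean((av - mean(av)) * (bv - mean(bv))) / (sa * sb)
}

# Run a function with a private RNG stream seeded by `seed`; the global
# .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fisher-Pearson g1 skewness and non-excess kurtosis (m4/m2^2).
skewness_g1 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

kurtosis_m4 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2
}
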