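# Parametric microglia-like image generator. Cells are a filled soma disc
# plus branched processes rendered as ~2 px wide random walks; stacks add the
# acquisition structure (frames within Z planes) and controllable corruption
# (noise, jitter, per-frame blur, Z shuffling) with full ground truth, so
# every downstream stage is testable without real two-photon data.

#' Specify a synthetic cell
#'
#' @param soma_center numeric length-2, (x, y) in micrometres.
#' @param soma_radius soma radius in micrometres (> 0).
#' @param n_primary number of primary processes leaving the soma (>= 0);
#'   0 gives a bare disc.
#' @param branch_length_mean mean primary process length in micrometres.
#' @param branch_prob per-step probability that a process spawns a side
#'   branch, in [0, 1].
#' @param tortuosity per-step heading noise (s.d. in radians, >= 0); 0 gives
#'   straight processes.
#' @param seed integer seed making the rendering deterministic.
#' @return object of class `cell_spec`.
#' @export
cell_spec <- function(soma_center, soma_radius, n_primary = 6L,
                      branch_length_mean = 30, branch_prob = 0.1,
                      tortuosity = 0.3, seed = 1L) {
  stopifnot(length(soma_center) == 2L, soma_radius > 0, n_primary >= 0,
            branch_prob >= 0, branch_prob <= 1, tortuosity >= 0)
  structure(list(soma_center = as.numeric(soma_center),
                 soma_radius = soma_radius,
                 n_primary = as.integer(n_primary),
                 branch_length_mean = branch_length_mean,
                 branch_prob = branch_prob,
                 tortuosity = tortuosity,
                 seed = as.integer(seed)),
            class = "cell_spec")
}

# Intensity design: background 20, soma 200, processes taper from 200 at the
# soma to ~140 at the tips (8-bit scale, before noise). The taper gives the
# iterative-threshold loop a smooth area/threshold curve, as in real images
# where distal processes are dimmer.
.SYN_BG <- 20
.SYN_FG <- 200
.SYN_TAPER <- 0.3

# Stamp a dot at floating-point pixel position (y, x): all pixels within
# distance 1, i.e. a swept disc giving ~2 px process width regardless of
# direction (keeps the rendered area close to length x width analytically).
.stamp <- function(canvas, truth, y, x, value) {
  yr <- round(y); xr <- round(x)
  for (dy in -1:1) for (dx in -1:1) {
    yy <- yr + dy; xx <- xr + dx
    if (yy >= 1 && yy <= nrow(canvas) && xx >= 1 && xx <= ncol(canvas) &&
        (yy - y)^2 + (xx - x)^2 < 1) {
      canvas[yy, xx] <- max(canvas[yy, xx], value)
      truth[yy, xx] <- TRUE
    }
  }
  list(canvas = canvas, truth = truth)
}

#' Render a single synthetic cell with ground truth
#'
#' @param spec a [cell_spec()].
#' @param shape image size in pixels, (ny, nx).
#' @param calibration micrometres per pixel (isotropic).
#' @return list with `image` (numeric matrix, 8-bit scale, no noise) and
#'   `truth`: `mask`, `soma_mask` (logical matrices), `n_primary`,
#'   `total_branch_count`, `branch_lengths` (micrometres).
#' @export
generate_cell_image <- function(spec, shape = c(128L, 128L), calibration = 1) {
  stopifnot(inherits(spec, "cell_spec"))
  ny <- shape[1L]; nx <- shape[2L]
  cx <- spec$soma_center[1L] / calibration
  cy <- spec$soma_center[2L] / calibration
  r <- spec$soma_radius / calibration
  if (2 * spec$soma_radius >= min(ny, nx) * calibration ||
      cx - r < 1 || cy - r < 1 || cx + r > nx || cy + r > ny) {
    stop("cell spec out of bounds: soma does not fit the image")
  }
  with_seed(spec$seed, {
    img <- matrix(.SYN_BG, ny, nx)
    truth <- matrix(FALSE, ny, nx)
    soma <- matrix(FALSE, ny, nx)
    ys <- matrix(seq_len(ny), ny, nx)
    xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    soma[(ys - cy)^2 + (xs - cx)^2 <= r^2] <- TRUE
    img[soma] <- .SYN_FG
    truth <- truth | soma
    branch_lengths <- numeric(0)
    n_branches <- 0L
    # walker: returns updated canvases; may recurse into side branches
    walk <- function(y, x, theta, len_px, depth, img, truth) {
      n_steps <- max(1L, round(len_px))
      taper0 <- 1
      for (s in seq_len(n_steps)) {
        y <- y + sin(theta); x <- x + cos(theta)
        if (y < 2 || y > ny - 2 || x < 2 || x > nx - 2) break
        frac <- s / n_steps
        val <- .SYN_FG * (1 - .SYN_TAPER * frac)
        st <- .stamp(img, truth, y, x, val)
        img <- st$canvas; truth <- st$truth
        theta <- theta + stats::rnorm(1, 0, spec$tortuosity * 0.2)
        if (depth < 3L && s > 2L && n_branches < 100L &&
            stats::runif(1) < spec$branch_prob) {
          n_branches <<- n_branches + 1L
          side <- theta + sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 1.1)
          child_len <- (n_steps - s) * stats::runif(1, 0.5, 0.9)
          if (child_len >= 2) {
            branch_lengths <<- c(branch_lengths, child_len * calibration)
            st <- walk(y, x, side, child_len, depth + 1L, img, truth)
            img <- st$img; truth <- st$truth
          }
        }
      }
      list(img = img, truth = truth)
    }
    if (spec$n_primary > 0L) {
      angles <- 2 * pi * (seq_len(spec$n_primary) - 1L) / spec$n_primary +
        stats::runif(1, 0, 2 * pi / max(1L, spec$n_primary))
      for (a in angles) {
        len_px <- spec$branch_length_mean *
          stats::runif(1, 0.8, 1.2) / calibration
        n_branches <- n_branches + 1L
        branch_lengths <- c(branch_lengths, len_px * calibration)
        y0 <- cy + (r - 0.5) * sin(a)
        x0 <- cx + (r - 0.5) * cos(a)
        st <- walk(y0, x0, a, len_px, 1L, img, truth)
        img <- st$img; truth <- st$truth
      }
    }
    list(image = img,
         truth = list(mask = truth, soma_mask = soma,
                      n_primary = spec$n_primary,
                      total_branch_count = n_branches,
                      branch_lengths = branch_lengths))
  })
}

#' Specify per-frame stack corruption
#'
#' @param noise_sd additive Gaussian noise s.d. (intensity units).
#' @param jitter_px maximum per-frame integer translation (pixels).
#' @param blur_sigmas per-frame Gaussian blur widths (pixels); recycled per
#'   plane if of length `frames_per_plane`, a scalar applies everywhere.
#' @param z_permutation permutation of plane indices, or `NULL` for identity.
#' @return object of class `stack_corruption`.
#' @export
stack_corruption <- function(noise_sd = 0, jitter_px = 0L, blur_sigmas = 0,
                             z_permutation = NULL) {
  stopifnot(noise_sd >= 0, jitter_px >= 0, all(blur_sigmas >= 0))
  if (!is.null(z_permutation)) z_permutation <- as.integer(z_permutation)
  structure(list(noise_sd = noise_sd, jitter_px = as.integer(jitter_px),
                 blur_sigmas = blur_sigmas, z_permutation = z_permutation),
            class = "stack_corruption")
}

#' Generate a corrupted 4-D acquisition stack with ground truth
#'
#' Emulates the acquisition order F1Z1, F2Z1, ..., F1Z2, ...: every Z plane is
#' imaged `frames_per_plane` times. Planes of the underlying volume differ by
#' a smooth lateral drift and focus change so that true Z order is
#' recoverable from inter-plane similarity.
#'
#' @param cells list of [cell_spec()] (or a single spec).
#' @param corruption a [stack_corruption()].
#' @param frames_per_plane frames acquired per Z plane (>= 1).
#' @param n_planes number of Z planes.
#' @param shape image size (ny, nx) in pixels.
#' @param calibration c(x, y, z) micrometres per pixel / per plane step.
#' @param seed integer seed for the corruption draws.
#' @return list with `stack` (a `raw_stack`: 4-D array frame x z x y x x plus
#'   calibration) and `truth` (per-frame shifts, blur schedule, true z order,
#'   clean plane images).
#' @export
generate_raw_stack <- function(cells, corruption = stack_corruption(),
                               frames_per_plane = 6L, n_planes = 8L,
                               shape = c(96L, 96L), calibration = c(1, 1, 1),
                               seed = 1L) {
  stopifnot(frames_per_plane >= 1L, n_planes >= 1L)
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  ny <- shape[1L]; nx <- shape[2L]
  base <- matrix(.SYN_BG, ny, nx)
  for (cs in cells) {
    ci <- generate_cell_image(cs, shape, calibration[1L])
    base <- pmax(base, ci$image)
  }
  mid <- (n_planes + 1) / 2
  # smooth volume model: lateral drift of the cell plus an AR(1) sequence of
  # smooth background fields, so adjacent planes are the most similar and
  # similarity decays monotonically with Z distance
  planes <- with_seed(seed + 104729L, {
    rho <- 0.85
    smooth_field <- function() {
      f <- blur_gaussian(matrix(stats::rnorm(ny * nx), ny, nx), 3)
      f / stats::sd(as.numeric(f)) * 18
    }
    field <- smooth_field()
    lapply(seq_len(n_planes), function(k) {
      drift <- k - as.integer(ceiling(mid))  # integer px, 1 px per plane
      img <- shift_mat(base, drift, -drift, fill = .SYN_BG)
      field <<- rho * field + sqrt(1 - rho^2) * smooth_field()
      blur_gaussian(img, 0.4) + field
    })
  })
  zp <- corruption$z_permutation
  if (is.null(zp)) zp <- seq_len(n_planes)
  stopifnot(length(zp) == n_planes, all(sort(zp) == seq_len(n_planes)))
  blur <- corruption$blur_sigmas
  if (length(blur) == 1L) blur <- rep(blur, frames_per_plane)
  if (length(blur) == frames_per_plane) blur <- rep(blur, n_planes)
  stopifnot(length(blur) == frames_per_plane * n_planes)
  with_seed(seed, {
    data <- array(0, dim = c(frames_per_plane, n_planes, ny, nx))
    shifts <- array(0L, dim = c(frames_per_plane, n_planes, 2L))
    for (z in seq_len(n_planes)) {
      src <- planes[[zp[z]]]
      for (f in seq_len(frames_per_plane)) {
        fi <- (z - 1L) * frames_per_plane + f
        img <- blur_gaussian(src, blur[fi])
        if (corruption$jitter_px > 0L) {
          dy <- sample(seq(-corruption$jitter_px, corruption$jitter_px), 1L)
          dx <- sample(seq(-corruption$jitter_px, corruption$jitter_px), 1L)
          shifts[f, z, ] <- c(dy, dx)
          img <- shift_mat(img, dy, dx, fill = .SYN_BG)
        }
        if (corruption$noise_sd > 0) {
          img <- img + matrix(stats::rnorm(ny * nx, 0, corruption$noise_sd), ny, nx)
        }
        data[f, z, , ] <- pmax(0, pmin(255, img))
      }
    }
    stack <- raw_stack(data, calibration)
    list(stack = stack,
         truth = list(shifts = shifts,
                      blur = matrix(blur, frames_per_plane, n_planes),
                      z_order = zp, planes = planes))
  })
}

#' Standard activation effect for condition datasets
#'
#' The "resting" group emulates ramified microglia (small soma, six long
#' processes); the "activated" group the amoeboid-like shift (larger soma,
#' fewer and shorter processes). Values in micrometres.
#'
#' @return list with `resting` and `activated` parameter lists.
#' @export
standard_effect <- function() {
  list(resting = list(soma_radius = 3.5, n_primary = 6, branch_length_mean = 30,
                      branch_prob = 0.10, tortuosity = 0.3),
       activated = list(soma_radius = 5.0, n_primary = 3, branch_length_mean = 12,
                        branch_prob = 0.04, tortuosity = 0.3))
}

#' Zero (null) effect: both groups drawn from the resting distribution
#' @return effect list usable with [generate_condition_dataset()].
#' @export
null_effect <- function() {
  e <- standard_effect()
  e$activated <- e$resting
  e
}

#' Draw labelled cell specifications for two conditions
#'
#' Per-cell parameters are drawn around the group means with ~10-15%
#' biological variability. A degenerate effect (identical groups) is allowed
#' and flagged via the `degenerate` attribute.
#'
#' @param n_cells_per_group cells per condition (>= 2).
#' @param effect list with `resting`/`activated` parameter lists, e.g.
#'   [standard_effect()].
#' @param seed integer seed.
#' @param soma_center cell position (x, y) in micrometres, common to all
#'   specs (each cell is rendered into its own image).
#' @return data-frame-like list: `specs` (list of `cell_spec`), `condition`
#'   (factor resting/activated), `animal` (factor, 4 pseudo-animals per
#'   group); attribute `degenerate` flags a zero effect.
#' @export
generate_condition_dataset <- function(n_cells_per_group, effect = standard_effect(),
                                       seed = 1L, soma_center = c(72, 72)) {
  stopifnot(n_cells_per_group >= 2L)
  degenerate <- identical(effect$resting, effect$activated)
  with_seed(seed, {
    draw <- function(p, n, grp) {
      lapply(seq_len(n), function(i) {
        nb <- max(0L, as.integer(round(stats::rnorm(1, p$n_primary, 0.8))))
        cell_spec(
          soma_center = soma_center,
          soma_radius = max(2.6, stats::rnorm(1, p$soma_radius, 0.08 * p$soma_radius)),
          n_primary = nb,
          branch_length_mean = max(4, stats::rnorm(1, p$branch_length_mean,
                                                   0.12 * p$branch_length_mean)),
          branch_prob = p$branch_prob,
          tortuosity = p$tortuosity,
          seed = stats::runif(1, 1, 2^30))
      })
    }
    specs <- c(draw(effect$resting, n_cells_per_group, "resting"),
               draw(effect$activated, n_cells_per_group, "activated"))
    out <- list(specs = specs,
                condition = factor(rep(c("resting", "activated"),
                                       each = n_cells_per_group),
                                   levels = c("resting", "activated")),
                animal = factor(rep(rep(paste0("a", 1:4), length.out = n_cells_per_group), 2)))
    attr(out, "degenerate") <- degenerate
    out
  })
}

#' Write a ground-truth sidecar as plain-text key-value pairs
#' @param truth truth list from [generate_raw_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  lines <- c(
    paste0("z_order=", paste(truth$z_order, collapse = ",")),
    paste0("blur=", paste(signif(as.numeric(truth$blur), 6), collapse = ",")),
    paste0("shifts_dy=", paste(as.integer(truth$shifts[, , 1L]), collapse = ",")),
    paste0("shifts_dx=", paste(as.integer(truth$shifts[, , 2L]), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
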