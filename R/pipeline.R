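# Orchestration and I/O: TIFF stack loading with the F-within-Z
# de-interleave, per-stage CSV outputs, and the two-phase workflow -- build
# the index on a labelled training condition pair, then apply it to novel
# test data at the chosen mask size.

#' Pipeline configuration
#'
#' @param calibration c(x, y, z) micrometres per pixel / plane.
#' @param frames_per_plane frames acquired per Z plane.
#' @param k_sharp,k_keep frame counts for reference building / retention.
#' @param sigma_log LoG blur-score scale (px).
#' @param mask_sizes target mask areas to sweep (um^2).
#' @param limit mask-area acceptance half-width (um^2).
#' @param max_iter threshold-iteration cap.
#' @param sholl_step Sholl radius step (um).
#' @param top_n discriminators in the preliminary index.
#' @param N_max maximum discriminators when optimising.
#' @param method "auc" or "lmm_p".
#' @param seed integer seed for synthetic-data commands.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(calibration = c(0.58, 0.58, 1), frames_per_plane = 6L,
                            k_sharp = 3L, k_keep = 2L, sigma_log = 1.5,
                            mask_sizes = seq(200, 800, by = 100), limit = 100,
                            max_iter = 25L, sholl_step = 2, top_n = 5L,
                            N_max = 15L, method = "auc", seed = 1L) {
  cfg <- list(calibration = calibration, frames_per_plane = as.integer(frames_per_plane),
              k_sharp = as.integer(k_sharp), k_keep = as.integer(k_keep),
              sigma_log = sigma_log, mask_sizes = mask_sizes, limit = limit,
              max_iter = as.integer(max_iter), sholl_step = sholl_step,
              top_n = as.integer(top_n), N_max = as.integer(N_max),
              method = method, seed = as.integer(seed))
  stopifnot(all(vapply(cfg[c("sigma_log", "limit", "sholl_step")], function(x) x > 0, TRUE)),
            length(cfg$mask_sizes) >= 1L)
  structure(cfg, class = "pipeline_config")
}

#' Load a multi-page TIFF as a raw 4-D stack
#'
#' De-interleaves pages using the F-within-Z convention (F1Z1, F2Z1, ...,
#' F1Z2, ...).
#'
#' @param path TIFF path.
#' @param frames_per_plane frames per Z plane; the page count must be an
#'   exact multiple.
#' @param calibration c(x, y, z) voxel size in micrometres.
#' @return a [raw_stack()].
#' @export
load_stack <- function(path, frames_per_plane, calibration = c(1, 1, 1)) {
  pages <- read_tiff(path)
  np <- length(pages)
  if (np %% frames_per_plane != 0L) {
    stop(np, " pages not divisible by ", frames_per_plane, " frames per plane")
  }
  nz <- np %/% frames_per_plane
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  data <- array(0, dim = c(frames_per_plane, nz, ny, nx))
  for (z in seq_len(nz)) for (f in seq_len(frames_per_plane)) {
    data[f, z, , ] <- pages[[(z - 1L) * frames_per_plane + f]]
  }
  raw_stack(data, calibration)
}

#' Save a raw or clean stack as multi-page TIFF
#' @param stack `raw_stack` (pages in F-within-Z order) or `clean_stack`.
#' @param path output path.
#' @param bits bits per sample.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path, bits = 8L) {
  pages <- if (inherits(stack, "raw_stack")) {
    d <- stack$data
    unlist(lapply(seq_len(dim(d)[2L]), function(z) {
      lapply(seq_len(dim(d)[1L]), function(f) d[f, z, , ])
    }), recursive = FALSE)
  } else {
    d <- if (inherits(stack, "clean_stack")) stack$data else stack
    lapply(seq_len(dim(d)[1L]), function(z) d[z, , ])
  }
  write_tiff(pages, path, bits)
}

# Segment + feature-extract every detected cell of one frame at one mask
# size. Returns a data frame of features plus segmentation metadata.
.cells_from_frame <- function(frame, mask_size, cfg, calibration_xy,
                              max_cells = Inf) {
  seeds <- detect_seeds(frame, calibration = calibration_xy)
  out <- list()
  masks <- list()
  if (nrow(seeds)) {
    for (i in seq_len(min(nrow(seeds), max_cells))) {
      er <- extract_roi(frame, seeds[i, ], calibration_xy)
      cm <- segment_cell(er$roi, er$seed, MS = mask_size, limit = cfg$limit,
                         max_iter = cfg$max_iter, calibration = calibration_xy)
      attr(cm, "offset") <- er$offset
      masks[[i]] <- cm
    }
    ok <- vapply(masks, function(m) m$status == "accepted", TRUE)
    masks <- review_masks(masks, seeds = seeds[ok, , drop = FALSE],
                          policy = "auto")
  }
  for (i in seq_along(masks)) {
    cm <- masks[[i]]
    row <- list(cell = i, seed_y = seeds[i, 1L], seed_x = seeds[i, 2L],
                status = cm$status, area = cm$area,
                threshold = cm$final_threshold, iterations = nrow(cm$history))
    if (cm$status == "accepted") {
      er <- extract_roi(frame, seeds[i, ], calibration_xy)
      soma <- detect_soma(er$roi, cm$mask, calibration_xy)
      if (!is.null(soma)) {
        fv <- extract_features(cm$mask, soma, calibration_xy, cfg$sholl_step)
        row$soma_origin <- soma$origin
        row <- c(row, as.list(fv))
      } else {
        row$status <- "rejected_unstable"
      }
    }
    out[[length(out) + 1L]] <- row
  }
  if (!length(out)) return(NULL)
  nm <- unique(unlist(lapply(out, names)))
  df <- do.call(rbind, lapply(out, function(r) {
    r[setdiff(nm, names(r))] <- NA
    as.data.frame(r[nm], check.names = FALSE)
  }))
  df
}

#' Run the full two-phase pipeline
#'
#' Training phase: every training stack is cleaned, cells are segmented and
#' measured at each candidate mask size, the best mask size is chosen, and
#' the feature count of the index is optimised. Test phase: test stacks are
#' processed at the chosen mask size and scored with the trained index.
#'
#' @param config a [pipeline_config()].
#' @param train named list of `raw_stack` objects (or TIFF paths).
#' @param train_labels factor, one two-level label per training stack.
#' @param train_animals factor of animal ids per training stack (optional).
#' @param test named list of stacks/paths (optional).
#' @param out_dir directory for CSV/JSON outputs, or `NULL` to skip writing.
#' @return list: `model`, `mask_size`, `train_features`, `train_index`,
#'   `test_features`, `test_index`, `report`.
#' @export
run_pipeline <- function(config, train, train_labels, train_animals = NULL,
                         test = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  train_labels <- as.factor(train_labels)
  if (nlevels(train_labels) != 2L) stop("training labels must be binary")
  get_stack <- function(s) {
    if (is.character(s)) load_stack(s, config$frames_per_plane, config$calibration)
    else s
  }
  measure_set <- function(stacks, mask_size) {
    rows <- list()
    for (si in seq_along(stacks)) {
      st <- get_stack(stacks[[si]])
      cs <- clean_stack(st, config$k_sharp, config$k_keep, config$sigma_log)
      projs <- project_substacks(cs)
      for (pi in seq_along(projs)) {
        df <- .cells_from_frame(projs[[pi]], mask_size, config,
                                config$calibration[1L])
        if (!is.null(df)) {
          df$stack <- if (!is.null(names(stacks))) names(stacks)[si] else si
          df$substack <- pi
          rows[[length(rows) + 1L]] <- df
        }
      }
    }
    if (!length(rows)) return(NULL)
    do.call(rbind, rows)
  }
  # training sweep over mask sizes
  tables <- list(); labels_list <- list(); animals_list <- list()
  for (ms in config$mask_sizes) {
    per_stack <- lapply(seq_along(train), function(si) {
      df <- measure_set(train[si], ms)
      if (!is.null(df) && nrow(df)) {
        df$condition <- train_labels[si]
        df$animal <- if (!is.null(train_animals)) train_animals[si] else
          factor(paste0("a", si))
      }
      df
    })
    tab <- do.call(rbind, per_stack)
    if (is.null(tab)) next
    acc <- tab[tab$status == "accepted" & !is.na(tab[["perimeter"]]), , drop = FALSE]
    if (nrow(acc) < 4L || length(unique(acc$condition)) < 2L) next
    tables[[as.character(ms)]] <- acc
    labels_list[[as.character(ms)]] <- droplevels(acc$condition)
    animals_list[[as.character(ms)]] <- acc$animal
  }
  if (!length(tables)) stop("no mask size produced enough accepted cells")
  feat_cols <- feature_names()
  feat_only <- lapply(tables, function(t) t[, feat_cols, drop = FALSE])
  ms_best <- choose_mask_size(feat_only, labels_list, method = config$method,
                              top_n = config$top_n, animal_list = animals_list)
  key <- as.character(ms_best)
  model <- optimize_feature_count(feat_only[[key]], labels_list[[key]],
                                  N_max = config$N_max, method = config$method,
                                  animal = animals_list[[key]],
                                  mask_size = ms_best)
  train_tab <- tables[[key]]
  train_idx <- apply_index(model, train_tab[, feat_cols, drop = FALSE])
  # test phase
  test_tab <- NULL; test_idx <- NULL
  if (!is.null(test) && length(test)) {
    ttab <- measure_set(test, ms_best)
    if (!is.null(ttab)) {
      test_tab <- ttab[ttab$status == "accepted" & !is.na(ttab[["perimeter"]]), ,
                       drop = FALSE]
      if (nrow(test_tab)) {
        test_idx <- apply_index(model, test_tab[, feat_cols, drop = FALSE],
                                mask_size = ms_best)
      }
    }
  }
  count_status <- function(tab) {
    if (is.null(tab)) return(table(factor(character(0))))
    table(tab$status)
  }
  report <- list(
    mask_size = ms_best,
    mask_size_scores = attr(ms_best, "scores"),
    n_features = model$n_features,
    selected_features = model$features,
    train_auc = roc_auc(train_idx, labels_list[[key]])$folded,
    train_cells = nrow(train_tab),
    test_cells = if (is.null(test_tab)) 0L else nrow(test_tab))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cbind(train_tab, index = train_idx),
                     file.path(out_dir, "train_features.csv"), row.names = FALSE)
    if (!is.null(test_tab) && nrow(test_tab)) {
      utils::write.csv(cbind(test_tab, index = test_idx),
                       file.path(out_dir, "test_features.csv"), row.names = FALSE)
    }
    write_index_model(model, file.path(out_dir, "index_model.json"))
  }
  list(model = model, mask_size = as.numeric(ms_best),
       train_features = train_tab, train_index = train_idx,
       test_features = test_tab, test_index = test_idx, report = report)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `synth-stack`, `synth-dataset`, `clean`,
#' `segment`, `features`, `train-index` and `apply-index`. Run with no
#' arguments for usage. Installed alongside the package under
#' `inst/cli/mgmorph`.
#'
#' @param args character vector, defaults to `commandArgs(trailingOnly=TRUE)`.
#' @return exit status, invisibly.
#' @export
mgmorph_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mgmorph <command> [options]",
    "  synth-stack  --out PATH [--seed N] [--planes N] [--frames N]",
    "  clean        --in PATH --out PATH [--frames N]",
    "  segment      --in PATH --out CSV --mask-size MS [--limit L]",
    "  features     --in PATH --out CSV --mask-size MS",
    "  train-index  --features CSV --labels COL --out MODEL.json [--n-max N]",
    "  apply-index  --features CSV --model MODEL.json --out CSV",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- if (i + 1L <= length(args)) args[i + 1L] else ""
    i <- i + 2L
  }
  num <- function(k, d) if (!is.null(opts[[k]])) as.numeric(opts[[k]]) else d
  chr <- function(k, d = NULL) if (!is.null(opts[[k]])) opts[[k]] else d
  switch(cmd,
    "synth-stack" = {
      seed <- as.integer(num("seed", 1))
      sp <- cell_spec(c(48, 48), 4, 5, 20, 0.05, 0.3, seed = seed)
      gs <- generate_raw_stack(sp, stack_corruption(noise_sd = 5, jitter_px = 1),
                               frames_per_plane = as.integer(num("frames", 6)),
                               n_planes = as.integer(num("planes", 8)),
                               seed = seed)
      save_stack(gs$stack, chr("out"))
      write_truth_sidecar(gs$truth, paste0(chr("out"), ".truth.txt"))
    },
    "clean" = {
      st <- load_stack(chr("in"), as.integer(num("frames", 6)))
      cs <- clean_stack(st)
      save_stack(cs, chr("out"))
    },
    "segment" = ,
    "features" = {
      st <- load_stack(chr("in"), as.integer(num("frames", 6)))
      cs <- clean_stack(st)
      projs <- project_substacks(cs)
      cfg <- pipeline_config(mask_sizes = num("mask-size", 400),
                             limit = num("limit", 100))
      dfs <- lapply(seq_along(projs), function(pi) {
        df <- .cells_from_frame(projs[[pi]], num("mask-size", 400), cfg,
                                cfg$calibration[1L])
        if (!is.null(df)) df$substack <- pi
        df
      })
      df <- do.call(rbind, dfs)
      utils::write.csv(df, chr("out"), row.names = FALSE)
    },
    "train-index" = {
      tab <- utils::read.csv(chr("features"), check.names = FALSE)
      lab <- as.factor(tab[[chr("labels", "condition")]])
      model <- optimize_feature_count(tab[, feature_names(), drop = FALSE], lab,
                                      N_max = as.integer(num("n-max", 15)))
      write_index_model(model, chr("out"))
    },
    "apply-index" = {
      tab <- utils::read.csv(chr("features"), check.names = FALSE)
      model <- read_index_model(chr("model"))
      tab$index <- apply_index(model, tab)
      utils::write.csv(tab, chr("out"), row.names = FALSE)
    },
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
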