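#' Run configuration
#'
#' Bundles every module's parameters for the end-to-end drivers. The `test`
#' profile (32x32 layers, 4 views x 9 locations, 15 epochs) targets minutes
#' on one CPU; `full` mirrors the complete protocol (128x128 layers,
#' 4 views x 25 locations = 100 transforms per object, 50 epochs).
#'
#' @param profile `"test"` or `"full"`.
#' @param seed base seed; all stochastic components draw named substreams
#'   from it.
#' @param ... overrides for any config entry.
#' @return `run_config` list.
#' @export
default_config <- function(profile = c("test", "full"), seed = 1, ...) {
  profile <- match.arg(profile)
  test <- profile == "test"
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    views = c(270, 315, 0, 45),
    grid_n = if (test) 3L else 5L,
    grid_spacing = 16L,
    canvas_size = 512L,
    retina_size = if (test) 64L else 128L,
    epochs = if (test) 15L else 50L,
    eta = c(0, 0.8, 0.8, 0.8),
    gabor = list(orientations = c(0, 45, 90, 135),
                 frequencies = c(0.03125, 0.0625, 0.125, 0.25),
                 sigma_per_cycle = 0.5),
    layers = default_layer_configs(profile),
    readout = list(n_bins = 10L, per_object = 25L, cv_folds = 5L),
    saliency = list(scales = c(32, 16, 8), sigma_frac = 0.15,
                    norm_sigma_frac = 0.06, n_norm = 2L,
                    k = 6L, threshold_frac = 0.2, patch_size = 384L),
    scene = list(n = 12L, size = 1024L, n_distractors = 2L, noise_amp = 10),
    match_radius = 64
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> profile=", x$profile, " seed=", x$seed,
      " views={", paste(x$views, collapse = ","), "} grid=",
      x$grid_n, "x", x$grid_n, "@", x$grid_spacing, "px epochs=", x$epochs,
      "\n", sep = "")
  invisible(x)
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Build the training set of V1 responses
#'
#' Renders every object at every trained view, filters the centred canvas
#' through the V1 front-end once per (object, view), and derives the
#' response at every grid offset by translating the retinal response
#' (exact up to border cells, since filtering is translation-equivariant
#' and the uniform background drives no response). `n_views * n_locations`
#' transforms per object: 4 x 25 = 100 in the full protocol.
#'
#' @param config a [default_config()].
#' @param cache_dir optional directory; the trainset is stored under a
#'   config-hash filename and re-used on identical config. A cache file
#'   whose stored hash disagrees with its name errors.
#' @return list of class `trainset`: per-object matrices
#'   (transform x input-dim) plus a `meta` tibble and the bank.
#' @export
build_trainset <- function(config, cache_dir = NULL) {
  h <- config_hash(config[c("views", "grid_n", "grid_spacing", "canvas_size",
                            "retina_size", "gabor")])
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0("trainset-", h, ".rds"))
    if (file.exists(f)) {
      ts <- readRDS(f)
      if (!identical(ts$hash, h))
        abort("trainset cache collision: stored config hash differs")
      return(ts)
    }
  }
  bank <- do.call(gabor_bank, config$gabor)
  grid <- make_translation_grid(config$grid_n, config$grid_spacing)
  meta <- tidyr::expand_grid(object_id = 0:3, view_deg = config$views, grid)
  per_obj <- purrr::map(0:3, function(id) {
    spec <- object_spec(id)
    rows <- purrr::map(config$views, function(v) {
      obj <- render_object(spec, v)
      t(vapply(seq_len(nrow(grid)),
               function(i) as.vector(v1_at_offset(obj, grid$dx[i], grid$dy[i],
                                                  bank, config)),
               numeric(config$retina_size^2 * n_channels(bank))))
    })
    do.call(rbind, rows)
  })
  ts <- structure(list(data = per_obj, meta = meta, bank = bank, hash = h,
                       config = config[c("views", "grid_n", "grid_spacing",
                                         "canvas_size", "retina_size", "gabor")]),
                  class = "trainset")
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(ts, file.path(cache_dir, paste0("trainset-", h, ".rds")))
  }
  ts
}

# V1 response of an object placed at (dx, dy) on the training canvas.
# Offsets that are whole multiples of the retinal stride reuse the centred
# response via exact translation equivariance; others filter the shifted
# canvas directly. The centred response is cached on the bank keyed by the
# object image.
v1_at_offset <- function(obj, dx, dy, bank, config) {
  stride <- config$canvas_size / config$retina_size
  if (dx %% stride == 0 && dy %% stride == 0) {
    key <- paste0("v1base_", config$retina_size, "_", rlang::hash(obj))
    if (is.null(bank$fft_cache[[key]]))
      bank$fft_cache[[key]] <- filter_image(place_on_canvas(obj, c(0, 0), config$canvas_size),
                                            bank, config$retina_size)
    shift_v1(bank$fft_cache[[key]], dx %/% stride, dy %/% stride)
  } else {
    filter_image(place_on_canvas(obj, c(dx, dy), config$canvas_size),
                 bank, config$retina_size)
  }
}

#' @export
print.trainset <- function(x, ...) {
  cat("<trainset> ", length(x$data), " objects x ", nrow(x$data[[1]]),
      " transforms, input dim ", ncol(x$data[[1]]), "\n", sep = "")
  invisible(x)
}

#' Train the network and fit the information readout
#'
#' End-to-end training driver: builds (or takes) the trainset, initialises
#' the network, runs the trace-rule training, collects the layer-4 response
#' tensor over all trained transforms, computes per-cell information,
#' selects the most selective cells per object, and trains the
#' pattern-associator readout on them.
#'
#' @param config a [default_config()].
#' @param trainset optional pre-built [build_trainset()] result.
#' @param train logical; `FALSE` skips the synaptic learning (the untrained
#'   control network — its readout is still fitted).
#' @return `visnet_study`: list with `net`, `trainset`, `tensor`, `info`,
#'   `cells`, `readout`, `history`, `config`.
#' @export
train_study <- function(config = default_config(), trainset = NULL, train = TRUE) {
  ts <- trainset %||% build_trainset(config)
  net <- init_network(config$layers, config$retina_size, n_channels(ts$bank),
                      seed = substream_seed(config$seed, "network"), eta = config$eta,
                      channel_weights = ts$bank$channels$frequency^2)
  history <- NULL
  if (train && config$epochs > 0)
    history <- train_all(net, ts$data, config$epochs,
                         seed = substream_seed(config$seed, "train"))
  tensor <- collect_responses(net, ts)
  info <- cell_information(tensor, config$readout$n_bins)
  cells <- select_cells(info, config$readout$per_object)
  n_tr <- nrow(ts$data[[1]])
  X <- do.call(cbind, purrr::map(seq_along(ts$data), function(o)
    matrix(tensor$rates[cells, o, ], length(cells))))
  labels <- rep(0:3, each = n_tr)
  readout <- train_readout(X, labels, object_ids = 0:3)
  structure(list(net = net, trainset = ts, tensor = tensor, info = info,
                 cells = cells, readout = readout, history = history,
                 config = config, config_hash = config_hash(config)),
            class = "visnet_study")
}

#' Layer-4 responses over a trainset
#'
#' Presents every transform of every object with learning off and stacks the
#' layer-4 firing into a [response_tensor()].
#'
#' @param net trained `visnet`.
#' @param ts a `trainset`.
#' @export
collect_responses <- function(net, ts) {
  S <- length(ts$data)
  Tn <- nrow(ts$data[[1]])
  g4 <- net$layers[[4]]$config$grid_size
  rates <- array(0, c(g4 * g4, S, Tn))
  for (o in seq_len(S)) for (t in seq_len(Tn)) {
    rates[, o, t] <- present(net, ts$data[[o]][t, ], learn = FALSE)$y4
  }
  response_tensor(rates, object_ids = 0:(S - 1))
}

#' @export
print.visnet_study <- function(x, ...) {
  cat("<visnet_study> profile=", x$config$profile,
      ", ", length(x$cells), " readout cells, top cell ",
      round(max(x$info$bits), 3), " bits\n", sep = "")
  invisible(x)
}

# Classify a set of V1 input vectors with a study's net + readout.
classify_inputs <- function(study, X) {
  preds <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    y4 <- present(study$net, X[i, ], learn = FALSE)$y4
    preds[i] <- classify(study$readout, y4[study$cells], quiet = TRUE)
  }
  preds
}

#' Translation generalisation sweep
#'
#' Tests view-invariant identification at offsets along the grid axes
#' (positions `(+-d, 0)` and `(0, +-d)` at every trained view), covering the
#' trained offsets (multiples of the grid spacing up to its extent) and
#' untrained intermediate and beyond-range offsets. Patches are rendered on
#' plain backgrounds.
#'
#' @param study a [train_study()] result.
#' @param distances offsets from the grid centre, pixels.
#' @return tibble `(distance, trained, n, percent_correct)`.
#' @export
evaluate_translation_sweep <- function(study,
                                       distances = c(0, 8, 16, 24, 32, 40, 48)) {
  cfg <- study$config
  bank <- study$trainset$bank
  trained_max <- (cfg$grid_n - 1) / 2 * cfg$grid_spacing
  res <- list()
  for (id in 0:3) {
    spec <- object_spec(id)
    for (v in cfg$views) {
      obj <- render_object(spec, v)
      for (d in distances) {
        offs <- if (d == 0) list(c(0, 0)) else list(c(d, 0), c(-d, 0), c(0, d), c(0, -d))
        X <- t(vapply(offs, function(o)
          as.vector(v1_at_offset(obj, o[1], o[2], bank, cfg)),
          numeric(cfg$retina_size^2 * n_channels(bank))))
        res[[length(res) + 1]] <- tibble(
          object_id = id, view_deg = v, distance = d,
          correct = classify_inputs(study, X) == id)
      }
    }
  }
  bind_rows(res) |>
    group_by(distance) |>
    summarise(n = n(), percent_correct = 100 * mean(correct), .groups = "drop") |>
    mutate(trained = distance %% cfg$grid_spacing == 0 & distance <= trained_max,
           .after = "distance")
}

#' View generalisation sweep
#'
#' Tests identification at the trained views and at `n_intermediate`
#' untrained views inside each 45-degree interval between consecutive
#' trained views (step 45/(n_intermediate + 1) degrees), on plain
#' backgrounds at the central location.
#'
#' @param study a [train_study()] result.
#' @param n_intermediate intermediate views per interval (default 6).
#' @return tibble `(view_deg, trained, n, percent_correct)`.
#' @export
evaluate_view_sweep <- function(study, n_intermediate = 6) {
  cfg <- study$config
  bank <- study$trainset$bank
  step <- 45 / (n_intermediate + 1)
  views <- sort(unique((270 + step * 0:(3 * (n_intermediate + 1))) %% 360))
  res <- list()
  for (id in 0:3) {
    spec <- object_spec(id)
    for (v in views) {
      x <- filter_image(place_on_canvas(render_object(spec, v), c(0, 0),
                                        cfg$canvas_size), bank, cfg$retina_size)
      res[[length(res) + 1]] <- tibble(
        object_id = id, view_deg = v,
        correct = classify_inputs(study, matrix(as.vector(x), 1)) == id)
    }
  }
  bind_rows(res) |>
    group_by(view_deg) |>
    summarise(n = n(), percent_correct = 100 * mean(correct), .groups = "drop") |>
    mutate(trained = view_deg %in% (cfg$views %% 360), .after = "view_deg")
}

#' Repeat a sweep over re-seeded networks
#'
#' Re-trains the study with different network seeds and aggregates a sweep's
#' percent-correct as mean and standard deviation per condition, mirroring
#' the repeat-with-different-connectivity-seeds protocol.
#'
#' @param config a [default_config()].
#' @param n_seeds number of independently seeded replicates.
#' @param sweep one of `"translation"`, `"view"`.
#' @param ... passed to the sweep function.
#' @return tibble with per-condition mean and sd of percent correct.
#' @export
sweep_replicates <- function(config, n_seeds = 10, sweep = c("translation", "view"), ...) {
  sweep <- match.arg(sweep)
  ts <- build_trainset(config)
  runs <- purrr::map(seq_len(n_seeds), function(i) {
    cfg_i <- config; cfg_i$seed <- substream_seed(config$seed, paste0("replicate", i))
    st <- train_study(cfg_i, trainset = ts)
    out <- if (sweep == "translation") evaluate_translation_sweep(st, ...)
           else evaluate_view_sweep(st, ...)
    mutate(out, replicate = i)
  })
  key <- if (sweep == "translation") "distance" else "view_deg"
  bind_rows(runs) |>
    group_by(.data[[key]], trained) |>
    summarise(mean_percent_correct = mean(percent_correct),
              sd_percent_correct = stats::sd(percent_correct),
              n_replicates = dplyr::n(), .groups = "drop")
}

#' Run the full two-stream pipeline over cluttered scenes
#'
#' For each scene: saliency map -> ranked fixations -> fixation-centred
#' patches (embedded centred on a mid-gray canvas to preserve training
#' scale) -> V1 -> network -> readout. Patches whose fixation lies within
#' `match_radius` of a ground-truth object centre are scored against that
#' object; remaining patches are reported separately as distractor
#' fixations. Scenes without ground truth are classified but excluded from
#' accuracy.
#'
#' @param study a [train_study()] result.
#' @param scenes list of `scene` objects (e.g. [make_scene_set()]).
#' @param fixations optional list of per-scene fixation tibbles (as returned
#'   in a previous report's `fixations`), bypassing the saliency stage —
#'   useful when re-classifying the same scenes with a different network,
#'   since fixations depend only on the scenes.
#' @return `scene_report`: list with `patches` (per-patch tibble),
#'   `accuracy`, `confusion` (matrix), `offsets` (tibble), `fixations`,
#'   `config_hash`, `seed`.
#' @export
run_scene_pipeline <- function(study, scenes, fixations = NULL) {
  cfg <- study$config
  sal <- cfg$saliency
  bank <- study$trainset$bank
  rows <- list(); offs <- list(); fxs <- vector("list", length(scenes))
  for (si in seq_along(scenes)) {
    sc <- scenes[[si]]
    if (is.null(fixations)) {
      sm <- saliency_map(sc$image, scales = sal$scales, sigma_frac = sal$sigma_frac,
                         norm_sigma_frac = sal$norm_sigma_frac, n_norm = sal$n_norm)
      fx <- extract_fixations(sm, k = sal$k, threshold_frac = sal$threshold_frac)
    } else {
      fx <- fixations[[si]]
    }
    fxs[[si]] <- fx
    offs[[si]] <- mutate(offset_statistics(fx, sc$truth, cfg$match_radius), scene = si)
    for (i in seq_len(nrow(fx))) {
      patch <- extract_patch(sc$image, c(fx$row[i], fx$col[i]), sal$patch_size)
      canvas <- matrix(127, cfg$canvas_size, cfg$canvas_size)
      o0 <- (cfg$canvas_size - sal$patch_size) %/% 2
      canvas[o0 + seq_len(sal$patch_size), o0 + seq_len(sal$patch_size)] <- patch
      x <- filter_image(canvas, bank, cfg$retina_size)
      pred <- classify_inputs(study, matrix(as.vector(x), 1))
      truth_id <- NA_integer_
      if (nrow(sc$truth) > 0) {
        d <- sqrt((sc$truth$row - fx$row[i])^2 + (sc$truth$col - fx$col[i])^2)
        if (min(d) <= cfg$match_radius) truth_id <- sc$truth$object_id[which.min(d)]
      }
      rows[[length(rows) + 1]] <- tibble(
        scene = si, fixation_rank = fx$rank[i], row = fx$row[i], col = fx$col[i],
        predicted = pred, truth = truth_id)
    }
  }
  patches <- bind_rows(rows)
  scored <- filter(patches, !is.na(truth))
  conf <- matrix(0L, 4, 4, dimnames = list(truth = 0:3, predicted = 0:3))
  for (i in seq_len(nrow(scored)))
    conf[scored$truth[i] + 1L, scored$predicted[i] + 1L] <-
      conf[scored$truth[i] + 1L, scored$predicted[i] + 1L] + 1L
  structure(list(
    patches = patches,
    accuracy = tibble(n_scored = nrow(scored),
                      n_distractor = sum(is.na(patches$truth)),
                      percent_correct = if (nrow(scored) > 0)
                        percent_correct(scored$predicted, scored$truth) else NA_real_),
    confusion = conf,
    offsets = bind_rows(offs),
    fixations = fxs,
    config_hash = study$config_hash,
    seed = cfg$seed
  ), class = "scene_report")
}

#' @export
print.scene_report <- function(x, ...) {
  cat("<scene_report> ", x$accuracy$n_scored, " scored patches, ",
      x$accuracy$n_distractor, " distractor fixations, ",
      round(x$accuracy$percent_correct, 1), "% correct\n", sep = "")
  invisible(x)
}
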