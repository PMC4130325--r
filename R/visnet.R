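#' Per-layer configuration of the hierarchical network
#'
#' @param grid_size neurons per side of the square layer grid.
#' @param fan_in synapses per neuron, sampled from the topologically
#'   corresponding neighbourhood of the source layer.
#' @param conn_sigma std (source-grid units) of the Gaussian used to sample
#'   afferent positions.
#' @param inhib_sigma,inhib_contrast lateral-inhibition filter: Gaussian
#'   surround width (grid units) and inhibitory gain.
#' @param sparseness_percentile fraction of neurons pushed below
#'   half-activation by the sparsifying sigmoid (e.g. 0.992 leaves ~0.8%
#'   of neurons above 0.5).
#' @param sigmoid_slope gain of the sigmoid (dimensionless; activations are
#'   rescaled to unit maximum before thresholding).
#' @param learning_rate Hebbian trace-rule rate for this layer.
#' @return `layer_config` list.
#' @export
layer_config <- function(grid_size, fan_in, conn_sigma, inhib_sigma,
                         inhib_contrast, sparseness_percentile,
                         sigmoid_slope, learning_rate) {
  if (fan_in < 1) abort("fan_in must be >= 1")
  if (sparseness_percentile <= 0 || sparseness_percentile >= 1)
    abort("sparseness_percentile must be in (0, 1)")
  if (learning_rate < 0) abort("learning_rate must be >= 0")
  structure(list(grid_size = as.integer(grid_size), fan_in = as.integer(fan_in),
                 conn_sigma = conn_sigma, inhib_sigma = inhib_sigma,
                 inhib_contrast = inhib_contrast,
                 sparseness_percentile = sparseness_percentile,
                 sigmoid_slope = sigmoid_slope, learning_rate = learning_rate),
            class = "layer_config")
}

#' Default layer configurations for a run profile
#'
#' The `test` profile uses 32x32 layers on a 64-cell retina (small
#' hierarchies of this size are known to generalise); `full` uses 128x128
#' layers on a 128-cell retina, totalling 65,536 neurons across the four
#' layers. Learning rates are 0.05, 0.03, 0.005, 0.005 for layers 1-4.
#' Sigmoid percentile/slope pairs and inhibition parameters follow the
#' canonical values for this model family, with inhibition radii scaled to
#' the grid and the layer-1 sampling radius scaled to the retina.
#'
#' @param profile `"test"` or `"full"`.
#' @return list of four [layer_config()]s.
#' @export
default_layer_configs <- function(profile = c("test", "full")) {
  profile <- match.arg(profile)
  g <- if (profile == "test") 32L else 128L
  retina <- if (profile == "test") 64L else 128L
  sc <- g / 32
  list(
    layer_config(g, 272L, 6 * retina / 32, 1.38 * sc, 1.5, 0.992, 190, 0.05),
    layer_config(g, 100L, 5 * sc, 2.70 * sc, 1.5, 0.980, 40, 0.03),
    layer_config(g, 100L, 5 * sc, 4.00 * sc, 1.6, 0.880, 75, 0.005),
    layer_config(g, 100L, 5 * sc, 6.00 * sc, 1.4, 0.910, 26, 0.005)
  )
}

# ---- connectivity -----------------------------------------------------------

# Sample fan_in distinct afferents for every neuron of a g x g layer from a
# source grid of src_g x src_g positions with n_ch channels per position.
# Positions are drawn from a Gaussian centred on the topologically
# corresponding source position; channels uniformly.
sample_connectivity <- function(g, src_g, n_ch, fan_in, sigma,
                                channel_weights = NULL) {
  n <- g * g
  idx <- matrix(0L, n, fan_in)
  centre <- function(i) (i - 0.5) * src_g / g + 0.5
  cw <- channel_weights %||% rep(1, n_ch)
  cw <- cw / sum(cw)
  for (i in seq_len(g)) {
    cr <- centre(i)
    for (j in seq_len(g)) {
      cc <- centre(j)
      got <- integer(0)
      while (length(got) < fan_in) {
        need <- fan_in - length(got)
        r <- round(rnorm(3 * need + 8, cr, sigma))
        c <- round(rnorm(3 * need + 8, cc, sigma))
        ch <- sample.int(n_ch, 3 * need + 8, replace = TRUE, prob = cw)
        ok <- r >= 1 & r <= src_g & c >= 1 & c <= src_g
        cand <- (ch[ok] - 1L) * src_g * src_g + (c[ok] - 1L) * src_g + r[ok]
        got <- unique(c(got, cand))
      }
      idx[(j - 1L) * g + i, ] <- got[seq_len(fan_in)]
    }
  }
  idx
}

normalise_rows <- function(w) {
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  w / nrm
}

#' Initialise the four-layer network
#'
#' Afferents of each neuron are sampled from a Gaussian around its
#' topologically corresponding position in the source layer (layer 1 samples
#' the V1 lattice across all channels); initial weights are positive random
#' and L2-normalised per neuron. Construction is deterministic given `seed`
#' (connectivity and weights draw from named substreams). At initialisation
#' the composed receptive field of a central layer-4 neuron is measured by
#' graph reachability; if it covers less than `min_coverage` of the retina,
#' initialisation fails with the measured value.
#'
#' @param configs list of four [layer_config()]s.
#' @param retina_size V1 lattice side.
#' @param n_channels number of V1 channels per lattice position.
#' @param seed integer seed.
#' @param eta trace decay parameter in `[0, 1)`: a scalar or one value per
#'   layer. `eta = 0` reduces that layer's learning to the plain Hebb rule
#'   (the default uses plain Hebb in layer 1, where position-specific
#'   feature analysers are wanted, and the trace in layers 2-4, where
#'   invariance is bound).
#' @param min_coverage minimum layer-4 retinal coverage fraction.
#' @param channel_weights optional sampling weight per V1 channel for the
#'   layer-1 afferents (the standard allocation weights frequency bands
#'   proportional to the square of their spatial frequency, giving most
#'   synapses to the fine-scale channels).
#' @return `visnet` object (an environment: layers mutate in place during
#'   training).
#' @export
init_network <- function(configs, retina_size, n_channels, seed = 1,
                         eta = c(0, 0.8, 0.8, 0.8), min_coverage = 0.95,
                         channel_weights = NULL) {
  if (length(configs) != 4) abort("exactly 4 layer configs are required")
  if (!length(eta) %in% c(1L, 4L) || any(eta < 0) || any(eta >= 1))
    abort("eta must be in [0, 1), one value or one per layer")
  eta <- rep(eta, length.out = 4)
  net <- new.env(parent = emptyenv())
  net$retina_size <- as.integer(retina_size)
  net$n_channels <- as.integer(n_channels)
  net$seed <- as.integer(seed)
  net$eta <- eta
  net$layers <- vector("list", 4)
  for (l in 1:4) {
    cfg <- configs[[l]]
    src_g <- if (l == 1) retina_size else configs[[l - 1]]$grid_size
    src_ch <- if (l == 1) n_channels else 1L
    idx <- withr::with_seed(substream_seed(seed, paste0("conn", l)),
                            sample_connectivity(cfg$grid_size, src_g, src_ch,
                                                cfg$fan_in, cfg$conn_sigma,
                                                if (l == 1) channel_weights))
    w <- withr::with_seed(substream_seed(seed, paste0("weights", l)),
                          matrix(runif(length(idx)), nrow(idx)))
    net$layers[[l]] <- list(config = cfg, idx = idx, w = normalise_rows(w),
                            trace = numeric(nrow(idx)), y = numeric(nrow(idx)),
                            src_g = src_g, src_ch = src_ch)
  }
  class(net) <- "visnet"
  cov <- layer4_coverage(net)
  if (cov < min_coverage)
    abort(paste0("layer-4 retinal coverage ", round(cov, 3), " < ",
                 min_coverage, "; increase conn_sigma"))
  net$coverage <- cov
  net
}

#' Retinal coverage of a central layer-4 neuron
#'
#' Brute-force union of afferent chains from one central layer-4 neuron down
#' to the retina; returns the fraction of retinal lattice positions reached.
#'
#' @param net a `visnet`.
#' @export
layer4_coverage <- function(net) {
  g4 <- net$layers[[4]]$config$grid_size
  ci <- (g4 %/% 2L - 1L) * g4 + g4 %/% 2L  # a central neuron
  src <- net$layers[[4]]$idx[ci, ]
  for (l in 3:1) {
    src <- unique(as.vector(net$layers[[l]]$idx[src, ]))
  }
  # collapse channels to spatial positions on the retina
  pos <- unique((src - 1L) %% (net$retina_size^2) + 1L)
  length(pos) / net$retina_size^2
}

#' @export
print.visnet <- function(x, ...) {
  g <- vapply(x$layers, function(l) l$config$grid_size, 1L)
  cat("<visnet> layers ", paste0(g, "x", g, collapse = " -> "),
      ", retina ", x$retina_size, "x", x$retina_size, " x ", x$n_channels,
      " channels, eta = {", paste(x$eta, collapse = ","), "}",
      ", layer-4 coverage ", round(x$coverage, 3), "\n", sep = "")
  invisible(x)
}

# ---- elementary operations (exported for direct use and testing) -----------

#' Feedforward activation of one layer
#'
#' `h_i = sum_j w_ij x_j` over each neuron's afferent synapses; equivalent to
#' a dense matrix-vector product with zeros at absent synapses.
#'
#' @param x source activation vector.
#' @param layer one element of `net$layers` (list with `idx`, `w`).
#' @return nonnegative activation vector, one entry per neuron.
#' @export
propagate <- function(x, layer) {
  rowSums(layer$w * matrix(x[layer$idx], nrow(layer$idx)))
}

#' Short-range lateral inhibition
#'
#' Convolves the activation grid with a centre-excitatory,
#' surround-inhibitory contrast filter (Gaussian surround of width
#' `inhib_sigma`, gain `inhib_contrast`, reflect borders) and rectifies at 0.
#' A neuron surrounded by equally active neighbours is suppressed relative to
#' an isolated neuron of the same amplitude.
#'
#' @param h activation matrix (square grid).
#' @param inhib_sigma,inhib_contrast filter parameters.
#' @return inhibited activation matrix, nonnegative.
#' @export
lateral_inhibit <- function(h, inhib_sigma, inhib_contrast) {
  K <- inhib_kernel(inhib_sigma, inhib_contrast)
  key <- paste0("i", nrow(h), "_", inhib_sigma, "_", inhib_contrast)
  r <- (nrow(K) - 1L) %/% 2L
  np <- nrow(h) + 2L * r
  if (is.null(.inhib_cache[[key]]))
    .inhib_cache[[key]] <- kernel_fft_set(list(K), np, np)
  pmax(fft_corr_bank(h, list(K), kernel_ffts = .inhib_cache[[key]], radius = r)[[1]], 0)
}

.inhib_cache <- new.env(parent = emptyenv())

# Centre-excitatory, surround-inhibitory contrast filter with unit total
# mass: K(d) = -contrast * exp(-d^2 / sigma^2) off-centre, and the centre
# compensates so that sum(K) = 1. A uniform field passes unchanged while an
# isolated peak is amplified by the centre gain, so a neuron surrounded by
# equally active neighbours ends up suppressed relative to an isolated one.
inhib_kernel <- function(inhib_sigma, inhib_contrast) {
  G <- gaussian_kernel(inhib_sigma / sqrt(2))  # exp(-d^2 / sigma^2)
  K <- -inhib_contrast * G
  ctr <- (nrow(G) + 1) %/% 2
  K[ctr, ctr] <- 1 + inhib_contrast * (sum(G) - 1)
  K
}

#' Sparseness-controlled sigmoid activation
#'
#' Rescales activations to unit maximum, thresholds at the given percentile
#' across the layer and applies a logistic of the given slope, so that about
#' `1 - percentile` of neurons end above half-activation. A layer whose
#' activations are all equal (e.g. blank input) degenerates to uniform 0.5
#' and is reported via a message.
#'
#' @param h nonnegative activation vector or matrix.
#' @param percentile sparseness percentile in (0, 1).
#' @param slope sigmoid gain.
#' @param quiet suppress the degenerate-input message.
#' @return activations in `[0, 1]`, same shape as `h`.
#' @export
apply_sigmoid_sparseness <- function(h, percentile, slope, quiet = FALSE) {
  hv <- as.vector(h)
  if (max(hv) == min(hv)) {
    if (!quiet) inform("degenerate all-equal activations: layer output uniform at 0.5")
    out <- rep(0.5, length(hv))
  } else {
    z <- hv / max(hv)
    th <- as.numeric(quantile(z, percentile))
    out <- logistic(slope * (z - th))
  }
  if (is.matrix(h)) matrix(out, nrow(h)) else out
}

#' Update the activity trace
#'
#' `trace(t) = (1 - eta) * y(t) + eta * trace(t-1)`, elementwise.
#'
#' @param y current firing vector.
#' @param trace previous trace vector.
#' @param eta decay parameter in `[0, 1)`.
#' @export
update_trace <- function(y, trace, eta) (1 - eta) * y + eta * trace

#' One trace-Hebbian learning step on a layer's weights
#'
#' `dw_ij = rate * trace_i * x_j` applied to existing synapses only, followed
#' by per-neuron L2 renormalisation. Weights remain nonnegative.
#'
#' @param layer layer list with `idx` and `w`.
#' @param x source activation vector.
#' @param trace post-synaptic trace vector (already updated for the current
#'   presentation).
#' @param rate learning rate.
#' @return the layer with updated weights.
#' @export
learn_step <- function(layer, x, trace, rate) {
  if (rate == 0) return(layer)
  layer$w <- normalise_rows(layer$w + rate * trace * matrix(x[layer$idx], nrow(layer$idx)))
  layer
}

#' Forward pass of the network
#'
#' Runs propagate -> lateral inhibition -> sparsifying sigmoid through the
#' four layers. With `learn = TRUE`, the per-layer trace is updated and the
#' trace-Hebbian step applied layer by layer during the pass. The network is
#' an environment and is modified in place when learning.
#'
#' @param net a `visnet`.
#' @param v1 `v1_response` array or plain numeric input vector.
#' @param learn apply trace update + learning.
#' @param quiet passed to [apply_sigmoid_sparseness()].
#' @return list of activation vectors `y1..y4` (invisibly the same vectors
#'   are stored on the network).
#' @export
present <- function(net, v1, learn = FALSE, quiet = TRUE) {
  x <- normalise_input(as.vector(v1))
  ys <- vector("list", 4)
  for (l in 1:4) {
    layer <- net$layers[[l]]
    cfg <- layer$config
    y <- layer_forward(layer, cfg, x, quiet = quiet)
    if (learn) {
      layer$trace <- update_trace(y, layer$trace, net$eta[l])
      layer <- learn_step(layer, x, layer$trace, cfg$learning_rate)
    }
    layer$y <- y
    net$layers[[l]] <- layer
    ys[[l]] <- y
    x <- normalise_input(y)
  }
  names(ys) <- paste0("y", 1:4)
  ys
}

# Unit-L2 scaling of a layer's input rates: the forward pass is invariant to
# input scale (activations are rescaled before the sigmoid), but the Hebbian
# increment is not — normalisation keeps the per-presentation weight change
# proportional to the learning rate for every layer and input magnitude.
normalise_input <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}

#' Reset all layer traces to zero
#' @param net a `visnet`.
#' @export
reset_traces <- function(net) {
  for (l in 1:4) net$layers[[l]]$trace <- numeric(length(net$layers[[l]]$trace))
  invisible(net)
}

#' Train on all transforms of one object
#'
#' Resets the trace in all layers, then presents the object's transforms in a
#' seeded random permutation with learning on — the temporal contiguity of a
#' single object's transforms is what the trace rule binds.
#'
#' @param net a `visnet`.
#' @param transforms matrix of V1 input vectors, one row per transform.
#' @param perm_seed integer seed for the permutation.
#' @return the permutation used, invisibly.
#' @export
train_object_sequence <- function(net, transforms, perm_seed = 1) {
  if (nrow(transforms) < 1) abort("need at least one transform")
  reset_traces(net)
  perm <- withr::with_seed(perm_seed, sample.int(nrow(transforms)))
  for (t in perm) present(net, transforms[t, ], learn = TRUE)
  invisible(perm)
}

#' Train the network on the full object set
#'
#' Trains the hierarchy one layer at a time, from layer 1 upward (the
#' standard protocol for competitive hierarchies: each layer's feature
#' combinations stabilise before the next layer learns on them). Within a
#' stage, each epoch iterates the objects; each object's transforms are
#' shown in a fresh seeded permutation after a trace reset. While a layer is
#' trained, the frozen lower layers' outputs are computed once and cached.
#' With `staged = FALSE` all four layers learn simultaneously during every
#' pass (each object via [train_object_sequence()]).
#'
#' Tracks the mean absolute weight change of the learning layer(s) per epoch
#' as a convergence diagnostic and aborts if it grows for five consecutive
#' epochs.
#'
#' @param net a `visnet`.
#' @param dataset list, one matrix of V1 row-vectors per object.
#' @param epochs training epochs per layer (0 leaves the network unchanged).
#' @param seed base seed for the permutation substreams.
#' @param staged train layers successively (default) or simultaneously.
#' @return tibble `(stage, epoch, layer, mean_abs_dw)` convergence log.
#' @export
train_all <- function(net, dataset, epochs, seed = 1, staged = TRUE) {
  if (length(dataset) == 0) abort("dataset is empty")
  if (epochs == 0) return(tibble(stage = integer(), epoch = integer(),
                                 layer = integer(), mean_abs_dw = numeric()))
  if (!staged) return(train_all_simultaneous(net, dataset, epochs, seed))
  log <- list()
  inputs <- dataset
  for (l in 1:4) {
    cfg <- net$layers[[l]]$config
    growing <- 0L; prev <- Inf; base_dw <- NA_real_
    for (e in seq_len(epochs)) {
      w_before <- net$layers[[l]]$w
      obj_order <- withr::with_seed(substream_seed(seed, paste0("objorder", l, "_", e)),
                                    sample(seq_along(inputs)))
      for (o in obj_order) {
        net$layers[[l]]$trace <- numeric(nrow(net$layers[[l]]$idx))
        perm <- withr::with_seed(
          substream_seed(seed, paste0("perm", l, "_", e, "_", o)),
          sample.int(nrow(inputs[[o]])))
        for (t in perm) {
          layer <- net$layers[[l]]
          x <- normalise_input(inputs[[o]][t, ])
          y <- layer_forward(layer, cfg, x)
          layer$trace <- update_trace(y, layer$trace, net$eta[l])
          layer <- learn_step(layer, x, layer$trace, cfg$learning_rate)
          layer$y <- y
          net$layers[[l]] <- layer
        }
      }
      dw <- mean(abs(net$layers[[l]]$w - w_before))
      log[[length(log) + 1]] <- tibble(stage = l, epoch = e, layer = l, mean_abs_dw = dw)
      if (growing == 0L) base_dw <- dw
      growing <- if (dw > prev) growing + 1L else 0L
      prev <- dw
      # sustained *and* substantial growth: modest early increases are normal
      # while neurons first specialise
      if (growing >= 5L && dw > 3 * base_dw)
        abort(paste0("layer ", l, " weight changes grew for 5 consecutive epochs",
                     " (epoch ", e, ", x", signif(dw / base_dw, 3),
                     "): training diverged"))
    }
    if (l < 4) inputs <- lapply(inputs, function(m) layer_outputs(net, l, m))
  }
  bind_rows(log)
}

# Forward step of a single layer: propagate -> inhibit -> sparsifying
# sigmoid. A constant (completely uninformative) input short-circuits to the
# degenerate uniform half-activation, so a blank canvas degenerates at every
# level of the hierarchy, not just the first.
layer_forward <- function(layer, cfg, x, quiet = TRUE) {
  if (max(x) == min(x)) {
    if (!quiet) inform("constant layer input: output degenerates to uniform 0.5")
    return(rep(0.5, cfg$grid_size^2))
  }
  h <- propagate(x, layer)
  hp <- lateral_inhibit(matrix(h, cfg$grid_size), cfg$inhib_sigma, cfg$inhib_contrast)
  as.vector(apply_sigmoid_sparseness(hp, cfg$sparseness_percentile,
                                     cfg$sigmoid_slope, quiet = quiet))
}

# Outputs of layer l (learning off) for a matrix of layer-(l-1) inputs.
layer_outputs <- function(net, l, inputs) {
  cfg <- net$layers[[l]]$config
  t(vapply(seq_len(nrow(inputs)), function(t) {
    layer_forward(net$layers[[l]], cfg, normalise_input(inputs[t, ]))
  }, numeric(cfg$grid_size^2)))
}

train_all_simultaneous <- function(net, dataset, epochs, seed) {
  log <- vector("list", epochs)
  growing <- 0L
  prev_total <- Inf
  base_total <- NA_real_
  for (e in seq_len(epochs)) {
    w_before <- lapply(net$layers, function(l) l$w)
    for (o in seq_along(dataset)) {
      train_object_sequence(net, dataset[[o]],
                            perm_seed = substream_seed(seed, paste0("perm", e, "_", o)))
    }
    dw <- vapply(1:4, function(l) mean(abs(net$layers[[l]]$w - w_before[[l]])), 1)
    log[[e]] <- tibble(stage = 1L, epoch = e, layer = 1:4, mean_abs_dw = dw)
    tot <- sum(dw)
    if (growing == 0L) base_total <- tot
    growing <- if (tot > prev_total) growing + 1L else 0L
    prev_total <- tot
    if (growing >= 5L && tot > 3 * base_total)
      abort(paste0("weight changes grew for 5 consecutive epochs (epoch ", e,
                   ", mean |dw| = ", signif(tot, 4), "): training diverged"))
  }
  bind_rows(log)
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a network checkpoint
#'
#' Serialises the complete network state (configs, connectivity, weights,
#' traces, seed) to a single file; the round trip is bit-exact.
#'
#' @param net a `visnet`.
#' @param path file path.
#' @export
save_network <- function(net, path) {
  snap <- list(retina_size = net$retina_size, n_channels = net$n_channels,
               seed = net$seed, eta = net$eta, coverage = net$coverage,
               layers = net$layers)
  saveRDS(snap, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  snap <- readRDS(path)
  net <- new.env(parent = emptyenv())
  for (nm in names(snap)) assign(nm, snap[[nm]], envir = net)
  class(net) <- "visnet"
  net
}

#' Snapshot a network as a plain list (for equality checks)
#' @param net a `visnet`.
#' @export
network_state <- function(net) {
  list(retina_size = net$retina_size, n_channels = net$n_channels,
       seed = net$seed, eta = net$eta, layers = net$layers)
}
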