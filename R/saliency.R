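#' Multi-scale feature pyramid for bottom-up saliency
#'
#' Builds intensity-contrast and orientation-energy feature maps at several
#' dyadic scales. Intensity contrast is the absolute deviation from a local
#' (Gaussian) mean, so constant scenes map to zero; orientation energy is the
#' rectified response magnitude of zero-mean Gabor kernels, computed on a
#' moderately downsampled copy of the scene and pooled to each pyramid scale.
#' Colour and motion channels are absent: the model operates on static
#' grayscale scenes.
#'
#' @param scene grayscale matrix.
#' @param scales pyramid map sides, at least 3 dyadic scales; graphs stay
#'   desk-sized (<= 64).
#' @param orientations orientation channels in degrees.
#' @param ori_res resolution at which orientation filtering is performed.
#' @param ori_frequency Gabor frequency (cycles/pixel) at `ori_res`.
#' @return list of feature maps with `channel` and `scale` attributes.
#' @export
feature_pyramid <- function(scene, scales = c(32, 16, 8),
                            orientations = c(0, 45, 90, 135),
                            ori_res = 128, ori_frequency = 0.125) {
  assert_image(scene, "scene")
  if (min(dim(scene)) < 2 * max(scales))
    abort("scene is smaller than the coarsest pyramid scale supports")
  maps <- list()
  small <- downsample_to(scene, ori_res)
  kernels <- lapply(orientations, function(th) gabor_kernel(th, ori_frequency, 0.5 / ori_frequency))
  energies <- lapply(fft_corr_bank(small, kernels), abs)
  for (sc in scales) {
    m <- downsample_to(scene, sc)
    blur <- fft_corr_bank(m, list(gaussian_kernel(max(sc / 8, 1), normalise = TRUE)))[[1]]
    maps[[length(maps) + 1]] <- structure(abs(m - blur), channel = "intensity", scale = sc)
    for (i in seq_along(orientations)) {
      em <- downsample_to(energies[[i]], sc)
      maps[[length(maps) + 1]] <- structure(em,
        channel = paste0("orientation(", orientations[i], ")"), scale = sc)
    }
  }
  maps
}

# Downsample a matrix to side n via block-mean, bridging through bilinear
# resampling when the side is not divisible.
downsample_to <- function(x, n) {
  if (nrow(x) %% n == 0 && ncol(x) %% n == 0) return(downsample_mean(x, n))
  k <- max(1, floor(min(dim(x)) / n)) * n
  downsample_mean(upsample_bilinear(x, k, k), n)
}

# Node coordinates and pairwise proximity kernel for an nr x nc map.
graph_proximity <- function(nr, nc, sigma) {
  rr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  d2 <- outer(rr, rr, "-")^2 + outer(cc, cc, "-")^2
  exp(-d2 / (2 * sigma^2))
}

# Equilibrium distribution of a column-stochastic transition matrix by power
# iteration (L1 tolerance), with a uniform teleport term guaranteeing
# ergodicity on degenerate maps.
markov_equilibrium <- function(W, tol = 1e-8, max_iter = 10000, teleport = 1e-6) {
  n <- ncol(W)
  W <- W + teleport * (max(W) + 1e-300)
  Tm <- sweep(W, 2, colSums(W), "/")
  p <- rep(1 / n, n)
  # lazy chain (T + I)/2: identical equilibrium, guaranteed aperiodic, so
  # power iteration cannot oscillate on near-bipartite dissimilarity graphs
  for (i in seq_len(max_iter)) {
    p2 <- (as.vector(Tm %*% p) + p) / 2
    p2 <- p2 / sum(p2)
    if (sum(abs(p2 - p)) < tol) return(list(p = p2, transition = Tm))
    p <- p2
  }
  abort(paste0("Markov equilibrium did not converge within ", max_iter, " iterations"))
}

#' Graph-based saliency activation of a feature map
#'
#' Builds a fully connected graph over map locations with edge weight
#' `|log(fm_i / fm_j)| * exp(-d(i,j)^2 / (2 sigma^2))`,
#' `sigma = sigma_frac * map width`, normalises outgoing weights into a
#' Markov matrix and returns its equilibrium distribution (power iteration):
#' mass accumulates at locations that are unlike their surroundings. Zeros in
#' the map are offset by a small epsilon before the log; a uniform teleport
#' weight keeps the chain ergodic, so a uniform map yields a uniform
#' equilibrium.
#'
#' @param fm feature map matrix.
#' @param sigma_frac proximity scale as a fraction of map width (floored at
#'   one map cell).
#' @param boundary_correct divide by the equilibrium of the proximity-only
#'   chain (same geometry, uniform dissimilarity), cancelling the centre
#'   bias that bounded lattices otherwise impose on the equilibrium; with
#'   the correction a uniform map yields an exactly uniform output.
#' @return activation map (same shape, sums to 1).
#' @export
gbvs_activate <- function(fm, sigma_frac = 0.15, boundary_correct = TRUE) {
  if (any(!is.finite(fm))) abort("feature map must be finite")
  eps <- 1e-6 * max(max(fm), 1e-300)
  lf <- log(as.vector(fm) + eps)
  D <- abs(outer(lf, lf, "-"))
  sig <- max(sigma_frac * ncol(fm), 1)
  # the ergodicity floor is proximity-shaped, so an all-equal map reduces to
  # the proximity-only chain and (after boundary correction) stays uniform
  W <- (D + 1e-6 * (max(D) + 1)) * graph_proximity(nrow(fm), ncol(fm), sig)
  p <- markov_equilibrium(W)$p
  if (boundary_correct) p <- boundary_corrected(p, nrow(fm), ncol(fm), sig)
  matrix(p, nrow(fm))
}

# Equilibrium of the proximity-only chain: the shape a featureless map would
# produce. Cached per (nr, nc, sigma).
.flat_equilibrium_cache <- new.env(parent = emptyenv())

flat_equilibrium <- function(nr, nc, sigma) {
  key <- paste0(nr, "x", nc, "@", signif(sigma, 8))
  if (is.null(.flat_equilibrium_cache[[key]])) {
    W0 <- graph_proximity(nr, nc, sigma)
    .flat_equilibrium_cache[[key]] <- markov_equilibrium(W0)$p
  }
  .flat_equilibrium_cache[[key]]
}

boundary_corrected <- function(p, nr, nc, sigma) {
  q <- p / flat_equilibrium(nr, nc, sigma)
  q / sum(q)
}

#' Mass-concentration normalisation of an activation map
#'
#' Second Markov pass with edge weights `am_j * exp(-d^2 / (2 sigma^2))`
#' toward target j: mass flows toward already-strong locations, so the
#' max/mean ratio of a peaked map does not decrease.
#'
#' @param am activation map (a distribution).
#' @param sigma_frac proximity scale as a fraction of map width (floored at
#'   one map cell).
#' @param boundary_correct as in [gbvs_activate()].
#' @return normalised map (sums to 1).
#' @export
gbvs_normalize <- function(am, sigma_frac = 0.15, boundary_correct = TRUE) {
  if (any(!is.finite(am))) abort("activation map must be finite")
  a <- as.vector(am)
  sig <- max(sigma_frac * ncol(am), 1)
  P <- graph_proximity(nrow(am), ncol(am), sig)
  # W[i, j] = am_i * prox(i, j): weight of the edge arriving at i, with a
  # proximity-shaped ergodicity floor (uniform input -> proximity-only chain)
  W <- (a + 1e-6 * (max(a) + 1e-300)) * P
  p <- markov_equilibrium(W)$p
  if (boundary_correct) p <- boundary_corrected(p, nrow(am), ncol(am), sig)
  matrix(p, nrow(am))
}

#' Combine normalised channel maps into the master saliency map
#'
#' Upsamples every map to the scene resolution (bilinear), averages across
#' channels and scales, and renormalises to unit sum.
#'
#' @param maps list of normalised maps.
#' @param scene_dim `c(rows, cols)` of the scene.
#' @return `saliency_map`: nonnegative matrix summing to 1.
#' @export
master_map <- function(maps, scene_dim) {
  if (length(maps) < 1) abort("need at least one map")
  acc <- matrix(0, scene_dim[1], scene_dim[2])
  for (m in maps) acc <- acc + upsample_bilinear(m, scene_dim[1], scene_dim[2])
  acc <- acc / length(maps)
  structure(acc / sum(acc), class = c("saliency_map", "matrix"))
}

#' Full saliency map of a scene
#'
#' Convenience wrapper: [feature_pyramid()] -> [gbvs_activate()] ->
#' iterated [gbvs_normalize()] per channel map -> [master_map()].
#' The normalisation pass is applied `n_norm` times with a tighter
#' proximity scale than the activation pass; iterating it concentrates the
#' mass of each channel map onto its genuine peaks before channels are
#' combined, which is what makes the thresholded components of the master
#' map separate into per-object regions.
#'
#' @param scene grayscale matrix or `scene` object.
#' @param ... passed to [feature_pyramid()].
#' @param sigma_frac proximity scale for the activation pass.
#' @param norm_sigma_frac proximity scale for the normalisation passes.
#' @param n_norm number of normalisation passes.
#' @return `saliency_map`.
#' @export
saliency_map <- function(scene, ..., sigma_frac = 0.15,
                         norm_sigma_frac = 0.06, n_norm = 2) {
  img <- if (inherits(scene, "scene")) scene$image else scene
  fps <- feature_pyramid(img, ...)
  norm <- lapply(fps, function(fm) {
    m <- gbvs_activate(fm, sigma_frac)
    for (i in seq_len(n_norm)) m <- gbvs_normalize(m, norm_sigma_frac)
    m
  })
  master_map(norm, dim(img))
}

#' Extract ranked fixations from a saliency map
#'
#' Thresholds the map at `threshold_frac` of its maximum, labels the salient
#' regions (connected components split at saliency saddles by a watershed
#' transform, so two nearby peaks joined by a shallow bridge count as two
#' regions), and takes each region's saliency-weighted centroid; the top
#' `k` regions by saliency mass are returned rank-ordered (ties broken by
#' (row, col) order of the centroids). Warns when fewer than `k` regions
#' exist.
#'
#' @param sm `saliency_map`.
#' @param k number of fixations (the standard protocol uses the 6 most
#'   salient regions per scene).
#' @param threshold_frac threshold as a fraction of the map maximum.
#' @param split_tolerance_frac minimum peak-to-saddle depth, as a fraction
#'   of the map maximum, for two peaks to count as separate regions; 0
#'   disables splitting (plain connected components).
#' @param centroid_power exponent applied to saliency values in the
#'   weighted centroid; powers above 1 emphasise the peak of a region over
#'   its diffuse skirt, pulling the fixation toward the most salient point.
#' @return tibble `(rank, row, col, mass)`.
#' @export
extract_fixations <- function(sm, k = 6, threshold_frac = 0.1,
                              split_tolerance_frac = 0.1,
                              centroid_power = 3) {
  if (k < 1) abort("k must be >= 1")
  m <- unclass(sm)
  mask <- m >= threshold_frac * max(m)
  if (split_tolerance_frac > 0) {
    lab <- EBImage::watershed(EBImage::Image(m * mask),
                              tolerance = split_tolerance_frac * max(m))
  } else {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  }
  lv <- as.vector(EBImage::imageData(lab))  # Image() keeps the matrix layout
  keep <- lv > 0 & as.vector(mask)
  sv <- as.vector(m)
  cw <- sv^centroid_power
  rows <- rep(seq_len(nrow(m)), times = ncol(m))
  cols <- rep(seq_len(ncol(m)), each = nrow(m))
  comp <- tibble(label = lv[keep], s = sv[keep], w = cw[keep],
                 row = rows[keep], col = cols[keep]) |>
    group_by(label) |>
    summarise(mass = sum(s), row = sum(row * w) / sum(w), col = sum(col * w) / sum(w),
              .groups = "drop") |>
    arrange(desc(mass), row, col) |>
    mutate(rank = row_number())
  if (nrow(comp) < k)
    warn(paste0("only ", nrow(comp), " salient regions found (requested ", k, ")"))
  comp[seq_len(min(k, nrow(comp))), c("rank", "row", "col", "mass")]
}

#' Cut a fixation-centred patch from a scene
#'
#' `patch_size` x `patch_size` crop centred on the fixation (the standard
#' patch is 384 px, larger than the 256-px training images, so a poorly
#' centred fixation still captures the whole object); regions outside the
#' scene are padded with mid-gray 127.
#'
#' @param scene grayscale matrix or `scene` object.
#' @param center fixation centre `c(row, col)` (fractional allowed).
#' @param patch_size even patch side, default 384.
#' @return `patch_size` x `patch_size` matrix.
#' @export
extract_patch <- function(scene, center, patch_size = 384) {
  img <- if (inherits(scene, "scene")) scene$image else scene
  if (patch_size %% 2 != 0) abort("patch_size must be even")
  r0 <- round(center[[1]]) - patch_size / 2
  c0 <- round(center[[2]]) - patch_size / 2
  out <- matrix(127, patch_size, patch_size)
  rr <- (r0 + 1):(r0 + patch_size); cc <- (c0 + 1):(c0 + patch_size)
  vr <- rr >= 1 & rr <= nrow(img); vc <- cc >= 1 & cc <= ncol(img)
  out[vr, vc] <- img[rr[vr], cc[vc]]
  out
}

#' Fixation-to-object offset statistics
#'
#' Matches each ground-truth object to its nearest fixation within
#' `match_radius` pixels and reports the Euclidean offset of the fixation
#' from the object centre; unmatched objects are recorded as misses.
#'
#' @param fixations tibble from [extract_fixations()].
#' @param truth ground-truth tibble (`object_id, view_deg, row, col`).
#' @param match_radius maximum centre-to-fixation distance for a match.
#' @return tibble `(object_id, view_deg, offset_px, fixation_rank, matched)`.
#' @export
offset_statistics <- function(fixations, truth, match_radius = 64) {
  purrr::pmap(truth, function(object_id, view_deg, row, col, ...) {
    if (nrow(fixations) == 0) {
      return(tibble(object_id = object_id, view_deg = view_deg,
                    offset_px = NA_real_, fixation_rank = NA_integer_, matched = FALSE))
    }
    d <- sqrt((fixations$row - row)^2 + (fixations$col - col)^2)
    i <- which.min(d)
    ok <- d[i] <= match_radius
    tibble(object_id = object_id, view_deg = view_deg,
           offset_px = if (ok) d[i] else NA_real_,
           fixation_rank = if (ok) fixations$rank[i] else NA_integer_,
           matched = ok)
  }) |> bind_rows()
}
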