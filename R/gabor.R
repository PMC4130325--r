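#' Build a bank of Gabor filters emulating V1 simple cells
#'
#' Constructs even-symmetric (cosine-phase) Gabor kernels at every combination
#' of orientation and spatial frequency. Each kernel is made exactly DC-free by
#' subtracting a scaled copy of its Gaussian envelope, then normalised to unit
#' L2 norm. Positive and negative lobes of the linear response are later split
#' into on/off polarity channels by half-wave rectification, so a bank with
#' `length(orientations) * length(frequencies)` kernels yields twice that many
#' response channels.
#'
#' @param orientations orientations in degrees (0 = vertical stripes varying
#'   along x). Default four orientations 45 degrees apart.
#' @param frequencies spatial frequencies in cycles/pixel, each in (0, 0.5).
#' @param sigma_per_cycle Gaussian envelope sigma expressed in wavelengths:
#'   `sigma = sigma_per_cycle / f` pixels. Default 0.5 gives roughly
#'   one-octave bandwidth.
#' @return An object of class `gabor_bank`: kernels plus a channel table.
#' @examples
#' bank <- gabor_bank()
#' n_channels(bank)  # 4 orientations x 4 frequencies x 2 polarities = 32
#' @export
gabor_bank <- function(orientations = c(0, 45, 90, 135),
                       frequencies = c(0.03125, 0.0625, 0.125, 0.25),
                       sigma_per_cycle = 0.5) {
  if (length(orientations) < 1 || length(frequencies) < 1)
    abort("need at least one orientation and one frequency")
  if (any(frequencies <= 0 | frequencies >= 0.5))
    abort("frequencies must lie strictly between 0 and the Nyquist limit 0.5 cycles/pixel")
  grid <- tidyr::expand_grid(frequency = frequencies, orientation = orientations)
  kernels <- purrr::pmap(grid, function(frequency, orientation) {
    gabor_kernel(orientation, frequency, sigma_per_cycle / frequency)
  })
  meta <- tidyr::expand_grid(grid, polarity = c("on", "off")) |>
    mutate(channel = row_number(), kernel_index = rep(seq_len(nrow(grid)), each = 2))
  structure(
    list(kernels = kernels, linear = grid, channels = meta,
         sigma_per_cycle = sigma_per_cycle, fft_cache = new.env(parent = emptyenv())),
    class = "gabor_bank"
  )
}

# A single even Gabor kernel: zero mean (within 1e-6 of its L1 mass), unit L2.
gabor_kernel <- function(orientation_deg, frequency, sigma) {
  r <- ceiling(2.5 * sigma)
  d <- -r:r
  X <- matrix(rep(d, each = length(d)), length(d))   # column offsets
  Y <- matrix(rep(d, times = length(d)), length(d))  # row offsets
  th <- orientation_deg * pi / 180
  Xr <- X * cos(th) + Y * sin(th)
  Yr <- -X * sin(th) + Y * cos(th)
  env <- exp(-(Xr^2 + Yr^2) / (2 * sigma^2))
  g <- env * cos(2 * pi * frequency * Xr)
  g <- g - env * (sum(g) / sum(env))   # exact DC removal, localised
  g / sqrt(sum(g^2))
}

#' @rdname gabor_bank
#' @param bank a `gabor_bank`.
#' @export
n_channels <- function(bank) nrow(bank$channels)

#' @export
print.gabor_bank <- function(x, ...) {
  cat("<gabor_bank> ", length(unique(x$linear$orientation)), " orientations x ",
      length(unique(x$linear$frequency)), " frequencies x 2 polarities = ",
      n_channels(x), " channels\n", sep = "")
  invisible(x)
}

# Rectified responses of the bank applied to an image at its own
# resolution: H x W x (2 * n kernels) array, channel order following
# bank$channels (on, off per kernel).
gabor_rectified <- function(img, bank) {
  assert_image(img)
  r <- max(vapply(bank$kernels, function(k) (nrow(k) - 1L) %/% 2L, 1L))
  key <- paste0("g", nrow(img) + 2 * r, "x", ncol(img) + 2 * r)
  cache <- bank$fft_cache
  if (is.null(cache[[key]]))
    cache[[key]] <- kernel_fft_set(bank$kernels, nrow(img) + 2 * r, ncol(img) + 2 * r)
  lin <- fft_corr_bank(img, bank$kernels, kernel_ffts = cache[[key]], radius = r)
  out <- array(0, c(nrow(img), ncol(img), 2L * length(lin)))
  for (i in seq_along(lin)) {
    out[, , 2L * i - 1L] <- pmax(lin[[i]], 0)
    out[, , 2L * i] <- pmax(-lin[[i]], 0)
  }
  out
}

#' Filter an image through the V1 front-end
#'
#' Block-mean subsamples the image onto the `lattice_size` retinal grid,
#' convolves it there with every kernel of the bank (reflect padding), and
#' half-wave rectifies into on/off polarity channels, so the retina carries
#' phase-resolved local orientation structure at lattice resolution — the
#' substrate the hierarchy's feature-combination learning builds on. All
#' output rates are nonnegative; frequencies are in cycles per lattice
#' pixel.
#'
#' @param img square numeric matrix (grayscale image); side must be a
#'   multiple of `lattice_size`.
#' @param bank a [gabor_bank()].
#' @param lattice_size retina grid dimension; must divide the image side.
#' @return `v1_response`: array `(lattice_row, lattice_col, channel)` with a
#'   `channels` attribute describing (orientation, frequency, polarity).
#' @export
filter_image <- function(img, bank, lattice_size) {
  assert_image(img)
  if (nrow(img) != ncol(img)) abort("image must be square")
  if (lattice_size > nrow(img)) abort("lattice_size must not exceed the image side")
  small <- if (nrow(img) == lattice_size) img else downsample_mean(img, lattice_size)
  new_v1_response(gabor_rectified(small, bank), bank)
}

# Translate a V1 response array by whole lattice cells (dx = columns,
# dy = rows), zero-filling uncovered cells. Because filtering is
# translation-equivariant and the background response is zero, this equals
# filtering the correspondingly shifted canvas (up to border cells).
shift_v1 <- function(v1, dx_cells = 0, dy_cells = 0) {
  d <- dim(v1)
  out <- array(0, d)
  sr <- seq_len(d[1]) - dy_cells
  sc <- seq_len(d[2]) - dx_cells
  vr <- sr >= 1 & sr <= d[1]; vc <- sc >= 1 & sc <= d[2]
  out[vr, vc, ] <- v1[sr[vr], sc[vc], , drop = FALSE]
  attributes(out) <- attributes(v1)
  out
}

new_v1_response <- function(arr, bank) {
  structure(arr, channels = bank$channels, class = c("v1_response", "array"))
}

#' @export
print.v1_response <- function(x, ...) {
  d <- dim(x)
  cat("<v1_response> ", d[1], "x", d[2], " lattice, ", d[3], " channels, ",
      "max rate ", signif(max(x), 4), "\n", sep = "")
  invisible(x)
}

# Flatten to the vector layout used by the network input.
as_input_vector <- function(v1) as.vector(v1)
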