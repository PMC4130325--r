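#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft quantile rnorm runif convolve
#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange group_by summarise ungroup bind_rows
#'   select desc row_number left_join n
#' @importFrom purrr map map_dbl map_int imap
NULL

# Deterministic substream seed: independent reproducible RNG streams derived
# from one base seed and a component label. Kept below 2^31 - 1.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 1009
  as.integer((as.numeric(seed) * 48271 + h * 16807 + 12345) %% 2147483647)
}

logistic <- function(z) 1 / (1 + exp(-z))

is_image <- function(x) is.matrix(x) && is.numeric(x)

assert_image <- function(x, what = "img") {
  if (!is_image(x)) abort(paste0("`", what, "` must be a numeric matrix (grayscale image)"))
  invisible(x)
}

# Reflect-pad a matrix by `r` pixels on every side.
pad_reflect <- function(x, r) {
  if (r == 0) return(x)
  n <- nrow(x); m <- ncol(x)
  if (r >= n || r >= m) abort("reflect padding larger than image")
  ri <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(m), m - seq_len(r))
  x[ri, ci]
}

# FFT-based correlation of one image with a bank of kernels, reflect-padded so
# results equal 'same'-size correlation with mirrored borders. Kernels are a
# list of odd-sized square matrices. Returns list of response matrices.
#
# For repeated calls at a fixed geometry the kernel FFTs are cached on the
# bank object by the caller.
fft_corr_bank <- function(img, kernels, kernel_ffts = NULL, radius = NULL) {
  r <- radius %||% max(vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, 1L))
  p <- pad_reflect(img, r)
  np <- nrow(p); mp <- ncol(p)
  Fp <- fft(p)
  if (is.null(kernel_ffts)) kernel_ffts <- kernel_fft_set(kernels, np, mp)
  lapply(kernel_ffts, function(Kf) {
    res <- Re(fft(Fp * Kf, inverse = TRUE)) / (np * mp)
    res[(r + 1):(np - r), (r + 1):(mp - r), drop = FALSE]
  })
}

# Precompute conjugate kernel FFTs at a padded geometry (np x mp).
kernel_fft_set <- function(kernels, np, mp) {
  lapply(kernels, function(k) {
    kr <- (nrow(k) - 1L) %/% 2L
    kp <- matrix(0, np, mp)
    # place kernel centred at (1,1) with circular wrap for correlation
    idx_r <- ((-kr:kr) %% np) + 1L
    idx_c <- ((-kr:kr) %% mp) + 1L
    kp[idx_r, idx_c] <- k
    Conj(fft(kp))
  })
}

# Direct (spatial-domain) correlation used as an oracle in tests and for small
# grids; reflect-padded, 'same' size.
corr2_direct <- function(img, k) {
  r <- (nrow(k) - 1L) %/% 2L
  p <- pad_reflect(img, r)
  out <- matrix(0, nrow(img), ncol(img))
  for (a in -r:r) for (b in -r:r) {
    out <- out + k[a + r + 1L, b + r + 1L] *
      p[(1 + r + a):(nrow(img) + r + a), (1 + r + b):(ncol(img) + r + b)]
  }
  out
}

# Block-mean pooling matrix mapping a length-`n_src` axis onto `n_dst` cells,
# for a source that has been displaced by `shift` pixels (content moved toward
# higher indices for positive shift; out-of-range content contributes 0).
pool_matrix <- function(n_src, n_dst, shift = 0) {
  s <- n_src / n_dst
  if (s != floor(s)) abort("pooling requires n_src divisible by n_dst")
  P <- matrix(0, n_dst, n_src)
  for (i in seq_len(n_dst)) {
    cols <- ((i - 1) * s + 1):(i * s) - shift
    cols <- cols[cols >= 1 & cols <= n_src]
    if (length(cols)) P[i, cols] <- 1 / s
  }
  P
}

# Bilinear interpolation matrix from n_src samples (cell centres) to n_dst.
bilinear_matrix <- function(n_src, n_dst) {
  P <- matrix(0, n_dst, n_src)
  for (j in seq_len(n_dst)) {
    u <- (j - 0.5) * n_src / n_dst + 0.5  # position in source index coords
    u <- min(max(u, 1), n_src)
    lo <- floor(u); hi <- min(lo + 1, n_src)
    w <- u - lo
    P[j, lo] <- P[j, lo] + (1 - w)
    P[j, hi] <- P[j, hi] + w
  }
  P
}

# Block-mean downsample a matrix to n_dst x n_dst.
downsample_mean <- function(x, n_dst) {
  Pr <- pool_matrix(nrow(x), n_dst)
  Pc <- pool_matrix(ncol(x), n_dst)
  Pr %*% x %*% t(Pc)
}

# Bilinear upsample a matrix to nr x nc.
upsample_bilinear <- function(x, nr, nc) {
  Br <- bilinear_matrix(nrow(x), nr)
  Bc <- bilinear_matrix(ncol(x), nc)
  Br %*% x %*% t(Bc)
}

# Small isotropic Gaussian kernel (unnormalised unless normalise).
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma), normalise = FALSE) {
  d <- -radius:radius
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  if (normalise) g <- g / sum(g)
  g
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
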