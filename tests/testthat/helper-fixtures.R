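# Shared lightweight fixtures. Heavy end-to-end fixtures live in
# helper-study.R and are built lazily, once per test run.

# A small, fast Gabor bank (higher frequencies only -> small kernels).
small_bank <- function() gabor_bank(frequencies = c(0.125, 0.25))

# A full-field sinusoidal grating, values centred on 127.
grating <- function(n, theta_deg, freq, amplitude = 100) {
  th <- theta_deg * pi / 180
  cols <- matrix(rep(seq_len(n), each = n), n)
  rows <- matrix(rep(seq_len(n), times = n), n)
  127 + amplitude * cos(2 * pi * freq * (cols * cos(th) + rows * sin(th)))
}

# Idealised response tensor: `cells` x 4 objects x `transforms`, all zero.
zero_tensor_rates <- function(cells = 1, transforms = 100) {
  array(0, c(cells, 4, transforms))
}

# A tiny connectivity "layer" plus its dense-matrix equivalent.
tiny_layer <- function(n_neurons = 4, n_src = 16, fan_in = 3, seed = 7) {
  withr::with_seed(seed, {
    idx <- t(replicate(n_neurons, sample.int(n_src, fan_in)))
    w <- matrix(runif(n_neurons * fan_in), n_neurons)
  })
  w <- w / sqrt(rowSums(w^2))
  dense <- matrix(0, n_neurons, n_src)
  for (i in seq_len(n_neurons)) for (j in seq_len(fan_in))
    dense[i, idx[i, j]] <- dense[i, idx[i, j]] + w[i, j]
  list(layer = list(idx = idx, w = w), dense = dense)
}
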