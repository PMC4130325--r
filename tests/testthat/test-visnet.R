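tiny_configs <- function(grid = 8L, fan = 12L, sigma = 4) {
  lapply(1:4, function(l)
    layer_config(grid, fan, sigma, 1.5, 1.5, 0.9, 40, c(0.05, 0.03, 0.005, 0.005)[l]))
}

test_that("network initialisation is seeded, normalised, and covers the retina", {
  cfgs <- tiny_configs()
  n1 <- init_network(cfgs, retina_size = 8, n_channels = 4, seed = 42)
  n2 <- init_network(cfgs, retina_size = 8, n_channels = 4, seed = 42)
  expect_identical(network_state(n1), network_state(n2))
  n3 <- init_network(cfgs, retina_size = 8, n_channels = 4, seed = 43)
  expect_false(identical(network_state(n1), network_state(n3)))
  for (l in 1:4)
    expect_equal(sqrt(rowSums(n1$layers[[l]]$w^2)), rep(1, 64), tolerance = 1e-9)
  expect_gte(n1$coverage, 0.95)
})

test_that("too-local connectivity fails the coverage check with a measured value", {
  cfgs <- tiny_configs(grid = 16L, fan = 2L, sigma = 0.25)
  expect_error(init_network(cfgs, retina_size = 16, n_channels = 2, seed = 1),
               "coverage")
})

test_that("sparse propagation equals the dense matrix product", {
  tl <- tiny_layer()
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- runif(16)
      expect_equal(propagate(x, tl$layer), as.vector(tl$dense %*% x),
                   tolerance = 1e-12)
    }
  })
  expect_equal(propagate(rep(0, 16), tl$layer), rep(0, 4))
})

test_that("lateral inhibition suppresses uniform fields relative to isolated peaks", {
  z <- matrix(0, 8, 8)
  expect_equal(lateral_inhibit(z, 1.5, 1.5), z)
  single <- z; single[4, 4] <- 1
  out <- lateral_inhibit(single, 1.5, 1.5)
  expect_equal(which.max(out), which.max(single))
  uniform <- matrix(1, 8, 8)
  u <- lateral_inhibit(uniform, 1.5, 1.5)
  expect_lt(max(u[3:6, 3:6]), max(out))
  expect_true(all(u >= 0))
})

test_that("the sparseness sigmoid hits its percentile target and is monotone", {
  withr::with_seed(3, h <- runif(400))
  y <- apply_sigmoid_sparseness(h, 0.95, 100)
  expect_true(abs(sum(y > 0.5) - 20) <= 1)
  expect_true(all(y >= 0 & y <= 1))
  # monotone: larger activation never maps below a smaller one
  o <- order(h)
  expect_true(all(diff(y[o]) >= -1e-12))
  # infinite-slope limit approaches a hard top-(1-p) mask
  hard <- apply_sigmoid_sparseness(h, 0.95, 1e6)
  expect_setequal(which(hard > 0.5), order(h, decreasing = TRUE)[1:20])
  expect_lt(max(hard[hard < 0.5]), 1e-6)
})

test_that("all-equal activations degenerate to uniform half-activation, with a note", {
  expect_message(y <- apply_sigmoid_sparseness(rep(2, 16), 0.9, 40, quiet = FALSE),
                 "degenerate")
  expect_equal(y, rep(0.5, 16))
})

test_that("the activity trace follows its exponential recursion exactly", {
  y <- c(1, 0.5)
  expect_equal(update_trace(y, c(9, 9), 0), y)
  # constant y converges geometrically
  tr <- c(0, 0)
  for (t in 1:6) tr <- update_trace(y, tr, 0.8)
  expect_equal(abs(tr - y), 0.8^6 * y, tolerance = 1e-12)
  # hand recursion for the {1, 0} sequence at eta = 0.8
  expect_equal(update_trace(0, update_trace(1, 0, 0.8), 0.8), 0.16)
  # explicit-loop oracle on a random sequence
  withr::with_seed(9, ys <- runif(20))
  tr1 <- 0
  for (v in ys) tr1 <- update_trace(v, tr1, 0.6)
  tr2 <- 0
  for (v in ys) tr2 <- (1 - 0.6) * v + 0.6 * tr2
  expect_identical(tr1, tr2)
})

test_that("the trace-Hebb step matches hand arithmetic and conserves norms", {
  layer <- list(idx = matrix(1:2, 1), w = matrix(c(0.6, 0.8), 1))
  out <- learn_step(layer, c(1, 0), trace = 1, rate = 0.05)
  expect_equal(as.vector(out$w),
               c(0.65, 0.8) / sqrt(0.65^2 + 0.8^2), tolerance = 1e-12)
  expect_identical(learn_step(layer, c(1, 0), 1, 0)$w, layer$w)   # rate 0
  expect_equal(learn_step(layer, c(1, 0), 0, 0.05)$w, layer$w)    # silent neuron
  expect_true(all(out$w >= 0))
})

test_that("forward passes are deterministic and blank input degenerates everywhere", {
  net <- init_network(tiny_configs(), retina_size = 8, n_channels = 4, seed = 5)
  withr::with_seed(2, x <- runif(8 * 8 * 4))
  y1 <- present(net, x, learn = FALSE)
  y2 <- present(net, x, learn = FALSE)
  expect_identical(y1, y2)
  blank <- present(net, rep(0, 8 * 8 * 4), learn = FALSE)
  for (l in 1:4) expect_equal(blank[[l]], rep(0.5, 64))
})

test_that("object sequences reset the trace and use fresh permutations", {
  net <- init_network(tiny_configs(), retina_size = 8, n_channels = 4, seed = 5)
  withr::with_seed(4, transforms <- matrix(runif(5 * 256), 5))
  present(net, transforms[1, ], learn = TRUE)
  expect_gt(max(net$layers[[2]]$trace), 0)
  p1 <- train_object_sequence(net, transforms, perm_seed = 1)
  p2 <- train_object_sequence(net, transforms, perm_seed = 2)
  expect_equal(sort(p1), 1:5)
  expect_false(identical(p1, p2))
  expect_error(train_object_sequence(net, transforms[0, , drop = FALSE]), "one")
})

test_that("training with zero epochs leaves the network untouched", {
  net <- init_network(tiny_configs(), retina_size = 8, n_channels = 4, seed = 5)
  before <- network_state(net)
  log <- train_all(net, list(matrix(runif(256), 1)), epochs = 0)
  expect_identical(network_state(net), before)
  expect_equal(nrow(log), 0)
})

test_that("staged training keeps unit weight norms and logs convergence", {
  net <- init_network(tiny_configs(), retina_size = 8, n_channels = 4, seed = 5)
  withr::with_seed(8, data <- lapply(1:2, function(o) matrix(runif(4 * 256), 4)))
  log <- train_all(net, data, epochs = 3, seed = 2)
  expect_equal(nrow(log), 12)  # 4 stages x 3 epochs
  expect_true(all(log$mean_abs_dw >= 0))
  for (l in 1:4)
    expect_equal(sqrt(rowSums(net$layers[[l]]$w^2)), rep(1, 64), tolerance = 1e-9)
})

test_that("with zero trace decay the staged update reduces to plain Hebb", {
  cfgs <- tiny_configs()
  a <- init_network(cfgs, 8, 4, seed = 5, eta = 0)
  b <- init_network(cfgs, 8, 4, seed = 5, eta = 0)
  withr::with_seed(8, data <- list(matrix(runif(4 * 256), 4)))
  train_all(a, data, epochs = 2, seed = 2)
  # manual plain-Hebb replica of the staged loop (trace == instantaneous y)
  inputs <- data
  for (l in 1:4) {
    cfg <- b$layers[[l]]$config
    for (e in 1:2) {
      oo <- withr::with_seed(visalscene:::substream_seed(2, paste0("objorder", l, "_", e)),
                             sample(seq_along(inputs)))
      for (o in oo) {
        b$layers[[l]]$trace <- numeric(64)
        perm <- withr::with_seed(visalscene:::substream_seed(2, paste0("perm", l, "_", e, "_", o)),
                                 sample.int(nrow(inputs[[o]])))
        for (t in perm) {
          layer <- b$layers[[l]]
          x <- visalscene:::normalise_input(inputs[[o]][t, ])
          h <- propagate(x, layer)
          hp <- lateral_inhibit(matrix(h, 8), cfg$inhib_sigma, cfg$inhib_contrast)
          y <- as.vector(apply_sigmoid_sparseness(hp, cfg$sparseness_percentile,
                                                  cfg$sigmoid_slope, quiet = TRUE))
          layer <- learn_step(layer, x, y, cfg$learning_rate)
          layer$y <- y
          b$layers[[l]] <- layer
        }
      }
    }
    if (l < 4) inputs <- lapply(inputs, function(m) visalscene:::layer_outputs(b, l, m))
  }
  for (l in 1:4) expect_identical(a$layers[[l]]$w, b$layers[[l]]$w)
})

test_that("checkpoints round-trip bit-exactly", {
  net <- init_network(tiny_configs(), 8, 4, seed = 5)
  train_all(net, list(matrix(runif(2 * 256), 2)), epochs = 1)
  path <- file.path(withr::local_tempdir(), "net.rds")
  save_network(net, path)
  net2 <- load_network(path)
  expect_identical(network_state(net), network_state(net2))
})
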