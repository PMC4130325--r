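gauss_blob <- function(n, r0, c0, sigma = 6, amp = 1) {
  d <- seq_len(n)
  amp * exp(-(outer((d - r0)^2, (d - c0)^2, "+")) / (2 * sigma^2))
}

test_that("feature pyramids are colour-free and vanish on constant scenes", {
  fps <- feature_pyramid(matrix(100, 256, 256))
  channels <- vapply(fps, attr, "", "channel")
  expect_false(any(grepl("colou?r", channels)))
  expect_setequal(unique(vapply(fps, attr, 1, "scale")), c(32, 16, 8))
  for (fm in fps) expect_lt(max(abs(fm)), 1e-6)
  expect_error(feature_pyramid(matrix(0, 40, 40)), "coarsest")
})

test_that("feature maps peak at a high-contrast blob across scales", {
  sc <- matrix(127, 256, 256) + 120 * gauss_blob(256, 64, 192, 10)
  fps <- feature_pyramid(sc)
  ints <- fps[vapply(fps, attr, "", "channel") == "intensity"]
  for (fm in ints) {
    peak <- which(fm == max(fm), arr.ind = TRUE)[1, ]
    scale_px <- 256 / nrow(fm)
    expect_lt(sqrt(sum((peak * scale_px - c(64, 192))^2)), 3 * scale_px)
  }
})

test_that("the Markov equilibrium matches a dense eigenvector oracle", {
  withr::with_seed(3, fm <- matrix(runif(36, 0.1, 1), 6, 6))
  p <- gbvs_activate(fm, 0.3, boundary_correct = FALSE)
  # oracle: dominant eigenvector of the explicitly built transition matrix
  eps <- 1e-6 * max(fm)
  lf <- log(as.vector(fm) + eps)
  D <- abs(outer(lf, lf, "-"))
  W <- (D + 1e-6 * (max(D) + 1)) * visalscene:::graph_proximity(6, 6, 0.3 * 6)
  W <- W + 1e-6 * (max(W) + 1e-300)
  Tm <- sweep(W, 2, colSums(W), "/")
  v <- Re(eigen(Tm)$vectors[, 1]); v <- v / sum(v)
  expect_lt(max(abs(as.vector(p) - v)), 1e-6)
  expect_equal(sum(p), 1, tolerance = 1e-9)
})

test_that("uniform feature maps yield uniform activation", {
  u <- gbvs_activate(matrix(1, 5, 5))
  expect_lt(max(u) - min(u), 1e-5)
  expect_equal(sum(u), 1, tolerance = 1e-9)
})

test_that("normalisation concentrates mass and preserves point masses", {
  blob <- gauss_blob(16, 8, 8, 2) + 0.01
  am <- blob / sum(blob)
  nm <- gbvs_normalize(am, 0.1)
  expect_equal(sum(nm), 1, tolerance = 1e-9)
  expect_gte(max(nm) / mean(nm), max(am) / mean(am))
  point <- matrix(1e-12, 9, 9); point[5, 5] <- 1; point <- point / sum(point)
  np <- gbvs_normalize(point, 0.1)
  expect_equal(as.vector(which(np == max(np), arr.ind = TRUE)[1, ]), c(5, 5))
})

test_that("master maps are permutation-invariant unit-sum distributions", {
  m1 <- gauss_blob(16, 4, 4); m1 <- m1 / sum(m1)
  m2 <- gauss_blob(8, 6, 2); m2 <- m2 / sum(m2)
  a <- master_map(list(m1, m2), c(64, 64))
  b <- master_map(list(m2, m1), c(64, 64))
  expect_equal(unclass(a), unclass(b))
  expect_equal(sum(a), 1, tolerance = 1e-9)
  expect_true(all(a >= 0))
  # a blob-peaked map combined with a uniform map keeps its argmax
  u <- matrix(1 / 256, 16, 16)
  comb <- master_map(list(m1, u), c(64, 64))
  peak <- which(unclass(comb) == max(comb), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum((peak - c(14, 14))^2)), 6)
})

test_that("fixation extraction finds weighted centroids, ranked by mass", {
  m <- gauss_blob(128, 40, 90, 4) + 0.5 * gauss_blob(128, 100, 30, 4)
  sm <- structure(m / sum(m), class = c("saliency_map", "matrix"))
  fx <- extract_fixations(sm, k = 2, threshold_frac = 0.1)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$rank, 1:2)
  expect_lt(abs(fx$row[1] - 40) + abs(fx$col[1] - 90), 1)
  expect_lt(abs(fx$row[2] - 100) + abs(fx$col[2] - 30), 1)
  expect_gt(fx$mass[1], fx$mass[2])
  expect_identical(fx, extract_fixations(sm, k = 2, threshold_frac = 0.1))
  expect_warning(extract_fixations(sm, k = 6, threshold_frac = 0.1), "salient regions")
})

test_that("patches crop around the centre and pad with mid-gray", {
  withr::with_seed(1, img <- matrix(runif(600 * 600, 0, 255), 600, 600))
  p <- extract_patch(img, c(300, 300), 384)
  expect_identical(p, img[109:492, 109:492])
  q <- extract_patch(img, c(1, 1), 384)
  expect_true(all(q[1:191, ] == 127))
  expect_true(all(q[, 1:191] == 127))
  expect_identical(q[192:384, 192:384], img[1:193, 1:193])
  expect_error(extract_patch(img, c(300, 300), 383), "even")
})

test_that("offset statistics match objects within the radius and report misses", {
  fx <- tibble::tibble(rank = 1:2, row = c(100, 500), col = c(100, 500), mass = c(2, 1))
  truth <- tibble::tibble(object_id = 0:1, view_deg = c(0, 45),
                          row = c(100, 300), col = c(100, 300))
  os <- offset_statistics(fx, truth, match_radius = 64)
  expect_equal(os$offset_px[1], 0)
  expect_equal(os$fixation_rank[1], 1L)
  expect_false(os$matched[2])
  expect_true(is.na(os$offset_px[2]))
})

test_that("rotating a scene by 90 degrees rotates the fixations with it", {
  img <- matrix(127, 256, 256) +
    110 * gauss_blob(256, 70, 180, 9) - 100 * gauss_blob(256, 190, 60, 9)
  rot <- t(img)[, nrow(img):1]  # 90 degrees clockwise
  fx1 <- suppressWarnings(extract_fixations(saliency_map(img), k = 2, threshold_frac = 0.3))
  fx2 <- suppressWarnings(extract_fixations(saliency_map(rot), k = 2, threshold_frac = 0.3))
  # map (row, col) -> (col, n + 1 - row) under the same rotation
  mapped <- tibble::tibble(row = fx1$col, col = 256 + 1 - fx1$row)
  for (i in seq_len(nrow(fx2))) {
    d <- sqrt((mapped$row - fx2$row[i])^2 + (mapped$col - fx2$col[i])^2)
    expect_lt(min(d), 1.5)
  }
})

test_that("every stage of the saliency pipeline emits a probability distribution", {
  img <- matrix(127, 256, 256) + 90 * gauss_blob(256, 100, 100, 12)
  fps <- feature_pyramid(img)
  for (fm in fps[c(1, 6, 11)]) {
    am <- gbvs_activate(fm)
    expect_equal(sum(am), 1, tolerance = 1e-9); expect_true(all(am >= 0))
    nm <- gbvs_normalize(am)
    expect_equal(sum(nm), 1, tolerance = 1e-9); expect_true(all(nm >= 0))
  }
  sm <- saliency_map(img)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_true(all(sm >= 0))
})
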