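ideal_cell_tensor <- function(preferred = 4, S = 4, T = 100) {
  rates <- array(0, c(1, S, T))
  rates[1, preferred, ] <- 1
  response_tensor(rates)
}

test_that("an ideal invariant cell carries exactly log2(S) bits about its object", {
  rt <- ideal_cell_tensor(preferred = 4)
  res <- single_cell_information(rt, 1)
  expect_identical(res$bits, 2)
  expect_equal(res$best_object, 3)  # ids are 0-based; the 4th object
})

test_that("constant cells carry zero bits and values respect the ceiling", {
  rt <- response_tensor(array(0.7, c(1, 4, 10)))
  expect_equal(single_cell_information(rt, 1)$bits, 0)
  withr::with_seed(21, rates <- array(runif(5 * 4 * 12), c(5, 4, 12)))
  info <- cell_information(response_tensor(rates))
  expect_true(all(info$bits >= 0 & info$bits <= 2))
  expect_true(all(as.matrix(info[paste0("info_", 0:3)]) >= 0))
})

test_that("binary cells match the closed form log2(S / n_preferred)", {
  # fires for objects {1, 2}, silent for {3, 4}
  rates <- zero_tensor_rates(transforms = 20)
  rates[1, 1:2, ] <- 1
  res <- single_cell_information(response_tensor(rates), 1)
  expect_equal(res$bits, 1)
  # brute-force plug-in oracle over the 2-bin joint distribution
  p_r_s <- rbind(c(0, 0, 1, 1), c(1, 1, 0, 0))  # P(r | s), rows r in {lo, hi}
  p_r <- rowMeans(p_r_s)
  oracle <- sum(ifelse(p_r_s[, 1] > 0, p_r_s[, 1] * log2(p_r_s[, 1] / p_r), 0))
  expect_equal(res$bits, oracle)
})

test_that("label shuffling drives the single-cell measure toward zero", {
  withr::with_seed(31, {
    rates <- array(0, c(1, 4, 100))
    rates[1, , ] <- matrix(rbinom(400, 1, 0.5), 4)  # object-independent firing
  })
  expect_lt(single_cell_information(response_tensor(rates), 1)$bits, 0.15)
})

test_that("population decoding recovers log2(S) bits from orthogonal patterns", {
  rates <- array(0, c(4, 4, 10))
  for (s in 1:4) rates[s, s, ] <- 1
  rt <- response_tensor(rates)
  expect_equal(multiple_cell_information(rt, 1:4, cv_folds = 5), 2)
  expect_error(multiple_cell_information(rt, integer(0)), "nonempty")
  expect_error(multiple_cell_information(rt, 1:4, cv_folds = 11), "cv_folds")
})

test_that("shuffled population labels decode to near-zero information", {
  withr::with_seed(41, rates <- array(runif(20 * 4 * 40), c(20, 4, 40)))
  # identical marginal structure across objects: permute transforms per cell
  expect_lt(multiple_cell_information(response_tensor(rates), 1:20, 4), 0.25)
})

test_that("confusion-matrix information matches direct summation", {
  conf <- matrix(1 / 30, 4, 4)
  diag(conf) <- 0.9 / 4  # 90% correct, symmetric 10% error
  off <- (1 - 0.9) / 12
  conf[row(conf) != col(conf)] <- off
  p <- conf / sum(conf)
  direct <- 0
  for (i in 1:4) for (j in 1:4)
    direct <- direct + p[i, j] * log2(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
  expect_equal(confusion_mutual_information(conf), direct, tolerance = 1e-12)
  expect_equal(confusion_mutual_information(diag(4)), 2)
})

test_that("population information grows with population size on separable data", {
  rates <- array(0, c(8, 4, 12))
  for (s in 1:4) rates[c(s, s + 4), s, ] <- 1
  withr::with_seed(51, rates <- rates + array(runif(length(rates), 0, 0.3), dim(rates)))
  rt <- response_tensor(rates)
  i1 <- multiple_cell_information(rt, 1, 4)
  i4 <- multiple_cell_information(rt, 1:4, 4)
  i8 <- multiple_cell_information(rt, 1:8, 4)
  expect_gte(i4 + 0.05, i1)
  expect_gte(i8 + 0.05, i4)
  expect_lte(i8, 2)
})

test_that("cell selection takes the top cells per object and ignores ordering", {
  withr::with_seed(61, rates <- array(runif(30 * 4 * 16), c(30, 4, 16)))
  rates[1, 1, ] <- 5; rates[2, 2, ] <- 5; rates[3, 3, ] <- 5; rates[4, 4, ] <- 5
  info <- cell_information(response_tensor(rates))
  top1 <- select_cells(info, per_object = 1)
  expect_setequal(top1, 1:4)
  sel <- select_cells(info, per_object = 3)
  expect_lte(length(sel), 12)
  # permuting row order of the table leaves the selected set unchanged
  expect_setequal(select_cells(info[sample(nrow(info)), ], per_object = 3), sel)
})

test_that("the Hebbian readout separates orthogonal classes perfectly", {
  x <- diag(4)[, rep(1:4, each = 3)]
  labels <- rep(0:3, each = 3)
  pa <- train_readout(x, labels)
  expect_equal(classify(pa, x, quiet = TRUE), labels)
  expect_warning(train_readout(cbind(x, 0), c(labels, 0)), "all-zero")
})

test_that("readout weights are the row-normalised target-input outer product", {
  x <- matrix(c(1, 0, 0,
                0, 2, 0), nrow = 3)  # 3 cells, 2 presentations
  pa <- train_readout(x, labels = c(0, 1), object_ids = 0:1)
  raw <- rbind(c(1, 0, 0), c(0, 2, 0))  # one-hot targets x inputs
  expect_equal(pa$w, raw / sqrt(rowSums(raw^2)), ignore_attr = TRUE)
})

test_that("classification ties fall to the lowest object id and are reported", {
  pa <- train_readout(diag(4), 0:3)
  expect_message(out <- classify(pa, rep(0, 4)), "tie")
  expect_equal(out, 0)
  withr::with_seed(71, {
    for (i in 1:10) {
      v <- runif(4)
      expect_equal(classify(pa, v, quiet = TRUE), which.max(pa$w %*% v) - 1L)
    }
  })
  expect_error(classify(pa, rep(0, 3)), "dimension")
})

test_that("percent correct reproduces the printed headline arithmetic", {
  expect_equal(percent_correct(c(rep(1, 43), rep(2, 5)), rep(1, 48)),
               100 * 43 / 48)
  expect_equal(round(percent_correct(c(rep(1, 43), rep(2, 5)), rep(1, 48))), 90)
  expect_equal(percent_correct(1:5, 1:5), 100)
  expect_error(percent_correct(1:3, 1:4), "equal length")
})
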