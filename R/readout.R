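#' Layer-4 response tensor
#'
#' Container for firing rates indexed by (cell, object, transform): the
#' substrate for the information measures and the pattern-associator readout.
#'
#' @param rates 3-D nonnegative array `(cell, object, transform)`, equal
#'   transform count per object.
#' @param object_ids identifiers for the object axis (default `0:(S-1)`).
#' @return `response_tensor`.
#' @export
response_tensor <- function(rates, object_ids = NULL) {
  if (length(dim(rates)) != 3) abort("rates must be a 3-D array (cell, object, transform)")
  if (any(!is.finite(rates)) || any(rates < 0)) abort("rates must be finite and nonnegative")
  object_ids <- object_ids %||% (seq_len(dim(rates)[2]) - 1L)
  structure(list(rates = rates, object_ids = as.integer(object_ids)),
            class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat("<response_tensor> ", d[1], " cells x ", d[2], " objects x ", d[3],
      " transforms\n", sep = "")
  invisible(x)
}

#' Stimulus-specific information of a single cell
#'
#' Quantises the cell's rates into `n_bins` equi-spaced bins over its
#' observed range and computes, for each object s,
#' `I(s) = sum_r P(r|s) log2( P(r|s) / P(r) )` with uniform object priors;
#' returns the information about the cell's most effective stimulus — the
#' object with the highest mean rate (ties to the lowest id) — and that
#' object. Anchoring on the most effective stimulus (rather than the bare
#' maximum of I(s)) means a cell that is merely predictably *silent* for
#' some object is not credited as selective for it. A constant-rate cell
#' carries 0 bits. The value is bounded by `log2(S)` for S objects: a cell
#' responding to all transforms of exactly one of 4 objects and to none of
#' the others reaches the 2-bit ceiling.
#'
#' @param rt a [response_tensor()].
#' @param cell cell index.
#' @param n_bins number of rate bins (>= 2).
#' @return list with `bits` and `best_object` (an object id).
#' @export
single_cell_information <- function(rt, cell, n_bins = 10) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  r <- rt$rates[cell, , , drop = TRUE]
  if (is.null(dim(r))) r <- matrix(r, nrow = dim(rt$rates)[2])
  S <- nrow(r); T <- ncol(r)
  if (T < 2) abort("need >= 2 transforms per object")
  rng <- range(r)
  if (rng[1] == rng[2])
    return(list(bits = 0, best_object = rt$object_ids[1]))
  bin <- pmin(floor((r - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  p_r_s <- vapply(seq_len(S), function(s) tabulate(bin[s, ], n_bins) / T,
                  numeric(n_bins))          # n_bins x S
  p_r <- rowMeans(p_r_s)                    # uniform priors
  info <- vapply(seq_len(S), function(s) {
    nz <- p_r_s[, s] > 0
    sum(p_r_s[nz, s] * log2(p_r_s[nz, s] / p_r[nz]))
  }, 1)
  best <- which.max(rowMeans(r))  # most effective stimulus, ties -> lowest id
  list(bits = info[best], best_object = rt$object_ids[best],
       per_object = stats::setNames(info, rt$object_ids))
}

#' Per-cell information table
#'
#' Runs [single_cell_information()] over all cells. Besides the
#' most-effective-stimulus information (`bits`, `best_object`), the table
#' carries one `info_<id>` column per object: the cell's stimulus-specific
#' information about that object, whether conveyed by firing or by
#' predictable silence.
#'
#' @inheritParams single_cell_information
#' @return tibble `(cell, bits, best_object, info_<id>...)`.
#' @export
cell_information <- function(rt, n_bins = 10) {
  n <- dim(rt$rates)[1]
  res <- purrr::map(seq_len(n), function(i) single_cell_information(rt, i, n_bins))
  per <- do.call(rbind, purrr::map(res, "per_object"))
  colnames(per) <- paste0("info_", rt$object_ids)
  dplyr::bind_cols(
    tibble(cell = seq_len(n),
           bits = map_dbl(res, "bits"),
           best_object = map_int(res, ~ as.integer(.x$best_object))),
    as_tibble(per)
  )
}

#' Multiple-cell information by cross-validated decoding
#'
#' Fits class mean vectors on training transforms, assigns each held-out
#' transform to the class with the highest normalised inner product (cosine),
#' accumulates the joint confusion distribution P(s, s_decoded) over folds,
#' and returns its mutual information in bits (plug-in estimate; at most
#' `log2(S)`). Folds are deterministic (round-robin over transform index).
#'
#' @param rt a [response_tensor()].
#' @param cell_subset cell indices to decode from.
#' @param cv_folds number of folds, `2 <= cv_folds <= T`.
#' @return information in bits.
#' @export
multiple_cell_information <- function(rt, cell_subset, cv_folds = 5) {
  if (length(cell_subset) < 1) abort("cell_subset must be nonempty")
  S <- dim(rt$rates)[2]; T <- dim(rt$rates)[3]
  if (cv_folds < 2 || cv_folds > T) abort("need T >= cv_folds >= 2")
  fold <- ((seq_len(T) - 1L) %% cv_folds) + 1L
  conf <- matrix(0, S, S)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    if (!any(tr) || !any(!tr)) abort("a fold has a missing class")
    means <- matrix(vapply(seq_len(S), function(s)
      rowMeans(matrix(rt$rates[cell_subset, s, tr], nrow = length(cell_subset))),
      numeric(length(cell_subset))), ncol = S)
    mn <- sqrt(colSums(means^2)); mn[mn == 0] <- 1
    means <- sweep(means, 2, mn, "/")
    for (s in seq_len(S)) for (t in which(!tr)) {
      x <- rt$rates[cell_subset, s, t]
      nx <- sqrt(sum(x^2))
      score <- if (nx == 0) rep(0, S) else as.vector(crossprod(means, x)) / nx
      conf[s, which.max(score)] <- conf[s, which.max(score)] + 1
    }
  }
  confusion_mutual_information(conf)
}

#' Mutual information of a confusion matrix, in bits
#'
#' Plug-in mutual information of the joint distribution obtained by
#' normalising a (true class x decoded class) contingency table.
#'
#' @param conf nonnegative matrix of counts.
#' @export
confusion_mutual_information <- function(conf) {
  p <- conf / sum(conf)
  ps <- rowSums(p); pd <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  sum(p[nz] * log2(p[nz] / (ps[nz[, 1]] * pd[nz[, 2]])))
}

#' Select the most object-selective cells
#'
#' For each object, picks the `per_object` cells carrying the most
#' stimulus-specific information about that object (the `info_<id>` columns
#' of [cell_information()]; ties broken by cell index) and returns the
#' union. Falls back to grouping by `best_object` when the per-object
#' columns are absent, warning when an object has fewer qualifying cells
#' than requested.
#'
#' @param info tibble from [cell_information()].
#' @param per_object cells to take per object (25 in the standard protocol).
#' @return integer vector of cell indices.
#' @export
select_cells <- function(info, per_object = 25) {
  sel <- integer(0)
  per_cols <- grep("^info_", names(info), value = TRUE)
  if (length(per_cols) > 0) {
    for (col in per_cols) {
      cand <- info |> arrange(desc(.data[[col]]), cell)
      sel <- c(sel, cand$cell[seq_len(min(per_object, nrow(cand)))])
    }
    return(sort(unique(sel)))
  }
  for (obj in sort(unique(info$best_object))) {
    cand <- info |> filter(best_object == obj) |> arrange(desc(bits), cell)
    if (nrow(cand) < per_object)
      warn(paste0("object ", obj, ": only ", nrow(cand),
                  " cells prefer it (requested ", per_object, ")"))
    sel <- c(sel, cand$cell[seq_len(min(per_object, nrow(cand)))])
  }
  sort(unique(sel))
}

#' Train the pattern-associator readout
#'
#' One-shot Hebbian batch association between input rate vectors and one-hot
#' object targets: `W = rate * targets %*% t(X)` — one output neuron per
#' object, no iteration, deterministic. Each output neuron's weight vector
#' is then L2-normalised (synaptic scaling, exactly as in the network
#' layers), so classification reduces to dot-product decoding against unit
#' class vectors and no object is favoured merely by a larger summed rate.
#'
#' @param x matrix of training inputs, one column per presentation
#'   (rows = cells).
#' @param labels object id per column.
#' @param object_ids full object id set (defaults to the sorted unique
#'   labels).
#' @param learning_rate associative rate (scales all weights; does not change
#'   classification).
#' @return `pattern_associator` with the weight matrix (objects x cells).
#' @export
train_readout <- function(x, labels, object_ids = NULL, learning_rate = 1) {
  object_ids <- object_ids %||% sort(unique(labels))
  if (ncol(x) != length(labels)) abort("one label per training column required")
  if (any(colSums(x) == 0))
    warn("some training inputs are all-zero: their object is undecidable from them")
  Tg <- vapply(labels, function(l) as.numeric(object_ids == l), numeric(length(object_ids)))
  W <- normalise_rows(learning_rate * Tg %*% t(x))
  structure(list(w = W, object_ids = as.integer(object_ids),
                 n_cells = nrow(x), learning_rate = learning_rate),
            class = "pattern_associator")
}

#' @export
print.pattern_associator <- function(x, ...) {
  cat("<pattern_associator> ", length(x$object_ids), " output neurons x ",
      x$n_cells, " cells\n", sep = "")
  invisible(x)
}

#' Classify a response vector
#'
#' Argmax over the output neurons; ties go to the lowest object id and are
#' reported via a message.
#'
#' @param pa a [train_readout()] result.
#' @param x response vector (or matrix with one column per case).
#' @param quiet suppress tie messages.
#' @return object id(s).
#' @export
classify <- function(pa, x, quiet = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) != pa$n_cells) abort("input dimension does not match the readout")
  scores <- pa$w %*% x
  out <- integer(ncol(x))
  for (j in seq_len(ncol(x))) {
    s <- scores[, j]
    best <- which(s == max(s))
    if (length(best) > 1 && !quiet)
      inform(paste0("tie between output neurons {",
                    paste(pa$object_ids[best], collapse = ","),
                    "}; taking the lowest id"))
    out[j] <- pa$object_ids[min(best)]
  }
  out
}

#' Percentage of correct predictions
#'
#' @param predictions,truth equal-length vectors.
#' @return percentage in `[0, 100]`.
#' @export
percent_correct <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1)
    abort("predictions and truth must have equal length >= 1")
  100 * mean(predictions == truth)
}
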