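#' Specification of a procedural 3-D-like object
#'
#' Four built-in object classes (ids 0-3) stand in for the two people and two
#' vehicles of the original study: two articulated biped-like forms and two
#' wheeled-vehicle forms. Each object is a set of 3-D ellipsoid parts
#' (axis-aligned semi-axes, per-part albedo) that is rotated about the
#' vertical axis by the view angle and orthographically projected, so its 2-D
#' silhouette changes smoothly with view. Rendering is fully deterministic
#' given `(object_id, view_deg, seed)`.
#'
#' @param object_id integer 0..3.
#' @param albedo_texture_seed integer seed for the deterministic surface grain.
#' @return `object_spec`: list with a parts tibble
#'   (`px, py, pz, a, b, c, albedo`; coordinates in pixels, x right, y depth,
#'   z up) plus the id and texture seed.
#' @export
object_spec <- function(object_id, albedo_texture_seed = 1000L + object_id) {
  if (!is.numeric(object_id) || length(object_id) != 1 || !(object_id %in% 0:3))
    abort(paste0("unknown object_id: ", paste(object_id, collapse = ","),
                 " (must be an integer in 0..3)"))
  parts <- switch(as.character(object_id),
    "0" = tibble(  # tall walker: small head, slim torso, long limbs
      px = c(0, 0, -30, 30, -13, 13, -13, 13),
      py = c(0, 0, 8, -8, 5, -5, 14, -14),
      pz = c(76, 28, 30, 30, -42, -42, -82, -82),
      a = c(17, 25, 8, 8, 10, 10, 13, 13),
      b = c(17, 15, 8, 8, 12, 12, 19, 19),
      c = c(17, 35, 29, 29, 40, 40, 8, 8),
      albedo = c(205, 95, 160, 160, 70, 70, 45, 45)
    ),
    "1" = tibble(  # broad figure, arms raised outward, wide stance; bright
      # head over a mid-dark body so no large bright mass remains
      px = c(0, 0, -42, 42, -22, 22),
      py = c(0, 0, -6, 6, 8, -8),
      pz = c(62, 14, 52, 52, -52, -52),
      a = c(23, 34, 10, 10, 12, 12),
      b = c(23, 21, 10, 10, 14, 14),
      c = c(23, 42, 34, 34, 38, 38),
      albedo = c(65, 185, 120, 120, 150, 150)
    ),
    "2" = tibble(  # open-top jeep: long dark low body, dark roll frame, a
      # thick bright diagonal bar across the flank, four large wheels
      px = c(0, 62, -20, -4, -52, 52, -52, 52),
      py = c(0, 0, 0, 2, 28, 28, -28, -28),
      pz = c(-22, -6, 16, -4, -48, -48, -48, -48),
      a = c(88, 22, 26, 58, 18, 18, 18, 18),
      b = c(32, 28, 24, 30, 7, 7, 7, 7),
      c = c(20, 12, 10, 11, 18, 18, 18, 18),
      rot = c(0, 0, 0, 40, 0, 0, 0, 0),
      albedo = c(45, 70, 60, 240, 35, 35, 35, 35)
    ),
    "3" = tibble(  # bus-like: long tall bright body, two widely spaced dark
      # horizontal bands, a periodic row of dark windows, small wheels
      px = c(0, 0, 0, -64, -32, 0, 32, 64, -44, 44, -44, 44),
      py = c(0, 1, 1, 2, 2, 2, 2, 2, 28, 28, -28, -28),
      pz = c(-4, 10, -22, 24, 24, 24, 24, 24, -48, -48, -48, -48),
      a = c(90, 92, 92, 7, 7, 7, 7, 7, 13, 13, 13, 13),
      b = c(30, 33, 33, 31, 31, 31, 31, 31, 6, 6, 6, 6),
      c = c(32, 7, 7, 9, 9, 9, 9, 9, 13, 13, 13, 13),
      albedo = c(210, 20, 20, 25, 25, 25, 25, 25, 35, 35, 35, 35)
    )
  )
  structure(list(object_id = as.integer(object_id), parts = parts,
                 albedo_texture_seed = as.integer(albedo_texture_seed)),
            class = "object_spec")
}

#' Render an object at a given view angle
#'
#' Rotates the part ensemble about the vertical axis by `view_deg`, projects
#' orthographically, and paints parts far-to-near with per-part albedo, a mild
#' lighting gradient, and deterministic surface grain. Output is a 256x256
#' grayscale image with intensities in 0-255 on a uniform background of 127.
#' A logical `mask` attribute marks object pixels (used when pasting objects
#' over textured scene backgrounds).
#'
#' @param spec an [object_spec()].
#' @param view_deg view angle in degrees, taken modulo 360.
#' @param size image side in pixels (default 256).
#' @return numeric matrix `size x size`, values in `[0, 255]`, background 127.
#' @export
render_object <- function(spec, view_deg, size = 256L) {
  if (!inherits(spec, "object_spec")) abort("`spec` must be an object_spec")
  phi <- (view_deg %% 360) * pi / 180
  n <- as.integer(size)
  img <- matrix(127, n, n)
  mask <- matrix(FALSE, n, n)
  ctr <- (n + 1) / 2
  cols <- matrix(rep(seq_len(n) - ctr, each = n), n)   # x (right)
  rows <- matrix(rep(seq_len(n) - ctr, times = n), n)  # z (down in raster)
  p <- spec$parts |>
    mutate(
      cx = px * cos(phi) - py * sin(phi),
      depth = px * sin(phi) + py * cos(phi),
      ax = sqrt((a * cos(phi))^2 + (b * sin(phi))^2),
      az = c
    ) |>
    arrange(depth)  # far first; nearer parts overwrite
  s <- spec$albedo_texture_seed
  k1 <- 0.21 + 0.13 * ((s * 7) %% 5)
  k2 <- 0.17 + 0.11 * ((s * 13) %% 7)
  ph <- (s %% 97) / 97 * 2 * pi
  grain <- 9 * sin(k1 * rows * (n / 256) + k2 * cols * (n / 256) + ph)
  rot <- if ("rot" %in% names(p)) p$rot * pi / 180 else rep(0, nrow(p))
  for (i in seq_len(nrow(p))) {
    dx <- cols - p$cx[i]
    dz <- rows + p$pz[i]              # raster row grows downward
    u <- (dx * cos(rot[i]) - dz * sin(rot[i])) / p$ax[i]
    v <- (dx * sin(rot[i]) + dz * cos(rot[i])) / p$az[i]
    inside <- (u^2 + v^2) <= 1
    if (!any(inside)) next
    shade <- p$albedo[i] * (1 - 0.25 * u[inside]) + grain[inside]
    img[inside] <- clamp(shade, 3, 252)
    mask[inside] <- TRUE
  }
  attr(img, "mask") <- mask
  img
}

#' Paste an object image onto a gray training canvas
#'
#' Centres the object image on a `canvas_size` x `canvas_size` background of
#' 127 displaced by `(dx, dy)` pixels (dx = columns rightward, dy = rows
#' downward), so that wrap-around effects cannot contaminate the spatial
#' filtering stage. Errors if the object would clip the canvas edge.
#'
#' @param obj square grayscale matrix (e.g. from [render_object()]).
#' @param offset integer vector `c(dx, dy)`.
#' @param canvas_size canvas side, default 512.
#' @return `canvas_size` x `canvas_size` matrix, background 127.
#' @export
place_on_canvas <- function(obj, offset = c(0, 0), canvas_size = 512L) {
  assert_image(obj, "obj")
  dx <- round(offset[[1]]); dy <- round(offset[[2]])
  n <- nrow(obj); cs <- as.integer(canvas_size)
  r0 <- (cs - n) %/% 2 + dy
  c0 <- (cs - n) %/% 2 + dx
  if (r0 < 0 || c0 < 0 || r0 + n > cs || c0 + n > cs)
    abort(paste0("offset (", dx, ",", dy, ") would clip the ", n,
                 "-pixel object outside the ", cs, "-pixel canvas"))
  canvas <- matrix(127, cs, cs)
  canvas[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)] <- obj
  canvas
}

#' Centred rectangular grid of training offsets
#'
#' @param n_per_side odd number of grid locations per axis.
#' @param spacing_px spacing between adjacent locations, pixels.
#' @return tibble with columns `dx`, `dy`; `n_per_side^2` rows symmetric
#'   about the origin.
#' @examples
#' make_translation_grid(5, 16)  # 25 offsets spanning -32..32
#' @export
make_translation_grid <- function(n_per_side, spacing_px) {
  if (n_per_side %% 2 != 1) abort("n_per_side must be odd so the grid is centred on 0")
  half <- (n_per_side - 1) / 2
  v <- seq(-half, half) * spacing_px
  tidyr::expand_grid(dy = v, dx = v)[, c("dx", "dy")]
}

# Textured clutter background: multi-scale filtered noise around mid-gray plus
# scattered high-contrast distractor blobs, so the saliency map has non-object
# peaks. Deterministic given the seed.
clutter_background <- function(seed, size = 1024L, noise_amp = 16,
                               n_distractors = 2L, distractor_contrast = 95,
                               avoid = NULL, avoid_radius = 220) {
  withr::with_seed(substream_seed(seed, "background"), {
    bg <- matrix(127, size, size)
    for (sc in c(16, 32, 64, 128)) {
      nz <- matrix(rnorm(sc * sc), sc, sc)
      bg <- bg + noise_amp * (16 / sc)^0.25 * upsample_bilinear(nz, size, size) / 2
    }
    # patchy texture regions
    reg <- upsample_bilinear(matrix(rnorm(64), 8, 8), size, size)
    bg <- bg + 10 * sign(reg) * abs(reg)^0.7
    ctr <- NULL
    placed <- 0L; tries <- 0L
    d <- seq_len(size)
    while (placed < n_distractors && tries < 200L) {
      tries <- tries + 1L
      rc <- runif(2, 140, size - 140)
      ok <- TRUE
      if (!is.null(avoid) && nrow(avoid) > 0)
        ok <- all(sqrt((avoid[[1]] - rc[1])^2 + (avoid[[2]] - rc[2])^2) > avoid_radius)
      if (!is.null(ctr))
        ok <- ok && all(sqrt((ctr[, 1] - rc[1])^2 + (ctr[, 2] - rc[2])^2) > 260)
      if (!ok) next
      placed <- placed + 1L
      ctr <- rbind(ctr, rc)
      sgn <- if (placed %% 2 == 0) -1 else 1
      rad <- runif(1, 30, 48)
      blob <- exp(-(outer((d - rc[1])^2, (d - rc[2])^2, "+")) / (2 * rad^2))
      bg <- bg + sgn * distractor_contrast * blob
    }
    clamp(bg, 0, 255)
  })
}

#' Compose a cluttered test scene with ground truth
#'
#' Renders each placement at its view angle and pastes the object pixels
#' (background pixels of the render are dropped) onto a textured clutter
#' background containing distractor blobs. Object bounding boxes must lie
#' fully inside the scene and must not overlap.
#'
#' @param background_seed integer; scenes are bit-identical given the same
#'   seed and placements.
#' @param placements tibble/data.frame with columns `object_id`, `view_deg`,
#'   `row`, `col` (object centre, 1-based scene coordinates). May be empty.
#' @param size scene side in pixels, >= 1024.
#' @param n_distractors number of high-contrast non-object blobs.
#' @param noise_amp clutter texture amplitude (gray levels).
#' @return `scene`: list with `image` (matrix) and `truth`
#'   (tibble `object_id, view_deg, row, col`).
#' @export
compose_scene <- function(background_seed, placements = NULL, size = 1024L,
                          n_distractors = 2L, noise_amp = 16) {
  if (size < 1024) abort("scene size must be at least 1024 pixels")
  if (is.null(placements) || nrow(placements) == 0) {
    img <- clutter_background(background_seed, size, noise_amp, n_distractors)
    return(structure(list(image = img,
                          truth = tibble(object_id = integer(), view_deg = numeric(),
                                         row = numeric(), col = numeric())),
                     class = "scene"))
  }
  pl <- as_tibble(placements)
  half <- 128
  if (any(pl$row - half < 1 | pl$row + half - 1 > size |
          pl$col - half < 1 | pl$col + half - 1 > size))
    abort("a placement's 256-pixel bounding box falls outside the scene")
  if (nrow(pl) > 1) {
    dd <- as.matrix(stats::dist(cbind(pl$row, pl$col), method = "maximum"))
    diag(dd) <- Inf
    if (any(dd < 256)) abort("object bounding boxes overlap")
  }
  img <- clutter_background(background_seed, size, noise_amp, n_distractors,
                            avoid = pl[, c("row", "col")])
  for (i in seq_len(nrow(pl))) {
    obj <- render_object(object_spec(pl$object_id[i]), pl$view_deg[i])
    m <- attr(obj, "mask")
    rr <- (pl$row[i] - half):(pl$row[i] + half - 1)
    cc <- (pl$col[i] - half):(pl$col[i] + half - 1)
    sub <- img[rr, cc]
    sub[m] <- obj[m]
    img[rr, cc] <- sub
  }
  structure(list(image = img,
                 truth = pl[, c("object_id", "view_deg", "row", "col")]),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> ", nrow(x$image), "x", ncol(x$image), " px, ",
      nrow(x$truth), " placed objects\n", sep = "")
  invisible(x)
}

#' Standard scene set for evaluation
#'
#' Builds `n` scenes, each containing all four objects exactly once, each in
#' one of its four trained views, at jittered quadrant positions. The view
#' assignment rotates across scenes so every object is seen in every trained
#' view across any 4 consecutive scenes.
#'
#' @param n number of scenes.
#' @param seed base seed (placement jitter and backgrounds derive from it).
#' @param views trained views, degrees.
#' @param size scene side.
#' @param n_distractors,noise_amp passed to [compose_scene()].
#' @return list of `scene` objects.
#' @export
make_scene_set <- function(n, seed = 1, views = c(270, 315, 0, 45),
                           size = 1024L, n_distractors = 2L, noise_amp = 16) {
  purrr::map(seq_len(n), function(i) {
    withr::with_seed(substream_seed(seed, paste0("scene", i)), {
      q <- size / 4
      centres <- rbind(c(q, q), c(q, 3 * q), c(3 * q, q), c(3 * q, 3 * q))
      centres <- centres[sample(4), , drop = FALSE] +
        matrix(round(runif(8, -q / 4, q / 4)), 4, 2)
      centres <- clamp(centres, 129, size - 128)
      pl <- tibble(
        object_id = 0:3,
        view_deg = views[((0:3 + i - 1) %% 4) + 1],
        row = centres[, 1], col = centres[, 2]
      )
    })
    compose_scene(substream_seed(seed, paste0("bg", i)), pl, size,
                  n_distractors, noise_amp)
  })
}

#' Write a scene as PNG plus a JSON ground-truth sidecar
#'
#' The sidecar records 0-based `[row, col]` centres.
#'
#' @param scene a `scene`.
#' @param path output PNG path; the sidecar gets extension `.json`.
#' @param scene_id identifier stored in the sidecar.
#' @export
write_scene <- function(scene, path, scene_id = basename(path)) {
  png::writePNG(scene$image / 255, path)
  side <- sub("\\.png$", ".json", path)
  gt <- list(scene_id = scene_id,
             placements = purrr::pmap(scene$truth, function(object_id, view_deg, row, col)
               list(object_id = object_id, view_deg = view_deg,
                    center = c(row - 1, col - 1))))
  jsonlite::write_json(gt, side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read a grayscale image (PNG) as a 0-255 matrix
#' @param path PNG file path.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * 255
}
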