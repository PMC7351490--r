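## Synthetic brightfield imaging of droplets in a channel.
##
## Stands in for the high-frame-rate camera: draws a bright-rimmed droplet on
## a darker oil background, with bacterial colonies rendered as clusters of
## dark granular spots, plus additive Gaussian pixel noise clipped to the
## 8-bit range. Not a physical optics model -- the scoring pipeline only
## needs texture contrast between empty, sparse and dense droplets.

## rendering palette (8-bit intensities)
.render_levels <- list(
  oil = 70,       # continuous oil phase
  interior = 150, # aqueous droplet interior
  rim = 220,      # bright droplet rim
  granule = 45    # darkest colony granule core
)

#' Specification of a synthetic droplet frame
#'
#' @param frame_width,frame_height Frame size in pixels. Defaults mirror a
#'   commodity high-frame-rate camera (672 x 360).
#' @param droplet_radius Droplet radius in pixels; the droplet must fit in
#'   the frame.
#' @param colony_class One of `"empty"`, `"sparse"`, `"dense"`.
#' @param colony_cell_count Number of granular colony spots. Must be zero
#'   exactly when `colony_class = "empty"`; defaults to 0 / 20 / 500 for
#'   empty / sparse / dense.
#' @param noise_sd Additive Gaussian pixel-noise standard deviation
#'   (intensity units, `>= 0`).
#' @param seed RNG seed; rendering is bit-reproducible per seed.
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(frame_width = 672L, frame_height = 360L,
                                 droplet_radius = 80L,
                                 colony_class = c("empty", "sparse", "dense"),
                                 colony_cell_count = NULL,
                                 noise_sd = 2, seed = 1L) {
  colony_class <- match.arg(colony_class)
  if (is.null(colony_cell_count)) {
    colony_cell_count <- switch(colony_class,
      empty = 0L, sparse = 20L, dense = 500L
    )
  }
  if (colony_cell_count < 0) {
    stop_invalid("`colony_cell_count` must be non-negative")
  }
  if ((colony_cell_count == 0) != (colony_class == "empty")) {
    stop_invalid("`colony_cell_count` must be 0 exactly for the empty class")
  }
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (2 * droplet_radius + 6 >= frame_width ||
      2 * droplet_radius + 6 >= frame_height) {
    stop_invalid("droplet (plus rim) does not fit within the frame")
  }
  structure(
    list(
      frame_width = as.integer(frame_width),
      frame_height = as.integer(frame_height),
      droplet_radius = as.integer(droplet_radius),
      colony_class = colony_class,
      colony_cell_count = as.integer(colony_cell_count),
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "synthetic_image_spec"
  )
}

#' Construct a channel frame
#'
#' @param pixels Integer matrix (rows x columns) of 8-bit intensities.
#' @param centerline_row Row index of the channel centerline.
#' @param junction_column Column index of the sorting junction.
#' @return An object of class `channel_frame`.
#' @export
channel_frame <- function(pixels, centerline_row, junction_column) {
  if (!is.matrix(pixels)) stop_invalid("`pixels` must be a matrix")
  if (centerline_row < 1 || centerline_row > nrow(pixels) ||
      junction_column < 1 || junction_column > ncol(pixels)) {
    stop_invalid("centerline/junction indices out of image bounds")
  }
  structure(
    list(
      pixels = pixels,
      centerline_row = as.integer(centerline_row),
      junction_column = as.integer(junction_column)
    ),
    class = "channel_frame"
  )
}

## scatter colony granules around a cluster centre and stamp them (darkening
## via pmin) onto `img`; returns the image and the colony pixel mask
.stamp_colony <- function(img, cx, cy, max_r, count) {
  mask <- matrix(FALSE, nrow(img), ncol(img))
  if (count == 0) {
    return(list(img = img, mask = mask))
  }
  # cluster centre jitters off the droplet centre; scatter widens slowly
  # with colony size so dense colonies fill most of the interior
  ccx <- cx + stats::runif(1, -0.2, 0.2) * max_r
  ccy <- cy + stats::runif(1, -0.2, 0.2) * max_r
  scatter <- max_r * (0.45 + 0.15 * log10(1 + count) / 3)
  gx <- stats::rnorm(count, ccx, scatter)
  gy <- stats::rnorm(count, ccy, scatter)
  # keep granules well inside the rim
  d <- sqrt((gx - cx)^2 + (gy - cy)^2)
  lim <- 0.8 * max_r
  out <- d > lim
  gx[out] <- cx + (gx[out] - cx) * lim / d[out]
  gy[out] <- cy + (gy[out] - cy) * lim / d[out]
  dark <- .render_levels$granule + stats::runif(count, 0, 25)
  for (g in seq_len(count)) {
    r0 <- round(gy[g]); c0 <- round(gx[g])
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r0 + dr; cc <- c0 + dc
      if (rr < 1 || rr > nrow(img) || cc < 1 || cc > ncol(img)) next
      # plus-shaped granule: centre pixel plus 4-neighbours
      if (abs(dr) + abs(dc) <= 1) {
        val <- dark[g] + 15 * (abs(dr) + abs(dc))
        if (val < img[rr, cc]) {
          img[rr, cc] <- val
          mask[rr, cc] <- TRUE
        }
      }
    }
  }
  list(img = img, mask = mask)
}

.add_noise_clip <- function(img, noise_sd) {
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  matrix(as.integer(pmin(255, pmax(0, round(img)))), nrow(img), ncol(img))
}

#' Render a synthetic channel frame with ground truth
#'
#' Draws one droplet (bright rim, lighter interior) on a darker oil
#' background near the sorting junction, stamps the colony, adds Gaussian
#' noise and clips to 8 bits. Deterministic per seed.
#'
#' @param spec A [synthetic_image_spec()].
#' @return A list with elements `frame` (a [channel_frame()]) and `truth`
#'   (list with `edge_left`, `edge_right`, `colony_class`,
#'   `colony_pixel_mask`).
#' @export
render_frame <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  with_seed(spec$seed, {
    h <- spec$frame_height; w <- spec$frame_width
    r <- spec$droplet_radius
    cy <- h %/% 2L
    junction <- w %/% 2L
    # droplet sits near the junction with a small jitter
    cx <- junction + round(stats::runif(1, -10, 10))
    img <- matrix(.render_levels$oil, h, w)
    cols <- matrix(rep(seq_len(w), each = h), h, w)
    rows <- matrix(rep(seq_len(h), times = w), h, w)
    d <- sqrt((cols - cx)^2 + (rows - cy)^2)
    img[d <= r] <- .render_levels$interior
    img[d <= r & d >= r - 3] <- .render_levels$rim
    # colonies settle near the droplet centre; confine the scatter to the
    # ~60x80 interior region the scorer analyzes so patch-level and
    # frame-level renderings share one texture scale
    st <- .stamp_colony(img, cx, cy, min(r - 4, 32), spec$colony_cell_count)
    img <- .add_noise_clip(st$img, spec$noise_sd)
    list(
      frame = channel_frame(img, cy, junction),
      truth = list(
        edge_left = cx - r,
        edge_right = cx + r,
        colony_class = spec$colony_class,
        colony_pixel_mask = st$mask,
        center = c(row = cy, col = cx),
        radius = r
      )
    )
  })
}

#' Render a droplet-interior patch directly
#'
#' Produces a patch with the same rendering model as [render_frame()] but
#' without the channel geometry: the droplet-interior background with a
#' colony stamped at the centre. Useful for texture-level experiments.
#'
#' @param colony_class `"empty"`, `"sparse"` or `"dense"`.
#' @param colony_cell_count Granule count (0 iff empty); `NULL` for the
#'   class default.
#' @param seed RNG seed.
#' @param height,width Patch size in pixels (default 60 x 80).
#' @param noise_sd Gaussian pixel-noise SD.
#' @return A list with `roi` (a `droplet_roi`) and `label` (the class).
#' @export
render_roi <- function(colony_class = c("empty", "sparse", "dense"),
                       colony_cell_count = NULL, seed = 1L,
                       height = 60L, width = 80L, noise_sd = 2) {
  colony_class <- match.arg(colony_class)
  if (is.null(colony_cell_count)) {
    colony_cell_count <- switch(colony_class,
      empty = 0L, sparse = 20L, dense = 500L
    )
  }
  if (colony_cell_count < 0) stop_invalid("`colony_cell_count` must be >= 0")
  if ((colony_cell_count == 0) != (colony_class == "empty")) {
    stop_invalid("`colony_cell_count` must be 0 exactly for the empty class")
  }
  with_seed(seed, {
    img <- matrix(.render_levels$interior, height, width)
    st <- .stamp_colony(
      img, width / 2, height / 2,
      min(height, width) / 2, colony_cell_count
    )
    img <- .add_noise_clip(st$img, noise_sd)
    list(
      roi = structure(
        list(pixels = img, left = NA_integer_, right = NA_integer_),
        class = "droplet_roi"
      ),
      label = colony_class
    )
  })
}

#' Write a frame to disk as PNG or TIFF
#'
#' @param frame A [channel_frame()] or an integer pixel matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_frame <- function(frame, path) {
  px <- if (inherits(frame, "channel_frame")) frame$pixels else frame
  img01 <- px / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img01, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img01, path, bits.per.sample = 8L)
  } else {
    stop_invalid("unsupported image extension: ", ext)
  }
  invisible(path)
}

#' Read a grayscale frame from PNG or TIFF
#'
#' @param path Image path.
#' @param centerline_row,junction_column Channel geometry; default to the
#'   image centre.
#' @return A [channel_frame()] with 8-bit integer pixels.
#' @export
read_frame <- function(path, centerline_row = NULL, junction_column = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop_invalid("unsupported image extension: ", ext)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse grayscale RGB
  px <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  channel_frame(
    px,
    centerline_row %||% (nrow(px) %/% 2L),
    junction_column %||% (ncol(px) %/% 2L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
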