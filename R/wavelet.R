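## Wavelet-frame texture features.
##
## The colony-density score is built from an undecimated (wavelet frame)
## biorthogonal-3.1 decomposition. Per sliding window the "LLH" subband is
## taken: one level of low-pass filtering along both axes followed by a
## second-level high-pass along the horizontal axis with the a-trous
## (zero-upsampled) filter. The subband is quantized into `gray_levels`
## equal-width bins over its observed range and summarized by a gray-level
## co-occurrence matrix (GLCM) at a fixed pixel displacement; each window
## contributes one amplitude-weighted texture-energy element to the feature
## vector. The Wavelet OD is the fraction of non-zero elements.

## biorthogonal 3.1 analysis filters (exact dyadic-rational x sqrt(2) forms)
bior31_filters <- function() {
  list(
    lo = sqrt(2) / 4 * c(-1, 3, 3, -1),
    hi = sqrt(2) / 8 * c(-1, 3, -3, 1)
  )
}

#' Texture-scoring configuration
#'
#' Parameters of the wavelet-frame texture pipeline. Defaults follow the
#' optimized sorting configuration: biorthogonal 3.1 wavelets, LLH subband,
#' 15 x 15 pixel windows with a 5 pixel step, 15 gray levels, and a (3, 3)
#' pixel co-occurrence displacement.
#'
#' @param wavelet_family Wavelet identifier; only `"bior3.1"` is built in.
#' @param subband Subband path; only `"LLH"` (level-1 low/low, level-2
#'   horizontal high) is built in.
#' @param window Sliding-window side length in pixels.
#' @param step Window step in pixels (`window >= step >= 1`).
#' @param gray_levels Number of quantization levels (`>= 2`).
#' @param displacement Integer co-occurrence offset `c(rows, cols)`.
#' @param nonzero_tolerance Feature elements with absolute value at or below
#'   this are counted as zero. Units are subband intensity (8-bit scale);
#'   the default is calibrated so that sensor-noise-only windows score zero
#'   while granular colony texture does not.
#' @param flat_tolerance Subband ranges below this are treated as flat
#'   (feature exactly 0), so constant patches never acquire phantom texture
#'   from float round-off.
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(wavelet_family = "bior3.1",
                           subband = "LLH",
                           window = 15L, step = 5L,
                           gray_levels = 15L,
                           displacement = c(3L, 3L),
                           nonzero_tolerance = 0.8,
                           flat_tolerance = 1e-6) {
  if (!identical(wavelet_family, "bior3.1")) {
    stop_invalid("only the 'bior3.1' wavelet family is available")
  }
  if (!identical(subband, "LLH")) {
    stop_invalid("only the 'LLH' subband is available")
  }
  window <- as.integer(window); step <- as.integer(step)
  gray_levels <- as.integer(gray_levels)
  if (window < step || step < 1L) stop_invalid("need window >= step >= 1")
  if (gray_levels < 2L) stop_invalid("`gray_levels` must be >= 2")
  displacement <- as.integer(displacement)
  if (length(displacement) != 2L || any(displacement < 0) ||
      any(displacement >= window) || all(displacement == 0L)) {
    stop_invalid("`displacement` must be two offsets in [0, window), not both 0")
  }
  if (nonzero_tolerance < 0 || flat_tolerance <= 0) {
    stop_invalid("tolerances must be non-negative (flat tolerance positive)")
  }
  structure(
    list(
      wavelet_family = wavelet_family, subband = subband,
      window = window, step = step, gray_levels = gray_levels,
      displacement = displacement,
      nonzero_tolerance = nonzero_tolerance,
      flat_tolerance = flat_tolerance
    ),
    class = "texture_config"
  )
}

## circulant matrix applying periodic convolution with filter f (a-trous
## dilation `dilate`); row i of the result is sum_k f[k] x[(i + (k-1)*dilate)
## mod n]. Cached per (n, filter, dilate).
.filter_cache <- new.env(parent = emptyenv())

.circulant_filter <- function(n, f, dilate = 1L) {
  key <- paste(n, paste(signif(f, 12), collapse = ","), dilate, sep = "|")
  got <- .filter_cache[[key]]
  if (!is.null(got)) return(got)
  m <- matrix(0, n, n)
  # centre the filter: tap j sits at offset (j - 1 - floor((len-1)/2)) * dilate
  off <- (seq_along(f) - 1L - (length(f) - 1L) %/% 2L) * dilate
  for (i in seq_len(n)) {
    idx <- ((i - 1L + off) %% n) + 1L
    for (j in seq_along(f)) {
      m[i, idx[j]] <- m[i, idx[j]] + f[j]
    }
  }
  .filter_cache[[key]] <- m
  m
}

## undecimated LLH subband of a (window-sized) patch, periodic extension:
## level-1 low-pass along rows and columns, then level-2 high-pass along the
## horizontal axis with the filter upsampled by 2
swt_llh_subband <- function(patch) {
  f <- bior31_filters()
  n <- nrow(patch); m <- ncol(patch)
  a_lo_r <- .circulant_filter(n, f$lo)           # vertical (along columns)
  a_lo_c <- .circulant_filter(m, f$lo)           # horizontal (along rows)
  a_hi_c2 <- .circulant_filter(m, f$hi, dilate = 2L)
  ll <- a_lo_r %*% patch %*% t(a_lo_c)
  ll %*% t(a_hi_c2)
}

## equal-width quantization of `x` into `levels` bins over its observed
## min-max; a flat input maps to level 1 everywhere
quantize_gray_levels <- function(x, levels, flat_tolerance = 1e-6) {
  rng <- range(x)
  if (diff(rng) <= flat_tolerance) {
    return(matrix(1L, nrow(x), ncol(x)))
  }
  q <- floor((x - rng[1]) / (diff(rng) / levels)) + 1L
  q[q > levels] <- levels
  matrix(as.integer(q), nrow(x), ncol(x))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized values at a fixed displacement and
#' normalizes by the number of pairs.
#'
#' @param q Integer matrix of gray levels in `1:levels`.
#' @param levels Number of gray levels.
#' @param displacement Integer offset `c(rows, cols)`.
#' @return A `levels` x `levels` matrix of pair frequencies summing to 1.
#' @export
glcm <- function(q, levels, displacement = c(3L, 3L)) {
  dr <- displacement[1]; dc <- displacement[2]
  nr <- nrow(q); nc <- ncol(q)
  if (dr >= nr || dc >= nc) stop_invalid("displacement exceeds patch size")
  a <- q[seq_len(nr - dr), seq_len(nc - dc), drop = FALSE]
  b <- q[seq_len(nr - dr) + dr, seq_len(nc - dc) + dc, drop = FALSE]
  counts <- matrix(
    tabulate((as.vector(b) - 1L) * levels + as.vector(a), nbins = levels^2),
    levels, levels
  )
  counts / sum(counts)
}

## GLCM contrast normalized to [0,1]: sum_ij P(i,j) ((i-j)/(G-1))^2
.glcm_contrast <- function(p, levels) {
  i <- matrix(rep(seq_len(levels), times = levels), levels, levels)
  j <- t(i)
  sum(p * ((i - j) / (levels - 1))^2)
}

## one texture-energy element for a window: subband amplitude (SD) weighted
## by the normalized GLCM contrast of the quantized subband. Flat windows
## (range below tolerance) contribute exactly 0.
.window_feature <- function(win, cfg) {
  sub <- swt_llh_subband(win)
  if (diff(range(sub)) <= cfg$flat_tolerance) {
    return(0)
  }
  q <- quantize_gray_levels(sub, cfg$gray_levels, cfg$flat_tolerance)
  p <- glcm(q, cfg$gray_levels, cfg$displacement)
  stats::sd(sub) * .glcm_contrast(p, cfg$gray_levels)
}

#' Wavelet texture feature vector of a droplet interior
#'
#' Slides a `window` x `window` window over the patch in `step`-pixel
#' increments (row-major window order) and emits one texture-energy element
#' per window: the standard deviation of the window's LLH wavelet-frame
#' subband weighted by the normalized contrast of its gray-level
#' co-occurrence matrix.
#'
#' @param roi A `droplet_roi` (from [extract_roi()] or [render_roi()]) or a
#'   plain pixel matrix.
#' @param cfg A [texture_config()].
#' @return Numeric feature vector, one element per window.
#' @export
wavelet_texture_vector <- function(roi, cfg = texture_config()) {
  px <- if (inherits(roi, "droplet_roi")) roi$pixels else roi
  if (!is.matrix(px)) stop_invalid("`roi` must be a droplet_roi or matrix")
  w <- cfg$window
  if (nrow(px) < w || ncol(px) < w) {
    stop_invalid("roi smaller than the texture window",
                 class = "dropcult_too_small")
  }
  row_starts <- seq(1L, nrow(px) - w + 1L, by = cfg$step)
  col_starts <- seq(1L, ncol(px) - w + 1L, by = cfg$step)
  feats <- numeric(length(row_starts) * length(col_starts))
  k <- 0L
  for (r0 in row_starts) {
    for (c0 in col_starts) {
      k <- k + 1L
      win <- px[r0:(r0 + w - 1L), c0:(c0 + w - 1L)]
      feats[k] <- .window_feature(win, cfg)
    }
  }
  feats
}

#' Wavelet OD from a texture feature vector
#'
#' The fraction of feature elements whose magnitude exceeds the non-zero
#' tolerance; bounded in `[0, 1]` with 0 for empty droplets and 1 for very
#' dense colonies.
#'
#' @param vector Numeric feature vector from [wavelet_texture_vector()].
#' @param cfg A [texture_config()] (supplies the tolerance).
#' @return An object of class `wavelet_score`: list with `value`,
#'   `feature_length`, `nonzero_count`.
#' @export
wavelet_od <- function(vector, cfg = texture_config()) {
  if (length(vector) == 0) {
    stop_invalid("feature vector is empty")
  }
  nz <- sum(abs(vector) > cfg$nonzero_tolerance)
  structure(
    list(
      value = nz / length(vector),
      feature_length = length(vector),
      nonzero_count = nz
    ),
    class = "wavelet_score"
  )
}

#' @export
print.wavelet_score <- function(x, ...) {
  cat(sprintf(
    "Wavelet OD = %.3f (%d of %d elements non-zero)\n",
    x$value, x$nonzero_count, x$feature_length
  ))
  invisible(x)
}
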