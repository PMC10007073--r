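#' Gradient orientation field
#'
#' Estimates the per-pixel gradient with 3 x 3 Prewitt kernels
#' (edge-replicate borders, responses scaled by 1/6 so magnitudes are in
#' gray levels per pixel) and folds the gradient angle into \[0°, 180°):
#' an orientation, not a signed direction.
#'
#' @param plane Numeric matrix, at least 5 x 5.
#' @return An object of class `orientation_field` with elements `phi`
#'   (degrees in \[0, 180)), `magnitude` (gray levels/pixel, >= 0), and —
#'   once [quantize_orientation()] has run — `quantized` (integer bin in
#'   `0 .. n_bins - 1`, `NA` for sub-threshold magnitude) and `n_bins`.
#' @examples
#' f <- gradient_orientation(matrix(rep(0:7 * 30, each = 8), 8, 8))
#' f$phi[4, 4]   # vertical luminance change: 90 degrees
#' @export
gradient_orientation <- function(plane) {
  check_plane(plane, "plane")
  kv <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, byrow = TRUE) / 6
  gv <- conv2_replicate(plane, kv)      # change along rows
  gh <- conv2_replicate(plane, t(kv))   # change along columns
  phi <- (atan2(gv, gh) * 180 / pi) %% 180
  structure(list(phi = phi, magnitude = sqrt(gv^2 + gh^2),
                 gv = gv, gh = gh, quantized = NULL, n_bins = NULL),
            class = "orientation_field")
}

#' Quantize gradient orientations into histogram bins
#'
#' Bin `k` covers `[k * 180 / n_bins, (k + 1) * 180 / n_bins)` degrees.
#' Pixels whose gradient magnitude does not exceed `mag_threshold` carry no
#' reliable orientation (flat regions) and are marked `NA`; they never
#' enter orientation histograms, so a uniform region has pattern
#' complexity 0.
#'
#' @param field An `orientation_field` from [gradient_orientation()].
#' @param n_bins Number of orientation bins over \[0°, 180°) (>= 2).
#' @param mag_threshold Gating threshold in gray levels/pixel.
#' @return The field with `quantized` and `n_bins` filled.
#' @export
quantize_orientation <- function(field, n_bins = 12L, mag_threshold = 2) {
  stopifnot(inherits(field, "orientation_field"))
  if (n_bins < 2L) {
    stop("n_bins must be at least 2", call. = FALSE)
  }
  q <- pmin(floor(field$phi / (180 / n_bins)), n_bins - 1L)
  q[field$magnitude <= mag_threshold] <- NA_integer_
  field$quantized <- q
  field$n_bins <- as.integer(n_bins)
  field
}

#' Pattern complexity: orientation-histogram sparsity
#'
#' For every pixel, builds the histogram of quantized orientations over a
#' square region and counts its occupied bins (the L0 norm). Diverse local
#' orientations (complex patterns) give high counts; regular structure
#' gives 1; flat regions give 0.
#'
#' @param field A quantized `orientation_field`
#'   (see [quantize_orientation()]).
#' @param region_window Odd region size in pixels.
#' @return Integer matrix of bin counts in `0 .. n_bins`.
#' @export
pattern_complexity <- function(field, region_window = 5L) {
  stopifnot(inherits(field, "orientation_field"))
  if (is.null(field$quantized)) {
    stop("orientation field has not been quantized; ",
         "run quantize_orientation() first", call. = FALSE)
  }
  if (region_window %% 2L != 1L || region_window < 1L) {
    stop("region_window must be an odd positive integer", call. = FALSE)
  }
  q <- field$quantized
  pc <- matrix(0L, nrow(q), ncol(q))
  for (b in 0:(field$n_bins - 1L)) {
    ind <- (!is.na(q) & q == b) * 1
    pc <- pc + (box_sum(ind, region_window) > 0.5)
  }
  pc
}

#' Pattern masking threshold
#'
#' Maps pattern complexity `PC` to a masking threshold
#' \deqn{PM = b_1 \, PC^{b_2} / (PC^2 + b_3^2),}
#' zero at `PC = 0` and strictly increasing: richer orientation content
#' hides distortion better.
#'
#' @param pc_map Non-negative pattern-complexity map
#'   (see [pattern_complexity()]).
#' @param b1 Proportional constant (default 0.8).
#' @param b2 Exponent controlling the gain (default 2.7).
#' @param b3 Small stabilizing constant (default 0.1).
#' @param channel Channel label for the result.
#' @return A [threshold_map()] of kind `"PM"`.
#' @export
pattern_masking <- function(pc_map, b1 = 0.8, b2 = 2.7, b3 = 0.1,
                            channel = NA_character_) {
  pc <- map_data(pc_map)
  if (any(pc < 0)) {
    stop("pattern complexity must be non-negative", call. = FALSE)
  }
  threshold_map(b1 * pc^b2 / (pc^2 + b3^2), "PM", channel)
}

#' Directional gradient magnitude
#'
#' Convolves the plane with four 5 x 5 directional kernels (0°, 45°, 90°,
#' 135°; the classical kernel bank of the nonlinear-additivity masking
#' lineage, each normalized by 1/16) and keeps the maximal absolute
#' response per pixel — the weighted average gradient around the pixel.
#' Zero-sum kernels make the response invariant to constant offsets.
#'
#' @param plane Numeric matrix, at least 5 x 5.
#' @return Non-negative numeric matrix of maximal directional gradients.
#' @export
directional_gradients <- function(plane) {
  check_plane(plane, "plane")
  g <- matrix(0, nrow(plane), ncol(plane))
  for (k in directional_kernels()) {
    g <- pmax(g, abs(conv2_replicate(plane, k)) / 16)
  }
  g
}

#' @rdname directional_gradients
#' @export
directional_kernels <- function() {
  list(
    deg0 = matrix(c(0, 0, 0, 0, 0,
                    1, 3, 8, 3, 1,
                    0, 0, 0, 0, 0,
                    -1, -3, -8, -3, -1,
                    0, 0, 0, 0, 0), 5, byrow = TRUE),
    deg45 = matrix(c(0, 0, 1, 0, 0,
                     0, 8, 3, 0, 0,
                     1, 3, 0, -3, -1,
                     0, 0, -3, -8, 0,
                     0, 0, -1, 0, 0), 5, byrow = TRUE),
    deg90 = matrix(c(0, 0, 1, 0, 0,
                     0, 0, 3, 8, 0,
                     -1, -3, 0, 3, 1,
                     0, -8, -3, 0, 0,
                     0, 0, -1, 0, 0), 5, byrow = TRUE),
    deg135 = matrix(c(0, 1, 0, -1, 0,
                      0, 3, 0, -3, 0,
                      0, 8, 0, -8, 0,
                      0, 3, 0, -3, 0,
                      0, 1, 0, -1, 0), 5, byrow = TRUE)
  )
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' gradient direction, and hysteresis thresholding (`low`, `high` on the
#' max-normalized magnitude; weak responses survive only in connected
#' components that contain a strong response).
#'
#' @param plane Numeric matrix, at least 5 x 5.
#' @param sigma Gaussian smoothing scale in pixels.
#' @param low,high Hysteresis thresholds on the normalized gradient
#'   magnitude, `0 <= low < high <= 1`.
#' @return Logical matrix: `TRUE` at edge pixels.
#' @export
canny_edges <- function(plane, sigma = 1.4, low = 0.1, high = 0.3) {
  check_plane(plane, "plane")
  if (!(low >= 0 && low < high && high <= 1)) {
    stop("hysteresis thresholds must satisfy 0 <= low < high <= 1",
         call. = FALSE)
  }
  ksz <- 2L * ceiling(3 * sigma) + 1L
  sm <- gaussian_smooth(plane, ksz, sigma)
  ks <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE)
  gy <- conv2_replicate(sm, ks)     # along rows
  gx <- conv2_replicate(sm, t(ks))  # along columns
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  # below a micro-gray-level of gradient there is nothing to detect
  if (mx <= 1e-6) {
    return(matrix(FALSE, nrow(plane), ncol(plane)))
  }
  mag <- mag / mx
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  n <- nrow(mag)
  m <- ncol(mag)
  p <- pad_replicate(mag, 1L)
  shift <- function(dr, dc) p[seq_len(n) + 1L + dr, seq_len(m) + 1L + dc]
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  n1 <- matrix(0, n, m)
  n2 <- matrix(0, n, m)
  pick <- function(sel, a, b) {
    n1[sel] <<- a[sel]
    n2[sel] <<- b[sel]
  }
  pick(sector == 0L, shift(0L, 1L), shift(0L, -1L))
  pick(sector == 45L, shift(1L, 1L), shift(-1L, -1L))
  pick(sector == 90L, shift(1L, 0L), shift(-1L, 0L))
  pick(sector == 135L, shift(1L, -1L), shift(-1L, 1L))
  keep <- mag >= n1 & mag >= n2
  weak <- keep & mag >= low
  strong <- keep & mag >= high
  if (!any(strong)) {
    return(matrix(FALSE, n, m))
  }
  labels <- EBImage::bwlabel(weak * 1)
  weak & labels %in% unique(labels[strong])
}

#' Edge-related weight map
#'
#' Detects edges with [canny_edges()], assigns `edge_value` at edge pixels
#' and 1 elsewhere, smooths with a Gaussian kernel, and clips to
#' `[edge_value, 1]`. The resulting weight suppresses the masking estimate
#' near edges, where the eye tolerates the least distortion.
#'
#' @inheritParams canny_edges
#' @param canny_sigma,low,high Canny parameters (see [canny_edges()]).
#' @param smooth_window,smooth_sigma Gaussian smoothing of the weight map.
#' @param edge_value Weight assigned on edges (default 0.1).
#' @return Numeric matrix with values in `[edge_value, 1]`.
#' @export
edge_weight <- function(plane, canny_sigma = 1.4, low = 0.1, high = 0.3,
                        smooth_window = 7L, smooth_sigma = 0.8,
                        edge_value = 0.1) {
  edges <- canny_edges(plane, canny_sigma, low, high)
  w <- matrix(1, nrow(plane), ncol(plane))
  w[edges] <- edge_value
  w <- gaussian_smooth(w, smooth_window, smooth_sigma)
  pmin(pmax(w, edge_value), 1)
}

#' Edge protection term
#'
#' \deqn{EP_\theta = \lambda_\theta \, G \, W,} where `G` is the maximal
#' directional gradient ([directional_gradients()]), `W` the edge-related
#' weight ([edge_weight()]), and `lambda` a per-channel gain
#' (Y 0.117, Cb 0.65, Cr 0.45). Small `W` at edges pulls the threshold
#' down there — protection — while strong non-edge gradients keep a high
#' masking allowance.
#'
#' @param g_map Non-negative gradient map.
#' @param w_map Weight map in `[0, 1]`.
#' @param channel `"Y"`, `"Cb"` or `"Cr"`.
#' @param lambda Named per-channel gains.
#' @return A [threshold_map()] of kind `"EP"`.
#' @export
edge_protection <- function(g_map, w_map, channel,
                            lambda = c(Y = 0.117, Cb = 0.65, Cr = 0.45)) {
  if (!channel %in% names(lambda)) {
    stop("unknown channel label '", channel, "'; expected one of ",
         paste(names(lambda), collapse = ", "), call. = FALSE)
  }
  check_same_shape(g_map, w_map)
  threshold_map(lambda[[channel]] * g_map * w_map, "EP", channel)
}
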