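# SDSP-style saliency: three simple priors combined by product. Saliency is
# computed once from the RGB image (at a reduced working resolution) and
# shared by all three channels.

rgb_to_lab <- function(rgb) {
  d <- dim(rgb$r)
  m <- cbind(as.vector(rgb$r), as.vector(rgb$g), as.vector(rgb$b)) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(l = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

resize_bilinear <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  # EBImage's first dimension is the matrix row dimension
  as.matrix(EBImage::resize(m, w = nr, h = nc, filter = "bilinear"))
}

fft_radial_freq <- function(n, m) {
  fr <- seq_len(n) - 1
  fr <- ifelse(fr <= n / 2, fr, fr - n) / n
  fc <- seq_len(m) - 1
  fc <- ifelse(fc <= m / 2, fc, fc - m) / m
  sqrt(outer(fr^2, rep(1, m)) + outer(rep(1, n), fc^2))
}

#' Saliency priors
#'
#' The three priors of the SDSP saliency detector:
#'
#' * `frequency_prior()` — band-pass energy: each CIE L*a*b* channel is
#'   filtered in the frequency domain by a log-Gabor transfer
#'   `exp(-(log(w / omega0))^2 / (2 sigma_f^2))` (zero DC response); the
#'   prior is the Euclidean norm of the three filtered responses,
#'   max-normalized to `[0, 1]`. Constant images score 0 everywhere.
#' * `location_prior()` — center bias `exp(-||x - c||^2 / sigma_d^2)` with
#'   `c` the image center in pixels.
#' * `color_prior()` — warm-color bias: with the a* and b* planes min-max
#'   normalized over the image to `a_n, b_n` in `[0, 1]`,
#'   `SC = 1 - exp(-(a_n^2 + b_n^2) / sigma_c^2)`. Constant-chroma images
#'   define `a_n = b_n = 0`.
#'
#' @param rgb An [rgb_image()].
#' @param omega0 Center frequency of the log-Gabor band-pass
#'   (cycles/pixel).
#' @param sigma_f Log-Gabor bandwidth parameter.
#' @param height,width Output dimensions in pixels.
#' @param sigma_d Center-bias scale in pixels.
#' @param sigma_c Color-prior scale.
#' @return A matrix with values in `[0, 1]`.
#' @name saliency_priors
NULL

#' @rdname saliency_priors
#' @export
frequency_prior <- function(rgb, omega0 = 0.002, sigma_f = 6.2) {
  stopifnot(inherits(rgb, "rgb_image"))
  if (omega0 <= 0 || sigma_f <= 0) {
    stop("omega0 and sigma_f must be positive", call. = FALSE)
  }
  lab <- rgb_to_lab(rgb)
  n <- nrow(rgb$r)
  m <- ncol(rgb$r)
  rho <- fft_radial_freq(n, m)
  lg <- exp(-(log(rho / omega0))^2 / (2 * sigma_f^2))
  lg[rho == 0] <- 0
  bp <- function(x) {
    Re(stats::fft(stats::fft(x) * lg, inverse = TRUE)) / (n * m)
  }
  sf <- sqrt(bp(lab$l)^2 + bp(lab$a)^2 + bp(lab$b)^2)
  mx <- max(sf)
  if (mx > 0) sf / mx else sf
}

#' @rdname saliency_priors
#' @export
location_prior <- function(height, width, sigma_d = 114) {
  if (sigma_d <= 0) {
    stop("sigma_d must be positive", call. = FALSE)
  }
  cr <- (height + 1) / 2
  cc <- (width + 1) / 2
  d2 <- outer((seq_len(height) - cr)^2, (seq_len(width) - cc)^2, `+`)
  exp(-d2 / sigma_d^2)
}

#' @rdname saliency_priors
#' @export
color_prior <- function(rgb, sigma_c = 0.25) {
  stopifnot(inherits(rgb, "rgb_image"))
  lab <- rgb_to_lab(rgb)
  mm <- function(x) {
    rng <- range(x)
    if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  }
  an <- mm(lab$a)
  bn <- mm(lab$b)
  1 - exp(-(an^2 + bn^2) / sigma_c^2)
}

#' Combine, normalize and invert saliency
#'
#' `combine_saliency()` multiplies the three priors pixel-wise.
#' `normalize_saliency()` min-max normalizes the raw map to `[0, 1]`
#' (a constant map normalizes to 0 everywhere: no region stands out, so
#' nothing is suppressed). `saliency_modulation()` converts normalized
#' saliency into the masking modulation factor `U = 1 - S'`: attended
#' regions tolerate less distortion, so their masking estimate shrinks.
#'
#' @param sf,sd,sc Prior maps of identical shape.
#' @param s Raw saliency map.
#' @param s_norm Normalized saliency in `[0, 1]`.
#' @return A numeric matrix.
#' @export
combine_saliency <- function(sf, sd, sc) {
  check_same_shape(sf, sd, sc)
  sf * sd * sc
}

#' @rdname combine_saliency
#' @export
normalize_saliency <- function(s) {
  if (!all(is.finite(s))) {
    stop("saliency map contains non-finite values", call. = FALSE)
  }
  rng <- range(s)
  if (rng[2] > rng[1]) (s - rng[1]) / (rng[2] - rng[1]) else s * 0
}

#' @rdname combine_saliency
#' @export
saliency_modulation <- function(s_norm) {
  if (any(s_norm < 0 | s_norm > 1)) {
    stop("normalized saliency must lie in [0, 1]", call. = FALSE)
  }
  1 - s_norm
}

#' Full saliency map with modulation factor
#'
#' Resizes the image so its longer side equals the configured working size
#' (bilinear; the center-bias scale `sigma_d` is defined at that
#' resolution), computes the three SDSP priors and their product there,
#' resizes the raw map back to the input size, then normalizes and inverts
#' it. With `saliency$enabled = FALSE` the modulation factor is 1
#' everywhere (masking unmodified).
#'
#' @param rgb An [rgb_image()].
#' @param config A [csjnd_config()].
#' @return A `saliency_map` object: list with `s` (raw, input size),
#'   `s_norm` in `[0, 1]`, `u = 1 - s_norm`, and `priors` (the three maps
#'   at the working resolution).
#' @export
compute_saliency <- function(rgb, config = csjnd_config()) {
  stopifnot(inherits(rgb, "rgb_image"))
  n <- nrow(rgb$r)
  m <- ncol(rgb$r)
  pars <- config$saliency
  if (!isTRUE(pars$enabled)) {
    z <- matrix(0, n, m)
    return(structure(list(s = z, s_norm = z, u = z + 1, priors = NULL),
                     class = "saliency_map"))
  }
  scl <- pars$working_size / max(n, m)
  wn <- max(5L, round(n * scl))
  wm <- max(5L, round(m * scl))
  small <- rgb_image(clip255(resize_bilinear(rgb$r, wn, wm)),
                     clip255(resize_bilinear(rgb$g, wn, wm)),
                     clip255(resize_bilinear(rgb$b, wn, wm)))
  sf <- frequency_prior(small, pars$omega0, pars$sigma_f)
  sd <- location_prior(wn, wm, pars$sigma_d)
  sc <- color_prior(small, pars$sigma_c)
  s_small <- combine_saliency(sf, sd, sc)
  s <- resize_bilinear(s_small, n, m)
  s_norm <- normalize_saliency(s)
  structure(list(s = s, s_norm = s_norm, u = saliency_modulation(s_norm),
                 priors = list(sf = sf, sd = sd, sc = sc)),
            class = "saliency_map")
}
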