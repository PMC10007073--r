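sign_field <- function(dims, seed) {
  with_seed(seed, {
    lapply(c("y", "cb", "cr"), function(ch) {
      matrix(sample(c(-1, 1), prod(dims), replace = TRUE), dims[1], dims[2])
    })
  })
}

sign_digest <- function(signs) {
  v <- unlist(lapply(signs, as.vector))
  pos <- sum((v > 0) * seq_along(v)) %% 2147483647
  sprintf("n=%d;pos=%d;sum=%d", length(v), pos, sum(v))
}

maps_as_list <- function(maps) {
  if (inherits(maps, "csjnd_result")) maps <- maps$maps
  stopifnot(is.list(maps), all(c("Y", "Cb", "Cr") %in% names(maps)))
  lapply(maps[c("Y", "Cb", "Cr")], map_data)
}

#' JND-guided noise injection
#'
#' Perturbs every pixel of every channel by its threshold:
#' \deqn{\hat F_\theta(x) = F_\theta(x) + \beta \, r(x) \, JND_\theta(x),}
#' where `r(x)` is a fair ±1 coin drawn independently per pixel and per
#' channel from a seeded generator, and `beta` scales the noise level.
#' The result is clipped to `[0, 255]`. An accurate threshold map hides
#' this noise; the injector is the standard probe for validating JND
#' models at matched noise energy.
#'
#' @param img A [ycbcr_image()].
#' @param maps Named list of Y/Cb/Cr [threshold_map()]s, or a
#'   `csjnd_result`.
#' @param beta Positive noise-level controller.
#' @param seed Integer seed for the sign field; equal seeds give
#'   bit-identical output.
#' @return An `injection_result`: list with `contaminated`
#'   ([ycbcr_image()]), `beta`, `achieved_psnr` (dB, pooled), `seed` and
#'   `sign_field_digest`.
#' @export
inject <- function(img, maps, beta, seed) {
  stopifnot(inherits(img, "ycbcr_image"))
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be a single positive value", call. = FALSE)
  }
  m <- maps_as_list(maps)
  check_same_shape(img$y, m$Y, m$Cb, m$Cr)
  signs <- sign_field(dim(img$y), seed)
  out <- inject_with_signs(img, m, beta, signs)
  structure(list(contaminated = out, beta = beta,
                 achieved_psnr = img_psnr(img, out), seed = seed,
                 sign_field_digest = sign_digest(signs)),
            class = "injection_result")
}

inject_with_signs <- function(img, m, beta, signs) {
  ycbcr_image(clip255(img$y + beta * signs[[1]] * m$Y),
              clip255(img$cb + beta * signs[[2]] * m$Cb),
              clip255(img$cr + beta * signs[[3]] * m$Cr),
              source = img$source)
}

#' Peak signal-to-noise ratio between two images
#'
#' `10 log10(255^2 / MSE)` with the mean squared error pooled over all
#' three channel planes (default), over Y only, or over RGB planes after
#' conversion. Identical images return `Inf`.
#'
#' @param a,b [ycbcr_image()]s of identical shape.
#' @param domain Pooling domain: `"ycbcr_pooled"` (default), `"y_only"`,
#'   or `"rgb_pooled"`.
#' @return PSNR in dB.
#' @examples
#' g <- matrix(100, 8, 8)
#' img <- ycbcr_image(g, g, g)
#' img_psnr(img, ycbcr_image(g + 5, g + 5, g + 5))   # 34.15 dB
#' @export
img_psnr <- function(a, b,
                     domain = c("ycbcr_pooled", "y_only", "rgb_pooled")) {
  domain <- match.arg(domain)
  stopifnot(inherits(a, "ycbcr_image"), inherits(b, "ycbcr_image"))
  check_same_shape(a$y, b$y)
  mse <- switch(domain,
    ycbcr_pooled = mean(c((a$y - b$y)^2, (a$cb - b$cb)^2,
                          (a$cr - b$cr)^2)),
    y_only = mean((a$y - b$y)^2),
    rgb_pooled = {
      ra <- ycbcr_to_rgb(a)
      rb <- ycbcr_to_rgb(b)
      mean(c((ra$r - rb$r)^2, (ra$g - rb$g)^2, (ra$b - rb$b)^2))
    })
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

#' Per-channel mean squared error
#'
#' @inheritParams img_psnr
#' @return Named numeric triple of MSEs (Y, Cb, Cr).
#' @export
channel_mse <- function(a, b) {
  stopifnot(inherits(a, "ycbcr_image"), inherits(b, "ycbcr_image"))
  check_same_shape(a$y, b$y)
  c(Y = mean((a$y - b$y)^2), Cb = mean((a$cb - b$cb)^2),
    Cr = mean((a$cr - b$cr)^2))
}

#' Calibrate the noise level to a target PSNR
#'
#' Different threshold maps inject different amounts of energy at
#' `beta = 1`; fair comparisons require equal energy. This bisects on
#' `beta` — with the ±1 sign field held fixed by `seed`, and clipping to
#' `[0, 255]` applied inside the loop — until the achieved pooled PSNR of
#' the contaminated image is within `tol` of `target_psnr`.
#'
#' @inheritParams inject
#' @param target_psnr Target PSNR in dB.
#' @param tol Acceptable deviation in dB (default 0.05).
#' @param max_iter Bisection iteration cap.
#' @return An `injection_result` (see [inject()]) at the calibrated
#'   `beta`.
#' @export
calibrate_beta <- function(img, maps, target_psnr, seed, tol = 0.05,
                           max_iter = 60L) {
  stopifnot(inherits(img, "ycbcr_image"))
  m <- maps_as_list(maps)
  check_same_shape(img$y, m$Y, m$Cb, m$Cr)
  if (all(m$Y == 0) && all(m$Cb == 0) && all(m$Cr == 0)) {
    stop("calibration impossible: all threshold maps are identically zero",
         call. = FALSE)
  }
  signs <- sign_field(dim(img$y), seed)
  f <- function(beta) {
    img_psnr(img, inject_with_signs(img, m, beta, signs))
  }
  lo <- 0
  hi <- 1
  p_hi <- f(hi)
  grow <- 0L
  while (p_hi > target_psnr && grow < 60L) {
    lo <- hi
    hi <- hi * 2
    p_hi <- f(hi)
    grow <- grow + 1L
  }
  if (p_hi > target_psnr) {
    stop(sprintf(paste0("calibration impossible: clipping limits the ",
                        "injectable energy (PSNR %.2f dB at beta = %.3g, ",
                        "target %.2f dB)"), p_hi, hi, target_psnr),
         call. = FALSE)
  }
  beta <- hi
  achieved <- p_hi
  for (i in seq_len(max_iter)) {
    if (abs(achieved - target_psnr) <= tol) break
    mid <- (lo + hi) / 2
    p_mid <- f(mid)
    if (p_mid > target_psnr) {
      lo <- mid
    } else {
      hi <- mid
    }
    beta <- mid
    achieved <- p_mid
  }
  if (abs(achieved - target_psnr) > tol) {
    stop(sprintf(paste0("beta calibration did not converge in %d ",
                        "iterations: bracket [%.6g, %.6g], achieved ",
                        "%.3f dB vs target %.3f dB"),
                 max_iter, lo, hi, achieved, target_psnr), call. = FALSE)
  }
  out <- inject_with_signs(img, m, beta, signs)
  structure(list(contaminated = out, beta = beta, achieved_psnr = achieved,
                 seed = seed, sign_field_digest = sign_digest(signs)),
            class = "injection_result")
}

#' Structural similarity between two planes
#'
#' Single-scale SSIM with the conventional 11 x 11 Gaussian window
#' (sigma 1.5), stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` for the
#' 8-bit dynamic range `L = 255`, and edge-replicate borders. Symmetric in
#' its arguments; 1 exactly for identical planes.
#'
#' @param a,b Numeric matrices of identical shape (gray levels).
#' @param dynamic_range Intensity range `L` (default 255).
#' @return Mean SSIM over the plane, in `[-1, 1]`.
#' @export
plane_ssim <- function(a, b, dynamic_range = 255) {
  check_same_shape(a, b)
  k <- gaussian_kernel(11L, 1.5)
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mu_a <- conv2_replicate(a, k)
  mu_b <- conv2_replicate(b, k)
  va <- conv2_replicate(a^2, k) - mu_a^2
  vb <- conv2_replicate(b^2, k) - mu_b^2
  cab <- conv2_replicate(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * cab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (va + vb + c2)
  mean(num / den)
}

#' Quality report for a contaminated image
#'
#' @param a,b [ycbcr_image()]s (reference, distorted).
#' @return List with pooled `psnr_db`, `ssim` (on the Y plane) and
#'   `channel_mse`.
#' @export
quality_score <- function(a, b) {
  list(psnr_db = img_psnr(a, b), ssim = plane_ssim(a$y, b$y),
       channel_mse = channel_mse(a, b))
}
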