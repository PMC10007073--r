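#' Local luminance statistics
#'
#' `local_mean()` is the unweighted arithmetic mean of a square
#' neighborhood (default 5 x 5); `local_contrast()` is the population
#' standard deviation (or variance, with `stat = "var"`) over the same
#' neighborhood. Borders use edge-replicate padding.
#'
#' The contrast statistic feeds the masking transducer of
#' [contrast_masking()], whose half-saturation constant `a2 = 26` lives on
#' the gray-level scale; the standard deviation is therefore the default.
#'
#' @param plane Numeric matrix of intensities (gray levels).
#' @param window Odd window size in pixels (`window = 1` is the identity).
#' @param stat `"std"` (default) or `"var"`.
#' @return Numeric matrix, same shape as `plane`.
#' @examples
#' local_mean(matrix(100, 6, 6))[1, 1]        # 100
#' local_contrast(matrix(7, 6, 6))[3, 3]      # 0
#' @export
local_mean <- function(plane, window = 5L) {
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  if (window == 1L) return(plane + 0)
  box_sum(plane, window) / window^2
}

#' @rdname local_mean
#' @export
local_contrast <- function(plane, window = 5L, stat = c("std", "var")) {
  stat <- match.arg(stat)
  if (window %% 2L != 1L || window < 1L) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  mu <- local_mean(plane, window)
  mu2 <- local_mean(plane^2, window)
  v <- pmax(mu2 - mu^2, 0)
  if (stat == "var") v else sqrt(v)
}

#' Luminance adaptation threshold
#'
#' Visibility threshold as a function of local background luminance
#' `l` (gray levels): high in the dark, minimal (3) at mid-gray 127,
#' rising gently toward white:
#' \deqn{LA = 17 (1 - \sqrt{l / 127}) + 3 \quad (l \le 127), \qquad
#'       LA = 3 (l - 127) / 128 + 3 \quad (l > 127).}
#' Continuous at `l = 127`.
#'
#' @param mean_map Local mean luminance, values in `[0, 255]`
#'   (see [local_mean()]).
#' @return A [threshold_map()] of kind `"LA"`.
#' @examples
#' luminance_adaptation(matrix(127, 5, 5))[1, 1]   # 3
#' luminance_adaptation(matrix(0, 5, 5))[1, 1]     # 20
#' @export
luminance_adaptation <- function(mean_map) {
  l <- map_data(mean_map)
  if (any(l < 0 | l > 255)) {
    stop("background luminance must lie in [0, 255]", call. = FALSE)
  }
  la <- ifelse(l <= 127,
               17 * (1 - sqrt(l / 127)) + 3,
               3 * (l - 127) / 128 + 3)
  threshold_map(la, "LA", "Y")
}

#' Contrast masking transducer
#'
#' Nonlinear transducer mapping local contrast `c` (gray levels) to a
#' masking threshold:
#' \deqn{CM = 0.115 \, a_1 c^{2.4} / (c^2 + a_2^2),}
#' zero at zero contrast, strictly increasing, and sublinear for large `c`
#' (asymptotic growth `c^{0.4}`), so strong textures are not over-credited.
#'
#' @param c_map Non-negative contrast map (see [local_contrast()]).
#' @param a1 Gain constant (default 16).
#' @param a2 Half-saturation constant in gray levels (default 26).
#' @param channel Channel label for the result.
#' @return A [threshold_map()] of kind `"CM"`.
#' @examples
#' contrast_masking(matrix(0, 5, 5))[1, 1]   # 0
#' @export
contrast_masking <- function(c_map, a1 = 16, a2 = 26,
                             channel = NA_character_) {
  cm <- map_data(c_map)
  if (any(cm < 0)) {
    stop("contrast values must be non-negative", call. = FALSE)
  }
  out <- 0.115 * a1 * cm^2.4 / (cm^2 + a2^2)
  threshold_map(out, "CM", channel)
}
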