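#' Visual masking and its saliency modulation
#'
#' The three masking factors are positively correlated, so they combine by
#' pixel-wise product: `VM = CM * PM * EP`. `modulate_masking()` then
#' applies the saliency modulation factor, `VMS = VM * U`; since
#' `U` is in `[0, 1]`, saliency can only reduce the masking estimate.
#'
#' @param cm,pm,ep [threshold_map()]s of kinds CM/PM/EP, same shape and
#'   channel.
#' @param vm A [threshold_map()] of kind VM.
#' @param u Modulation factor map in `[0, 1]` (see [compute_saliency()]).
#' @return A [threshold_map()] of kind `"VM"` / `"VMS"`.
#' @export
visual_masking <- function(cm, pm, ep) {
  check_same_shape(cm, pm, ep)
  chans <- c(map_channel(cm), map_channel(pm), map_channel(ep))
  chans <- chans[!is.na(chans)]
  if (length(unique(chans)) > 1L) {
    stop("masking factors carry different channel labels: ",
         paste(unique(chans), collapse = ", "), call. = FALSE)
  }
  ch <- if (length(chans)) chans[[1L]] else NA_character_
  threshold_map(map_data(cm) * map_data(pm) * map_data(ep), "VM", ch)
}

#' @rdname visual_masking
#' @export
modulate_masking <- function(vm, u) {
  check_same_shape(vm, u)
  threshold_map(map_data(vm) * u, "VMS", map_channel(vm))
}

#' NAMM fusion of adaptation and masking
#'
#' Nonlinear additivity model for masking:
#' \deqn{JND = LA + VMS - \alpha \min(LA, VMS),}
#' where `alpha` discounts the overlap between luminance adaptation and
#' masking (default 0.3). The result is sandwiched between
#' `max(LA, VMS)` and `LA + VMS` for any `alpha` in `[0, 1)`.
#'
#' @param la Luminance-adaptation [threshold_map()].
#' @param vms Masking [threshold_map()] (saliency-modulated or not).
#' @param alpha Gain reduction factor in `[0, 1)`.
#' @param kind Label for the fused map (`"JND_S"` by default).
#' @return A [threshold_map()].
#' @examples
#' la <- threshold_map(matrix(20, 5, 5), "LA")
#' vm <- threshold_map(matrix(10, 5, 5), "VMS")
#' namm_fuse(la, vm)[1, 1]   # 20 + 10 - 0.3 * 10 = 27
#' @export
namm_fuse <- function(la, vms, alpha = 0.3, kind = "JND_S") {
  check_same_shape(la, vms)
  if (alpha < 0 || alpha >= 1) {
    stop("alpha must lie in [0, 1)", call. = FALSE)
  }
  la <- map_data(la)
  vms_d <- map_data(vms)
  threshold_map(la + vms_d - alpha * pmin(la, vms_d), kind,
                map_channel(vms))
}

#' Color-sensitivity parameters and weights
#'
#' The eye resolves distortion in Y at a larger critical viewing distance
#' than in Cb or Cr (ratio `D_Y : D_Cb : D_Cr = 1 : 0.432 : 0.501`).
#' `sensitivity_params()` converts the distance ratio into per-channel
#' sensitivity parameters — each channel's squared share,
#' `S_theta = D_theta^2 / sum(D^2)`, summing to 1.
#' `cs_weights()` inverts the sensitivities (a more sensitive channel must
#' get a smaller threshold) and normalizes so the three weights sum to 3:
#' `CS_theta = 3 (1/S_theta) / sum(1/S)`.
#'
#' With the default ratio the sensitivity parameters are approximately
#' (0.696, 0.130, 0.175); starting from the published rounded triple
#' (0.695, 0.130, 0.175) the weights are (0.291, 1.554, 1.155).
#'
#' @param d_ratio Positive critical-distance ratio, named Y/Cb/Cr.
#' @param s_params Sensitivity parameters in `(0, 1)`.
#' @return A named numeric triple.
#' @examples
#' sensitivity_params(c(Y = 1, Cb = 1, Cr = 1))   # thirds
#' cs_weights(c(Y = 1, Cb = 1, Cr = 1) / 3)       # all ones
#' @export
sensitivity_params <- function(d_ratio = c(Y = 1, Cb = 0.432, Cr = 0.501)) {
  if (length(d_ratio) != 3L || any(d_ratio <= 0)) {
    stop("d_ratio must be three positive values", call. = FALSE)
  }
  s <- d_ratio^2 / sum(d_ratio^2)
  names(s) <- c("Y", "Cb", "Cr")
  s
}

#' @rdname sensitivity_params
#' @export
cs_weights <- function(s_params) {
  if (length(s_params) != 3L || any(s_params <= 0) || any(s_params >= 1)) {
    stop("sensitivity parameters must be three values in (0, 1)",
         call. = FALSE)
  }
  inv <- 1 / s_params
  w <- 3 * inv / sum(inv)
  names(w) <- c("Y", "Cb", "Cr")
  w
}

#' Apply a color-sensitivity weight to a sub-threshold map
#'
#' Scales a channel's fused JND map by that channel's weight:
#' `CSJND_theta = CS_theta * JND_theta`.
#'
#' @param jnd A [threshold_map()] with a Y/Cb/Cr channel label.
#' @param weights Named weight triple from [cs_weights()].
#' @param kind Label for the result (default `"CSJND"`).
#' @return A [threshold_map()].
#' @export
apply_cs <- function(jnd, weights, kind = "CSJND") {
  ch <- map_channel(jnd)
  if (is.na(ch) || !ch %in% names(weights)) {
    stop("threshold map must carry a channel label matching a weight",
         call. = FALSE)
  }
  threshold_map(weights[[ch]] * map_data(jnd), kind, ch)
}

model_weights <- function(config) {
  if (config$fusion$cs_from == "printed") {
    cs_weights(printed_sensitivity)
  } else {
    cs_weights(sensitivity_params(config$fusion$d_ratio))
  }
}

#' Compute per-channel JND maps
#'
#' Runs the whole pipeline on one image: luminance adaptation from the
#' local mean of Y (shared by all channels by default); per channel, the
#' contrast, pattern and edge-protection terms multiplied into the masking
#' estimate; saliency modulation; NAMM fusion; and color-sensitivity
#' weighting. The configured `variant` picks which stages are active:
#'
#' * `"B"`  — adaptation + masking only,
#' * `"S"`  — base + saliency modulation,
#' * `"C"`  — base + color-sensitivity weighting,
#' * `"full"` — base + saliency + color sensitivity.
#'
#' @param rgb An [rgb_image()] (or a path readable by [read_rgb()]).
#' @param config A [csjnd_config()].
#' @return An object of class `csjnd_result`: list with `maps` (named
#'   [threshold_map()]s for Y, Cb, Cr), `ycbcr` (the converted image),
#'   `variant`, `weights` (the triple actually applied), `saliency`, and
#'   `components` (per-channel LA/CM/PM/EP/VM/VMS maps).
#' @examples
#' img <- generate_fixture(fixture_spec("flat", c(32, 32), level = 128))
#' res <- csjnd_compute(img, csjnd_config(variant = "B"))
#' res$maps$Y[16, 16]
#' @export
csjnd_compute <- function(rgb, config = csjnd_config()) {
  if (is.character(rgb)) {
    rgb <- read_rgb(rgb)
  }
  stopifnot(inherits(rgb, "rgb_image"), inherits(config, "csjnd_config"))
  ycc <- rgb_to_ycbcr(rgb)
  variant <- config$variant
  be <- config$base_effects
  st <- config$structure

  use_saliency <- variant %in% c("S", "full") && isTRUE(config$saliency$enabled)
  sal <- if (use_saliency) {
    compute_saliency(rgb, config)
  } else {
    n <- nrow(ycc$y)
    structure(list(s = matrix(0, n, ncol(ycc$y)),
                   s_norm = matrix(0, n, ncol(ycc$y)),
                   u = matrix(1, n, ncol(ycc$y)), priors = NULL),
              class = "saliency_map")
  }

  weights <- if (variant %in% c("C", "full")) {
    model_weights(config)
  } else {
    c(Y = 1, Cb = 1, Cr = 1)
  }

  la_y <- luminance_adaptation(local_mean(ycc$y, be$window))
  w_luma <- if (st$edge_source == "luma") {
    edge_weight(ycc$y, st$canny_sigma, st$canny_low, st$canny_high,
                st$smooth_window, st$smooth_sigma, st$edge_value)
  } else {
    NULL
  }

  planes <- list(Y = ycc$y, Cb = ycc$cb, Cr = ycc$cr)
  fused_kind <- if (use_saliency) "JND_S" else "JND_B"
  final_kind <- switch(variant, B = "JND_B", S = "JND_S", C = "JND_C",
                       full = "CSJND")
  maps <- list()
  components <- list()
  for (ch in names(planes)) {
    p <- planes[[ch]]
    cm <- contrast_masking(local_contrast(p, be$window, be$contrast_stat),
                           be$a1, be$a2, channel = ch)
    field <- quantize_orientation(gradient_orientation(p),
                                  st$n_bins, st$mag_threshold)
    pm <- pattern_masking(pattern_complexity(field, st$region_window),
                          st$b1, st$b2, st$b3, channel = ch)
    w <- if (is.null(w_luma)) {
      edge_weight(p, st$canny_sigma, st$canny_low, st$canny_high,
                  st$smooth_window, st$smooth_sigma, st$edge_value)
    } else {
      w_luma
    }
    ep <- edge_protection(directional_gradients(p), w, ch, st$lambda)
    vm <- visual_masking(cm, pm, ep)
    vms <- modulate_masking(vm, sal$u)
    la <- if (config$fusion$la_source == "luma" || ch == "Y") {
      threshold_map(map_data(la_y), "LA", ch)
    } else {
      threshold_map(map_data(
        luminance_adaptation(local_mean(p, be$window))), "LA", ch)
    }
    jnd <- namm_fuse(la, vms, config$alpha, kind = fused_kind)
    maps[[ch]] <- apply_cs(jnd, weights, kind = final_kind)
    components[[ch]] <- list(la = la, cm = cm, pm = pm, ep = ep,
                             vm = vm, vms = vms, jnd = jnd)
  }
  structure(list(maps = maps, ycbcr = ycc, variant = variant,
                 weights = weights, saliency = sal,
                 components = components, config = config),
            class = "csjnd_result")
}

#' @export
print.csjnd_result <- function(x, ...) {
  cat(sprintf("<csjnd_result variant=%s %d x %d>\n", x$variant,
              nrow(x$maps$Y), ncol(x$maps$Y)))
  cat(sprintf("  weights: Y=%.3f Cb=%.3f Cr=%.3f\n",
              x$weights[["Y"]], x$weights[["Cb"]], x$weights[["Cr"]]))
  for (ch in names(x$maps)) {
    cat(sprintf("  %s: mean threshold %.3f\n", ch, mean(x$maps[[ch]])))
  }
  invisible(x)
}
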