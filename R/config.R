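#' Model configuration
#'
#' Collects every tunable constant of the model in one nested list. Call
#' with named arguments to override individual entries; unspecified entries
#' keep their defaults. Sections:
#'
#' * `alpha` — NAMM gain-reduction factor for the overlap between luminance
#'   adaptation and masking (default 0.3).
#' * `variant` — which model variant [csjnd_compute()] builds: `"B"`
#'   (base: adaptation + masking), `"S"` (base + saliency modulation),
#'   `"C"` (base + color-sensitivity weighting), `"full"` (both).
#' * `base_effects` — `window` (odd, pixels) for the local mean and
#'   contrast statistics; transducer constants `a1`, `a2`; `contrast_stat`
#'   chooses whether the contrast term is the local standard deviation
#'   (`"std"`, default) or variance (`"var"`).
#' * `structure` — orientation-histogram settings (`n_bins` over
#'   \[0°, 180°), `region_window`, `mag_threshold` in gray levels/pixel),
#'   pattern-masking constants `b1`, `b2`, `b3`, the Canny parameters used
#'   by the edge weight (`canny_sigma`, `canny_low`, `canny_high`), the
#'   edge-weight smoothing (`smooth_window`, `smooth_sigma`, `edge_value`),
#'   per-channel edge-protection gains `lambda` and `edge_source`
#'   (`"per_channel"` or `"luma"`).
#' * `saliency` — SDSP parameters (`omega0`, `sigma_f` for the log-Gabor
#'   band-pass; `sigma_d` pixels for the center bias at the working
#'   resolution; `sigma_c` for the warm-color prior), `working_size`
#'   (longer image side, pixels, at which saliency is computed) and
#'   `enabled` (off forces the modulation factor to 1 everywhere).
#' * `fusion` — `d_ratio`, the critical viewing-distance ratio
#'   D_Y : D_Cb : D_Cr behind the color-sensitivity weights; `cs_from`
#'   selects whether weights start from the published rounded sensitivity
#'   parameters (`"printed"`, default: (0.695, 0.130, 0.175)) or are
#'   recomputed unrounded from `d_ratio` (`"unrounded"`); `la_source`
#'   computes luminance adaptation once on Y (`"luma"`, default) or per
#'   channel.
#' * `noise` — `psnr_domain`: pooling used by [img_psnr()] (`"ycbcr_pooled"`
#'   default, `"y_only"`, `"rgb_pooled"`).
#'
#' @param alpha NAMM gain reduction factor in `[0, 1)`.
#' @param variant Model variant, one of `"full"`, `"B"`, `"S"`, `"C"`.
#' @param base_effects,structure,saliency,fusion,noise Named lists merged
#'   over the section defaults.
#' @return A list of class `csjnd_config`.
#' @examples
#' cfg <- csjnd_config(variant = "B", base_effects = list(window = 3))
#' cfg$base_effects$window
#' @export
csjnd_config <- function(alpha = 0.3,
                         variant = c("full", "B", "S", "C"),
                         base_effects = list(),
                         structure = list(),
                         saliency = list(),
                         fusion = list(),
                         noise = list()) {
  variant <- match.arg(variant)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop("alpha must be a single value in [0, 1)", call. = FALSE)
  }
  defaults <- list(
    base_effects = list(window = 5L, a1 = 16, a2 = 26,
                        contrast_stat = "std"),
    structure = list(n_bins = 12L, region_window = 5L, mag_threshold = 2,
                     b1 = 0.8, b2 = 2.7, b3 = 0.1,
                     canny_sigma = 1.4, canny_low = 0.1, canny_high = 0.3,
                     smooth_window = 7L, smooth_sigma = 0.8,
                     edge_value = 0.1,
                     lambda = c(Y = 0.117, Cb = 0.65, Cr = 0.45),
                     edge_source = "per_channel"),
    saliency = list(enabled = TRUE, omega0 = 0.002, sigma_f = 6.2,
                    sigma_d = 114, sigma_c = 0.25, working_size = 256L),
    fusion = list(d_ratio = c(Y = 1, Cb = 0.432, Cr = 0.501),
                  cs_from = "printed", la_source = "luma"),
    noise = list(psnr_domain = "ycbcr_pooled")
  )
  cfg <- list(
    alpha = alpha,
    variant = variant,
    base_effects = utils::modifyList(defaults$base_effects, base_effects),
    structure = utils::modifyList(defaults$structure, structure),
    saliency = utils::modifyList(defaults$saliency, saliency),
    fusion = utils::modifyList(defaults$fusion, fusion),
    noise = utils::modifyList(defaults$noise, noise)
  )
  cfg$fusion$cs_from <- match.arg(cfg$fusion$cs_from,
                                  c("printed", "unrounded"))
  cfg$fusion$la_source <- match.arg(cfg$fusion$la_source,
                                    c("luma", "per_channel"))
  cfg$structure$edge_source <- match.arg(cfg$structure$edge_source,
                                         c("per_channel", "luma"))
  cfg$noise$psnr_domain <- match.arg(cfg$noise$psnr_domain,
                                     c("ycbcr_pooled", "y_only",
                                       "rgb_pooled"))
  structure(cfg, class = "csjnd_config")
}

# Published rounded perceptual-sensitivity parameters for Y/Cb/Cr, from the
# contrast-sensitivity study behind the color-sensitivity weights. Used when
# fusion$cs_from == "printed".
printed_sensitivity <- c(Y = 0.695, Cb = 0.130, Cr = 0.175)
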