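#' Synthetic test stimuli with known analytic properties
#'
#' `fixture_spec()` describes a deterministic synthetic image;
#' `generate_fixture()` renders it as an [rgb_image()]. Every kind has a
#' known ground truth that exercises one stage of the model:
#'
#' * `flat` — constant gray `level`: zero contrast and zero pattern
#'   complexity, so the JND map reduces to weighted luminance adaptation.
#' * `ramp` — horizontal luminance ramp 0..255: sweeps the adaptation
#'   curve.
#' * `grating` — sinusoid of known `angle` (degrees), `period` (pixels)
#'   and `amplitude` around mid-gray: one dominant orientation bin.
#' * `checkerboard` — alternating blocks of `block` pixels at two levels:
#'   two orientations, strong regular structure.
#' * `step_edge` — two half-planes (`orientation` `"horizontal"` or
#'   `"vertical"`): a single known edge line for the edge detector.
#' * `random_texture` — seeded uniform intensity noise of `amplitude`
#'   around `level`, mild independent color noise: dense orientation
#'   content, high contrast.
#' * `two_region` — left half flat gray, right half seeded warm-colored
#'   texture: saliency and channel-allocation experiments.
#'
#' Generation is a pure function of the spec (seed included); equal specs
#' render bit-identical images.
#'
#' @param kind Fixture kind (see above).
#' @param size Integer `(height, width)`, each at least 16.
#' @param ... Kind parameters: `level`, `amplitude`, `period`, `angle`,
#'   `block`, `orientation`, `position`, `seed`.
#' @param spec A `fixture_spec`.
#' @return `fixture_spec()`: a spec object. `generate_fixture()`: an
#'   [rgb_image()].
#' @examples
#' img <- generate_fixture(fixture_spec("flat", c(32, 32), level = 200))
#' img$r[1, 1]
#' @export
fixture_spec <- function(kind = c("flat", "ramp", "grating", "checkerboard",
                                  "step_edge", "random_texture",
                                  "two_region"),
                         size = c(128L, 128L), ...) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 16L)) {
    stop("size must be (height, width), each at least 16", call. = FALSE)
  }
  params <- list(...)
  defaults <- switch(kind,
    flat = list(level = 128),
    ramp = list(),
    grating = list(angle = 0, period = 8, amplitude = 60, level = 128),
    checkerboard = list(block = 8L, low = 64, high = 192),
    step_edge = list(orientation = "horizontal", position = NULL,
                     low = 0, high = 255),
    random_texture = list(level = 128, amplitude = 60, seed = 7L,
                          color_amplitude = 20),
    two_region = list(level = 128, amplitude = 60, seed = 13L)
  )
  structure(list(kind = kind, size = size,
                 params = utils::modifyList(defaults, params)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  h <- spec$size[1]
  w <- spec$size[2]
  p <- spec$params
  gray <- function(m) rgb_image(m, m, m)
  img <- switch(spec$kind,
    flat = gray(matrix(p$level, h, w)),
    ramp = gray(matrix(rep(seq(0, 255, length.out = w), each = h), h, w)),
    grating = {
      th <- p$angle * pi / 180
      ri <- matrix(seq_len(h), h, w)
      ci <- matrix(seq_len(w), h, w, byrow = TRUE)
      u <- ci * cos(th) + ri * sin(th)
      gray(clip255(p$level + p$amplitude * sin(2 * pi * u / p$period)))
    },
    checkerboard = {
      ri <- matrix(seq_len(h) - 1L, h, w) %/% p$block
      ci <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE) %/% p$block
      gray(ifelse((ri + ci) %% 2 == 0, p$low, p$high))
    },
    step_edge = {
      pos <- if (is.null(p$position)) {
        if (p$orientation == "horizontal") h %/% 2L else w %/% 2L
      } else {
        p$position
      }
      m <- if (p$orientation == "horizontal") {
        matrix(ifelse(seq_len(h) <= pos, p$low, p$high), h, w)
      } else {
        matrix(ifelse(seq_len(w) <= pos, p$low, p$high), h, w,
               byrow = TRUE)
      }
      gray(m)
    },
    random_texture = with_seed(p$seed, {
      base <- matrix(p$level + stats::runif(h * w, -1, 1) * p$amplitude,
                     h, w)
      ca <- p$color_amplitude
      rgb_image(clip255(base + matrix(stats::runif(h * w, -1, 1) * ca,
                                      h, w)),
                clip255(base + matrix(stats::runif(h * w, -1, 1) * ca,
                                      h, w)),
                clip255(base + matrix(stats::runif(h * w, -1, 1) * ca,
                                      h, w)))
    }),
    two_region = with_seed(p$seed, {
      half <- w %/% 2L
      texl <- function(lo, hi) {
        m <- matrix(p$level, h, w)
        m[, (half + 1L):w] <- stats::runif(h * (w - half), lo, hi)
        m
      }
      # warm (reddish-yellow) texture on the right half
      rgb_image(clip255(texl(120, 255)), clip255(texl(60, 200)),
                clip255(texl(0, 120)))
    })
  )
  img$source <- sprintf("fixture:%s(%dx%d)", spec$kind, h, w)
  img
}

#' Canonical regression fixture suite
#'
#' Twelve deterministic stimuli at 128 x 128 and 192 x 128, covering every
#' fixture kind with fixed seeds. Each regenerates bit-identically across
#' runs; unit and acceptance tests consume only these.
#'
#' @return A named list of 12 `fixture_spec` objects.
#' @export
fixture_suite <- function() {
  list(
    flat_mid = fixture_spec("flat", c(128L, 128L), level = 128),
    flat_dark = fixture_spec("flat", c(128L, 192L), level = 60),
    ramp = fixture_spec("ramp", c(128L, 128L)),
    grating_h = fixture_spec("grating", c(128L, 128L), angle = 0,
                             period = 8),
    grating_diag = fixture_spec("grating", c(128L, 192L), angle = 45,
                                period = 12),
    checker_8 = fixture_spec("checkerboard", c(128L, 128L), block = 8L),
    checker_16 = fixture_spec("checkerboard", c(128L, 192L), block = 16L),
    edge_v = fixture_spec("step_edge", c(128L, 128L),
                          orientation = "vertical", low = 40, high = 215),
    edge_h = fixture_spec("step_edge", c(128L, 192L),
                          orientation = "horizontal", low = 40,
                          high = 215),
    texture_7 = fixture_spec("random_texture", c(128L, 128L), seed = 7L),
    texture_11 = fixture_spec("random_texture", c(128L, 192L),
                              seed = 11L),
    two_region = fixture_spec("two_region", c(128L, 128L), seed = 13L)
  )
}
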