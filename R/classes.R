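#' Image and map containers
#'
#' The package works on plain numeric matrices indexed `[row, col]`
#' (0-based pixel coordinates in the model's conventions map to row/col - 1).
#' Three light containers group planes and carry labels:
#'
#' * `rgb_image()` — three aligned R/G/B planes on the 8-bit scale `[0, 255]`.
#' * `ycbcr_image()` — three aligned Y/Cb/Cr planes on the 8-bit scale.
#' * `threshold_map()` — one per-pixel visibility-threshold plane (gray
#'   levels, non-negative), labelled with the effect it stores (`"LA"`,
#'   `"CM"`, `"PM"`, `"EP"`, `"VM"`, `"VMS"`, `"JND_B"`, `"JND_S"`,
#'   `"JND_C"`, `"CSJND"`) and the channel it belongs to.
#'
#' All constructors validate finiteness and shape agreement; image planes
#' must be at least 5 x 5 (minimum window support).
#'
#' @param r,g,b,y,cb,cr Numeric matrices of identical dimensions.
#' @param source Optional path or description of the image origin.
#' @param data Numeric matrix of non-negative thresholds.
#' @param kind Label of the effect stored in a threshold map.
#' @param channel Channel label (`"Y"`, `"Cb"` or `"Cr"`).
#' @return An object of class `rgb_image`, `ycbcr_image` or `threshold_map`.
#' @examples
#' img <- rgb_image(matrix(128, 8, 8), matrix(128, 8, 8), matrix(128, 8, 8))
#' dim(img$r)
#' @name containers
NULL

check_plane <- function(x, what, lo = NULL, hi = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 5L || ncol(x) < 5L) {
    stop(what, " must be at least 5 x 5 pixels", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  if (!is.null(lo) && any(x < lo | x > hi)) {
    stop(what, " has values outside [", lo, ", ", hi, "]", call. = FALSE)
  }
  invisible(x)
}

check_same_shape <- function(...) {
  mats <- list(...)
  d <- dim(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(dim(m), d)) {
      stop("planes must share identical dimensions", call. = FALSE)
    }
  }
  invisible(d)
}

#' @rdname containers
#' @export
rgb_image <- function(r, g, b, source = NULL) {
  check_plane(r, "R plane", 0, 255)
  check_plane(g, "G plane", 0, 255)
  check_plane(b, "B plane", 0, 255)
  check_same_shape(r, g, b)
  structure(list(r = r, g = g, b = b, source = source), class = "rgb_image")
}

#' @rdname containers
#' @export
ycbcr_image <- function(y, cb, cr, source = NULL) {
  check_plane(y, "Y plane", 0, 255)
  check_plane(cb, "Cb plane")
  check_plane(cr, "Cr plane")
  check_same_shape(y, cb, cr)
  structure(list(y = y, cb = cb, cr = cr, source = source),
            class = "ycbcr_image")
}

map_kinds <- c("LA", "CM", "PM", "EP", "VM", "VMS",
               "JND_B", "JND_S", "JND_C", "CSJND")

#' @rdname containers
#' @export
threshold_map <- function(data, kind, channel = NA_character_) {
  kind <- match.arg(kind, map_kinds)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("threshold data must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("threshold map contains non-finite values", call. = FALSE)
  }
  if (any(data < 0)) {
    stop("threshold map contains negative values", call. = FALSE)
  }
  structure(data, kind = kind, channel = channel,
            class = c("threshold_map", class(data)))
}

map_data <- function(x) {
  if (inherits(x, "threshold_map")) {
    attributes(x)[c("kind", "channel", "class")] <- NULL
  }
  x
}

map_channel <- function(x) attr(x, "channel")

#' @export
print.threshold_map <- function(x, ...) {
  cat(sprintf("<threshold_map %s[%s] %d x %d, range [%.4g, %.4g]>\n",
              attr(x, "kind"), attr(x, "channel"), nrow(x), ncol(x),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' @export
print.ycbcr_image <- function(x, ...) {
  cat(sprintf("<ycbcr_image %d x %d>\n", nrow(x$y), ncol(x$y)))
  invisible(x)
}
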