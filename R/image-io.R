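#' Read an 8-bit color image
#'
#' Decodes a PNG or TIFF file into an [rgb_image()] with planes on the
#' `[0, 255]` scale. Grayscale inputs are replicated to three identical
#' planes; an alpha channel, if present, is dropped.
#'
#' @param path Path to an 8-bit PNG or TIFF file.
#' @return An [rgb_image()].
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    a <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop("failed to decode PNG '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    info <- attr(a, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8) {
      stop("unsupported bit depth (", info$bit.depth, ") in ", path,
           ": only 8-bit images are supported", call. = FALSE)
    }
    a
  } else if (ext %in% c("tif", "tiff")) {
    a <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop("failed to decode TIFF '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    bps <- attr(a, "bits.per.sample")
    if (!is.null(bps) && bps > 8) {
      stop("unsupported bit depth (", bps, ") in ", path,
           ": only 8-bit images are supported", call. = FALSE)
    }
    a
  } else {
    stop("unsupported image format '", ext, "' for ", path,
         ": supported formats are PNG and TIFF", call. = FALSE)
  }
  if (is.matrix(arr)) {
    p <- matrix(as.numeric(arr) * 255, nrow(arr), ncol(arr))
    return(rgb_image(p, p, p, source = path))
  }
  nc <- dim(arr)[3]
  if (nc == 2L) {          # gray + alpha
    p <- arr[, , 1L] * 255
    return(rgb_image(p, p, p, source = path))
  }
  rgb_image(arr[, , 1L] * 255, arr[, , 2L] * 255, arr[, , 3L] * 255,
            source = path)
}

#' Write an 8-bit PNG image
#'
#' Quantizes planes to the 8-bit range (round half away from zero, clip to
#' `[0, 255]`) and writes a color PNG.
#'
#' @param img An [rgb_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  arr <- array(0, c(nrow(img$r), ncol(img$r), 3L))
  arr[, , 1L] <- quantize_u8(img$r) / 255
  arr[, , 2L] <- quantize_u8(img$g) / 255
  arr[, , 3L] <- quantize_u8(img$b) / 255
  png::writePNG(arr, path)
  invisible(path)
}

# Full-range BT.601 (JPEG-convention) RGB <-> YCbCr matrices.
.ycc_fwd <- matrix(c(0.299, 0.587, 0.114,
                     -0.168736, -0.331264, 0.5,
                     0.5, -0.418688, -0.081312),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("y", "cb", "cr"), c("r", "g", "b")))
.ycc_off <- c(0, 128, 128)
.ycc_inv <- solve(.ycc_fwd)

#' RGB / YCbCr conversion
#'
#' Full-range BT.601 (JPEG convention) color transform:
#' `Y = 0.299 R + 0.587 G + 0.114 B`,
#' `Cb = 128 - 0.168736 R - 0.331264 G + 0.5 B`,
#' `Cr = 128 + 0.5 R - 0.418688 G - 0.081312 B`, clipped to `[0, 255]`.
#' `ycbcr_to_rgb()` applies the exact matrix inverse (then clips), so a
#' round trip that does not clip deviates by well under one gray level.
#'
#' @param rgb An [rgb_image()].
#' @param img A [ycbcr_image()].
#' @return A [ycbcr_image()] or [rgb_image()].
#' @examples
#' g <- matrix(128, 8, 8)
#' ycc <- rgb_to_ycbcr(rgb_image(g, g, g))
#' range(ycc$cb)   # neutral chroma: 128
#' @export
rgb_to_ycbcr <- function(rgb) {
  stopifnot(inherits(rgb, "rgb_image"))
  lin <- function(i) {
    clip255(.ycc_off[i] + .ycc_fwd[i, 1] * rgb$r + .ycc_fwd[i, 2] * rgb$g +
              .ycc_fwd[i, 3] * rgb$b)
  }
  ycbcr_image(lin(1), lin(2), lin(3), source = rgb$source)
}

#' @rdname rgb_to_ycbcr
#' @export
ycbcr_to_rgb <- function(img) {
  stopifnot(inherits(img, "ycbcr_image"))
  y <- img$y
  cb <- img$cb - 128
  cr <- img$cr - 128
  lin <- function(i) {
    clip255(.ycc_inv[i, 1] * y + .ycc_inv[i, 2] * cb + .ycc_inv[i, 3] * cr)
  }
  rgb_image(lin(1), lin(2), lin(3), source = img$source)
}

#' Read and write floating-point maps as TIFF
#'
#' Threshold and saliency maps are stored as single-plane 32-bit IEEE
#' float TIFF (little-endian, one strip, no compression), so values outside
#' `[0, 1]` survive unchanged; the round trip is exact at float32
#' precision. Files are readable by any TIFF reader that supports float
#' sample format.
#'
#' @param map Numeric matrix (finite values), e.g. a [threshold_map()].
#' @param path Output / input path.
#' @return `write_map()`: `path` invisibly. `read_map()`: a numeric matrix.
#' @export
write_map <- function(map, path) {
  m <- map_data(map)
  stopifnot(is.matrix(m), is.numeric(m))
  if (!all(is.finite(m))) {
    stop("map contains non-finite values", call. = FALSE)
  }
  h <- nrow(m)
  w <- ncol(m)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write map to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  nbytes <- 4L * h * w
  ifd_offset <- 8L + nbytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  tags <- list(
    # tag, type (3 = SHORT, 4 = LONG), value
    c(256L, 4L, w),        # ImageWidth
    c(257L, 4L, h),        # ImageLength
    c(258L, 3L, 32L),      # BitsPerSample
    c(259L, 3L, 1L),       # Compression: none
    c(262L, 3L, 1L),       # Photometric: BlackIsZero
    c(273L, 4L, 8L),       # StripOffsets
    c(277L, 3L, 1L),       # SamplesPerPixel
    c(278L, 4L, h),        # RowsPerStrip
    c(279L, 4L, nbytes),   # StripByteCounts
    c(339L, 3L, 3L)        # SampleFormat: IEEE float
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1L], con, size = 2, endian = "little")
    writeBin(tg[2L], con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (tg[2L] == 3L) {
      writeBin(tg[3L], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[3L], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read map: file does not exist: ", path, call. = FALSE)
  }
  tiff::readTIFF(path)
}
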