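# Shared test helpers: independent brute-force oracles and small builders.

# Per-pixel orientation-histogram recount, written independently of the
# box-sum pipeline: replicate-pad the quantized map, gather every region
# explicitly, count distinct non-NA bins.
pc_bruteforce <- function(field, region_window) {
  q <- field$quantized
  n <- nrow(q)
  m <- ncol(q)
  pad <- (region_window - 1L) %/% 2L
  ri <- c(rep(1L, pad), seq_len(n), rep(n, pad))
  ci <- c(rep(1L, pad), seq_len(m), rep(m, pad))
  qp <- q[ri, ci]
  out <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      reg <- qp[i:(i + 2L * pad), j:(j + 2L * pad)]
      out[i, j] <- length(unique(reg[!is.na(reg)]))
    }
  }
  out
}

# Orientation field with hand-picked angles and uniform strong magnitude.
field_from_phi <- function(phi, magnitude = 10) {
  structure(list(phi = phi,
                 magnitude = matrix(magnitude, nrow(phi), ncol(phi)),
                 quantized = NULL, n_bins = NULL),
            class = "orientation_field")
}

# Strip threshold_map labels down to a plain numeric matrix.
mval <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

const_maps <- function(dims, y = 1, cb = 1, cr = 1) {
  list(Y = threshold_map(matrix(y, dims[1], dims[2]), "CSJND", "Y"),
       Cb = threshold_map(matrix(cb, dims[1], dims[2]), "CSJND", "Cb"),
       Cr = threshold_map(matrix(cr, dims[1], dims[2]), "CSJND", "Cr"))
}

gray_image <- function(level, h = 16, w = 16) {
  m <- matrix(level, h, w)
  ycbcr_image(m, matrix(128, h, w), matrix(128, h, w))
}
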