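# Internal 2-D filtering primitives. All spatial operators in the model use
# edge-replicate padding; kernels are small (<= 9x9), so an explicit
# shift-and-add correlation is exact (no FFT roundoff) and fast enough.

pad_replicate <- function(x, pr, pc = pr) {
  n <- nrow(x)
  m <- ncol(x)
  ri <- c(rep(1L, pr), seq_len(n), rep(n, pr))
  ci <- c(rep(1L, pc), seq_len(m), rep(m, pc))
  x[ri, ci, drop = FALSE]
}

# Cross-correlation of `x` with kernel `k` (odd dimensions), edge-replicate
# borders, output the same size as `x`.
conv2_replicate <- function(x, k) {
  kr <- nrow(k)
  kc <- ncol(k)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  pr <- (kr - 1L) %/% 2L
  pc <- (kc - 1L) %/% 2L
  xp <- pad_replicate(x, pr, pc)
  out <- matrix(0, nrow(x), ncol(x))
  rows <- seq_len(nrow(x))
  cols <- seq_len(ncol(x))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- k[i, j]
      if (w != 0) {
        out <- out + w * xp[rows + (i - 1L), cols + (j - 1L)]
      }
    }
  }
  out
}

# Unweighted box sum over an odd window.
box_sum <- function(x, window) {
  conv2_replicate(x, matrix(1, window, window))
}

gaussian_kernel <- function(size, sigma) {
  stopifnot(size %% 2L == 1L, sigma > 0)
  h <- (size - 1L) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

gaussian_smooth <- function(x, size, sigma) {
  conv2_replicate(x, gaussian_kernel(size, sigma))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Round half away from zero (image quantization convention), then clip to
# the 8-bit range.
quantize_u8 <- function(x) {
  clip255(sign(x) * floor(abs(x) + 0.5))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
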