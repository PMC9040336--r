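#' Ring of residues modulo 2^n
#'
#' All shares in the package live in `Z_{2^n}` for a power-of-two-friendly bit
#' width `n` (Boolean shares are the `n = 1` case). Elements are stored as
#' doubles, which represent every integer in `[0, 2^52)` exactly; modular
#' products for `n > 26` are computed by 16-bit limb splitting so no
#' intermediate exceeds 2^53.
#'
#' @param n Bit width (1 to 48).
#' @return An object of class `share_ring` with fields `n` and `modulus`.
#' @examples
#' r <- share_ring(3)
#' r$modulus # 8
#' @export
share_ring <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n <= 48, n == floor(n))
  structure(list(n = n, modulus = 2^n), class = "share_ring")
}

#' @export
print.share_ring <- function(x, ...) {
  cat(sprintf("<share_ring Z_{2^%d}>\n", x$n))
  invisible(x)
}

# x %% m for ring elements (doubles); keeps results in [0, m)
rmod <- function(x, m) x %% m

# (a * b) %% m exactly, for 0 <= a, b < m <= 2^48
mulmod <- function(a, b, m) {
  if (m <= 2^26) return((a * b) %% m)
  bhi <- b %/% 65536
  blo <- b %% 65536
  (((a * bhi) %% m) * 65536 + a * blo) %% m
}

# uniform draw from [0, m) using R's PRNG
rand_ring <- function(len, m) {
  if (m <= .Machine$integer.max) {
    sample.int(m, len, replace = TRUE) - 1
  } else {
    floor(stats::runif(len) * m)
  }
}

# bits of x (LSB first) as a len x n 0/1 matrix
int_bits <- function(x, n) {
  out <- matrix(0, length(x), n)
  for (k in seq_len(n)) {
    out[, k] <- x %% 2
    x <- x %/% 2
  }
  out
}
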