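#' Secure subprotocols on shared values
#'
#' Dealer-assisted constructions of the comparison-style subprotocols used by
#' the search protocols. All of them follow the same pattern: the trusted
#' initializer hands out a uniform mask with correlated Boolean bit shares,
#' the nodes open a masked (hence uniform) value, and the result is assembled
#' with Boolean gates. Round and byte counts depend only on the ring width and
#' operand length, never on the secrets, so the communication pattern is
#' input-independent.
#'
#' @name subprotocols
NULL

# Boolean bit shares of x (LSB first) via mask-and-open + borrow-ripple:
# open c = x + r, then compute the bits of c - r with a subtraction circuit
# on public c-bits and shared r-bits. One AND round per bit position.
bit_decompose <- function(env, x) {
  n <- sh_width(x)
  len <- length(x)
  mp <- ti_masked_pair(env, len, n)
  c_pub <- mpc_reconst(env, mpc_add(x, mp$r), label = "bitdec")
  cbits <- int_bits(c_pub, n)
  out <- vector("list", n)
  borrow <- public_bool(rep(0, len))
  for (k in seq_len(n)) {
    rk <- mp$bits[[k]]
    ck <- cbits[, k]
    out[[k]] <- bool_xor_public(bool_xor(rk, borrow), ck)
    if (k < n) {
      # borrow-out of (c_k - r_k - borrow): r AND b if c=1, r OR b if c=0
      t <- bool_and(env, rk, borrow)
      borrow <- bool_xor(t, bool_and_public(bool_xor(rk, borrow), 1 - ck))
    }
  }
  out
}

#' Equality test on shares
#'
#' Opens the uniformly masked difference `x - y + r`, then checks the opened
#' value against the Boolean-shared bits of `r` with an XNOR layer and a
#' log-depth AND tree.
#'
#' @param env An [mpc_env()].
#' @param x,y `mpc_shares` of equal width (scalars recycle).
#' @return `mpc_bool` reconstructing to 1 where `x == y`.
#' @export
mpc_equality <- function(env, x, y) {
  stopifnot(sh_width(x) == sh_width(y))
  p <- recycle2(x, y); x <- p[[1]]; y <- p[[2]]
  n <- sh_width(x)
  len <- length(x)
  mp <- ti_masked_pair(env, len, n)
  c_pub <- mpc_reconst(env, mpc_add(mpc_sub(x, y), mp$r), label = "equality")
  cbits <- int_bits(c_pub, n)
  # x == y  iff  c == r: XNOR each bit, AND-reduce
  xn <- lapply(seq_len(n), function(k) bool_not(bool_xor_public(mp$bits[[k]], cbits[, k])))
  bool_and_tree_batched(env, xn)
}

#' Comparison `x < y` on shares
#'
#' Bit-decomposes both operands (batched), locates the most significant
#' differing bit with a prefix-OR chain, and outputs that bit of `y`.
#' Operands are compared as unsigned integers over the full ring.
#'
#' @inheritParams mpc_equality
#' @return `mpc_bool` reconstructing to 1 where `x < y`.
#' @export
mpc_comp <- function(env, x, y) {
  stopifnot(sh_width(x) == sh_width(y))
  p <- recycle2(x, y); x <- p[[1]]; y <- p[[2]]
  n <- sh_width(x)
  len <- length(x)
  both <- bit_decompose(env, sh_c(x, y))
  xb <- lapply(both, function(b) bool_slice(b, seq_len(len)))
  yb <- lapply(both, function(b) bool_slice(b, len + seq_len(len)))
  d <- lapply(seq_len(n), function(k) bool_xor(xb[[k]], yb[[k]]))
  # prefix OR from the MSB down; w_k = first (most significant) set bit of d
  pref <- vector("list", n)
  pref[[n]] <- d[[n]]
  for (k in rev(seq_len(n - 1))) {
    pref[[k]] <- bool_or(env, pref[[k + 1]], d[[k]])
  }
  w <- vector("list", n)
  w[[n]] <- pref[[n]]
  for (k in seq_len(n - 1)) w[[k]] <- bool_xor(pref[[k]], pref[[k + 1]])
  # x < y iff y's bit is set at the first differing position (w is one-hot)
  prod <- bool_and(env, do.call(bool_c, w), do.call(bool_c, yb))
  out <- public_bool(rep(0, len))
  for (k in seq_len(n)) out <- bool_xor(out, bool_slice(prod, (k - 1) * len + seq_len(len)))
  out
}

#' Boolean-to-arithmetic share conversion
#'
#' Uses a dealer bit `b` shared in both domains: the nodes open `z = x XOR b`
#' (uniform) and compute `x = z + b - 2zb` locally on the arithmetic shares.
#'
#' @param env An [mpc_env()].
#' @param x `mpc_bool`.
#' @param n Target ring width.
#' @return `mpc_shares` reconstructing to 0 or 1.
#' @export
mpc_b2a <- function(env, x, n = env$n) {
  len <- length(x$b0)
  bp <- ti_bit_pair(env, len, n)
  z <- bool_reconst(env, bool_xor(x, bp$bool), label = "b2a")
  mpc_add_const(mpc_scalar_mul(1 - 2 * z, bp$arith), z)
}

#' Lift shares into a larger ring
#'
#' Opens the value masked modulo the small ring, recovers the wrap bit with a
#' borrow circuit against the dealer mask's bits, and corrects in the large
#' ring: `x = c - r + 2^m [c < r]`.
#'
#' @param env An [mpc_env()].
#' @param x `mpc_shares` over `Z_{2^m}`.
#' @param n_to Target width, `n_to > m`.
#' @return `mpc_shares` over `Z_{2^n_to}` with the same integer value.
#' @export
mpc_cast_up <- function(env, x, n_to) {
  m <- sh_width(x)
  if (n_to <= m) stop("cast_up target width must exceed the source width")
  len <- length(x)
  cp <- ti_cast_pair(env, len, m, n_to)
  c_pub <- mpc_reconst(env, mpc_add(x, cp$small), label = "castup")
  cbits <- int_bits(c_pub, m)
  # borrow chain of c - r: final borrow = [c < r]
  borrow <- public_bool(rep(0, len))
  for (k in seq_len(m)) {
    rk <- cp$bits[[k]]
    ck <- cbits[, k]
    t <- bool_and(env, rk, borrow)
    borrow <- bool_xor(t, bool_and_public(bool_xor(rk, borrow), 1 - ck))
  }
  wrap <- mpc_b2a(env, borrow, n = n_to)
  mpc_add_const(mpc_add(mpc_scalar_mul(2^m, wrap), mpc_neg(cp$big)), c_pub)
}

#' Oblivious selection
#'
#' `Choose(x, y, e) = y + e (x - y)`: returns `x` where the shared bit `e`
#' is 1 and `y` where it is 0. `e` must be an arithmetic share of 0/1 (apply
#' [mpc_b2a()] to a Boolean flag first). One multiplication round.
#'
#' @param env An [mpc_env()].
#' @param x,y `mpc_shares` (scalars recycle).
#' @param e Arithmetic share of a bit.
#' @export
mpc_choose <- function(env, x, y, e) {
  p <- recycle2(x, y); x <- p[[1]]; y <- p[[2]]
  mpc_add(y, mpc_mult(env, e, mpc_sub(x, y)))
}
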