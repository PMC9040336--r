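#' Simulated two-node secure-computation environment
#'
#' Creates the in-process harness emulating the four protocol roles: query
#' holder (A), database holder / trusted initializer (B), and computing nodes
#' P0 and P1. The harness runs synchronously: a "round" is one P0-P1 message
#' exchange, and independent subprotocol instances issued together are batched
#' into the same round. Every message is attributed to the current phase
#' (`offline`, `db_prep` or `search`) in the [transcript][mpc_transcript].
#'
#' Byte accounting: one ring element costs `n/8` bytes, one Boolean share 1
#' byte. Search-phase bytes count the P0 to P1 payload (the protocols are
#' symmetric, so P1 to P0 is identical); offline and DB-preparation bytes
#' count the payload B sends to one node. Messages addressed to the query
#' holder (final results) are not part of the node transcript.
#'
#' @param n Default ring bit width for arithmetic shares.
#' @param seed Optional integer seed for the harness PRNG; if supplied, the
#'   whole simulation (masks, shares, Beaver triples) is reproducible.
#' @return An environment of class `mpc_env`.
#' @examples
#' env <- mpc_env(n = 3, seed = 1)
#' sh <- mpc_share(env, 2)
#' mpc_reconst(env, sh) # 2
#' @export
mpc_env <- function(n = 16, seed = NULL) {
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$phase <- "offline"
  env$tr <- list(
    offline = c(rounds = 0, bytes = 0),
    db_prep = c(rounds = 0, bytes = 0),
    search  = c(rounds = 0, bytes = 0)
  )
  env$pool_arith <- NULL # vector Beaver triple pool (a0,a1,b0,b1,c0,c1, width)
  env$pool_bool <- NULL
  env$capture_opens <- FALSE
  env$opens <- list()
  env$seed <- seed
  if (!is.null(seed)) set.seed(seed)
  class(env) <- c("mpc_env", "environment")
  env
}

#' @export
print.mpc_env <- function(x, ...) {
  cat(sprintf("<mpc_env Z_{2^%d}, phase=%s>\n", x$n, x$phase))
  tr <- mpc_transcript(x)
  for (ph in names(tr)) {
    cat(sprintf("  %-8s rounds=%d bytes=%g\n", ph, tr[[ph]]["rounds"], tr[[ph]]["bytes"]))
  }
  invisible(x)
}

#' Set the protocol phase messages are attributed to
#'
#' @param env An [mpc_env()].
#' @param phase One of `"offline"`, `"db_prep"`, `"search"`.
#' @export
mpc_phase <- function(env, phase = c("offline", "db_prep", "search")) {
  env$phase <- match.arg(phase)
  invisible(env)
}

#' Per-phase communication transcript
#'
#' @param env An [mpc_env()].
#' @return Named list with `rounds` and `bytes` per phase.
#' @export
mpc_transcript <- function(env) env$tr

#' Reset the transcript counters (all phases)
#' @param env An [mpc_env()].
#' @export
mpc_transcript_reset <- function(env) {
  env$tr <- list(
    offline = c(rounds = 0, bytes = 0),
    db_prep = c(rounds = 0, bytes = 0),
    search  = c(rounds = 0, bytes = 0)
  )
  invisible(env)
}

record_comm <- function(env, rounds = 0, bytes = 0, phase = env$phase) {
  env$tr[[phase]] <- env$tr[[phase]] + c(rounds = rounds, bytes = bytes)
  invisible(NULL)
}

record_open <- function(env, what, values) {
  if (isTRUE(env$capture_opens)) {
    env$opens[[length(env$opens) + 1L]] <- list(what = what, values = values)
  }
  invisible(NULL)
}

## ---- share objects ---------------------------------------------------------

new_shares <- function(s0, s1, n) {
  structure(list(s0 = s0, s1 = s1), n = n, class = "mpc_shares")
}

new_bool <- function(b0, b1) {
  structure(list(b0 = b0, b1 = b1), class = "mpc_bool")
}

#' @export
print.mpc_shares <- function(x, ...) {
  cat(sprintf("<mpc_shares len=%d over Z_{2^%d}>\n", length(x$s0), attr(x, "n")))
  invisible(x)
}

#' @export
print.mpc_bool <- function(x, ...) {
  cat(sprintf("<mpc_bool len=%d>\n", length(x$b0)))
  invisible(x)
}

#' @export
length.mpc_shares <- function(x) length(x$s0)

#' @export
length.mpc_bool <- function(x) length(x$b0)

sh_width <- function(x) attr(x, "n")

# concatenate shared vectors (same width)
sh_c <- function(...) {
  xs <- list(...)
  n <- sh_width(xs[[1]])
  stopifnot(all(vapply(xs, sh_width, 0) == n))
  new_shares(
    unlist(lapply(xs, `[[`, "s0"), use.names = FALSE),
    unlist(lapply(xs, `[[`, "s1"), use.names = FALSE),
    n
  )
}

bool_c <- function(...) {
  xs <- list(...)
  new_bool(
    unlist(lapply(xs, `[[`, "b0"), use.names = FALSE),
    unlist(lapply(xs, `[[`, "b1"), use.names = FALSE)
  )
}

# subset by 1-based index vector
sh_slice <- function(x, i) new_shares(x$s0[i], x$s1[i], sh_width(x))
bool_slice <- function(x, i) new_bool(x$b0[i], x$b1[i])

# element at 0-based position (table lookup at a public index)
sh_at <- function(x, i0) sh_slice(x, i0 + 1)

sh_rep <- function(x, times) new_shares(rep(x$s0, times), rep(x$s1, times), sh_width(x))
bool_rep <- function(x, times) new_bool(rep(x$b0, times), rep(x$b1, times))

#' Public constant as a trivially-shared value
#'
#' Both halves are known to the nodes (P0 holds the value, P1 holds zero); no
#' communication is involved.
#'
#' @param x Values in `[0, 2^n)`.
#' @param n Ring width.
#' @export
public_share <- function(x, n) {
  m <- 2^n
  stopifnot(all(x >= 0 & x < m))
  new_shares(rmod(x, m), rep(0, length(x)), n)
}

public_bool <- function(b) new_bool(b %% 2, rep(0, length(b)))

## ---- Share / Reconst -------------------------------------------------------

#' Split secrets into additive shares over Z_{2^n}
#'
#' `Share(x)` draws a fresh uniform `r` and emits the pair `(r, x - r mod 2^n)`
#' so either share alone is uniformly distributed and reveals nothing.
#' Distribution bytes (one node's payload) are charged to the current phase.
#'
#' @param env An [mpc_env()].
#' @param x Numeric vector of secrets, each in `[0, 2^n)`.
#' @param n Ring width (defaults to the environment's).
#' @return An `mpc_shares` vector.
#' @export
mpc_share <- function(env, x, n = env$n) {
  m <- 2^n
  if (any(x < 0 | x >= m)) {
    stop(sprintf("secret out of ring range [0, 2^%d)", n))
  }
  r <- rand_ring(length(x), m)
  record_comm(env, bytes = length(x) * n / 8)
  new_shares(r, rmod(x - r, m), n)
}

#' Reconstruct secrets from a pair of additive shares
#'
#' When `to = "nodes"` the exchange between P0 and P1 is one communication
#' round; `to = "alice"` models the final hand-over of result shares to the
#' query holder and does not touch the node transcript.
#'
#' @param env An [mpc_env()].
#' @param x An `mpc_shares` vector.
#' @param to Recipient of the opened value.
#' @param label Tag under which the opening is logged when open-capture is on.
#' @return Numeric vector `(s0 + s1) mod 2^n`.
#' @export
mpc_reconst <- function(env, x, to = c("nodes", "alice"), label = "reconst") {
  to <- match.arg(to)
  n <- sh_width(x)
  v <- rmod(x$s0 + x$s1, 2^n)
  if (to == "nodes") {
    record_comm(env, rounds = 1, bytes = length(v) * n / 8)
    record_open(env, label, v)
  }
  v
}

## ---- local linear algebra on shares ---------------------------------------

#' Local share arithmetic
#'
#' Addition, subtraction, negation, and multiplication or addition by public
#' constants act share-wise and need no communication.
#'
#' @param x,y `mpc_shares` vectors of equal width (scalar recycles).
#' @param k Public constant(s).
#' @name share-arith
NULL

recycle2 <- function(x, y) {
  lx <- length(x$s0); ly <- length(y$s0)
  if (lx == ly) return(list(x, y))
  if (lx == 1) return(list(sh_rep(x, ly), y))
  if (ly == 1) return(list(x, sh_rep(y, lx)))
  stop("incompatible share lengths")
}

#' @rdname share-arith
#' @export
mpc_add <- function(x, y) {
  stopifnot(sh_width(x) == sh_width(y))
  p <- recycle2(x, y); x <- p[[1]]; y <- p[[2]]
  m <- 2^sh_width(x)
  new_shares(rmod(x$s0 + y$s0, m), rmod(x$s1 + y$s1, m), sh_width(x))
}

#' @rdname share-arith
#' @export
mpc_sub <- function(x, y) {
  stopifnot(sh_width(x) == sh_width(y))
  p <- recycle2(x, y); x <- p[[1]]; y <- p[[2]]
  m <- 2^sh_width(x)
  new_shares(rmod(x$s0 - y$s0, m), rmod(x$s1 - y$s1, m), sh_width(x))
}

#' @rdname share-arith
#' @export
mpc_neg <- function(x) {
  m <- 2^sh_width(x)
  new_shares(rmod(-x$s0, m), rmod(-x$s1, m), sh_width(x))
}

#' @rdname share-arith
#' @export
mpc_add_const <- function(x, k) {
  m <- 2^sh_width(x)
  new_shares(rmod(x$s0 + k, m), x$s1, sh_width(x))
}

#' @rdname share-arith
#' @export
mpc_scalar_mul <- function(k, x) {
  m <- 2^sh_width(x)
  k <- rmod(k, m)
  new_shares(mulmod(k, x$s0, m), mulmod(k, x$s1, m), sh_width(x))
}

## ---- trusted initializer ---------------------------------------------------

# fresh correlated randomness from B; bytes go to the offline phase
ti_bytes <- function(env, bytes) record_comm(env, bytes = bytes, phase = "offline")

ti_arith_triple <- function(env, len, n) {
  m <- 2^n
  a <- rand_ring(len, m); b <- rand_ring(len, m); cc <- mulmod(a, b, m)
  a0 <- rand_ring(len, m); b0 <- rand_ring(len, m); c0 <- rand_ring(len, m)
  ti_bytes(env, 3 * len * n / 8)
  list(
    a = new_shares(a0, rmod(a - a0, m), n),
    b = new_shares(b0, rmod(b - b0, m), n),
    c = new_shares(c0, rmod(cc - c0, m), n)
  )
}

ti_bool_triple <- function(env, len) {
  a <- rand_ring(len, 2); b <- rand_ring(len, 2); cc <- a * b
  a0 <- rand_ring(len, 2); b0 <- rand_ring(len, 2); c0 <- rand_ring(len, 2)
  ti_bytes(env, 3 * len)
  list(
    a = new_bool(a0, (a - a0) %% 2),
    b = new_bool(b0, (b - b0) %% 2),
    c = new_bool(c0, (cc - c0) %% 2)
  )
}

# uniform r with arithmetic shares (width n) and Boolean shares of its bits
ti_masked_pair <- function(env, len, n) {
  m <- 2^n
  r <- rand_ring(len, m)
  r0 <- rand_ring(len, m)
  bits <- int_bits(r, n)
  b0 <- matrix(rand_ring(len * n, 2), len, n)
  ti_bytes(env, len * n / 8 + len * n)
  list(
    r = new_shares(r0, rmod(r - r0, m), n),
    bits = lapply(seq_len(n), function(k) new_bool(b0[, k], (bits[, k] - b0[, k]) %% 2))
  )
}

# random bit shared both as Boolean and arithmetically in ring `n`
ti_bit_pair <- function(env, len, n) {
  b <- rand_ring(len, 2)
  bb0 <- rand_ring(len, 2)
  m <- 2^n
  ba0 <- rand_ring(len, m)
  ti_bytes(env, len * (1 + n / 8))
  list(
    bool = new_bool(bb0, (b - bb0) %% 2),
    arith = new_shares(ba0, rmod(b - ba0, m), n)
  )
}

# uniform r in [0, 2^m_small): shares in the small ring, Boolean bit shares,
# and shares of the same integer in the big ring (for CastUp)
ti_cast_pair <- function(env, len, m_small, n_big) {
  ms <- 2^m_small; mb <- 2^n_big
  r <- rand_ring(len, ms)
  rs0 <- rand_ring(len, ms)
  rb0 <- rand_ring(len, mb)
  bits <- int_bits(r, m_small)
  b0 <- matrix(rand_ring(len * m_small, 2), len, m_small)
  ti_bytes(env, len * (m_small / 8 + n_big / 8 + m_small))
  list(
    small = new_shares(rs0, rmod(r - rs0, ms), m_small),
    big = new_shares(rb0, rmod(r - rb0, mb), n_big),
    bits = lapply(seq_len(m_small), function(k) new_bool(b0[, k], (bits[, k] - b0[, k]) %% 2))
  )
}

#' Pre-distribute Beaver triples from the trusted initializer
#'
#' The database holder plays trusted initializer: in the offline phase it
#' generates multiplication triples `(a, b, c)` with `ab = c mod 2^n` and
#' distributes additive shares to the nodes. [mpc_mult()] and [bool_and()]
#' consume the pool and transparently top it up (still charged to the offline
#' phase) when it runs dry.
#'
#' @param env An [mpc_env()].
#' @param count_arith,count_bool Number of arithmetic / Boolean triples.
#' @param n Ring width for the arithmetic triples.
#' @export
trusted_init <- function(env, count_arith = 0, count_bool = 0, n = env$n) {
  if (count_arith > 0) {
    t <- ti_arith_triple(env, count_arith, n)
    env$pool_arith <- if (is.null(env$pool_arith)) t else
      list(a = sh_c(env$pool_arith$a, t$a), b = sh_c(env$pool_arith$b, t$b),
           c = sh_c(env$pool_arith$c, t$c))
  }
  if (count_bool > 0) {
    t <- ti_bool_triple(env, count_bool)
    env$pool_bool <- if (is.null(env$pool_bool)) t else
      list(a = bool_c(env$pool_bool$a, t$a), b = bool_c(env$pool_bool$b, t$b),
           c = bool_c(env$pool_bool$c, t$c))
  }
  invisible(env)
}

#' Number of unconsumed pooled Beaver triples
#' @param env An [mpc_env()].
#' @return Named vector `c(arith = , bool = )`.
#' @export
triple_pool_size <- function(env) {
  c(arith = if (is.null(env$pool_arith)) 0L else length(env$pool_arith$a),
    bool = if (is.null(env$pool_bool)) 0L else length(env$pool_bool$a))
}

#' A single explicit Beaver triple
#'
#' Mostly useful for tests: the returned handle carries a consumed flag and
#' [mpc_mult()] refuses to use it twice.
#'
#' @param env An [mpc_env()].
#' @param n Ring width.
#' @export
beaver_triple <- function(env, n = env$n) {
  t <- ti_arith_triple(env, 1, n)
  h <- new.env(parent = emptyenv())
  h$a <- t$a; h$b <- t$b; h$c <- t$c; h$used <- FALSE; h$n <- n
  class(h) <- "beaver_triple"
  h
}

# take `len` arithmetic triples of width n from the pool (top up if needed)
take_arith_triples <- function(env, len, n) {
  pool <- env$pool_arith
  if (!is.null(pool) && sh_width(pool$a) == n && length(pool$a) >= len) {
    idx <- seq_len(len)
    out <- list(a = sh_slice(pool$a, idx), b = sh_slice(pool$b, idx), c = sh_slice(pool$c, idx))
    keep <- setdiff(seq_along(pool$a$s0), idx)
    env$pool_arith <- if (length(keep)) list(a = sh_slice(pool$a, keep),
                                             b = sh_slice(pool$b, keep),
                                             c = sh_slice(pool$c, keep)) else NULL
    out
  } else {
    ti_arith_triple(env, len, n)
  }
}

take_bool_triples <- function(env, len) {
  pool <- env$pool_bool
  if (!is.null(pool) && length(pool$a) >= len) {
    idx <- seq_len(len)
    out <- list(a = bool_slice(pool$a, idx), b = bool_slice(pool$b, idx), c = bool_slice(pool$c, idx))
    keep <- setdiff(seq_along(pool$a$b0), idx)
    env$pool_bool <- if (length(keep)) list(a = bool_slice(pool$a, keep),
                                            b = bool_slice(pool$b, keep),
                                            c = bool_slice(pool$c, keep)) else NULL
    out
  } else {
    ti_bool_triple(env, len)
  }
}

## ---- multiplication --------------------------------------------------------

#' Beaver-triple secure multiplication
#'
#' Three-step protocol: each node masks its operand shares with the triple
#' (`x' = x - a`, `y' = y - b`), the masked values are opened (one round, two
#' ring elements per element per direction), and the product share is
#' assembled locally as `x'y' + x'b_i + y'a_i + c_i`. The opened values are
#' uniform because `a` and `b` are.
#'
#' @param env An [mpc_env()].
#' @param x,y `mpc_shares` of the same width (scalars recycle).
#' @param triple Optional explicit [beaver_triple()] (length-1 operands only);
#'   reusing a consumed triple is an error.
#' @return `mpc_shares` reconstructing to `xy mod 2^n`.
#' @export
mpc_mult <- function(env, x, y, triple = NULL) {
  stopifnot(sh_width(x) == sh_width(y))
  p <- recycle2(x, y); x <- p[[1]]; y <- p[[2]]
  n <- sh_width(x); m <- 2^n
  len <- length(x)
  if (!is.null(triple)) {
    stopifnot(inherits(triple, "beaver_triple"))
    if (triple$used) stop("Beaver triple already consumed")
    if (triple$n != n || len != 1) stop("triple/operand mismatch")
    triple$used <- TRUE
    tr <- list(a = triple$a, b = triple$b, c = triple$c)
  } else {
    tr <- take_arith_triples(env, len, n)
  }
  xd <- mpc_sub(x, tr$a)
  yd <- mpc_sub(y, tr$b)
  record_comm(env, rounds = 1, bytes = 2 * len * n / 8)
  xp <- rmod(xd$s0 + xd$s1, m)
  yp <- rmod(yd$s0 + yd$s1, m)
  record_open(env, "mult", c(xp, yp))
  z0 <- rmod(mulmod(xp, yp, m) + mulmod(xp, tr$b$s0, m) + mulmod(yp, tr$a$s0, m) + tr$c$s0, m)
  z1 <- rmod(mulmod(xp, tr$b$s1, m) + mulmod(yp, tr$a$s1, m) + tr$c$s1, m)
  new_shares(z0, z1, n)
}

## ---- Boolean sharing and gates --------------------------------------------

#' Boolean (XOR) sharing
#'
#' @param env An [mpc_env()].
#' @param b 0/1 vector.
#' @return `mpc_bool` whose halves XOR to `b`.
#' @export
bool_share <- function(env, b) {
  stopifnot(all(b %in% c(0, 1)))
  r <- rand_ring(length(b), 2)
  record_comm(env, bytes = length(b))
  new_bool(r, (b - r) %% 2)
}

#' @rdname bool_share
#' @param x An `mpc_bool`.
#' @param to,label See [mpc_reconst()].
#' @export
bool_reconst <- function(env, x, to = c("nodes", "alice"), label = "bool") {
  to <- match.arg(to)
  v <- (x$b0 + x$b1) %% 2
  if (to == "nodes") {
    record_comm(env, rounds = 1, bytes = length(v))
    record_open(env, label, v)
  }
  v
}

#' Boolean gates over XOR shares
#'
#' XOR and NOT are local; AND consumes one Boolean Beaver triple per element
#' (one round); OR is `NOT(AND(NOT x, NOT y))`.
#'
#' @param env An [mpc_env()] (AND/OR only).
#' @param x,y `mpc_bool` vectors (scalars recycle).
#' @name bool-gates
NULL

brecycle2 <- function(x, y) {
  lx <- length(x$b0); ly <- length(y$b0)
  if (lx == ly) return(list(x, y))
  if (lx == 1) return(list(bool_rep(x, ly), y))
  if (ly == 1) return(list(x, bool_rep(y, lx)))
  stop("incompatible bool share lengths")
}

#' @rdname bool-gates
#' @export
bool_xor <- function(x, y) {
  p <- brecycle2(x, y); x <- p[[1]]; y <- p[[2]]
  new_bool((x$b0 + y$b0) %% 2, (x$b1 + y$b1) %% 2)
}

#' @rdname bool-gates
#' @export
bool_not <- function(x) new_bool((x$b0 + 1) %% 2, x$b1)

#' @rdname bool-gates
#' @export
bool_and <- function(env, x, y) {
  p <- brecycle2(x, y); x <- p[[1]]; y <- p[[2]]
  len <- length(x$b0)
  tr <- take_bool_triples(env, len)
  xp <- (x$b0 + tr$a$b0 + x$b1 + tr$a$b1) %% 2
  yp <- (y$b0 + tr$b$b0 + y$b1 + tr$b$b1) %% 2
  record_comm(env, rounds = 1, bytes = 2 * len)
  record_open(env, "and", c(xp, yp))
  z0 <- (xp * yp + xp * tr$b$b0 + yp * tr$a$b0 + tr$c$b0) %% 2
  z1 <- (xp * tr$b$b1 + yp * tr$a$b1 + tr$c$b1) %% 2
  new_bool(z0, z1)
}

#' @rdname bool-gates
#' @export
bool_or <- function(env, x, y) bool_not(bool_and(env, bool_not(x), bool_not(y)))

# XOR with a public bit vector (flip P0's half where the bit is 1)
bool_xor_public <- function(x, b) new_bool((x$b0 + b) %% 2, x$b1)

# AND with a public bit vector (zero the share where the bit is 0) — local
bool_and_public <- function(x, b) new_bool(x$b0 * b, x$b1 * b)

# OR-reduce a list of equal-length mpc_bool by a balanced tree of ANDs
bool_or_tree <- function(env, xs) {
  while (length(xs) > 1) {
    nx <- list()
    i <- 1
    while (i + 1 <= length(xs)) {
      nx[[length(nx) + 1L]] <- bool_or(env, xs[[i]], xs[[i + 1]])
      i <- i + 2
    }
    if (i == length(xs)) nx[[length(nx) + 1L]] <- xs[[i]]
    xs <- nx
  }
  xs[[1]]
}

# AND-reduce, pairs batched into one AND call per tree level
bool_and_tree_batched <- function(env, xs) {
  while (length(xs) > 1) {
    k <- length(xs) %/% 2
    left <- do.call(bool_c, xs[seq_len(k)])
    right <- do.call(bool_c, xs[k + seq_len(k)])
    z <- bool_and(env, left, right)
    len1 <- length(xs[[1]]$b0)
    nx <- lapply(seq_len(k), function(i) bool_slice(z, (i - 1) * len1 + seq_len(len1)))
    if (2 * k < length(xs)) nx[[k + 1L]] <- xs[[length(xs)]]
    xs <- nx
  }
  xs[[1]]
}
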