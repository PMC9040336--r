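#' Unary query encoding
#'
#' Encodes a query `w` as four 0/1 indicator vectors `q_A, q_C, q_G, q_T` of
#' length `l`, with `q_c[j] = 1` iff `w[j] = c`. The inner product of the
#' encoding with the four masked lookup tables selects the active letter's
#' table entry without revealing the letter.
#'
#' @param w Query string over ACGT.
#' @return 4 x l 0/1 matrix with rownames A,C,G,T.
#' @export
encode_query <- function(w) {
  codes <- dna_codes(w)
  m <- matrix(0, 4, length(codes), dimnames = list(DNA_LETTERS, NULL))
  m[cbind(codes, seq_along(codes))] <- 1
  m
}

#' Decode a unary query encoding back to the string
#' @param q A 4 x l encoding from [encode_query()].
#' @export
decode_query <- function(q) {
  stopifnot(nrow(q) == 4, all(colSums(q) == 1))
  paste(DNA_LETTERS[apply(q, 2, which.max)], collapse = "")
}

# masked/rotated copy of one lookup table (length Np, values mod Np):
# prev = inbound rotation (previous round's mask), out = outbound value mask
mask_rotate <- function(V, prev, out, Np) {
  idx <- seq_len(Np)
  rot <- if (prev == 0) V else V[(idx - 1 - prev) %% Np + 1]
  (rot + out) %% Np
}

# shared per-letter masked table family for rounds 1..depth with mask chain r
share_lf_family <- function(env, tab, r, depth) {
  Np <- tab$Np
  out <- vector("list", depth)
  for (j in seq_len(depth)) {
    prev <- if (j == 1) 0 else r[j - 1]
    out[[j]] <- lapply(tab$V, function(V) mpc_share(env, mask_rotate(V, prev, r[j], Np)))
  }
  out
}

#' Secure LPM: DB preparation
#'
#' Builds the FM tables on the reversed database and, for each round
#' `j = 0..l-1` and letter `c`, the masked tables
#' `R_{c,f}^j[i] = (V_c[(i - r_f^{j-1}) mod N'] + r_f^j) mod N'` (and the
#' `g`-family with the `r_g` chain), plus the shared mask-difference vector
#' `r'[j] = (r_f^j - r_g^j) mod N'` used by the width-zero check. All four
#' letters of a round share the same mask pair, which is what makes the
#' recursion across letters possible. `8*l` vectors of length `N' = N + 1`
#' are shared in the DB-preparation phase.
#'
#' @param t Database string over ACGT (the reversal is internal).
#' @param ell Query length the tables support.
#' @param env An [mpc_env()]; requires `2^n >= 4 N'` so that the constants
#'   `-N', 0, N'` are distinct ring elements.
#' @param masks_f,masks_g Optional fixed mask chains of length `ell`.
#' @return Object of class `lpm_db`.
#' @export
prepare_lpm_db <- function(t, ell, env, masks_f = NULL, masks_g = NULL) {
  stopifnot(ell >= 1)
  tab <- build_fm_tables(reverse_seq(t))
  Np <- tab$Np
  if (2^env$n < 4 * Np) stop("ring too small: need 2^n >= 4 N'")
  if (is.null(masks_f)) masks_f <- rand_ring(ell, Np)
  if (is.null(masks_g)) masks_g <- rand_ring(ell, Np)
  mpc_phase(env, "db_prep")
  Rf <- share_lf_family(env, tab, masks_f, ell)
  Rg <- share_lf_family(env, tab, masks_g, ell)
  rprime <- mpc_share(env, (masks_f - masks_g) %% Np)
  structure(list(Rf = Rf, Rg = Rg, rprime = rprime,
                 N = tab$N, Np = Np, ell = ell, n = env$n,
                 masks_f = masks_f, masks_g = masks_g, tab = tab),
            class = "lpm_db")
}

# shared width-zero test: d = hat_f - hat_g - r'[j] equals one of -N', 0, N'
width_zero_check <- function(env, hat_f, hat_g, rprime_j, Np, n) {
  d <- mpc_sub(mpc_sub(hat_f, hat_g), rprime_j)
  consts <- public_share(c(2^n - Np, 0, Np), n)
  eqs <- mpc_equality(env, sh_rep(d, 3), consts)
  bool_or_tree(env, lapply(1:3, function(i) bool_slice(eqs, i)))
}

#' Secure LPM: search phase
#'
#' Runs the l-round masked backward search: each round the nodes select the
#' active letter's masked table entry for both interval bounds by an inner
#' product with the shared query encoding (one multiplication round), open the
#' two masked bounds to use as the next round's public indices, and test the
#' masked interval width for zero with three Equality calls OR-combined. All
#' `l` rounds always run, so the communication pattern is input-independent.
#' Only the equality-result vector `o` is revealed, and only to the query
#' holder: `o[i] = 1` iff the interval collapsed at the i-th reference, so the
#' decoded LPM length is `min{i : o[i] = 1} - 1` (or `l` if `o` is all-zero).
#'
#' @param w Query string over ACGT with `nchar(w) == db$ell`.
#' @param db An `lpm_db` from [prepare_lpm_db()].
#' @param env The same [mpc_env()].
#' @return List: `o` (0/1 vector of length l), `length` (decoded LPM length),
#'   `match` (the matched prefix of `w`), `disclosed` (matrix of opened
#'   masked bounds per round).
#' @export
lpm_search <- function(w, db, env) {
  q <- encode_query(w)
  if (ncol(q) != db$ell) stop("query length does not match the prepared tables")
  mpc_phase(env, "search")
  qsh <- lapply(seq_len(4), function(c) mpc_share(env, q[c, ]))
  f <- 0; g <- db$N
  o <- vector("list", db$ell)
  disclosed <- matrix(0, db$ell, 2, dimnames = list(NULL, c("f", "g")))
  for (j in seq_len(db$ell)) {
    qj <- sh_c(qsh[[1]] |> sh_slice(j), qsh[[2]] |> sh_slice(j),
               qsh[[3]] |> sh_slice(j), qsh[[4]] |> sh_slice(j))
    entries <- sh_c(
      do.call(sh_c, lapply(1:4, function(c) sh_at(db$Rf[[j]][[c]], f))),
      do.call(sh_c, lapply(1:4, function(c) sh_at(db$Rg[[j]][[c]], g)))
    )
    prods <- mpc_mult(env, sh_c(qj, qj), entries)
    hat_f <- sh_slice(prods, 1)
    for (c in 2:4) hat_f <- mpc_add(hat_f, sh_slice(prods, c))
    hat_g <- sh_slice(prods, 5)
    for (c in 6:8) hat_g <- mpc_add(hat_g, sh_slice(prods, c))
    opened <- mpc_reconst(env, sh_c(hat_f, hat_g), label = "lpm_bounds")
    o[[j]] <- width_zero_check(env, hat_f, hat_g, sh_slice(db$rprime, j), db$Np, db$n)
    f <- opened[1]; g <- opened[2]
    disclosed[j, ] <- opened
  }
  obits <- bool_reconst(env, do.call(bool_c, o), to = "alice")
  decode_lpm_result(w, obits, disclosed)
}

decode_lpm_result <- function(w, obits, disclosed) {
  hit <- which(obits == 1)
  len <- if (length(hit)) hit[1] - 1 else length(obits)
  list(o = obits, length = len, match = substr(w, 1, len), disclosed = disclosed)
}
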