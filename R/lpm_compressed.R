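#' Rotated unit-step lookup table with offset correction
#'
#' The LF tables `V_c` are non-decreasing with unit steps, which is what
#' makes the coarse/residual decomposition of the compressed protocol
#' possible — but a plain circular rotation would break monotonicity at the
#' seam. This constructor subtracts one of two offsets on either side of the
#' seam so the rotated table
#' \deqn{V'[(i + r) \bmod N'] = V[i] - o \ (i \le (i+r) \bmod N'),\quad
#'       V[i] - \bar o \ \text{otherwise}}
#' with `o = V[(N'-1-r) mod N'] - V[N'-1]` and
#' `obar = V[(N'-1-r) mod N'] - V[0]` is again unit-step everywhere
#' (`0 <= V'[i+1] - V'[i] <= 1`). The true entry is recovered as
#' `V[i] = V'[(i+r) mod N'] + o` when `i <= (i+r) mod N'`, else `+ obar`.
#'
#' @param V Unit-step vector of length `N'` (one of the `V_c`).
#' @param r Rotation amount in `[0, N')`.
#' @return List `vp` (the rotated table), `o`, `obar`.
#' @export
build_rotated_table <- function(V, r) {
  Np <- length(V)
  r <- r %% Np
  i <- seq_len(Np) - 1 # source index
  dest <- (i + r) %% Np
  o <- V[(Np - 1 - r) %% Np + 1] - V[Np]
  obar <- V[(Np - 1 - r) %% Np + 1] - V[1]
  vp <- numeric(Np)
  off <- ifelse(i <= dest, o, obar)
  vp[dest + 1] <- V[i + 1] - off
  list(vp = vp, o = o, obar = obar)
}

#' Coarse/residual split of a unit-step table
#'
#' Samples every `M`-th entry into the coarse vector `Q` and keeps the
#' small difference to the preceding sample as the residual
#' `R[i] = V'[i] - V'[M floor(i/M)]`; the unit-step property bounds residuals
#' by `M - 1`, so they fit in `m = log2(M)` bits while `Q` keeps the full
#' width. `V'[i] = Q[floor(i/M)] + R[i]` for every `i`.
#'
#' @param vp Unit-step vector.
#' @param M Stride, a power of two.
#' @return List `Q` (length `ceiling(N'/M)`), `R` (length `N'`).
#' @export
sample_split <- function(vp, M) {
  Np <- length(vp)
  i <- seq_len(Np) - 1
  Q <- vp[seq(1, Np, by = M)]
  R <- vp - vp[(i %/% M) * M + 1]
  list(Q = Q, R = R)
}

#' Compressed-share secure LPM: DB preparation
#'
#' For each round and letter, the database holder rotates the unit-step LF
#' table by a fresh mask ([build_rotated_table()]), splits it into an n-bit
#' coarse vector and an m-bit residual vector ([sample_split()]), and shares
#' the residuals over `Z_{2^m}`, everything else (coarse values, the two
#' offsets, the rotation mask itself) over `Z_{2^n}`. Because residuals
#' dominate the table, the DB-preparation payload shrinks by roughly `n/m`
#' for large `M` relative to [prepare_lpm_db()]. Unlike the ss-ROT-chained
#' tables, the bounds here stay *exact* in the shares; each round only a
#' freshly masked index is opened.
#'
#' @param t Database string over ACGT (reversal internal).
#' @param ell Query length.
#' @param m Residual share width; `M = 2^m` is the sampling stride.
#' @param env An [mpc_env()] with width `n > m` and `2^n >= 4 N'`.
#' @param masks_f,masks_g Optional fixed rotation masks, length `ell`.
#' @return Object of class `lpm2_db`.
#' @export
prepare_lpm2_db <- function(t, ell, m = 8, env = NULL, masks_f = NULL, masks_g = NULL) {
  stopifnot(ell >= 1, !is.null(env))
  n <- env$n
  if (m >= n) stop("residual width m must be smaller than the share width n")
  tab <- build_fm_tables(reverse_seq(t))
  Np <- tab$Np
  if (2^n < 4 * Np) stop("ring too small: need 2^n >= 4 N'")
  M <- 2^m
  if (is.null(masks_f)) masks_f <- rand_ring(ell, Np)
  if (is.null(masks_g)) masks_g <- rand_ring(ell, Np)
  mpc_phase(env, "db_prep")
  fam <- function(masks) {
    lapply(seq_len(ell), function(j) {
      per_letter <- lapply(tab$V, function(V) {
        rt <- build_rotated_table(V, masks[j])
        sp <- sample_split(rt$vp, M)
        list(
          Q = mpc_share(env, rmod(sp$Q, 2^n), n = n),
          R = mpc_share(env, sp$R, n = m),
          o = mpc_share(env, rmod(rt$o, 2^n), n = n),
          obar = mpc_share(env, rmod(rt$obar, 2^n), n = n)
        )
      })
      list(tables = per_letter, rmask = mpc_share(env, masks[j], n = n))
    })
  }
  structure(list(f = fam(masks_f), g = fam(masks_g),
                 N = tab$N, Np = Np, ell = ell, n = n, m = m, M = M,
                 masks_f = masks_f, masks_g = masks_g, tab = tab),
            class = "lpm2_db")
}

# one bound update: select letter, castup residual, apply offset by comparison
lpm2_bound_step <- function(env, side, j, qj, bound_sh, db) {
  n <- db$n
  tabs <- side[[j]]$tables
  # open the masked index p = (true bound + r) mod N'; the sum is opened in
  # Z_{2^n} (no wrap: both terms < N' <= 2^n/4) and reduced mod N' publicly
  s <- mpc_reconst(env, mpc_add(bound_sh, side[[j]]$rmask), label = "lpm2_index")
  p <- s %% db$Np
  rv <- do.call(sh_c, lapply(tabs, function(tb) sh_at(tb$R, p)))
  rv_up <- mpc_cast_up(env, rv, n)
  qv <- do.call(sh_c, lapply(tabs, function(tb) sh_at(tb$Q, p %/% db$M)))
  ov <- do.call(sh_c, lapply(tabs, function(tb) tb$o))
  obv <- do.call(sh_c, lapply(tabs, function(tb) tb$obar))
  sel <- mpc_mult(env, sh_rep(qj, 3), sh_c(mpc_add(qv, rv_up), ov, obv))
  acc <- function(k) {
    out <- sh_slice(sel, (k - 1) * 4 + 1)
    for (c in 2:4) out <- mpc_add(out, sh_slice(sel, (k - 1) * 4 + c))
    out
  }
  vsel <- acc(1); osel <- acc(2); obsel <- acc(3)
  # offset branch: true bound <= p, evaluated as bound < p + 1
  le <- mpc_comp(env, bound_sh, public_share(p + 1, n))
  lea <- mpc_b2a(env, le, n)
  list(bound = mpc_add(vsel, mpc_choose(env, osel, obsel, lea)), p = p)
}

#' Compressed-share secure LPM: search phase
#'
#' Per round: open the masked true bounds, index the coarse and residual
#' tables at the opened position, CastUp the m-bit residual share, select the
#' active letter's value and offsets by inner product with the query
#' encoding, pick the offset with a comparison against the opened index, and
#' add it — yielding exact shares of the next bounds. The width-zero test is
#' then a single Equality of the two bound shares (no mask-difference vector
#' needed). Output and decoding are identical to [lpm_search()].
#'
#' @param w Query string with `nchar(w) == db$ell`.
#' @param db An `lpm2_db` from [prepare_lpm2_db()].
#' @param env The same [mpc_env()].
#' @return As [lpm_search()]: `o`, `length`, `match`, `disclosed`.
#' @export
lpm2_search <- function(w, db, env) {
  q <- encode_query(w)
  if (ncol(q) != db$ell) stop("query length does not match the prepared tables")
  mpc_phase(env, "search")
  n <- db$n
  qsh <- lapply(seq_len(4), function(c) mpc_share(env, q[c, ]))
  fsh <- public_share(0, n)
  gsh <- public_share(db$N, n)
  o <- vector("list", db$ell)
  disclosed <- matrix(0, db$ell, 2, dimnames = list(NULL, c("pf", "pg")))
  for (j in seq_len(db$ell)) {
    qj <- do.call(sh_c, lapply(qsh, function(s) sh_slice(s, j)))
    stf <- lpm2_bound_step(env, db$f, j, qj, fsh, db)
    stg <- lpm2_bound_step(env, db$g, j, qj, gsh, db)
    fsh <- stf$bound; gsh <- stg$bound
    o[[j]] <- mpc_equality(env, fsh, gsh)
    disclosed[j, ] <- c(stf$p, stg$p)
  }
  obits <- bool_reconst(env, do.call(bool_c, o), to = "alice")
  decode_lpm_result(w, obits, disclosed)
}
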