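#' Secret-shared recursive oblivious transfer: DB preparation
#'
#' The database holder turns a lookup vector `V` (values in `[0, N)`) into
#' `ell` masked/rotated copies
#' \deqn{R^0[i] = (V[i] + r^0) \bmod N,\quad
#'       R^j[i] = (V[(i - r^{j-1}) \bmod N] + r^j) \bmod N,\quad
#'       R^{\ell-1}[i] = V[(i - r^{\ell-2}) \bmod N] \bmod N}
#' with fresh uniform masks `r^0..r^{ell-2}` in `[0, N)`, and distributes
#' element-wise additive shares to the nodes (DB-preparation phase). Chaining
#' the copies lets the nodes evaluate the `ell`-fold recursion
#' `V[V[...V[p0]...]]` while only ever opening mask-randomized indices.
#'
#' @param V Numeric vector, `0 <= V[i] < N`.
#' @param ell Recursion depth, at least 2.
#' @param env An [mpc_env()]; its ring must satisfy `2^n >= N`.
#' @param masks Optional fixed masks (length `ell - 1`), e.g. to reproduce a
#'   worked example; default fresh uniform.
#' @return Object of class `ssrot_db`: `shares` (list of `ell` shared
#'   vectors), `N`, `ell`, and (database-holder private, for tests) `masks`.
#' @export
prepare_ssrot <- function(V, ell, env, masks = NULL) {
  N <- length(V)
  if (ell < 2) stop("recursion depth ell must be at least 2")
  if (any(V < 0 | V >= N)) stop("table entries must lie in [0, N)")
  if (2^env$n < N) stop("ring too small for table indices: need 2^n >= N")
  if (is.null(masks)) masks <- rand_ring(ell - 1, N)
  stopifnot(length(masks) == ell - 1)
  mpc_phase(env, "db_prep")
  idx <- seq_len(N)
  shares <- vector("list", ell)
  for (j in seq_len(ell)) {
    rot <- if (j == 1) V else V[(idx - 1 - masks[j - 1]) %% N + 1]
    tabj <- if (j < ell) (rot + masks[j]) %% N else rot %% N
    shares[[j]] <- mpc_share(env, tabj)
  }
  structure(list(shares = shares, N = N, ell = ell, masks = masks),
            class = "ssrot_db")
}

#' Secret-shared recursive oblivious transfer: search phase
#'
#' Step 1: for `j = 0..ell-2` the nodes jointly reconstruct
#' `p_{j+1} = R^j[p_j]`, a masked (uniform) index. Step 2: they output their
#' shares of `R^{ell-1}[p_{ell-1}]` without reconstruction; the pair
#' reconstructs to `V^{(ell)}[p0] mod N`. Search cost is `ell - 1` rounds plus
#' the result hand-over, independent of `N`.
#'
#' @param db An `ssrot_db` from [prepare_ssrot()].
#' @param p0 Initial position in `[0, N)`.
#' @param env The same [mpc_env()] used for preparation.
#' @return List: `share` (result `mpc_shares`, length 1), `disclosed`
#'   (the `ell - 1` opened masked indices), `value` (the reconstruction the
#'   querying party performs).
#' @export
ssrot_search <- function(db, p0, env) {
  if (p0 < 0 || p0 >= db$N) stop("initial position out of [0, N)")
  mpc_phase(env, "search")
  p <- p0
  disclosed <- numeric(db$ell - 1)
  for (j in seq_len(db$ell - 1)) {
    p <- mpc_reconst(env, sh_at(db$shares[[j]], p), label = "ssrot_index")
    disclosed[j] <- p
  }
  out <- sh_at(db$shares[[db$ell]], p)
  list(share = out,
       disclosed = disclosed,
       value = mpc_reconst(env, out, to = "alice"))
}
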