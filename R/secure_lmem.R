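#' Secure LMEM: DB preparation
#'
#' Extends the LPM table family to the maximal-exact-match walk. On top of
#' masked LF tables `R_{c,f}`, `R_{c,g}` (now to depth `2l - 1`, the number of
#' search rounds) and the mask-difference vector `r'`, the database holder
#' shares six rotated copies of the auxiliary arrays per round `j`:
#'
#' * `W_{l,f}^j`, `W_{l,g}^j` — the LCP array rotated by the *same* inbound
#'   masks as the corresponding LF families (values unmasked, but shared), so
#'   that indexing them with the opened masked bounds yields shares of
#'   `LCP[f]`, `LCP[g]`;
#' * `W_{p,f}^j`, `W_{p,g}^j` — the PSV array, rotated by `r_f^{j-1}` /
#'   `r_g^{j-1}` but both value-masked with `r_f^j`, because a PSV result
#'   becomes the next *lower* bound;
#' * `W_{n,f}^j`, `W_{n,g}^j` — the NSV array, value-masked with `r_g^j`
#'   (next *upper* bound).
#'
#' This mask discipline keeps the recursion well-formed whichever branch
#' (extension or parent interval) each round takes. All tables have length
#' `N' = N + 1` and values reduced mod `N'`.
#'
#' @param t Database string over ACGT (reversal internal).
#' @param ell Query length.
#' @param env An [mpc_env()] with `2^n >= 4 N'`.
#' @param masks_f,masks_g Optional fixed mask chains of length `2*ell - 1`.
#' @return Object of class `lmem_db`.
#' @export
prepare_lmem_db <- function(t, ell, env, masks_f = NULL, masks_g = NULL) {
  stopifnot(ell >= 1)
  tab <- build_fm_tables(reverse_seq(t))
  lcp <- build_lcp_psv_nsv(tab)
  Np <- tab$Np
  if (2^env$n < 4 * Np) stop("ring too small: need 2^n >= 4 N'")
  depth <- 2 * ell - 1
  if (is.null(masks_f)) masks_f <- rand_ring(depth, Np)
  if (is.null(masks_g)) masks_g <- rand_ring(depth, Np)
  stopifnot(length(masks_f) == depth, length(masks_g) == depth)
  mpc_phase(env, "db_prep")
  Rf <- share_lf_family(env, tab, masks_f, depth)
  Rg <- share_lf_family(env, tab, masks_g, depth)
  rprime <- mpc_share(env, (masks_f - masks_g) %% Np)
  Wlf <- vector("list", depth); Wlg <- vector("list", depth)
  Wpf <- vector("list", depth); Wpg <- vector("list", depth)
  Wnf <- vector("list", depth); Wng <- vector("list", depth)
  for (j in seq_len(depth)) {
    pf <- if (j == 1) 0 else masks_f[j - 1]
    pg <- if (j == 1) 0 else masks_g[j - 1]
    Wlf[[j]] <- mpc_share(env, mask_rotate(lcp$lcp %% Np, pf, 0, Np))
    Wlg[[j]] <- mpc_share(env, mask_rotate(lcp$lcp %% Np, pg, 0, Np))
    Wpf[[j]] <- mpc_share(env, mask_rotate(lcp$psv, pf, masks_f[j], Np))
    Wpg[[j]] <- mpc_share(env, mask_rotate(lcp$psv, pg, masks_f[j], Np))
    Wnf[[j]] <- mpc_share(env, mask_rotate(lcp$nsv, pf, masks_g[j], Np))
    Wng[[j]] <- mpc_share(env, mask_rotate(lcp$nsv, pg, masks_g[j], Np))
  }
  structure(list(Rf = Rf, Rg = Rg, rprime = rprime,
                 Wlf = Wlf, Wlg = Wlg, Wpf = Wpf, Wpg = Wpg, Wnf = Wnf, Wng = Wng,
                 N = tab$N, Np = Np, ell = ell, depth = depth, n = env$n,
                 masks_f = masks_f, masks_g = masks_g, tab = tab, lcp = lcp),
            class = "lmem_db")
}

# local prefix-shift of a shared unit vector: (0, u[0], ..., u[l-2])
shift_right <- function(u) {
  l <- length(u)
  new_shares(c(0, u$s0[-l]), c(0, u$s1[-l]), sh_width(u))
}

# local sum of a shared vector's entries
sh_sum <- function(x) {
  m <- 2^sh_width(x)
  new_shares(rmod(sum(x$s0), m), rmod(sum(x$s1), m), sh_width(x))
}

#' Secure LMEM: search phase
#'
#' Runs `2l - 1` fixed rounds over the masked tables. Each round the nodes:
#' select the current query letter's encoding as the inner product of the
#' shared unary query vectors with the shared unit position vector `u`;
#' compute the masked backward extension of both bounds; test the extension's
#' width for zero (`e1`); look up shares of `LCP[f]`, `LCP[g]` and decide the
#' parent-interval branch `e2 = [LCP[g] <= LCP[f]]`; obliviously pick the next
#' interval (extension if it is non-empty, else the PSV/NSV parent); update
#' the match state — on extension the length `m` grows by one and `u` shifts
#' right, on parent-fallback `m` drops to the parent's lcp-value
#' `c = max(LCP[f], LCP[g])` and the left end advances to `p + m - c` while
#' `u` holds; and fold the running maximum with a strict comparison (the
#' first maximum wins). A failed extension at `m = 0` means the letter does
#' not occur in the database at all; the walk then advances past it
#' (`u` shifts, `m` stays 0), detected with one extra Equality against zero.
#' State updates freeze (via Choose) once `u` has shifted out, so late rounds
#' are no-ops with an unchanged communication pattern. Only the final
#' (length, left position) shares go to the query holder.
#'
#' @param w Query string with `nchar(w) == db$ell`.
#' @param db An `lmem_db` from [prepare_lmem_db()].
#' @param env The same [mpc_env()].
#' @param trace If `TRUE`, also return a glass-box per-round reconstruction
#'   of the hidden state (test instrumentation; bypasses the transcript).
#' @return List: `length`, `position` (0-based left end of the LMEM in `w`),
#'   `match` (the matched substring), `disclosed` (opened masked bounds),
#'   and optionally `trace`.
#' @export
lmem_search <- function(w, db, env, trace = FALSE) {
  q <- encode_query(w)
  if (ncol(q) != db$ell) stop("query length does not match the prepared tables")
  mpc_phase(env, "search")
  n <- db$n
  l <- db$ell
  qsh <- lapply(seq_len(4), function(c) mpc_share(env, q[c, ]))
  u <- mpc_share(env, c(1, rep(0, l - 1)))
  zero <- public_share(0, n)
  m <- zero; p <- zero; best <- zero; bestp <- zero
  f <- 0; g <- db$N
  disclosed <- matrix(0, db$depth, 2, dimnames = list(NULL, c("f", "g")))
  tr <- if (trace) vector("list", db$depth) else NULL
  for (j in seq_len(db$depth)) {
    # (a) letter encoding at the current right end: a_c = <q_c, u>
    qcat <- do.call(sh_c, qsh)
    prods <- mpc_mult(env, qcat, sh_rep(u, 4))
    a <- lapply(1:4, function(c) sh_sum(sh_slice(prods, (c - 1) * l + seq_len(l))))
    # (b) masked backward extension of both bounds
    entries <- sh_c(
      do.call(sh_c, lapply(1:4, function(c) sh_at(db$Rf[[j]][[c]], f))),
      do.call(sh_c, lapply(1:4, function(c) sh_at(db$Rg[[j]][[c]], g)))
    )
    acat <- do.call(sh_c, c(a, a))
    hp <- mpc_mult(env, acat, entries)
    hat_f <- sh_slice(hp, 1)
    for (c in 2:4) hat_f <- mpc_add(hat_f, sh_slice(hp, c))
    hat_g <- sh_slice(hp, 5)
    for (c in 6:8) hat_g <- mpc_add(hat_g, sh_slice(hp, c))
    # (c) flags: failed extension, parent branch, zero-length match, activity
    e1 <- width_zero_check(env, hat_f, hat_g, sh_slice(db$rprime, j), db$Np, n)
    lcp_f <- sh_at(db$Wlf[[j]], f)
    lcp_g <- sh_at(db$Wlg[[j]], g)
    e2 <- bool_not(mpc_comp(env, lcp_f, lcp_g)) # [LCP[g] <= LCP[f]]
    em0 <- mpc_equality(env, m, zero)
    e1a <- mpc_b2a(env, e1, n)
    e2a <- mpc_b2a(env, e2, n)
    em0a <- mpc_b2a(env, em0, n)
    x <- sh_sum(u) # active flag: u is a unit vector or all-zero
    # (d) parent-interval candidate and its lcp-value
    cval <- mpc_choose(env, lcp_f, lcp_g, e2a)
    par_f <- mpc_choose(env, sh_at(db$Wpf[[j]], f), sh_at(db$Wpg[[j]], g), e2a)
    par_g <- mpc_choose(env, sh_at(db$Wnf[[j]], f), sh_at(db$Wng[[j]], g), e2a)
    # (e) next interval: parent on failed extension, else the extension
    next_f <- mpc_choose(env, par_f, hat_f, e1a)
    next_g <- mpc_choose(env, par_g, hat_g, e1a)
    # (f) match length / left position, frozen when inactive
    m_upd <- mpc_choose(env, mpc_choose(env, m, cval, em0a), mpc_add_const(m, 1), e1a)
    p_fb <- mpc_sub(mpc_add(p, m), cval)
    p_upd <- mpc_choose(env, mpc_choose(env, mpc_add_const(p, 1), p_fb, em0a), p, e1a)
    m_new <- mpc_choose(env, m_upd, m, x)
    p_new <- mpc_choose(env, p_upd, p, x)
    # (g) u holds on parent-fallback (e1 and m > 0), shifts otherwise
    fb <- bool_and(env, e1, bool_not(em0))
    fba <- mpc_b2a(env, fb, n)
    u <- mpc_choose(env, u, shift_right(u), sh_rep(fba, l))
    # (h) running maximum, strict comparison so the first maximum wins
    gt <- mpc_comp(env, best, m_new)
    cond <- mpc_mult(env, mpc_b2a(env, gt, n), x)
    best <- mpc_choose(env, m_new, best, cond)
    bestp <- mpc_choose(env, p_new, bestp, cond)
    m <- m_new; p <- p_new
    # (i) open the next masked bounds for the following round's lookups
    opened <- mpc_reconst(env, sh_c(next_f, next_g), label = "lmem_bounds")
    f <- opened[1]; g <- opened[2]
    disclosed[j, ] <- opened
    if (trace) {
      gb <- function(s) rmod(s$s0 + s$s1, 2^n)
      tr[[j]] <- list(u = gb(u), m = gb(m), p = gb(p), best = gb(best),
                      e1 = (e1$b0 + e1$b1) %% 2)
    }
  }
  len <- mpc_reconst(env, best, to = "alice")
  pos <- mpc_reconst(env, bestp, to = "alice")
  out <- list(length = len, position = pos,
              match = substr(w, pos + 1, pos + len), disclosed = disclosed)
  if (trace) out$trace <- tr
  out
}
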