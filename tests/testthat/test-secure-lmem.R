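test_that("auxiliary table families follow the mask discipline", {
  set.seed(60)
  t <- rand_genome(36)
  ell <- 4
  env <- mpc_env(n = 16, seed = 1)
  db <- prepare_lmem_db(t, ell, env)
  tab <- build_fm_tables(reverse_seq(t))
  st <- build_lcp_psv_nsv(tab)
  Np <- tab$Np
  idx <- seq_len(Np)
  rotate <- function(V, r) if (r == 0) V else V[(idx - 1 - r) %% Np + 1]
  for (j in seq_len(db$depth)) {
    pf <- if (j == 1) 0 else db$masks_f[j - 1]
    pg <- if (j == 1) 0 else db$masks_g[j - 1]
    # LCP copies: rotated by the R-family masks, values unmasked
    expect_equal(reveal(db$Wlf[[j]]), rotate(st$lcp %% Np, pf))
    expect_equal(reveal(db$Wlg[[j]]), rotate(st$lcp %% Np, pg))
    # PSV outputs carry the f-mask, NSV outputs the g-mask, on both variants
    expect_equal(reveal(db$Wpf[[j]]), (rotate(st$psv, pf) + db$masks_f[j]) %% Np)
    expect_equal(reveal(db$Wpg[[j]]), (rotate(st$psv, pg) + db$masks_f[j]) %% Np)
    expect_equal(reveal(db$Wnf[[j]]), (rotate(st$nsv, pf) + db$masks_g[j]) %% Np)
    expect_equal(reveal(db$Wng[[j]]), (rotate(st$nsv, pg) + db$masks_g[j]) %% Np)
    # de-randomizing a PSV lookup with the f-mask recovers PSV values
    expect_equal((reveal(db$Wpf[[j]]) - db$masks_f[j]) %% Np, rotate(st$psv, pf))
  }
  # zero masks leave all auxiliary tables in the clear
  env0 <- mpc_env(n = 16, seed = 2)
  z <- rep(0, 2 * 3 - 1)
  db0 <- prepare_lmem_db(t, 3, env0, masks_f = z, masks_g = z)
  expect_equal(reveal(db0$Wlf[[2]]), st$lcp)
  expect_equal(reveal(db0$Wpf[[2]]), st$psv)
  expect_equal(reveal(db0$Wng[[2]]), st$nsv)
})

test_that("a query that is a database substring is found in full at position 0", {
  env <- mpc_env(n = 16, seed = 3)
  db <- prepare_lmem_db("TGCATTAG", 4, env)
  res <- lmem_search("GCAT", db, env)
  expect_equal(res$length, 4)
  expect_equal(res$position, 0)
  expect_equal(res$match, "GCAT")
})

test_that("a query with no matching letter reports (0, 0)", {
  env <- mpc_env(n = 16, seed = 4)
  db <- prepare_lmem_db("ACACACAC", 2, env)
  res <- lmem_search("GT", db, env)
  expect_equal(res$length, 0)
  expect_equal(res$position, 0)
})

test_that("secure LMEM equals the brute-force oracle with valid positions", {
  set.seed(61)
  for (rep in 1:40) {
    t <- rand_genome(sample(20:200, 1))
    w <- rand_dna(sample(2:16, 1))
    env <- mpc_env(n = 16, seed = 700 + rep)
    db <- prepare_lmem_db(t, nchar(w), env)
    res <- lmem_search(w, db, env)
    want <- oracle_lmem(w, t)
    expect_equal(res$length, want$length)
    if (res$length > 0) {
      expect_true(oracle_occurs(substr(w, res$position + 1,
                                       res$position + res$length), t))
    }
  }
})

test_that("the hidden position vector u stays a unit vector or empties", {
  set.seed(62)
  for (rep in 1:6) {
    t <- rand_genome(sample(20:80, 1))
    w <- rand_dna(6)
    env <- mpc_env(n = 16, seed = 800 + rep)
    db <- prepare_lmem_db(t, 6, env)
    res <- lmem_search(w, db, env, trace = TRUE)
    for (st in res$trace) {
      expect_lte(sum(st$u), 1)
      expect_true(all(st$u %in% c(0, 1)))
    }
    # once empty, u stays empty
    act <- vapply(res$trace, function(s) sum(s$u), 0)
    expect_true(all(diff(act) <= 0) || all(act == act[1]))
  }
})

test_that("round count is 2l - 1 and the search transcript is N-invariant", {
  run <- function(N, ell, seed) {
    set.seed(seed)
    t <- rand_genome(N); w <- rand_dna(ell)
    env <- mpc_env(n = 16, seed = seed)
    db <- prepare_lmem_db(t, ell, env)
    lmem_search(w, db, env)
    mpc_transcript(env)$search
  }
  a <- run(60, 5, 1)
  b <- run(900, 5, 2)
  expect_identical(a, b)
  # per-round cost is fixed, so rounds scale with the 2l - 1 round count
  c10 <- run(60, 10, 3)
  expect_equal(c10[["rounds"]] / (2 * 10 - 1), a[["rounds"]] / (2 * 5 - 1))
})
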