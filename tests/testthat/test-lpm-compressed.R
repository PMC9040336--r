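test_that("rotated tables are unit-step and invert with the right offset", {
  set.seed(70)
  for (rep in 1:20) {
    t <- rand_dna(sample(5:64, 1))
    tab <- build_fm_tables(t)
    Np <- tab$Np
    for (c in 1:4) {
      V <- tab$V[[c]]
      r <- sample(0:(Np - 1), 1)
      rt <- build_rotated_table(V, r)
      d <- diff(rt$vp)
      expect_true(all(d >= 0 & d <= 1))
      i <- seq_len(Np) - 1
      dest <- (i + r) %% Np
      rec <- rt$vp[dest + 1] + ifelse(i <= dest, rt$o, rt$obar)
      expect_equal(rec, V)
    }
    # zero rotation is the identity
    rt0 <- build_rotated_table(tab$V$A, 0)
    expect_equal(rt0$vp, tab$V$A)
    expect_equal(rt0$o, 0)
  }
})

test_that("coarse/residual split reassembles exactly with bounded residuals", {
  set.seed(71)
  for (rep in 1:15) {
    t <- rand_dna(sample(10:200, 1))
    tab <- build_fm_tables(t)
    rt <- build_rotated_table(tab$V$C, sample(0:tab$N, 1))
    for (m in c(2, 4, 8)) {
      M <- 2^m
      sp <- sample_split(rt$vp, M)
      expect_true(all(sp$R >= 0 & sp$R < M))
      i <- seq_along(rt$vp) - 1
      expect_equal(sp$Q[i %/% M + 1] + sp$R, rt$vp)
      expect_equal(length(sp$Q), ceiling(tab$Np / M))
    }
    # stride beyond the table: one coarse entry, residuals relative to it
    spb <- sample_split(rt$vp, 2^ceiling(log2(tab$Np + 1)))
    expect_equal(length(spb$Q), 1)
    expect_equal(spb$R, rt$vp - rt$vp[1])
  }
})

test_that("parameter validation enforces m < n and the ring bound", {
  env <- mpc_env(n = 16, seed = 1)
  expect_error(prepare_lpm2_db("ACGT", 2, m = 16, env = env), "smaller")
  env_small <- mpc_env(n = 8, seed = 1)
  expect_error(prepare_lpm2_db(rand_dna(200), 2, m = 4, env = env_small), "ring too small")
})

test_that("worked example matches the uncompressed protocol output", {
  env <- mpc_env(n = 16, seed = 2)
  db <- prepare_lpm2_db("TGCA", 3, m = 8, env = env)
  res <- lpm2_search("GCT", db, env)
  expect_equal(res$o, c(0, 0, 1))
  expect_equal(res$length, 2)
  expect_equal(res$match, "GC")
})

test_that("zero rotation masks disclose the true bound trajectory", {
  set.seed(72)
  t <- rand_dna(50)
  w <- rand_dna(5)
  env <- mpc_env(n = 16, seed = 3)
  db <- prepare_lpm2_db(t, 5, m = 8, env = env,
                        masks_f = rep(0, 5), masks_g = rep(0, 5))
  res <- lpm2_search(w, db, env)
  # the index opened in round j is the interval *entering* that round
  tab <- build_fm_tables(reverse_seq(t))
  iv <- c(0, tab$N)
  for (j in 1:5) {
    expect_equal(unname(res$disclosed[j, ]), iv)
    iv <- backward_extend(iv, substr(w, j, j), tab)
  }
})

test_that("compressed and uncompressed LPM agree with each other and the oracle", {
  set.seed(73)
  for (rep in 1:40) {
    t <- rand_dna(sample(10:200, 1))
    w <- rand_dna(sample(1:20, 1))
    e1 <- mpc_env(n = 16, seed = 900 + rep)
    r1 <- lpm_search(w, prepare_lpm_db(t, nchar(w), e1), e1)
    e2 <- mpc_env(n = 16, seed = 950 + rep)
    r2 <- lpm2_search(w, prepare_lpm2_db(t, nchar(w), m = 8, env = e2), e2)
    expect_identical(r1$o, r2$o)
    expect_equal(r2$length, oracle_lpm(w, t))
  }
})

test_that("share compression shrinks DB-preparation bytes as predicted", {
  prep_bytes <- function(N, compressed) {
    set.seed(74)
    t <- rand_dna(N)
    env <- mpc_env(n = 16, seed = 4)
    if (compressed) prepare_lpm2_db(t, 8, m = 8, env = env)
    else prepare_lpm_db(t, 8, env)
    mpc_transcript(env)$db_prep[["bytes"]]
  }
  for (N in c(500, 4000)) {
    plain <- prep_bytes(N, FALSE)
    comp <- prep_bytes(N, TRUE)
    expect_lt(comp, plain)
    # m/n = 1/2 plus the coarse-table and offset terms
    expect_lt(comp / plain, 0.60)
    expect_gt(comp / plain, 0.45)
  }
})

test_that("compressed search rounds are N-invariant and exceed the plain protocol's", {
  run <- function(N, ell, seed, compressed) {
    set.seed(seed)
    t <- rand_dna(N); w <- rand_dna(ell)
    env <- mpc_env(n = 16, seed = seed)
    if (compressed) lpm2_search(w, prepare_lpm2_db(t, ell, m = 8, env = env), env)
    else lpm_search(w, prepare_lpm_db(t, ell, env), env)
    mpc_transcript(env)$search
  }
  a <- run(100, 6, 1, TRUE)
  b <- run(2000, 6, 2, TRUE)
  expect_identical(a, b)
  plain <- run(100, 6, 3, FALSE)
  expect_gt(a[["rounds"]], plain[["rounds"]])
})
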