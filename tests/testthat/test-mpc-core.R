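test_that("share/reconst round-trips the whole ring", {
  env <- mpc_env(n = 3, seed = 1)
  for (x in 0:7) expect_equal(mpc_reconst(env, mpc_share(env, x)), x)
  env16 <- mpc_env(n = 16, seed = 2)
  xs <- sample(0:65535, 1e4, replace = TRUE)
  expect_equal(mpc_reconst(env16, mpc_share(env16, xs)), xs)
  expect_error(mpc_share(env, 8), "range")
  expect_error(mpc_share(env, -1), "range")
})

test_that("individual shares of a secret are uniform", {
  env <- mpc_env(n = 8, seed = 3)
  s0 <- mpc_share(env, rep(42, 2e4))$s0
  expect_true(uniform_chisq_ok(tabulate(s0 + 1, nbins = 256)))
})

test_that("local addition, subtraction and scalar multiplication agree with ring arithmetic", {
  env <- mpc_env(n = 16, seed = 4)
  xs <- sample(0:65535, 500, TRUE); ys <- sample(0:65535, 500, TRUE)
  x <- mpc_share(env, xs); y <- mpc_share(env, ys)
  before <- mpc_transcript(env)
  expect_equal(mpc_reconst(env, mpc_add(x, y), to = "alice"), (xs + ys) %% 2^16)
  expect_equal(mpc_reconst(env, mpc_sub(x, y), to = "alice"), (xs - ys) %% 2^16)
  expect_equal(mpc_reconst(env, mpc_scalar_mul(12345, x), to = "alice"),
               (12345 * xs) %% 2^16)
  expect_equal(mpc_reconst(env, mpc_add_const(x, 7), to = "alice"), (xs + 7) %% 2^16)
  # zero communication for local gates
  expect_identical(mpc_transcript(env), before)
  # x + 0 = x
  zero <- public_share(0, 16)
  expect_equal(mpc_reconst(env, mpc_add(x, zero), to = "alice"), xs)
})

test_that("Beaver multiplication matches the plaintext product", {
  env <- mpc_env(n = 16, seed = 5)
  xs <- as.numeric(sample(0:65535, 1000, TRUE))
  ys <- as.numeric(sample(0:65535, 1000, TRUE))
  z <- mpc_mult(env, mpc_share(env, xs), mpc_share(env, ys))
  expect_equal(mpc_reconst(env, z, to = "alice"), (xs * ys) %% 2^16)
  # annihilator
  z0 <- mpc_mult(env, mpc_share(env, xs[1:50]), public_share(rep(0, 50), 16))
  expect_equal(mpc_reconst(env, z0, to = "alice"), rep(0, 50))
  # wide ring: products that overflow 2^53 must still reduce exactly
  env32 <- mpc_env(n = 32, seed = 6)
  a <- c(2^31 + 12345, 4294967295); b <- c(2^31 + 999, 4294967295)
  z32 <- mpc_mult(env32, mpc_share(env32, a), mpc_share(env32, b))
  expect_equal(mpc_reconst(env32, z32, to = "alice"),
               c((12345 * 999 + 2^31 * (12345 + 999)) %% 2^32, 1))
})

test_that("an explicit Beaver triple cannot be consumed twice", {
  env <- mpc_env(n = 16, seed = 7)
  bt <- beaver_triple(env)
  x <- mpc_share(env, 3); y <- mpc_share(env, 9)
  expect_equal(mpc_reconst(env, mpc_mult(env, x, y, triple = bt), to = "alice"), 27)
  expect_error(mpc_mult(env, x, y, triple = bt), "consumed")
})

test_that("trusted initializer distributes valid triples and linear offline bytes", {
  env <- mpc_env(n = 16, seed = 8)
  trusted_init(env, count_arith = 64, count_bool = 32)
  expect_identical(triple_pool_size(env), c(arith = 64L, bool = 32L))
  p <- env$pool_arith
  expect_equal((reveal(p$a) * reveal(p$b)) %% 2^16, reveal(p$c))
  pb <- env$pool_bool
  expect_equal(((pb$a$b0 + pb$a$b1) * (pb$b$b0 + pb$b$b1)) %% 2,
               (pb$c$b0 + pb$c$b1) %% 2)
  # empty request leaves pools untouched, bytes grow linearly in the count
  b1 <- mpc_transcript(env)$offline[["bytes"]]
  trusted_init(env, count_arith = 0, count_bool = 0)
  expect_equal(mpc_transcript(env)$offline[["bytes"]], b1)
  trusted_init(env, count_arith = 64)
  b2 <- mpc_transcript(env)$offline[["bytes"]]
  trusted_init(env, count_arith = 128)
  b3 <- mpc_transcript(env)$offline[["bytes"]]
  expect_equal(b3 - b2, 2 * (b2 - b1))
})

test_that("opened values inside multiplication are uniformly masked", {
  env <- mpc_env(n = 8, seed = 9)
  env$capture_opens <- TRUE
  n_trials <- 12000
  x <- mpc_share(env, rep(3, n_trials)) # fixed secrets, fresh triples
  y <- mpc_share(env, rep(200, n_trials))
  invisible(mpc_mult(env, x, y))
  opened <- env$opens[[length(env$opens)]]$values
  xp <- opened[seq_len(n_trials)]
  yp <- opened[n_trials + seq_len(n_trials)]
  expect_true(uniform_chisq_ok(tabulate(xp + 1, nbins = 256)))
  expect_true(uniform_chisq_ok(tabulate(yp + 1, nbins = 256)))
})

test_that("Boolean gates realize their truth tables", {
  env <- mpc_env(n = 16, seed = 10)
  combos <- expand.grid(x = 0:1, y = 0:1)
  x <- bool_share(env, combos$x); y <- bool_share(env, combos$y)
  expect_equal(bool_reconst(env, bool_xor(x, y), to = "alice"), (combos$x + combos$y) %% 2)
  expect_equal(bool_reconst(env, bool_and(env, x, y), to = "alice"), combos$x * combos$y)
  expect_equal(bool_reconst(env, bool_or(env, x, y), to = "alice"),
               as.numeric(combos$x | combos$y))
  expect_equal(bool_reconst(env, bool_not(x), to = "alice"), 1 - combos$x)
  expect_equal(bool_reconst(env, bool_not(bool_not(x)), to = "alice"), combos$x)
})

test_that("search transcripts are identical across runs and across secret inputs", {
  run <- function(w, t, seed) {
    env <- mpc_env(n = 16, seed = seed)
    db <- prepare_lpm_db(t, nchar(w), env)
    lpm_search(w, db, env)
    mpc_transcript(env)$search
  }
  set.seed(11)
  t1 <- rand_dna(60); t2 <- rand_dna(60)
  a <- run("GATTAC", t1, 1)
  b <- run("GATTAC", t1, 99) # same inputs, different randomness
  c <- run("CCCCCC", t2, 5)  # different secrets, same sizes
  expect_identical(a, b)
  expect_identical(a, c)
})
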