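test_that("FM tables on small hand-checked sequences", {
  tab <- build_fm_tables("ACGT")
  expect_equal(tab$sa, 0:3)
  expect_equal(privmatch:::codes_to_dna(tab$bwt), "TACG")
  expect_equal(tab$V$G[1], 2) # V_G[0]
  expect_equal(tab$V$A, c(0, 0, 1, 1, 1))
  tabA <- build_fm_tables("AAAA")
  expect_equal(tabA$V$A, c(0, 1, 2, 3, 4))
  expect_true(all(tabA$V$C == 4) && all(tabA$V$T == 4))
  expect_error(build_fm_tables("ACGN"), "position 4")
})

test_that("per-letter tables are unit-step and jointly cover the string", {
  set.seed(30)
  for (rep in 1:10) {
    tab <- build_fm_tables(rand_dna(sample(5:150, 1)))
    steps <- 0
    for (c in 1:4) {
      d <- diff(tab$V[[c]])
      expect_true(all(d >= 0 & d <= 1))
      steps <- steps + tab$V[[c]][tab$Np] - tab$V[[c]][1]
    }
    expect_equal(steps, tab$N)
  }
})

test_that("backward search interval width counts cyclic occurrences", {
  set.seed(31)
  for (rep in 1:40) {
    t <- rand_dna(sample(5:200, 1))
    tab <- build_fm_tables(t)
    pat <- rand_dna(sample(1:6, 1))
    iv <- c(0, tab$N)
    for (k in nchar(pat):1) iv <- backward_extend(iv, substr(pat, k, k), tab)
    expect_equal(iv[2] - iv[1], oracle_count(pat, t))
  }
  # the empty pattern is the identity start, and widths only shrink
  tab <- build_fm_tables("GATTACA")
  iv <- c(0, tab$N)
  for (l in c("A", "C", "A")) {
    iv2 <- backward_extend(iv, l, tab)
    expect_lte(iv2[2] - iv2[1], iv[2] - iv[1])
    iv <- iv2
  }
})

test_that("LCP/PSV/NSV match brute-force definitions", {
  set.seed(32)
  for (rep in 1:12) {
    t <- rand_dna(sample(4:64, 1))
    tab <- build_fm_tables(t)
    st <- build_lcp_psv_nsv(tab)
    N <- tab$N
    lcp_bf <- numeric(N + 1)
    for (i in seq_len(N - 1)) {
      lcp_bf[i + 1] <- oracle_rotation_lcp(t, tab$sa[i], tab$sa[i + 1])
    }
    expect_equal(st$lcp, lcp_bf)
    for (i in 0:N) {
      smaller_left <- which(st$lcp[seq_len(i)] < st$lcp[i + 1]) - 1
      expect_equal(st$psv[i + 1], if (length(smaller_left)) max(smaller_left) else 0)
      cand <- if (i < N) i + which(st$lcp[seq(i + 1, N) + 1] < st$lcp[i + 1]) else integer(0)
      cand <- cand[cand < N]
      expect_equal(st$nsv[i + 1], if (length(cand)) min(cand) else N)
    }
  }
  # adjacent rotations of a 4-letter de Bruijn-like string share nothing
  st0 <- build_lcp_psv_nsv(build_fm_tables("ACGT"))
  expect_equal(st0$lcp, rep(0, 5))
})

test_that("parent_interval climbs to the enclosing lcp-interval", {
  set.seed(33)
  for (rep in 1:15) {
    t <- rand_dna(sample(8:64, 1))
    tab <- build_fm_tables(t)
    st <- build_lcp_psv_nsv(tab)
    pat <- rand_dna(sample(2:5, 1))
    iv <- c(0, tab$N)
    for (k in nchar(pat):1) iv <- backward_extend(iv, substr(pat, k, k), tab)
    if (iv[1] >= iv[2]) next
    pr <- parent_interval(iv, st)
    # contains the child and is no narrower
    expect_lte(pr$iv[1], iv[1])
    expect_gte(pr$iv[2], iv[2])
    expect_equal(pr$value, max(st$lcp[iv[1] + 1], st$lcp[iv[2] + 1]))
    # all rotations inside the parent share a prefix of its lcp-value
    if (pr$iv[2] - pr$iv[1] >= 2 && pr$value > 0) {
      for (r in (pr$iv[1] + 1):(pr$iv[2] - 1)) {
        expect_gte(oracle_rotation_lcp(t, tab$sa[r], tab$sa[r + 1]), pr$value)
      }
    }
  }
  # root is its own parent
  tab <- build_fm_tables("GATTACA")
  st <- build_lcp_psv_nsv(tab)
  expect_equal(parent_interval(c(0, 7), st), list(iv = c(0, 7), value = 0))
})

test_that("plaintext LPM and LMEM agree with naive scans", {
  expect_equal(plaintext_lpm("GCT", "TGCA"), 2)
  expect_equal(plaintext_lpm("GCA", "TGCA"), 3) # full query occurs
  set.seed(34)
  for (rep in 1:1000) {
    t <- rand_dna(sample(10:200, 1))
    w <- rand_dna(sample(1:20, 1))
    tab <- build_fm_tables(reverse_seq(t))
    st <- build_lcp_psv_nsv(tab)
    expect_equal(plaintext_lpm(w, tab), oracle_lpm(w, t))
    got <- plaintext_lmem(w, tab, lcp = st)
    want <- oracle_lmem(w, t)
    expect_equal(got$length, want$length)
    if (got$length > 0) {
      expect_true(oracle_occurs(substr(w, got$position + 1,
                                       got$position + got$length), t))
    }
  }
})

test_that("plaintext LMEM handles degenerate inputs", {
  full <- plaintext_lmem("GCAT", "TGCATA")
  expect_equal(full, list(length = 4, position = 0))
  none <- plaintext_lmem("GT", "ACACAC")
  expect_equal(none, list(length = 0, position = 0))
  periodic <- plaintext_lmem("ACAC", "ACACACAC")
  expect_equal(periodic$length, 4)
})
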