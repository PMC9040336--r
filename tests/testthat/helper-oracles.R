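# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own scan functions and FM machinery.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# genome guaranteed to contain all four letters (precondition of the
# maximal-exact-match walk)
rand_genome <- function(n) {
  stopifnot(n >= 4)
  repeat {
    s <- sample(c("A", "C", "G", "T"), n, TRUE)
    if (length(unique(s)) == 4) return(paste(s, collapse = ""))
  }
}

# cyclic occurrence: pattern matches the circular string t
oracle_occurs <- function(sub, t) {
  if (nchar(sub) == 0) return(TRUE)
  win <- substr(strrep(t, ceiling(1 + nchar(sub) / nchar(t))),
                1, nchar(t) + nchar(sub) - 1)
  grepl(sub, win, fixed = TRUE)
}

# number of cyclic occurrence start positions of `sub` in `t`
oracle_count <- function(sub, t) {
  N <- nchar(t)
  if (nchar(sub) == 0) return(N)
  win <- strrep(t, ceiling(1 + nchar(sub) / N))
  sum(vapply(seq_len(N), function(i) {
    substr(win, i, i + nchar(sub) - 1) == sub
  }, TRUE))
}

oracle_lpm <- function(w, t) {
  k <- 0
  while (k < nchar(w) && oracle_occurs(substr(w, 1, k + 1), t)) k <- k + 1
  k
}

# full (i, j) enumeration of substring matches
oracle_lmem <- function(w, t) {
  l <- nchar(w)
  best <- 0; bestp <- 0
  for (i in seq_len(l)) {
    for (j in i:l) {
      if (j - i + 1 <= best) next
      if (oracle_occurs(substr(w, i, j), t)) {
        best <- j - i + 1; bestp <- i - 1
      } else break
    }
  }
  list(length = best, position = bestp)
}

# pairwise longest common prefix of two rotations of t (capped at N)
oracle_rotation_lcp <- function(t, a, b) {
  N <- nchar(t)
  dd <- strrep(t, 2)
  ra <- substr(dd, a + 1, a + N)
  rb <- substr(dd, b + 1, b + N)
  h <- 0
  while (h < N && substr(ra, h + 1, h + 1) == substr(rb, h + 1, h + 1)) h <- h + 1
  h
}

# chi-square uniformity test statistic exceeds the alpha critical value?
uniform_chisq_ok <- function(counts, alpha = 0.001) {
  k <- length(counts)
  expected <- sum(counts) / k
  x2 <- sum((counts - expected)^2 / expected)
  x2 < stats::qchisq(1 - alpha, df = k - 1)
}

# glass-box reconstruction of a shared vector (test instrumentation only)
reveal <- function(sh) (sh$s0 + sh$s1) %% 2^attr(sh, "n")
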