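## Plaintext index construction and search. These tables are both the source
## material the database holder masks for the secure protocols and the
## correctness oracle the protocol tests compare against.

DNA_LETTERS <- c("A", "C", "G", "T")

#' Validate and encode a DNA string
#'
#' Only the ordered alphabet A < C < G < T is accepted.
#'
#' @param s A single string over ACGT.
#' @return Integer codes 1..4.
#' @export
dna_codes <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  raw <- as.integer(charToRaw(s))
  codes <- match(raw, c(65L, 67L, 71L, 84L)) # A C G T
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("non-ACGT symbol '%s' at position %d (1-based)",
                 rawToChar(as.raw(raw[bad])), bad))
  }
  codes
}

codes_to_dna <- function(codes) paste(DNA_LETTERS[codes], collapse = "")

#' Reverse a DNA string
#' @param s String over ACGT.
#' @export
reverse_seq <- function(s) codes_to_dna(rev(dna_codes(s)))

# rotation array by circular prefix doubling (0-based positions): sorts the
# N cyclic rotations, breaking ties between equal rotations (periodic
# strings) by position. This is the sentinel-free order under which
# L[i] = S[(SA[i]-1) mod N] gives an exact LF mapping for cyclic matching.
suffix_array <- function(codes) {
  N <- length(codes)
  if (N == 1) return(0L)
  rk <- codes
  k <- 1L
  idx0 <- seq_len(N) - 1L
  while (k < N) {
    key2 <- rk[(idx0 + k) %% N + 1L]
    o <- order(rk, key2, method = "radix")
    r1 <- rk[o]
    r2 <- key2[o]
    new_rk <- cumsum(c(1L, as.integer(r1[-1] != r1[-N] | r2[-1] != r2[-N])))
    rk[o] <- new_rk
    if (new_rk[N] == N) break
    k <- 2L * k
  }
  order(rk, idx0) - 1L
}

#' Build FM-index lookup tables
#'
#' Constructs, for a sequence `S` of length `N`: the suffix array, the
#' sentinel-free cyclic BWT `L[i] = S[(SA[i] - 1 + N) mod N]`, and the four
#' per-letter lookup vectors `V_c` of length `N' = N + 1` with
#' `V_c[i] = LF_c(i, S) = CF_c(L) + Rank_c(i, L)`. Backward search is then a
#' pure table lookup ([backward_extend()]). Coordinates are 0-based and
#' intervals half-open.
#'
#' Callers running a prefix search supply the *reversed* database themselves
#' (see [plaintext_lpm()], which handles the reversal).
#'
#' @param s Sequence string over ACGT.
#' @return Object of class `fm_tables`: fields `N`, `Np`, `seq` (codes),
#'   `sa` (0-based), `bwt` (codes), and `V` (list `A`,`C`,`G`,`T`; each a
#'   length-`N+1` vector, entry `i` of the table is element `i + 1`).
#' @examples
#' tab <- build_fm_tables("ACGT")
#' tab$V$G[1] # V_G[0] = 2
#' @export
build_fm_tables <- function(s) {
  codes <- dna_codes(s)
  N <- length(codes)
  sa <- suffix_array(codes)
  bwt <- codes[(sa - 1L) %% N + 1L]
  counts <- tabulate(bwt, nbins = 4)
  cf <- c(0, cumsum(counts))[1:4]
  V <- lapply(1:4, function(c) cf[c] + c(0, cumsum(bwt == c)))
  names(V) <- DNA_LETTERS
  structure(list(N = N, Np = N + 1L, seq = codes, sa = sa, bwt = bwt, V = V),
            class = "fm_tables")
}

#' @export
print.fm_tables <- function(x, ...) {
  cat(sprintf("<fm_tables N=%d, BWT=%s%s>\n", x$N,
              codes_to_dna(x$bwt[seq_len(min(x$N, 40))]),
              if (x$N > 40) "..." else ""))
  invisible(x)
}

#' One backward-search step
#'
#' Maps the suffix-array interval of pattern `x` to the interval of `cx` via
#' `[f', g') = [V_c[f], V_c[g])`.
#'
#' @param iv Numeric `c(f, g)`, half-open 0-based interval with
#'   `0 <= f <= g <= N`.
#' @param letter One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param tab An `fm_tables`.
#' @return The extended interval `c(f', g')`.
#' @export
backward_extend <- function(iv, letter, tab) {
  V <- tab$V[[letter]]
  c(V[iv[1] + 1], V[iv[2] + 1])
}

#' LCP array with previous/next-smaller-value indices
#'
#' `LCP[i]` is the longest-common-prefix length of the suffixes at `SA[i-1]`
#' and `SA[i]` (Kasai's algorithm); the boundary entries `LCP[0]` and `LCP[N]`
#' are 0. `PSV[i]` / `NSV[i]` are the nearest positions left / right of `i`
#' with a strictly smaller LCP value, clamped to `0` / `N` when absent, which
#' is what the parent-interval jump of a maximal-exact-match walk needs.
#' All three arrays have length `N + 1` so they can be masked alongside the
#' `V_c` tables.
#'
#' @param tab An `fm_tables`.
#' @return Object of class `lcp_structures` with fields `lcp`, `psv`, `nsv`
#'   (length `N + 1`, 0-based entry `i` at index `i + 1`).
#' @export
build_lcp_psv_nsv <- function(tab) {
  N <- tab$N
  codes <- tab$seq
  sa <- tab$sa
  lcp <- numeric(N + 1) # entry i+1 = LCP[i]; boundaries 0
  if (N > 1) {
    # adjacent-rotation comparison, capped at N: the cyclic analogue of the
    # LCP array, consistent with the rotation-sorted index so that
    # lcp-intervals coincide with the intervals backward search produces.
    # Cheap for genomic data where the expected common prefix is ~ log4(N).
    for (r in 1:(N - 1L)) {
      a <- sa[r] # 0-based starts of the two adjacent rotations
      b <- sa[r + 1L]
      h <- 0L
      while (h < N && codes[(a + h) %% N + 1L] == codes[(b + h) %% N + 1L]) h <- h + 1L
      lcp[r + 1L] <- h
    }
  }
  psv <- numeric(N + 1)
  nsv <- numeric(N + 1)
  # stack scans over positions 0..N (values at i+1)
  stk <- integer(0)
  for (i in 0:N) {
    while (length(stk) && lcp[stk[length(stk)] + 1L] >= lcp[i + 1L]) stk <- stk[-length(stk)]
    psv[i + 1L] <- if (length(stk)) stk[length(stk)] else 0
    stk <- c(stk, i)
  }
  stk <- integer(0)
  for (i in N:0) {
    while (length(stk) && lcp[stk[length(stk)] + 1L] >= lcp[i + 1L]) stk <- stk[-length(stk)]
    # NSV is defined over j < N; clamp to N when no smaller value follows
    nsv[i + 1L] <- if (length(stk) && stk[length(stk)] < N) stk[length(stk)] else N
    stk <- c(stk, i)
  }
  structure(list(lcp = lcp, psv = psv, nsv = nsv, N = N), class = "lcp_structures")
}

#' Parent lcp-interval
#'
#' Jumps from the interval `[f, g)` to its parent lcp-interval:
#' `[PSV[f], NSV[f])` when `LCP[g] <= LCP[f]`, else `[PSV[g], NSV[g])`. The
#' returned `value` is the parent's lcp-value `max(LCP[f], LCP[g])`. The root
#' interval `[0, N)` is its own parent with value 0.
#'
#' @param iv Numeric `c(f, g)`.
#' @param lcp An `lcp_structures`.
#' @return List with `iv` (parent interval) and `value` (its lcp-value).
#' @export
parent_interval <- function(iv, lcp) {
  f <- iv[1]; g <- iv[2]
  if (f == 0 && g == lcp$N) return(list(iv = c(0, lcp$N), value = 0))
  lf <- lcp$lcp[f + 1]; lg <- lcp$lcp[g + 1]
  if (lg <= lf) {
    list(iv = c(lcp$psv[f + 1], lcp$nsv[f + 1]), value = max(lf, lg))
  } else {
    list(iv = c(lcp$psv[g + 1], lcp$nsv[g + 1]), value = max(lf, lg))
  }
}

#' Longest prefix match (plaintext reference)
#'
#' Length of the longest prefix of `w` occurring in `T`, computed by backward
#' search over the FM tables of the reversed database (so the match is
#' extended `w[0], w[1], ...`).
#'
#' @param w Query string over ACGT.
#' @param t Database string over ACGT, or a prebuilt `fm_tables` of the
#'   *reversed* database.
#' @return Integer match length in `[0, nchar(w)]`.
#' @export
plaintext_lpm <- function(w, t) {
  tab <- if (inherits(t, "fm_tables")) t else build_fm_tables(reverse_seq(t))
  wl <- strsplit(w, "")[[1]]
  if (!all(wl %in% DNA_LETTERS)) stop("query contains non-ACGT symbols")
  iv <- c(0, tab$N)
  for (k in seq_along(wl)) {
    iv <- backward_extend(iv, wl[k], tab)
    if (iv[1] >= iv[2]) return(k - 1L)
  }
  length(wl)
}

#' Longest maximal exact match (plaintext reference)
#'
#' Finds the longest substring of `w` occurring anywhere in `T` with a single
#' left-to-right walk: extend the current match by backward search on the
#' reversed database; on failure jump to the parent lcp-interval, which
#' truncates the match to the parent's lcp-value `c` and advances the left
#' end to `p + m - c`. At most `2*nchar(w)` steps. Of equally long matches
#' the leftmost-ending one is reported (strict-greater maximum update).
#'
#' @inheritParams plaintext_lpm
#' @param lcp Optional prebuilt `lcp_structures` matching `t`.
#' @return List with `length` and `position` (0-based left end in `w`).
#' @export
plaintext_lmem <- function(w, t, lcp = NULL) {
  tab <- if (inherits(t, "fm_tables")) t else build_fm_tables(reverse_seq(t))
  if (is.null(lcp)) lcp <- build_lcp_psv_nsv(tab)
  wl <- strsplit(w, "")[[1]]
  if (!all(wl %in% DNA_LETTERS)) stop("query contains non-ACGT symbols")
  l <- length(wl)
  iv <- c(0, tab$N)
  m <- 0; right <- 0; p <- 0
  best <- 0; bestp <- 0
  while (right < l) {
    iv2 <- backward_extend(iv, wl[right + 1], tab)
    if (iv2[1] < iv2[2]) {
      iv <- iv2; m <- m + 1; right <- right + 1
      if (m > best) { best <- m; bestp <- right - m }
    } else if (m == 0) {
      right <- right + 1; p <- p + 1 # letter absent from the database
    } else {
      pr <- parent_interval(iv, lcp)
      p <- p + m - pr$value
      m <- pr$value
      iv <- pr$iv
    }
  }
  list(length = best, position = bestp)
}
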