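#' Synthetic genome/query fixture generator
#'
#' Emulates the study conditions at desk scale: a uniform-random ACGT genome
#' of length `N` and queries of length `l` built by copying a genome
#' substring of random core length and appending random letters, so that
#' matches of known minimum length are planted. The ground truths recorded
#' with each query (LPM length, LMEM length and left position) are not the
#' planted parameters but are re-derived by brute-force scans at generation
#' time, under the cyclic occurrence semantics of the sentinel-free index.
#' Generation is deterministic under `seed`.
#'
#' @param N Genome length (`N >= 4`; genomes are redrawn until all four
#'   letters occur, a precondition of the maximal-exact-match walk).
#' @param ell Query length, `1 <= ell <= N`.
#' @param n_queries Number of queries.
#' @param seed Integer seed.
#' @return Object of class `pm_fixture`: `genome`, and a data.frame `queries`
#'   with columns `query`, `lpm`, `lmem`, `lmem_pos`.
#' @export
generate_fixture <- function(N, ell, n_queries = 1, seed = 1) {
  if (!(N >= ell && ell >= 1)) stop("need N >= ell >= 1")
  set.seed(seed)
  genome <- random_genome(N)
  qs <- vapply(seq_len(n_queries), function(i) {
    core_len <- sample.int(ell, 1)
    start <- sample.int(N - core_len + 1, 1)
    core <- substr(genome, start, start + core_len - 1)
    tail_len <- ell - core_len
    paste0(core, paste(sample(DNA_LETTERS, tail_len, TRUE), collapse = ""))
  }, "")
  truths <- lapply(qs, function(w) {
    lm <- naive_lmem_scan(w, genome)
    data.frame(query = w, lpm = naive_lpm_scan(w, genome),
               lmem = lm$length, lmem_pos = lm$position)
  })
  structure(list(genome = genome, queries = do.call(rbind, truths),
                 N = N, ell = ell, seed = seed),
            class = "pm_fixture")
}

random_genome <- function(N) {
  repeat {
    g <- sample(DNA_LETTERS, N, TRUE)
    if (N < 4 || length(unique(g)) == 4) return(paste(g, collapse = ""))
  }
}

#' Brute-force occurrence scans (test oracles)
#'
#' Cyclic occurrence semantics: a pattern occurs in `t` if it is a substring
#' of `t` read circularly (matches may span the rotation seam), matching the
#' sentinel-free index convention.
#'
#' @param sub,w Pattern / query strings.
#' @param t Database string.
#' @name naive-scans
#' @export
occurs_cyclic <- function(sub, t) {
  if (nchar(sub) == 0) return(TRUE)
  grepl(sub, substr(strrep(t, ceiling(1 + nchar(sub) / nchar(t))),
                    1, nchar(t) + nchar(sub) - 1), fixed = TRUE)
}

#' @rdname naive-scans
#' @export
naive_lpm_scan <- function(w, t) {
  l <- nchar(w)
  k <- 0
  while (k < l && occurs_cyclic(substr(w, 1, k + 1), t)) k <- k + 1
  k
}

#' @rdname naive-scans
#' @export
naive_lmem_scan <- function(w, t) {
  l <- nchar(w)
  best <- 0; bestp <- 0
  for (i in seq_len(l)) {
    k <- best # a longer match must beat the current best
    while (i + k <= l) {
      if (!occurs_cyclic(substr(w, i, i + k), t)) break
      if (k + 1 > best) { best <- k + 1; bestp <- i - 1 }
      k <- k + 1
    }
  }
  list(length = best, position = bestp)
}

#' Network environments and the delay model
#'
#' The end-to-end search delay over a network is estimated as
#' `D/k + e*T/1000` seconds for `D` transferred bytes, bandwidth `k`
#' (bytes/s), latency `e` (ms) and `T` communication rounds. Three named
#' presets are provided: LAN (0.2 ms, 10 Gbps), WAN1 (10 ms, 100 Mbps) and
#' WAN2 (50 ms, 10 Mbps).
#'
#' @param name Preset name, or use `latency_ms`/`bandwidth_bps` directly.
#' @param latency_ms,bandwidth_bps Custom environment parameters (bandwidth
#'   in bits per second).
#' @return Object of class `net_env` with `latency_ms` and `bandwidth_Bps`
#'   (bytes per second).
#' @examples
#' estimate_delay(net_environment("WAN2"), rounds = 100, bytes = 0) # 5 s
#' @export
net_environment <- function(name = NULL, latency_ms = NULL, bandwidth_bps = NULL) {
  presets <- list(
    LAN = c(0.2, 10e9),
    WAN1 = c(10, 100e6),
    WAN2 = c(50, 10e6)
  )
  if (!is.null(name)) {
    if (!name %in% names(presets)) stop("unknown network preset: ", name)
    latency_ms <- presets[[name]][1]
    bandwidth_bps <- presets[[name]][2]
  }
  stopifnot(!is.null(latency_ms), !is.null(bandwidth_bps))
  if (bandwidth_bps <= 0) stop("bandwidth must be positive")
  structure(list(name = name %||% "custom", latency_ms = latency_ms,
                 bandwidth_Bps = bandwidth_bps / 8),
            class = "net_env")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname net_environment
#' @param env A `net_env`.
#' @param rounds Communication rounds `T`.
#' @param bytes Transferred bytes `D`.
#' @export
estimate_delay <- function(env, rounds, bytes) {
  stopifnot(inherits(env, "net_env"))
  bytes / env$bandwidth_Bps + env$latency_ms * rounds / 1000
}

#' Serialize a transcript as JSON
#'
#' @param env An [mpc_env()].
#' @param file Optional path; if omitted the JSON string is returned.
#' @export
transcript_json <- function(env, file = NULL) {
  tr <- lapply(mpc_transcript(env), as.list)
  js <- jsonlite::toJSON(tr, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

#' Benchmark harness over an (N, l) grid
#'
#' For each grid cell: generate a fixture, run DB preparation and one search
#' with the requested protocol, and report per-phase transcript rounds/bytes,
#' wall-clock time, and the estimated network delay of the search phase.
#' Mirrors the structure of the published experiment at desk scale — the
#' point being that search-phase rounds and bytes do not move with `N`.
#'
#' @param protocol One of `"ssrot"`, `"lpm"`, `"lmem"`, `"lpm2"`.
#' @param N_grid,ell_grid Vectors of database / query lengths.
#' @param net A [net_environment()] (default WAN1).
#' @param seed Integer seed.
#' @param n Ring width; default 16 for `N < 1e5`, else 32.
#' @param m Residual width for `"lpm2"`.
#' @return data.frame, one row per cell.
#' @export
run_experiment <- function(protocol = c("lpm", "lmem", "lpm2", "ssrot"),
                           N_grid, ell_grid, net = net_environment("WAN1"),
                           seed = 1, n = NULL, m = 8) {
  protocol <- match.arg(protocol)
  grid <- expand.grid(N = N_grid, ell = ell_grid)
  if (nrow(grid) == 0) {
    return(data.frame(protocol = character(), N = numeric(), ell = numeric(),
                      n = integer(), offline_bytes = numeric(),
                      db_prep_bytes = numeric(), search_rounds = numeric(),
                      search_bytes = numeric(), prep_s = numeric(),
                      search_s = numeric(), est_delay_s = numeric()))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    N <- grid$N[i]; ell <- grid$ell[i]
    nw <- n %||% default_ring_width(N)
    fx <- generate_fixture(N, ell, 1, seed + i)
    env <- mpc_env(n = nw, seed = seed + 1000 + i)
    w <- fx$queries$query[1]
    t_prep <- system.time(db <- switch(protocol,
      ssrot = prepare_ssrot(sample.int(N, N) - 1, max(ell, 2), env),
      lpm = prepare_lpm_db(fx$genome, ell, env),
      lmem = prepare_lmem_db(fx$genome, ell, env),
      lpm2 = prepare_lpm2_db(fx$genome, ell, m = m, env = env)
    ))[["elapsed"]]
    t_search <- system.time(switch(protocol,
      ssrot = ssrot_search(db, 0, env),
      lpm = lpm_search(w, db, env),
      lmem = lmem_search(w, db, env),
      lpm2 = lpm2_search(w, db, env)
    ))[["elapsed"]]
    tr <- mpc_transcript(env)
    data.frame(
      protocol = protocol, N = N, ell = ell, n = nw,
      offline_bytes = tr$offline[["bytes"]],
      db_prep_bytes = tr$db_prep[["bytes"]],
      search_rounds = tr$search[["rounds"]],
      search_bytes = tr$search[["bytes"]],
      prep_s = t_prep, search_s = t_search,
      est_delay_s = estimate_delay(net, tr$search[["rounds"]], tr$search[["bytes"]])
    )
  })
  do.call(rbind, rows)
}

#' Default ring width policy
#'
#' 16 bits below `N = 1e5`, 32 bits above, following the published runs; the
#' protocols additionally validate `2^n >= 4 N'`.
#'
#' @param N Database length.
#' @export
default_ring_width <- function(N) if (N < 1e5) 16L else 32L
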