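# privmatch

Privacy-preserving variable-length substring matching over secret shares —
an R simulation of two-party secure search between a query holder and a
genome database holder.

## The problem

A researcher holds a short DNA query `w` (length ℓ); a data steward holds a
long database sequence `T` (length N). The researcher should learn the
**longest prefix match** (LPM: the longest prefix of `w` occurring in `T`)
or the **longest maximal exact match** (LMEM: the longest substring of `w`
occurring in `T`, with its position in `w`) — and nothing else. The steward
learns nothing. Both inputs are split with 2-out-of-2 additive secret
sharing over Z\_{2^n} and processed by two non-colluding computing nodes in
the semi-honest model, with the steward doubling as trusted initializer
(Beaver triples and correlated randomness, distributed offline).

The package is aimed at people studying secure-computation protocol
structure: it simulates all four roles in-process and records a faithful
per-phase **transcript** (communication rounds and bytes between the nodes)
so the protocols' defining property can be measured — after DB preparation,
*search cost is independent of the database length N*.

## What is inside

- **MPC core** — additive sharing, Beaver-triple multiplication, Boolean
  gates, and dealer-assisted Equality / Comp / CastUp / B2A / Choose
  subprotocols with input-independent communication patterns.
- **FM-index tables** — sentinel-free (rotation-order) suffix/BWT tables
  `V_c[i] = LF_c(i)` turning backward search into table lookups, plus
  cyclic LCP with PSV/NSV for parent-interval jumps; also the plaintext
  LPM/LMEM reference implementations used as oracles.
- **ss-ROT** — secret-shared recursive oblivious transfer: masked, rotated
  table chains `R^j[i] = (V[(i - r^{j-1}) mod N] + r^j) mod N` that let the
  nodes evaluate `V[V[...V[p0]]]` while opening only uniformly masked
  indices.
- **Secure LPM** (ℓ rounds), **Secure LMEM** (2ℓ−1 rounds with masked
  LCP/PSV/NSV table families and an oblivious match-state machine), and
  **compressed-share LPM** (unit-step table rotation + coarse/residual
  split, trading extra CastUp/Comp rounds for ~n/m-fold smaller database
  shares).
- **Workbench** — fixture generator with brute-force-verified truths,
  FASTA and share-container I/O, a network-delay model
  `D/k + e·T/1000` with LAN/WAN presets, a benchmark grid harness, and a
  CLI (`exec/privmatch`).

## Worked example

The textbook-sized scenario: database `T = TGCA` (the index is built on its
reversal `ACGT`), query `w = GCT`.

```r
library(privmatch)
env <- mpc_env(n = 16, seed = 1)
db  <- prepare_lpm_db("TGCA", ell = 3, env)
res <- lpm_search("GCT", db, env)
res$o      # 0 0 1
res$match  # "GC"
mpc_transcript(env)$search
# rounds  bytes
#     27    432
```

The backward search survives `G` and `GC` and collapses at the third
reference, so the query holder's result vector is `o = (0, 0, 1)`: the
longest prefix of `GCT` in `TGCA` is `GC`, length 2. The 27 search rounds
and 432 bytes depend only on ℓ and the ring width — never on N:

```r
run_experiment("lpm", N_grid = c(1000, 10000), ell_grid = 25, seed = 1)
#     N ell db_prep_bytes search_rounds search_bytes est_delay_s
#  1000  25        400450           225         3600    2.250288
# 10000  25       4000450           225         3600    2.250288
```

DB preparation grows with N; the search columns do not move. The same
holds for LMEM:

```r
env2 <- mpc_env(n = 16, seed = 2)
db2  <- prepare_lmem_db("GCACTAGAGGGAACAG", ell = 6, env2)
lmem_search("TTAGAG", db2, env2)[c("length", "position", "match")]
# $length 5, $position 1, $match "TAGAG"
```

The longest substring of `TTAGAG` occurring in the database is `TAGAG`
(length 5, starting at 0-based position 1 of the query).

From a shell, the same flows are available as
`exec/privmatch gen-fixture | prepare-db | search | oracle | estimate-net |
bench`.

## Scope notes

Semi-honest security, two computing nodes, in-process simulation (no
sockets, R's seedable PRNG rather than a CSPRNG); match *locations in the
database* and all-MEM enumeration are out of scope. Occurrence semantics is
cyclic at the rotation seam of the sentinel-free index — see the methods
vignette (`vignettes/secure-substring-matching.Rmd`) for why, and for the
full design rationale.
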