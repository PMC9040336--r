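---
title: "Secure substring matching over secret shares: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure substring matching over secret shares: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privmatch)
```

## The problem and the trust model

Two parties want to compare sequences without showing them to each other: a
query holder has a short DNA string $w$ (length $\ell$), a database holder
has a long one $T$ (length $N$), and the query holder should learn only the
longest prefix of $w$ occurring in $T$ (LPM) or the longest substring of $w$
occurring in $T$ (the longest maximal exact match, LMEM) — nothing else, and
the database holder should learn nothing at all.

`privmatch` simulates the standard outsourced two-party setting: the inputs
are split with 2-out-of-2 additive secret sharing over $\mathbb{Z}_{2^n}$ and
handed to two non-colluding computing nodes $P_0$, $P_1$; the database holder
doubles as trusted initializer, distributing Beaver triples and other
correlated randomness before any query arrives. Security is semi-honest:
nodes follow the protocol but may analyze everything they see. All four
roles run in one R process; what the simulation preserves faithfully is the
*message structure* — which values are opened, in which order, in how many
P0–P1 rounds, and how many bytes — recorded per phase (offline, DB
preparation, search) in a transcript.

The package is a protocol emulator for studying correctness and
communication structure. It uses R's seedable PRNG throughout rather than a
cryptographic generator, runs in one process rather than over sockets, and
is not hardened against side channels; none of that affects the quantities
it is built to measure.

## Index structure

The search substrate is an FM-index materialized as lookup tables: for the
(reversed) database, per-letter vectors $V_c[i] = \mathrm{LF}_c(i) =
\mathrm{CF}_c + \mathrm{Rank}_c(i, L)$ of length $N' = N + 1$ turn one
backward-search step into a pure table lookup,
$[f', g') = [V_c[f], V_c[g])$. Matching a prefix of $w$ is then $\ell$
successive lookups starting from $[0, N)$, and the match is lost exactly
when $f = g$.

Two conventions matter and were genuinely open:

* **No sentinel, rotation order.** The tables are built on the plain string
  with the cyclic predecessor BWT $L[i] = S[(SA[i]-1) \bmod N]$. For this to
  be self-consistent the index must sort *rotations*, not suffixes (ties
  between equal rotations broken by position): mixing suffix order with the
  cyclic BWT shifts intervals by one around the rotation seam, which a
  maximal-exact-match walk amplifies into wrong answers. With rotation
  order, an interval's width is exactly the number of *cyclic* occurrences
  of the pattern. Consequence: a match may span the seam between the last
  and first character of $T$; the package's oracles and fixtures use the
  cyclic semantics throughout, and on random genomic-scale data seam
  matches are rare (they require the pattern to straddle one fixed
  boundary).
* **Cyclic LCP.** The LMEM walk needs the LCP array with
  previous/next-smaller-value indices (PSV/NSV) to jump to the parent
  lcp-interval when an extension fails. For consistency with rotation
  order, LCP values compare rotations (capped at $N$), not suffixes;
  otherwise values truncate at the string end and the lcp-interval tree
  disagrees with the intervals backward search actually produces (this
  surfaced as rare wrong walks, about 0.4% of random instances, before the
  change; afterwards 1000/1000 random instances agree with the brute-force
  oracle, including periodic strings).

Boundary entries $\mathrm{LCP}[0] = \mathrm{LCP}[N] = 0$ act as sentinels;
PSV clamps to 0 and NSV to $N$; the root interval $[0, N)$ is defined to be
its own parent with lcp-value 0.

## The oblivious lookup primitive

The heart of the stack is secret-shared recursive oblivious transfer
(ss-ROT): evaluating $V[V[\cdots V[p_0]]]$ ($\ell$-fold) so that the nodes
learn nothing about $V$. The database holder prepares $\ell$ copies of $V$,
each rotated by the previous round's mask and value-masked with the next:
$R^j[i] = (V[(i - r^{j-1}) \bmod N] + r^j) \bmod N$ (no output mask on the
last copy). In the search phase the nodes open $p_{j+1} = R^j[p_j]$ — a
uniformly masked, hence harmless, index — and output the final entry as
shares. Everything after DB preparation costs $O(\ell)$ time, bytes and
rounds, independent of $N$: that is the property the whole design exists
for, and the transcript tests pin it down ($N = 10^3$ vs $10^4$ transcripts
are byte-identical at fixed $\ell$).

## The three search protocols

**Secure LPM** instantiates ss-ROT chains for all four letters and both
interval bounds ($8\ell$ masked vectors, common masks per round so the
recursion works across letters). The query holder shares four unary
indicator vectors $q_c$ (one-hot per position); each round the nodes select
the active letter's table entry by the inner product
$\sum_c q_c[j] \cdot R^j_{c,\cdot}[\cdot]$ — one Beaver round — open both
masked bounds, and test the interval width for zero. Because the bounds
carry different masks, the width test checks whether
$f_j - g_j - r'[j-1] \in \{-N', 0, N'\}$ using the pre-shared mask
difference $r'$; the three Equality outputs are OR-combined. The query
holder receives only the bit vector $o$; its first 1 at position $i$
decodes to LPM length $i - 1$ ($\ell$ if absent). All $\ell$ rounds always
run — no early termination — so the communication pattern carries no
information about the result.

**Secure LMEM** runs the parent-interval walk for $2\ell - 1$ fixed rounds
with tables to matching depth. Six additional rotated table families serve
the auxiliary arrays: LCP copies rotated like the corresponding bound's LF
tables (values unmasked but shared), PSV copies value-masked with the
round's *f*-mask (a PSV result becomes the new lower bound), NSV copies
with the *g*-mask. The hidden state is a unit vector $u$ marking the
match's right end in $w$ (shifted on extension, held on fallback), the
match length $m$, left end $p$, and the running maximum. Each round
computes the extension, the width-zero flag $e_1$, the branch flag
$e_2 = [\mathrm{LCP}[g] \le \mathrm{LCP}[f]]$, picks extension or parent by
Choose, and updates $m \leftarrow m + 1$ or $m \leftarrow c =
\max(\mathrm{LCP}[f], \mathrm{LCP}[g])$ with $p \leftarrow p + m - c$.
The running maximum uses a strict comparison, so among equally long matches
the first (leftmost-ending) one is reported.

Two points the source material leaves contradictory or unhandled were
resolved as follows, with the brute-force oracle as arbiter:

* $u$ shifts on *successful extension* (the overview's semantics), not on
  the opposite polarity a proof sketch suggests; the same arbitration
  applies to the $j = 0$ masking of the PSV/NSV families (the prose's
  uniform f-mask/g-mask discipline, not the displayed $j = 0$ special
  case).
* A failed extension at $m = 0$ means the current query letter occurs
  nowhere in $T$; retrying it from the root forever would silently miss
  matches later in the query. The walk therefore advances past such a
  letter ($u$ shifts, $m$ stays 0, $p$ advances), detected obliviously by
  one extra Equality of $m$ with 0 per round. On genomes containing all
  four letters this path never triggers; the fixture generator guarantees
  such genomes, and the degenerate case is covered by its own tests.
* Once $u$ shifts out entirely the query is exhausted; an activity flag
  $x = \sum_t u[t]$ (a local share sum, since $u$ is one-hot or zero)
  freezes $m$, $p$ and the maximum via Choose so the remaining rounds are
  no-ops with an unchanged message pattern. The bounds opened in those late
  rounds degenerate to the letter-selection of an all-zero encoding; the
  uniformity tests therefore sample first-round disclosures, which exist in
  every run.

**Compressed-share LPM** attacks the DB-preparation payload ($8 \ell N'$
ring elements for plain LPM). The LF tables are unit-step
($0 \le V_c[i+1] - V_c[i] \le 1$), so after a seam-correcting rotation
(two offsets $o, \bar o$ keep the rotated table unit-step — the package
verifies this exhaustively) a table splits into a coarse sample
$Q[p] = V'[pM]$ every $M = 2^m$ positions at full width $n$ and residuals
$R[i] = V'[i] - V'[M\lfloor i/M \rfloor] < M$ shared over $\mathbb{Z}_{2^m}$.
For $m = 8$, $n = 16$ this roughly halves the DB-preparation bytes (ratio
$\approx m/n$ plus the coarse-table term). The price is paid at search
time: each round opens a freshly masked index ($p_j = (f_j + r) \bmod N'$,
with the sum opened in $\mathbb{Z}_{2^n}$ — no wrap since $2^n \ge 4N'$ —
and reduced publicly), casts the residual share up to $n$ bits, and selects
the offset by comparing the secret bound against the public index. Bounds
stay exact in the shares, so the width test is a single Equality per round.
The extra CastUp/Comp/MULT stages multiply the round count by a constant;
transcripts confirm rounds stay $N$-invariant and exceed plain LPM's by a
fixed factor.

## Subprotocol constructions

The comparison-style subprotocols (Table-style contract: Equality, Comp,
CastUp, B2A, Choose) are built from trusted-initializer correlated
randomness; their internal structure is a design choice of this package,
subject to three requirements: the contract, a round count that depends
only on the ring width, and never opening an unmasked secret-dependent
value.

* **Equality**: open $x - y + r$ for a dealer-random $r$ with
  Boolean-shared bits; XNOR the public bits against the shared bits; AND
  tree of depth $\lceil \log_2 n \rceil$.
* **Comp** ($x < y$, unsigned over the full ring): bit-decompose both
  operands — open $x + r$, subtract the shared bits of $r$ with a
  borrow-ripple circuit (one AND round per bit, batched across elements) —
  then find the most significant differing bit with a prefix-OR chain and
  output that bit of $y$.
* **CastUp**: open $x + r \bmod 2^m$, recover the wrap bit $[c < r]$ with
  the borrow circuit, and correct in the large ring using the dealer's
  same-value shares there.
* **B2A**: open $x \oplus b$ for a dealer bit shared in both domains;
  $x = z + b - 2zb$ locally.

Rounds per call are constants of $n$ (e.g. at $n = 16$: Equality 5, Comp
$\approx 2n$), so protocol search rounds are exact multiples of the round
count — the transcript scaling tests assert perfect linearity in $\ell$.
The dealer material is generated lazily and charged to the offline phase,
keeping search transcripts deterministic; a pre-filled pool
(`trusted_init()`) behaves identically.

## Parameters

* `n` — share width. Default 16 for $N < 10^5$, 32 above (the published
  runs' policy), with the validated constraint $2^n \ge 4N'$ so that
  $-N', 0, N'$ are distinct ring representatives in the width test.
* `m` — residual width of the compressed protocol, default 8
  ($M = 256$); must satisfy $m < n$.
* `ell` — query length; LMEM tables are built to depth $2\ell - 1$, the
  number of rounds the walk needs in the worst case (up to $\ell$
  extensions and $\ell - 1$ fallbacks).
* Masks are drawn uniformly from $[0, N')$ — only the residue mod $N'$
  enters the tables — and can be pinned to reproduce worked examples.

## What the synthetic data emulates — and what it does not

`generate_fixture()` draws uniform ACGT genomes (redrawn until all four
letters occur, the walk's natural precondition) and builds queries by
copying a random-length genome substring and padding with random letters,
so matches of known minimum length are planted; the recorded truths are
re-derived by brute-force scans at generation time. Uniform genomes lack
the repeat structure, homopolymer runs, GC skew and N-runs of real
chromosomes. That is immaterial for the protocols' *correctness* claims
(they are exact for any ACGT input, and the oracle suites cover periodic
and degenerate strings) and for the *transcript* claims (communication is
input-independent by construction — the tests verify transcripts are
identical across different inputs). It does mean measured wall-clock times
say nothing about genome-scale performance, and non-ACGT characters are a
hard error by design. The published human-chromosome benchmarks at
$N = 10^7$ are emulated structurally, not reproduced: the test and
benchmark sizes here are $N \le 10^4$ and $\ell \le 100$, which this
package handles in seconds while exhibiting the same $N$-free search
transcripts.

## Numerical and degenerate-input choices

Ring elements are doubles; modular products for $n > 26$ use 16-bit limb
splitting so no intermediate exceeds $2^{53}$ (covering $n = 32$ exactly).
Coordinates are 0-based with half-open intervals everywhere. Degenerate
inputs: empty-width extensions stay empty; queries longer than the
prepared tables are an error; table values out of $[0, N)$, non-ACGT
symbols (with position), recursion depth below 2 for ss-ROT, and ring
widths violating $2^n \ge 4N'$ are all rejected at entry. The uniformity
tests use a fixed significance of $\alpha = 0.001$ with $\ge 10^4$
fresh-mask repetitions at small $N$, sampling disclosures that exist in
every run (first-round bounds).

## Known limitations

* Semi-honest, two computing nodes, in-process simulation only; no
  malicious security, no real network (delays are estimated from the
  transcript via $D/k + eT/1000$ with LAN/WAN presets).
* Output privacy (what many adaptive queries reveal about $T$) is out of
  scope, as is reporting match *locations in the database*, enumerating
  all MEMs, and the compressed representation for LMEM.
* Cyclic occurrence semantics at the rotation seam, as discussed above.
* The compressed protocol's opened index $s = f_j + r$ is opened in
  $\mathbb{Z}_{2^n}$ before public reduction mod $N'$; the raw sum's
  distribution is not perfectly uniform (it carries carry information),
  which is why the distribution-uniformity test suite covers the ss-ROT
  family of protocols and not this opening.

## A worked example

```{r example}
env <- mpc_env(n = 16, seed = 1)
db <- prepare_lpm_db("TGCA", ell = 3, env)
res <- lpm_search("GCT", db, env)
res$o
res$match
mpc_transcript(env)$search
```

The collapse at the third reference (`o = (0, 0, 1)`) decodes to the
longest prefix match `GC` of length 2.
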