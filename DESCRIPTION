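Package: privmatch
Title: Privacy-Preserving Variable-Length Substring Matching over Secret Shares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of two-party secure substring search between a query
    holder and a genome database holder. Implements 2-out-of-2 additive secret
    sharing over Z_{2^n} with Beaver-triple multiplication and a trusted
    initializer, FM-index lookup tables with LCP/PSV/NSV auxiliary arrays,
    secret-shared recursive oblivious transfer (ss-ROT) for oblivious
    recursive table lookup, and three search protocols built on it: secure
    longest prefix match (LPM), secure longest maximal exact match (LMEM),
    and a compressed-share LPM variant that trades search-time subprotocol
    calls for smaller database shares. Simulated computing nodes record
    per-phase communication transcripts (rounds and bytes) so that the
    protocols' database-length-independent search complexity can be measured.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
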