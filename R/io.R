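#' Read a single-record DNA FASTA file
#'
#' Multi-record files are an error; sequences are uppercased and validated
#' against the ACGT alphabet.
#'
#' @param path FASTA file path.
#' @return The sequence as a character string.
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1) stop("expected a single-record FASTA, found ", length(set))
  s <- toupper(as.character(set[[1]]))
  dna_codes(s) # validation
  s
}

#' Write a sequence as single-record FASTA (60-column wrapping)
#'
#' @param s Sequence string over ACGT.
#' @param path Output path.
#' @param name Record name.
#' @export
write_dna_fasta <- function(s, path, name = "seq") {
  dna_codes(s)
  set <- Biostrings::DNAStringSet(s)
  names(set) <- name
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

## ---- share containers ------------------------------------------------------

write_le_array <- function(x, width_bytes, path) {
  len <- length(x)
  m <- vapply(seq_len(width_bytes) - 1, function(b) x %/% 256^b %% 256,
              numeric(len))
  if (len == 1) m <- matrix(m, nrow = 1)
  writeBin(as.raw(t(m)), path)
}

read_le_array <- function(path, width_bytes, len) {
  raw <- readBin(path, "raw", n = width_bytes * len)
  m <- matrix(as.integer(raw), nrow = width_bytes)
  as.numeric(colSums(m * 256^(seq_len(width_bytes) - 1)))
}

# private database-holder fields never written to the nodes' containers
PRIVATE_DB_FIELDS <- c("masks", "masks_f", "masks_g", "tab", "lcp")

# replace every mpc_shares node by a JSON-able stub; collect the arrays
skeletonize <- function(x, path, sink) {
  if (inherits(x, "mpc_shares")) {
    nm <- paste0("v", length(sink$arrays))
    sink$arrays[[nm]] <- x
    return(list(.share = nm, n = sh_width(x), len = length(x)))
  }
  if (is.list(x)) {
    kept <- if (!is.null(names(x))) setdiff(names(x), PRIVATE_DB_FIELDS) else seq_along(x)
    out <- lapply(if (is.character(kept)) x[kept] else x, skeletonize,
                  path = path, sink = sink)
    return(out)
  }
  x
}

unskeletonize <- function(x, dir) {
  if (is.list(x) && !is.null(x$.share)) {
    wb <- ceiling(x$n / 8)
    s0 <- read_le_array(file.path(dir, "party0", paste0(x$.share, ".bin")), wb, x$len)
    s1 <- read_le_array(file.path(dir, "party1", paste0(x$.share, ".bin")), wb, x$len)
    return(new_shares(s0, s1, x$n))
  }
  if (is.list(x)) return(lapply(x, unskeletonize, dir = dir))
  x
}

#' Write a prepared database's share container
#'
#' Materializes the per-party view of a prepared protocol database as a
#' directory: `manifest.json` (protocol, parameters, and the structural
#' skeleton of the shared tables) plus flat little-endian fixed-width arrays
#' under `party0/` and `party1/`, one file per shared vector at
#' `ceiling(width/8)` bytes per element. The database holder's private
#' material (masks, plaintext tables) is never written.
#'
#' @param db A prepared database (`ssrot_db`, `lpm_db`, `lmem_db`, `lpm2_db`).
#' @param dir Output directory (created).
#' @export
write_share_container <- function(db, dir) {
  protocol <- sub("_db$", "", class(db)[1])
  dir.create(file.path(dir, "party0"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "party1"), recursive = TRUE, showWarnings = FALSE)
  sink <- new.env(parent = emptyenv())
  sink$arrays <- list()
  skel <- skeletonize(unclass(db), character(), sink)
  for (nm in names(sink$arrays)) {
    sh <- sink$arrays[[nm]]
    wb <- ceiling(sh_width(sh) / 8)
    write_le_array(sh$s0, wb, file.path(dir, "party0", paste0(nm, ".bin")))
    write_le_array(sh$s1, wb, file.path(dir, "party1", paste0(nm, ".bin")))
  }
  manifest <- list(protocol = protocol, class = class(db)[1], skeleton = skel)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a share container back into a prepared-database object
#'
#' @param dir Container directory from [write_share_container()].
#' @export
read_share_container <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  db <- unskeletonize(manifest$skeleton, dir)
  # scalars arrive as length-1 lists from JSON
  for (nm in names(db)) if (is.list(db[[nm]]) && is.null(names(db[[nm]])) &&
                            length(db[[nm]]) >= 1 && !inherits(db[[nm]], "mpc_shares") &&
                            all(vapply(db[[nm]], function(e) is.atomic(e) && length(e) == 1, TRUE))) {
    db[[nm]] <- unlist(db[[nm]])
  }
  class(db) <- manifest$class
  db
}
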