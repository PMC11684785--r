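# internal helpers shared across modules

# Run code under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards so pipeline determinism never leaks into user sessions.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# stable SHA-1 of an R object, used to stamp provenance into artifacts
config_hash <- function(x) digest::digest(x, algo = "sha1")

# translate in-frame nucleotide strings with the standard genetic code
# (codon lookup against Biostrings::GENETIC_CODE; far cheaper than S4
# dispatch when called once per receptor chain)
translate_nt <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s) || !nzchar(s)) return("")
    n <- nchar(s)
    codons <- substring(s, seq(1, n, 3), pmin(seq(3, n + 2, 3), n))
    aa <- unname(Biostrings::GENETIC_CODE[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

`%not_in%` <- function(x, table) !(x %in% table)
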