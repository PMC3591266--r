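# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (the global .Random.seed is restored on exit).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample from the elements of x (never from 1:x when x is scalar)
sample_from <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# residue compatibility check, vectorised over rows
is_compatible <- function(residue, ptm_type) {
  ok <- logical(length(residue))
  for (t in names(PTM_COMPAT)) {
    sel <- ptm_type == t
    ok[sel] <- residue[sel] %in% PTM_COMPAT[[t]]
  }
  ok
}

# split a protein sequence into a character vector of residues
seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1L]]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
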