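# Internal helpers shared across modules.

# The 20 canonical amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Characters tolerated inside sequences but excluded from motif counting and
# scored as zero: alignment padding plus ambiguous/non-standard residues.
ZERO_SCORE_CHARS <- c("-", "X", "U", "B", "Z")

PAD_CHAR <- "-"

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package internals do
#' not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a character vector (polynomial rolling hash).
# Used to derive per-item seeds so sampling is invariant to input order.
stable_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Combine a root seed with a per-item hash, staying within 31 bits.
derive_seed <- function(root_seed, key) {
  as.integer((as.numeric(root_seed) * 2654435761 + stable_hash(key)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[phoslink] ", sprintf(...))
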