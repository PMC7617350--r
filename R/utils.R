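#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded simulator calls never perturb the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

# Reverse-complement of an A/C/G/T/N string (uppercase).
revcomp <- function(seq) {
  x <- chartr("ACGTN", "TGCAN", seq)
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# Random DNA string(s) of the given length, uniform base composition.
rand_dna <- function(n, length_bp) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length strings, byte-wise.
str_mismatches <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a proportion as a percentage with one decimal, the reporting
# convention used throughout.
fmt_pct <- function(p) sprintf("%.1f%%", 100 * p)
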