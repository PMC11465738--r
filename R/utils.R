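# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
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
  set.seed(as.integer(seed))
  force(code)
}

# 20 standard amino acids.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

#' Round to a number of significant figures for reporting
#'
#' Convenience wrapper around [signif()] used when quoting derived constants
#' (e.g. catalytic efficiencies) the way they appear in enzymology tables.
#'
#' @param x numeric vector.
#' @param digits significant figures (default 2).
#' @return `x` rounded to `digits` significant figures.
#' @export
signif_report <- function(x, digits = 2) signif(x, digits)

stop_invalid <- function(msg) stop(msg, call. = FALSE)
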