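# Independent oracles used across the test files.

# brute-force sliding-window motif scan (character-by-character)
oracle_scan <- function(sequence, motif) {
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(motif, "")[[1]]
  k <- length(p)
  n <- length(s)
  hits <- integer(0)
  if (n >= k) {
    for (i in 1:(n - k + 1L)) {
      ok <- TRUE
      for (j in 1:k) {
        if (!(p[j] %in% c("x", "X")) && s[i + j - 1L] != toupper(p[j])) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# exhaustive global-alignment oracle for short strings: enumerate every
# alignment, keep max score (match +1 / mismatch 0 / gap -1), then max
# matches, and report identity over that alignment's length
oracle_identity <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  res <- list()
  rec <- function(i, j, score, matches, len) {
    if (i > length(A) && j > length(B)) {
      res[[length(res) + 1L]] <<- c(score, matches, len)
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      m <- as.integer(A[i] == B[j])
      rec(i + 1L, j + 1L, score + m, matches + m, len + 1L)
    }
    if (i <= length(A)) rec(i + 1L, j, score - 1L, matches, len + 1L)
    if (j <= length(B)) rec(i, j + 1L, score - 1L, matches, len + 1L)
  }
  rec(1L, 1L, 0L, 0L, 0L)
  m <- do.call(rbind, res)
  m <- m[m[, 1] == max(m[, 1]), , drop = FALSE]
  m <- m[m[, 2] == max(m[, 2]), , drop = FALSE]
  100 * m[1, 2] / m[1, 3]
}

# run the full cascade on a fixture and return the selected ids (sorted)
cascade_select <- function(fx) {
  rep <- compile_report(
    fx$proteins, fx$domain_table, fx$similarity_table,
    fx$topology_table, fx$metadata, fx$config
  )
  sort(rep$protein_id[rep$selected])
}

# unique scratch file path for format round-trip tests
withr_local_file <- function(name) tempfile(pattern = paste0(name, "_"))

random_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""
  )
}
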