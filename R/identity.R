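# Global pairwise identity and greedy identity clustering.
#
# The screen only needs a simple, symmetric identity measure to flag
# near-redundant candidates, so a self-contained Needleman-Wunsch aligner is
# used: match +1, mismatch 0, linear gap -1, identity counted over the full
# alignment length including end gaps.  Among equally scoring alignments the
# one with the most identical columns is taken; because the total score fixes
# the number of diagonal steps once the match count is known, this choice
# makes the reported identity unique and symmetric in its arguments.

#' Percent identity between two protein sequences
#'
#' Global (end-to-end) alignment with match +1, mismatch 0 and linear gap
#' penalty -1; identity is `100 * matches / alignment length` where the
#' alignment length includes gap columns.  The value is symmetric and lies in
#' \eqn{[0, 100]}.
#'
#' @param a,b non-empty amino-acid strings.
#' @return Percent identity (numeric scalar).
#' @export
#' @examples
#' pairwise_identity("ACDE", "ACDE") # 100
#' pairwise_identity("ACDE", "ACDF") # 75
pairwise_identity <- function(a, b) {
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b)) {
    stop_invalid("pairwise_identity() needs two non-empty sequences")
  }
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1L, m + 1L) # optimal score
  M <- matrix(0, n + 1L, m + 1L) # max matches among optimal alignments
  H[1L, ] <- -(0:m)
  H[, 1L] <- -(0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) 1L else 0L
      d <- H[i, j] + s
      u <- H[i, j + 1L] - 1L
      l <- H[i + 1L, j] - 1L
      h <- max(d, u, l)
      mm <- -Inf
      if (d == h) mm <- M[i, j] + s
      if (u == h) mm <- max(mm, M[i, j + 1L])
      if (l == h) mm <- max(mm, M[i + 1L, j])
      H[i + 1L, j + 1L] <- h
      M[i + 1L, j + 1L] <- mm
    }
  }
  score <- H[n + 1L, m + 1L]
  matches <- M[n + 1L, m + 1L]
  # diagonal steps are determined by (score, matches): score = matches - gaps,
  # gaps = n + m - 2 * diag  =>  diag = (score - matches + n + m) / 2
  diag_steps <- (score - matches + n + m) / 2
  aln_len <- n + m - diag_steps
  100 * matches / aln_len
}

#' Greedy identity-based de-duplication of candidate proteins
#'
#' Sequences are visited in order of decreasing length (ties broken by id,
#' lexicographically).  Each sequence joins the first existing representative
#' to which its identity is at or above `identity_cutoff` (inclusive, so a
#' pair at exactly the cutoff is merged); otherwise it founds a new cluster.
#' All returned representatives are mutually below the cutoff.
#'
#' @param proteins data frame with columns `id` and `sequence`.
#' @param identity_cutoff percent identity threshold in `(0, 100]`.
#' @return Character vector of representative ids (in founding order).
#' @export
dedup_candidates <- function(proteins, identity_cutoff = 90) {
  stopifnot(
    is.data.frame(proteins), all(c("id", "sequence") %in% names(proteins)),
    identity_cutoff > 0, identity_cutoff <= 100
  )
  if (nrow(proteins) == 0L) {
    return(character(0))
  }
  ord <- order(-nchar(proteins$sequence), proteins$id, method = "radix")
  ids <- proteins$id[ord]
  seqs <- proteins$sequence[ord]
  rep_ids <- character(0)
  rep_seqs <- character(0)
  for (k in seq_along(ids)) {
    absorbed <- FALSE
    for (r in seq_along(rep_seqs)) {
      if (pairwise_identity(seqs[k], rep_seqs[r]) >= identity_cutoff) {
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      rep_ids <- c(rep_ids, ids[k])
      rep_seqs <- c(rep_seqs, seqs[k])
    }
  }
  rep_ids
}
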