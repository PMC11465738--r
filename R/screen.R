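# The two-branch candidate screening cascade.
#
# Branch 1 ("scap"): any hit against the curated set of CA-related Pfam
# profiles.  Branch 2 ("fnr"): for proteins without SCAP hits only, a
# similarity hit against a keyword-filtered reference at e-value <= cutoff.
# Survivors are checked for active-site motifs, gene boundaries, length,
# sampling environment and mutual redundancy.

#' Keep reference titles matching CA keywords
#'
#' Implements the keyword filter used to build the similarity-branch
#' reference: a title is kept iff it contains a multi-word keyword as a
#' case-insensitive substring on word boundaries, or matches a single-word
#' keyword as a whole token.  Tokens are maximal alphabetic runs, so the
#' keyword `"ca"` matches the token "Ca" but not "calcium".
#'
#' @param titles character vector of sequence titles/headers.
#' @param keywords character vector of keywords/phrases (non-empty).
#' @return Integer indices of kept titles.
#' @export
#' @examples
#' filter_reference_by_keywords(
#'   c("putative carbonic anhydrase", "calcium-binding protein"),
#'   c("carbonic anhydrase", "ca")
#' )
filter_reference_by_keywords <- function(titles,
                                         keywords = c(
                                           "carbonic anhydrase",
                                           "carbonic dehydratase", "ca"
                                         )) {
  if (length(keywords) == 0L) stop_invalid("keywords must be non-empty")
  is_multi <- grepl("\\s", keywords)
  multi <- tolower(keywords[is_multi])
  single <- tolower(keywords[!is_multi])
  esc <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
  keep <- vapply(titles, function(tt) {
    lt <- tolower(tt)
    for (kw in multi) {
      pat <- paste0("(?<![a-z])", esc(kw), "(?![a-z])")
      if (grepl(pat, lt, perl = TRUE)) {
        return(TRUE)
      }
    }
    if (length(single) > 0L) {
      toks <- tolower(regmatches(tt, gregexpr("[A-Za-z]+", tt))[[1]])
      if (any(toks %in% single)) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  which(keep)
}

#' Domain-evidence (SCAP) branch selection
#'
#' Returns the ids of proteins with at least one domain hit whose profile
#' accession belongs to the configured SCAP set.  No e-value threshold is
#' applied here: the reporting thresholds of the upstream domain search are
#' taken as given.
#'
#' @param hits data frame of domain hits (see [read_domtbl()]); needs columns
#'   `protein_id` and `profile_accession`.
#' @param config a [screen_config()].
#' @return Character vector of protein ids (sorted, unique).
#' @export
select_scap_hits <- function(hits, config = screen_config()) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(character(0))
  }
  sort(unique(hits$protein_id[hits$profile_accession %in% config$scap_accessions]))
}

#' Similarity-evidence (fnr) branch selection
#'
#' Returns query ids with at least one similarity hit at e-value less than or
#' equal to the configured cutoff (inclusive bound).  Intended for proteins
#' that had no SCAP domain hit.
#'
#' @param hits data frame of similarity hits with columns `query_id` and
#'   `evalue`.
#' @inheritParams select_scap_hits
#' @return Character vector of query ids (sorted, unique).
#' @export
select_similarity_hits <- function(hits, config = screen_config()) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(character(0))
  }
  if (any(hits$evalue < 0)) stop_invalid("negative e-value in similarity hits")
  sort(unique(hits$query_id[hits$evalue <= config$evalue_cutoff]))
}

#' Scan a protein sequence for active-site motifs
#'
#' Patterns are residue letters with `x` (or `X`) as a single-residue
#' wildcard; matches may overlap.  Positions are 1-based match starts.
#'
#' @param sequence non-empty amino-acid string.
#' @param motifs character vector of patterns, default the beta-CA
#'   active-site motifs.
#' @return Named list (one element per motif) of integer position vectors.
#' @export
#' @examples
#' scan_motifs("CADARHAAC") # CxDxR at 1, HxxC at 6
scan_motifs <- function(sequence, motifs = c("CxDxR", "HxxC")) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop_invalid("scan_motifs() needs one non-empty sequence")
  }
  seq_up <- toupper(sequence)
  out <- lapply(motifs, function(m) {
    chars <- strsplit(m, "")[[1]]
    rx <- paste0(ifelse(chars %in% c("x", "X"), ".", toupper(chars)),
      collapse = ""
    )
    # zero-width lookahead so overlapping matches are all reported
    hits <- gregexpr(paste0("(?=", rx, ")"), seq_up, perl = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  })
  names(out) <- motifs
  out
}

#' Check gene start/stop codons
#'
#' @param gene_nt nucleotide string, length at least 6.
#' @param config a [screen_config()] supplying the codon sets.
#' @param tolerate_n if `TRUE`, genes containing `N` return both flags
#'   `FALSE` instead of erroring.
#' @return List with logical fields `has_start` and `has_stop`.
#' @export
check_gene_boundaries <- function(gene_nt, config = screen_config(),
                                  tolerate_n = FALSE) {
  gene <- toupper(gene_nt)
  if (nchar(gene) < 6L) stop_invalid("gene shorter than two codons")
  if (grepl("[^ACGTN]", gene)) stop_invalid("non-ACGT characters in gene")
  if (grepl("N", gene, fixed = TRUE)) {
    if (tolerate_n) {
      return(list(has_start = FALSE, has_stop = FALSE))
    }
    stop_invalid("ambiguous base N in gene (set tolerate_n = TRUE to allow)")
  }
  n <- nchar(gene)
  list(
    has_start = substr(gene, 1L, 3L) %in% config$start_codons,
    has_stop = substr(gene, n - 2L, n) %in% config$stop_codons
  )
}

#' Filter samples by environmental conditions
#'
#' Keeps samples whose registered temperature is at or above
#' `config$min_temperature` (inclusive) and, when `config$require_alkaline`,
#' whose pH is above 7.
#'
#' @param metadata data frame with columns `sample_id`, `temperature`, `ph`.
#' @inheritParams select_scap_hits
#' @return Character vector of kept sample ids.
#' @export
filter_samples_by_environment <- function(metadata, config = screen_config()) {
  stopifnot(all(c("sample_id", "temperature", "ph") %in% names(metadata)))
  keep <- metadata$temperature >= config$min_temperature
  if (isTRUE(config$require_alkaline)) keep <- keep & metadata$ph > 7
  metadata$sample_id[keep]
}

#' Run the full screening cascade and compile a candidate report
#'
#' Applies, in order: branch assignment (SCAP domain evidence first, the
#' similarity branch only for SCAP non-hits), environmental filtering of the
#' source sample, motif scanning, gene-boundary checks, length checks,
#' signal-peptide/transmembrane flagging, and greedy identity
#' de-duplication among the proteins passing everything else.  A protein is
#' `selected` iff it passes every criterion and is its cluster's
#' representative.  Topology flags reject only under
#' `sp_tm_policy = "reject"`; by default they are recorded as reasons.
#'
#' @param proteins data frame with columns `id`, `sequence`, `gene_nt`
#'   (NA allowed), `sample_id`, and optionally `start_truncated`,
#'   `end_truncated`.
#' @param domain_hits,similarity_hits annotation tables (may be `NULL`); every
#'   referenced protein id must exist in `proteins`.
#' @param topology data frame with columns `protein_id`, `sp`, `tm`
#'   (may be `NULL`; missing proteins are treated as no SP/TM).
#' @param metadata sample metadata (see [filter_samples_by_environment()]).
#' @inheritParams select_scap_hits
#' @return A data frame of class `"candidate_report"`, one row per protein
#'   (sorted by id), with the branch, per-check outcomes, motif positions
#'   (list columns), `cluster_representative`, `selected` and a `reasons`
#'   string collecting every failed criterion.
#' @export
compile_report <- function(proteins, domain_hits = NULL,
                           similarity_hits = NULL, topology = NULL,
                           metadata = NULL, config = screen_config()) {
  stopifnot(all(c("id", "sequence", "sample_id") %in% names(proteins)))
  ids <- proteins$id
  if (anyDuplicated(ids)) stop_invalid("duplicate protein ids")
  check_refs <- function(tab, col, what) {
    if (!is.null(tab) && nrow(tab) > 0L && !all(tab[[col]] %in% ids)) {
      stop_invalid(paste0(what, " references unknown protein id(s): ",
        paste(setdiff(unique(tab[[col]]), ids), collapse = ", ")
      ))
    }
  }
  check_refs(domain_hits, "protein_id", "domain table")
  check_refs(similarity_hits, "query_id", "similarity table")
  check_refs(topology, "protein_id", "topology table")

  ord <- order(ids, method = "radix")
  proteins <- proteins[ord, , drop = FALSE]
  ids <- proteins$id
  n <- length(ids)

  # branch assignment: fnr only receives SCAP non-hits
  scap_ids <- select_scap_hits(domain_hits, config)
  sim_pool <- similarity_hits
  if (!is.null(sim_pool) && nrow(sim_pool) > 0L) {
    sim_pool <- sim_pool[!(sim_pool$query_id %in% scap_ids), , drop = FALSE]
  }
  fnr_ids <- select_similarity_hits(sim_pool, config)
  branch <- rep("none", n)
  branch[ids %in% scap_ids] <- "scap"
  branch[ids %in% fnr_ids] <- "fnr"

  # environment
  env_samples <- if (is.null(metadata)) {
    character(0)
  } else {
    filter_samples_by_environment(metadata, config)
  }
  known_samples <- if (is.null(metadata)) character(0) else metadata$sample_id
  env_ok <- proteins$sample_id %in% env_samples

  # per-protein sequence checks
  motif_positions <- lapply(proteins$sequence, scan_motifs, motifs = config$motifs)
  motifs_ok <- vapply(
    motif_positions,
    function(mp) all(vapply(mp, length, integer(1)) > 0L), logical(1)
  )

  has_gene <- if ("gene_nt" %in% names(proteins)) {
    !is.na(proteins$gene_nt) & nzchar(proteins$gene_nt)
  } else {
    rep(FALSE, n)
  }
  start_ok <- stop_ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(has_gene[i])) {
      bc <- check_gene_boundaries(proteins$gene_nt[i], config, tolerate_n = TRUE)
      start_ok[i] <- bc$has_start
      stop_ok[i] <- bc$has_stop
    }
  }
  boundary_ok <- start_ok & stop_ok

  len <- nchar(proteins$sequence)
  lw <- config$length_window * config$family_mean_length
  length_ok <- len >= lw[1] & len <= lw[2]

  sp_or_tm <- rep(FALSE, n)
  if (!is.null(topology) && nrow(topology) > 0L) {
    idx <- match(ids, topology$protein_id)
    flag <- (topology$sp | topology$tm)[idx]
    sp_or_tm <- ifelse(is.na(flag), FALSE, flag)
  }
  topo_pass <- if (config$sp_tm_policy == "reject") !sp_or_tm else rep(TRUE, n)

  pass_pre_dedup <- branch != "none" & env_ok & motifs_ok & boundary_ok &
    length_ok & topo_pass
  reps <- dedup_candidates(
    proteins[pass_pre_dedup, c("id", "sequence"), drop = FALSE],
    config$identity_cutoff
  )
  cluster_representative <- pass_pre_dedup & ids %in% reps
  selected <- pass_pre_dedup & cluster_representative

  reasons <- vapply(seq_len(n), function(i) {
    r <- character(0)
    if (branch[i] == "none") r <- c(r, "no SCAP domain or qualifying similarity hit")
    if (!env_ok[i]) {
      r <- c(r, if (proteins$sample_id[i] %in% known_samples) {
        "sample environment fails temperature/alkalinity filter"
      } else {
        "no metadata for source sample"
      })
    }
    if (!motifs_ok[i]) r <- c(r, "missing active-site motif(s)")
    if (!isTRUE(has_gene[i])) {
      r <- c(r, "no gene sequence for boundary check")
    } else if (!boundary_ok[i]) r <- c(r, "invalid start and/or stop codon")
    if (!length_ok[i]) r <- c(r, "length outside family window")
    if (sp_or_tm[i]) {
      r <- c(r, if (config$sp_tm_policy == "reject") {
        "signal peptide / transmembrane region predicted (rejected)"
      } else {
        "signal peptide / transmembrane region predicted (flagged)"
      })
    }
    if (pass_pre_dedup[i] && !cluster_representative[i]) {
      r <- c(r, "redundant with a selected representative")
    }
    paste(r, collapse = "; ")
  }, character(1))

  out <- data.frame(
    protein_id = ids,
    branch = branch,
    env_ok = env_ok,
    motifs_ok = motifs_ok,
    start_ok = start_ok,
    stop_ok = stop_ok,
    boundary_ok = boundary_ok,
    length = len,
    length_ok = length_ok,
    sp_or_tm = sp_or_tm,
    cluster_representative = cluster_representative,
    selected = selected,
    reasons = reasons,
    stringsAsFactors = FALSE
  )
  out$motif_hits <- motif_positions
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(
    "Candidate screening report:", nrow(x), "proteins,",
    sum(x$selected), "selected\n"
  )
  print.data.frame(
    x[, c(
      "protein_id", "branch", "env_ok", "motifs_ok", "boundary_ok",
      "length_ok", "cluster_representative", "selected"
    )],
    row.names = FALSE, ...
  )
  invisible(x)
}
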