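# Readers and writers for the standard annotation formats the screen
# consumes: FASTA (via Biostrings), HMMER3 domain tables (domtblout),
# 12-column tabular BLAST, Phobius short format, TSV sample metadata and
# time/value CSV traces.  The synthetic generators write through the same
# functions, so every format is round-trip tested.

#' Read/write protein or nucleotide FASTA
#'
#' Thin wrappers around \pkg{Biostrings}; sequence names are taken up to the
#' first whitespace.
#'
#' @param path file path.
#' @param sequences named character vector of sequences.
#' @param type `"AA"` or `"DNA"` (write only).
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- switch(type,
    AA = Biostrings::AAStringSet(sequences),
    DNA = Biostrings::DNAStringSet(sequences)
  )
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# canonical column order for the in-memory domain-hit table
DOMTBL_COLS <- c(
  "protein_id", "profile_accession", "profile_name",
  "i_evalue", "bit_score", "env_from", "env_to"
)

#' Read an HMMER3 per-domain table (domtblout)
#'
#' Parses the whitespace-delimited 22-column-plus-description format written
#' by `hmmscan --domtblout`, where the target is the profile and the query is
#' the protein.  Only the fields used by the screen are retained.
#'
#' @param path file path.
#' @return Data frame with columns `protein_id`, `profile_accession`,
#'   `profile_name`, `i_evalue`, `bit_score`, `env_from`, `env_to`.
#' @export
read_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(stats::setNames(
      data.frame(
        character(0), character(0), character(0), numeric(0),
        numeric(0), integer(0), integer(0)
      ), DOMTBL_COLS
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(fields, length, integer(1)) < 22L
  if (any(bad)) stop_invalid("malformed domtblout row (fewer than 22 fields)")
  get <- function(k) vapply(fields, `[[`, character(1), k)
  out <- data.frame(
    protein_id = get(4),
    profile_accession = get(2),
    profile_name = get(1),
    i_evalue = as.numeric(get(13)),
    bit_score = as.numeric(get(14)),
    env_from = as.integer(get(20)),
    env_to = as.integer(get(21)),
    stringsAsFactors = FALSE
  )
  if (any(out$env_from > out$env_to) || any(out$i_evalue < 0)) {
    stop_invalid("invalid domain coordinates or e-values in domtblout")
  }
  out
}

#' @rdname read_domtbl
#' @param hits data frame as returned by [read_domtbl()]; additional HMMER
#'   fields not represented in memory are written as placeholders.
#' @export
write_domtbl <- function(hits, path) {
  stopifnot(all(DOMTBL_COLS %in% names(hits)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  ), con)
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      hits$profile_name[i], hits$profile_accession[i], 200L,
      hits$protein_id[i], "-", 200L,
      hits$i_evalue[i], hits$bit_score[i], 0, 1L, 1L,
      hits$i_evalue[i], hits$i_evalue[i], hits$bit_score[i], 0,
      1L, 100L, hits$env_from[i], hits$env_to[i],
      hits$env_from[i], hits$env_to[i], 0.95
    ), con)
  }
  invisible(path)
}

BLAST_COLS <- c(
  "query_id", "subject_id", "pct_identity", "length", "mismatch",
  "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bit_score"
)

#' Read/write 12-column tabular BLAST output
#'
#' The standard tab-separated `outfmt 6` layout: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path file path.
#' @return Data frame with snake-case column names (`query_id`, `subject_id`,
#'   `pct_identity`, ..., `evalue`, `bit_score`).
#' @export
read_blast_tab <- function(path) {
  out <- read.table(path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    col.names = BLAST_COLS, colClasses = c(
      "character", "character", "numeric", "integer", "integer", "integer",
      "integer", "integer", "integer", "integer", "numeric", "numeric"
    )
  )
  if (any(out$evalue < 0) ||
    any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop_invalid("invalid e-value or percent identity in BLAST table")
  }
  out
}

#' @rdname read_blast_tab
#' @param hits data frame with the [read_blast_tab()] columns.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(BLAST_COLS %in% names(hits)))
  write.table(hits[, BLAST_COLS],
    file = path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read/write Phobius short-format topology predictions
#'
#' The short format is one row per protein: sequence id, number of predicted
#' transmembrane segments, a signal-peptide call (`Y`/`0`), and the topology
#' string.
#'
#' @param path file path.
#' @return Data frame with columns `protein_id`, `sp`, `tm` (logicals) and
#'   `prediction`.
#' @export
read_phobius <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^SEQ", lines)] # header ("SEQENCE ID ...")
  if (length(lines) == 0L) {
    return(data.frame(
      protein_id = character(0), sp = logical(0),
      tm = logical(0), prediction = character(0)
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  data.frame(
    protein_id = vapply(fields, `[[`, character(1), 1),
    sp = vapply(fields, `[[`, character(1), 3) == "Y",
    tm = as.integer(vapply(fields, `[[`, character(1), 2)) > 0L,
    prediction = vapply(fields, function(f) paste(f[-(1:3)], collapse = " "), character(1)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_phobius
#' @param topology data frame with columns `protein_id`, `sp`, `tm` and
#'   optionally `prediction`.
#' @export
write_phobius <- function(topology, path) {
  stopifnot(all(c("protein_id", "sp", "tm") %in% names(topology)))
  pred <- topology$prediction
  if (is.null(pred)) {
    pred <- ifelse(topology$tm, "i10-29o",
      ifelse(topology$sp, "n4-15c20/21o", "o")
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("SEQENCE ID                     TM SP PREDICTION", con)
  for (i in seq_len(nrow(topology))) {
    writeLines(sprintf(
      "%-30s %2d  %s %s", topology$protein_id[i],
      if (topology$tm[i]) 1L else 0L,
      if (topology$sp[i]) "Y" else "0", pred[i]
    ), con)
  }
  invisible(path)
}

#' Read/write sample metadata TSV
#'
#' Tab-separated with header columns `sample_id`, `temperature`, `ph`,
#' `description`.
#'
#' @param path file path.
#' @return Data frame of sample metadata.
#' @export
read_metadata <- function(path) {
  out <- read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, quote = ""
  )
  stopifnot(all(c("sample_id", "temperature", "ph") %in% names(out)))
  if (any(out$ph < 0 | out$ph > 14) || any(!is.finite(out$temperature))) {
    stop_invalid("metadata pH outside [0, 14] or non-finite temperature")
  }
  out
}

#' @rdname read_metadata
#' @param metadata data frame of sample metadata.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata,
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read/write a time/value CSV trace
#'
#' Two-column CSV with header; used for stopped-flow traces
#' (`time`, `absorbance`), decay series (`time_h`, `residual_pct`) and
#' reactor pressure series (`time_min`, `pressure_pa`).
#'
#' @param path file path.
#' @param trace two-column data frame.
#' @return `read_trace_csv()` returns the data frame as stored.
#' @export
read_trace_csv <- function(path) {
  out <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (ncol(out) < 2L) stop_invalid("trace CSV needs two columns")
  out
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  write.table(trace,
    file = path, sep = ",", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a candidate report as TSV plus a JSON summary
#'
#' The TSV holds one row per protein with motif positions collapsed to
#' comma-separated strings; the JSON summary records the counts per branch
#' and the selected ids.
#'
#' @param report a `candidate_report` from [compile_report()].
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the list written to JSON.
#' @export
write_candidate_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "candidate_report"))
  if (!is.null(tsv_path)) {
    flat <- as.data.frame(report[, setdiff(names(report), "motif_hits")])
    for (m in names(report$motif_hits[[1]])) {
      flat[[paste0("motif_", gsub("[^A-Za-z]", "", m))]] <- vapply(
        report$motif_hits, function(h) paste(h[[m]], collapse = ","), character(1)
      )
    }
    write.table(flat, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    n_proteins = nrow(report),
    n_selected = sum(report$selected),
    branch_counts = as.list(table(report$branch)),
    selected = report$protein_id[report$selected]
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(summary)
}

#' Write or read a complete screen fixture as files
#'
#' Serialises a [make_screen_fixture()] result to a directory using the same
#' formats the analysis readers consume (protein and gene FASTA, domtblout,
#' tabular BLAST, Phobius short format, metadata TSV, truth id list), and
#' reads such a directory back into the inputs of [compile_report()].
#'
#' @param fixture a `screen_fixture` (see [make_screen_fixture()]).
#' @param dir output directory (created if needed).
#' @return `write_screen_fixture()` returns `dir`; `read_screen_fixture()`
#'   returns a list with elements `proteins`, `domain_table`,
#'   `similarity_table`, `topology_table`, `metadata`, `truth`.
#' @export
write_screen_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(stats::setNames(fixture$proteins$sequence, fixture$proteins$id),
    p("proteins.faa"),
    type = "AA"
  )
  genes <- fixture$proteins[!is.na(fixture$proteins$gene_nt), ]
  write_fasta(stats::setNames(genes$gene_nt, genes$id), p("genes.fna"),
    type = "DNA"
  )
  write.table(fixture$proteins[, c("id", "sample_id")],
    file = p("protein_samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  write_domtbl(fixture$domain_table, p("domains.domtbl"))
  write_blast_tab(fixture$similarity_table, p("similarity.tsv"))
  write_phobius(fixture$topology_table, p("topology.txt"))
  write_metadata(fixture$metadata, p("metadata.tsv"))
  writeLines(fixture$truth, p("truth.txt"))
  invisible(dir)
}

#' @rdname write_screen_fixture
#' @export
read_screen_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  aa <- read_fasta(p("proteins.faa"))
  nt <- read_fasta(p("genes.fna"))
  smp <- read.table(p("protein_samples.tsv"),
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE
  )
  proteins <- data.frame(
    id = names(aa), sequence = unname(aa),
    gene_nt = unname(nt[names(aa)]),
    sample_id = smp$sample_id[match(names(aa), smp$id)],
    stringsAsFactors = FALSE
  )
  list(
    proteins = proteins,
    domain_table = read_domtbl(p("domains.domtbl")),
    similarity_table = read_blast_tab(p("similarity.tsv")),
    topology_table = read_phobius(p("topology.txt")),
    metadata = read_metadata(p("metadata.tsv")),
    truth = readLines(p("truth.txt"))
  )
}
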