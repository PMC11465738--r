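# Seeded generator for screening fixtures: protein sets with planted
# CA-like positives and decoys that each violate a known cascade criterion,
# plus the matching annotation tables and sample metadata.

# instantiate a motif pattern, replacing the x wildcard with random residues
instantiate_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  chars[chars %in% c("x", "X")] <- sample(AA_ALPHABET, sum(chars %in% c("x", "X")),
    replace = TRUE
  )
  paste(chars, collapse = "")
}

# random protein containing one instance of each motif, at non-overlapping
# offsets, one motif per equal-length segment; motifs are kept clear of the
# last 8 residues so C-terminal trimming (near-duplicate decoys) cannot
# destroy them
plant_motifs <- function(len, motifs) {
  s <- strsplit(random_aa(len), "")[[1]]
  k <- length(motifs)
  seg <- floor(len / k)
  for (m in seq_len(k)) {
    inst <- strsplit(instantiate_motif(motifs[m]), "")[[1]]
    lo <- (m - 1L) * seg + 1L
    hi <- min(m * seg, len - 8L) - length(inst)
    pos <- if (hi > lo) sample(lo:hi, 1L) else lo
    s[pos:(pos + length(inst) - 1L)] <- inst
  }
  paste(s, collapse = "")
}

# mutate the sequence until the given motif no longer matches anywhere
strip_motif <- function(sequence, motif) {
  repeat {
    hits <- scan_motifs(sequence, motif)[[1]]
    if (length(hits) == 0L) {
      return(sequence)
    }
    chars <- strsplit(sequence, "")[[1]]
    first <- strsplit(motif, "")[[1]][1]
    repl <- sample(setdiff(AA_ALPHABET, first), 1L)
    chars[hits[1]] <- repl
    sequence <- paste(chars, collapse = "")
  }
}

# gene with requested boundary codons and random, stop-free interior
make_gene <- function(n_codons, start = "ATG", stop = "TAA") {
  interior <- c(
    "GCT", "GCA", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT", "AAA",
    "CTG", "AAT", "CCG", "CAG", "CGT", "TCT", "ACC", "GTT", "TGG"
  )
  mid <- paste(sample(interior, max(n_codons - 2L, 1L), replace = TRUE),
    collapse = ""
  )
  paste0(start, mid, stop)
}

#' Generate a synthetic screening fixture with planted positives
#'
#' Builds `n_proteins` protein records of which `n_positives` are planted
#' true positives: they carry both active-site motifs, a valid start and stop
#' codon on their gene, a length inside the configured family window, a
#' sampling site passing the environment filter, and either a SCAP domain hit
#' or a similarity hit at or below the e-value cutoff.  The remaining decoys
#' each violate a designated criterion (no evidence, missing motif, bad gene
#' boundaries, aberrant length, cold/acidic sampling site, or near-duplicate
#' of a positive); with at least six decoys every criterion is violated at
#' least once.  Running [compile_report()] on the fixture with the same
#' configuration selects exactly the planted ids.
#'
#' @param n_proteins total number of proteins.
#' @param n_positives number of planted positives (`<= n_proteins`).
#' @param seed integer seed; output is deterministic given the seed.
#' @param config a [screen_config()].
#' @return A list of class `"screen_fixture"` with elements `proteins`,
#'   `domain_table`, `similarity_table`, `topology_table`, `metadata`,
#'   `truth` (planted ids) and `config`.
#' @export
#' @examples
#' fx <- make_screen_fixture(12, 4, seed = 7)
#' length(fx$truth)
make_screen_fixture <- function(n_proteins, n_positives, seed,
                                config = screen_config()) {
  if (n_positives > n_proteins || n_positives < 0) {
    stop_invalid("need 0 <= n_positives <= n_proteins")
  }
  with_seed(seed, {
    ids <- sprintf("prot_%03d", seq_len(n_proteins))
    pos_ids <- if (n_positives > 0) sample(ids, n_positives) else character(0)
    dec_ids <- setdiff(ids, pos_ids)

    hot <- data.frame(
      sample_id = sprintf("hot_spring_%d", 1:3),
      temperature = round(runif(3, max(config$min_temperature, 85), 97), 1),
      ph = round(runif(3, 8, 10), 2),
      description = "terrestrial hot spring sediment",
      stringsAsFactors = FALSE
    )
    cold <- data.frame(
      sample_id = "mesophilic_1", temperature = 25, ph = 6.5,
      description = "temperate freshwater sediment",
      stringsAsFactors = FALSE
    )
    metadata <- rbind(hot, cold)

    lw <- config$length_window * config$family_mean_length
    pos_len_range <- c(ceiling(lw[1] * 1.3), floor(lw[2] * 0.75))

    proteins <- data.frame(
      id = ids, sequence = NA_character_, gene_nt = NA_character_,
      sample_id = NA_character_, start_truncated = FALSE,
      end_truncated = FALSE, stringsAsFactors = FALSE
    )
    domain_rows <- list()
    sim_rows <- list()
    sp_flags <- stats::setNames(rep(FALSE, n_proteins), ids)

    scap_hit <- function(id, len) {
      data.frame(
        protein_id = id, profile_accession = "PF00484.21",
        profile_name = "Pro_CA",
        i_evalue = 10^-sample(15:40, 1L),
        bit_score = round(runif(1, 60, 200), 1),
        env_from = 3L, env_to = as.integer(len - 2L),
        stringsAsFactors = FALSE
      )
    }
    sim_hit <- function(id, evalue) {
      data.frame(
        query_id = id,
        subject_id = sprintf("WP_%09d.1", sample(1e6, 1L)),
        pct_identity = round(runif(1, 40, 95), 1),
        length = 150L, mismatch = 20L, gapopen = 2L, qstart = 1L,
        qend = 150L, sstart = 1L, send = 150L,
        evalue = evalue, bit_score = round(runif(1, 150, 400), 1),
        stringsAsFactors = FALSE
      )
    }

    # --- positives -------------------------------------------------------
    for (k in seq_along(pos_ids)) {
      id <- pos_ids[k]
      i <- match(id, ids)
      len <- sample(pos_len_range[1]:pos_len_range[2], 1L)
      proteins$sequence[i] <- plant_motifs(len, config$motifs)
      proteins$gene_nt[i] <- make_gene(len + 1L,
        start = sample(config$start_codons, 1L),
        stop = sample(config$stop_codons, 1L)
      )
      proteins$sample_id[i] <- sample(hot$sample_id, 1L)
      # alternate evidence branch: odd positives via SCAP, even via fnr
      if (k %% 2L == 1L) {
        domain_rows[[length(domain_rows) + 1L]] <- scap_hit(id, len)
      } else {
        sim_rows[[length(sim_rows) + 1L]] <- sim_hit(id, 10^-sample(55:120, 1L))
      }
    }

    # --- decoys ----------------------------------------------------------
    types <- c(
      "no_evidence", "no_motif", "bad_boundaries", "bad_length",
      "bad_environment", "near_duplicate"
    )
    if (n_positives == 0L) types[types == "near_duplicate"] <- "no_evidence"
    for (k in seq_along(dec_ids)) {
      id <- dec_ids[k]
      i <- match(id, ids)
      type <- types[(k - 1L) %% length(types) + 1L]
      len <- sample(pos_len_range[1]:pos_len_range[2], 1L)
      sq <- plant_motifs(len, config$motifs)
      gene <- make_gene(len + 1L)
      smp <- sample(hot$sample_id, 1L)
      evidence <- "scap"
      if (type == "no_evidence") {
        evidence <- "none"
        # a similarity hit too weak to qualify, for realism
        sim_rows[[length(sim_rows) + 1L]] <- sim_hit(id, 10^-sample(3:20, 1L))
        sp_flags[id] <- TRUE # SP flag rides along on a failing decoy
      } else if (type == "no_motif") {
        sq <- strip_motif(sq, config$motifs[1])
      } else if (type == "bad_boundaries") {
        gene <- make_gene(len + 1L, start = "CCC", stop = "CCC")
      } else if (type == "bad_length") {
        len <- max(10L, floor(lw[1] * 0.4))
        sq <- plant_motifs(len, config$motifs)
        gene <- make_gene(len + 1L)
      } else if (type == "bad_environment") {
        smp <- cold$sample_id
      } else if (type == "near_duplicate") {
        template <- proteins$sequence[match(pos_ids[(k - 1L) %% n_positives + 1L], ids)]
        chars <- strsplit(template, "")[[1]]
        tlen <- length(chars)
        # keep planted motif instances intact while mutating ~3% elsewhere
        mot <- scan_motifs(template, config$motifs)
        protected <- unlist(lapply(seq_along(mot), function(m) {
          w <- nchar(names(mot)[m])
          unlist(lapply(mot[[m]], function(p) p:(p + w - 1L)))
        }))
        free <- setdiff(seq_len(tlen - 6L), protected)
        nmut <- max(1L, ceiling(0.03 * tlen))
        at <- sample(free, min(nmut, length(free)))
        for (p in at) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
        sq <- paste(chars[seq_len(tlen - 6L)], collapse = "") # 6 aa shorter
        len <- tlen - 6L
        gene <- make_gene(len + 1L)
      }
      proteins$sequence[i] <- sq
      proteins$gene_nt[i] <- gene
      proteins$sample_id[i] <- smp
      if (evidence == "scap") {
        domain_rows[[length(domain_rows) + 1L]] <- scap_hit(id, nchar(sq))
      }
    }

    domain_table <- if (length(domain_rows)) {
      do.call(rbind, domain_rows)
    } else {
      stats::setNames(data.frame(
        character(0), character(0), character(0),
        numeric(0), numeric(0), integer(0), integer(0)
      ), DOMTBL_COLS)
    }
    similarity_table <- if (length(sim_rows)) {
      do.call(rbind, sim_rows)
    } else {
      stats::setNames(
        data.frame(
          character(0), character(0), numeric(0), integer(0),
          integer(0), integer(0), integer(0), integer(0), integer(0),
          integer(0), numeric(0), numeric(0)
        ), BLAST_COLS
      )
    }
    topology_table <- data.frame(
      protein_id = ids, sp = unname(sp_flags), tm = FALSE,
      stringsAsFactors = FALSE
    )

    structure(
      list(
        proteins = proteins, domain_table = domain_table,
        similarity_table = similarity_table,
        topology_table = topology_table, metadata = metadata,
        truth = sort(pos_ids), config = config
      ),
      class = "screen_fixture"
    )
  })
}

#' @export
print.screen_fixture <- function(x, ...) {
  cat(
    "Synthetic screen fixture:", nrow(x$proteins), "proteins,",
    length(x$truth), "planted positives\n"
  )
  invisible(x)
}
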