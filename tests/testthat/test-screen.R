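# Screening cascade operations.

test_that("keyword filter matches phrases on word boundaries and single words as whole tokens", {
  kw <- c("carbonic anhydrase", "carbonic dehydratase", "ca")
  expect_equal(
    filter_reference_by_keywords("putative carbonic anhydrase [organism]", kw), 1L
  )
  expect_equal(
    filter_reference_by_keywords("calcium-binding protein", kw), integer(0)
  )
  expect_equal(filter_reference_by_keywords("Ca channel subunit", kw), 1L)
  # phrase must sit on word boundaries; token matching is case-insensitive
  expect_equal(
    filter_reference_by_keywords(
      c(
        "dicarbonic anhydraselike protein", # embedded, not on boundaries
        "Carbonic Dehydratase, partial",
        "CA", "cap protein"
      ), kw
    ),
    c(2L, 3L)
  )
  expect_error(filter_reference_by_keywords("x", character(0)), "non-empty")
})

test_that("SCAP branch keeps any protein with at least one SCAP profile hit, no e-value cut", {
  cfg <- screen_config()
  hits <- data.frame(
    protein_id = c("p1", "p2", "p3"),
    profile_accession = c("PF00484.21", "PF99999.1", "PF00194.23"),
    i_evalue = c(0.5, 1e-80, 1e-3) # weak hits still count
  )
  expect_equal(select_scap_hits(hits, cfg), c("p1", "p3"))
  expect_equal(select_scap_hits(hits[0, ], cfg), character(0))
})

test_that("similarity branch applies the inclusive 1e-50 e-value bound", {
  cfg <- screen_config()
  hits <- data.frame(
    query_id = c("a", "b", "c"),
    evalue = c(1e-50, 1e-49, 0)
  )
  expect_equal(select_similarity_hits(hits, cfg), c("a", "c"))
  expect_error(
    select_similarity_hits(data.frame(query_id = "a", evalue = -1), cfg),
    "negative"
  )
})

test_that("motif scan finds overlapping 1-based matches and agrees with the brute-force oracle", {
  hits <- scan_motifs("CADARHAAC")
  expect_equal(hits$CxDxR, 1L)
  expect_equal(hits$HxxC, 6L)
  expect_equal(lengths(scan_motifs("AAAAA")), c(CxDxR = 0L, HxxC = 0L))
  # oracle-derived value for a sequence with decoy prefix characters
  expect_equal(scan_motifs("CCDCRCDER", "CxDxR")[[1]], oracle_scan("CCDCRCDER", "CxDxR"))
  expect_equal(scan_motifs("CCDCRCDER", "CxDxR")[[1]], 1L)
  # overlapping matches are all reported
  expect_equal(scan_motifs("HHAACAAC", "HxxC")[[1]], oracle_scan("HHAACAAC", "HxxC"))
  withr_seed <- 424
  set.seed(withr_seed)
  for (i in 1:200) {
    s <- random_seq(sample(5:50, 1))
    for (m in c("CxDxR", "HxxC")) {
      expect_identical(scan_motifs(s, m)[[1]], oracle_scan(s, m))
    }
  }
  expect_error(scan_motifs(""), "non-empty")
})

test_that("gene boundary check recognises the accepted start and stop codon sets", {
  cfg <- screen_config()
  expect_equal(
    check_gene_boundaries("ATGAAATAA", cfg),
    list(has_start = TRUE, has_stop = TRUE)
  )
  expect_equal(
    check_gene_boundaries("GTGAAATAG", cfg),
    list(has_start = TRUE, has_stop = TRUE)
  )
  expect_equal(
    check_gene_boundaries("CCCAAACCC", cfg),
    list(has_start = FALSE, has_stop = FALSE)
  )
  expect_equal(
    check_gene_boundaries("TTGAAATGA", cfg),
    list(has_start = TRUE, has_stop = TRUE)
  )
  expect_error(check_gene_boundaries("ATGAAZTAA", cfg), "non-ACGT")
  expect_error(check_gene_boundaries("ATGANATAA", cfg), "ambiguous")
  expect_equal(
    check_gene_boundaries("ATGANATAA", cfg, tolerate_n = TRUE),
    list(has_start = FALSE, has_stop = FALSE)
  )
})

test_that("pairwise identity matches exhaustive alignment oracle and is symmetric", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 100)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 75)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  set.seed(11)
  for (i in 1:40) {
    a <- random_seq(sample(2:6, 1))
    b <- random_seq(sample(2:6, 1))
    expect_equal(pairwise_identity(a, b), oracle_identity(a, b),
      info = paste(a, b)
    )
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "A"), "non-empty")
})

test_that("de-duplication merges at the inclusive cutoff and leaves representatives below it", {
  p <- data.frame(
    id = c("x", "y", "z"),
    sequence = c("ACDEFGHIKL", "ACDEFGHIKL", "WWWWYYYYWW")
  )
  expect_length(dedup_candidates(p, 90), 2L)
  # exactly at the cutoff: 9/10 identical columns = 90% -> merged
  q <- data.frame(id = c("a", "b"), sequence = c("ACDEFGHIKL", "ACDEFGHIKW"))
  expect_equal(pairwise_identity(q$sequence[1], q$sequence[2]), 90)
  expect_length(dedup_candidates(q, 90), 1L)
  # any output set is mutually below the cutoff (all-pairs oracle)
  set.seed(5)
  pool <- data.frame(
    id = sprintf("s%02d", 1:12),
    sequence = replicate(12, random_seq(sample(8:14, 1)))
  )
  reps <- dedup_candidates(pool, 60)
  seqs <- pool$sequence[match(reps, pool$id)]
  if (length(reps) > 1) {
    for (i in 1:(length(reps) - 1)) {
      for (j in (i + 1):length(reps)) {
        expect_lt(pairwise_identity(seqs[i], seqs[j]), 60)
      }
    }
  }
})

test_that("environment filter applies inclusive temperature and alkalinity rules", {
  md <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    temperature = c(90, 89.9, 95, 80),
    ph = c(9, 9, 6.5, 7.0)
  )
  cfg90 <- screen_config(min_temperature = 90)
  expect_equal(filter_samples_by_environment(md, cfg90), "a")
  # pH exactly 7 is not alkaline
  cfg80 <- screen_config(min_temperature = 80)
  expect_equal(filter_samples_by_environment(md, cfg80), c("a", "b"))
  cfg_noalk <- screen_config(min_temperature = 80, require_alkaline = FALSE)
  expect_equal(filter_samples_by_environment(md, cfg_noalk), c("a", "b", "c", "d"))
})

test_that("full cascade selects exactly the planted positives and reports failure reasons", {
  fx <- make_screen_fixture(12, 4, seed = 7)
  rep <- compile_report(
    fx$proteins, fx$domain_table, fx$similarity_table,
    fx$topology_table, fx$metadata, fx$config
  )
  expect_equal(sort(rep$protein_id[rep$selected]), fx$truth)
  # environment failure recorded with a reason
  cold <- rep[!rep$env_ok, ]
  expect_gt(nrow(cold), 0)
  expect_false(any(cold$selected))
  expect_true(all(grepl("environment", cold$reasons)))
  # a near-duplicate of a positive is present and marked non-representative
  dup <- rep[rep$branch != "none" & rep$env_ok & rep$motifs_ok &
    rep$boundary_ok & rep$length_ok & !rep$selected, ]
  expect_gt(nrow(dup), 0)
  expect_true(any(grepl("redundant", dup$reasons)))
})

test_that("cascade report is invariant to input row order", {
  fx <- make_screen_fixture(10, 3, seed = 3)
  rep1 <- compile_report(
    fx$proteins, fx$domain_table, fx$similarity_table,
    fx$topology_table, fx$metadata, fx$config
  )
  set.seed(99)
  shuf <- function(df) df[sample(nrow(df)), , drop = FALSE]
  rep2 <- compile_report(
    shuf(fx$proteins), shuf(fx$domain_table), shuf(fx$similarity_table),
    shuf(fx$topology_table), shuf(fx$metadata), fx$config
  )
  rownames(rep1) <- rownames(rep2) <- NULL
  expect_equal(rep1, rep2)
})

test_that("no protein is assigned to both evidence branches", {
  for (s in 1:5) {
    fx <- make_screen_fixture(10, 4, seed = s)
    rep <- compile_report(
      fx$proteins, fx$domain_table, fx$similarity_table,
      fx$topology_table, fx$metadata, fx$config
    )
    scap <- select_scap_hits(fx$domain_table, fx$config)
    expect_length(intersect(rep$protein_id[rep$branch == "fnr"], scap), 0)
  }
})

test_that("annotations referencing unknown proteins raise a referential-integrity error", {
  fx <- make_screen_fixture(6, 2, seed = 1)
  bad <- fx$domain_table
  bad$protein_id[1] <- "ghost_001"
  expect_error(
    compile_report(
      fx$proteins, bad, fx$similarity_table,
      fx$topology_table, fx$metadata, fx$config
    ),
    "unknown protein"
  )
})
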