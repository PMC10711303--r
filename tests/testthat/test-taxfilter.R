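r1 <- filter_preset("round1")
r2 <- filter_preset("round2")

test_that("hit-table parsing: identity case, round trip, validation", {
  empty <- read_hit_table(text = character(0), dialect = "outfmt6_tax")
  expect_equal(nrow(empty), 0L)

  row <- paste("q1", "s1", "80.0", "100", "5", "1", "1", "100", "1", "100",
               "1e-30", "180.5", "60", amoebozoa_lineage, sep = "\t")
  h <- read_hit_table(text = row, dialect = "outfmt6_tax")
  expect_equal(nrow(h), 1L)
  expect_equal(h$pident, 80)
  expect_equal(h$qcovs, 60)
  expect_length(split_lineage <- strsplit(h$lineage, ";")[[1]], 4L)
  expect_equal(trimws(split_lineage)[3], "Amoebozoa")

  tmp <- withr::local_tempfile()
  write_hit_table(h, tmp, "outfmt6_tax")
  expect_equal(read_hit_table(tmp, "outfmt6_tax"), h)

  bad <- sub("80.0", "101.0", row, fixed = TRUE)
  expect_error(read_hit_table(text = bad, dialect = "outfmt6_tax"),
               "line 1.*pident")
  short <- paste("q1", "s1", "80.0", sep = "\t")
  expect_error(read_hit_table(text = short, dialect = "outfmt6"), "line 1")
  expect_error(read_hit_table(text = sub("1e-30", "-1", row, fixed = TRUE),
                              dialect = "outfmt6_tax"), "evalue")
})

test_that("classify_hit applies thresholds inclusively with a target veto", {
  # round 1 thresholds 75/50
  expect_equal(classify_hit(hit_row("q", pident = 80, qcovs = 60), r1),
               "CONTAMINANT_EVIDENCE")
  expect_equal(classify_hit(hit_row("q", pident = 75, qcovs = 50), r1),
               "CONTAMINANT_EVIDENCE")          # inclusive thresholds
  expect_equal(classify_hit(hit_row("q", pident = 74.9, qcovs = 99), r1),
               "UNINFORMATIVE")
  expect_equal(classify_hit(hit_row("q", pident = 99, qcovs = 49.9), r1),
               "UNINFORMATIVE")
  # target-clade membership wins regardless of identity
  expect_equal(classify_hit(hit_row("q", pident = 99.9,
                                    lineage = amoebozoa_lineage), r1),
               "TARGET_EVIDENCE")
  # unknown taxonomy is never contaminant evidence
  expect_equal(classify_hit(hit_row("q", pident = 99,
                                    lineage = NA_character_), r1),
               "UNINFORMATIVE")
  # round 2: identity 70, no coverage requirement
  expect_equal(classify_hit(hit_row("q", pident = 72, qcovs = NA), r2),
               "CONTAMINANT_EVIDENCE")
  expect_equal(classify_hit(hit_row("q", pident = 69.9, qcovs = NA), r2),
               "UNINFORMATIVE")
})

test_that("filter_sequences: removal policies, no-hit keeps, orphan warning", {
  nohits <- filter_sequences(c("a", "b"), hit_row("z")[0, ], r1)
  expect_equal(nohits$kept_ids, c("a", "b"))
  expect_equal(nohits$removed_ids, character(0))

  # contaminant + target evidence on the same id: policy truth table
  hits <- hits_of(hit_row("a", "s1", pident = 90, qcovs = 80),
                  hit_row("a", "s2", pident = 50, qcovs = 80,
                          lineage = amoebozoa_lineage))
  veto <- filter_sequences("a", hits, r1)
  expect_equal(veto$kept_ids, "a")
  noveto <- filter_sequences(
    "a", hits, filter_config(1e-2, 5, 75, 50, "Amoebozoa",
                             "NO_TARGET_AMONG_QUALIFYING"))
  expect_equal(noveto$removed_ids, "a")
  # contaminant evidence alone removes under both policies
  alone <- filter_sequences("a", hit_row("a", pident = 90, qcovs = 80), r1)
  expect_equal(alone$removed_ids, "a")

  expect_warning(r <- filter_sequences("a", hit_row("ghost"), r1),
                 "not in the input set")
  expect_equal(r$kept_ids, "a")
})

test_that("E-value cutoff and best-N limit are enforced defensively", {
  # 6 hits for one query: the contaminant hit is 6th by bitscore and must
  # be dropped by the best-5 rule; a weak-E-value contaminant is dropped too
  hits <- do.call(rbind, c(
    lapply(1:5, function(i)
      hit_row("a", sprintf("t%d", i), pident = 40, qcovs = 80,
              bitscore = 500 - i, lineage = amoebozoa_lineage)),
    list(hit_row("a", "bad", pident = 95, qcovs = 95, bitscore = 100),
         hit_row("b", "bad2", pident = 95, qcovs = 95, evalue = 0.5))))
  rep <- filter_sequences(c("a", "b"), hits, r1)
  expect_equal(rep$removed_ids, character(0))
  # pre-filtering to the retained set gives the identical report
  pre <- hits[hits$evalue <= 1e-2, ]
  pre <- pre[order(pre$qseqid, -pre$bitscore), ]
  pre <- pre[stats::ave(seq_len(nrow(pre)), pre$qseqid, FUN = seq_along) <= 5, ]
  rep_pre <- filter_sequences(c("a", "b"), pre, r1)
  expect_equal(rep_pre$kept_ids, rep$kept_ids)
  expect_equal(rep_pre$removed_ids, rep$removed_ids)
})

test_that("two-round filtering: presets, boundaries and staging", {
  # all hits to the target clade: nothing removed in either round
  tr <- c("t1", "t2"); pr <- c("t1.p1", "t2.p1")
  target_hits <- hits_of(hit_row("t1", lineage = amoebozoa_lineage),
                         hit_row("t2", lineage = amoebozoa_lineage))
  aa_target <- hits_of(hit_row("t1.p1", lineage = amoebozoa_lineage))
  rep <- two_round_filter(tr, target_hits, pr, aa_target)
  expect_equal(rep$removed_transcripts, character(0))
  expect_equal(rep$removed_proteins, character(0))

  # round-2 identity boundary: 72 removes, 69.9 keeps
  aa <- hits_of(hit_row("t1.p1", pident = 72, qcovs = NA),
                hit_row("t2.p1", pident = 69.9, qcovs = NA))
  rep <- two_round_filter(tr, target_hits, pr, aa)
  expect_equal(rep$removed_proteins, "t1.p1")
  expect_equal(rep$decisions$round[rep$decisions$id == "t1.p1"], 2L)

  # protein of a transcript removed in round 1 is excluded and flagged
  nt <- hit_row("t1", pident = 90, qcovs = 80)
  expect_warning(
    rep <- two_round_filter(tr, nt, pr, aa_target[0, ]),
    "map to transcripts removed")
  expect_equal(rep$removed_transcripts, "t1")
  expect_equal(rep$removed_proteins, "t1.p1")
  expect_equal(rep$decisions$round[rep$decisions$id == "t1.p1"], 1L)
})

test_that("filter invariants: partition, monotonicity, idempotence, order",  {
  set.seed(71)
  for (rep_i in 1:20) {
    ids <- sprintf("s%03d", 1:40)
    n_hits <- 120
    hits <- hit_row(sample(ids, n_hits, TRUE),
                    sseqid = sprintf("x%03d", 1:n_hits),
                    pident = runif(n_hits, 40, 100),
                    qcovs = runif(n_hits, 10, 100),
                    evalue = 10^runif(n_hits, -40, 0),
                    bitscore = runif(n_hits, 50, 900),
                    lineage = sample(c(amoebozoa_lineage, bacteria_lineage,
                                       NA_character_), n_hits, TRUE))
    r <- filter_sequences(ids, hits, r1)
    # partition
    expect_setequal(c(r$kept_ids, r$removed_ids), ids)
    expect_length(intersect(r$kept_ids, r$removed_ids), 0L)
    # monotonicity: a stricter identity threshold never removes more
    stricter <- filter_config(1e-2, 5, 90, 50, "Amoebozoa")
    r_strict <- filter_sequences(ids, hits, stricter)
    expect_true(all(r_strict$removed_ids %in% r$removed_ids))
    # idempotence on the kept set
    again <- filter_sequences(r$kept_ids, hits[hits$qseqid %in% r$kept_ids, ],
                              r1)
    expect_length(again$removed_ids, 0L)
    # order-independence
    perm <- hits[sample.int(n_hits), ]
    r_perm <- filter_sequences(ids, perm, r1)
    expect_equal(r_perm$kept_ids, r$kept_ids)
    expect_equal(r_perm$removed_ids, r$removed_ids)
  }
})

test_that("planted two-stage contaminants are removed in their proper round", {
  cfg <- sim_config(seed = 7, n_genuine = 80, n_contaminant = 20,
                    round2_fraction = 0.5)
  d <- sim_decontam_inputs(cfg)
  rep <- suppressWarnings(
    two_round_filter(d$transcript_ids, d$nt_hits, d$protein_ids, d$aa_hits))
  expect_setequal(rep$removed_transcripts, d$truth$contaminant_transcripts_round1)
  r2_removed <- rep$decisions$id[rep$decisions$type == "protein" &
                                   rep$decisions$round %in% 2L]
  expect_setequal(r2_removed, d$truth$contaminant_proteins_round2)
})
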