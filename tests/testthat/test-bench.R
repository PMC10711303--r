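test_that("reference label sets: counts, provenance, ambiguity error", {
  labs <- build_reference_labels(c("m1", "m2"), c("r1", "r2", "r3"))
  expect_equal(nrow(labs), 5L)
  expect_equal(sum(labs$truth == "MRO"), 2L)
  expect_true(all(labs$provenance[labs$truth == "MRO"] == "KNOWN_MRO"))
  # KNOWN_MRO provenance iff truth MRO
  expect_true(all((labs$provenance == "KNOWN_MRO") == (labs$truth == "MRO")))
  # duplicates within a set collapse
  expect_equal(nrow(build_reference_labels(c("m1", "m1"), "r1")), 2L)
  expect_error(build_reference_labels(c("m1"), c("m1", "r1")),
               "ambiguous truth")
  expect_error(build_reference_labels("m1", "r1", "r1"),
               "both ribosomal and replisomal")
})

test_that("normalization: PT->MT rule, vocabulary check, NO_CALL", {
  # a tool without a non-plant mode: plastid counts as mitochondrial
  dl <- tool_profile("DeepLoc2", c("Mitochondrion", "Plastid", "Other"),
                     "Mitochondrion", "Plastid", has_nonplant_mode = FALSE)
  got <- normalize_calls(
    data.frame(protein_id = c("a", "b", "c", "d"),
               raw_class = c("Plastid", "Mitochondrion", "Other", NA)), dl)
  expect_equal(got$normalized_class,
               c("PT_TO_MT", "MT", "NON_MT", "NO_CALL"))
  expect_true(all(is_positive_call(got$normalized_class[1:2])))
  # the same raw label from a tool run in non-plant mode stays negative
  tp <- tool_profile("TargetP2", c("Mitochondrion", "Plastid", "Other"),
                     "Mitochondrion", "Plastid", has_nonplant_mode = TRUE)
  got2 <- normalize_calls(data.frame(protein_id = "a", raw_class = "Plastid"),
                          tp)
  expect_equal(got2$normalized_class, "NON_MT")
  expect_error(normalize_calls(
    data.frame(protein_id = "a", raw_class = "Cytoplasmic"), tp),
    "TargetP2.*Cytoplasmic")
  expect_error(tool_profile("t", "A", "B"), "positive_classes")
})

test_that("confusion: formulas, rounding, zero denominators, policies", {
  labs <- build_reference_labels(sprintf("m%02d", 1:10), sprintf("c%02d", 1:10))
  perfect <- rbind(call_row("T", labs$protein_id[labs$truth == "MRO"], "MT"),
                   call_row("T", labs$protein_id[labs$truth != "MRO"],
                            "NON_MT"))
  cs <- confusion(perfect, labs, "T")
  expect_equal(c(cs$TP, cs$TN, cs$FP, cs$FN), c(10L, 10L, 0L, 0L))
  expect_equal(cs$sensitivity_percent, 100)
  expect_equal(cs$specificity_percent, 100)

  # TP=31, FP=1 -> specificity 96.875, printed 97
  labs2 <- build_reference_labels(sprintf("m%02d", 1:40), sprintf("c%02d", 1:9))
  calls2 <- rbind(call_row("T", sprintf("m%02d", 1:31), "MT"),
                  call_row("T", "c01", "MT"))
  cs2 <- confusion(calls2, labs2, "T")
  expect_equal(cs2$TP, 31L)
  expect_equal(cs2$FP, 1L)
  expect_equal(cs2$specificity_percent, 100 * 31 / 32)
  expect_equal(round_half_up(cs2$specificity_percent), 97)

  # an unscored labelled protein is a negative under the default policy...
  expect_equal(cs2$FN, 9L)
  expect_equal(cs2$TN, 8L)
  # ...and leaves the denominators under "exclude"
  cs3 <- confusion(calls2, labs2, "T", no_call = "exclude")
  expect_equal(cs3$FN, 0L)
  expect_equal(cs3$TN + cs3$FP, 1L)

  # a predictor with no positives has undefined specificity, never 0 or 100
  none <- call_row("T", labs$protein_id, "NON_MT")
  expect_true(is.na(confusion(none, labs, "T")$specificity_percent))
  expect_error(confusion(perfect, labs, "missing_tool"), "scored no")
  expect_error(confusion(rbind(perfect, call_row("T", "m01", "MT")),
                         labs, "T"), "multiple calls")
})

test_that("denominators are tool-invariant under the negative-call policy", {
  set.seed(5)
  labs <- build_reference_labels(sprintf("m%02d", 1:20), sprintf("c%02d", 1:50))
  sums <- lapply(c("A", "B", "C"), function(t) {
    scored <- sample(labs$protein_id, 55)
    calls <- call_row(t, scored,
                      sample(c("MT", "NON_MT", "NO_CALL"), 55, TRUE))
    confusion(calls, labs, t)
  })
  expect_equal(unique(vapply(sums, function(s) s$TP + s$FN, numeric(1))), 20)
  expect_equal(unique(vapply(sums, function(s) s$TN + s$FP, numeric(1))), 50)
})

test_that("rank_and_select reproduces the benchmark ordering and tie rules", {
  # the three published survivors: specificity 97/79/100, sensitivity 46/45/77
  printed <- data.frame(
    tool_name = c("TargetP2", "PProwler", "DeepLoc2", "NommPred"),
    sensitivity_percent = c(46, 45, 77, 36),
    specificity_percent = c(97, 79, 100, 30),
    stringsAsFactors = FALSE)
  expect_equal(rank_and_select(printed, k = 3, min_specificity = 50),
               c("DeepLoc2", "TargetP2", "PProwler"))
  # below-threshold tools are excluded even if k is not reached
  expect_warning(sel <- rank_and_select(printed, k = 4, min_specificity = 50),
                 "only 3")
  expect_equal(sel, c("DeepLoc2", "TargetP2", "PProwler"))
  expect_warning(none <- rank_and_select(printed, k = 1,
                                         min_specificity = 100.5),
                 "only 0")
  expect_length(none, 0L)
  # deterministic name tie-break equals a brute-force sort
  set.seed(9)
  for (i in 1:20) {
    tools <- sprintf("t%02d", sample(20, 6))
    df <- data.frame(tool_name = tools,
                     sensitivity_percent = sample(c(40, 70), 6, TRUE),
                     specificity_percent = sample(c(80, 95), 6, TRUE),
                     stringsAsFactors = FALSE)
    brute <- df[order(-df$specificity_percent, -df$sensitivity_percent,
                      df$tool_name), "tool_name"]
    expect_equal(rank_and_select(df, k = 6, min_specificity = 0), brute)
  }
})

test_that("venn partition: trivial mass, sum property, permutation", {
  labs <- build_reference_labels(sprintf("m%02d", 1:12), sprintf("c%02d", 1:30))
  tools <- c("A", "B", "C")
  allpos <- do.call(rbind, lapply(tools, function(t)
    rbind(call_row(t, labs$protein_id[labs$truth == "MRO"], "MT"),
          call_row(t, labs$protein_id[labs$truth != "MRO"], "NON_MT"))))
  vp <- venn_partition(allpos, labs, tools, "MRO", "POSITIVES")
  expect_equal(unname(vp$cell_counts["A+B+C"]), 12L)
  expect_equal(sum(vp$cell_counts), vp$total)

  expect_error(venn_partition(allpos, labs, c("A", "B")), "three")
  expect_error(venn_partition(allpos, labs, c("A", "B", "Z")), "Z")

  set.seed(11)
  for (i in 1:10) {
    calls <- do.call(rbind, lapply(tools, function(t)
      call_row(t, labs$protein_id,
               sample(c("MT", "PT_TO_MT", "NON_MT", "NO_CALL"), nrow(labs),
                      TRUE))))
    for (tr in c("MRO", "NON_MRO")) for (pol in c("POSITIVES", "NEGATIVES")) {
      vp <- venn_partition(calls, labs, tools, tr, pol)
      expect_equal(sum(vp$cell_counts), sum(labs$truth == tr))
      # tool-order permutation only relabels cells
      perm <- sample(tools)
      vp2 <- venn_partition(calls, labs, perm, tr, pol)
      relabel <- function(nm) if (!nzchar(nm)) "" else
        paste(sort(strsplit(nm, "+", fixed = TRUE)[[1]]), collapse = "+")
      c1 <- setNames(as.integer(vp$cell_counts),
                     vapply(names(vp$cell_counts), relabel, character(1)))
      c2 <- setNames(as.integer(vp2$cell_counts),
                     vapply(names(vp2$cell_counts), relabel, character(1)))
      expect_equal(c1[sort(names(c1))], c2[sort(names(c1))])
    }
  }
})

test_that("reciprocal best hits follow the tie-break rule exactly", {
  mk <- function(q, s, bits, ev = 1e-10) {
    data.frame(qseqid = q, sseqid = s, pident = 50, length = 100L,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
               sstart = 1L, send = 100L, evalue = ev, bitscore = bits,
               qcovs = NA_real_, lineage = NA_character_,
               stringsAsFactors = FALSE)
  }
  # mutual best
  expect_equal(rbh_pairs(mk("a", "b", 100), mk("b", "a", 90)),
               data.frame(id_a = "a", id_b = "b", stringsAsFactors = FALSE))
  # non-reciprocal
  expect_equal(nrow(rbh_pairs(mk("a", "b", 100),
                              rbind(mk("b", "c", 90), mk("b", "a", 80)))), 0L)
  expect_equal(nrow(rbh_pairs(mk("a", "b", 100), mk("b", "a", 90)[0, ])), 0L)

  # exhaustive check of the (bitscore, evalue, subject) rule on small tables
  brute_best <- function(hits, q) {
    h <- hits[hits$qseqid == q, , drop = FALSE]
    h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    if (nrow(h) == 0L) NA_character_ else h$sseqid[1]
  }
  set.seed(23)
  for (i in 1:30) {
    a_ids <- sprintf("a%d", 1:5); b_ids <- sprintf("b%d", 1:5)
    ab <- mk(sample(a_ids, 12, TRUE), sample(b_ids, 12, TRUE),
             sample(c(100, 200, 300), 12, TRUE),
             sample(c(1e-5, 1e-9), 12, TRUE))
    ba <- mk(sample(b_ids, 12, TRUE), sample(a_ids, 12, TRUE),
             sample(c(100, 200, 300), 12, TRUE),
             sample(c(1e-5, 1e-9), 12, TRUE))
    got <- rbh_pairs(ab, ba)
    want <- do.call(rbind, lapply(a_ids, function(a) {
      b <- brute_best(ab, a)
      if (!is.na(b) && identical(brute_best(ba, b), a))
        data.frame(id_a = a, id_b = b, stringsAsFactors = FALSE)
    }))
    if (is.null(want))
      want <- data.frame(id_a = character(0), id_b = character(0),
                         stringsAsFactors = FALSE)
    expect_equal(got, want[order(want$id_a), ], ignore_attr = TRUE)
  }
})

test_that("call and label tables round-trip through TSV", {
  cfg <- sim_config(seed = 3, n_mro_refs = 10, n_cyto_refs = 20)
  b <- sim_predictor_calls(cfg)
  tmp <- withr::local_tempfile()
  write_calls(b$calls, tmp)
  expect_equal(read_calls(tmp), b$calls)
  tmp2 <- withr::local_tempfile()
  write_labels(b$labels, tmp2)
  expect_equal(read_labels(tmp2), b$labels)
})
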