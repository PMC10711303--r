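#' Build a reference label set for predictor benchmarking
#'
#' The benchmark truth set combines bona-fide MRO proteins (positives) with
#' cytosolic proteins (negatives) drawn from ribosomal and replisomal
#' homologue sets.  The three id sets must be pairwise disjoint; an id
#' appearing in both an MRO and a cytosolic set has ambiguous truth and is a
#' hard error.  Duplicates within a set are collapsed.
#'
#' @param known_mro_ids ids of previously characterized MRO proteins.
#' @param ribosomal_ids ids of ribosomal-protein homologues (cytosolic).
#' @param replisomal_ids ids of replisomal-protein homologues (cytosolic).
#' @param species optional named character vector id -> species.
#' @return data.frame with columns `protein_id`, `truth` (`"MRO"` /
#'   `"NON_MRO"`), `provenance` (`"KNOWN_MRO"` / `"RIBOSOMAL"` /
#'   `"REPLISOMAL"`), `species`.
#' @export
build_reference_labels <- function(known_mro_ids, ribosomal_ids,
                                   replisomal_ids = character(0),
                                   species = NULL) {
  known_mro_ids <- unique(as.character(known_mro_ids))
  ribosomal_ids <- unique(as.character(ribosomal_ids))
  replisomal_ids <- unique(as.character(replisomal_ids))
  cyto <- c(ribosomal_ids, replisomal_ids)
  clash <- intersect(known_mro_ids, cyto)
  if (length(clash))
    stopf("ambiguous truth: id(s) in both MRO and cytosolic sets: %s",
          paste(head(clash, 5), collapse = ", "))
  dup <- intersect(ribosomal_ids, replisomal_ids)
  if (length(dup))
    stopf("id(s) in both ribosomal and replisomal sets: %s",
          paste(head(dup, 5), collapse = ", "))
  labels <- data.frame(
    protein_id = c(known_mro_ids, ribosomal_ids, replisomal_ids),
    truth = c(rep("MRO", length(known_mro_ids)), rep("NON_MRO", length(cyto))),
    provenance = c(rep("KNOWN_MRO", length(known_mro_ids)),
                   rep("RIBOSOMAL", length(ribosomal_ids)),
                   rep("REPLISOMAL", length(replisomal_ids))),
    stringsAsFactors = FALSE)
  labels$species <- if (is.null(species)) NA_character_
                    else unname(species[labels$protein_id])
  labels
}

#' Describe a localization predictor's output vocabulary
#'
#' @param tool_name predictor name.
#' @param class_vocabulary all raw labels the tool can emit.
#' @param positive_classes raw labels meaning mitochondrial targeting.
#' @param plastid_classes raw labels meaning plastid targeting.
#' @param has_nonplant_mode `TRUE` when the tool was (or can be) run with a
#'   non-plant option, so plastid calls are taken at face value.  When
#'   `FALSE`, plastid calls are re-mapped to mitochondrial (the "PT->MT"
#'   rule): plastidial and mitochondrial N-terminal targeting signals share
#'   characteristics, and the organisms under study carry no plastid.
#' @return an object of class `tool_profile`.
#' @export
tool_profile <- function(tool_name, class_vocabulary, positive_classes,
                         plastid_classes = character(0),
                         has_nonplant_mode = TRUE) {
  stopifnot(is_string(tool_name))
  if (!all(positive_classes %in% class_vocabulary))
    stopf("tool %s: positive_classes outside class_vocabulary", tool_name)
  if (!all(plastid_classes %in% class_vocabulary))
    stopf("tool %s: plastid_classes outside class_vocabulary", tool_name)
  structure(list(tool_name = tool_name,
                 class_vocabulary = unique(class_vocabulary),
                 positive_classes = unique(positive_classes),
                 plastid_classes = unique(plastid_classes),
                 has_nonplant_mode = isTRUE(has_nonplant_mode)),
            class = "tool_profile")
}

#' Normalize heterogeneous predictor output to a common verdict
#'
#' Maps each raw class to one of `MT` (mitochondrial), `PT_TO_MT` (plastid
#' call counted as mitochondrial under the PT->MT rule, only for tools
#' without a non-plant mode), `NON_MT`, or `NO_CALL` (missing prediction:
#' `NA` or empty raw class).  `MT` and `PT_TO_MT` both count as positive.
#'
#' @param raw data.frame with columns `protein_id`, `raw_class` and
#'   optionally `score`.
#' @param profile a [tool_profile()].
#' @return data.frame of normalized calls: `tool_name`, `protein_id`,
#'   `raw_class`, `normalized_class`, `score`.
#' @export
normalize_calls <- function(raw, profile) {
  stopifnot(inherits(profile, "tool_profile"))
  rc <- as.character(raw$raw_class)
  missing <- is.na(rc) | !nzchar(rc)
  unknown <- !missing & !(rc %in% profile$class_vocabulary)
  if (any(unknown))
    stopf("tool %s: raw class '%s' not in its vocabulary",
          profile$tool_name, rc[which(unknown)[1]])
  norm <- rep("NON_MT", length(rc))
  norm[rc %in% profile$positive_classes] <- "MT"
  plast <- rc %in% profile$plastid_classes
  norm[plast] <- if (profile$has_nonplant_mode) "NON_MT" else "PT_TO_MT"
  norm[missing] <- "NO_CALL"
  data.frame(tool_name = profile$tool_name,
             protein_id = as.character(raw$protein_id),
             raw_class = rc,
             normalized_class = norm,
             score = if ("score" %in% names(raw)) raw$score else NA_real_,
             stringsAsFactors = FALSE)
}

# a normalized call counts as a mitochondrial positive
is_positive_call <- function(normalized_class) {
  normalized_class %in% c("MT", "PT_TO_MT")
}

# per-tool positive/negative verdict for every labelled protein.
# no_call = "negative": a missing prediction counts as a negative call
# (an unpredicted MRO protein is a false negative); "exclude": the protein
# leaves the tool's denominators.
verdicts_for_tool <- function(calls, labels, tool,
                              no_call = c("negative", "exclude")) {
  no_call <- match.arg(no_call)
  tc <- calls[calls$tool_name == tool, , drop = FALSE]
  if (anyDuplicated(tc$protein_id))
    stopf("tool %s: multiple calls for protein '%s'",
          tool, tc$protein_id[duplicated(tc$protein_id)][1])
  idx <- match(labels$protein_id, tc$protein_id)
  if (all(is.na(idx)))
    stopf("tool %s scored no labelled protein", tool)
  norm <- ifelse(is.na(idx), "NO_CALL", tc$normalized_class[idx])
  keep <- if (no_call == "exclude") norm != "NO_CALL"
          else rep(TRUE, length(norm))
  data.frame(protein_id = labels$protein_id[keep],
             truth = labels$truth[keep],
             positive = is_positive_call(norm[keep]),
             stringsAsFactors = FALSE)
}

#' Confusion matrix and metrics for one predictor
#'
#' Categories follow the benchmark convention for MRO reference sets:
#' TP = MRO-labelled proteins with a positive (mitochondrial) call;
#' FN = MRO-labelled without; FP = cytosolic (NON_MRO) with a positive call;
#' TN = cytosolic without.  Sensitivity is `100 * TP / (TP + FN)`.
#' "Specificity" follows the same benchmark's naming and is
#' `100 * TP / (TP + FP)` — the quantity usually called precision.
#' Metrics are kept at full precision; [round_half_up()] reproduces printed
#' integer percentages.  A zero denominator yields `NA` (never 0 or 100).
#'
#' @param calls normalized calls ([normalize_calls()]) for one or more tools.
#' @param labels reference labels ([build_reference_labels()]).
#' @param tool tool name to score.
#' @param no_call `"negative"` (default; a missing prediction is a negative
#'   call) or `"exclude"` (unscored proteins leave the denominators).
#' @return object of class `confusion_summary`: `tool_name`, `TP`, `TN`,
#'   `FP`, `FN`, `sensitivity_percent`, `specificity_percent`, `no_call`.
#' @export
confusion <- function(calls, labels, tool, no_call = c("negative", "exclude")) {
  no_call <- match.arg(no_call)
  v <- verdicts_for_tool(calls, labels, tool, no_call)
  if (nrow(v) == 0L)
    stopf("tool %s scored no labelled protein", tool)
  tp <- sum(v$truth == "MRO" & v$positive)
  fn <- sum(v$truth == "MRO" & !v$positive)
  fp <- sum(v$truth == "NON_MRO" & v$positive)
  tn <- sum(v$truth == "NON_MRO" & !v$positive)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  structure(list(tool_name = tool, TP = tp, TN = tn, FP = fp, FN = fn,
                 sensitivity_percent = sens, specificity_percent = spec,
                 no_call = no_call),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("%s: TP=%d TN=%d FP=%d FN=%d  sensitivity=%s%%  specificity=%s%%\n",
              x$tool_name, x$TP, x$TN, x$FP, x$FN,
              if (is.na(x$sensitivity_percent)) "NA"
              else round_half_up(x$sensitivity_percent),
              if (is.na(x$specificity_percent)) "NA"
              else round_half_up(x$specificity_percent)))
  invisible(x)
}

#' @export
as.data.frame.confusion_summary <- function(x, ...) {
  data.frame(tool_name = x$tool_name, TP = x$TP, TN = x$TN, FP = x$FP,
             FN = x$FN, sensitivity_percent = x$sensitivity_percent,
             specificity_percent = x$specificity_percent,
             stringsAsFactors = FALSE)
}

# coerce a list of confusion_summary (or a data.frame) to one data.frame
summaries_frame <- function(summaries) {
  if (is.data.frame(summaries)) return(summaries)
  if (inherits(summaries, "confusion_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, as.data.frame))
}

#' Rank predictors and select the best performers
#'
#' Tools whose specificity (in the TP/(TP+FP) sense) is below
#' `min_specificity` — or undefined — are excluded; survivors are ordered by
#' specificity, then sensitivity, then tool name (all deterministic), and
#' the first `k` are returned.
#'
#' @param summaries list of [confusion()] results or a data.frame with
#'   columns `tool_name`, `sensitivity_percent`, `specificity_percent`.
#' @param k number of tools to select (default 3).
#' @param min_specificity exclusion threshold in percent (default 50).
#' @return character vector of selected tool names (with a warning when
#'   fewer than `k` tools survive).
#' @export
rank_and_select <- function(summaries, k = 3L, min_specificity = 50) {
  stopifnot(k >= 1)
  df <- summaries_frame(summaries)
  df <- df[!is.na(df$specificity_percent) &
             df$specificity_percent >= min_specificity, , drop = FALSE]
  df <- df[order(-df$specificity_percent, -df$sensitivity_percent,
                 df$tool_name), , drop = FALSE]
  if (nrow(df) < k)
    warnf("only %d tool(s) meet min_specificity %g; returning all",
          nrow(df), min_specificity)
  head(df$tool_name, k)
}

#' Three-tool agreement partition (Venn cells)
#'
#' Partitions reference proteins of one truth class by which subset of three
#' predictors issued the focal call.  With `truth = "MRO"` and
#' `polarity = "POSITIVES"` the cells are the true-positive Venn diagram;
#' `truth = "NON_MRO"` / `"POSITIVES"` gives false positives;
#' `truth = "MRO"` / `"NEGATIVES"` false negatives; and
#' `truth = "NON_MRO"` / `"NEGATIVES"` true negatives.  Only proteins scored
#' by all three tools enter; each is assigned to exactly one of the 8 cells
#' (the empty cell collects proteins for which no tool made the focal call),
#' so cell counts always sum to the class total.
#'
#' @param calls normalized calls for (at least) the three tools.
#' @param labels reference labels.
#' @param tools exactly three tool names.
#' @param truth `"MRO"` or `"NON_MRO"`.
#' @param polarity `"POSITIVES"` or `"NEGATIVES"`.
#' @param no_call forwarded to the per-tool verdicts (default `"negative"`).
#' @return object of class `agreement_partition` with `cell_counts`, a named
#'   integer vector over the 8 tool subsets (names like `"A+B"`, `""` for
#'   the empty subset), plus `tools`, `truth`, `polarity`, `total`.
#' @export
venn_partition <- function(calls, labels, tools,
                           truth = c("MRO", "NON_MRO"),
                           polarity = c("POSITIVES", "NEGATIVES"),
                           no_call = "negative") {
  truth <- match.arg(truth)
  polarity <- match.arg(polarity)
  if (length(tools) != 3L || anyDuplicated(tools))
    stopf("venn_partition requires exactly three distinct tools")
  missing <- setdiff(tools, unique(calls$tool_name))
  if (length(missing))
    stopf("no calls found for tool(s): %s", paste(missing, collapse = ", "))
  no_call <- match.arg(no_call, c("negative", "exclude"))
  lab <- labels[labels$truth == truth, , drop = FALSE]
  verd <- lapply(tools, function(t) {
    tc <- calls[calls$tool_name == t, , drop = FALSE]
    idx <- match(lab$protein_id, tc$protein_id)
    norm <- ifelse(is.na(idx), "NO_CALL", tc$normalized_class[idx])
    scored <- !is.na(idx)
    if (no_call == "exclude") scored <- scored & norm != "NO_CALL"
    list(scored = scored, norm = norm)
  })
  scored_all <- Reduce(`&`, lapply(verd, `[[`, "scored"))
  focal <- vapply(verd, function(v) {
    pos <- is_positive_call(v$norm)
    if (polarity == "POSITIVES") pos else !pos
  }, logical(nrow(lab)))
  if (is.null(dim(focal))) focal <- matrix(focal, nrow = nrow(lab))
  focal <- focal[scored_all, , drop = FALSE]
  masks <- 0:7                         # bit i set <=> tool i made the call
  subsets <- vapply(masks, function(m)
    paste(tools[bitwAnd(m, 2^(0:2)) > 0], collapse = "+"), character(1))
  key <- 1L + as.integer(focal %*% 2^(0:2))
  counts <- setNames(tabulate(key, nbins = 8L), subsets)
  structure(list(cell_counts = counts, tools = tools, truth = truth,
                 polarity = polarity, total = sum(scored_all)),
            class = "agreement_partition")
}

#' @export
print.agreement_partition <- function(x, ...) {
  cat(sprintf("Agreement partition (%s, %s): %d proteins\n",
              x$truth, x$polarity, x$total))
  for (i in seq_along(x$cell_counts)) {
    nm <- names(x$cell_counts)[i]
    cat(sprintf("  [%s] %d\n", if (nzchar(nm)) nm else "none",
                x$cell_counts[i]))
  }
  invisible(x)
}

#' Reciprocal best hits between two sequence sets
#'
#' For each query the best hit is chosen by bitscore (descending), then
#' E-value (ascending), then subject id (lexicographic); multiple HSPs to
#' the same subject are collapsed to the best one first.  A pair `(a, b)`
#' is reported iff `b` is `a`'s unique best hit in the A->B table and `a` is
#' `b`'s unique best hit in the B->A table.
#'
#' @param hits_ab hit table of set A searched against set B.
#' @param hits_ba hit table of set B searched against set A.
#' @return data.frame with columns `id_a`, `id_b`, sorted by `id_a`.
#' @export
rbh_pairs <- function(hits_ab, hits_ba) {
  best_of <- function(hits) {
    if (nrow(hits) == 0L)
      return(data.frame(qseqid = character(0), sseqid = character(0),
                        stringsAsFactors = FALSE))
    ord <- order(hits$qseqid, hits$sseqid, -hits$bitscore, hits$evalue)
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits[c("qseqid", "sseqid")]), , drop = FALSE]
    ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
    hits <- hits[ord, , drop = FALSE]
    first <- !duplicated(hits$qseqid)
    hits[first, c("qseqid", "sseqid"), drop = FALSE]
  }
  ab <- best_of(hits_ab)
  ba <- best_of(hits_ba)
  back <- setNames(ba$sseqid, ba$qseqid)
  mutual <- !is.na(back[ab$sseqid]) & back[ab$sseqid] == ab$qseqid
  out <- data.frame(id_a = ab$qseqid[mutual], id_b = ab$sseqid[mutual],
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write normalized predictor calls and reference labels as TSV
#'
#' @param calls,labels data.frames in the package's normalized layouts.
#' @param file path.
#' @return the data (readers) or the path, invisibly (writers).
#' @name bench_io
NULL

#' @rdname bench_io
#' @export
write_calls <- function(calls, file) write_tsv(calls, file)

#' @rdname bench_io
#' @export
read_calls <- function(file) {
  df <- read_tsv(file, colClasses = c(tool_name = "character",
                                      protein_id = "character",
                                      raw_class = "character",
                                      normalized_class = "character"))
  df
}

#' @rdname bench_io
#' @export
write_labels <- function(labels, file) write_tsv(labels, file)

#' @rdname bench_io
#' @export
read_labels <- function(file) {
  read_tsv(file, colClasses = c(protein_id = "character",
                                truth = "character",
                                provenance = "character",
                                species = "character"))
}
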