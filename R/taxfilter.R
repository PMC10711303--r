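#' Configuration of one decontamination round
#'
#' A decontamination round screens assembled sequences against an annotated
#' hit table and removes sequences whose qualifying best hits fall outside
#' the target clade at or above the stated identity (and, optionally,
#' coverage) thresholds.
#'
#' @param evalue_cutoff maximum E-value for a hit to qualify.
#' @param max_hits_per_query number of best hits retained per query
#'   (bitscore desc, then E-value asc, then subject id).
#' @param identity_threshold_percent percent identity at or above which a
#'   non-target hit counts as contaminant evidence.
#' @param coverage_threshold_percent percent query coverage threshold, or
#'   `NULL` when the round imposes none.
#' @param target_clade taxon name whose presence anywhere in a subject's
#'   lineage marks the hit as target evidence.
#' @param removal_policy `"ANY_QUALIFYING_NONTARGET"` (default): a sequence
#'   is removed when it has at least one contaminant-evidence hit and no
#'   target-evidence hit (target-clade veto).
#'   `"NO_TARGET_AMONG_QUALIFYING"`: any contaminant-evidence hit removes the
#'   sequence even when a target-clade hit co-occurs among its qualifying
#'   hits (no veto).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(evalue_cutoff, max_hits_per_query,
                          identity_threshold_percent,
                          coverage_threshold_percent = NULL,
                          target_clade = "Amoebozoa",
                          removal_policy = c("ANY_QUALIFYING_NONTARGET",
                                             "NO_TARGET_AMONG_QUALIFYING")) {
  removal_policy <- match.arg(removal_policy)
  stopifnot(is.numeric(evalue_cutoff), evalue_cutoff >= 0,
            max_hits_per_query >= 1)
  if (identity_threshold_percent < 0 || identity_threshold_percent > 100)
    stopf("identity_threshold_percent must lie in [0, 100]")
  if (!is.null(coverage_threshold_percent) &&
      (coverage_threshold_percent < 0 || coverage_threshold_percent > 100))
    stopf("coverage_threshold_percent must lie in [0, 100]")
  if (!is_string(target_clade)) stopf("target_clade must be a single taxon name")
  structure(list(evalue_cutoff = evalue_cutoff,
                 max_hits_per_query = as.integer(max_hits_per_query),
                 identity_threshold_percent = identity_threshold_percent,
                 coverage_threshold_percent = coverage_threshold_percent,
                 target_clade = target_clade,
                 removal_policy = removal_policy),
            class = "filter_config")
}

#' Decontamination presets
#'
#' `"round1"` is the nucleotide-level screen: E-value cutoff 1e-2, five best
#' hits, identity >= 75 %, query coverage >= 50 %.  `"round2"` is the
#' protein-level screen on round-1 survivors: E-value cutoff 1e-5, one hit,
#' identity >= 70 %, no coverage threshold.  Thresholds are inclusive: a hit
#' at exactly the threshold counts as contaminant evidence.
#'
#' @param round `"round1"` or `"round2"`.
#' @param target_clade target clade name (default `"Amoebozoa"`).
#' @param removal_policy see [filter_config()].
#' @return a `filter_config`.
#' @export
filter_preset <- function(round = c("round1", "round2"),
                          target_clade = "Amoebozoa",
                          removal_policy = "ANY_QUALIFYING_NONTARGET") {
  round <- match.arg(round)
  switch(round,
    round1 = filter_config(1e-2, 5L, 75, 50, target_clade, removal_policy),
    round2 = filter_config(1e-5, 1L, 70, NULL, target_clade, removal_policy))
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Decontamination round configuration\n")
  cat(sprintf("  E-value cutoff:      %g (best %d hit%s per query)\n",
              x$evalue_cutoff, x$max_hits_per_query,
              if (x$max_hits_per_query > 1) "s" else ""))
  cat(sprintf("  identity threshold:  >= %g %%\n", x$identity_threshold_percent))
  cat(sprintf("  coverage threshold:  %s\n",
              if (is.null(x$coverage_threshold_percent)) "none"
              else sprintf(">= %g %%", x$coverage_threshold_percent)))
  cat(sprintf("  target clade:        %s\n  removal policy:      %s\n",
              x$target_clade, x$removal_policy))
  invisible(x)
}

#' Classify hits as target, contaminant or uninformative evidence
#'
#' A hit is `TARGET_EVIDENCE` when the target clade appears (exact name
#' match) anywhere in its subject lineage, regardless of identity.  It is
#' `CONTAMINANT_EVIDENCE` when the target clade is absent from a known
#' lineage and the hit's percent identity is at or above the round's
#' threshold (and its query coverage at or above the coverage threshold, when
#' one is set).  Everything else — including every hit with unknown
#' taxonomy — is `UNINFORMATIVE`: absence of evidence never removes data.
#'
#' @param hits data.frame of hits ([read_hit_table()]); one or many rows.
#' @param config a [filter_config()].
#' @return character vector of classifications, one per hit row.
#' @export
classify_hit <- function(hits, config) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(hits)
  out <- rep("UNINFORMATIVE", n)
  known <- !is.na(hits$lineage)
  is_target <- logical(n)
  is_target[known] <- lineage_has_clade(hits$lineage[known],
                                        config$target_clade)
  out[known & is_target] <- "TARGET_EVIDENCE"
  qual <- known & !is_target &
    !is.na(hits$pident) & hits$pident >= config$identity_threshold_percent
  if (!is.null(config$coverage_threshold_percent))
    qual <- qual & !is.na(hits$qcovs) &
      hits$qcovs >= config$coverage_threshold_percent
  out[qual] <- "CONTAMINANT_EVIDENCE"
  out
}

# defensively enforce the round's E-value cutoff and best-N limit:
# sort by bitscore desc, E-value asc, subject id asc, take top N per query
retain_hits <- function(hits, config) {
  hits <- hits[!is.na(hits$evalue) & hits$evalue <= config$evalue_cutoff, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(hits)), hits$qseqid, FUN = seq_along)
  hits <- hits[rank <= config$max_hits_per_query, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter a sequence set by taxonomy-annotated hits
#'
#' Applies one decontamination round.  The E-value cutoff and best-N-hits
#' limit are enforced internally, so pre-filtered and raw hit tables give
#' identical results.  A sequence with no qualifying hits is kept.
#'
#' @param ids character vector of sequence ids in the assembly.
#' @param hits hit table restricted (or not) to this round's search.
#' @param config a [filter_config()].
#' @return an object of class `filter_report` with elements `kept_ids`,
#'   `removed_ids`, `evidence` (data.frame of retained hits with their
#'   classification) and `config`.  `kept_ids` and `removed_ids` partition
#'   `ids`.
#' @export
filter_sequences <- function(ids, hits, config) {
  stopifnot(inherits(config, "filter_config"))
  ids <- unique(as.character(ids))
  if (nrow(hits) > 0) {
    orphan <- !(hits$qseqid %in% ids)
    if (any(orphan)) {
      warnf("%d hit(s) reference sequence ids not in the input set; ignored",
            sum(orphan))
      hits <- hits[!orphan, , drop = FALSE]
    }
  }
  hits <- retain_hits(hits, config)
  cls <- classify_hit(hits, config)
  evidence <- cbind(hits, classification = cls, stringsAsFactors = FALSE)
  has_contam <- unique(hits$qseqid[cls == "CONTAMINANT_EVIDENCE"])
  has_target <- unique(hits$qseqid[cls == "TARGET_EVIDENCE"])
  removed <- switch(config$removal_policy,
    ANY_QUALIFYING_NONTARGET = setdiff(has_contam, has_target),
    NO_TARGET_AMONG_QUALIFYING = has_contam)
  removed <- sort(intersect(removed, ids))
  structure(list(kept_ids = setdiff(ids, removed),
                 removed_ids = removed,
                 evidence = evidence,
                 config = config),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Decontamination report: %d kept, %d removed (policy %s)\n",
              length(x$kept_ids), length(x$removed_ids),
              x$config$removal_policy))
  invisible(x)
}

#' Two-round taxonomy-aware decontamination
#'
#' Round 1 screens assembled transcripts against a nucleotide-level hit
#' table ([filter_preset()] `"round1"`).  Proteins predicted from surviving
#' transcripts then undergo round 2 against a protein-level table
#' (`"round2"`).  A protein whose source transcript was removed in round 1
#' is excluded before round 2 and flagged with removal round 1.
#'
#' @param nucleotide_ids transcript ids entering round 1.
#' @param nt_hits nucleotide-level hit table (with lineage annotation).
#' @param protein_ids protein ids entering round 2.
#' @param aa_hits protein-level hit table.
#' @param protein_to_transcript named character vector mapping protein id to
#'   source transcript id.  By default a trailing `.p<number>` suffix is
#'   stripped, the TransDecoder convention.
#' @param target_clade target clade name.
#' @param round1,round2 `filter_config`s; default the presets.
#' @return object of class `two_round_report`: the per-round
#'   `filter_report`s, a combined `decisions` data.frame
#'   (`id`, `type`, `decision`, `round`) recording which round removed each
#'   sequence, and convenience vectors `kept_proteins`/`removed_proteins`.
#' @export
two_round_filter <- function(nucleotide_ids, nt_hits, protein_ids, aa_hits,
                             protein_to_transcript = NULL,
                             target_clade = "Amoebozoa",
                             round1 = filter_preset("round1", target_clade),
                             round2 = filter_preset("round2", target_clade)) {
  nucleotide_ids <- unique(as.character(nucleotide_ids))
  protein_ids <- unique(as.character(protein_ids))
  if (is.null(protein_to_transcript))
    protein_to_transcript <- setNames(sub("\\.p[0-9]+$", "", protein_ids),
                                      protein_ids)
  r1 <- filter_sequences(nucleotide_ids, nt_hits, round1)

  src <- protein_to_transcript[protein_ids]
  orphaned <- protein_ids[!is.na(src) & src %in% r1$removed_ids]
  if (length(orphaned))
    warnf("%d protein(s) map to transcripts removed in round 1; excluded",
          length(orphaned))
  round2_input <- setdiff(protein_ids, orphaned)
  r2 <- filter_sequences(round2_input, aa_hits, round2)

  decision_rows <- function(id, type, decision, round)
    data.frame(id = id, type = rep_len(type, length(id)),
               decision = rep_len(decision, length(id)),
               round = rep_len(round, length(id)), stringsAsFactors = FALSE)
  decisions <- rbind(
    decision_rows(r1$kept_ids, "transcript", "kept", NA_integer_),
    decision_rows(r1$removed_ids, "transcript", "removed", 1L),
    decision_rows(orphaned, "protein", "removed", 1L),
    decision_rows(r2$kept_ids, "protein", "kept", NA_integer_),
    decision_rows(r2$removed_ids, "protein", "removed", 2L))
  decisions <- decisions[order(decisions$type, decisions$id), ]
  rownames(decisions) <- NULL
  structure(list(round1 = r1, round2 = r2,
                 decisions = decisions,
                 kept_transcripts = r1$kept_ids,
                 removed_transcripts = r1$removed_ids,
                 kept_proteins = r2$kept_ids,
                 removed_proteins = sort(c(orphaned, r2$removed_ids))),
            class = "two_round_report")
}

#' @export
print.two_round_report <- function(x, ...) {
  cat("Two-round decontamination\n")
  cat(sprintf("  round 1: %d/%d transcripts removed\n",
              length(x$removed_transcripts),
              length(x$kept_transcripts) + length(x$removed_transcripts)))
  cat(sprintf("  round 2: %d/%d proteins removed (incl. %d orphaned)\n",
              length(x$removed_proteins),
              length(x$kept_proteins) + length(x$removed_proteins),
              sum(x$decisions$type == "protein" & x$decisions$round %in% 1L)))
  invisible(x)
}

#' Write a per-sequence decontamination decision table
#'
#' @param report a `two_round_report` or `filter_report`.
#' @param file output TSV path.
#' @return the path, invisibly.
#' @export
write_filter_report <- function(report, file) {
  if (inherits(report, "two_round_report")) {
    write_tsv(report$decisions, file)
  } else if (inherits(report, "filter_report")) {
    df <- rbind(
      data.frame(id = report$kept_ids, decision = "kept",
                 stringsAsFactors = FALSE),
      data.frame(id = report$removed_ids, decision = "removed",
                 stringsAsFactors = FALSE))
    write_tsv(df[order(df$id), ], file)
  } else stopf("unsupported report class")
  invisible(file)
}
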