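#' Two-evidence consensus call for one protein
#'
#' A protein is classified as a putative MRO protein when it is predicted
#' mitochondrion-localized by at least `k` of the selected best-performing
#' predictors (default `k = 1`, "at least one"), or when it shows
#' phylogenetic affinity with a previously characterized MRO protein
#' (`homology_affinity`, established externally by gene-tree inspection and
#' supplied as a flag).
#'
#' @param votes named logical vector of per-tool positive votes.
#' @param homology_affinity logical.
#' @param selected_tools tools whose votes count (default: all in `votes`);
#'   a selected tool absent from `votes` is an error.
#' @param k minimum number of positive votes (default 1).
#' @return `"MRO"` or `"NON_MRO"`.
#' @export
consensus_call <- function(votes, homology_affinity,
                           selected_tools = names(votes), k = 1L) {
  stopifnot(k >= 1)
  missing <- setdiff(selected_tools, names(votes))
  if (length(missing))
    stopf("selected tool(s) missing from votes: %s",
          paste(missing, collapse = ", "))
  v <- votes[selected_tools]
  if (anyNA(v)) stopf("votes must be TRUE/FALSE for all selected tools")
  if (sum(v) >= k || isTRUE(homology_affinity)) "MRO" else "NON_MRO"
}

#' Assemble a per-protein evidence table
#'
#' Combines predictor votes, homology affinity and N-terminal
#' targeting-sequence detection into one record per protein, applying
#' [consensus_call()] row-wise.  A protein with an incomplete N-terminus
#' (no detectable NTS) can still be called MRO through `homology_affinity`.
#'
#' @param protein_id,species character vectors (recycled scalars allowed).
#' @param votes logical matrix or data.frame, proteins x tools, columns
#'   named by tool.
#' @param homology_affinity logical vector.
#' @param nts_detected logical vector (default: any positive vote).
#' @param affinity_note free-text justification for affinity flags.
#' @param selected_tools,k forwarded to [consensus_call()].
#' @return data.frame with one row per protein: `protein_id`, `species`,
#'   `vote_<tool>` columns, `n_votes`, `vote_positive`, `homology_affinity`,
#'   `nts_detected`, `affinity_note`, `final_call`.
#' @export
evidence_table <- function(protein_id, species, votes, homology_affinity,
                           nts_detected = NULL, affinity_note = NA_character_,
                           selected_tools = colnames(votes), k = 1L) {
  votes <- as.matrix(as.data.frame(votes))
  storage.mode(votes) <- "logical"
  n <- length(protein_id)
  stopifnot(nrow(votes) == n)
  missing <- setdiff(selected_tools, colnames(votes))
  if (length(missing))
    stopf("selected tool(s) missing from votes: %s",
          paste(missing, collapse = ", "))
  sel <- votes[, selected_tools, drop = FALSE]
  n_votes <- rowSums(sel)
  vote_positive <- n_votes >= k
  final <- ifelse(vote_positive | homology_affinity, "MRO", "NON_MRO")
  out <- data.frame(protein_id = as.character(protein_id),
                    species = rep_len(as.character(species), n),
                    stringsAsFactors = FALSE)
  for (t in colnames(votes)) out[[paste0("vote_", t)]] <- votes[, t]
  out$n_votes <- as.integer(n_votes)
  out$vote_positive <- vote_positive
  out$homology_affinity <- as.logical(homology_affinity)
  out$nts_detected <- if (is.null(nts_detected)) vote_positive
                      else as.logical(nts_detected)
  out$affinity_note <- rep_len(as.character(affinity_note), n)
  out$final_call <- final
  out
}

# per-protein evidence grade, strongest first
grade_levels <- c("PREDICTED_MRO", "CLADE_ONLY", "CYTOSOLIC_ONLY", "ABSENT")

protein_grade <- function(evidence) {
  ifelse(evidence$vote_positive, "PREDICTED_MRO",
         ifelse(evidence$homology_affinity, "CLADE_ONLY", "CYTOSOLIC_ONLY"))
}

#' Build a species-by-component presence/absence matrix
#'
#' Each cell of the matrix summarizes the proteins that a component map
#' assigns to one pathway component in one species.  Under coding
#' `"MRO_STRICT"` a component is present when at least one mapped protein
#' has `final_call == "MRO"`; `"MRO_PLUS_CLADE"` additionally counts
#' proteins flagged `homology_affinity` even when their final call is
#' NON_MRO (the two codings coincide under the default consensus rule,
#' where affinity alone already yields an MRO call).  The cell's evidence
#' grade is the strongest grade among its mapped proteins:
#' `PREDICTED_MRO` > `CLADE_ONLY` > `CYTOSOLIC_ONLY` > `ABSENT`.
#'
#' @param evidence evidence table ([evidence_table()]).
#' @param cmap component map: data.frame with columns `component`,
#'   `pathway`, `species`, `protein_id` (one row per mapped protein).
#' @param coding `"MRO_PLUS_CLADE"` (default) or `"MRO_STRICT"`.
#' @return object of class `character_matrix`: `species` (rows, sorted),
#'   `components` (columns, in first-appearance order), `pathway` (named
#'   by component), binary `state` matrix and character `grade` matrix.
#' @export
build_character_matrix <- function(evidence, cmap,
                                   coding = c("MRO_PLUS_CLADE", "MRO_STRICT")) {
  coding <- match.arg(coding)
  need <- c("component", "species", "protein_id")
  if (!all(need %in% names(cmap)))
    stopf("component map needs columns: %s", paste(need, collapse = ", "))
  if (!"pathway" %in% names(cmap)) cmap$pathway <- NA_character_
  all_components <- unique(cmap$component)
  all_pathway <- setNames(cmap$pathway[match(all_components, cmap$component)],
                          all_components)
  # rows with an empty protein_id declare a component without mapping it
  declared <- is.na(cmap$protein_id) | !nzchar(cmap$protein_id)
  cmap_decl <- cmap[declared, , drop = FALSE]
  cmap <- cmap[!declared, , drop = FALSE]
  key_e <- paste(evidence$species, evidence$protein_id, sep = "\r")
  key_m <- paste(cmap$species, cmap$protein_id, sep = "\r")
  bad <- which(!key_m %in% key_e)
  if (length(bad))
    stopf("component map references protein '%s' absent from species '%s'",
          cmap$protein_id[bad[1]], cmap$species[bad[1]])
  species <- sort(unique(c(evidence$species,
                           cmap$species[nzchar(cmap$species)])))
  components <- all_components
  state <- matrix(0L, length(species), length(components),
                  dimnames = list(species, components))
  grade <- matrix("ABSENT", length(species), length(components),
                  dimnames = list(species, components))
  ev <- evidence
  ev$grade <- protein_grade(ev)
  ev$qualifies <- switch(coding,
    MRO_STRICT = ev$final_call == "MRO",
    MRO_PLUS_CLADE = ev$final_call == "MRO" | ev$homology_affinity)
  idx <- match(key_m, key_e)
  cmap$grade <- ev$grade[idx]
  cmap$qualifies <- ev$qualifies[idx]
  for (i in seq_len(nrow(cmap))) {
    sp <- cmap$species[i]; co <- cmap$component[i]
    if (cmap$qualifies[i]) state[sp, co] <- 1L
    if (match(cmap$grade[i], grade_levels) < match(grade[sp, co], grade_levels))
      grade[sp, co] <- cmap$grade[i]
  }
  orphan_cols <- setdiff(components, cmap$component)
  if (length(orphan_cols))
    warnf("component(s) with no species entry: %s",
          paste(orphan_cols, collapse = ", "))
  pathway <- all_pathway
  structure(list(species = species, components = components,
                 pathway = pathway, state = state, grade = grade,
                 coding = coding),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("Character matrix: %d species x %d components (coding %s)\n",
              length(x$species), length(x$components), x$coding))
  print(x$state)
  invisible(x)
}

#' Read/write evidence tables and character matrices as TSV
#'
#' `write_evidence()`/`read_evidence()` round-trip the evidence table
#' losslessly.  `write_character_matrix()` writes the binary state matrix
#' with species as rows; `read_character_matrix()` restores a plain binary
#' matrix (grades are written alongside with suffix `.grades.tsv`).
#'
#' @param evidence evidence table; `x` a `character_matrix`; `file` a path.
#' @name mrocall_io
NULL

#' @rdname mrocall_io
#' @export
write_evidence <- function(evidence, file) write_tsv(evidence, file)

#' @rdname mrocall_io
#' @export
read_evidence <- function(file) {
  df <- read_tsv(file)
  for (col in grep("^vote_|^vote_positive$|^homology_affinity$|^nts_detected$",
                   names(df), value = TRUE))
    df[[col]] <- as.logical(df[[col]])
  for (col in intersect(c("protein_id", "species", "affinity_note",
                          "final_call"), names(df)))
    df[[col]] <- as.character(df[[col]])
  df
}

#' @rdname mrocall_io
#' @export
write_character_matrix <- function(x, file) {
  stopifnot(inherits(x, "character_matrix"))
  df <- data.frame(species = rownames(x$state), x$state, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, file)
  gr <- data.frame(species = rownames(x$grade), x$grade, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(gr, paste0(file, ".grades.tsv"))
  invisible(file)
}

#' @rdname mrocall_io
#' @export
read_character_matrix <- function(file) {
  df <- read_tsv(file)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$species
  m
}
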