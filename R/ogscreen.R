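#' Parse an OrthoFinder-style orthogroup file
#'
#' Reads the `"OG0000001: spA|p1 spB|p7 ..."` dialect: one group per line,
#' group id before the first colon, members whitespace-separated.  A protein
#' may belong to at most one orthogroup; duplicate membership (within or
#' across groups) is an error.
#'
#' @param file path (used when `text` is `NULL`).
#' @param text optional character content.
#' @return data.frame with columns `og_id`, `member` (one row per member),
#'   preserving file order.
#' @export
parse_orthogroups <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text))
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(og_id = character(0), member = character(0),
                      stringsAsFactors = FALSE))
  sep <- regexpr(":", lines, fixed = TRUE)
  if (any(sep < 0))
    stopf("orthogroup line %d lacks the 'OG: members' colon separator",
          which(sep < 0)[1])
  og <- trimws(substr(lines, 1, sep - 1))
  members <- strsplit(trimws(substring(lines, sep + 1)), "[ \t]+")
  if (anyDuplicated(og))
    stopf("duplicate orthogroup id '%s'", og[duplicated(og)][1])
  out <- data.frame(og_id = rep(og, lengths(members)),
                    member = unlist(members),
                    stringsAsFactors = FALSE)
  out <- out[nzchar(out$member), , drop = FALSE]
  if (anyDuplicated(out$member))
    stopf("protein '%s' belongs to more than one orthogroup",
          out$member[duplicated(out$member)][1])
  rownames(out) <- NULL
  out
}

#' Write orthogroups in the same dialect
#'
#' @param ogs data.frame (`og_id`, `member`) as from [parse_orthogroups()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_orthogroups <- function(ogs, file) {
  split_members <- split(ogs$member, factor(ogs$og_id, unique(ogs$og_id)))
  writeLines(vapply(names(split_members), function(id)
    paste0(id, ": ", paste(split_members[[id]], collapse = " ")),
    character(1)), file)
  invisible(file)
}

#' Orthogroup enrichment in MRO-predicted proteins
#'
#' Integrates orthogroup clustering with targeting predictions: orthogroups
#' whose members are unexpectedly often predicted MRO-localized point to
#' additional organellar proteins missed by targeted searches.  For each
#' orthogroup the upper-tail hypergeometric probability of observing at
#' least the seen number of MRO members is computed (drawing the group's
#' members from a universe containing `|mro_set|` MRO-predicted proteins),
#' with Benjamini-Hochberg correction across groups.  A descriptive
#' fraction-threshold mode is available as the non-inferential alternative.
#'
#' @param ogs data.frame (`og_id`, `member`).
#' @param mro_set character vector of MRO-predicted protein ids.
#' @param universe character vector of all protein ids, or `NULL` to use
#'   `universe_size` with the assumption `mro_set` is inside the universe.
#' @param universe_size integer; required when `universe` is `NULL`.
#' @param method `"hypergeometric"` (default) or `"fraction"`.
#' @param min_fraction threshold used by the fraction mode (default 0.5).
#' @param p_type `"upper"` (default): conservative upper-tail probability
#'   `P(X >= x)`; `"mid"`: mid-p `P(X > x) + P(X = x)/2`; `"randomized"`:
#'   fuzzy p-value `P(X > x) + U * P(X = x)` with `U ~ Uniform(0,1)`, which
#'   is exactly uniform under the null despite the discreteness of the
#'   hypergeometric statistic (useful for calibration checks; consumes RNG).
#' @return data.frame of class `og_enrichment`: `og_id`, `n_members`,
#'   `n_mro`, `fraction`, and for the hypergeometric mode `p_value`,
#'   `q_value`, sorted by `q_value` then decreasing `fraction`; for the
#'   fraction mode a logical `enriched` column, sorted by decreasing
#'   fraction.
#' @export
og_enrichment <- function(ogs, mro_set, universe = NULL, universe_size = NULL,
                          method = c("hypergeometric", "fraction"),
                          min_fraction = 0.5,
                          p_type = c("upper", "mid", "randomized")) {
  method <- match.arg(method)
  p_type <- match.arg(p_type)
  mro_set <- unique(as.character(mro_set))
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    universe_size <- length(universe)
    outside <- setdiff(ogs$member, universe)
    if (length(outside))
      stopf("orthogroup member '%s' outside the universe", outside[1])
    if (length(setdiff(mro_set, universe)))
      stopf("mro_set contains ids outside the universe")
  } else {
    if (is.null(universe_size)) stopf("supply universe or universe_size")
    if (universe_size < length(mro_set))
      stopf("universe_size smaller than |mro_set|")
  }
  K <- length(mro_set)
  N <- universe_size
  ids <- unique(ogs$og_id)
  n_members <- as.integer(table(factor(ogs$og_id, ids)))
  n_mro <- vapply(split(ogs$member, factor(ogs$og_id, ids)),
                  function(m) sum(m %in% mro_set), integer(1))
  out <- data.frame(og_id = ids, n_members = n_members,
                    n_mro = as.integer(n_mro),
                    fraction = as.numeric(n_mro) / n_members,
                    stringsAsFactors = FALSE)
  if (method == "hypergeometric") {
    # X ~ Hypergeometric(K MRO, N-K other, n_members drawn)
    p_gt <- phyper(out$n_mro, K, N - K, out$n_members, lower.tail = FALSE)
    p_eq <- stats::dhyper(out$n_mro, K, N - K, out$n_members)
    out$p_value <- switch(p_type,
      upper = p_gt + p_eq,                       # P[X >= x]
      mid = p_gt + 0.5 * p_eq,
      randomized = p_gt + runif(nrow(out)) * p_eq)
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out <- out[order(out$q_value, -out$fraction, out$og_id), , drop = FALSE]
  } else {
    out$enriched <- out$fraction >= min_fraction
    out <- out[order(-out$fraction, out$og_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("og_enrichment", class(out))
  out
}
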