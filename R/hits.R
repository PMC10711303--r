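#' Read a tabular similarity-search hit table
#'
#' Parses BLAST/DIAMOND `-outfmt 6`-style tab-separated tables.  The core 12
#' columns are `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore`; the `outfmt6_tax` dialect additionally
#' carries `qcovs` (query coverage, percent) and a subject `lineage` column
#' holding a semicolon-separated taxon path (root to leaf).  A 13-column
#' `outfmt6` table is accepted as core + `qcovs`.
#'
#' Values are validated on input: `pident` and `qcovs` must lie in
#' \[0, 100\], `evalue` and `bitscore` must be non-negative.  A malformed row
#' raises an error naming its line number.  Row order is preserved.
#'
#' @param file path to a tab-separated hit table, or a connection.
#' @param dialect `"outfmt6"` (12 or 13 columns) or `"outfmt6_tax"`
#'   (14 columns, `qcovs` and `lineage` required).
#' @param text optional character scalar/vector with the table content,
#'   used instead of `file`.
#' @return a data.frame with one row per hit; `lineage` is a
#'   semicolon-separated string or `NA` when taxonomy is unavailable.
#' @seealso [write_hit_table()] for the inverse operation.
#' @export
read_hit_table <- function(file, dialect = c("outfmt6", "outfmt6_tax"),
                           text = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (!is.null(text)) {
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    readLines(file)
  }
  lines <- lines[nzchar(lines)]
  core <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 14),
                                  c(core, "qcovs", "lineage")))
    for (col in c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                  "sstart", "send", "evalue", "bitscore", "qcovs"))
      out[[col]] <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- switch(dialect, outfmt6 = c(12L, 13L), outfmt6_tax = 14L)
  bad <- which(!nf %in% expected)
  if (length(bad))
    stopf("hit table line %d: expected %s tab-separated fields, found %d",
          bad[1], paste(expected, collapse = " or "), nf[bad[1]])
  ncols <- max(nf)
  m <- matrix(NA_character_, nrow = length(fields), ncol = ncols)
  for (i in seq_along(fields)) m[i, seq_len(nf[i])] <- fields[[i]]
  cols <- core
  if (ncols >= 13L) cols <- c(cols, "qcovs")
  if (ncols == 14L) cols <- c(cols, "lineage")
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  num_cols <- intersect(c("pident", "length", "mismatch", "gapopen", "qstart",
                          "qend", "sstart", "send", "evalue", "bitscore",
                          "qcovs"), cols)
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    nab <- which(is.na(v) & !(out[[col]] %in% c("NA", "")))
    if (length(nab))
      stopf("hit table line %d: column '%s' is not numeric ('%s')",
            nab[1], col, out[[col]][nab[1]])
    out[[col]] <- v
  }
  check_range <- function(col, lo, hi) {
    v <- out[[col]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad))
      stopf("hit table line %d: %s %.4g outside [%g, %g]",
            bad[1], col, v[bad[1]], lo, hi)
  }
  check_range("pident", 0, 100)
  if ("qcovs" %in% cols) check_range("qcovs", 0, 100)
  check_range("evalue", 0, Inf)
  check_range("bitscore", 0, Inf)
  if (!"qcovs" %in% cols) out$qcovs <- NA_real_
  if (!"lineage" %in% cols) out$lineage <- NA_character_
  out$lineage[!is.na(out$lineage) &
                (out$lineage == "NA" | !nzchar(trimws(out$lineage)))] <-
    NA_character_
  out
}

#' Write a hit table in outfmt6(+taxonomy) layout
#'
#' @param hits data.frame as returned by [read_hit_table()].
#' @param file output path.
#' @param dialect `"outfmt6"` writes the 12 core columns plus `qcovs` when
#'   present; `"outfmt6_tax"` writes 14 columns including `lineage`.
#' @return the path, invisibly.
#' @export
write_hit_table <- function(hits, file, dialect = c("outfmt6", "outfmt6_tax")) {
  dialect <- match.arg(dialect)
  core <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  cols <- switch(dialect,
                 outfmt6 = if (all(is.na(hits$qcovs))) core else c(core, "qcovs"),
                 outfmt6_tax = c(core, "qcovs", "lineage"))
  missing <- setdiff(cols, names(hits))
  if (length(missing))
    stopf("hit table lacks column(s): %s", paste(missing, collapse = ", "))
  write.table(hits[, cols, drop = FALSE], file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(file)
}

# split a semicolon lineage path into trimmed taxon names
split_lineage <- function(lineage) {
  if (is.na(lineage)) return(character(0))
  trimws(unlist(strsplit(lineage, ";", fixed = TRUE)))
}

# exact-name membership of `clade` in each row's lineage path (vectorized)
lineage_has_clade <- function(lineage, clade) {
  vapply(lineage, function(x) clade %in% split_lineage(x), logical(1),
         USE.NAMES = FALSE)
}
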