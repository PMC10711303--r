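# shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages in localization
#' benchmarks conventionally round half up (96.875 -> 97).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# TSV writers/readers used by all modules: plain, tab-separated, no quoting
# games, "NA" for missing, deterministic column order.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = colClasses, check.names = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# draw from Normal(mean, sd) truncated to [lo, hi] by inverse-CDF sampling
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}
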