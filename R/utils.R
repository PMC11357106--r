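# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed Integer seed, or NULL to leave the RNG stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Validate a data frame of 0-based half-open genomic intervals
#'
#' Intervals use the BED convention throughout the package: `start` is
#' 0-based inclusive, `end` is exclusive, and `0 <= start < end`.
#'
#' @param x data.frame with columns chrom, start, end (and optionally strand).
#' @param chrom_lengths Optional named vector of chromosome lengths (bp);
#'   when given, intervals must lie within their chromosome.
#' @param what Label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
#' @noRd
validate_intervals <- function(x, chrom_lengths = NULL, what = "interval") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stopf("%s table must have columns %s", what, paste(need, collapse = ", "))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    bad <- which(x$start < 0 | x$start >= x$end)[1]
    stopf("%s %d violates 0 <= start < end (start=%s, end=%s)",
          what, bad, x$start[bad], x$end[bad])
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_lengths))
    if (length(unknown) > 0) {
      stopf("%s on undeclared chromosome(s): %s", what,
            paste(unknown, collapse = ", "))
    }
    over <- x$end > unname(chrom_lengths[x$chrom])
    if (any(over)) {
      bad <- which(over)[1]
      stopf("%s %d exceeds declared length of %s (end=%s > %s)",
            what, bad, x$chrom[bad], x$end[bad],
            chrom_lengths[x$chrom[bad]])
    }
  }
  invisible(x)
}

# IRanges view of 0-based half-open intervals (per chromosome work is done by
# the callers; this converts one block of rows).
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Count, for each row of `query`, whether it overlaps any row of `subject`
# (any-bp overlap, chromosome-aware). Both are 0-based half-open data frames.
overlaps_any <- function(query, subject) {
  hit <- logical(nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0) next
    ov <- IRanges::overlapsAny(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si])
    )
    hit[qi] <- ov
  }
  hit
}
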