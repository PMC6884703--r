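# Repeat-track and crosslink-site readers for the flanking-sequence module.

#' Read a repeat annotation track
#'
#' Accepts either the UCSC `rmsk` table dump (17 tab-separated columns,
#' 0-based `genoStart`) or native RepeatMasker `.out` (whitespace-separated,
#' 3 header lines, 1-based query begin, strand `C` meaning minus).
#' The format is autodetected.
#'
#' @param path path to the repeat file
#' @param family_filter optional substring; only repeats whose family or name
#'   contains it are returned (e.g. `"Alu"`)
#' @return a `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `repeat_name`, `repeat_family`
#' @export
read_repeat_track <- function(path, family_filter = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  is_out <- length(lines) > 0L &&
    (grepl("^\\s*SW", lines[1L]) || grepl("^\\s*score", lines[1L]) ||
       !grepl("\t", lines[1L]))
  if (is_out) {
    lines <- lines[!grepl("^\\s*(SW|score|$)", lines)]
    fields <- strsplit(trimws(lines), "\\s+")
    keep <- lengths(fields) >= 11L
    fields <- fields[keep]
    if (!length(fields)) return(.empty_repeats())
    out <- data.frame(
      contig = vapply(fields, `[`, "", 5L),
      start = as.integer(vapply(fields, `[`, "", 6L)) - 1L,
      end = as.integer(vapply(fields, `[`, "", 7L)),
      strand = ifelse(vapply(fields, `[`, "", 9L) == "C", "-", "+"),
      repeat_name = vapply(fields, `[`, "", 10L),
      repeat_family = vapply(fields, `[`, "", 11L),
      stringsAsFactors = FALSE
    )
  } else {
    fields <- .split_tsv(lines)
    if (any(lengths(fields) < 13L)) {
      .stopf("rmsk TSV needs >= 13 columns (line %d)",
             which(lengths(fields) < 13L)[1L])
    }
    out <- data.frame(
      contig = vapply(fields, `[`, "", 6L),
      start = as.integer(vapply(fields, `[`, "", 7L)),
      end = as.integer(vapply(fields, `[`, "", 8L)),
      strand = vapply(fields, `[`, "", 10L),
      repeat_name = vapply(fields, `[`, "", 11L),
      repeat_family = vapply(fields, `[`, "", 13L),
      stringsAsFactors = FALSE
    )
  }
  if (any(out$start >= out$end)) .stopf("repeat with start >= end in %s", path)
  if (!is.null(family_filter)) {
    out <- out[grepl(family_filter, out$repeat_family, fixed = TRUE) |
                 grepl(family_filter, out$repeat_name, fixed = TRUE), ,
               drop = FALSE]
  }
  .reset_rownames(out)
}

.empty_repeats <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), repeat_name = character(),
             repeat_family = character(), stringsAsFactors = FALSE)
}

#' Read single-nucleotide crosslink sites from a BED6 file
#'
#' The score column is interpreted as the per-site signal (e.g. crosslink
#' read count); intervals wider than one nucleotide are an error.
#'
#' @param path path to the BED file
#' @return a `data.frame` with columns `contig`, `pos` (0-based), `strand`,
#'   `score`
#' @export
read_crosslink_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(contig = character(), pos = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- .split_tsv(lines)
  if (any(lengths(fields) < 6L)) {
    .stopf("crosslink BED needs 6 columns (line %d)",
           which(lengths(fields) < 6L)[1L])
  }
  start <- as.integer(vapply(fields, `[`, "", 2L))
  end <- as.integer(vapply(fields, `[`, "", 3L))
  if (any(end - start != 1L)) {
    .stopf("crosslink sites must be single-nucleotide intervals (line %d)",
           which(end - start != 1L)[1L])
  }
  out <- data.frame(
    contig = vapply(fields, `[`, "", 1L),
    pos = start,
    strand = .check_strand(vapply(fields, `[`, "", 6L), path),
    score = as.numeric(vapply(fields, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  .reset_rownames(out)
}
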