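# Interop readers for the two upstream circRNA callers.  Both emit BED-based
# coordinates (0-based half-open), which is already the internal convention.

#' Read circRNA candidates from a caller output file
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`findcirc_bed`}{BED6+ as written by find_circ: the score column
#'     carries the back-splice read count and one of the extra columns holds
#'     space- or comma-separated keyword flags. Rows lacking
#'     `required_keyword` are dropped (set it to `NULL` to keep everything).}
#'   \item{`circexplorer_table`}{BED12+ as written by CIRCexplorer; column 13
#'     carries the back-splice read count.}
#' }
#'
#' @param path path to the caller output
#' @param dialect `"findcirc_bed"` or `"circexplorer_table"`
#' @param required_keyword keyword a findcirc row must carry to be kept
#' @return a `data.frame` of candidates with columns `contig`, `start`,
#'   `end`, `strand`, `provenance`, `reported_count`
#' @export
read_caller_candidates <- function(path, dialect = c("findcirc_bed",
                                                     "circexplorer_table"),
                                   required_keyword = "CIRCULAR") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track") &
                   nzchar(lines)]
  if (!length(lines)) return(.empty_candidates())
  fields <- .split_tsv(lines)
  if (dialect == "findcirc_bed") {
    if (any(lengths(fields) < 6L)) {
      .stopf("findcirc dialect needs >= 6 columns (line %d)",
             which(lengths(fields) < 6L)[1L])
    }
    if (!is.null(required_keyword)) {
      has_kw <- vapply(fields, function(f) {
        any(grepl(required_keyword, f[-(1:4)], fixed = TRUE))
      }, logical(1L))
      fields <- fields[has_kw]
      if (!length(fields)) return(.empty_candidates())
    }
    out <- data.frame(
      contig = vapply(fields, `[`, "", 1L),
      start = as.integer(vapply(fields, `[`, "", 2L)),
      end = as.integer(vapply(fields, `[`, "", 3L)),
      strand = vapply(fields, `[`, "", 6L),
      provenance = "finder_A",
      reported_count = as.numeric(vapply(fields, `[`, "", 5L)),
      stringsAsFactors = FALSE
    )
  } else {
    if (any(lengths(fields) < 13L)) {
      .stopf("circexplorer dialect needs >= 13 columns (line %d)",
             which(lengths(fields) < 13L)[1L])
    }
    out <- data.frame(
      contig = vapply(fields, `[`, "", 1L),
      start = as.integer(vapply(fields, `[`, "", 2L)),
      end = as.integer(vapply(fields, `[`, "", 3L)),
      strand = vapply(fields, `[`, "", 6L),
      provenance = "finder_B",
      reported_count = as.numeric(vapply(fields, `[`, "", 13L)),
      stringsAsFactors = FALSE
    )
  }
  .check_strand(out$strand, path)
  if (any(out$start < 0L) || any(out$start >= out$end)) {
    .stopf("invalid candidate interval in %s", path)
  }
  .reset_rownames(out)
}

.empty_candidates <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), provenance = character(),
             reported_count = numeric(), stringsAsFactors = FALSE)
}
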