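# Internal catalog TSV: a BED6-compatible prefix (contig, start, end, name,
# distinct-read count, strand) followed by typed extra columns.  The header
# documents column names and the coordinate convention; a second header line
# records column types so that read(write(x)) is the identity.

.catalog_type <- function(x) {
  if (is.integer(x)) "integer"
  else if (is.numeric(x)) "numeric"
  else if (is.logical(x)) "logical"
  else "character"
}

#' Write a circRNA catalog to TSV
#'
#' Records are written in canonical order (contig, start, end, strand) with
#' a BED6-compatible prefix. Any columns beyond the coordinate fields are
#' preserved as typed extra columns so the file round-trips through
#' [read_catalog()] unchanged.
#'
#' @param records `data.frame` with at least `contig`, `start`, `end`,
#'   `strand`; a `name` column defaults to the coordinate-derived circRNA id
#'   and a `score` column to the total distinct-read count when present
#' @param path output path
#' @return `path`, invisibly
#' @export
write_catalog <- function(records, path) {
  need <- c("contig", "start", "end", "strand")
  if (!all(need %in% names(records))) {
    .stopf("catalog needs columns: %s", paste(need, collapse = ", "))
  }
  if (!"name" %in% names(records)) {
    records$name <- circ_id(records$contig, records$start, records$end,
                            records$strand)
  }
  if (!"score" %in% names(records)) {
    dcols <- grep("^distinct_reads\\.", names(records), value = TRUE)
    records$score <- if (length(dcols)) {
      as.integer(rowSums(records[, dcols, drop = FALSE]))
    } else 0L
  }
  prefix <- c("contig", "start", "end", "name", "score", "strand")
  extras <- setdiff(names(records), prefix)
  records <- .canonical_order(records)[, c(prefix, extras), drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# circkit catalog; coordinates are 0-based half-open; BED6 prefix then typed extras",
    paste0("#coltypes\t", paste(vapply(records, .catalog_type, ""),
                                collapse = "\t")),
    paste0("#columns\t", paste(names(records), collapse = "\t"))
  ), con)
  if (nrow(records)) {
    write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a circRNA catalog written by [write_catalog()]
#'
#' @param path path to the catalog TSV
#' @return the catalog `data.frame`, with column types restored
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  types_line <- hdr[startsWith(hdr, "#coltypes\t")]
  cols_line <- hdr[startsWith(hdr, "#columns\t")]
  if (!length(types_line) || !length(cols_line)) {
    .stopf("%s is not a circkit catalog (missing typed header)", path)
  }
  types <- strsplit(sub("^#coltypes\t", "", types_line[1L]), "\t")[[1L]]
  cols <- strsplit(sub("^#columns\t", "", cols_line[1L]), "\t")[[1L]]
  out <- if (length(body)) {
    read.delim(text = body, header = FALSE, sep = "\t",
               colClasses = types, na.strings = "NA",
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(setNames(lapply(types, function(tp) vector(tp, 0L)), cols))
  }
  names(out) <- cols
  .reset_rownames(out)
}
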