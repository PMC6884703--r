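# Readers for the STAR-style junction table dialects.  Both dialects are
# tool-specific TSVs without an R parser in the Bioconductor stack, so they
# are parsed here directly.  Source coordinates are 1-based; everything is
# converted to the internal 0-based half-open convention on the way in.

.read_lines_chunked <- function(path, chunk_size, fun) {
  con <- file(path, open = "r")
  on.exit(close(con))
  offset <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (!length(lines)) break
    fun(lines, offset)
    offset <- offset + length(lines)
  }
  invisible(NULL)
}

.split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a STAR-style chimeric junction table
#'
#' Parses the classic 14-column `Chimeric.out.junction` dialect as well as
#' the extended dialect (header row naming the first column `chr_donorA`,
#' comment lines, extra columns; only the first 14 columns are used).
#' Dialect detection is automatic.
#'
#' Donor/acceptor columns give the 1-based position of the first intronic
#' base 3' of the donor exon and of the intronic base adjacent to the
#' acceptor exon; both are converted to 0-based positions. Rows whose two
#' junction contigs differ are kept but flagged `cross_contig` so that
#' back-splice calling can exclude and tally them.
#'
#' @param path path to the table
#' @param sample_id sample label attached to every record
#' @param callback optional function; when supplied the file is processed in
#'   chunks of `chunk_size` data rows, `callback(records)` is called per chunk
#'   and nothing is returned (bounded-memory streaming)
#' @param chunk_size rows per chunk in streaming mode
#' @return a `data.frame` of chimeric records (one row per read), or
#'   `invisible(NULL)` in streaming mode
#' @export
read_chimeric_table <- function(path, sample_id, callback = NULL,
                                chunk_size = 50000L) {
  parse_chunk <- function(lines, offset) {
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- seq_along(lines)[keep] + offset
    lines <- lines[keep]
    if (!length(lines)) return(.empty_chimeric(sample_id))
    fields <- .split_tsv(lines)
    # extended dialect ships a header row naming the donor contig column
    if (offset == 0L && length(fields) && fields[[1L]][1L] %in%
        c("chr_donorA", "chr_donor")) {
      fields <- fields[-1L]
      lineno <- lineno[-1L]
      if (!length(fields)) return(.empty_chimeric(sample_id))
    }
    nf <- lengths(fields)
    bad <- which(nf < 14L)
    if (length(bad)) {
      .stopf("malformed chimeric row at line %d: %d columns (expected >= 14)",
             lineno[bad[1L]], nf[bad[1L]])
    }
    m <- t(vapply(fields, function(f) f[1:14], character(14L)))
    strand <- m[, 3L]
    okstr <- strand %in% c("+", "-")
    if (any(!okstr)) {
      .stopf("unknown strand symbol '%s' at line %d",
             strand[which(!okstr)[1L]], lineno[which(!okstr)[1L]])
    }
    data.frame(
      read_id = m[, 10L],
      contig = m[, 1L],
      contig_acceptor = m[, 4L],
      strand = strand,
      donor_site = as.integer(m[, 2L]) - 1L,
      acceptor_site = as.integer(m[, 5L]) - 1L,
      strand_acceptor = m[, 6L],
      motif_code = as.integer(m[, 7L]),
      seg1_pos = as.integer(m[, 11L]) - 1L,
      seg1_cigar = m[, 12L],
      seg2_pos = as.integer(m[, 13L]) - 1L,
      seg2_cigar = m[, 14L],
      sample_id = sample_id,
      cross_contig = m[, 1L] != m[, 4L],
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(callback)) {
    .read_lines_chunked(path, chunk_size, function(lines, offset) {
      callback(parse_chunk(lines, offset))
    })
    return(invisible(NULL))
  }
  out <- parse_chunk(readLines(path), 0L)
  .reset_rownames(out)
}

.empty_chimeric <- function(sample_id) {
  data.frame(
    read_id = character(), contig = character(),
    contig_acceptor = character(), strand = character(),
    donor_site = integer(), acceptor_site = integer(),
    strand_acceptor = character(), motif_code = integer(),
    seg1_pos = integer(), seg1_cigar = character(),
    seg2_pos = integer(), seg2_cigar = character(),
    sample_id = character(), cross_contig = logical(),
    stringsAsFactors = FALSE
  )
}

#' Read a STAR-style linear splice-junction table (SJ dialect)
#'
#' Nine tab-separated columns: contig, 1-based inclusive intron start and
#' end, numeric strand code (0 = unknown, 1 = `+`, 2 = `-`), motif code,
#' annotated flag, unique-read count, multi-read count, max overhang.
#' Intron intervals are converted to 0-based half-open.
#'
#' @inheritParams read_chimeric_table
#' @return a `data.frame` of linear junction records
#' @export
read_linear_junctions <- function(path, sample_id, callback = NULL,
                                  chunk_size = 50000L) {
  parse_chunk <- function(lines, offset) {
    keep <- !startsWith(lines, "#") & nzchar(lines)
    lineno <- seq_along(lines)[keep] + offset
    lines <- lines[keep]
    if (!length(lines)) return(.empty_linear(sample_id))
    fields <- .split_tsv(lines)
    nf <- lengths(fields)
    bad <- which(nf < 9L)
    if (length(bad)) {
      .stopf("malformed SJ row at line %d: %d columns (expected 9)",
             lineno[bad[1L]], nf[bad[1L]])
    }
    m <- t(vapply(fields, function(f) f[1:9], character(9L)))
    uniq <- suppressWarnings(as.integer(m[, 7L]))
    mult <- suppressWarnings(as.integer(m[, 8L]))
    if (anyNA(uniq) || anyNA(mult)) {
      i <- which(is.na(uniq) | is.na(mult))[1L]
      .stopf("non-numeric read count at line %d", lineno[i])
    }
    if (any(uniq < 0L) || any(mult < 0L)) {
      i <- which(uniq < 0L | mult < 0L)[1L]
      .stopf("negative read count at line %d", lineno[i])
    }
    code <- m[, 4L]
    strand <- c("0" = "*", "1" = "+", "2" = "-")[code]
    if (anyNA(strand)) {
      .stopf("unknown strand code '%s' at line %d",
             code[which(is.na(strand))[1L]], lineno[which(is.na(strand))[1L]])
    }
    data.frame(
      contig = m[, 1L],
      intron_start = as.integer(m[, 2L]) - 1L,
      intron_end = as.integer(m[, 3L]),
      strand = unname(strand),
      motif_code = as.integer(m[, 5L]),
      annotated_flag = m[, 6L] != "0",
      unique_reads = uniq,
      multi_reads = mult,
      sample_id = sample_id,
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(callback)) {
    .read_lines_chunked(path, chunk_size, function(lines, offset) {
      callback(parse_chunk(lines, offset))
    })
    return(invisible(NULL))
  }
  .reset_rownames(parse_chunk(readLines(path), 0L))
}

.empty_linear <- function(sample_id) {
  data.frame(
    contig = character(), intron_start = integer(), intron_end = integer(),
    strand = character(), motif_code = integer(), annotated_flag = logical(),
    unique_reads = integer(), multi_reads = integer(), sample_id = character(),
    stringsAsFactors = FALSE
  )
}
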