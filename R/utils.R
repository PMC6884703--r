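#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end), strand
# explicit.  All readers convert into this convention; all writers convert
# out of it where the external dialect requires 1-based coordinates.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.check_strand <- function(strand, where = "input") {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    .stopf("unknown strand symbol '%s' in %s", strand[which(bad)[1L]], where)
  }
  strand
}

#' Canonical circRNA identifier from junction coordinates
#'
#' Coordinate-derived identifiers are collision-free with gene identifiers
#' (the `circ|` prefix is reserved) and stable across runs.
#'
#' @param contig,start,end,strand junction coordinates (0-based half-open)
#' @return character vector of identifiers
#' @export
circ_id <- function(contig, start, end, strand) {
  sprintf("circ|%s:%d-%d:%s", contig, as.integer(start), as.integer(end), strand)
}

# canonical catalog ordering: (contig, start, end, strand)
.canonical_order <- function(df) {
  df[order(df$contig, df$start, df$end, df$strand), , drop = FALSE]
}

.reset_rownames <- function(df) {
  rownames(df) <- NULL
  df
}

# split "35M" style CIGARs; returns total read bases consumed (M/I/S excluded
# per op set below).  Aligned length = bases of the read aligned to the
# reference at the junction flank: M, =, X ops.
.cigar_aligned_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || !nzchar(cg)) return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg)) {
      .stopf("malformed CIGAR string '%s'", cg)
    }
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    type <- sub("^[0-9]+", "", ops)
    sum(n[type %in% c("M", "=", "X")])
  }, integer(1L), USE.NAMES = FALSE)
}

# GRanges helper: build from 0-based half-open internal coordinates
.as_granges <- function(contig, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}
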