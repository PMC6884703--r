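#' Load a genome FASTA into memory
#'
#' Wraps [Biostrings::readDNAStringSet()] and strips FASTA description text
#' after the first whitespace so contig names match annotation files.
#'
#' @param path path to an (uncompressed or gzipped) FASTA file
#' @return a named [Biostrings::DNAStringSet] (one element per contig)
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_genome(seqs)
}

#' Coerce named sequences to a genome object
#'
#' A genome is represented as a named [Biostrings::DNAStringSet] with one
#' element per contig and unique contig names.
#'
#' @param x a named character vector or `DNAStringSet` (one element per contig)
#' @return a named `DNAStringSet`
#' @export
as_genome <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  stopifnot(is(x, "DNAStringSet"))
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(!nzchar(names(x)))) {
    .stopf("genome contigs must have unique non-empty names")
  }
  x
}

#' Contig lengths of a genome
#' @param genome a genome `DNAStringSet` (see [as_genome()])
#' @return named integer vector
#' @export
contig_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Extract genomic sequence on the internal coordinate convention
#'
#' @param genome a genome `DNAStringSet` (see [as_genome()])
#' @param contig contig name
#' @param start,end 0-based half-open interval
#' @param strand if `"-"`, the reverse complement is returned
#' @return an uppercase character string of exactly `end - start` bases
#' @export
genome_subseq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) .stopf("unknown contig '%s'", contig)
  len <- length(genome[[contig]])
  if (start < 0L || end > len || start > end) {
    .stopf("interval [%d,%d) out of range for contig '%s' (length %d)",
           start, end, contig, len)
  }
  s <- Biostrings::subseq(genome[[contig]], start = start + 1L, width = end - start)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
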