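# Back-splice junction calling from chimeric records.
#
# A chimeric record supports a back-splice junction when both segments map
# to the same contig and strand and the donor/acceptor sites are in
# head-to-tail order: on the + strand the donor lies downstream (higher
# coordinate) of the acceptor, mirrored on the - strand.  The circularized
# span is the exonic interval between the two splice sites:
#   + strand: start = acceptor_site + 1 (first base of the acceptor exon),
#             end   = donor_site       (exclusive; donor exon ends at
#                                       donor_site - 1)
#   - strand: start = donor_site + 1, end = acceptor_site.

#' Call back-splice junctions from chimeric records
#'
#' @param records chimeric records from [read_chimeric_table()] (one or more
#'   samples row-bound together)
#' @param min_overhang minimum aligned length (from the CIGAR) of the
#'   shorter of the two read segments; defaults to 15, the chimeric overhang
#'   used at alignment time
#' @return a `backsplice_calls` object: list with `junctions` (one row per
#'   distinct junction with read tallies), `records` (the input annotated
#'   with the junction each qualifying record supports), and `tally` (counts
#'   of non-qualifying records by reason)
#' @export
call_junctions <- function(records, min_overhang = 15L) {
  stopifnot(min_overhang >= 1L)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  cross <- if ("cross_contig" %in% names(records)) records$cross_contig
           else records$contig != records$contig_acceptor
  reason[cross] <- "cross_contig"
  sconf <- is.na(reason) & records$strand != records$strand_acceptor
  reason[sconf] <- "strand_conflict"
  h2t <- ifelse(records$strand == "+",
                records$donor_site > records$acceptor_site,
                records$donor_site < records$acceptor_site)
  reason[is.na(reason) & !h2t] <- "not_head_to_tail"
  ov <- pmin(.cigar_aligned_length(records$seg1_cigar),
             .cigar_aligned_length(records$seg2_cigar))
  reason[is.na(reason) & ov < min_overhang] <- "low_overhang"

  qual <- is.na(reason)
  start <- ifelse(records$strand == "+", records$acceptor_site + 1L,
                  records$donor_site + 1L)
  end <- ifelse(records$strand == "+", records$donor_site,
                records$acceptor_site)
  key <- circ_id(records$contig, start, end, records$strand)
  records$junction_id <- ifelse(qual, key, NA_character_)
  records$junction_start <- ifelse(qual, start, NA_integer_)
  records$junction_end <- ifelse(qual, end, NA_integer_)
  records$reject_reason <- reason

  qrec <- records[qual, , drop = FALSE]
  if (nrow(qrec)) {
    first <- !duplicated(qrec$junction_id)
    junctions <- data.frame(
      contig = qrec$contig[first],
      start = qrec$junction_start[first],
      end = qrec$junction_end[first],
      strand = qrec$strand[first],
      name = qrec$junction_id[first],
      n_reads = as.integer(table(qrec$junction_id)[qrec$junction_id[first]]),
      stringsAsFactors = FALSE
    )
    junctions <- .reset_rownames(.canonical_order(junctions))
  } else {
    junctions <- data.frame(contig = character(), start = integer(),
                            end = integer(), strand = character(),
                            name = character(), n_reads = integer(),
                            stringsAsFactors = FALSE)
  }
  tally <- c(qualifying = sum(qual),
             cross_contig = sum(reason == "cross_contig", na.rm = TRUE),
             strand_conflict = sum(reason == "strand_conflict", na.rm = TRUE),
             not_head_to_tail = sum(reason == "not_head_to_tail", na.rm = TRUE),
             low_overhang = sum(reason == "low_overhang", na.rm = TRUE))
  structure(list(junctions = junctions, records = records, tally = tally),
            class = "backsplice_calls")
}

#' @export
print.backsplice_calls <- function(x, ...) {
  cat(sprintf("backsplice_calls: %d junctions from %d qualifying records\n",
              nrow(x$junctions), x$tally[["qualifying"]]))
  nonq <- x$tally[setdiff(names(x$tally), "qualifying")]
  nonq <- nonq[nonq > 0]
  if (length(nonq)) {
    cat("  excluded:", paste(sprintf("%s=%d", names(nonq), nonq),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify the splice-site motif of back-splice junctions
#'
#' On the + strand the donor dinucleotide is the genome at `[end, end+2)`
#' and the acceptor dinucleotide at `[start-2, start)`; `GT_AG` requires
#' GT donor and AG acceptor, `GC_AG` a GC donor. On the - strand the same
#' rule is applied to the reverse complement (plus-strand context
#' `CT..AC` therefore reads `GT_AG`). Motifs containing N, and any other
#' pairing, classify as `other`.
#'
#' @param junctions `data.frame` with `contig`, `start`, `end`, `strand`
#' @param genome a genome `DNAStringSet` (see [as_genome()])
#' @return character vector in `{"GT_AG", "GC_AG", "other"}`
#' @export
classify_motif <- function(junctions, genome) {
  lens <- contig_lengths(genome)
  vapply(seq_len(nrow(junctions)), function(i) {
    contig <- junctions$contig[i]
    start <- junctions$start[i]
    end <- junctions$end[i]
    if (!contig %in% names(lens)) .stopf("unknown contig '%s'", contig)
    if (start < 2L || end + 2L > lens[[contig]]) {
      .stopf("junction %s within 2 nt of a contig boundary",
             circ_id(contig, start, end, junctions$strand[i]))
    }
    if (junctions$strand[i] == "+") {
      donor <- genome_subseq(genome, contig, end, end + 2L)
      acceptor <- genome_subseq(genome, contig, start - 2L, start)
    } else {
      donor <- .revcomp(genome_subseq(genome, contig, start - 2L, start))
      acceptor <- .revcomp(genome_subseq(genome, contig, end, end + 2L))
    }
    if (acceptor != "AG") "other"
    else if (donor == "GT") "GT_AG"
    else if (donor == "GC") "GC_AG"
    else "other"
  }, character(1L))
}

#' Flag whether each back-splice boundary uses an annotated splice site
#'
#' A side is `annotated` when its boundary coincides exactly with an exon
#' boundary of the matching type in any transcript on the same strand:
#' the acceptor boundary with an exon start (in transcript orientation),
#' the donor boundary with an exon end. Otherwise it is `de_novo`.
#'
#' @param junctions `data.frame` with `contig`, `start`, `end`, `strand`
#' @param models a [transcript_models] object
#' @return `junctions` with `acceptor_status` and `donor_status` columns
#' @export
annotate_splice_status <- function(junctions, models) {
  ex <- models$exons
  keyset <- function(contig, pos, strand) paste(contig, pos, strand)
  # genomic exon starts are acceptor boundaries on +, donor boundaries on -
  starts_plus <- keyset(ex$contig[ex$strand == "+"],
                        ex$start[ex$strand == "+"], "+")
  ends_plus <- keyset(ex$contig[ex$strand == "+"],
                      ex$end[ex$strand == "+"], "+")
  starts_minus <- keyset(ex$contig[ex$strand == "-"],
                         ex$start[ex$strand == "-"], "-")
  ends_minus <- keyset(ex$contig[ex$strand == "-"],
                       ex$end[ex$strand == "-"], "-")
  plus <- junctions$strand == "+"
  kstart <- keyset(junctions$contig, junctions$start, junctions$strand)
  kend <- keyset(junctions$contig, junctions$end, junctions$strand)
  acceptor_ok <- ifelse(plus, kstart %in% starts_plus, kend %in% ends_minus)
  donor_ok <- ifelse(plus, kend %in% ends_plus, kstart %in% starts_minus)
  junctions$acceptor_status <- ifelse(acceptor_ok, "annotated", "de_novo")
  junctions$donor_status <- ifelse(donor_ok, "annotated", "de_novo")
  junctions
}
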