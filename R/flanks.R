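# Flanking-intron analyses: repeat pair orientation, inverted-sequence
# complementarity, crosslink-site merging, and signal metaprofiles.

.flank_windows <- function(junction, window, contig_len = NULL) {
  # intronic windows immediately outside the boundaries, genomic coords
  left <- c(max(0L, junction$start - window), junction$start)
  right_end <- junction$end + window
  if (!is.null(contig_len)) right_end <- min(right_end, contig_len)
  right <- c(junction$end, right_end)
  list(left = left, right = right)
}

#' Repeat presence and pair orientation in flanking windows
#'
#' A side "has" a repeat when at least one family repeat overlaps the
#' intronic window (default 500 nt) immediately outside that boundary.
#' Orientation is evaluated over all cross-side repeat pairs: `inverted`
#' when any pair lies on opposite strands, `same` when pairs exist and all
#' strands agree, `none` when either side is empty.
#'
#' @param catalog `data.frame` with `contig`, `start`, `end`, `strand`
#' @param repeats repeat track from [read_repeat_track()]
#' @param window flank width in nt
#' @param family substring selecting the repeat family (default `"Alu"`)
#' @param contig_lens optional named contig lengths for window truncation
#' @return `catalog` with `repeat_left`, `repeat_right`,
#'   `repeat_orientation` columns
#' @export
repeat_pair_orientation <- function(catalog, repeats, window = 500L,
                                    family = "Alu", contig_lens = NULL) {
  reps <- repeats[grepl(family, repeats$repeat_family, fixed = TRUE) |
                    grepl(family, repeats$repeat_name, fixed = TRUE), ,
                  drop = FALSE]
  n <- nrow(catalog)
  left_hit <- right_hit <- logical(n)
  orient <- character(n)
  for (i in seq_len(n)) {
    cl <- if (!is.null(contig_lens)) contig_lens[[catalog$contig[i]]] else NULL
    w <- .flank_windows(catalog[i, , drop = FALSE], window, cl)
    on_ctg <- reps$contig == catalog$contig[i]
    inl <- on_ctg & reps$start < w$left[2L] & reps$end > w$left[1L]
    inr <- on_ctg & reps$start < w$right[2L] & reps$end > w$right[1L]
    left_hit[i] <- any(inl)
    right_hit[i] <- any(inr)
    if (!any(inl) || !any(inr)) {
      orient[i] <- "none"
    } else {
      pairs_opposite <- outer(reps$strand[inl], reps$strand[inr], `!=`)
      orient[i] <- if (any(pairs_opposite)) "inverted" else "same"
    }
  }
  catalog$repeat_left <- left_hit
  catalog$repeat_right <- right_hit
  catalog$repeat_orientation <- orient
  catalog
}

#' Reverse-complementary sequence in flanking windows
#'
#' Smith-Waterman local alignment of the window upstream of the left
#' boundary against the reverse complement of the window downstream of the
#' right boundary (both 500 nt by default), scored with match +1,
#' mismatch -1, gap opening 10 and gap extension 4. A junction is flagged
#' `complementary` when the best local alignment reaches both the identity
#' and length thresholds.
#'
#' @param catalog `data.frame` with `contig`, `start`, `end`, `strand`
#' @param genome a genome `DNAStringSet` (see [as_genome()])
#' @param window flank width in nt (truncated at contig ends with a warning)
#' @param gap_open,gap_extend,match,mismatch alignment parameters
#' @param min_identity,min_length thresholds for the `complementary` flag
#' @return `catalog` with `aln_length`, `aln_identity`, `aln_score`,
#'   `complementary` columns (`NA` when a window is shorter than 10 nt)
#' @export
inverted_complementarity <- function(catalog, genome, window = 500L,
                                     gap_open = 10, gap_extend = 4,
                                     match = 1, mismatch = -1,
                                     min_identity = 85, min_length = 40L) {
  lens <- contig_lengths(genome)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch)
  n <- nrow(catalog)
  alen <- rep(NA_integer_, n)
  aid <- ascore <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ctg <- catalog$contig[i]
    if (!ctg %in% names(lens)) .stopf("unknown contig '%s'", ctg)
    w <- .flank_windows(catalog[i, , drop = FALSE], window, lens[[ctg]])
    if (w$left[1L] > catalog$start[i] - window ||
        w$right[2L] < catalog$end[i] + window) {
      .warnf("flanking window truncated at contig boundary for %s",
             circ_id(ctg, catalog$start[i], catalog$end[i],
                     catalog$strand[i]))
    }
    if (diff(w$left) < 10L || diff(w$right) < 10L) next
    up <- genome_subseq(genome, ctg, w$left[1L], w$left[2L])
    down <- genome_subseq(genome, ctg, w$right[1L], w$right[2L])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(up),
      Biostrings::reverseComplement(Biostrings::DNAString(down)),
      type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    alen[i] <- Biostrings::nchar(aln)
    aid[i] <- Biostrings::pid(aln, type = "PID1")
    ascore[i] <- Biostrings::score(aln)
  }
  catalog$aln_length <- alen
  catalog$aln_identity <- aid
  catalog$aln_score <- ascore
  catalog$complementary <- !is.na(alen) & aid >= min_identity &
    alen >= min_length
  catalog
}

#' Merge nearby single-nucleotide crosslink sites
#'
#' Same-contig, same-strand sites whose successive positions lie at most
#' `max_gap` nt apart join one cluster (transitively). Idempotent on its
#' own output representation.
#'
#' @param sites `data.frame` from [read_crosslink_bed()] (`contig`, `pos`,
#'   `strand`, `score`)
#' @param max_gap maximum distance between successive sites in a cluster
#' @return `data.frame` of clusters: `contig`, `start`, `end` (0-based
#'   half-open span), `strand`, `n_sites`, `score` (summed)
#' @export
merge_crosslink_sites <- function(sites, max_gap = 8L) {
  if (!nrow(sites)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_sites = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  sites <- sites[order(sites$contig, sites$strand, sites$pos), , drop = FALSE]
  grp <- paste(sites$contig, sites$strand)
  new_cluster <- c(TRUE, diff(sites$pos) > max_gap | grp[-1L] != grp[-nrow(sites)])
  cl <- cumsum(new_cluster)
  out <- data.frame(
    contig = tapply(sites$contig, cl, `[`, 1L),
    start = as.integer(tapply(sites$pos, cl, min)),
    end = as.integer(tapply(sites$pos, cl, max)) + 1L,
    strand = tapply(sites$strand, cl, `[`, 1L),
    n_sites = as.integer(tapply(sites$pos, cl, length)),
    score = as.numeric(tapply(sites$score, cl, sum)),
    stringsAsFactors = FALSE
  )
  .reset_rownames(out)
}

# relative positions for one junction side; intronic positions are negative
# on the acceptor side and positive on the donor side; exon positions start
# at 0 (acceptor) / end at -1 (donor)
.side_positions <- function(junction, side, intron_window, exon_window) {
  plus <- junction$strand == "+"
  if (side == "acceptor") {
    rel <- c(seq(-intron_window, -1L), seq(0L, exon_window - 1L))
    pos <- if (plus) junction$start + rel
           else junction$end - 1L - rel
  } else {
    rel <- c(seq(-exon_window, -1L), seq(1L, intron_window))
    genomic_off <- ifelse(rel < 0, rel, rel - 1L)
    pos <- if (plus) junction$end + genomic_off
           else junction$start - 1L - genomic_off
  }
  list(rel = rel, pos = pos)
}

#' Metaprofile of per-position signal around back-splice sites
#'
#' For each junction and side (acceptor and donor, in transcript
#' orientation), signal scores at each relative position are averaged over
#' all junctions. Intronic positions count negative (acceptor side) or
#' positive (donor side) from the boundary; the first/last `exon_window`
#' nucleotides of the circularized exons complete the window. Positions
#' beyond contig ends contribute zero while the junction still counts, so
#' `sum(mean) * n` equals the total overlapped signal.
#'
#' @param junctions `data.frame` with `contig`, `start`, `end`, `strand`
#' @param sites crosslink sites (`contig`, `pos`, `strand`, `score`)
#' @param intron_window intronic window width in nt (default 250)
#' @param exon_window exonic window width in nt (default 50)
#' @return list with `acceptor` and `donor` `data.frame`s (`rel_pos`,
#'   `mean_coverage`) and `n_junctions`
#' @export
signal_metaprofile <- function(junctions, sites, intron_window = 250L,
                               exon_window = 50L) {
  n <- nrow(junctions)
  if (!n) .stopf("empty junction set")
  skey <- paste(sites$contig, sites$pos, sites$strand)
  score_at <- function(contig, pos, strand) {
    v <- sites$score[match(paste(contig, pos, strand), skey)]
    v[is.na(v)] <- 0
    v
  }
  one_side <- function(side) {
    total <- NULL
    for (i in seq_len(n)) {
      sp <- .side_positions(junctions[i, , drop = FALSE], side,
                            intron_window, exon_window)
      v <- score_at(junctions$contig[i], sp$pos, junctions$strand[i])
      if (is.null(total)) {
        total <- v
        rel <- sp$rel
      } else total <- total + v
    }
    data.frame(rel_pos = rel, mean_coverage = total / n)
  }
  list(acceptor = one_side("acceptor"), donor = one_side("donor"),
       n_junctions = n)
}
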