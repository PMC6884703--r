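# Parental-transcript assignment and molecular characterization.
#
# A circRNA boundary "matches" an annotated splice site when it coincides
# exactly with an exon boundary of the parental transcript in genomic
# coordinates: the left junction boundary with an exon start, the right
# boundary with an exon end (this holds on both strands; on the minus
# strand the donor exon starts at the junction start).  Parental choice
# priority: canonical transcripts with both boundaries matching, then
# non-canonical with both, then canonical with one side, then non-canonical
# with one side, then (as a labeled fallback) the transcript with the
# largest exonic overlap; ties broken by longer CDS, then transcript id.

.tx_candidates <- function(junction, models) {
  tx <- models$transcripts
  ex <- models$exons
  sel_tx <- tx$contig == junction$contig & tx$strand == junction$strand &
    tx$start < junction$end & tx$end > junction$start
  tx <- tx[sel_tx, , drop = FALSE]
  if (!nrow(tx)) return(NULL)
  res <- lapply(seq_len(nrow(tx)), function(i) {
    te <- ex[ex$transcript_id == tx$transcript_id[i], , drop = FALSE]
    ovl <- te$start < junction$end & te$end > junction$start
    if (!any(ovl)) return(NULL)
    left <- any(te$start == junction$start)
    right <- any(te$end == junction$end)
    list(transcript = tx[i, , drop = FALSE], exons = te,
         n_match = left + right, both = left && right,
         overlap_nt = sum(pmin(te$end[ovl], junction$end) -
                            pmax(te$start[ovl], junction$start)))
  })
  res[!vapply(res, is.null, TRUE)]
}

.pick_parental <- function(cands) {
  if (!length(cands)) return(NULL)
  score <- vapply(cands, function(cc) {
    canonical <- isTRUE(cc$transcript$canonical)
    # priority levels: lower is better
    level <- if (cc$both && canonical) 1L
    else if (cc$both) 2L
    else if (cc$n_match == 1L && canonical) 3L
    else if (cc$n_match == 1L) 4L
    else if (canonical) 5L else 6L
    level
  }, integer(1L))
  best <- which(score == min(score))
  if (length(best) > 1L) {
    cds_len <- vapply(cands[best], function(cc) {
      if (is.na(cc$transcript$cds_start)) 0L
      else cc$transcript$cds_end - cc$transcript$cds_start
    }, integer(1L))
    best <- best[order(-cds_len,
                       vapply(cands[best], function(cc)
                         cc$transcript$transcript_id, ""))]
  }
  cands[[best[1L]]]
}

#' Assign parental transcripts and internal exons to a catalog
#'
#' For every junction, overlapping genes decide the coarse class
#' (intergenic, intronic, ambiguous when two mutually overlapping genes are
#' hit, multi-gene when the overlapped genes are disjoint). Within a single
#' gene, the best parental transcript is chosen by exact splice-site
#' coincidence with canonical transcripts preferred; all of the parental
#' transcript's exons between the back-splice sites (boundary exons
#' included) are taken as the circRNA's internal exons.
#'
#' @param catalog `data.frame` with `contig`, `start`, `end`, `strand`
#' @param models a [transcript_models] object
#' @return `catalog` with columns `gene_id`, `gene_name`,
#'   `parental_transcript`, `origin_class`, `boundary_matches` (0/1/2),
#'   `acceptor_exon_rank`, `donor_exon_rank`, `n_internal_exons`,
#'   `spliced_length`, `span`
#' @export
assign_parental_transcripts <- function(catalog, models) {
  n <- nrow(catalog)
  out <- catalog
  out$gene_id <- NA_character_
  out$gene_name <- NA_character_
  out$parental_transcript <- NA_character_
  out$origin_class <- NA_character_
  out$boundary_matches <- NA_integer_
  out$acceptor_exon_rank <- NA_integer_
  out$donor_exon_rank <- NA_integer_
  out$n_internal_exons <- 0L
  out$spliced_length <- NA_integer_
  out$span <- catalog$end - catalog$start
  if (!n) return(out)
  ovl_genes <- .overlapping_gene_ids(catalog, models)
  genes <- models$genes
  for (i in seq_len(n)) {
    junction <- catalog[i, , drop = FALSE]
    gids <- unique(ovl_genes[[i]])
    if (!length(gids)) {
      out$origin_class[i] <- "intergenic"
      next
    }
    if (length(gids) > 1L) {
      g <- genes[genes$gene_id %in% gids, , drop = FALSE]
      disjoint <- FALSE
      for (a in seq_len(nrow(g) - 1L)) {
        for (b in seq(a + 1L, nrow(g))) {
          if (g$contig[a] != g$contig[b] || g$end[a] <= g$start[b] ||
              g$end[b] <= g$start[a]) disjoint <- TRUE
        }
      }
      out$origin_class[i] <- if (disjoint) "multi_gene" else "ambiguous"
      next
    }
    out$gene_id[i] <- gids
    out$gene_name[i] <- genes$gene_name[genes$gene_id == gids]
    cands <- .tx_candidates(junction, models)
    if (is.null(cands) || !length(cands)) {
      out$origin_class[i] <- "intronic"
      next
    }
    best <- .pick_parental(cands)
    out$parental_transcript[i] <- best$transcript$transcript_id
    out$boundary_matches[i] <- as.integer(best$n_match)
    internal <- best$exons[best$exons$start < junction$end &
                             best$exons$end > junction$start, , drop = FALSE]
    out$n_internal_exons[i] <- nrow(internal)
    out$spliced_length[i] <- sum(pmin(internal$end, junction$end) -
                                   pmax(internal$start, junction$start))
    out$acceptor_exon_rank[i] <- min(internal$rank)
    out$donor_exon_rank[i] <- max(internal$rank)
    out$origin_class[i] <- "exonic"
  }
  # refine exonic class by boundary regions of the parental transcript
  exonic <- which(out$origin_class == "exonic")
  if (length(exonic)) {
    regions <- classify_origin(out[exonic, , drop = FALSE], models)
    out$acceptor_region <- NA_character_
    out$donor_region <- NA_character_
    out$acceptor_region[exonic] <- regions$acceptor_region
    out$donor_region[exonic] <- regions$donor_region
    out$origin_class[exonic] <- regions$origin_class
  } else {
    out$acceptor_region <- NA_character_
    out$donor_region <- NA_character_
  }
  out
}

#' Classify the transcript region at each back-splice boundary
#'
#' The first base of the acceptor exon and the last base of the donor exon
#' are located within the parental transcript: inside the annotated CDS,
#' the 5' or 3' UTR (decided in transcript orientation), a non-coding exon,
#' or an intron. The overall class summarizes the pair with precedence
#' CDS > UTR5 > UTR3 > noncoding_exon > intronic.
#'
#' @param catalog rows with `parental_transcript` assigned
#' @param models a [transcript_models] object
#' @return `data.frame` with `acceptor_region`, `donor_region`,
#'   `origin_class`
#' @export
classify_origin <- function(catalog, models) {
  tx <- models$transcripts
  ex <- models$exons
  one_region <- function(tx_row, pos) {
    te <- ex[ex$transcript_id == tx_row$transcript_id, , drop = FALSE]
    in_exon <- any(te$start <= pos & pos < te$end)
    if (!in_exon) return("intron")
    if (is.na(tx_row$cds_start)) return("noncoding_exon")
    if (tx_row$cds_start <= pos && pos < tx_row$cds_end) return("CDS")
    left_of_cds <- pos < tx_row$cds_start
    if (tx_row$strand == "+") {
      if (left_of_cds) "UTR5" else "UTR3"
    } else {
      if (left_of_cds) "UTR3" else "UTR5"
    }
  }
  n <- nrow(catalog)
  acc <- don <- overall <- character(n)
  for (i in seq_len(n)) {
    txid <- catalog$parental_transcript[i]
    if (is.na(txid)) {
      acc[i] <- don[i] <- "none"
      overall[i] <- "intergenic"
      next
    }
    tx_row <- tx[tx$transcript_id == txid, , drop = FALSE]
    plus <- catalog$strand[i] == "+"
    acc_pos <- if (plus) catalog$start[i] else catalog$end[i] - 1L
    don_pos <- if (plus) catalog$end[i] - 1L else catalog$start[i]
    acc[i] <- one_region(tx_row, acc_pos)
    don[i] <- one_region(tx_row, don_pos)
    pair <- c(acc[i], don[i])
    overall[i] <- if ("CDS" %in% pair) "CDS"
    else if ("UTR5" %in% pair) "UTR5"
    else if ("UTR3" %in% pair) "UTR3"
    else if ("noncoding_exon" %in% pair) "noncoding_exon"
    else "intronic"
  }
  data.frame(acceptor_region = acc, donor_region = don,
             origin_class = overall, stringsAsFactors = FALSE)
}

#' Internal exons of annotated circRNAs
#'
#' @param catalog output of [assign_parental_transcripts()]
#' @param models a [transcript_models] object
#' @return `data.frame` of internal exons (`name`, `gene_id`,
#'   `transcript_id`, `contig`, `start`, `end`, `rank`)
#' @export
internal_exon_table <- function(catalog, models) {
  ex <- models$exons
  rows <- which(!is.na(catalog$parental_transcript))
  out <- lapply(rows, function(i) {
    te <- ex[ex$transcript_id == catalog$parental_transcript[i], ,
             drop = FALSE]
    te <- te[te$start < catalog$end[i] & te$end > catalog$start[i], ,
             drop = FALSE]
    if (!nrow(te)) return(NULL)
    data.frame(name = circ_id(catalog$contig[i], catalog$start[i],
                              catalog$end[i], catalog$strand[i]),
               gene_id = te$gene_id, transcript_id = te$transcript_id,
               contig = te$contig, start = te$start, end = te$end,
               rank = te$rank, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(name = character(), gene_id = character(),
                      transcript_id = character(), contig = character(),
                      start = integer(), end = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  .reset_rownames(do.call(rbind, out))
}

#' Exon-rank spectrum of back-splice sites
#'
#' For rank `r` the normalized frequency is the number of circRNAs using
#' rank `r` as acceptor (or donor) divided by the number of genes that have
#' at least `r + 1` exons; ranks whose denominator is zero are omitted with
#' a warning.
#'
#' @param catalog output of [assign_parental_transcripts()]; only rows with
#'   a parental transcript and both ranks contribute
#' @param models a [transcript_models] object
#' @param side `"acceptor"` or `"donor"`
#' @return `data.frame` with `rank`, `count`, `n_genes`, `norm_freq`
#' @export
exon_rank_spectrum <- function(catalog, models, side = c("acceptor", "donor")) {
  side <- match.arg(side)
  col <- paste0(side, "_exon_rank")
  ranks <- catalog[[col]]
  ranks <- ranks[!is.na(ranks)]
  if (!length(ranks)) {
    return(data.frame(rank = integer(), count = integer(),
                      n_genes = integer(), norm_freq = numeric()))
  }
  tab <- table(ranks)
  rank_vals <- as.integer(names(tab))
  n_genes <- vapply(rank_vals, function(r) {
    sum(models$genes$n_exons >= r + 1L)
  }, numeric(1L))
  drop <- n_genes == 0
  if (any(drop)) {
    .warnf("rank(s) %s omitted: no gene has enough exons",
           paste(rank_vals[drop], collapse = ", "))
  }
  data.frame(rank = rank_vals[!drop],
             count = as.integer(tab)[!drop],
             n_genes = as.integer(n_genes[!drop]),
             norm_freq = as.integer(tab)[!drop] / n_genes[!drop])
}

#' Alternative back-splicing summary
#'
#' Counts distinct circRNA isoforms per host gene and flags back-splice
#' sites that pair with more than one partner site (alternative usage),
#' separately for acceptor and donor sites.
#'
#' @param catalog annotated catalog with `gene_id` (rows without a host
#'   gene are ignored)
#' @return list with `per_gene` (`gene_id`, `n_isoforms`), `sites` (one row
#'   per distinct site with `side`, `n_partners`, `alternative`),
#'   `fraction_alt_acceptor`, `fraction_alt_donor`, `fraction_alt_sites`
#' @export
alt_backsplice_summary <- function(catalog) {
  cat_g <- catalog[!is.na(catalog$gene_id), , drop = FALSE]
  per_gene <- if (nrow(cat_g)) {
    stats::aggregate(list(n_isoforms = cat_g$start),
                     by = list(gene_id = cat_g$gene_id), FUN = length)
  } else data.frame(gene_id = character(), n_isoforms = integer())
  plus <- cat_g$strand == "+"
  acc_pos <- ifelse(plus, cat_g$start, cat_g$end)
  don_pos <- ifelse(plus, cat_g$end, cat_g$start)
  site_key <- function(pos) paste(cat_g$contig, pos, cat_g$strand)
  acc_key <- site_key(acc_pos)
  don_key <- site_key(don_pos)
  n_partners <- function(keys, partners) {
    vapply(split(partners, keys), function(p) length(unique(p)), integer(1L))
  }
  acc_part <- n_partners(acc_key, don_pos)
  don_part <- n_partners(don_key, acc_pos)
  sites <- rbind(
    data.frame(site = names(acc_part), side = "acceptor",
               n_partners = as.integer(acc_part),
               stringsAsFactors = FALSE),
    data.frame(site = names(don_part), side = "donor",
               n_partners = as.integer(don_part),
               stringsAsFactors = FALSE)
  )
  sites$alternative <- sites$n_partners > 1L
  frac <- function(side) {
    s <- sites[sites$side == side, , drop = FALSE]
    if (!nrow(s)) return(NA_real_)
    mean(s$alternative)
  }
  list(per_gene = .reset_rownames(per_gene),
       sites = .reset_rownames(sites),
       fraction_alt_acceptor = frac("acceptor"),
       fraction_alt_donor = frac("donor"),
       fraction_alt_sites = if (nrow(sites)) mean(sites$alternative)
                            else NA_real_)
}

#' Length features of annotated circRNAs
#'
#' Adds flanking intron lengths (the parental transcript's introns
#' immediately outside the circularized span; `NA` at terminal exons),
#' boundary exon lengths, spliced length and genomic span.
#'
#' @param catalog output of [assign_parental_transcripts()]
#' @param models a [transcript_models] object
#' @return `catalog` with `flank_intron_up`, `flank_intron_down`,
#'   `acceptor_exon_length`, `donor_exon_length` columns added
#' @export
length_features <- function(catalog, models) {
  ex <- models$exons
  n <- nrow(catalog)
  up <- dn <- rep(NA_integer_, n)
  acc_len <- don_len <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    txid <- catalog$parental_transcript[i]
    if (is.na(txid)) next
    te <- ex[ex$transcript_id == txid, , drop = FALSE]
    te <- te[order(te$start), , drop = FALSE]
    if (nrow(te) > 1L) {
      introns <- data.frame(start = te$end[-nrow(te)], end = te$start[-1L])
      left <- introns[introns$end == catalog$start[i], , drop = FALSE]
      right <- introns[introns$start == catalog$end[i], , drop = FALSE]
      left_len <- if (nrow(left)) left$end[1L] - left$start[1L] else NA_integer_
      right_len <- if (nrow(right)) right$end[1L] - right$start[1L] else NA_integer_
    } else {
      left_len <- right_len <- NA_integer_
    }
    plus <- catalog$strand[i] == "+"
    # upstream = 5' of the acceptor exon in transcript orientation
    up[i] <- if (plus) left_len else right_len
    dn[i] <- if (plus) right_len else left_len
    internal <- te[te$start < catalog$end[i] & te$end > catalog$start[i], ,
                   drop = FALSE]
    if (nrow(internal)) {
      leftmost <- internal[which.min(internal$start), , drop = FALSE]
      rightmost <- internal[which.max(internal$end), , drop = FALSE]
      acc_ex <- if (plus) leftmost else rightmost
      don_ex <- if (plus) rightmost else leftmost
      acc_len[i] <- acc_ex$end - acc_ex$start
      don_len[i] <- don_ex$end - don_ex$start
    }
  }
  catalog$flank_intron_up <- up
  catalog$flank_intron_down <- dn
  catalog$acceptor_exon_length <- acc_len
  catalog$donor_exon_length <- don_len
  if (!"span" %in% names(catalog)) catalog$span <- catalog$end - catalog$start
  catalog
}
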