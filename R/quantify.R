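# Back-splice read recounting and abundance metrics.
#
# PCR duplicates are flagged from mapping coordinates, not read sequence:
# two reads are duplicates when both aligned segments share positions and
# CIGARs.  Presence thresholds use distinct reads; abundance metrics use
# all reads.

.dup_key <- function(records) {
  paste(records$sample_id, records$contig, records$strand,
        records$seg1_pos, records$seg1_cigar,
        records$seg2_pos, records$seg2_cigar, sep = "\r")
}

#' Flag coordinate-based PCR duplicates among chimeric records
#'
#' Within each sample, records sharing (contig, strand, segment positions,
#' segment CIGARs) are one molecule: the first occurrence is kept as
#' non-duplicate, the rest are flagged. Idempotent.
#'
#' @param records chimeric records (any number of samples)
#' @return `records` with a logical `is_duplicate` column
#' @export
flag_duplicates <- function(records) {
  records$is_duplicate <- duplicated(.dup_key(records))
  records
}

#' Recount back-splice support for a catalog from chimeric records
#'
#' Each qualifying record (same contig and strand, head-to-tail segment
#' order) is assigned to its exact junction; per sample, `all_reads` counts
#' every record and `distinct_reads` counts coordinate-distinct records
#' (see [flag_duplicates()]). Junctions without records keep zero counts.
#'
#' @param catalog `data.frame` with `contig`, `start`, `end`, `strand`
#' @param records chimeric records covering all samples
#' @param libraries `data.frame` with columns `sample_id`, `condition`,
#'   `library_size`
#' @param min_overhang passed to [call_junctions()]
#' @return `catalog` with `all_reads.<sample>` and `distinct_reads.<sample>`
#'   integer columns for every sample in `libraries`
#' @export
count_backsplice <- function(catalog, records, libraries, min_overhang = 15L) {
  stopifnot(all(c("sample_id", "library_size") %in% names(libraries)))
  if (any(libraries$library_size <= 0)) .stopf("library size must be > 0")
  extra <- setdiff(unique(records$sample_id), libraries$sample_id)
  if (length(extra)) {
    .stopf("records carry sample(s) absent from libraries: %s",
           paste(extra, collapse = ", "))
  }
  calls <- call_junctions(records, min_overhang = min_overhang)
  qrec <- calls$records[!is.na(calls$records$junction_id), , drop = FALSE]
  qrec <- flag_duplicates(qrec)
  key <- circ_id(catalog$contig, catalog$start, catalog$end, catalog$strand)
  samples <- libraries$sample_id
  for (s in samples) {
    rs <- qrec[qrec$sample_id == s, , drop = FALSE]
    all_tab <- table(rs$junction_id)
    dis_tab <- table(rs$junction_id[!rs$is_duplicate])
    a <- as.integer(all_tab[key]); a[is.na(a)] <- 0L
    d <- as.integer(dis_tab[key]); d[is.na(d)] <- 0L
    catalog[[paste0("all_reads.", s)]] <- a
    catalog[[paste0("distinct_reads.", s)]] <- d
  }
  catalog
}

#' Back-splice reads per million mapped reads
#'
#' @param all_reads back-splice read count (all reads, duplicates included)
#' @param library_size total mapped reads in the sample library
#' @return `all_reads / library_size * 1e6`
#' @export
rpm <- function(all_reads, library_size) {
  if (any(library_size <= 0)) .stopf("library size must be > 0")
  all_reads / library_size * 1e6
}

#' Linear-junction support at the splice sites of back-splice junctions
#'
#' For each back-splice boundary, the unique-read counts of all linear
#' introns sharing that exact splice site are summed (introns ending at the
#' left boundary, introns starting at the right boundary); the returned
#' support is the mean of the two sums. Missing junctions contribute zero.
#'
#' @param junctions `data.frame` with `contig`, `start`, `end`, `strand`
#' @param linear linear junction records from [read_linear_junctions()]
#'   for one sample
#' @param use_multi also count multi-mapping reads
#' @return numeric vector of mean linear counts (may be fractional)
#' @export
linear_support <- function(junctions, linear, use_multi = FALSE) {
  counts <- linear$unique_reads +
    if (use_multi) linear$multi_reads else 0L
  strand_ok <- function(jstr) linear$strand == jstr | linear$strand == "*"
  vapply(seq_len(nrow(junctions)), function(i) {
    sel <- linear$contig == junctions$contig[i] &
      strand_ok(junctions$strand[i])
    left <- sum(counts[sel & linear$intron_end == junctions$start[i]])
    right <- sum(counts[sel & linear$intron_start == junctions$end[i]])
    (left + right) / 2
  }, numeric(1L))
}

#' Circular-to-linear ratio
#'
#' Back-splice reads divided by the linear-junction reads after adding a
#' pseudocount of 1 to the denominator (optionally to both sides).
#'
#' @param all_reads back-splice reads
#' @param linear_reads mean linear-junction reads at the same splice sites
#' @param pseudocount stabilizing constant, default 1
#' @param both_sides add the pseudocount to the numerator as well
#' @return numeric CLR values
#' @export
clr <- function(all_reads, linear_reads, pseudocount = 1, both_sides = FALSE) {
  stopifnot(all(all_reads >= 0), all(linear_reads >= 0))
  num <- all_reads + if (both_sides) pseudocount else 0
  num / (linear_reads + pseudocount)
}

#' Percent circularized
#'
#' `100 * back / (back + linear)`: the relative abundance of the circular
#' isoform among all isoforms using the same splice sites. Undefined (NA)
#' when both counts are zero.
#'
#' @inheritParams clr
#' @return numeric vector in `[0, 100]`, `NA` where undefined
#' @export
percent_circularized <- function(all_reads, linear_reads) {
  stopifnot(all(all_reads >= 0), all(linear_reads >= 0))
  out <- 100 * all_reads / (all_reads + linear_reads)
  out[all_reads == 0 & linear_reads == 0] <- NA_real_
  out
}

#' Fold change in mean CLR between two conditions
#'
#' @param clr_matrix numeric matrix of CLR values, rows = circRNAs, columns
#'   named by sample id
#' @param libraries sample table with `sample_id` and `condition`
#' @param condition_a,condition_b condition labels (fold = B over A)
#' @return numeric vector; `Inf` where mean CLR in A is zero but B is not,
#'   `1` where both means are zero
#' @export
clr_shift <- function(clr_matrix, libraries, condition_a, condition_b) {
  clr_matrix <- as.matrix(clr_matrix)
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% libraries$condition) {
      .stopf("unknown condition label '%s'", cond)
    }
  }
  sa <- libraries$sample_id[libraries$condition == condition_a]
  sb <- libraries$sample_id[libraries$condition == condition_b]
  if (!all(c(sa, sb) %in% colnames(clr_matrix))) {
    .stopf("clr_matrix lacks columns for some samples")
  }
  ma <- rowMeans(clr_matrix[, sa, drop = FALSE])
  mb <- rowMeans(clr_matrix[, sb, drop = FALSE])
  out <- mb / ma
  out[ma == 0 & mb == 0] <- 1
  out[ma == 0 & mb > 0] <- Inf
  out
}

#' Host-gene expression in TPM with circle-internal exons excluded
#'
#' Reads from exons predicted to be internal to a circRNA are omitted; by
#' default the effective gene length excludes those exon lengths as well,
#' so that the rate is not biased downward for host genes.
#'
#' @param exon_counts `data.frame` with `gene_id`, `contig`, `start`, `end`
#'   and one integer count column per sample (named by sample id)
#' @param models a [transcript_models] object; every exon in `exon_counts`
#'   must exist in the models
#' @param internal_exons `data.frame` with `contig`, `start`, `end` of
#'   exons internal to any circRNA (e.g. from [assign_parental_transcripts()])
#' @param samples sample ids; defaults to every non-coordinate column
#' @param exclude_internal_length also drop internal exon lengths from the
#'   effective length
#' @return `data.frame` with `gene_id`, `counts.<sample>` and `tpm.<sample>`;
#'   TPM columns sum to 1e6 whenever any gene has signal
#' @export
host_tpm <- function(exon_counts, models, internal_exons = NULL,
                     samples = NULL, exclude_internal_length = TRUE) {
  coord_cols <- c("gene_id", "contig", "start", "end")
  stopifnot(all(coord_cols %in% names(exon_counts)))
  if (is.null(samples)) samples <- setdiff(names(exon_counts), coord_cols)
  ekey <- function(df) paste(df$contig, df$start, df$end)
  known <- ekey(models$exons)
  missing <- !ekey(exon_counts) %in% known
  if (any(missing)) {
    .stopf("exon(s) in counts absent from models: %s",
           paste(head(ekey(exon_counts)[missing], 3L), collapse = "; "))
  }
  internal <- if (is.null(internal_exons) || !nrow(internal_exons)) {
    rep(FALSE, nrow(exon_counts))
  } else {
    ekey(exon_counts) %in% ekey(internal_exons)
  }
  len <- exon_counts$end - exon_counts$start
  gene_ids <- sort(unique(exon_counts$gene_id))
  use <- !internal
  len_use <- if (exclude_internal_length) use else rep(TRUE, length(len))
  eff_len <- vapply(gene_ids, function(g) {
    sum(len[exon_counts$gene_id == g & len_use])
  }, numeric(1L))
  all_internal <- eff_len == 0
  if (any(all_internal)) {
    .warnf("gene(s) with every exon circle-internal get TPM 0: %s",
           paste(gene_ids[all_internal], collapse = ", "))
  }
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (s in samples) {
    cnt <- vapply(gene_ids, function(g) {
      sel <- exon_counts$gene_id == g & use
      sum(exon_counts[[s]][sel])
    }, numeric(1L))
    rate <- ifelse(eff_len > 0, cnt / (eff_len / 1000), 0)
    tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate * 0
    out[[paste0("counts.", s)]] <- cnt
    out[[paste0("tpm.", s)]] <- tpm
  }
  .reset_rownames(out)
}

#' Quantify a catalog: counts, RPM, linear support, CLR, percent circularized
#'
#' Convenience composition used by the pipeline: recounts back-splice
#' support per sample, then derives every abundance metric.
#'
#' @inheritParams count_backsplice
#' @param linear linear junction records for all samples (with `sample_id`)
#' @param ... passed to [clr()]
#' @return the catalog with, per sample, `all_reads.*`, `distinct_reads.*`,
#'   `rpm.*`, `linear.*`, `clr.*`, `pct_circ.*` columns
#' @export
quantify_catalog <- function(catalog, records, linear, libraries,
                             min_overhang = 15L, ...) {
  catalog <- count_backsplice(catalog, records, libraries,
                              min_overhang = min_overhang)
  for (i in seq_len(nrow(libraries))) {
    s <- libraries$sample_id[i]
    all_r <- catalog[[paste0("all_reads.", s)]]
    lin <- linear_support(catalog, linear[linear$sample_id == s, ,
                                          drop = FALSE])
    catalog[[paste0("rpm.", s)]] <- rpm(all_r, libraries$library_size[i])
    catalog[[paste0("linear.", s)]] <- lin
    catalog[[paste0("clr.", s)]] <- clr(all_r, lin, ...)
    catalog[[paste0("pct_circ.", s)]] <- percent_circularized(all_r, lin)
  }
  catalog
}
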