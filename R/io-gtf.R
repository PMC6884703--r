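# Gene-annotation input: GTF is parsed with rtracklayer (the standard
# Bioconductor reader) and reshaped into a light-weight transcript-model
# container used throughout the package.

#' Build a transcript-model container
#'
#' @param transcripts `data.frame` with columns `transcript_id`, `gene_id`,
#'   `gene_name`, `contig`, `strand` and optionally `support_level`
#'   (integer, `NA` allowed), `canonical` (logical), `cds_start`, `cds_end`
#'   (0-based half-open genomic CDS extent, `NA` if non-coding)
#' @param exons `data.frame` with columns `transcript_id`, `contig`, `start`,
#'   `end` (0-based half-open), `strand`; exon rank (1-based, in transcript
#'   orientation) is recomputed here
#' @return a `transcript_models` object with elements `transcripts`, `exons`
#'   (with `rank` and `gene_id` columns) and `genes` (genomic extent per gene)
#' @export
transcript_models <- function(transcripts, exons) {
  need_tx <- c("transcript_id", "gene_id", "gene_name", "contig", "strand")
  if (!all(need_tx %in% names(transcripts))) {
    .stopf("transcripts table must have columns: %s",
           paste(need_tx, collapse = ", "))
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    .stopf("duplicate transcript_id in transcripts table")
  }
  for (col in c("support_level")) {
    if (!col %in% names(transcripts)) transcripts[[col]] <- NA_integer_
  }
  if (!"canonical" %in% names(transcripts)) transcripts$canonical <- FALSE
  for (col in c("cds_start", "cds_end")) {
    if (!col %in% names(transcripts)) transcripts[[col]] <- NA_integer_
  }
  .check_strand(transcripts$strand, "transcripts table")
  missing_tx <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(missing_tx)) {
    .stopf("exon without parent transcript: %s",
           paste(head(missing_tx, 5L), collapse = ", "))
  }
  if (any(exons$start >= exons$end)) .stopf("exon with start >= end")

  exons$gene_id <- transcripts$gene_id[match(exons$transcript_id,
                                             transcripts$transcript_id)]
  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  # rank 1 is the 5'-most exon in transcript orientation
  exons$rank <- stats::ave(exons$start, exons$transcript_id,
                           FUN = seq_along)
  minus <- transcripts$strand[match(exons$transcript_id,
                                    transcripts$transcript_id)] == "-"
  n_ex <- stats::ave(exons$start, exons$transcript_id, FUN = length)
  exons$rank <- ifelse(minus, n_ex - exons$rank + 1, exons$rank)
  exons$rank <- as.integer(exons$rank)

  tx_start <- tapply(exons$start, exons$transcript_id, min)
  tx_end <- tapply(exons$end, exons$transcript_id, max)
  transcripts$start <- as.integer(tx_start[transcripts$transcript_id])
  transcripts$end <- as.integer(tx_end[transcripts$transcript_id])

  gsplit <- split(transcripts, transcripts$gene_id)
  genes <- do.call(rbind, lapply(gsplit, function(g) {
    gid <- g$gene_id[1L]
    # gene exon count = largest exon count among the gene's transcripts
    n_ex_gene <- max(tapply(exons$rank[exons$gene_id == gid],
                            exons$transcript_id[exons$gene_id == gid], max))
    data.frame(gene_id = gid, gene_name = g$gene_name[1L],
               contig = g$contig[1L], start = min(g$start),
               end = max(g$end), strand = g$strand[1L],
               n_exons = as.integer(n_ex_gene),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(transcripts = .reset_rownames(transcripts),
         exons = .reset_rownames(exons),
         genes = .reset_rownames(genes)),
    class = "transcript_models"
  )
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("transcript_models: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Read gene annotation from a GTF file
#'
#' Exons are grouped per transcript and ranked 5' to 3' in transcript
#' orientation. A transcript support-level filter is applied when the
#' attribute is present (transcripts without a support level pass by
#' default). Transcripts carrying a `tag` attribute containing
#' `"canonical"`, or listed in `canonical_ids`, are flagged canonical.
#'
#' @param path path to a GTF file with exon (and optionally CDS) features
#' @param support_levels integer vector of support levels to keep; `NULL`
#'   disables the filter
#' @param canonical_ids optional character vector of canonical transcript ids
#' @return a [transcript_models] object
#' @export
read_gene_annotation <- function(path, support_levels = c(1L, 2L),
                                 canonical_ids = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ex <- gr[type == "exon"]
  if (!length(ex)) .stopf("no exon features in %s", path)
  exm <- S4Vectors::mcols(ex)
  if (is.null(exm$transcript_id) || anyNA(exm$transcript_id)) {
    bad <- which(is.na(exm$transcript_id))
    .stopf("exon without parent transcript (exon feature %s)",
           paste(head(bad, 5L), collapse = ", "))
  }
  exons <- data.frame(
    transcript_id = as.character(exm$transcript_id),
    contig = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE
  )
  first <- !duplicated(exons$transcript_id)
  gene_id <- as.character(exm$gene_id)
  gene_name <- if (!is.null(exm$gene_name)) as.character(exm$gene_name) else gene_id
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  tsl <- rep(NA_integer_, sum(first))
  if (!is.null(exm$transcript_support_level)) {
    tsl <- suppressWarnings(
      as.integer(as.character(exm$transcript_support_level))[first])
  }
  canon <- rep(FALSE, sum(first))
  if (!is.null(exm$tag)) {
    canon <- grepl("canonical", as.character(exm$tag)[first],
                   ignore.case = TRUE)
  }
  transcripts <- data.frame(
    transcript_id = exons$transcript_id[first],
    gene_id = gene_id[first],
    gene_name = gene_name[first],
    contig = exons$contig[first],
    strand = exons$strand[first],
    support_level = tsl,
    canonical = canon,
    stringsAsFactors = FALSE
  )
  if (!is.null(canonical_ids)) {
    transcripts$canonical <- transcripts$canonical |
      transcripts$transcript_id %in% canonical_ids
  }
  cds <- gr[type == "CDS"]
  if (length(cds)) {
    cid <- as.character(S4Vectors::mcols(cds)$transcript_id)
    cs <- tapply(GenomicRanges::start(cds) - 1L, cid, min)
    ce <- tapply(GenomicRanges::end(cds), cid, max)
    transcripts$cds_start <- as.integer(cs[transcripts$transcript_id])
    transcripts$cds_end <- as.integer(ce[transcripts$transcript_id])
  }
  if (!is.null(support_levels)) {
    keep <- is.na(transcripts$support_level) |
      transcripts$support_level %in% support_levels
    transcripts <- transcripts[keep, , drop = FALSE]
    exons <- exons[exons$transcript_id %in% transcripts$transcript_id, ,
                   drop = FALSE]
    if (!nrow(transcripts)) .stopf("no transcripts pass the support-level filter")
  }
  transcript_models(transcripts, exons)
}

#' Write transcript models to a GTF file
#'
#' Emits gene, transcript, exon and (when present) CDS features with 1-based
#' inclusive coordinates. Mainly used to serialize simulated annotations.
#'
#' @param models a [transcript_models] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  ex <- models$exons
  gn <- models$genes
  fmt <- function(contig, src, type, start0, end0, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            contig, src, type, start0 + 1L, end0, strand, attrs)
  }
  lines <- character(0)
  for (i in seq_len(nrow(gn))) {
    lines <- c(lines, fmt(gn$contig[i], "circkit", "gene", gn$start[i],
                          gn$end[i], gn$strand[i],
                          sprintf('gene_id "%s"; gene_name "%s";',
                                  gn$gene_id[i], gn$gene_name[i])))
    gtx <- tx[tx$gene_id == gn$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(gtx))) {
      base_attr <- sprintf(
        'gene_id "%s"; gene_name "%s"; transcript_id "%s";%s',
        gtx$gene_id[j], gtx$gene_name[j], gtx$transcript_id[j],
        if (isTRUE(gtx$canonical[j])) ' tag "canonical";' else "")
      lines <- c(lines, fmt(gtx$contig[j], "circkit", "transcript",
                            gtx$start[j], gtx$end[j], gtx$strand[j],
                            base_attr))
      tex <- ex[ex$transcript_id == gtx$transcript_id[j], , drop = FALSE]
      tex <- tex[order(tex$start), , drop = FALSE]
      for (k in seq_len(nrow(tex))) {
        lines <- c(lines, fmt(tex$contig[k], "circkit", "exon",
                              tex$start[k], tex$end[k], tex$strand[k],
                              sprintf('%s exon_number "%d";',
                                      base_attr, tex$rank[k])))
      }
      if (!is.na(gtx$cds_start[j])) {
        for (k in seq_len(nrow(tex))) {
          cs <- max(tex$start[k], gtx$cds_start[j])
          ce <- min(tex$end[k], gtx$cds_end[j])
          if (cs < ce) {
            lines <- c(lines, fmt(tex$contig[k], "circkit", "CDS", cs, ce,
                                  tex$strand[k], base_attr))
          }
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
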