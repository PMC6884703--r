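# Candidate harmonization and the artifact filter cascade.

#' Filter configuration for the circRNA catalog
#'
#' Defaults mirror the consolidated pipeline: genomic span of at most
#' 100 kb, canonical GT/AG or GC/AG splice motifs, no spanning of multiple
#' non-overlapping genes, and at least two coordinate-distinct back-splice
#' reads in at least one sample.
#'
#' @param max_span_nt maximum `end - start` (inclusive bound)
#' @param allowed_motifs motif classes accepted by the motif rule
#' @param min_distinct_reads distinct-read presence threshold
#' @param min_samples_with_min_reads number of samples that must meet it
#' @param exclude_multi_gene reject candidates spanning two or more
#'   non-overlapping genes
#' @return a `filter_config` list
#' @export
filter_config <- function(max_span_nt = 100000L,
                          allowed_motifs = c("GT_AG", "GC_AG"),
                          min_distinct_reads = 2L,
                          min_samples_with_min_reads = 1L,
                          exclude_multi_gene = TRUE) {
  stopifnot(max_span_nt > 0, min_distinct_reads >= 1)
  structure(list(max_span_nt = max_span_nt,
                 allowed_motifs = allowed_motifs,
                 min_distinct_reads = min_distinct_reads,
                 min_samples_with_min_reads = min_samples_with_min_reads,
                 exclude_multi_gene = exclude_multi_gene),
            class = "filter_config")
}

#' Union circRNA candidates from multiple sources
#'
#' Candidates with identical (contig, start, end, strand) are merged;
#' provenance becomes the union of sources and per-source reported counts
#' are kept side by side (`reported.<source>` columns). Candidates whose
#' boundaries differ by small offsets are NOT merged: exact agreement after
#' coordinate normalization is required, and near-misses within
#' `near_window` nt are flagged `near_duplicate` for diagnostics.
#'
#' @param ... candidate `data.frame`s with columns `contig`, `start`, `end`,
#'   `strand`, `provenance`, `reported_count`
#' @param near_window distance (nt) within which distinct candidates are
#'   flagged as near-duplicates
#' @return merged candidate `data.frame` in canonical order
#' @export
harmonize_candidates <- function(..., near_window = 2L) {
  sets <- list(...)
  sets <- sets[vapply(sets, nrow, 0L) > 0]
  if (!length(sets)) return(.empty_candidates())
  all_c <- do.call(rbind, lapply(sets, function(s) {
    s[, c("contig", "start", "end", "strand", "provenance",
          "reported_count")]
  }))
  key <- circ_id(all_c$contig, all_c$start, all_c$end, all_c$strand)
  first <- !duplicated(key)
  out <- all_c[first, c("contig", "start", "end", "strand"), drop = FALSE]
  okey <- key[first]
  out$provenance <- vapply(okey, function(k) {
    paste(sort(unique(all_c$provenance[key == k])), collapse = ",")
  }, character(1L))
  for (src in sort(unique(all_c$provenance))) {
    cnt <- vapply(okey, function(k) {
      v <- all_c$reported_count[key == k & all_c$provenance == src]
      if (length(v)) sum(v) else NA_real_
    }, numeric(1L))
    out[[paste0("reported.", src)]] <- cnt
  }
  out <- .reset_rownames(.canonical_order(out))
  n <- nrow(out)
  near <- rep(FALSE, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- i + 1L
      while (j <= n && out$contig[j] == out$contig[i] &&
             out$start[j] - out$start[i] <= near_window) {
        if (out$strand[j] == out$strand[i] &&
            abs(out$end[j] - out$end[i]) <= near_window) {
          near[i] <- near[j] <- TRUE
        }
        j <- j + 1L
      }
    }
  }
  out$near_duplicate <- near
  out
}

.overlapping_gene_ids <- function(candidates, models) {
  if (!nrow(candidates)) return(vector("list", 0L))
  gq <- .as_granges(candidates$contig, candidates$start, candidates$end)
  gg <- .as_granges(models$genes$contig, models$genes$start,
                    models$genes$end)
  hits <- GenomicRanges::findOverlaps(gq, gg, ignore.strand = TRUE)
  split(models$genes$gene_id[S4Vectors::subjectHits(hits)],
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(candidates))))
}

# TRUE when the candidate overlaps >= 2 genes that are themselves disjoint
.spans_multiple_genes <- function(candidates, models) {
  ovl <- .overlapping_gene_ids(candidates, models)
  genes <- models$genes
  vapply(ovl, function(gids) {
    gids <- unique(gids)
    if (length(gids) < 2L) return(FALSE)
    g <- genes[genes$gene_id %in% gids, , drop = FALSE]
    for (i in seq_len(nrow(g) - 1L)) {
      for (j in seq(i + 1L, nrow(g))) {
        disjoint <- g$contig[i] != g$contig[j] ||
          g$end[i] <= g$start[j] || g$end[j] <= g$start[i]
        if (disjoint) return(TRUE)
      }
    }
    FALSE
  }, logical(1L))
}

#' Apply the artifact filter cascade to quantified candidates
#'
#' Rules are applied in a fixed, reported order -- span, motif, multi-gene,
#' support -- and each rejected candidate is tallied under the first rule it
#' fails, so that `retained + sum(tally)` equals the input size.
#'
#' @param candidates quantified candidates: coordinate columns plus
#'   `distinct_reads.<sample>` columns (from [count_backsplice()]); a
#'   `motif_class` column is computed from `genome` when absent
#' @param models a [transcript_models] object for the multi-gene rule
#' @param config a [filter_config]
#' @param genome genome `DNAStringSet`, required when `motif_class` is absent
#' @return list with `catalog` (survivors), `rejected` (with a
#'   `reject_rule` column) and `tally` (named integer vector per rule)
#' @export
apply_filters <- function(candidates, models, config = filter_config(),
                          genome = NULL) {
  stopifnot(inherits(config, "filter_config"))
  dcols <- grep("^distinct_reads\\.", names(candidates), value = TRUE)
  if (!length(dcols)) {
    .stopf("candidate support missing: run count_backsplice() first (no distinct_reads.* columns)")
  }
  if (!"motif_class" %in% names(candidates)) {
    if (is.null(genome)) .stopf("motif_class absent and no genome supplied")
    candidates$motif_class <- classify_motif(candidates, genome)
  }
  n <- nrow(candidates)
  rule <- rep(NA_character_, n)
  span <- candidates$end - candidates$start
  rule[span > config$max_span_nt] <- "span"
  rule[is.na(rule) &
         !candidates$motif_class %in% config$allowed_motifs] <- "motif"
  if (config$exclude_multi_gene && n > 0L) {
    multi <- .spans_multiple_genes(candidates, models)
    rule[is.na(rule) & multi] <- "multi_gene"
  }
  dmat <- as.matrix(candidates[, dcols, drop = FALSE])
  n_ok <- rowSums(dmat >= config$min_distinct_reads)
  rule[is.na(rule) & n_ok < config$min_samples_with_min_reads] <- "support"

  keep <- is.na(rule)
  rejected <- candidates[!keep, , drop = FALSE]
  rejected$reject_rule <- rule[!keep]
  tally <- vapply(c("span", "motif", "multi_gene", "support"),
                  function(r) sum(rule == r, na.rm = TRUE), integer(1L))
  list(catalog = .reset_rownames(candidates[keep, , drop = FALSE]),
       rejected = .reset_rownames(rejected),
       tally = tally)
}

#' High-confidence circRNA subset
#'
#' Keeps circRNAs with at least `min_reads` back-splice reads (all reads,
#' duplicates included) in at least `min_samples` samples.
#'
#' @param catalog quantified catalog with `all_reads.<sample>` columns
#' @param min_reads per-sample read threshold (default 5)
#' @param min_samples number of samples required to meet it (default 2)
#' @param samples restrict the rule to these sample ids
#' @return the qualifying subset of `catalog`
#' @export
high_confidence_subset <- function(catalog, min_reads = 5L, min_samples = 2L,
                                   samples = NULL) {
  acols <- grep("^all_reads\\.", names(catalog), value = TRUE)
  if (!is.null(samples)) {
    acols <- paste0("all_reads.", samples)
    if (!all(acols %in% names(catalog))) .stopf("unknown sample id(s)")
  }
  if (min_samples > length(acols)) {
    .stopf("min_samples (%d) exceeds available samples (%d)",
           min_samples, length(acols))
  }
  amat <- as.matrix(catalog[, acols, drop = FALSE])
  keep <- rowSums(amat >= min_reads) >= min_samples
  .reset_rownames(catalog[keep, , drop = FALSE])
}
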