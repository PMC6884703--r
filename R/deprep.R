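# Differential-expression preparation: the combined gene + circRNA count
# matrix, testing eligibility, and the join of external DE results back to
# the catalog.  The negative-binomial model itself is delegated to an
# external engine (e.g. DESeq2); this module owns only matrix construction,
# eligibility, thresholds and joins.

#' Build the combined gene + circRNA count matrix
#'
#' Raw back-splice read counts of the circRNAs are stacked under the raw
#' gene counts so that an external DE engine can estimate library sizes and
#' dispersions from both. Genes below the total-count floor are dropped;
#' circRNA row ids are coordinate-derived (`circ|` prefix) and therefore
#' collision-free with gene ids.
#'
#' @param gene_counts integer matrix (genes x samples) with rownames
#' @param catalog quantified catalog with `all_reads.<sample>` columns
#' @param min_gene_total total-count floor for genes (default 10)
#' @return list with `counts` (integer matrix) and `row_type`
#'   (`"gene"`/`"circ"` per row)
#' @export
build_combined_matrix <- function(gene_counts, catalog, min_gene_total = 10L) {
  gene_counts <- as.matrix(gene_counts)
  samples <- colnames(gene_counts)
  acols <- paste0("all_reads.", samples)
  missing <- setdiff(acols, names(catalog))
  extra_cols <- setdiff(grep("^all_reads\\.", names(catalog), value = TRUE),
                        acols)
  if (length(missing) || length(extra_cols)) {
    .stopf("sample mismatch between gene counts and catalog: missing {%s}, extra {%s}",
           paste(sub("^all_reads\\.", "", missing), collapse = ", "),
           paste(sub("^all_reads\\.", "", extra_cols), collapse = ", "))
  }
  keep <- rowSums(gene_counts) >= min_gene_total
  gm <- gene_counts[keep, , drop = FALSE]
  ids <- circ_id(catalog$contig, catalog$start, catalog$end, catalog$strand)
  if (anyDuplicated(ids)) {
    .stopf("duplicate circRNA id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cm <- as.matrix(catalog[, acols, drop = FALSE])
  colnames(cm) <- samples
  rownames(cm) <- ids
  counts <- rbind(gm, cm)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) .stopf("negative counts in combined matrix")
  list(counts = counts,
       row_type = c(rep("gene", nrow(gm)), rep("circ", nrow(cm))))
}

#' circRNAs eligible for differential-expression testing
#'
#' The high-confidence rule (at least `min_reads` back-splice reads in at
#' least `min_samples` samples) applied within each sample group
#' (e.g. cell line): a circRNA qualifies if any single group satisfies it.
#'
#' @param catalog quantified catalog with `all_reads.<sample>` columns
#' @param groups named character vector mapping sample id to group label
#' @param min_reads,min_samples per-group rule thresholds
#' @return the eligible subset with an `eligible_group` column (first
#'   qualifying group)
#' @export
de_candidate_table <- function(catalog, groups, min_reads = 5L,
                               min_samples = 2L) {
  acols <- paste0("all_reads.", names(groups))
  if (!all(acols %in% names(catalog))) {
    .stopf("unknown grouping label: sample(s) %s absent from catalog",
           paste(setdiff(names(groups), sub("^all_reads\\.", "",
             grep("^all_reads\\.", names(catalog), value = TRUE))),
             collapse = ", "))
  }
  amat <- as.matrix(catalog[, acols, drop = FALSE])
  colnames(amat) <- names(groups)
  elig_group <- rep(NA_character_, nrow(catalog))
  for (g in unique(groups)) {
    cols <- names(groups)[groups == g]
    ok <- rowSums(amat[, cols, drop = FALSE] >= min_reads) >= min_samples
    elig_group[is.na(elig_group) & ok] <- g
  }
  out <- catalog[!is.na(elig_group), , drop = FALSE]
  out$eligible_group <- elig_group[!is.na(elig_group)]
  .reset_rownames(out)
}

#' Export count matrix and design for an external DE engine
#'
#' @param combined output of [build_combined_matrix()]
#' @param design `data.frame` with `sample_id` and `condition`
#' @param prefix output path prefix; writes `<prefix>_counts.tsv` and
#'   `<prefix>_design.tsv`
#' @return the two paths, invisibly
#' @export
export_de_inputs <- function(combined, design, prefix) {
  stopifnot(all(c("sample_id", "condition") %in% names(design)))
  missing <- setdiff(colnames(combined$counts), design$sample_id)
  if (length(missing)) {
    .stopf("design lacks sample(s): %s", paste(missing, collapse = ", "))
  }
  counts_path <- paste0(prefix, "_counts.tsv")
  design_path <- paste0(prefix, "_design.tsv")
  df <- data.frame(id = rownames(combined$counts),
                   row_type = combined$row_type,
                   combined$counts, check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts = counts_path, design = design_path))
}

#' Join external DE results back to the catalog
#'
#' Reads a TSV with columns `id`, `log2_fold_change`, `padj` and joins the
#' circRNA rows to the catalog by coordinate-derived id. Every catalog row
#' is preserved: rows without a result are marked `untested` (a three-state
#' contract -- significant / not_significant / untested).
#'
#' @param catalog the circRNA catalog
#' @param path path to the DE result TSV
#' @param fdr adjusted-p significance threshold (default 0.1)
#' @return `catalog` with `log2_fold_change`, `padj`, `de_status` columns
#' @export
import_de_results <- function(catalog, path, fdr = 0.1) {
  res <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "log2_fold_change", "padj")
  if (!all(need %in% names(res))) {
    .stopf("DE results need columns: %s", paste(need, collapse = ", "))
  }
  ids <- circ_id(catalog$contig, catalog$start, catalog$end, catalog$strand)
  circ_res <- res[startsWith(res$id, "circ|"), , drop = FALSE]
  unknown <- setdiff(circ_res$id, ids)
  if (length(unknown)) {
    .warnf("DE result id(s) absent from the catalog: %s",
           paste(head(unknown, 5L), collapse = ", "))
  }
  m <- match(ids, circ_res$id)
  catalog$log2_fold_change <- circ_res$log2_fold_change[m]
  catalog$padj <- circ_res$padj[m]
  catalog$de_status <- ifelse(
    is.na(m), "untested",
    ifelse(!is.na(circ_res$padj[m]) & circ_res$padj[m] < fdr,
           "significant", "not_significant"))
  catalog
}
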