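# End-to-end driver: detect -> harmonize -> recount -> filter -> quantify.

#' Run the consolidated circRNA pipeline on junction evidence
#'
#' Calls back-splice junctions from the chimeric records, unions them with
#' any caller-provided candidate sets, recounts per-sample support with
#' coordinate-based duplicate flagging, applies the artifact filter cascade
#' (span, motif, multi-gene, support), and computes abundance metrics (RPM,
#' linear support, CLR, percent circularized) for the surviving catalog.
#'
#' @param chimeric chimeric records (all samples row-bound), e.g. from
#'   [read_chimeric_table()]
#' @param linear linear junction records for all samples
#' @param libraries sample table (`sample_id`, `condition`, `library_size`)
#' @param genome a genome `DNAStringSet` (see [as_genome()])
#' @param models a [transcript_models] object
#' @param caller_candidates optional list of candidate `data.frame`s from
#'   [read_caller_candidates()]
#' @param config a [filter_config]
#' @param min_overhang minimum chimeric segment overhang (nt)
#' @param annotate also run parental-transcript assignment on the catalog
#' @return list with `catalog` (filtered, quantified, optionally
#'   annotated), `rejected`, `tally` (per-rule rejections), `calls` (the
#'   raw junction calls) and `candidates` (the harmonized pre-filter set)
#' @export
circ_pipeline <- function(chimeric, linear, libraries, genome, models,
                          caller_candidates = list(),
                          config = filter_config(), min_overhang = 15L,
                          annotate = TRUE) {
  calls <- call_junctions(chimeric, min_overhang = min_overhang)
  native <- calls$junctions
  native_cand <- data.frame(
    contig = native$contig, start = native$start, end = native$end,
    strand = native$strand, provenance = "native",
    reported_count = native$n_reads, stringsAsFactors = FALSE)
  candidates <- do.call(harmonize_candidates,
                        c(list(native_cand), caller_candidates))
  candidates <- count_backsplice(candidates, chimeric, libraries,
                                 min_overhang = min_overhang)
  candidates$motif_class <- classify_motif(candidates, genome)
  candidates <- annotate_splice_status(candidates, models)
  filt <- apply_filters(candidates, models, config)
  catalog <- filt$catalog
  if (nrow(catalog) && !"name" %in% names(catalog)) {
    catalog$name <- circ_id(catalog$contig, catalog$start, catalog$end,
                            catalog$strand)
  }
  if (nrow(catalog)) {
    catalog <- quantify_catalog(catalog, chimeric, linear, libraries,
                                min_overhang = min_overhang)
    if (annotate) catalog <- assign_parental_transcripts(catalog, models)
  }
  list(catalog = catalog, rejected = filt$rejected, tally = filt$tally,
       calls = calls, candidates = candidates)
}
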