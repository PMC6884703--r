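# Synthetic genomes, annotations and junction evidence with ground truth.
#
# The simulator states a small but complete world: multi-exon genes with
# canonical GT/GC..AG intron motifs on both strands, planted circRNAs with
# per-sample back-splice evidence including coordinate-identical PCR
# duplicates, linear junction support at every annotated intron, and one
# artifact family per filter rule (over-long span, non-canonical motif,
# junctions bridging two disjoint genes, single-read support).  Evidence is
# represented at the junction level (chimeric/SJ records), where the
# pipeline's scope begins; no FASTQ is generated.

#' Simulation configuration
#'
#' @param seed integer RNG seed (all randomness in the simulator derives
#'   from it; identical seeds give identical output)
#' @param n_genes number of genes on the single simulated contig
#' @param exons_per_gene inclusive range of exon counts per gene
#' @param exon_length,intron_length,intergenic inclusive length ranges (nt)
#' @param n_circ number of planted true circRNAs
#' @param circ_reads inclusive range of distinct back-splice reads per
#'   circRNA per sample
#' @param duplicate_rate expected PCR-duplicate fraction per distinct read
#' @param linear_reads inclusive range of unique linear-junction reads per
#'   annotated intron per sample
#' @param artifacts named counts per artifact category
#' @param n_samples number of samples
#' @param conditions condition label per sample (recycled)
#' @param library_size total mapped reads per sample library (recycled)
#' @param gc_donor_fraction fraction of introns given a GC (not GT) donor
#' @param seg_len aligned segment length used for synthesized CIGARs
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, exons_per_gene = c(4L, 8L),
                       exon_length = c(100L, 300L),
                       intron_length = c(400L, 1500L),
                       intergenic = c(1000L, 3000L),
                       n_circ = 30L, circ_reads = c(2L, 10L),
                       duplicate_rate = 0.2,
                       linear_reads = c(5L, 50L),
                       artifacts = c(long_span = 5L,
                                     non_canonical_motif = 5L,
                                     multi_gene = 5L, low_support = 5L),
                       n_samples = 4L,
                       conditions = c("normoxia", "hypoxia"),
                       library_size = 1e6,
                       gc_donor_fraction = 0.1,
                       seg_len = 35L) {
  stopifnot(exons_per_gene[1] >= 3L, n_genes >= 0L,
            all(exon_length > 0), all(intron_length > 4),
            duplicate_rate >= 0, duplicate_rate < 1)
  structure(list(
    seed = as.integer(seed), n_genes = n_genes,
    exons_per_gene = exons_per_gene, exon_length = exon_length,
    intron_length = intron_length, intergenic = intergenic,
    n_circ = n_circ, circ_reads = circ_reads,
    duplicate_rate = duplicate_rate, linear_reads = linear_reads,
    artifacts = artifacts, n_samples = n_samples,
    conditions = rep_len(conditions, n_samples),
    library_size = rep_len(library_size, n_samples),
    gc_donor_fraction = gc_donor_fraction, seg_len = seg_len
  ), class = "sim_config")
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a genome and gene annotation
#'
#' Builds one contig of random sequence carrying `n_genes` multi-exon genes
#' (strands alternating), overwrites every annotated intron boundary with a
#' canonical donor/acceptor motif (GT or, with probability
#' `gc_donor_fraction`, GC; acceptor always AG -- read on the template
#' strand of the gene), and reserves motif-controlled slots beyond the last
#' gene for span and motif artifacts.
#'
#' @param config a [sim_config]
#' @return a `circ_simulation` list with `genome`, `models`, `config` and
#'   `artifact_slots`
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- list(); exons <- list(); tx <- list()
  cursor <- 1000L
  for (g in seq_len(config$n_genes)) {
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_ex <- .runif_int(1L, config$exons_per_gene)
    ex_len <- .runif_int(n_ex, config$exon_length)
    in_len <- .runif_int(max(n_ex - 1L, 0L), config$intron_length)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- cursor
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      ends[k] <- pos + ex_len[k]
      pos <- ends[k] + if (k < n_ex) in_len[k] else 0L
    }
    gid <- sprintf("G%03d", g)
    txid <- sprintf("TX%03d", g)
    # CDS spans from inside the 2nd to inside the 2nd-to-last exon
    cds_start <- if (n_ex >= 3L) starts[2L] + 10L else NA_integer_
    cds_end <- if (n_ex >= 3L) ends[n_ex - 1L] - 10L else NA_integer_
    tx[[g]] <- data.frame(
      transcript_id = txid, gene_id = gid, gene_name = gid,
      contig = "chrS", strand = strand, support_level = 1L,
      canonical = TRUE, cds_start = cds_start, cds_end = cds_end,
      stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(
      transcript_id = txid, contig = "chrS", start = starts, end = ends,
      strand = strand, stringsAsFactors = FALSE)
    cursor <- pos + .runif_int(1L, config$intergenic)
  }
  layout_end <- if (config$n_genes > 0L) {
    max(vapply(exons, function(e) max(e$end), 0L))
  } else 1000L

  # artifact slots beyond the last gene: motif-controlled boundaries
  slots <- list()
  acur <- layout_end + 500L
  n_nc <- config$artifacts[["non_canonical_motif"]]
  if (!is.na(n_nc) && n_nc > 0L) {
    for (i in seq_len(n_nc)) {
      s <- acur + 200L
      e <- s + 4000L + 37L * i
      slots[[length(slots) + 1L]] <- data.frame(
        category = "non_canonical_motif", contig = "chrS", start = s,
        end = e, strand = "+", stringsAsFactors = FALSE)
      acur <- e + 200L
    }
  }
  n_ls <- config$artifacts[["long_span"]]
  if (!is.na(n_ls) && n_ls > 0L) {
    base <- acur + 100L
    for (i in seq_len(n_ls)) {
      s <- base + 7L * i
      e <- s + 100001L + 13L * i
      slots[[length(slots) + 1L]] <- data.frame(
        category = "long_span", contig = "chrS", start = s, end = e,
        strand = "+", stringsAsFactors = FALSE)
    }
    acur <- base + 7L * n_ls + 100001L + 13L * n_ls
  }
  contig_len <- acur + 2000L

  seq_chars <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  plant <- function(pos0, motif) {
    # pos0 is 0-based; overwrite length-2 motifs
    seq_chars[(pos0 + 1L):(pos0 + nchar(motif))] <<-
      strsplit(motif, "")[[1L]]
  }
  for (g in seq_len(config$n_genes)) {
    e <- exons[[g]]
    strand <- tx[[g]]$strand
    if (nrow(e) < 2L) next
    for (k in seq_len(nrow(e) - 1L)) {
      istart <- e$end[k]; iend <- e$start[k + 1L]
      gc <- stats::runif(1L) < config$gc_donor_fraction
      if (strand == "+") {
        plant(istart, if (gc) "GC" else "GT")
        plant(iend - 2L, "AG")
      } else {
        plant(istart, "CT")
        plant(iend - 2L, if (gc) "GC" else "AC")
      }
    }
  }
  for (sl in slots) {
    if (sl$category == "long_span") {
      plant(sl$start - 2L, "AG"); plant(sl$end, "GT")
    } else {
      plant(sl$start - 2L, "TT"); plant(sl$end, "TT")
    }
  }
  genome <- as_genome(setNames(paste(seq_chars, collapse = ""), "chrS"))
  models <- if (config$n_genes > 0L) {
    transcript_models(do.call(rbind, tx), do.call(rbind, exons))
  } else NULL
  artifact_slots <- if (length(slots)) do.call(rbind, slots) else
    data.frame(category = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  structure(list(genome = genome, models = models, config = config,
                 artifact_slots = artifact_slots),
            class = "circ_simulation")
}

# GC donors on the minus strand read "GC" after reverse complement, i.e.
# plus-strand "GC" at the intron 3' end -- planted above as the acceptor-side
# dinucleotide replacement of "AC".

#' Plant junction evidence for true circRNAs and artifacts
#'
#' Emits per-sample chimeric records (with coordinate-identical PCR
#' duplicates), linear SJ records for every annotated intron, caller-style
#' candidate tables for the true circRNAs, the sample table, and a truth
#' table whose `expected_fate` is derivable from category and counts.
#'
#' @param sim a `circ_simulation` from [simulate_genome()]
#' @return list with `chimeric`, `linear`, `libraries`, `finder_A`,
#'   `finder_B`, `truth`
#' @export
plant_circ_evidence <- function(sim) {
  stopifnot(inherits(sim, "circ_simulation"))
  config <- sim$config
  models <- sim$models
  set.seed(config$seed + 7L)
  samples <- sprintf("S%d", seq_len(config$n_samples))
  libraries <- data.frame(sample_id = samples,
                          condition = config$conditions,
                          library_size = config$library_size,
                          stringsAsFactors = FALSE)

  # candidate internal exon blocks: (gene, genomic exon i..j), boundaries at
  # internal exons so both splice sites are annotated and canonical
  blocks <- list()
  for (t in seq_len(nrow(models$transcripts))) {
    txid <- models$transcripts$transcript_id[t]
    e <- models$exons[models$exons$transcript_id == txid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    n_ex <- nrow(e)
    if (n_ex < 3L) next
    for (i in 2L:(n_ex - 1L)) {
      for (j in i:(n_ex - 1L)) {
        blocks[[length(blocks) + 1L]] <- data.frame(
          gene_id = models$transcripts$gene_id[t],
          contig = e$contig[1L], start = e$start[i], end = e$end[j],
          strand = e$strand[1L], stringsAsFactors = FALSE)
      }
    }
  }
  blocks <- do.call(rbind, blocks)
  n_low <- config$artifacts[["low_support"]]
  need <- config$n_circ + max(n_low, 0L, na.rm = TRUE)
  if (nrow(blocks) < need) {
    .stopf("gene structure supports only %d circRNA blocks, %d requested",
           nrow(blocks), need)
  }
  pick <- sample(nrow(blocks), need)
  true_j <- blocks[pick[seq_len(config$n_circ)], , drop = FALSE]
  low_j <- if (n_low > 0L) {
    blocks[pick[config$n_circ + seq_len(n_low)], , drop = FALSE]
  } else blocks[0L, ]

  # multi-gene artifacts: consecutive plus-strand gene pairs
  n_mg <- config$artifacts[["multi_gene"]]
  mg_j <- NULL
  if (!is.na(n_mg) && n_mg > 0L) {
    plus_genes <- models$genes[models$genes$strand == "+", , drop = FALSE]
    plus_genes <- plus_genes[order(plus_genes$start), , drop = FALSE]
    if (nrow(plus_genes) < n_mg + 1L) {
      .stopf("need %d plus-strand genes for multi-gene artifacts, have %d",
             n_mg + 1L, nrow(plus_genes))
    }
    mg <- list()
    for (i in seq_len(n_mg)) {
      ga <- plus_genes$gene_id[i]; gb <- plus_genes$gene_id[i + 1L]
      ea <- models$exons[models$exons$gene_id == ga, , drop = FALSE]
      ea <- ea[order(ea$start), , drop = FALSE]
      eb <- models$exons[models$exons$gene_id == gb, , drop = FALSE]
      eb <- eb[order(eb$start), , drop = FALSE]
      mg[[i]] <- data.frame(
        gene_id = NA_character_, contig = ea$contig[1L],
        start = ea$start[2L], end = eb$end[nrow(eb) - 1L], strand = "+",
        stringsAsFactors = FALSE)
    }
    mg_j <- do.call(rbind, mg)
  }
  slot_j <- sim$artifact_slots

  junctions <- rbind(
    cbind(true_j[, c("contig", "start", "end", "strand")],
          category = "true_circ"),
    if (nrow(low_j)) cbind(low_j[, c("contig", "start", "end", "strand")],
                           category = "low_support"),
    if (!is.null(mg_j)) cbind(mg_j[, c("contig", "start", "end", "strand")],
                              category = "multi_gene"),
    if (nrow(slot_j)) slot_j[, c("contig", "start", "end", "strand",
                                 "category")]
  )
  if (anyDuplicated(circ_id(junctions$contig, junctions$start,
                            junctions$end, junctions$strand))) {
    .stopf("planted junctions collide; change the seed or layout")
  }

  # distinct read counts per junction x sample
  n_j <- nrow(junctions)
  distinct <- matrix(0L, n_j, config$n_samples,
                     dimnames = list(NULL, samples))
  dup <- matrix(0L, n_j, config$n_samples, dimnames = list(NULL, samples))
  for (i in seq_len(n_j)) {
    cat_i <- junctions$category[i]
    if (cat_i == "low_support") {
      distinct[i, 1L] <- 1L
    } else if (cat_i == "true_circ") {
      distinct[i, ] <- .runif_int(config$n_samples, config$circ_reads)
      dup[i, ] <- stats::rbinom(config$n_samples, distinct[i, ],
                                config$duplicate_rate)
    } else {
      distinct[i, ] <- .runif_int(config$n_samples, c(2L, 4L))
    }
  }

  # chimeric records
  seg <- config$seg_len
  cig <- sprintf("%dM", seg)
  rec <- vector("list", n_j * config$n_samples)
  ridx <- 0L
  read_no <- 0L
  for (i in seq_len(n_j)) {
    plus <- junctions$strand[i] == "+"
    donor_site <- if (plus) junctions$end[i] else junctions$start[i] - 1L
    acceptor_site <- if (plus) junctions$start[i] - 1L else junctions$end[i]
    for (s in seq_along(samples)) {
      d <- distinct[i, s]
      if (d == 0L) next
      k <- seq_len(d) - 1L
      seg1 <- pmax(0L, junctions$end[i] - seg - k)
      seg2 <- junctions$start[i] + k
      n_dup <- dup[i, s]
      idx <- c(seq_len(d), rep(1L, n_dup))  # duplicates copy the first read
      read_no <- read_no + length(idx)
      ridx <- ridx + 1L
      rec[[ridx]] <- data.frame(
        read_id = sprintf("R%07d", read_no - length(idx) + seq_along(idx)),
        contig = junctions$contig[i],
        contig_acceptor = junctions$contig[i],
        strand = junctions$strand[i],
        donor_site = donor_site, acceptor_site = acceptor_site,
        strand_acceptor = junctions$strand[i],
        motif_code = 1L,
        seg1_pos = seg1[idx], seg1_cigar = cig,
        seg2_pos = seg2[idx], seg2_cigar = cig,
        sample_id = samples[s], cross_contig = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  chimeric <- do.call(rbind, rec[seq_len(ridx)])

  # linear SJ records for every annotated intron, per sample
  introns <- list()
  for (t in seq_len(nrow(models$transcripts))) {
    txid <- models$transcripts$transcript_id[t]
    e <- models$exons[models$exons$transcript_id == txid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    introns[[t]] <- data.frame(
      contig = e$contig[1L], intron_start = e$end[-nrow(e)],
      intron_end = e$start[-1L], strand = e$strand[1L],
      stringsAsFactors = FALSE)
  }
  introns <- do.call(rbind, introns)
  lin <- list()
  lin_counts <- matrix(0L, nrow(introns), config$n_samples,
                       dimnames = list(NULL, samples))
  for (s in seq_along(samples)) {
    u <- .runif_int(nrow(introns), config$linear_reads)
    lin_counts[, s] <- u
    lin[[s]] <- data.frame(
      contig = introns$contig, intron_start = introns$intron_start,
      intron_end = introns$intron_end, strand = introns$strand,
      motif_code = 1L, annotated_flag = TRUE, unique_reads = u,
      multi_reads = 0L, sample_id = samples[s], stringsAsFactors = FALSE)
  }
  linear <- do.call(rbind, lin)

  # truth table with planted counts, linear support and expected fate
  truth <- junctions
  truth$name <- circ_id(truth$contig, truth$start, truth$end, truth$strand)
  truth$expected_fate <- c(true_circ = "pass",
                           long_span = "reject_span",
                           non_canonical_motif = "reject_motif",
                           multi_gene = "reject_multi_gene",
                           low_support = "reject_support")[truth$category]
  for (s in seq_along(samples)) {
    truth[[paste0("planted_distinct.", samples[s])]] <- distinct[, s]
    truth[[paste0("planted_all.", samples[s])]] <- distinct[, s] + dup[, s]
    left <- vapply(seq_len(n_j), function(i) {
      sum(lin_counts[introns$intron_end == truth$start[i] &
                       introns$contig == truth$contig[i], s])
    }, numeric(1L))
    right <- vapply(seq_len(n_j), function(i) {
      sum(lin_counts[introns$intron_start == truth$end[i] &
                       introns$contig == truth$contig[i], s])
    }, numeric(1L))
    truth[[paste0("planted_linear.", samples[s])]] <- (left + right) / 2
  }

  # caller-style candidate sets: both callers report the true circRNAs
  total_distinct <- rowSums(distinct)
  is_true <- junctions$category == "true_circ"
  finder_A <- data.frame(
    contig = junctions$contig[is_true], start = junctions$start[is_true],
    end = junctions$end[is_true], strand = junctions$strand[is_true],
    provenance = "finder_A", reported_count = total_distinct[is_true],
    stringsAsFactors = FALSE)
  finder_B <- finder_A
  finder_B$provenance <- "finder_B"

  list(chimeric = .reset_rownames(chimeric),
       linear = .reset_rownames(linear),
       libraries = libraries,
       finder_A = .reset_rownames(finder_A),
       finder_B = .reset_rownames(finder_B),
       truth = .reset_rownames(truth))
}

#' Compare a filtered catalog against the simulator truth table
#'
#' Exact-coordinate matching: precision = TP/(TP+FP), recall = TP/(TP+FN)
#' where positives are truth entries with expected fate `"pass"`.
#'
#' @param catalog filtered catalog (`contig`, `start`, `end`, `strand`)
#' @param truth truth table from [plant_circ_evidence()]
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn` and
#'   `per_category` confusion counts
#' @export
evaluate_against_truth <- function(catalog, truth) {
  got <- circ_id(catalog$contig, catalog$start, catalog$end, catalog$strand)
  want <- truth$name[truth$expected_fate == "pass"]
  tp <- sum(got %in% want)
  fp <- sum(!got %in% want)
  fn <- sum(!want %in% got)
  per_cat <- do.call(rbind, lapply(split(truth, truth$category), function(tr) {
    data.frame(category = tr$category[1L],
               planted = nrow(tr),
               in_catalog = sum(tr$name %in% got),
               stringsAsFactors = FALSE)
  }))
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn,
       per_category = .reset_rownames(per_cat))
}

#' Write simulator output as pipeline input files
#'
#' Serializes the simulated world into the external dialects the readers
#' accept: genome FASTA, annotation GTF, per-sample 14-column chimeric
#' tables and SJ tables, caller-style BED6+/BED12+ candidate files, a truth
#' TSV and a library-size TSV.
#'
#' @param sim a `circ_simulation`
#' @param evidence output of [plant_circ_evidence()]
#' @param dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_sim_fixtures <- function(sim, evidence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             truth = file.path(dir, "truth.tsv"),
             libraries = file.path(dir, "libraries.tsv"),
             finder_A = file.path(dir, "finder_A.bed"),
             finder_B = file.path(dir, "finder_B.txt"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(
    setNames(as.character(sim$genome), names(sim$genome))), paths[["fasta"]])
  write_gtf(sim$models, paths[["gtf"]])
  write.table(evidence$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(evidence$libraries, paths[["libraries"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  fa <- evidence$finder_A
  writeLines(sprintf("%s\t%d\t%d\tcirc_%d\t%g\t%s\tCIRCULAR",
                     fa$contig, fa$start, fa$end, seq_len(nrow(fa)),
                     fa$reported_count, fa$strand), paths[["finder_A"]])
  fb <- evidence$finder_B
  writeLines(sprintf(
    "%s\t%d\t%d\tcirc_%d\t0\t%s\t%d\t%d\t0,0,0\t1\t%d\t0\t%g",
    fb$contig, fb$start, fb$end, seq_len(nrow(fb)), fb$strand,
    fb$start, fb$end, fb$end - fb$start, fb$reported_count),
    paths[["finder_B"]])
  for (s in unique(evidence$libraries$sample_id)) {
    ch <- evidence$chimeric[evidence$chimeric$sample_id == s, , drop = FALSE]
    p <- file.path(dir, sprintf("%s.chimeric.junction", s))
    writeLines(sprintf(
      "%s\t%d\t%s\t%s\t%d\t%s\t%d\t-1\t-1\t%s\t%d\t%s\t%d\t%s",
      ch$contig, ch$donor_site + 1L, ch$strand, ch$contig_acceptor,
      ch$acceptor_site + 1L, ch$strand_acceptor, ch$motif_code, ch$read_id,
      ch$seg1_pos + 1L, ch$seg1_cigar, ch$seg2_pos + 1L, ch$seg2_cigar), p)
    paths[[paste0("chimeric.", s)]] <- p
    lj <- evidence$linear[evidence$linear$sample_id == s, , drop = FALSE]
    p2 <- file.path(dir, sprintf("%s.SJ.out.tab", s))
    code <- c("+" = 1L, "-" = 2L, "*" = 0L)[lj$strand]
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                       lj$contig, lj$intron_start + 1L, lj$intron_end,
                       code, lj$motif_code, as.integer(lj$annotated_flag),
                       lj$unique_reads, lj$multi_reads, 20L), p2)
    paths[[paste0("sj.", s)]] <- p2
  }
  invisible(paths)
}
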