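# Shared fixtures and independent oracles, all built in code at test time.

# one chimeric record row with overridable fields
make_chim <- function(read_id = "r1", contig = "chrT", strand = "+",
                      donor_site = 2000L, acceptor_site = 999L,
                      contig_acceptor = contig, strand_acceptor = strand,
                      motif_code = 1L, seg1_pos = 1950L,
                      seg1_cigar = "35M", seg2_pos = 1000L,
                      seg2_cigar = "35M", sample_id = "S1",
                      cross_contig = contig != contig_acceptor) {
  data.frame(read_id = read_id, contig = contig,
             contig_acceptor = contig_acceptor, strand = strand,
             donor_site = donor_site, acceptor_site = acceptor_site,
             strand_acceptor = strand_acceptor, motif_code = motif_code,
             seg1_pos = seg1_pos, seg1_cigar = seg1_cigar,
             seg2_pos = seg2_pos, seg2_cigar = seg2_cigar,
             sample_id = sample_id, cross_contig = cross_contig,
             stringsAsFactors = FALSE)
}

make_linear <- function(contig = "chrT", intron_start = 0L,
                        intron_end = 100L, strand = "+", unique_reads = 1L,
                        multi_reads = 0L, sample_id = "S1") {
  data.frame(contig = contig, intron_start = intron_start,
             intron_end = intron_end, strand = strand, motif_code = 1L,
             annotated_flag = TRUE, unique_reads = unique_reads,
             multi_reads = multi_reads, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

make_libs <- function(samples = "S1", condition = "normoxia",
                      library_size = 1e6) {
  data.frame(sample_id = samples,
             condition = rep_len(condition, length(samples)),
             library_size = rep_len(library_size, length(samples)),
             stringsAsFactors = FALSE)
}

# gene A on + with a canonical 5-exon transcript and a non-canonical
# exon-skipping variant; overlapping genes B/C; distant gene D
toy_models_basic <- function() {
  tx <- data.frame(
    transcript_id = c("TXA1", "TXA2", "TXB1", "TXC1", "TXD1"),
    gene_id = c("GA", "GA", "GB", "GC", "GD"),
    gene_name = c("GA", "GA", "GB", "GC", "GD"),
    contig = "chrT", strand = c("+", "+", "+", "+", "+"),
    support_level = 1L,
    canonical = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    cds_start = c(320L, 320L, NA, NA, NA),
    cds_end = c(780L, 780L, NA, NA, NA),
    stringsAsFactors = FALSE)
  exA1 <- data.frame(transcript_id = "TXA1", contig = "chrT",
                     start = c(100L, 300L, 500L, 700L, 900L),
                     end = c(200L, 400L, 600L, 800L, 1000L),
                     strand = "+", stringsAsFactors = FALSE)
  exA2 <- data.frame(transcript_id = "TXA2", contig = "chrT",
                     start = c(100L, 300L, 700L, 900L),
                     end = c(200L, 400L, 800L, 1000L),
                     strand = "+", stringsAsFactors = FALSE)
  exB <- data.frame(transcript_id = "TXB1", contig = "chrT",
                    start = c(2000L, 2200L, 2400L),
                    end = c(2100L, 2300L, 2500L),
                    strand = "+", stringsAsFactors = FALSE)
  exC <- data.frame(transcript_id = "TXC1", contig = "chrT",
                    start = c(2450L, 2700L), end = c(2550L, 2800L),
                    strand = "+", stringsAsFactors = FALSE)
  exD <- data.frame(transcript_id = "TXD1", contig = "chrT",
                    start = c(5000L, 5400L), end = c(5200L, 5600L),
                    strand = "+", stringsAsFactors = FALSE)
  transcript_models(tx, rbind(exA1, exA2, exB, exC, exD))
}

# three single-transcript genes with 3, 4 and 6 exons (for rank spectra)
toy_models_ranks <- function() {
  mk <- function(txid, gid, n_ex, offset) {
    starts <- offset + (seq_len(n_ex) - 1L) * 300L
    data.frame(transcript_id = txid, contig = "chrT",
               start = starts, end = starts + 150L, strand = "+",
               stringsAsFactors = FALSE)
  }
  tx <- data.frame(
    transcript_id = c("TR1", "TR2", "TR3"),
    gene_id = c("g1", "g2", "g3"), gene_name = c("g1", "g2", "g3"),
    contig = "chrT", strand = "+", support_level = 1L, canonical = TRUE,
    cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE)
  transcript_models(tx, rbind(mk("TR1", "g1", 3L, 1000L),
                              mk("TR2", "g2", 4L, 4000L),
                              mk("TR3", "g3", 6L, 8000L)))
}

# random genome with a deterministic seed; returns a character string
random_seq <- function(len, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent local-alignment oracle: Gotoh affine-gap Smith-Waterman with
# full traceback; gap of length L costs gap_open + L * gap_ext (matching
# the convention of the implementation under test)
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap_open = 10,
                      gap_ext = 4) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (horizontal)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_ext,
                               X[i, j + 1L] - gap_ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_ext,
                               Y[i + 1L, j] - gap_ext)
    }
  }
  score <- max(M)
  best <- which(M == score, arr.ind = TRUE)[1L, ]
  i <- best[1L]; j <- best[2L]
  state <- "M"
  len <- 0L; nmatch <- 0L
  eq <- function(x, y) abs(x - y) < 1e-9
  repeat {
    if (state == "M") {
      if (eq(M[i, j], 0)) break  # local alignment start
      is_match <- av[i - 1L] == bv[j - 1L]
      s <- if (is_match) match else mismatch
      if (is_match) nmatch <- nmatch + 1L
      len <- len + 1L
      prev <- M[i, j] - s
      cand <- c(M = M[i - 1L, j - 1L], X = X[i - 1L, j - 1L],
                Y = Y[i - 1L, j - 1L])
      hit <- names(cand)[eq(cand, prev)]
      state <- if (length(hit)) hit[1L] else "M"
      i <- i - 1L; j <- j - 1L
    } else if (state == "X") {
      len <- len + 1L
      state <- if (eq(X[i, j], M[i - 1L, j] - gap_open - gap_ext)) "M"
               else "X"
      i <- i - 1L
    } else {
      len <- len + 1L
      state <- if (eq(Y[i, j], M[i, j - 1L] - gap_open - gap_ext)) "M"
               else "Y"
      j <- j - 1L
    }
  }
  list(score = score, length = len,
       identity = if (len > 0) 100 * nmatch / len else NA_real_)
}

revcomp_str <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}
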