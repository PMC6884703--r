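# Duplicate flagging, recounting and abundance metrics.

test_that("duplicate flagging is positional, per sample, and idempotent", {
  rec <- rbind(
    make_chim(read_id = "r1", seg1_pos = 100L, seg2_pos = 500L),
    make_chim(read_id = "r2", seg1_pos = 100L, seg2_pos = 500L),
    make_chim(read_id = "r3", seg1_pos = 120L, seg2_pos = 500L),
    # same coordinates in another sample: not a duplicate there
    make_chim(read_id = "r4", seg1_pos = 100L, seg2_pos = 500L,
              sample_id = "S2")
  )
  fl <- flag_duplicates(rec)
  expect_equal(fl$is_duplicate, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(flag_duplicates(fl)$is_duplicate, fl$is_duplicate)
})

test_that("recounting matches a brute-force nested-loop oracle with duplicates", {
  set.seed(7)
  n_rec <- 1000L
  n_junc <- 100L
  juncs <- data.frame(
    contig = "chrT",
    start = 1000L + 100L * seq_len(n_junc),
    strand = rep(c("+", "-"), length.out = n_junc),
    stringsAsFactors = FALSE)
  juncs$end <- juncs$start + 5000L
  pick <- sample.int(n_junc, n_rec, replace = TRUE)
  samples <- sample(c("S1", "S2"), n_rec, replace = TRUE)
  seg1 <- sample.int(50L, n_rec, replace = TRUE)  # few values => duplicates
  rec <- do.call(rbind, lapply(seq_len(n_rec), function(i) {
    j <- juncs[pick[i], ]
    d <- if (j$strand == "+") j$end else j$start - 1L
    a <- if (j$strand == "+") j$start - 1L else j$end
    make_chim(read_id = paste0("r", i), strand = j$strand,
              strand_acceptor = j$strand, donor_site = d, acceptor_site = a,
              seg1_pos = j$start + seg1[i], seg2_pos = j$start + 7L,
              sample_id = samples[i])
  }))
  libs <- make_libs(c("S1", "S2"))
  counted <- count_backsplice(juncs, rec, libs)
  for (s in c("S1", "S2")) {
    for (k in seq_len(n_junc)) {
      hit <- pick == k & samples == s
      expect_identical(counted[[paste0("all_reads.", s)]][k],
                       sum(hit))
      expect_identical(counted[[paste0("distinct_reads.", s)]][k],
                       length(unique(seg1[hit])))
    }
  }
  dall <- as.matrix(counted[, grep("^all_reads", names(counted))])
  ddis <- as.matrix(counted[, grep("^distinct_reads", names(counted))])
  expect_true(all(ddis <= dall))
})

test_that("junctions with no evidence keep zero counts and unknown samples error", {
  juncs <- data.frame(contig = "chrT", start = 10L, end = 500L,
                      strand = "+", stringsAsFactors = FALSE)
  counted <- count_backsplice(juncs, make_chim()[0, ], make_libs("S1"))
  expect_equal(counted$all_reads.S1, 0L)
  expect_error(count_backsplice(juncs, make_chim(sample_id = "SX"),
                                make_libs("S1")), "SX")
})

test_that("rpm follows the per-million formula and is scale invariant", {
  expect_equal(rpm(50, 1e7), 5.0)
  expect_equal(rpm(0, 1e7), 0.0)
  set.seed(3)
  k <- sample.int(1000L, 20L); L <- sample(1e6:1e7, 20L)
  expect_equal(rpm(2 * k, 2 * L), rpm(k, L))
  expect_error(rpm(1, 0), "library size")
})

test_that("linear support sums per splice site and averages the two sides", {
  jx <- data.frame(contig = "chrT", start = 1000L, end = 2000L,
                   strand = "+", stringsAsFactors = FALSE)
  lin <- rbind(
    make_linear(intron_start = 500L, intron_end = 1000L, unique_reads = 8L),
    make_linear(intron_start = 2000L, intron_end = 2600L, unique_reads = 4L)
  )
  expect_equal(linear_support(jx, lin), 6.0)
  expect_equal(linear_support(jx, lin[0, ]), 0.0)
  # two alternative linear partners sharing the donor site: 3 + 2, acceptor 5
  lin2 <- rbind(
    make_linear(intron_start = 500L, intron_end = 1000L, unique_reads = 5L),
    make_linear(intron_start = 2000L, intron_end = 2600L, unique_reads = 3L),
    make_linear(intron_start = 2000L, intron_end = 3000L, unique_reads = 2L)
  )
  expect_equal(linear_support(jx, lin2), 5.0)
})

test_that("CLR and percent circularized follow their formulas exactly", {
  expect_equal(clr(10, 4), 2.0)
  expect_equal(clr(0, 100), 0.0)
  expect_equal(clr(7, 0), 7.0)
  expect_equal(percent_circularized(5, 5), 50.0)
  expect_equal(percent_circularized(9, 1), 90.0)
  expect_equal(percent_circularized(0, 12), 0.0)
  expect_true(is.na(percent_circularized(0, 0)))
})

test_that("metric identities hold over random count pairs", {
  set.seed(17)
  b <- sample(0:500, 2000L, replace = TRUE)
  l <- sample(0:500, 2000L, replace = TRUE)
  pc <- percent_circularized(b, l)
  expect_true(all(pc >= 0 & pc <= 100, na.rm = TRUE))
  expect_equal(clr(b, l), b / (l + 1))
  pos <- l > 0
  clr_raw <- b[pos] / l[pos]
  expect_equal(pc[pos], 100 * clr_raw / (1 + clr_raw), tolerance = 1e-9)
})

test_that("CLR shift compares condition means with degenerate markers", {
  m <- rbind(c(1, 1, 2, 2), c(0.5, 0.5, 0.5, 0.5), c(0, 0, 0.5, 0.5),
             c(0, 0, 0, 0))
  colnames(m) <- paste0("S", 1:4)
  libs <- make_libs(paste0("S", 1:4),
                    condition = c("normoxia", "normoxia",
                                  "hypoxia", "hypoxia"))
  fc <- clr_shift(m, libs, "normoxia", "hypoxia")
  expect_equal(fc, c(2, 1, Inf, 1))
  expect_error(clr_shift(m, libs, "normoxia", "anoxia"), "condition")
})

test_that("host TPM normalizes to 1e6 and honors internal-exon exclusion", {
  models <- toy_models_ranks()
  ex <- models$exons
  counts <- data.frame(gene_id = ex$gene_id, contig = ex$contig,
                       start = ex$start, end = ex$end,
                       stringsAsFactors = FALSE)
  # single gene: whatever the counts, TPM is 1e6
  one <- counts[counts$gene_id == "g1", ]
  one$S1 <- c(10L, 20L, 5L)
  t1 <- host_tpm(one, models)
  expect_equal(t1$tpm.S1, 1e6)
  # two genes, equal counts over equal lengths: an even split
  two <- counts[counts$gene_id %in% c("g1", "g2"), ]
  two$S1 <- ifelse(two$gene_id == "g1", 10L, 10L)
  two <- two[c(1:3, 4:6), ]  # 3 exons each (drop g2 4th)
  t2 <- host_tpm(two, models)
  expect_equal(t2$tpm.S1, c(5e5, 5e5))
  # three genes with one internal exon: spreadsheet recomputation
  three <- counts
  three$S1 <- seq_len(nrow(three)) * 10L
  internal <- three[three$gene_id == "g2", ][2L, c("contig", "start", "end")]
  t3 <- host_tpm(three, models, internal_exons = internal)
  sel <- !(paste(three$contig, three$start) %in%
             paste(internal$contig, internal$start))
  cnt <- tapply(three$S1[sel], three$gene_id[sel], sum)
  len <- tapply((three$end - three$start)[sel], three$gene_id[sel], sum)
  rate <- as.numeric(cnt / (len / 1000))
  expect_equal(t3$tpm.S1, rate / sum(rate) * 1e6)
  expect_equal(sum(t3$tpm.S1), 1e6, tolerance = 1e-6)
})

test_that("TPM columns sum to 1e6 on randomized fixtures", {
  set.seed(23)
  models <- toy_models_ranks()
  ex <- models$exons
  for (it in 1:5) {
    counts <- data.frame(gene_id = ex$gene_id, contig = ex$contig,
                         start = ex$start, end = ex$end,
                         A = sample(0:100, nrow(ex), replace = TRUE),
                         B = sample(0:100, nrow(ex), replace = TRUE),
                         stringsAsFactors = FALSE)
    internal <- counts[sample(nrow(counts), 2L), c("contig", "start", "end")]
    tt <- host_tpm(counts, models, internal_exons = internal)
    expect_equal(sum(tt$tpm.A), 1e6, tolerance = 1e-6)
    expect_equal(sum(tt$tpm.B), 1e6, tolerance = 1e-6)
  }
})

test_that("unknown exons in the count table are rejected", {
  models <- toy_models_ranks()
  counts <- data.frame(gene_id = "gX", contig = "chrT", start = 1L,
                       end = 100L, S1 = 5L, stringsAsFactors = FALSE)
  expect_error(host_tpm(counts, models), "absent from models")
})
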