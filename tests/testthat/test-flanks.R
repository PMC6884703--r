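# Flanking repeats, inverted complementarity, crosslink merging,
# metaprofiles.

test_that("repeat pair orientation distinguishes inverted, same and none", {
  catalog <- data.frame(contig = "chrT", start = 2000L, end = 5000L,
                        strand = "+", stringsAsFactors = FALSE)
  mk_rep <- function(start, end, strand) {
    data.frame(contig = "chrT", start = start, end = end, strand = strand,
               repeat_name = "AluSx", repeat_family = "SINE/Alu",
               stringsAsFactors = FALSE)
  }
  inv <- repeat_pair_orientation(catalog,
                                 rbind(mk_rep(1600L, 1900L, "+"),
                                       mk_rep(5100L, 5400L, "-")))
  expect_equal(inv$repeat_orientation, "inverted")
  same <- repeat_pair_orientation(catalog,
                                  rbind(mk_rep(1600L, 1900L, "+"),
                                        mk_rep(5100L, 5400L, "+")))
  expect_equal(same$repeat_orientation, "same")
  none <- repeat_pair_orientation(catalog, mk_rep(1600L, 1900L, "+"))
  expect_equal(none$repeat_orientation, "none")
  expect_true(none$repeat_left)
  expect_false(none$repeat_right)
  # non-family repeats are ignored
  l1 <- repeat_pair_orientation(catalog, within(mk_rep(1600L, 1900L, "+"), {
    repeat_name <- "L1MA"; repeat_family <- "LINE/L1"
  }))
  expect_equal(l1$repeat_orientation, "none")
})

test_that("planted inverted repeats are detected at the stated thresholds", {
  # windows are poly-A around the planted repeat so the local alignment
  # cannot extend past it (poly-A aligns against poly-T after reverse
  # complementation); junction [1500,2500): windows [1000,1500), [2500,3000)
  planted_genome <- function(frag) {
    pad <- function(n) strrep("A", n)
    paste0(random_seq(1000L, seed = 13),
           pad(200L), frag, pad(300L - nchar(frag)),
           random_seq(1000L, seed = 14),
           pad(200L), revcomp_str(frag), pad(300L - nchar(frag)),
           random_seq(1000L, seed = 15))
  }
  catalog <- data.frame(contig = "c", start = 1500L, end = 2500L,
                        strand = "+", stringsAsFactors = FALSE)
  frag50 <- random_seq(50L, seed = 99)
  hit <- inverted_complementarity(catalog,
                                  as_genome(c(c = planted_genome(frag50))))
  expect_gte(hit$aln_length, 50L)
  expect_equal(hit$aln_identity, 100)
  expect_true(hit$complementary)

  frag39 <- random_seq(39L, seed = 98)
  miss <- inverted_complementarity(catalog,
                                   as_genome(c(c = planted_genome(frag39))))
  expect_false(miss$complementary)
  expect_equal(miss$aln_identity, 100)
  expect_lt(miss$aln_length, 40L)
})

test_that("random windows stay below thresholds; oracle agrees with the score", {
  # independent random flanks: the Gotoh oracle recomputes the best local
  # alignment of upstream vs reverse-complemented downstream window
  g <- as_genome(c(c = random_seq(1000L, seed = 77)))
  catalog <- data.frame(contig = "c", start = 300L, end = 600L,
                        strand = "+", stringsAsFactors = FALSE)
  res <- inverted_complementarity(catalog, g, window = 120L)
  up <- genome_subseq(g, "c", 180L, 300L)
  down <- genome_subseq(g, "c", 600L, 720L)
  oracle <- sw_oracle(up, revcomp_str(down))
  expect_equal(res$aln_score, oracle$score)
  expect_equal(res$aln_length, oracle$length)
  expect_equal(res$aln_identity, oracle$identity, tolerance = 1e-6)
  expect_false(res$complementary)
})

test_that("alignment score is symmetric under window swap with complementation", {
  g <- as_genome(c(c = random_seq(1200L, seed = 55)))
  catalog <- data.frame(contig = "c", start = 400L, end = 800L,
                        strand = "+", stringsAsFactors = FALSE)
  a <- inverted_complementarity(catalog, g, window = 150L)
  # swap: align downstream window against revcomp(upstream window)
  up <- genome_subseq(g, "c", 250L, 400L)
  down <- genome_subseq(g, "c", 800L, 950L)
  sw1 <- sw_oracle(up, revcomp_str(down))
  sw2 <- sw_oracle(down, revcomp_str(up))
  expect_equal(sw1$score, sw2$score)
  expect_equal(a$aln_score, sw1$score)
})

test_that("short windows after truncation give an undefined marker", {
  g <- as_genome(c(c = random_seq(600L, seed = 5)))
  catalog <- data.frame(contig = "c", start = 5L, end = 595L,
                        strand = "+", stringsAsFactors = FALSE)
  expect_warning(res <- inverted_complementarity(catalog, g, window = 100L),
                 "truncated")
  expect_true(is.na(res$aln_length))
  expect_true(is.na(res$complementary) || res$complementary == FALSE)
})

test_that("crosslink sites merge at gap <= 8 nt, transitively", {
  mk <- function(pos) data.frame(contig = "c", pos = pos, strand = "+",
                                 score = 1, stringsAsFactors = FALSE)
  m1 <- merge_crosslink_sites(mk(c(10L, 17L)))
  expect_equal(nrow(m1), 1L)
  m2 <- merge_crosslink_sites(mk(c(10L, 19L)))
  expect_equal(nrow(m2), 2L)
  m3 <- merge_crosslink_sites(mk(c(10L, 17L, 24L)))
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$start, 10L)
  expect_equal(m3$end, 25L)
  # strand separation, order independence, idempotence on representation
  sites <- rbind(mk(c(40L, 35L, 100L)),
                 within(mk(38L), strand <- "-"))
  a <- merge_crosslink_sites(sites)
  b <- merge_crosslink_sites(sites[sample(nrow(sites)), ])
  expect_identical(a, b)
  expect_equal(nrow(a), 3L)
})

test_that("metaprofile places signal at the expected relative positions", {
  jx <- data.frame(contig = "c", start = 1000L, end = 2000L, strand = "+",
                   stringsAsFactors = FALSE)
  # one signal unit 5 nt into the upstream intron of the acceptor
  sites <- data.frame(contig = "c", pos = 995L, strand = "+", score = 1,
                      stringsAsFactors = FALSE)
  prof <- signal_metaprofile(jx, sites, intron_window = 50L,
                             exon_window = 10L)
  expect_equal(prof$acceptor$mean_coverage[prof$acceptor$rel_pos == -5L], 1)
  expect_equal(sum(prof$acceptor$mean_coverage), 1)
  expect_equal(sum(prof$donor$mean_coverage), 0)

  # two junctions with signal at the same relative offset average to 1
  jx2 <- rbind(jx, data.frame(contig = "c", start = 5000L, end = 6000L,
                              strand = "+", stringsAsFactors = FALSE))
  sites2 <- rbind(sites, data.frame(contig = "c", pos = 4995L,
                                    strand = "+", score = 1,
                                    stringsAsFactors = FALSE))
  prof2 <- signal_metaprofile(jx2, sites2, intron_window = 50L,
                              exon_window = 10L)
  expect_equal(prof2$acceptor$mean_coverage[prof2$acceptor$rel_pos == -5L],
               1)
  expect_error(signal_metaprofile(jx[0, ], sites), "empty")
})

test_that("metaprofile respects strand orientation and shift equivariance", {
  jxm <- data.frame(contig = "c", start = 1000L, end = 2000L, strand = "-",
                    stringsAsFactors = FALSE)
  # on the minus strand the acceptor-side intron lies right of `end`
  sites <- data.frame(contig = "c", pos = 2004L, strand = "-", score = 2,
                      stringsAsFactors = FALSE)
  prof <- signal_metaprofile(jxm, sites, intron_window = 50L,
                             exon_window = 10L)
  expect_equal(prof$acceptor$mean_coverage[prof$acceptor$rel_pos == -5L], 2)
  # shifting all signal positions by +k shifts plus-strand profiles by +k
  jx <- data.frame(contig = "c", start = 1000L, end = 2000L, strand = "+",
                   stringsAsFactors = FALSE)
  s0 <- data.frame(contig = "c", pos = 990L, strand = "+", score = 1,
                   stringsAsFactors = FALSE)
  p0 <- signal_metaprofile(jx, s0, 50L, 10L)
  s1 <- transform(s0, pos = pos + 3L)
  p1 <- signal_metaprofile(jx, s1, 50L, 10L)
  expect_equal(p1$acceptor$mean_coverage[p1$acceptor$rel_pos == -7L],
               p0$acceptor$mean_coverage[p0$acceptor$rel_pos == -10L])
})

test_that("metaprofile conservation identity holds exactly on integers", {
  set.seed(61)
  jx <- data.frame(contig = "c",
                   start = c(1000L, 3000L, 7000L),
                   end = c(2000L, 4000L, 8000L),
                   strand = c("+", "-", "+"),
                   stringsAsFactors = FALSE)
  sites <- data.frame(contig = "c",
                      pos = sample(500L:8500L, 200L),
                      strand = sample(c("+", "-"), 200L, replace = TRUE),
                      score = sample(1:5, 200L, replace = TRUE),
                      stringsAsFactors = FALSE)
  iw <- 100L; ew <- 20L
  prof <- signal_metaprofile(jx, sites, iw, ew)
  # oracle: total signal inside each junction's windows, summed per side
  total_side <- function(side) {
    tot <- 0
    for (i in seq_len(nrow(jx))) {
      plus <- jx$strand[i] == "+"
      if (side == "acceptor") {
        rng <- if (plus) (jx$start[i] - iw):(jx$start[i] + ew - 1L)
               else (jx$end[i] - ew):(jx$end[i] + iw - 1L)
      } else {
        rng <- if (plus) (jx$end[i] - ew):(jx$end[i] + iw - 1L)
               else (jx$start[i] - iw):(jx$start[i] + ew - 1L)
      }
      sel <- sites$pos %in% rng & sites$strand == jx$strand[i] &
        sites$contig == jx$contig[i]
      tot <- tot + sum(sites$score[sel])
    }
    tot
  }
  expect_equal(sum(prof$acceptor$mean_coverage) * nrow(jx),
               total_side("acceptor"))
  expect_equal(sum(prof$donor$mean_coverage) * nrow(jx),
               total_side("donor"))
})
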