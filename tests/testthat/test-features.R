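test_that("peak counting matches a quadratic brute-force counter", {
  regions <- gr("chr1", c(0, 100, 300), c(100, 200, 500))
  peaks <- gr("chr1", c(10, 40, 60, 95, 350), c(20, 50, 70, 105, 400))
  expect_equal(count_peak_overlaps(regions, peaks), c(4L, 1L, 1L))
  ## the peak at [95,105) straddles two adjacent regions and counts in both
  set.seed(14)
  for (rep in 1:5) {
    rg <- gr("chr1", s <- sample(0:5000, 30), s + sample(20:400, 30, TRUE))
    pk <- gr("chr1", s2 <- sample(0:5400, 80), s2 + sample(5:50, 80, TRUE))
    brute <- vapply(seq_along(rg), function(i) sum(vapply(seq_along(pk),
      function(j) GenomicRanges::start(pk)[j] <= GenomicRanges::end(rg)[i] &&
        GenomicRanges::end(pk)[j] >= GenomicRanges::start(rg)[i],
      logical(1))), integer(1))
    expect_equal(count_peak_overlaps(rg, pk), brute)
  }
})

test_that("signal aggregation is exact, additive and rejects overlapping tracks", {
  region <- gr("chr1", 100, 200)
  track <- grw("chr1", c(0, 150), c(150, 400), c(2, 2))
  expect_equal(aggregate_signal(region, track, "sum"), 200)
  expect_equal(aggregate_signal(region, track, "mean"), 2)
  ## splitting a region at any interior point: sums add to the whole
  set.seed(4)
  track2 <- grw("chr1", seq(0, 900, 100), seq(100, 1000, 100), runif(10, 0, 5))
  whole <- aggregate_signal(gr("chr1", 37, 913), track2, "sum")
  for (cut in c(38, 100, 500, 912)) {
    parts <- aggregate_signal(gr("chr1", c(37, cut), c(cut, 913)), track2, "sum")
    expect_equal(sum(parts), whole)
  }
  ## per-base accumulation oracle
  vals <- rep(0, 1000)
  for (i in seq_along(track2))
    vals[seq(GenomicRanges::start(track2)[i], GenomicRanges::end(track2)[i])] <-
      track2$value[i]
  for (rep in 1:10) {
    a <- sample(0:900, 1); b <- a + sample(10:99, 1)
    expect_equal(aggregate_signal(gr("chr1", a, b), track2, "sum"),
                 sum(vals[(a + 1):b]), tolerance = 1e-9)
  }
  bad <- grw("chr1", c(0, 50), c(100, 150), c(1, 1))
  expect_error(aggregate_signal(region, bad), "overlap")
})

test_that("conservation averages over scored bases only", {
  region <- gr("chr1", 0, 100)
  expect_equal(as.numeric(mean_conservation(region, grw("chr1", 0, 100, 0.5))),
               0.5)
  ## half scored at 1.0, half unscored: scored-base denominator gives 1.0
  half <- grw("chr1", 0, 50, 1)
  expect_equal(as.numeric(mean_conservation(region, half)), 1)
  none <- mean_conservation(region, grw("chr1", 500, 600, 0.7))
  expect_equal(as.numeric(none), 0)
  expect_true(attr(none, "no_score"))
  expect_error(mean_conservation(region, grw("chr1", 0, 10, 1.4)), "\\[0, 1\\]")
  ## per-base oracle on a patchy track
  set.seed(6)
  st <- seq(0, 900, 100); keep <- sample(c(TRUE, FALSE), 10, TRUE)
  tr <- grw("chr1", st[keep], st[keep] + 60, round(runif(sum(keep)), 3))
  vals <- rep(NA_real_, 1000)
  for (i in seq_along(tr))
    vals[seq(GenomicRanges::start(tr)[i], GenomicRanges::end(tr)[i])] <- tr$value[i]
  for (rep in 1:10) {
    a <- sample(0:800, 1); b <- a + sample(20:150, 1)
    v <- vals[(a + 1):b]
    want <- if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    expect_equal(as.numeric(mean_conservation(gr("chr1", a, b), tr)), want)
  }
})

test_that("bedGraph I/O round-trips and rejects malformed records", {
  f <- withr::local_tempfile()
  tr <- grw("chr1", c(0, 200), c(100, 300), c(1.5, 2.25))
  write_bedgraph(tr, f)
  tr2 <- read_bedgraph(f)
  expect_equal(GenomicRanges::start(tr), GenomicRanges::start(tr2))
  expect_equal(tr$value, tr2$value)
  writeLines(c("chr1\t0\t100\t1.0", "chr1\t200\t100\t1.0"), f)
  expect_error(read_bedgraph(f), "line 2")
})

test_that("reference thresholds follow the linear-interpolation quantile rule", {
  ref <- data.frame(x = c(1, 2, 3, 4))
  th <- reference_thresholds(ref, list(x = list(statistic = "median",
                                                transform = "identity")))
  expect_equal(unname(th), 2.5)
  expect_equal(unname(reference_thresholds(ref, list(x = list(
    statistic = "q3", transform = "identity")))), 3.25)
  expect_equal(unname(reference_thresholds(ref, list(x = list(
    statistic = "mean", transform = "identity")))), 2.5)
  ## p95 of 100 equally spaced values starting at 0, step 0.01
  ref2 <- data.frame(x = seq(0, 0.99, by = 0.01))
  expect_equal(unname(reference_thresholds(ref2, list(x = list(
    statistic = "p95", transform = "identity")))), 0.9405)
  ## constant reference: every statistic equals the constant
  ref3 <- data.frame(x = rep(7, 12))
  for (s in c("median", "mean", "q3", "p95"))
    expect_equal(unname(reference_thresholds(ref3, list(x = list(
      statistic = s, transform = "identity")))), 7)
  ## log2p1 transform applies before the statistic
  expect_equal(unname(reference_thresholds(ref, list(x = list(
    statistic = "mean", transform = "log2p1")))), mean(log2(ref$x + 1)))
  expect_error(reference_thresholds(ref[0, , drop = FALSE],
                                    list(x = list(statistic = "mean",
                                                  transform = "identity"))),
               "empty reference")
})

make_test_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("motif scanning finds planted consensus sites strand-symmetrically", {
  motif <- "TGACGTCA"
  pfm <- matrix(5, 4, 8, dimnames = list(c("A", "C", "G", "T")))
  for (j in 1:8) pfm[substr(motif, j, j), j] <- 85
  set.seed(8)
  bg <- crossreg:::random_dna(500)
  ## plant 5 copies at well-separated offsets
  at <- c(50, 150, 250, 350, 450)
  for (a in at) substr(bg, a, a + 7) <- motif
  genome <- make_test_genome(c(chr1 = bg))
  region <- gr("chr1", 0, 500)
  n <- scan_tfbs(region, genome, list(M = pfm))
  expect_gte(n, 5)
  ## reverse complementing the sequence leaves the count unchanged
  genome_rc <- make_test_genome(c(chr1 = crossreg:::revcomp_chr(bg)))
  expect_equal(scan_tfbs(region, genome_rc, list(M = pfm)), n)
  ## hit counts are monotone non-increasing in the threshold
  counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99), function(t)
    scan_tfbs(region, genome, list(M = pfm), rel_threshold = t), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(scan_tfbs(gr("chr1", 0, 600), genome, list(M = pfm)),
               "outside genome")
})

test_that("motif scanning agrees with Biostrings matchPWM on planted sites", {
  motif <- "GCCACGTG"
  pfm <- matrix(1, 4, 8, dimnames = list(c("A", "C", "G", "T")))
  for (j in 1:8) pfm[substr(motif, j, j), j] <- 97
  set.seed(15)
  bg <- crossreg:::random_dna(2000)
  at <- sort(sample(seq(20, 1970, by = 30), 6))
  for (a in at) substr(bg, a, a + 7) <- motif
  genome <- make_test_genome(c(chr1 = bg))
  ours <- scan_tfbs(gr("chr1", 0, 2000), genome, list(M = pfm),
                    rel_threshold = 0.9)
  prob <- sweep(pfm, 2, colSums(pfm), "/")
  fwd <- Biostrings::matchPWM(prob, Biostrings::DNAString(bg), min.score = "90%")
  rev <- Biostrings::matchPWM(Biostrings::reverseComplement(prob),
                              Biostrings::DNAString(bg), min.score = "90%")
  expect_equal(ours, length(fwd) + length(rev))
})

test_that("featurize assembles the per-region feature table", {
  fx <- small_fixture()
  ud <- merge_datasets(list(mapped = gr(
    fx$manifest$t_chrom[!is.na(fx$manifest$t_start)],
    fx$manifest$t_start[!is.na(fx$manifest$t_start)],
    fx$manifest$t_end[!is.na(fx$manifest$t_start)],
    names = make.unique(fx$manifest$name[!is.na(fx$manifest$t_start)]))))
  ft <- featurize(ud, cage = fx$cage, h3k27ac = fx$h3k27ac,
                  rnaseq = fx$rnaseq, conservation = fx$conservation,
                  genome = fx$target_seq, pwms = fx$pwms)
  expect_equal(nrow(ft), length(ud))
  expect_true(all(ft$phastcons >= 0 & ft$phastcons <= 1))
  expect_true(all(ft$cage_count >= 0))
  ## active regions carry visibly more signal than inactive ones
  man <- fx$manifest[!is.na(fx$manifest$t_start), ]
  act <- GenomicRanges::reduce(gr(man$t_chrom[man$active], man$t_start[man$active],
                                  man$t_end[man$active]))
  is_active <- GenomicRanges::countOverlaps(ud, act) > 0
  expect_gt(median(ft$h3k27ac_signal[is_active] / ft$length[is_active]),
            5 * median(ft$h3k27ac_signal[!is_active] / ft$length[!is_active]))
})
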