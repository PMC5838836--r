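test_that("gapped k-mer feature extraction follows the combinatorial closed form", {
  ## a sequence shorter than l yields nothing
  expect_length(extract_gkm_features("ACGTACGTA", l = 10, k = 6)$idx, 0)
  ## single window, l=4, k=2: exactly choose(4,2)=6 features
  f <- extract_gkm_features("ACGT", l = 4, k = 2, collapse_rc = FALSE)
  expect_equal(sum(f$counts), 6)
  ## total feature mass of an N-free sequence is (L-l+1) * choose(l,k)
  set.seed(2)
  for (rep in 1:5) {
    L <- sample(15:60, 1)
    s <- crossreg:::random_dna(L)
    f <- extract_gkm_features(s, l = 10, k = 6)
    expect_equal(sum(f$counts), (L - 10 + 1) * choose(10, 6))
  }
  ## windows containing N are skipped: 25-mer with N at position 13 keeps
  ## only the 3 leftmost and 3 rightmost of its 16 windows
  s <- paste0(strrep("A", 12), "N", strrep("C", 12))
  f <- extract_gkm_features(s, l = 10, k = 6)
  expect_equal(sum(f$counts), 6 * choose(10, 6))
  expect_error(extract_gkm_features("ACGT", l = 2, k = 3), "l must be >= k")
})

test_that("reverse-complement collapsing maps a motif and its RC to one feature set", {
  s <- "TGACGTCATG"
  f1 <- extract_gkm_features(s, 10, 6)
  f2 <- extract_gkm_features(crossreg:::revcomp_chr(s), 10, 6)
  expect_equal(f1$idx, f2$idx)
  expect_equal(f1$counts, f2$counts)
  ## without collapsing the feature sets differ
  g1 <- extract_gkm_features(s, 10, 6, collapse_rc = FALSE)
  g2 <- extract_gkm_features(crossreg:::revcomp_chr(s), 10, 6,
                             collapse_rc = FALSE)
  expect_false(identical(g1$idx, g2$idx))
})

test_that("training-set negatives are length-matched, seeded and avoid positives", {
  fx <- small_fixture()
  pos <- fx$regions[fx$regions$class == "enhancer"][1:10]
  ts1 <- make_training_set(pos, fx$source_seq, seed = 3)
  ts2 <- make_training_set(pos, fx$source_seq, seed = 3)
  ts3 <- make_training_set(pos, fx$source_seq, seed = 4)
  expect_identical(ts1$neg_seqs, ts2$neg_seqs)
  expect_false(identical(ts1$neg_seqs, ts3$neg_seqs))
  expect_equal(sort(nchar(ts1$neg_seqs)), sort(nchar(ts1$pos_seqs)))
  expect_equal(sum(GenomicRanges::countOverlaps(ts1$neg_regions, pos)), 0)
  ## a genome with no room errors out
  tiny <- Biostrings::DNAStringSet(c(chrZ = "ACGT"))
  expect_error(make_training_set(pos, tiny), "too small")
})

test_that("negative GC content tracks the genome background", {
  ## uniform-random fixture genome: GC of sampled negatives should be
  ## indistinguishable from GC of independent random windows
  set.seed(3)
  genome <- Biostrings::DNAStringSet(c(chr1 = crossreg:::random_dna(200000)))
  w <- 150
  starts <- sample.int(200000 - w, 500)
  pos <- gr("chr1", starts[1:250], starts[1:250] + w)
  ts <- make_training_set(pos, genome, n_neg_per_pos = 2, seed = 3)
  gc <- function(s) vapply(strsplit(s, ""), function(x)
    mean(x %in% c("G", "C")), numeric(1))
  bgw <- vapply(starts[251:500], function(a) as.character(
    Biostrings::subseq(genome[[1]], a + 1, a + w)), character(1))
  ks <- suppressWarnings(stats::ks.test(gc(ts$neg_seqs), gc(bgw)))
  expect_gt(ks$p.value, 0.01)
})

test_that("training is deterministic and recovers a planted motif", {
  sim <- simulate_motif_sequences(60, 60, len = 80, seed = 11)
  m1 <- train_gkm(pos_seqs = sim$pos_seqs, neg_seqs = sim$neg_seqs, seed = 11)
  m2 <- train_gkm(pos_seqs = sim$pos_seqs, neg_seqs = sim$neg_seqs, seed = 11)
  expect_identical(m1$alpha, m2$alpha)
  expect_identical(lmer_weights(m1, c("TGACGTCATG", "ACGTACGTAC")),
                   lmer_weights(m2, c("TGACGTCATG", "ACGTACGTAC")))
  expect_gt(m1$cv_auc, 0.9)
  ## motif-embedding l-mers rank far above random l-mers
  set.seed(1)
  rand_lmers <- vapply(1:1000, function(i) crossreg:::random_dna(10),
                       character(1))
  motif_lmers <- c("TGACGTCATG", "ATGACGTCAT", "CTGACGTCAG")
  wr <- lmer_weights(m1, rand_lmers)
  wm <- lmer_weights(m1, motif_lmers)
  expect_true(all(wm > quantile(wr, 0.99)))
  ## degenerate input errors
  expect_error(train_gkm(pos_seqs = sim$pos_seqs, neg_seqs = character(0)),
               "single-class")
  expect_error(train_gkm(pos_seqs = sim$pos_seqs[1:5],
                         neg_seqs = sim$neg_seqs[1:5]), "at least 20")
})

test_that("shuffled labels destroy classification", {
  sim <- simulate_motif_sequences(60, 60, len = 80, seed = 11)
  set.seed(11)
  all_seqs <- sample(c(sim$pos_seqs, sim$neg_seqs))
  m <- train_gkm(pos_seqs = all_seqs[1:60], neg_seqs = all_seqs[61:120],
                 seed = 11)
  expect_gt(m$cv_auc, 0.35)
  expect_lt(m$cv_auc, 0.65)
})

test_that("delta scores are zero on identity and antisymmetric for SNVs", {
  sim <- simulate_motif_sequences(30, 30, len = 60, seed = 5)
  m <- train_gkm(pos_seqs = sim$pos_seqs, neg_seqs = sim$neg_seqs, seed = 5)
  set.seed(6)
  for (rep in 1:10) {
    ctx <- crossreg:::random_dna(19)
    ref <- substr(ctx, 10, 10)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    expect_identical(delta_svm(ctx, ref, ref, m), 0)
    d <- delta_svm(ctx, ref, alt, m)
    ctx_alt <- ctx; substr(ctx_alt, 10, 10) <- alt
    expect_equal(delta_svm(ctx_alt, alt, ref, m), -d, tolerance = 1e-10)
    ## RC invariance: the same variant read on the other strand
    d_rc <- delta_svm(crossreg:::revcomp_chr(ctx),
                      crossreg:::revcomp_chr(ref),
                      crossreg:::revcomp_chr(alt), m)
    expect_equal(d_rc, d, tolerance = 1e-10)
  }
  expect_error(delta_svm("ACGT", "G", "T", m), "length")
  expect_error(delta_svm(crossreg:::random_dna(19), "X", "A", m))
})

test_that("indel deltas use all windows intersecting the edited span", {
  sim <- simulate_motif_sequences(30, 30, len = 60, seed = 5)
  m <- train_gkm(pos_seqs = sim$pos_seqs, neg_seqs = sim$neg_seqs, seed = 5)
  set.seed(7)
  ctx <- crossreg:::random_dna(2 * 9 + 3)     # 3-base reference allele
  ref <- substr(ctx, 10, 12)
  d <- delta_svm(ctx, ref, substr(ref, 1, 1), m)   # 3 bp -> 1 bp contraction
  ## equals the direct window-sum difference
  alt_seq <- paste0(substr(ctx, 1, 9), substr(ref, 1, 1), substr(ctx, 13, 21))
  want <- score_sequences(m, alt_seq) - score_sequences(m, ctx)
  expect_equal(d, want)
})

test_that("motif-disrupting variants score negative, restoring ones positive", {
  sim <- simulate_motif_sequences(60, 60, len = 80, seed = 11)
  m <- train_gkm(pos_seqs = sim$pos_seqs, neg_seqs = sim$neg_seqs, seed = 11)
  motif <- "TGACGTCA"
  set.seed(12)
  for (rep in 1:5) {
    ctx <- crossreg:::random_dna(19)
    substr(ctx, 7, 14) <- motif     # motif covers the centre (position 10)
    ref <- substr(ctx, 10, 10)      # consensus base 'C' (motif position 4)
    alt <- "A"
    d_dis <- delta_svm(ctx, ref, alt, m)
    expect_lt(d_dis, 0)
    ctx_broken <- ctx; substr(ctx_broken, 10, 10) <- alt
    expect_gt(delta_svm(ctx_broken, alt, ref, m), 0)
  }
})

test_that("score percentiles flag the tails of the distribution", {
  set.seed(5)
  dist <- rnorm(100000)
  med <- score_percentile(median(dist), dist)
  expect_false(med$significant)
  low <- score_percentile(min(dist) - 1, dist)
  expect_true(low$significant)
  expect_equal(low$percentile, 0)
  ## two-sided flag rate on a standard-normal sample is 5%
  flags <- score_percentile(dist[1:20000], dist)$significant
  expect_gt(mean(flags), 0.047); expect_lt(mean(flags), 0.053)
  ## the flagged scores are exactly those beyond +/-1.96 (up to quantile noise)
  qs <- quantile(dist, c(0.025, 0.975))
  expect_equal(unname(qs), c(-1.96, 1.96), tolerance = 0.02)
  ## one-sided |score| reading
  one <- score_percentile(c(0, 3), dist, two_sided = FALSE)
  expect_equal(one$significant, c(FALSE, TRUE))
})
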