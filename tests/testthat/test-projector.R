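## A chain with a known internal structure: 100 bp chromosome, one chain
## whose blocks cover bases [0,25) only within [0,100).
partial_chain <- function() {
  crossreg:::new_chain(1, 100, "chr1", 200, 0, 100, "chrA", 200, "+", 0, 25,
                       cbind(size = 25, dt = 75, dq = 0))
}

test_that("coverage thresholds gate mapping as specified", {
  cs <- chain_set(list(partial_chain()))
  ## 25 of 100 bases aligned: coverage 0.25
  pr <- project_interval("chr1", 0, 100, cs, min_match = 0.2)
  expect_equal(pr$status, "mapped")
  expect_equal(pr$coverage, 0.25)
  pr <- project_interval("chr1", 0, 100, cs, min_match = 0.55)
  expect_equal(pr$status, "unmapped")
  ## fully inside one aligned block: coverage 1, length preserved
  cs2 <- chain_set(list(crossreg:::identity_chain(1, "chr1", 1000)))
  pr <- project_interval("chr1", 100, 200, cs2, 0.2)
  expect_equal(pr$coverage, 1)
  expect_equal(pr$t_end - pr$t_start, 100)
  expect_error(project_interval("chrX", 0, 10, cs2), "unknown chromosome")
  expect_error(project_interval("chr1", 5, 5, cs2), "zero-length")
})

test_that("two passing chains are ambiguous unless multiple mapping is on", {
  cs <- chain_set(list(
    crossreg:::identity_chain(1, "chr1", 1000, t_chrom = "chrA"),
    crossreg:::new_chain(2, 50, "chr1", 1000, 0, 1000, "chrB", 1000, "+",
                         0, 1000, cbind(size = 1000, dt = 0, dq = 0))))
  one <- project_interval("chr1", 10, 60, cs, 0.2, allow_multiple = FALSE)
  expect_equal(one$status, "ambiguous")
  multi <- project_interval("chr1", 10, 60, cs, 0.2, allow_multiple = TRUE)
  expect_equal(nrow(multi), 2)
  ## deterministic order: equal coverage, so score decides
  expect_equal(multi$chain_id, c(1, 2))
})

test_that("projection matches the per-base oracle on random chains", {
  set.seed(11)
  for (rep in 1:30) {
    ch <- random_chain(rep)
    cs <- chain_set(list(ch))
    for (j in 1:5) {
      w <- sample(5:200, 1)
      start <- sample.int(10000 - w, 1) - 1
      want <- oracle_project(ch, start, start + w)
      got <- project_interval("chr1", start, start + w, cs, min_match = 1e-9)
      if (want$cov == 0) {
        expect_equal(got$status, "unmapped")
      } else {
        expect_equal(got$coverage, want$cov)
        expect_equal(got$t_start, want$t_start)
        expect_equal(got$t_end, want$t_end)
      }
    }
  }
})

test_that("mapped sets are nested across the minMatch threshold sweep", {
  fx <- small_fixture()
  thresholds <- c(0.1, 0.2, 0.3, 0.4, 0.55, 0.7, 0.8, 0.9, 0.95)
  df <- crossreg:::as_region_df(fx$regions)
  mapped_at <- lapply(thresholds, function(t) {
    ok <- vapply(seq_len(nrow(df)), function(i) {
      project_interval(df$chrom[i], df$start[i], df$end[i], fx$fwd,
                       min_match = t)$status == "mapped"
    }, logical(1))
    df$name[ok]
  })
  for (i in seq_along(thresholds)[-1])
    expect_true(all(mapped_at[[i]] %in% mapped_at[[i - 1]]))
})

test_that("reciprocal check enforces the 25-bp border tolerance", {
  size <- 10000
  cs <- chain_set(list(crossreg:::identity_chain(1, "chr1", size)))
  params <- projection_params()
  pr <- project_interval("chr1", 500, 700, cs, 0.2)
  ## identity chains: accepted, borders exact
  ok <- reciprocal_check(list(chrom = "chr1", start = 500, end = 700), pr,
                         invert_chains(cs), params)
  expect_true(ok$accepted)
  ## reverse chain with a planted 30-bp shift: back-projection lands 30 bp
  ## away -> rejected; a 20-bp shift is within tolerance
  shifted_rev <- function(shift) {
    chain_set(list(crossreg:::new_chain(
      1, 100, "chr1", size, 0, size - shift, "chr1", size, "+",
      shift, size, cbind(size = size - shift, dt = 0, dq = 0))))
  }
  bad <- reciprocal_check(list(chrom = "chr1", start = 500, end = 700), pr,
                          shifted_rev(30), params)
  expect_false(bad$accepted)
  expect_equal(bad$reason, "boundary_tolerance")
  ok2 <- reciprocal_check(list(chrom = "chr1", start = 500, end = 700), pr,
                          shifted_rev(20), params)
  expect_true(ok2$accepted)
  ## duplicated back-projection -> not_unique
  dup_rev <- chain_set(list(
    crossreg:::identity_chain(1, "chr1", size),
    crossreg:::new_chain(2, 90, "chr1", size, 0, size, "chr2", size, "+",
                         0, size, cbind(size = size, dt = 0, dq = 0))))
  amb <- reciprocal_check(list(chrom = "chr1", start = 500, end = 700), pr,
                          dup_rev, params)
  expect_false(amb$accepted)
  expect_equal(amb$reason, "not_unique")
})

test_that("two-stage mapping recovers planted orthologs and rescues duplicates", {
  fx <- small_fixture()
  m <- hprs_map(fx$regions, fx$fwd, fx$rev)
  man <- fx$manifest
  ## every non-deleted region is recovered
  non_del <- unique(man$name[man$expected_stage != "unmapped"])
  got <- m$results[m$results$status == "mapped", ]
  expect_true(all(non_del %in% got$name))
  ## deleted regions stay unmapped
  del <- unique(man$name[man$expected_stage == "unmapped"])
  expect_true(all(m$results$status[m$results$name %in% del] == "unmapped"))
  ## stage assignment matches the ground truth; coordinates exact
  for (nm in non_del) {
    want <- man[man$name == nm, ]
    have <- got[got$name == nm, ]
    expect_equal(sort(unique(have$stage)),
                 sort(unique(want$expected_stage)), info = nm)
    expect_setequal(paste(have$t_chrom, have$t_start, have$t_end),
                    paste(want$t_chrom, want$t_start, want$t_end))
  }
  ## rescue hits all satisfy the stringent threshold; stages are disjoint
  expect_true(all(got$coverage[got$stage == "rescue"] >= 0.8))
  expect_length(intersect(got$name[got$stage == "primary"],
                          got$name[got$stage == "rescue"]), 0)
})

test_that("round trip through fwd and rev chains restores block-contained intervals", {
  fx <- small_fixture()
  df <- crossreg:::as_region_df(fx$regions)
  man <- fx$manifest
  primary <- df[df$name %in% man$name[man$expected_stage == "primary"], ]
  for (i in seq_len(min(nrow(primary), 20))) {
    r <- primary[i, ]
    fwd <- project_interval(r$chrom, r$start, r$end, fx$fwd, 0.2)
    back <- project_interval(fwd$t_chrom, fwd$t_start, fwd$t_end, fx$rev, 0.2)
    expect_equal(back$t_chrom, r$chrom)
    expect_equal(back$t_start, r$start)
    expect_equal(back$t_end, r$end)
  }
})

test_that("anchor pairs are projected jointly and inversions flip one strand", {
  fx <- small_fixture()
  man <- fx$manifest
  plus <- man[man$expected_stage == "primary" & man$strand == "+", ][1, ]
  minus <- man[man$expected_stage == "primary" & man$strand == "-", ][1, ]
  gone <- man[man$expected_stage == "unmapped", ][1, ]
  pairs <- data.frame(
    chrom_a = c(plus$chrom, plus$chrom),
    start_a = c(plus$start, plus$start), end_a = c(plus$end, plus$end),
    chrom_b = c(minus$chrom, gone$chrom),
    start_b = c(minus$start, gone$start), end_b = c(minus$end, gone$end),
    name = c("inv_pair", "lost_pair"))
  res <- project_pairs(pairs, fx$fwd, fx$rev)
  expect_equal(res$pairs$name, "inv_pair")
  expect_equal(res$dropped, 2L)
  expect_equal(res$pairs$strand_a, "+")
  expect_equal(res$pairs$strand_b, "-")
  expect_equal(res$pairs$start_b, minus$t_start)
})
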