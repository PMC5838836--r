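## Shared oracles and builders.  The oracles recompute quantities by
## explicit per-base / quadratic enumeration, independently of the
## package's interval arithmetic.

## Enumerate every aligned (source, forward-target) base pair of a chain by
## walking its raw blocks with an explicit loop.
oracle_base_map <- function(ch) {
  b <- ch$blocks
  s <- ch$s_start; q <- ch$t_start
  src <- list(); tgt <- list()
  for (i in seq_len(nrow(b))) {
    off <- seq_len(b[i, "size"]) - 1
    src[[i]] <- s + off
    qq <- q + off
    tgt[[i]] <- if (ch$t_strand == "+") qq else ch$t_size - 1 - qq
    s <- s + b[i, "size"] + b[i, "dt"]
    q <- q + b[i, "size"] + b[i, "dq"]
  }
  data.frame(src = unlist(src), tgt = unlist(tgt))
}

## Brute-force projection of [start, end) through one chain.
oracle_project <- function(ch, start, end) {
  m <- oracle_base_map(ch)
  m <- m[m$src >= start & m$src < end, ]
  if (!nrow(m)) return(list(cov = 0))
  first <- m$tgt[which.min(m$src)]
  last <- m$tgt[which.max(m$src)]
  list(cov = nrow(m) / (end - start),
       t_start = min(first, last), t_end = max(first, last) + 1)
}

## Random multi-block chain on a given source chromosome.
random_chain <- function(id, s_chrom = "chr1", s_size = 10000,
                         t_chrom = "chrA", t_size = 12000,
                         n_blocks = sample(1:6, 1),
                         strand = sample(c("+", "-"), 1)) {
  sizes <- sample(5:60, n_blocks, replace = TRUE)
  dt <- c(sample(0:40, n_blocks - 1, replace = TRUE), 0)
  dq <- c(sample(0:40, n_blocks - 1, replace = TRUE), 0)
  s_span <- sum(sizes + dt); q_span <- sum(sizes + dq)
  s_start <- sample.int(s_size - s_span, 1) - 1
  q_start <- sample.int(t_size - q_span, 1) - 1
  crossreg:::new_chain(id, 100, s_chrom, s_size, s_start, s_start + s_span,
                       t_chrom, t_size, strand, q_start, q_start + q_span,
                       cbind(size = sizes, dt = dt, dq = dq))
}

## Small cached fixture reused across test files (expensive to build).
small_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) {
      fx <<- generate_fixture(fixture_config(
        seed = 42, chrom_sizes = c(chr1 = 2e5, chr2 = 2e5),
        n_promoters = 15, n_enhancers = 25, n_tfbs = 10,
        n_snp_neutral = 60, n_snp_disrupting = 8))
    }
    fx
  }
})

gr <- function(chrom, start, end, names = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (!is.null(names)) names(g) <- names
  g
}

grw <- function(chrom, start, end, value) {
  g <- gr(chrom, start, end)
  S4Vectors::mcols(g)$value <- value
  g
}
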