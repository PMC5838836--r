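## Per-region feature computation: CAGE peak counts, signal aggregation
## over bedGraph tracks, conservation averaging, PWM motif-hit counting and
## reference-derived thresholds.

#' Read a 4-column bedGraph track
#'
#' @param path bedGraph path (optionally gzipped).
#' @return `GRanges` with a numeric `value` metadata column.
#' @export
read_bedgraph <- function(path) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "[ \t]+")
  if (any(lengths(fields) != 4))
    stop("expected 4 bedGraph fields at line ",
         lineno[which(lengths(fields) != 4)[1]])
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  value <- as.numeric(m[, 4])
  bad <- which(is.na(start) | is.na(end) | is.na(value) | start >= end)
  if (length(bad)) stop("malformed bedGraph record at line ", lineno[bad[1]])
  gr <- GenomicRanges::GRanges(m[, 1], IRanges::IRanges(start + 1, end))
  S4Vectors::mcols(gr)$value <- value
  gr
}

#' Write a GRanges with a value column as bedGraph
#' @param gr `GRanges` with `value` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(gr, path) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr <- gr[o]
  writeLines(paste(as.character(GenomicRanges::seqnames(gr)),
                   format(GenomicRanges::start(gr) - 1L, scientific = FALSE,
                          trim = TRUE),
                   format(GenomicRanges::end(gr), scientific = FALSE,
                          trim = TRUE),
                   format(S4Vectors::mcols(gr)$value, scientific = FALSE,
                          trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' Count peak overlaps per region
#'
#' A peak counts for a region when they share at least one base; a peak
#' spanning two regions counts in both.
#'
#' @param regions,peaks `GRanges`.
#' @return integer vector, one count per region.
#' @export
count_peak_overlaps <- function(regions, peaks) {
  GenomicRanges::countOverlaps(regions, peaks, ignore.strand = TRUE)
}

#' Aggregate a bedGraph signal over regions
#'
#' In `sum` mode each region receives the sum of `overlap length x value`
#' over track intervals; `mean` mode divides by the region length.  Bases
#' absent from the track contribute zero.  Overlapping track intervals are
#' an error.
#'
#' @param regions `GRanges`.
#' @param track `GRanges` with `value` column ([read_bedgraph()]).
#' @param mode `"sum"` or `"mean"`.
#' @return numeric vector per region.
#' @export
aggregate_signal <- function(regions, track, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (length(track) &&
      any(GenomicRanges::countOverlaps(track, track, ignore.strand = TRUE) > 1))
    stop("track intervals overlap")
  hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ovl <- pmin(GenomicRanges::end(regions)[q], GenomicRanges::end(track)[s]) -
    pmax(GenomicRanges::start(regions)[q], GenomicRanges::start(track)[s]) + 1
  contrib <- ovl * S4Vectors::mcols(track)$value[s]
  out <- rep(0, length(regions))
  if (length(q)) {
    agg <- tapply(contrib, q, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  if (mode == "mean") out <- out / GenomicRanges::width(regions)
  out
}

#' Mean per-base conservation over scored bases
#'
#' Averages a per-base score track (values in \[0, 1\]) over each region,
#' using only scored bases in the denominator; regions with no scored base
#' get 0 and are flagged.
#'
#' @param regions `GRanges`.
#' @param track per-base score `GRanges` with `value` in \[0, 1\].
#' @return numeric vector with attribute `no_score` (logical vector marking
#'   regions without any scored base).
#' @export
mean_conservation <- function(regions, track) {
  v <- S4Vectors::mcols(track)$value
  if (any(v < 0 | v > 1)) stop("conservation scores must lie in [0, 1]")
  if (length(track) &&
      any(GenomicRanges::countOverlaps(track, track, ignore.strand = TRUE) > 1))
    stop("track intervals overlap")
  hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ovl <- pmin(GenomicRanges::end(regions)[q], GenomicRanges::end(track)[s]) -
    pmax(GenomicRanges::start(regions)[q], GenomicRanges::start(track)[s]) + 1
  num <- rep(0, length(regions)); den <- rep(0, length(regions))
  if (length(q)) {
    a <- tapply(ovl * v[s], q, sum); d <- tapply(ovl, q, sum)
    num[as.integer(names(a))] <- as.numeric(a)
    den[as.integer(names(d))] <- as.numeric(d)
  }
  out <- ifelse(den > 0, num / den, 0)
  attr(out, "no_score") <- den == 0
  out
}

#' Read JASPAR-style position frequency matrices
#'
#' Accepts the common JASPAR text dialects: a `>ID NAME` header followed by
#' four rows, either `A [ 1 2 3 ]` style or bare numbers in A/C/G/T order.
#'
#' @param path PFM text file.
#' @return named list of 4 x w count matrices with rownames A, C, G, T.
#' @export
read_jaspar_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("no PWM headers ('>') found in ", path)
  pwms <- list()
  for (h in seq_along(hdr)) {
    from <- hdr[h] + 1
    to <- if (h < length(hdr)) hdr[h + 1] - 1 else length(lines)
    rows <- lines[from:to]
    if (length(rows) != 4) stop("PWM must have 4 rows: ", lines[hdr[h]])
    parse_row <- function(r) {
      r <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[?", "", r)
      r <- gsub("\\]", "", r)
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1]])
    }
    m <- do.call(rbind, lapply(rows, parse_row))
    rownames(m) <- c("A", "C", "G", "T")
    if (any(colSums(m) <= 0)) stop("PWM columns must sum to positive counts")
    id <- sub("^>\\s*", "", lines[hdr[h]])
    id <- strsplit(id, "[ \t]+")[[1]][1]
    pwms[[id]] <- m
  }
  pwms
}

## log2 odds matrix from a count PFM; eps avoids -Inf on zero counts.
pwm_log_odds <- function(pfm, background = rep(0.25, 4), eps = 1e-4) {
  p <- sweep(pfm, 2, colSums(pfm), "/")
  log2((p + eps) / (background + eps))
}

DNA_INT <- c(A = 0L, C = 1L, G = 2L, T = 3L)

seq_to_int <- function(s) {
  unname(DNA_INT[strsplit(toupper(s), "")[[1]]])
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Score all windows of an integer-encoded sequence against a log-odds
## matrix; returns numeric vector of window scores (NA where the window
## contains an ambiguous base).
pwm_window_scores <- function(si, lom) {
  w <- ncol(lom)
  n <- length(si) - w + 1
  if (n < 1) return(numeric(0))
  idx <- outer(seq_len(n), 0:(w - 1), "+")
  base <- matrix(si[idx], nrow = n)
  sc <- matrix(NA_real_, n, w)
  for (j in seq_len(w)) sc[, j] <- lom[base[, j] + 1L, j]
  rowSums(sc)
}

## Greedy collapse: keep best-scoring non-overlapping windows of width w.
collapse_hits <- function(starts, scores, w) {
  if (!length(starts)) return(integer(0))
  o <- order(-scores, starts)
  kept <- numeric(0)
  for (s in starts[o]) {
    if (!any(abs(kept - s) < w)) kept <- c(kept, s)
  }
  sort(kept)
}

#' Count motif hits per region by PWM scanning
#'
#' Every window on both strands is scored with summed log2 odds
#' (`log2((p + eps) / (bg + eps))`); a hit is a window scoring at least
#' `rel_threshold` times the maximum achievable score of that PWM.
#' Overlapping hits of one PWM on one strand collapse to the best-scoring
#' window.  The returned count totals hits over all PWMs and both strands.
#'
#' @param regions `GRanges`.
#' @param genome named `DNAStringSet` (or FASTA path).
#' @param pwms list of count PFMs ([read_jaspar_pwms()]).
#' @param rel_threshold fraction of the maximum achievable score (default
#'   0.8).
#' @param background base frequencies (A, C, G, T).
#' @param eps pseudo-frequency in the log-odds (default 1e-4).
#' @return integer vector of hit counts per region.
#' @export
scan_tfbs <- function(regions, genome, pwms, rel_threshold = 0.8,
                      background = rep(0.25, 4), eps = 1e-4) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom <- as.character(GenomicRanges::seqnames(regions))
  if (!all(chrom %in% names(genome)))
    stop("region chromosome missing from genome: ",
         setdiff(chrom, names(genome))[1])
  st <- GenomicRanges::start(regions); en <- GenomicRanges::end(regions)
  too_big <- which(en > Biostrings::width(genome)[match(chrom, names(genome))] |
                     st < 1)
  if (length(too_big)) stop("region outside genome bounds: ", too_big[1])
  loms <- lapply(pwms, pwm_log_odds, background = background, eps = eps)
  maxsc <- vapply(loms, function(m) sum(apply(m, 2, max)), numeric(1))
  counts <- integer(length(regions))
  for (i in seq_along(regions)) {
    s <- as.character(Biostrings::subseq(genome[[chrom[i]]], st[i], en[i]))
    for (strand_seq in c(s, revcomp_chr(s))) {
      si <- seq_to_int(strand_seq)
      for (p in seq_along(loms)) {
        w <- ncol(loms[[p]])
        sc <- pwm_window_scores(si, loms[[p]])
        hit <- which(!is.na(sc) & sc >= rel_threshold * maxsc[p])
        counts[i] <- counts[i] +
          length(collapse_hits(hit, sc[hit], w))
      }
    }
  }
  counts
}

#' Reference-derived feature thresholds
#'
#' Computes, for each feature, the requested statistic over the reference
#' region set's feature values.  Quantiles use linear interpolation between
#' order statistics; the `log2p1` transform applies `log2(x + 1)` before the
#' statistic.
#'
#' @param reference_features data.frame of feature values over the
#'   reference set.
#' @param specs named list; each element a list with `statistic` (one of
#'   `"median"`, `"mean"`, `"q3"`, `"p95"`) and `transform` (`"identity"`
#'   or `"log2p1"`).  Names select columns of `reference_features`.
#' @return named numeric vector of thresholds (on the transformed scale).
#' @export
reference_thresholds <- function(reference_features, specs) {
  if (!nrow(reference_features)) stop("empty reference set")
  vapply(names(specs), function(f) {
    spec <- specs[[f]]
    x <- reference_features[[f]]
    if (is.null(x)) stop("missing reference feature column: ", f)
    if (identical(spec$transform, "log2p1")) x <- log2(x + 1)
    switch(spec$statistic,
           median = unname(quantile(x, 0.5, type = 7)),
           mean = mean(x),
           q3 = unname(quantile(x, 0.75, type = 7)),
           p95 = unname(quantile(x, 0.95, type = 7)),
           stop("unknown statistic: ", spec$statistic))
  }, numeric(1))
}

#' Compute the full per-region feature table
#'
#' Convenience wrapper assembling the feature vector consumed by the filter
#' cascade: CAGE peak count, H3K27Ac and RNA-seq signal (summed by
#' default), mean conservation, annotation count, motif-hit count and an
#' optional gapped k-mer model score.
#'
#' @param regions `GRanges` (an `annotation_count` metadata column, e.g.
#'   from [merge_datasets()], is carried through; otherwise 1).
#' @param cage `GRanges` of CAGE peaks, or NULL.
#' @param h3k27ac,rnaseq,conservation bedGraph `GRanges`, or NULL.
#' @param genome,pwms for [scan_tfbs()], or NULL to skip.
#' @param model optional [train_gkm()] model used to score region sequences.
#' @param signal_mode `"sum"` (default) or `"mean"` for the signal tracks.
#' @return data.frame keyed by region name with the feature columns
#'   `cage_count`, `h3k27ac_signal`, `rnaseq_signal`, `phastcons`,
#'   `annotation_count`, `tfbs_count`, `svm_score`, `length`.
#' @export
featurize <- function(regions, cage = NULL, h3k27ac = NULL, rnaseq = NULL,
                      conservation = NULL, genome = NULL, pwms = NULL,
                      model = NULL, signal_mode = "sum") {
  n <- length(regions)
  nm <- names(regions)
  if (is.null(nm)) nm <- paste0("region_", seq_len(n))
  ann <- S4Vectors::mcols(regions)$annotation_count
  if (is.null(ann)) ann <- rep(1L, n)
  df <- data.frame(
    name = nm,
    length = GenomicRanges::width(regions),
    cage_count = if (is.null(cage)) rep(0L, n) else
      count_peak_overlaps(regions, cage),
    h3k27ac_signal = if (is.null(h3k27ac)) rep(0, n) else
      aggregate_signal(regions, h3k27ac, signal_mode),
    rnaseq_signal = if (is.null(rnaseq)) rep(0, n) else
      aggregate_signal(regions, rnaseq, signal_mode),
    phastcons = if (is.null(conservation)) rep(0, n) else
      as.numeric(mean_conservation(regions, conservation)),
    annotation_count = ann,
    tfbs_count = if (is.null(genome) || is.null(pwms)) rep(0L, n) else
      scan_tfbs(regions, genome, pwms),
    stringsAsFactors = FALSE)
  df$svm_score <- if (is.null(model) || is.null(genome)) NA_real_ else {
    g <- if (is.character(genome)) Biostrings::readDNAStringSet(genome)
         else genome
    names(g) <- sub("\\s.*", "", names(g))
    seqs <- vapply(seq_len(n), function(i)
      as.character(Biostrings::subseq(
        g[[as.character(GenomicRanges::seqnames(regions)[i])]],
        GenomicRanges::start(regions)[i], GenomicRanges::end(regions)[i])),
      character(1))
    score_sequences(model, seqs)
  }
  df
}
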