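## BED I/O, interval algebra, universal-dataset merging and overlap /
## SNP-set statistics.
##
## Region containers are GRanges (1-based closed, the Bioconductor
## convention); BED files and the projection layer use 0-based half-open
## coordinates, converted at the boundary.

#' Read a BED file as a GRanges
#'
#' BED3 to BED6 are accepted; missing names are auto-generated, the score
#' column (if present) is kept in `score`.  Malformed coordinates raise an
#' error naming the line.
#'
#' @param path BED file path (optionally gzipped).
#' @param source_dataset optional label stored in the `source_dataset`
#'   metadata column.
#' @return `GRanges` with names and metadata columns.
#' @export
read_bed <- function(path, source_dataset = NA_character_) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "[ \t]+")
  nfield <- lengths(fields)
  if (any(nfield < 3))
    stop("fewer than 3 BED fields at line ", lineno[which(nfield < 3)[1]])
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("non-integer coordinates at line ", lineno[bad[1]])
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", lineno[bad[1]])
  name <- ifelse(nfield >= 4, vapply(fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, character(1)),
    NA_character_)
  auto <- is.na(name) | name == "."
  name[auto] <- paste0("region_", which(keep)[auto])
  score <- ifelse(nfield >= 5, suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_,
           character(1)))), NA_real_)
  strand <- ifelse(nfield >= 6, vapply(fields, function(f)
    if (length(f) >= 6) f[6] else "*", character(1)), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1, end),
                               strand = strand)
  names(gr) <- name
  S4Vectors::mcols(gr)$score <- score
  S4Vectors::mcols(gr)$source_dataset <- source_dataset
  gr
}

#' Write a GRanges as BED
#'
#' Regions are written sorted by (chrom, start, end) as BED6 (or BED3/BED4
#' if names/scores are absent).  Coordinates are converted back to 0-based
#' half-open.
#'
#' @param gr `GRanges`.
#' @param path output path.
#' @param score optional numeric vector for the score column (defaults to
#'   the `score` metadata column, else 0).
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, score = NULL) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr <- gr[o]
  nm <- names(gr)
  if (is.null(nm)) nm <- paste0("region_", seq_along(gr))
  if (is.null(score)) score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- rep(0, length(gr))
  score[is.na(score)] <- 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 format(GenomicRanges::start(gr) - 1L, scientific = FALSE,
                        trim = TRUE),
                 format(GenomicRanges::end(gr), scientific = FALSE,
                        trim = TRUE),
                 nm, score, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Merge labelled datasets into non-overlapping regions
#'
#' Regions overlapping by at least one base, or book-ended (separated by at
#' most `merge_distance` bases, default 0), are unioned.  Contributing names
#' are collapsed comma-separated, prefixed with their dataset label, and
#' `annotation_count` records how many regions contributed.  The operation
#' is idempotent and independent of dataset order up to name ordering within
#' a merged region (names are sorted by position, then label).
#'
#' @param datasets named list of `GRanges` (the names are the dataset
#'   labels), or a single `GRanges`.
#' @param merge_distance maximum gap, in bases, across which regions are
#'   still unioned.
#' @return `GRanges` sorted and pairwise non-overlapping, with metadata
#'   columns `names` (comma-joined provenance) and `annotation_count`.
#' @export
merge_datasets <- function(datasets, merge_distance = 0) {
  if (is(datasets, "GRanges")) datasets <- list(dataset = datasets)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  tagged <- lapply(names(datasets), function(lab) {
    gr <- datasets[[lab]]
    nm <- names(gr)
    if (is.null(nm)) nm <- paste0("region_", seq_along(gr))
    GenomicRanges::strand(gr) <- "*"
    S4Vectors::mcols(gr) <- NULL
    names(gr) <- paste0(lab, ":", nm)
    gr
  })
  all <- do.call(c, tagged)
  merged <- GenomicRanges::reduce(all, min.gapwidth = merge_distance + 1L,
                                  ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(merged, all, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  o <- order(q, GenomicRanges::start(all)[s], names(all)[s])
  q <- q[o]; s <- s[o]
  nms <- vapply(split(names(all)[s], factor(q, levels = seq_along(merged))),
                function(x) paste(x, collapse = ","), character(1))
  S4Vectors::mcols(merged)$names <- unname(nms)
  S4Vectors::mcols(merged)$annotation_count <-
    tabulate(q, nbins = length(merged))
  names(merged) <- paste0("merged_", seq_along(merged))
  merged
}

#' Overlap statistics between a query and a reference region set
#'
#' Overlap means at least one shared base; percentages are reported to one
#' decimal.
#'
#' @param query,reference `GRanges`.
#' @param genome_size_mb total genome size in Mb (needed for `pct_genome`).
#' @return list with `n_query_hitting_ref`, `n_ref_covered`,
#'   `pct_ref_covered`, `query_total_mb` and `pct_genome`.
#' @export
overlap_stats <- function(query, reference, genome_size_mb = NA_real_) {
  if (length(reference) == 0) stop("empty reference set")
  nq <- sum(GenomicRanges::countOverlaps(query, reference,
                                         ignore.strand = TRUE) > 0)
  nr <- sum(GenomicRanges::countOverlaps(reference, query,
                                         ignore.strand = TRUE) > 0)
  qmb <- sum(GenomicRanges::width(GenomicRanges::reduce(
    query, ignore.strand = TRUE))) / 1e6
  list(n_query_hitting_ref = nq,
       n_ref_covered = nr,
       pct_ref_covered = round(100 * nr / length(reference), 1),
       query_total_mb = qmb,
       pct_genome = if (is.na(genome_size_mb)) NA_real_ else
         round(100 * qmb / genome_size_mb, 3))
}

#' Read a tab-separated SNP table
#'
#' Expected columns: chrom, pos (1-based), id, ref, alt, and optionally p
#' (association p-value).  Positions are converted to 0-based internally
#' (column `pos0`).
#'
#' @param path TSV path.
#' @return data.frame with columns `chrom`, `pos`, `pos0`, `id`, `ref`,
#'   `alt` and optionally `p`.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  df$pos0 <- df$pos - 1
  df
}

snp_granges <- function(snps) {
  GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, width = 1))
}

#' SNP-set enrichment across significance bins
#'
#' For each category (a region set selecting SNPs, or a logical index into
#' the table), samples `n_sample` member SNPs without replacement (seeded)
#' and counts those with -log10(p) at or above each bin threshold.
#' Categories smaller than `n_sample` are counted in full and scaled by
#' `n_sample / size`.
#'
#' @param snps data.frame from [read_snp_table()] with a `p` column in
#'   (0, 1].
#' @param categories named list; each element either a `GRanges` (SNPs
#'   falling in the regions form the category) or a logical/integer vector
#'   indexing rows of `snps`.
#' @param n_sample number of SNPs sampled per category.
#' @param seed RNG seed for the sampling.
#' @param bins -log10(p) thresholds (default 1..20).
#' @return matrix of (scaled) counts, categories x bins.
#' @export
snp_set_enrichment <- function(snps, categories, n_sample, seed = 1,
                               bins = 1:20) {
  if (is.null(snps$p) || any(snps$p <= 0 | snps$p > 1))
    stop("p-values must be in (0, 1]")
  gr <- snp_granges(snps)
  nlp <- -log10(snps$p)
  out <- matrix(0, length(categories), length(bins),
                dimnames = list(names(categories), paste0("bin", bins)))
  set.seed(seed)
  for (ci in seq_along(categories)) {
    cat_i <- categories[[ci]]
    idx <- if (is(cat_i, "GRanges")) {
      which(GenomicRanges::countOverlaps(gr, cat_i, ignore.strand = TRUE) > 0)
    } else if (is.logical(cat_i)) which(cat_i) else as.integer(cat_i)
    if (length(idx) == 0) stop("empty category: ", names(categories)[ci])
    if (length(idx) >= n_sample) {
      idx <- sample(idx, n_sample)
      scale <- 1
    } else {
      scale <- n_sample / length(idx)
    }
    v <- nlp[idx]
    out[ci, ] <- vapply(bins, function(b) sum(v >= b), numeric(1)) * scale
  }
  out
}
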