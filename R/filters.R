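## The species-specific filter cascade: seven predicates over the region
## feature table, combined as a union by default, with enhancer/promoter
## density ratios (count per Mb) as the enrichment criterion.

#' Default filter specifications
#'
#' One spec per filter layer.  Each carries the statistic used to resolve
#' its threshold from the reference set, the transform applied before
#' thresholding, and an `enabled` flag.  Defaults: CAGE (count rule plus a
#' raw-mean RNA-seq rescue), H3K27Ac at the median of `log2(x+1)` reference
#' signal, RNA-seq at the 3rd quartile, model score at the reference
#' median for regions shorter than 3000 bp, annotation count at the 3rd
#' quartile, conservation at the 95th percentile, motif count at the mean.
#'
#' @param enabled character vector of filters to enable (default all).
#' @return named list of filter specs.
#' @export
default_filter_specs <- function(enabled = c("CAGE", "H3K27Ac", "RNAseq",
                                             "SVM", "AnnCount", "PhastCons",
                                             "TFBScount")) {
  specs <- list(
    CAGE = list(statistic = "mean", transform = "identity",
                min_peaks = 2L, rescue_peaks = 1L),
    H3K27Ac = list(statistic = "median", transform = "log2p1"),
    RNAseq = list(statistic = "q3", transform = "log2p1"),
    SVM = list(statistic = "median", transform = "identity",
               max_length = 3000L),
    AnnCount = list(statistic = "q3", transform = "identity"),
    PhastCons = list(statistic = "p95", transform = "identity"),
    TFBScount = list(statistic = "mean", transform = "identity"))
  for (f in names(specs)) specs[[f]]$enabled <- f %in% enabled
  specs
}

filter_feature_column <- c(CAGE = "cage_count", H3K27Ac = "h3k27ac_signal",
                           RNAseq = "rnaseq_signal", SVM = "svm_score",
                           AnnCount = "annotation_count",
                           PhastCons = "phastcons", TFBScount = "tfbs_count")

## Resolve every enabled filter's threshold against the reference feature
## table; returns the spec list with `threshold` fields filled in.
resolve_filter_thresholds <- function(specs, reference_features) {
  for (f in names(specs)) {
    if (!specs[[f]]$enabled) next
    col <- filter_feature_column[[f]]
    if (is.null(reference_features[[col]]))
      stop("missing reference feature column for filter ", f, ": ", col)
    specs[[f]]$threshold <- reference_thresholds(
      reference_features,
      setNames(list(list(statistic = specs[[f]]$statistic,
                         transform = specs[[f]]$transform)), col))[[1]]
    if (f == "CAGE")
      specs[[f]]$rnaseq_mean <- mean(reference_features$rnaseq_signal)
  }
  specs
}

## Logical pass vector for one filter over the feature table.
filter_predicate <- function(fname, spec, features) {
  col <- filter_feature_column[[fname]]
  x <- features[[col]]
  if (is.null(x)) stop("missing feature column for filter ", fname, ": ", col)
  switch(fname,
    CAGE = features$cage_count >= spec$min_peaks |
      (features$cage_count == spec$rescue_peaks &
         features$rnaseq_signal > spec$rnaseq_mean),
    SVM = features$length < spec$max_length & !is.na(x) & x >= spec$threshold,
    {
      if (identical(spec$transform, "log2p1")) x <- log2(x + 1)
      !is.na(x) & x >= spec$threshold
    })
}

#' Apply the filter cascade to the universal dataset
#'
#' Resolves each enabled filter's threshold against the reference feature
#' table, evaluates every filter independently, and retains a region when
#' it passes at least one enabled filter (`combine = "union"`, the default)
#' or all of them (`"intersection"`).  The per-filter report gives each
#' filter's independent retention statistics; when reference enhancer /
#' promoter sets are supplied it includes density ratios via
#' [enrichment_ratio()].
#'
#' @param universal `GRanges` of universal-dataset regions (names must match
#'   `features$name`).
#' @param features data.frame from [featurize()].
#' @param reference_features data.frame of the same feature columns over
#'   the species-specific reference regions.
#' @param specs filter specs ([default_filter_specs()]).
#' @param combine `"union"` or `"intersection"`.
#' @param ref_enh,ref_prom optional reference enhancer / promoter `GRanges`
#'   for the enrichment report.
#' @return list of class `filtered_dataset`: `regions` (retained `GRanges`
#'   with a `passing_filters` column), `pass` (region x filter logical
#'   matrix), `report` (per-filter stats), `specs` (with resolved
#'   thresholds).
#' @export
apply_filters <- function(universal, features, reference_features,
                          specs = default_filter_specs(),
                          combine = c("union", "intersection"),
                          ref_enh = NULL, ref_prom = NULL) {
  combine <- match.arg(combine)
  stopifnot(length(universal) == nrow(features))
  specs <- resolve_filter_thresholds(specs, reference_features)
  on <- names(specs)[vapply(specs, `[[`, logical(1), "enabled")]
  pass <- matrix(FALSE, nrow(features), length(specs),
                 dimnames = list(features$name, names(specs)))
  for (f in on) pass[, f] <- filter_predicate(f, specs[[f]], features)
  keep <- if (!length(on)) rep(FALSE, nrow(features))
          else if (combine == "union") rowSums(pass[, on, drop = FALSE]) > 0
          else rowSums(pass[, on, drop = FALSE]) == length(on)
  retained <- universal[keep]
  S4Vectors::mcols(retained)$passing_filters <- apply(
    pass[keep, on, drop = FALSE], 1,
    function(z) paste(on[z], collapse = ","))
  report <- do.call(rbind, lapply(on, function(f) {
    sel <- universal[pass[, f]]
    mb <- sum(GenomicRanges::width(sel)) / 1e6
    data.frame(filter = f,
               statistic = specs[[f]]$statistic,
               threshold = specs[[f]]$threshold %||% NA_real_,
               n_retained = sum(pass[, f]),
               retained_mb = mb,
               ratio_E = if (!is.null(ref_enh) && mb > 0)
                 round(sum(GenomicRanges::countOverlaps(
                   ref_enh, sel, ignore.strand = TRUE) > 0) / mb, 1)
                 else NA_real_,
               ratio_P = if (!is.null(ref_prom) && mb > 0)
                 round(sum(GenomicRanges::countOverlaps(
                   ref_prom, sel, ignore.strand = TRUE) > 0) / mb, 1)
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(regions = retained, pass = pass, report = report,
                 specs = specs, combine = combine),
            class = "filtered_dataset")
}

#' @export
print.filtered_dataset <- function(x, ...) {
  cat(sprintf("filtered_dataset: %d of %d regions retained (%s of filters)\n",
              length(x$regions), nrow(x$pass), x$combine))
  if (!is.null(x$report)) print(x$report, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enhancer / promoter density of a predicted dataset
#'
#' Ratio_E is the number of reference enhancers overlapped by the dataset
#' divided by the dataset's total length in Mb (Ratio_P analogously for
#' promoters); the fold columns compare these densities with the whole-
#' genome baseline.
#'
#' @param dataset `GRanges` of predicted regions.
#' @param ref_enh,ref_prom reference enhancer / promoter `GRanges`.
#' @param genome_size_mb genome size in Mb for the baseline.
#' @return list with `n_regions`, `total_length_mb`,
#'   `n_overlapping_ref_enh`, `n_overlapping_ref_prom`, `ratio_E`,
#'   `ratio_P` (1 decimal), `fold_vs_genome_E`, `fold_vs_genome_P`.
#' @export
enrichment_ratio <- function(dataset, ref_enh, ref_prom = NULL,
                             genome_size_mb = NA_real_) {
  mb <- sum(GenomicRanges::width(dataset)) / 1e6
  if (mb == 0) stop("zero-length dataset")
  n_e <- sum(GenomicRanges::countOverlaps(ref_enh, dataset,
                                          ignore.strand = TRUE) > 0)
  n_p <- if (is.null(ref_prom)) NA_integer_ else
    sum(GenomicRanges::countOverlaps(ref_prom, dataset,
                                     ignore.strand = TRUE) > 0)
  list(n_regions = length(dataset),
       total_length_mb = mb,
       n_overlapping_ref_enh = n_e,
       n_overlapping_ref_prom = n_p,
       ratio_E = ratio_per_mb(n_e, mb),
       ratio_P = if (is.na(n_p)) NA_real_ else ratio_per_mb(n_p, mb),
       fold_vs_genome_E = if (is.na(genome_size_mb)) NA_real_ else
         (n_e / mb) / (length(ref_enh) / genome_size_mb),
       fold_vs_genome_P = if (is.na(genome_size_mb) || is.na(n_p)) NA_real_
         else (n_p / mb) / (length(ref_prom) / genome_size_mb))
}

#' Region density per Mb
#'
#' The arithmetic core of the enrichment ratios: `count / length_mb`,
#' reported to one decimal.
#'
#' @param n count of reference regions overlapped.
#' @param length_mb total dataset length in Mb.
#' @return numeric, rounded to 1 decimal.
#' @export
ratio_per_mb <- function(n, length_mb) {
  if (length_mb <= 0) stop("length must be positive")
  round(n / length_mb, 1)
}

#' Fold enrichment from coverage percentages
#'
#' The ratio of the percentage of reference regions covered to the
#' percentage of the genome covered; reports round it to an integer.
#'
#' @param pct_ref_covered percentage of reference regions covered.
#' @param pct_genome_covered percentage of the genome covered.
#' @return numeric fold (unrounded).
#' @export
fold_enrichment <- function(pct_ref_covered, pct_genome_covered) {
  if (any(pct_genome_covered <= 0)) stop("genome coverage must be positive")
  pct_ref_covered / pct_genome_covered
}

#' Evaluate a grid of filter parameterisations
#'
#' Each candidate spec is applied independently to the universal dataset
#' (never sequentially), reporting retained size and enhancer/promoter
#' density so the best-enriching parameterisation per filter can be read
#' off.  Rows are sorted by filter, then `ratio_E` descending.
#'
#' @inheritParams apply_filters
#' @param grid named list: per filter name, a list of candidate specs (each
#'   like an entry of [default_filter_specs()]).
#' @return data.frame with columns `filter`, `statistic`, `transform`,
#'   `n_retained`, `retained_mb`, `ratio_E`, `ratio_P`.
#' @export
optimize_filter_params <- function(universal, features, reference_features,
                                   grid, ref_enh, ref_prom = NULL) {
  if (!length(grid)) stop("empty parameter grid")
  rows <- list()
  for (f in names(grid)) {
    for (spec in grid[[f]]) {
      spec$enabled <- TRUE
      sp <- resolve_filter_thresholds(setNames(list(spec), f),
                                      reference_features)
      p <- filter_predicate(f, sp[[f]], features)
      sel <- universal[p]
      mb <- sum(GenomicRanges::width(sel)) / 1e6
      rows[[length(rows) + 1L]] <- data.frame(
        filter = f, statistic = spec$statistic,
        transform = spec$transform %||% "identity",
        n_retained = sum(p), retained_mb = mb,
        ratio_E = if (mb > 0) round(sum(GenomicRanges::countOverlaps(
          ref_enh, sel, ignore.strand = TRUE) > 0) / mb, 1) else NA_real_,
        ratio_P = if (!is.null(ref_prom) && mb > 0)
          round(sum(GenomicRanges::countOverlaps(
            ref_prom, sel, ignore.strand = TRUE) > 0) / mb, 1) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$filter, -out$ratio_E), , drop = FALSE]
}
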