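## Interval projection with minMatch semantics, reciprocal validation and
## the multi-mapping rescue round.

#' Projection parameters
#'
#' @param min_match_main minimum fraction of a region's bases that must fall
#'   inside aligned chain blocks for the strict single-mapping stage
#'   (default 0.2, the optimised mapping threshold).
#' @param min_match_multi stricter coverage threshold for the multi-mapping
#'   rescue round (default 0.8).
#' @param recip_tolerance_bp maximum allowed shift, in bases, of either
#'   border of the reciprocally mapped region relative to the original
#'   (default 25).
#' @param recip_min_match coverage threshold used for the reciprocal
#'   back-projection; defaults to `min_match_main`.
#' @return A list of class `projection_params`.
#' @export
projection_params <- function(min_match_main = 0.2, min_match_multi = 0.8,
                              recip_tolerance_bp = 25,
                              recip_min_match = NULL) {
  stopifnot(min_match_main > 0, min_match_main <= min_match_multi,
            min_match_multi <= 1, recip_tolerance_bp >= 0)
  if (is.null(recip_min_match)) recip_min_match <- min_match_main
  structure(list(min_match_main = min_match_main,
                 min_match_multi = min_match_multi,
                 recip_tolerance_bp = recip_tolerance_bp,
                 recip_min_match = recip_min_match),
            class = "projection_params")
}

proj_row <- function(chrom, start, end, name = NA_character_,
                     t_chrom = NA_character_, t_start = NA_real_,
                     t_end = NA_real_, strand = NA_character_,
                     coverage = NA_real_, chain_id = NA_integer_,
                     stage = NA_character_, status) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             t_chrom = t_chrom, t_start = t_start, t_end = t_end,
             strand = strand, coverage = coverage, chain_id = chain_id,
             stage = stage, status = status, stringsAsFactors = FALSE)
}

## Coverage and projected span of [start, end) through one chain.
project_through_chain <- function(ch, start, end) {
  seg <- chain_segments(ch)
  ov <- pmin(end, seg$s_end) - pmax(start, seg$s_start)
  cov_bases <- sum(pmax(ov, 0))
  if (cov_bases == 0)
    return(list(cov_bases = 0))
  hit <- which(ov > 0)
  p1 <- max(start, seg$s_start[hit[1]])           # first aligned base
  p2 <- min(end, seg$s_end[hit[length(hit)]]) - 1 # last aligned base
  f <- map_positions(ch, c(p1, p2))
  list(cov_bases = cov_bases, t_start = min(f), t_end = max(f) + 1)
}

#' Project one interval through a chain set
#'
#' For every chain overlapping the interval, coverage is the fraction of the
#' interval's bases lying inside aligned blocks of that chain; a chain passes
#' when coverage >= `min_match`.  The projected span runs from the projection
#' of the first to the last aligned base (forward target coordinates, with a
#' strand flag for '-' chains).
#'
#' With `allow_multiple = FALSE`, exactly one passing chain yields a `mapped`
#' result, more than one yields a single `ambiguous` result and none yields
#' `unmapped`.  With `allow_multiple = TRUE`, one row per passing chain is
#' returned, ordered by coverage, then chain score, then chain id
#' (descending).
#'
#' @param chrom,start,end interval to project (0-based half-open).
#' @param chains a [chain_set()] whose source assembly carries the interval.
#' @param min_match minimum coverage fraction.
#' @param allow_multiple keep all passing chains?
#' @param name optional region name carried through.
#' @return A data.frame of projection results.
#' @export
project_interval <- function(chrom, start, end, chains, min_match = 0.2,
                             allow_multiple = FALSE, name = NA_character_) {
  if (!chrom %in% names(chains$from_sizes))
    stop("unknown chromosome: ", chrom)
  if (end - start < 1) stop("zero-length interval: ", chrom, ":", start)
  len <- end - start
  cand <- chains_overlapping(chains, chrom, start, end)
  res <- list()
  for (ch in cand) {
    pr <- project_through_chain(ch, start, end)
    cov <- pr$cov_bases / len
    if (pr$cov_bases > 0 && cov >= min_match) {
      res[[length(res) + 1L]] <- list(
        row = proj_row(chrom, start, end, name, ch$t_chrom, pr$t_start,
                       pr$t_end, ch$t_strand, cov, ch$id,
                       NA_character_, "mapped"),
        score = ch$score)
    }
  }
  if (length(res) == 0)
    return(proj_row(chrom, start, end, name, status = "unmapped"))
  if (!allow_multiple) {
    if (length(res) > 1)
      return(proj_row(chrom, start, end, name, status = "ambiguous"))
    return(res[[1]]$row)
  }
  rows <- do.call(rbind, lapply(res, `[[`, "row"))
  scores <- vapply(res, `[[`, numeric(1), "score")
  rows[order(-rows$coverage, -scores, -rows$chain_id), , drop = FALSE]
}

#' Reciprocal validation of a projected region
#'
#' Back-projects the target interval through the reverse chain set in strict
#' single-mapping mode and accepts the projection only when the
#' back-projection maps, returns to the original chromosome, and both
#' borders land within `recip_tolerance_bp` of the original borders.
#'
#' @param orig list or data.frame row with `chrom`, `start`, `end`.
#' @param proj a mapped row from [project_interval()].
#' @param reverse_chains [chain_set()] in the opposite direction.
#' @param params [projection_params()].
#' @return list with `accepted` flag and a `reason` string
#'   (`ok`, `not_mapped`, `not_unique`, `wrong_chrom`, `boundary_tolerance`).
#' @export
reciprocal_check <- function(orig, proj, reverse_chains, params) {
  stopifnot(proj$status == "mapped")
  back <- project_interval(proj$t_chrom, proj$t_start, proj$t_end,
                           reverse_chains,
                           min_match = params$recip_min_match,
                           allow_multiple = FALSE)
  if (back$status == "ambiguous")
    return(list(accepted = FALSE, reason = "not_unique"))
  if (back$status != "mapped")
    return(list(accepted = FALSE, reason = "not_mapped"))
  if (back$t_chrom != orig$chrom)
    return(list(accepted = FALSE, reason = "wrong_chrom"))
  tol <- params$recip_tolerance_bp
  if (abs(back$t_start - orig$start) > tol || abs(back$t_end - orig$end) > tol)
    return(list(accepted = FALSE, reason = "boundary_tolerance"))
  list(accepted = TRUE, reason = "ok")
}

#' Two-stage projection of a regulatory dataset
#'
#' Stage 1 projects every region in strict single-mapping mode at
#' `min_match_main` and keeps regions that pass [reciprocal_check()]
#' (`stage = "primary"`).  Stage 2 re-projects everything else with multiple
#' mapping allowed at the stringent `min_match_multi` threshold and keeps all
#' passing targets (`stage = "rescue"`), recovering duplicated loci.
#'
#' @param regions a `GRanges` (names used as region names) or a data.frame
#'   with `chrom`, `start`, `end`, `name`.
#' @param fwd,rev forward and reverse [chain_set()]s between the same two
#'   assemblies.
#' @param params [projection_params()].
#' @return list of class `hprs_map` with elements `results` (one row per
#'   mapping outcome), `summary` (per-status counts) and `recovered_rate`
#'   (fraction of input regions with at least one accepted mapping).
#' @export
hprs_map <- function(regions, fwd, rev, params = projection_params()) {
  if (!setequal(names(fwd$from_sizes), names(rev$to_sizes)) ||
      !setequal(names(fwd$to_sizes), names(rev$from_sizes)))
    stop("assembly mismatch between forward and reverse chain sets")
  df <- as_region_df(regions)
  n <- nrow(df)
  out <- vector("list", n)
  needs_rescue <- logical(n)
  for (i in seq_len(n)) {
    r <- df[i, ]
    pr <- project_interval(r$chrom, r$start, r$end, fwd,
                           min_match = params$min_match_main,
                           allow_multiple = FALSE, name = r$name)
    if (pr$status == "mapped") {
      rc <- reciprocal_check(r, pr, rev, params)
      if (rc$accepted) {
        pr$stage <- "primary"
        out[[i]] <- pr
      } else {
        pr$status <- "reciprocal_fail"
        out[[i]] <- pr
        needs_rescue[i] <- TRUE
      }
    } else {
      out[[i]] <- pr
      needs_rescue[i] <- TRUE
    }
  }
  for (i in which(needs_rescue)) {
    r <- df[i, ]
    pr <- project_interval(r$chrom, r$start, r$end, fwd,
                           min_match = params$min_match_multi,
                           allow_multiple = TRUE, name = r$name)
    if (pr$status[1] == "mapped") {
      pr$stage <- "rescue"
      out[[i]] <- pr
    }   # else keep the stage-1 failure row
  }
  results <- do.call(rbind, out)
  rownames(results) <- NULL
  acc <- results$status == "mapped"
  recovered <- length(unique(results$name[acc]))
  structure(list(
    results = results,
    summary = table(factor(results$status,
                           levels = c("mapped", "unmapped", "ambiguous",
                                      "reciprocal_fail"))),
    recovered_rate = recovered / n,
    params = params), class = "hprs_map")
}

#' @export
print.hprs_map <- function(x, ...) {
  cat("hprs_map:", nrow(x$results), "mapping outcomes\n")
  print(x$summary)
  cat(sprintf("recovered rate: %.3f\n", x$recovered_rate))
  invisible(x)
}

#' Project anchor pairs (e.g. chromatin-interaction anchors)
#'
#' Each anchor is mapped independently with [hprs_map()] semantics; a pair is
#' reported only when both anchors map (the top-ranked target is used when a
#' rescue round yields several).
#'
#' @param pairs data.frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b` and optional `name`.
#' @inheritParams hprs_map
#' @return list with `pairs` (projected pairs, orientation preserved) and
#'   `dropped` (input row indices with an unmapped anchor).
#' @export
project_pairs <- function(pairs, fwd, rev, params = projection_params()) {
  if (is.null(pairs$name)) pairs$name <- paste0("pair_", seq_len(nrow(pairs)))
  a <- data.frame(chrom = pairs$chrom_a, start = pairs$start_a,
                  end = pairs$end_a, name = pairs$name)
  b <- data.frame(chrom = pairs$chrom_b, start = pairs$start_b,
                  end = pairs$end_b, name = pairs$name)
  ma <- hprs_map(a, fwd, rev, params)$results
  mb <- hprs_map(b, fwd, rev, params)$results
  top1 <- function(m) m[m$status == "mapped" & !duplicated(m$name), ]
  ma <- top1(ma); mb <- top1(mb)
  keep <- pairs$name %in% ma$name & pairs$name %in% mb$name
  ia <- match(pairs$name[keep], ma$name)
  ib <- match(pairs$name[keep], mb$name)
  out <- data.frame(
    name = pairs$name[keep],
    chrom_a = ma$t_chrom[ia], start_a = ma$t_start[ia], end_a = ma$t_end[ia],
    strand_a = ma$strand[ia],
    chrom_b = mb$t_chrom[ib], start_b = mb$t_start[ib], end_b = mb$t_end[ib],
    strand_b = mb$strand[ib], stringsAsFactors = FALSE)
  list(pairs = out, dropped = which(!keep))
}

## Accept GRanges or data.frame region input; return a plain data.frame.
as_region_df <- function(regions) {
  if (is(regions, "GRanges")) {
    nm <- names(regions)
    if (is.null(nm)) nm <- paste0("region_", seq_along(regions))
    data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
               start = GenomicRanges::start(regions) - 1L,
               end = GenomicRanges::end(regions),
               name = nm, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(regions)
    if (is.null(df$name)) df$name <- paste0("region_", seq_len(nrow(df)))
    df[, c("chrom", "start", "end", "name")]
  }
}
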