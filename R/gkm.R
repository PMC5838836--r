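## Gapped k-mer sequence model and deltaSVM variant scoring.
##
## Sequences are represented by counts of gapped words: for every l-length
## window and every of the choose(l, k) subsets of k informative positions,
## the (pattern, word) pair is one feature.  Feature ids are canonicalized
## under reverse complement by default, so a motif and its reverse
## complement share features.  The classifier is a dual-form ridge
## (regularized least squares on +/-1 labels), solved in closed form on the
## gapped k-mer kernel; the full l-mer weight table is derived lazily by
## scoring single l-mers through the kernel.

.gkm_cache <- new.env(parent = emptyenv())

## Pattern bookkeeping for (l, k): position subsets, per-pattern offsets,
## reverse-complement pattern index and word table.
gkm_patterns <- function(l, k) {
  if (l < k) stop("l must be >= k")
  key <- paste(l, k, sep = "_")
  if (!is.null(.gkm_cache[[key]])) return(.gkm_cache[[key]])
  pat <- combn(l, k)                      # k x C
  C <- ncol(pat)
  ## selection matrix: word = window_bases %*% S  (l x C)
  S <- matrix(0, l, C)
  for (p in seq_len(C)) S[pat[, p], p] <- 4^(0:(k - 1))
  keys <- apply(pat, 2, paste, collapse = ",")
  rcpat <- apply(pat, 2, function(P) sort(l + 1 - P))
  rcp <- match(apply(rcpat, 2, paste, collapse = ","), keys)
  ## reverse-complement table over 4^k words
  w <- 0:(4^k - 1)
  digits <- sapply(0:(k - 1), function(j) (w %/% 4^j) %% 4)  # 4^k x k
  rcw <- as.integer(
    (3 - digits[, k:1, drop = FALSE]) %*% 4^(0:(k - 1)))
  info <- list(l = l, k = k, C = C, S = S, rcp = rcp, rcw = rcw,
               offset = (seq_len(C) - 1) * 4^k,
               dim = C * 4^k)
  .gkm_cache[[key]] <- info
  info
}

#' Gapped k-mer feature counts of one sequence
#'
#' Scans every l-length window of the forward strand (windows containing N
#' are skipped) and counts each of the choose(l, k) gapped words per
#' window.  With `collapse_rc = TRUE` (default) feature ids are
#' canonicalized under reverse complement.  The total feature mass of a
#' sequence of length L without N is `(L - l + 1) * choose(l, k)`.
#'
#' @param seq character sequence over A, C, G, T, N.
#' @param l word length (default 10).
#' @param k informative positions (default 6).
#' @param collapse_rc canonicalize features under reverse complement?
#' @return list with `idx` (sorted 1-based feature indices), `counts`
#'   (matching counts) and `dim` (feature-space size).
#' @export
extract_gkm_features <- function(seq, l = 10, k = 6, collapse_rc = TRUE) {
  info <- gkm_patterns(l, k)
  si <- seq_to_int(seq)
  W <- length(si) - l + 1
  if (W < 1)
    return(list(idx = integer(0), counts = numeric(0), dim = info$dim))
  idx <- outer(seq_len(W), 0:(l - 1), "+")
  M <- matrix(si[idx], W, l)
  ok <- rowSums(is.na(M)) == 0
  M <- M[ok, , drop = FALSE]
  if (!nrow(M))
    return(list(idx = integer(0), counts = numeric(0), dim = info$dim))
  words <- M %*% info$S                       # nW x C
  enc <- sweep(words, 2, info$offset, "+")
  if (collapse_rc) {
    rcenc <- matrix(info$rcw[words + 1], nrow(words)) +
      rep((info$rcp - 1) * 4^info$k, each = nrow(words))
    enc <- pmin(enc, rcenc)
  }
  v <- sort(as.numeric(enc))
  r <- rle(v)
  list(idx = r$values + 1, counts = as.numeric(r$lengths), dim = info$dim)
}

## Sparse feature matrix (sequences x features).
gkm_feature_matrix <- function(seqs, l, k, collapse_rc = TRUE) {
  feats <- lapply(seqs, extract_gkm_features, l = l, k = k,
                  collapse_rc = collapse_rc)
  nnz <- vapply(feats, function(f) length(f$idx), integer(1))
  Matrix::sparseMatrix(
    i = rep(seq_along(seqs), nnz),
    j = unlist(lapply(feats, `[[`, "idx")),
    x = unlist(lapply(feats, `[[`, "counts")),
    dims = c(length(seqs), gkm_patterns(l, k)$dim))
}

auc_score <- function(scores, positive) {
  r <- rank(scores)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Build a length-matched training set
#'
#' For each positive region, samples (seeded, uniform over valid
#' placements) a genomic interval of the same length that does not overlap
#' positives or exclusions; candidates containing N are resampled up to 100
#' times.  The negative length multiset therefore equals the positives'.
#'
#' @param positives `GRanges` of positive regions.
#' @param genome named `DNAStringSet` or FASTA path.
#' @param n_neg_per_pos negatives sampled per positive (default 1).
#' @param seed RNG seed.
#' @param exclusions optional `GRanges` additionally excluded.
#' @return list of class `training_set` with `pos_seqs`, `neg_seqs`,
#'   `neg_regions`, `seed`.
#' @export
make_training_set <- function(positives, genome, n_neg_per_pos = 1,
                              seed = 1, exclusions = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  chr_len <- setNames(Biostrings::width(genome), names(genome))
  pos_chrom <- as.character(GenomicRanges::seqnames(positives))
  if (!all(pos_chrom %in% names(chr_len)) ||
      any(GenomicRanges::end(positives) > chr_len[pos_chrom]))
    stop("genome too small to place negatives (positives out of bounds)")
  forbidden <- GenomicRanges::reduce(suppressWarnings(c(
    GenomicRanges::granges(positives),
    if (is.null(exclusions)) GenomicRanges::GRanges()
    else GenomicRanges::granges(exclusions))), ignore.strand = TRUE)
  get_seq <- function(chrom, start, end)
    as.character(Biostrings::subseq(genome[[chrom]], start, end))
  pos_seqs <- vapply(seq_along(positives), function(i) get_seq(
    as.character(GenomicRanges::seqnames(positives)[i]),
    GenomicRanges::start(positives)[i], GenomicRanges::end(positives)[i]),
    character(1))
  set.seed(seed)
  neg <- list()
  for (i in seq_along(positives)) {
    w <- GenomicRanges::width(positives)[i]
    valid <- chr_len[chr_len >= w]
    if (!length(valid)) stop("genome too small to place negatives")
    for (j in seq_len(n_neg_per_pos)) {
      placed <- FALSE
      for (try in 1:100) {
        chrom <- sample(names(valid), 1, prob = valid - w + 1)
        start <- sample.int(chr_len[[chrom]] - w + 1, 1)
        cand <- GenomicRanges::GRanges(chrom,
                                       IRanges::IRanges(start, start + w - 1))
        if (sum(suppressWarnings(GenomicRanges::countOverlaps(
          cand, forbidden, ignore.strand = TRUE))) > 0)
          next
        s <- get_seq(chrom, start, start + w - 1)
        if (grepl("N", s, fixed = TRUE)) next
        neg[[length(neg) + 1L]] <- list(chrom = chrom, start = start,
                                        end = start + w - 1, seq = s)
        placed <- TRUE
        break
      }
      if (!placed) stop("genome too small to place negatives ",
                        "(100 placement attempts failed)")
    }
  }
  structure(list(
    pos_seqs = pos_seqs,
    neg_seqs = vapply(neg, `[[`, character(1), "seq"),
    neg_regions = GenomicRanges::GRanges(
      vapply(neg, `[[`, character(1), "chrom"),
      IRanges::IRanges(vapply(neg, `[[`, numeric(1), "start"),
                       vapply(neg, `[[`, numeric(1), "end"))),
    seed = seed), class = "training_set")
}

#' Train a gapped k-mer classifier
#'
#' Fits a dual-form ridge classifier (closed-form regularized least squares
#' on +/-1 labels) on gapped k-mer feature counts, and reports held-out AUC
#' from stratified cross-validation on the precomputed kernel.  Training is
#' deterministic given the training set and seed.
#'
#' @param ts a `training_set` from [make_training_set()], or NULL when
#'   `pos_seqs` / `neg_seqs` are given directly.
#' @param pos_seqs,neg_seqs character vectors of sequences (alternative to
#'   `ts`).
#' @param l,k word length and informative positions (defaults 10, 6).
#' @param C regularization (ridge penalty `1/C`; default 1).
#' @param seed seed for the cross-validation folds.
#' @param nfolds cross-validation folds (default 5).
#' @param collapse_rc canonicalize features under reverse complement?
#' @return object of class `gkm_model` with elements `alpha` (dual
#'   coefficients), `X` (sparse training feature matrix), `cv_auc`,
#'   `fold_auc` and the training metadata.
#' @export
train_gkm <- function(ts = NULL, pos_seqs = NULL, neg_seqs = NULL,
                      l = 10, k = 6, C = 1, seed = 1, nfolds = 5,
                      collapse_rc = TRUE) {
  if (!is.null(ts)) { pos_seqs <- ts$pos_seqs; neg_seqs <- ts$neg_seqs }
  np <- length(pos_seqs); nn <- length(neg_seqs)
  if (np == 0 || nn == 0) stop("degenerate single-class input")
  if (np < 20 || nn < 20)
    stop("need at least 20 positives and 20 negatives")
  X <- gkm_feature_matrix(c(pos_seqs, neg_seqs), l, k, collapse_rc)
  y <- c(rep(1, np), rep(-1, nn))
  n <- np + nn
  K <- as.matrix(Matrix::tcrossprod(X))
  lambda <- 1 / C
  alpha <- solve(K + lambda * diag(n), y)
  ## stratified CV on the precomputed kernel
  set.seed(seed)
  fold <- integer(n)
  fold[seq_len(np)] <- sample(rep(seq_len(nfolds), length.out = np))
  fold[np + seq_len(nn)] <- sample(rep(seq_len(nfolds), length.out = nn))
  fold_auc <- vapply(seq_len(nfolds), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    a <- solve(K[tr, tr] + lambda * diag(length(tr)), y[tr])
    auc_score(as.numeric(K[te, tr, drop = FALSE] %*% a), y[te] > 0)
  }, numeric(1))
  structure(list(l = l, k = k, C = C, seed = seed, nfolds = nfolds,
                 collapse_rc = collapse_rc, alpha = alpha, X = X, y = y,
                 n_pos = np, n_neg = nn,
                 fold_auc = fold_auc, cv_auc = mean(fold_auc)),
            class = "gkm_model")
}

#' @export
print.gkm_model <- function(x, ...) {
  cat(sprintf(paste0("gapped k-mer classifier (l=%d, k=%d, C=%g): ",
                     "%d pos / %d neg, CV AUC %.3f\n"),
              x$l, x$k, x$C, x$n_pos, x$n_neg, x$cv_auc))
  invisible(x)
}

#' @export
summary.gkm_model <- function(object, ...) {
  print(object)
  cat("per-fold AUC:", paste(sprintf("%.3f", object$fold_auc),
                             collapse = " "), "\n")
  invisible(object)
}

#' Score sequences with a gapped k-mer model
#'
#' The score of a sequence equals the sum of derived l-mer weights of all
#' its windows.
#'
#' @param model a `gkm_model`.
#' @param seqs character vector of sequences.
#' @return numeric scores.
#' @export
score_sequences <- function(model, seqs) {
  Xq <- gkm_feature_matrix(seqs, model$l, model$k, model$collapse_rc)
  as.numeric(Matrix::tcrossprod(Xq, model$X) %*% model$alpha)
}

#' @export
predict.gkm_model <- function(object, seqs, type = c("score", "class"), ...) {
  s <- score_sequences(object, seqs)
  if (match.arg(type) == "class") s > 0 else s
}

#' Derived l-mer weights
#'
#' Weight of an l-mer = linear score of its feature vector; the full 4^l
#' table is never materialised, weights are computed for the l-mers asked
#' for.
#'
#' @param model a `gkm_model`.
#' @param lmers character vector of l-mers (each of length `model$l`).
#' @return named numeric weights.
#' @export
lmer_weights <- function(model, lmers) {
  if (any(nchar(lmers) != model$l))
    stop("all l-mers must have length ", model$l)
  setNames(score_sequences(model, lmers), lmers)
}

#' @export
coef.gkm_model <- function(object, ...) object$alpha

#' deltaSVM variant score
#'
#' The sum of model weights of all l-length windows overlapping the variant
#' in the alternate sequence minus the reference sequence.  The reference
#' context must have length `2 * (l - 1) + nchar(ref)` with the reference
#' allele starting at position `l`; for indels the window set is all l-mers
#' intersecting the edited span in each sequence.  Identity
#' (`delta(ref -> ref) == 0`) and antisymmetry
#' (`delta(ref -> alt) == -delta(alt -> ref)`) hold exactly for SNVs.
#'
#' @param context reference sequence window centred on the variant.
#' @param ref_allele,alt_allele allele strings (possibly multi-base).
#' @param model a `gkm_model`.
#' @return numeric delta score.
#' @export
delta_svm <- function(context, ref_allele, alt_allele, model) {
  l <- model$l
  context <- toupper(context)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  nr <- nchar(ref_allele)
  if (nchar(context) != 2 * (l - 1) + nr)
    stop("context must have length ", 2 * (l - 1) + nr,
         " for a ", nr, "-base reference allele")
  if (substr(context, l, l + nr - 1) != ref_allele)
    stop("context does not carry the reference allele at its centre")
  alt_seq <- paste0(substr(context, 1, l - 1), alt_allele,
                    substr(context, l + nr, nchar(context)))
  score_sequences(model, alt_seq) - score_sequences(model, context)
}

#' Percentile and significance of a score in a score distribution
#'
#' With the default two-sided reading, a score is significant when it falls
#' outside the central 95% range (at or below the 2.5th, or at or above the
#' 97.5th percentile).  `two_sided = FALSE` instead flags scores whose
#' magnitude reaches the 95th percentile of absolute scores.
#'
#' @param score numeric score(s).
#' @param score_distribution reference score distribution.
#' @param two_sided use the central-range reading (default TRUE)?
#' @return data.frame with `score`, `percentile` and `significant`.
#' @export
score_percentile <- function(score, score_distribution, two_sided = TRUE) {
  if (!length(score_distribution)) stop("empty score distribution")
  pct <- vapply(score, function(s)
    100 * mean(score_distribution <= s), numeric(1))
  if (two_sided) {
    qs <- quantile(score_distribution, c(0.025, 0.975), type = 7)
    sig <- score <= qs[1] | score >= qs[2]
  } else {
    q <- quantile(abs(score_distribution), 0.95, type = 7)
    sig <- abs(score) >= q
  }
  data.frame(score = score, percentile = pct, significant = unname(sig))
}
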