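#' @importFrom methods is
#' @importFrom stats quantile median rnorm runif rbinom rexp setNames
#' @importFrom utils head tail combn
NULL

## UCSC chain model -----------------------------------------------------------
##
## A chain records one pairwise alignment between a "source" assembly (the
## assembly regions are projected FROM; the tName side of the UCSC header,
## always '+' strand) and a "target" assembly (the qName side).  Coordinates
## are 0-based half-open throughout.  For target strand '-', stored target
## coordinates are on the reversed sequence; forward-strand coordinates are
## (target_size - end, target_size - start).

new_chain <- function(id, score, s_chrom, s_size, s_start, s_end,
                      t_chrom, t_size, t_strand, t_start, t_end, blocks) {
  structure(list(
    id = as.integer(id), score = as.numeric(score),
    s_chrom = s_chrom, s_size = as.numeric(s_size),
    s_start = as.numeric(s_start), s_end = as.numeric(s_end),
    t_chrom = t_chrom, t_size = as.numeric(t_size), t_strand = t_strand,
    t_start = as.numeric(t_start), t_end = as.numeric(t_end),
    blocks = blocks  # matrix with columns size, dt, dq
  ), class = "chain")
}

validate_chain <- function(ch, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" (chain header at line %d)", line)
  b <- ch$blocks
  if (any(b[, "size"] <= 0)) stop("chain ", ch$id, ": block size <= 0", where)
  if (any(b[, c("dt", "dq")] < 0)) stop("chain ", ch$id, ": negative gap", where)
  n <- nrow(b)
  if (b[n, "dt"] != 0 || b[n, "dq"] != 0)
    stop("chain ", ch$id, ": final block must have dt = dq = 0", where)
  if (ch$s_start >= ch$s_end || ch$t_start >= ch$t_end)
    stop("chain ", ch$id, ": start >= end", where)
  if (sum(b[, "size"] + b[, "dt"]) != ch$s_end - ch$s_start)
    stop("chain ", ch$id, ": block-sum mismatch on source side", where)
  if (sum(b[, "size"] + b[, "dq"]) != ch$t_end - ch$t_start)
    stop("chain ", ch$id, ": block-sum mismatch on target side", where)
  invisible(ch)
}

#' Create a chain set
#'
#' Bundles a list of chains with the chromosome sizes of the two assemblies
#' they connect.  Overlapping source spans across chains are allowed (and
#' required for duplication rescue); queries return all overlapping chains.
#'
#' @param chains list of chain objects.
#' @param from_sizes,to_sizes named numeric vectors of chromosome lengths for
#'   the source and target assemblies.  Defaulted from the chain headers.
#' @param from_name,to_name assembly labels.
#' @return An object of class `chain_set`.
#' @export
chain_set <- function(chains, from_sizes = NULL, to_sizes = NULL,
                      from_name = "source", to_name = "target") {
  if (is.null(from_sizes)) {
    from_sizes <- vapply(chains, function(ch) ch$s_size, numeric(1))
    names(from_sizes) <- vapply(chains, function(ch) ch$s_chrom, character(1))
    from_sizes <- from_sizes[!duplicated(names(from_sizes))]
  }
  if (is.null(to_sizes)) {
    to_sizes <- vapply(chains, function(ch) ch$t_size, numeric(1))
    names(to_sizes) <- vapply(chains, function(ch) ch$t_chrom, character(1))
    to_sizes <- to_sizes[!duplicated(names(to_sizes))]
  }
  for (ch in chains) {
    if (!is.na(from_sizes[ch$s_chrom]) &&
        from_sizes[ch$s_chrom] != ch$s_size)
      stop("inconsistent source size for chromosome ", ch$s_chrom)
  }
  ids <- vapply(chains, function(ch) ch$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate chain id: ",
                               ids[duplicated(ids)][1])
  structure(list(chains = chains, from_sizes = from_sizes,
                 to_sizes = to_sizes, from_name = from_name,
                 to_name = to_name),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set: %d chains, %s (%d seq) -> %s (%d seq)\n",
              length(x$chains), x$from_name, length(x$from_sizes),
              x$to_name, length(x$to_sizes)))
  invisible(x)
}

#' @export
length.chain_set <- function(x) length(x$chains)

## All chains whose source span overlaps [start, end) on chrom.
chains_overlapping <- function(cs, chrom, start, end) {
  hit <- vapply(cs$chains, function(ch)
    ch$s_chrom == chrom && ch$s_start < end && ch$s_end > start, logical(1))
  cs$chains[hit]
}

#' Parse a UCSC chain file
#'
#' Reads the standard chain dialect
#' (`chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` headers followed by `size dt dq` block lines).  Reading is
#' gzip-transparent.  All structural invariants (block sums, positive sizes,
#' strand conventions, unique ids) are enforced; violations raise an error
#' naming the offending line.
#'
#' @param path path to a chain file (optionally gzipped).
#' @param from_name,to_name assembly labels for the resulting set.
#' @return A [chain_set()].
#' @export
parse_chain_file <- function(path, from_name = "source", to_name = "target") {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  chains <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) != 13)
      stop("malformed chain header at line ", i)
    if (f[5] != "+")
      stop("source strand must be '+' at line ", i)
    if (!f[10] %in% c("+", "-"))
      stop("invalid target strand at line ", i)
    hdr_line <- i
    num <- suppressWarnings(as.numeric(f[c(2, 4, 6, 7, 9, 11, 12, 13)]))
    if (anyNA(num)) stop("non-numeric field in chain header at line ", i)
    i <- i + 1L
    rows <- list()
    repeat {
      if (i > n) stop("unterminated chain block starting at line ", hdr_line)
      b <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      v <- suppressWarnings(as.numeric(b))
      if (anyNA(v) || !length(v) %in% c(1, 3))
        stop("malformed block line at line ", i)
      if (length(v) == 1) v <- c(v, 0, 0)
      rows[[length(rows) + 1L]] <- v
      i <- i + 1L
      if (length(b) == 1) break
    }
    blocks <- do.call(rbind, rows)
    colnames(blocks) <- c("size", "dt", "dq")
    ch <- new_chain(id = num[8], score = num[1],
                    s_chrom = f[3], s_size = num[2],
                    s_start = num[3], s_end = num[4],
                    t_chrom = f[8], t_size = num[5], t_strand = f[10],
                    t_start = num[6], t_end = num[7], blocks = blocks)
    validate_chain(ch, hdr_line)
    chains[[length(chains) + 1L]] <- ch
  }
  chain_set(chains, from_name = from_name, to_name = to_name)
}

#' Write a chain set in UCSC chain format
#'
#' Inverse of [parse_chain_file()]: `parse_chain_file(write_chain_file(x))`
#' reproduces `x` chain-for-chain.
#'
#' @param cs a [chain_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain_file <- function(cs, path) {
  out <- character(0)
  fmt_n <- function(x) format(x, scientific = FALSE, trim = TRUE)
  for (ch in cs$chains) {
    hdr <- paste("chain", fmt_n(ch$score), ch$s_chrom, fmt_n(ch$s_size), "+",
                 fmt_n(ch$s_start), fmt_n(ch$s_end), ch$t_chrom,
                 fmt_n(ch$t_size), ch$t_strand, fmt_n(ch$t_start),
                 fmt_n(ch$t_end), fmt_n(ch$id))
    b <- ch$blocks
    n <- nrow(b)
    body <- character(n)
    if (n > 1)
      body[seq_len(n - 1)] <- paste(fmt_n(b[-n, "size"]), fmt_n(b[-n, "dt"]),
                                    fmt_n(b[-n, "dq"]))
    body[n] <- fmt_n(b[n, "size"])
    out <- c(out, hdr, body, "")
  }
  writeLines(out, path)
  invisible(path)
}

## Aligned segment pairs of a chain in absolute coordinates.  Target
## coordinates are returned in FORWARD orientation; for '-' strand chains
## segment k of the source pairs with the reverse-complemented target
## segment, so within a segment source base s_start+j maps to target
## forward base t_end-1-j.
chain_segments <- function(ch) {
  b <- ch$blocks
  sz <- b[, "size"]
  s0 <- ch$s_start + c(0, cumsum(sz + b[, "dt"]))[seq_along(sz)]
  q0 <- ch$t_start + c(0, cumsum(sz + b[, "dq"]))[seq_along(sz)]
  if (ch$t_strand == "+") {
    t0 <- q0
  } else {
    t0 <- ch$t_size - (q0 + sz)   # forward-orientation start
  }
  data.frame(s_start = s0, s_end = s0 + sz, t_start = t0, t_end = t0 + sz)
}

## Map a vector of source positions through one chain.  Returns forward
## target positions (NA where unaligned).
map_positions <- function(ch, pos) {
  seg <- chain_segments(ch)
  out <- rep(NA_real_, length(pos))
  idx <- findInterval(pos, seg$s_start)
  ok <- idx >= 1 & pos < seg$s_end[pmax(idx, 1)]
  i <- idx[ok]
  off <- pos[ok] - seg$s_start[i]
  out[ok] <- if (ch$t_strand == "+") seg$t_start[i] + off
             else seg$t_end[i] - 1 - off
  out
}

#' Invert a chain set
#'
#' Swaps the source and target sides of every chain, normalising so that the
#' new source strand is always '+'.  Projection through the inverted set
#' reverses the original per-base mapping exactly.
#'
#' @param cs a [chain_set()].
#' @return A [chain_set()] in the opposite direction.
#' @export
invert_chains <- function(cs) {
  inv <- lapply(cs$chains, function(ch) {
    seg <- chain_segments(ch)  # target coords already forward
    if (ch$t_strand == "-") {
      ## reverse segment order so new-source (old target) coords ascend;
      ## old source then descends, i.e. new target is on '-' strand
      seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    }
    sz <- seg$s_end - seg$s_start
    ns <- nrow(seg)
    new_s_start <- seg$t_start; new_s_end <- seg$t_end
    if (ch$t_strand == "+") {
      new_t_start <- seg$s_start; new_t_end <- seg$s_end
    } else {
      ## new target ('-') stored coords are on the reversed old-source seq
      new_t_start <- ch$s_size - seg$s_end
      new_t_end <- ch$s_size - seg$s_start
    }
    dt <- c(new_s_start[-1] - new_s_end[-ns], 0)
    dq <- c(new_t_start[-1] - new_t_end[-ns], 0)
    if (ns == 1) { dt <- 0; dq <- 0 }
    blocks <- cbind(size = sz, dt = dt, dq = dq)
    ch2 <- new_chain(id = ch$id, score = ch$score,
                     s_chrom = ch$t_chrom, s_size = ch$t_size,
                     s_start = new_s_start[1], s_end = new_s_end[ns],
                     t_chrom = ch$s_chrom, t_size = ch$s_size,
                     t_strand = ch$t_strand,
                     t_start = new_t_start[1], t_end = new_t_end[ns],
                     blocks = blocks)
    validate_chain(ch2)
  })
  chain_set(inv, from_sizes = cs$to_sizes, to_sizes = cs$from_sizes,
            from_name = cs$to_name, to_name = cs$from_name)
}

## Single-block identity chain helper (used widely in tests and fixtures).
identity_chain <- function(id, chrom, size, t_chrom = chrom, score = 1000) {
  new_chain(id, score, chrom, size, 0, size, t_chrom, size, "+", 0, size,
            cbind(size = size, dt = 0, dq = 0))
}
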