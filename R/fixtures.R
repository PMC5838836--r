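## Seeded synthetic-data generator: a miniature source/target genome pair
## related by a known rearrangement plan, with ground-truth chains,
## planted regulatory regions, signal tracks, motifs and variants.
##
## The event plan is applied left-to-right on a coordinate map and the
## chains are generated directly from that map (never re-aligned), so the
## ground truth is exact by construction.  Small indel events (deletion,
## insertion) become gaps inside the main colinear chain; inversions,
## tandem-duplication copies and translocations become chains of their own,
## which is what makes duplicated loci ambiguous in strict single-mapping
## mode and recoverable only by the rescue round.

FIXTURE_MOTIF_ENH <- "TGACGTCA"   # planted in active enhancer-like regions
FIXTURE_MOTIF_TFBS <- "GCCACGTG"  # planted in TFBS-like regions

#' Fixture configuration
#'
#' @param seed RNG seed; the whole fixture is a deterministic function of
#'   the configuration.
#' @param chrom_sizes named vector of source chromosome lengths (default
#'   two 1 Mb chromosomes).
#' @param events data.frame with columns `chrom`, `type` (one of
#'   `translocation`, `inversion`, `deletion`, `insertion`,
#'   `tandem_duplication`), `start`, `end` (source coordinates, 0-based
#'   half-open; for insertions `start == end` and `size` gives the inserted
#'   length).  Defaults to one event of each type per chromosome.
#' @param n_promoters,n_enhancers,n_tfbs planted regions per class.
#' @param active_fraction fraction of promoters/enhancers marked active
#'   (these carry signal and motifs).
#' @param enrichment_factor signal multiple of active regions over the
#'   background tracks.
#' @param n_snp_neutral,n_snp_disrupting planted variants: background SNVs
#'   and motif-disrupting SNVs inside active enhancers.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 42,
                           chrom_sizes = c(chr1 = 1e6, chr2 = 1e6),
                           events = default_event_plan(chrom_sizes),
                           n_promoters = 40, n_enhancers = 60, n_tfbs = 40,
                           active_fraction = 0.5, enrichment_factor = 8,
                           n_snp_neutral = 200, n_snp_disrupting = 20) {
  cfg <- list(seed = seed, chrom_sizes = chrom_sizes, events = events,
              n_promoters = n_promoters, n_enhancers = n_enhancers,
              n_tfbs = n_tfbs, active_fraction = active_fraction,
              enrichment_factor = enrichment_factor,
              n_snp_neutral = n_snp_neutral,
              n_snp_disrupting = n_snp_disrupting)
  validate_event_plan(cfg)
  structure(cfg, class = "fixture_config")
}

#' Default rearrangement plan: one event of each type per chromosome
#' @param chrom_sizes named vector of source chromosome lengths.
#' @return events data.frame (see [fixture_config()]).
#' @export
default_event_plan <- function(chrom_sizes) {
  do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    at <- function(f) round(L * f)
    data.frame(
      chrom = ch,
      type = c("inversion", "deletion", "insertion", "tandem_duplication",
               "translocation"),
      start = c(at(0.30), at(0.45), at(0.55), at(0.65), at(0.80)),
      end = c(at(0.30) + 6000, at(0.45) + 2000, at(0.55),
              at(0.65) + 3000, at(0.80) + 4000),
      size = c(NA, NA, 2000, NA, NA),
      stringsAsFactors = FALSE)
  }))
}

validate_event_plan <- function(cfg) {
  ev <- cfg$events
  if (is.null(ev) || !nrow(ev)) return(invisible(cfg))
  ok_types <- c("translocation", "inversion", "deletion", "insertion",
                "tandem_duplication")
  if (!all(ev$type %in% ok_types))
    stop("unknown event type: ", setdiff(ev$type, ok_types)[1])
  for (ch in unique(ev$chrom)) {
    if (!ch %in% names(cfg$chrom_sizes))
      stop("event on unknown chromosome ", ch)
    e <- ev[ev$chrom == ch, ]
    e <- e[order(e$start), ]
    if (any(e$start < 0) || any(e$end > cfg$chrom_sizes[[ch]]))
      stop("event plan exceeds genome on ", ch)
    if (any(e$end < e$start)) stop("event with end < start on ", ch)
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping events on ", ch)
  }
  invisible(cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Apply the event plan to one chromosome.  Returns the ordered target
## pieces: aligned pieces carry source coordinates, strand and a chain
## group; novel pieces carry only a length.
chrom_pieces <- function(chrom, L, events) {
  ev <- events[events$chrom == chrom, , drop = FALSE]
  ev <- ev[order(ev$start), , drop = FALSE]
  pieces <- list(); defer <- list()
  add <- function(p) pieces[[length(pieces) + 1L]] <<- p
  pos <- 0
  gi <- 0L
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    gi <- gi + 1L
    if (e$start > pos)
      add(list(type = "aligned", s_start = pos, s_end = e$start,
               strand = "+", group = "main"))
    if (e$type == "deletion") {
      ## nothing in target
    } else if (e$type == "insertion") {
      add(list(type = "novel", len = e$size))
    } else if (e$type == "inversion") {
      add(list(type = "aligned", s_start = e$start, s_end = e$end,
               strand = "-", group = paste0(chrom, "_inv_", gi)))
    } else if (e$type == "tandem_duplication") {
      add(list(type = "aligned", s_start = e$start, s_end = e$end,
               strand = "+", group = "main"))
      add(list(type = "aligned", s_start = e$start, s_end = e$end,
               strand = "+", group = paste0(chrom, "_dup_", gi)))
    } else if (e$type == "translocation") {
      defer[[length(defer) + 1L]] <-
        list(type = "aligned", s_start = e$start, s_end = e$end,
             strand = "+", group = paste0(chrom, "_trans_", gi))
    }
    pos <- e$end
  }
  if (pos < L)
    add(list(type = "aligned", s_start = pos, s_end = L,
             strand = "+", group = "main"))
  for (d in defer) add(d)
  ## assign target coordinates
  tpos <- 0
  for (i in seq_along(pieces)) {
    len <- if (pieces[[i]]$type == "novel") pieces[[i]]$len
           else pieces[[i]]$s_end - pieces[[i]]$s_start
    pieces[[i]]$t_start <- tpos
    pieces[[i]]$t_end <- tpos + len
    tpos <- tpos + len
  }
  attr(pieces, "target_len") <- tpos
  pieces
}

## Aligned-segment table for one chromosome's pieces.
pieces_segments <- function(pieces, chrom) {
  al <- Filter(function(p) p$type == "aligned", pieces)
  if (!length(al)) return(NULL)
  data.frame(chrom = chrom,
             s_start = vapply(al, `[[`, numeric(1), "s_start"),
             s_end = vapply(al, `[[`, numeric(1), "s_end"),
             t_start = vapply(al, `[[`, numeric(1), "t_start"),
             t_end = vapply(al, `[[`, numeric(1), "t_end"),
             strand = vapply(al, `[[`, character(1), "strand"),
             group = vapply(al, `[[`, character(1), "group"),
             stringsAsFactors = FALSE)
}

## Build the chains (source -> target) of one chromosome from its segment
## table.  The main group becomes one multi-block chain; every other group
## becomes a single-block chain.
segments_to_chains <- function(seg, s_size, t_size, first_id) {
  chains <- list(); id <- first_id
  for (g in unique(seg$group)) {
    sg <- seg[seg$group == g, , drop = FALSE]
    sg <- sg[order(sg$s_start), , drop = FALSE]
    strand <- sg$strand[1]
    sz <- sg$s_end - sg$s_start
    ns <- nrow(sg)
    if (strand == "+") {
      q_start <- sg$t_start; q_end <- sg$t_end
    } else {
      q_start <- t_size - sg$t_end; q_end <- t_size - sg$t_start
    }
    dt <- if (ns > 1) c(sg$s_start[-1] - sg$s_end[-ns], 0) else 0
    dq <- if (ns > 1) c(q_start[-1] - q_end[-ns], 0) else 0
    ch <- new_chain(id = id, score = sum(sz) * 100,
                    s_chrom = sg$chrom[1], s_size = s_size,
                    s_start = sg$s_start[1], s_end = sg$s_end[ns],
                    t_chrom = paste0(sg$chrom[1], "T"), t_size = t_size,
                    t_strand = strand,
                    t_start = q_start[1], t_end = q_end[ns],
                    blocks = cbind(size = sz, dt = dt, dq = dq))
    chains[[length(chains) + 1L]] <- validate_chain(ch)
    id <- id + 1L
  }
  chains
}

## Sample n non-overlapping intervals with lengths in len_range inside the
## given container intervals (data.frame with s_start/s_end), avoiding
## `taken` (2-column matrix of start/end on the same chromosome).
sample_intervals <- function(n, len_range, containers, taken, margin = 60) {
  out <- matrix(numeric(0), 0, 2)
  wts <- pmax(containers$s_end - containers$s_start - 2 * margin, 0)
  if (!any(wts > 0)) stop("no room to place regions")
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:300) {
      ci <- sample.int(nrow(containers), 1, prob = wts)
      w <- sample(len_range[1]:len_range[2], 1)
      lo <- containers$s_start[ci] + margin
      hi <- containers$s_end[ci] - margin - w
      if (hi <= lo) next
      a <- lo + sample.int(hi - lo, 1)
      b <- a + w
      all_taken <- rbind(taken, out)
      if (nrow(all_taken) &&
          any(a < all_taken[, 2] & b > all_taken[, 1])) next
      out <- rbind(out, c(a, b))
      placed <- TRUE
      break
    }
    if (!placed) stop("no room to place regions (300 attempts failed)")
  }
  out
}

## target coordinates of a source interval fully inside one segment
segment_project <- function(seg, a, b) {
  if (seg$strand == "+") {
    c(seg$t_start + (a - seg$s_start), seg$t_start + (b - seg$s_start))
  } else {
    c(seg$t_start + (seg$s_end - b), seg$t_start + (seg$s_end - a))
  }
}

#' Generate a complete synthetic fixture
#'
#' Builds a source genome, applies the rearrangement plan to produce the
#' target genome, emits forward/reverse chains that describe the
#' transformation exactly, plants regulatory regions (with motif insertions
#' in active regions), signal and conservation tracks enriched over active
#' regions, reference enhancer/promoter sets, and a SNP table with
#' motif-disrupting variants.  Regenerating with the same configuration is
#' byte-identical.
#'
#' @param cfg a [fixture_config()].
#' @param outdir optional directory; when given, all components are written
#'   as FASTA / chain / BED / bedGraph / TSV files and the returned object
#'   gains a `paths` element.
#' @return list of class `fixture` with the in-memory components:
#'   `source_seq`, `target_seq` (`DNAStringSet`), `fwd`, `rev`
#'   ([chain_set()]), `regions` (source `GRanges`), `manifest` (ground
#'   truth, one row per expected mapping outcome), `cage`, `h3k27ac`,
#'   `rnaseq`, `conservation` (`GRanges` tracks in target coordinates),
#'   `ref_enh`, `ref_prom`, `pwms`, `snps`, `target_sizes`.
#' @export
generate_fixture <- function(cfg = fixture_config(), outdir = NULL) {
  set.seed(cfg$seed)
  src <- lapply(cfg$chrom_sizes, random_dna)

  ## --- plant regions on the source, per chromosome ----------------------
  all_pieces <- list(); seg_tabs <- list()
  for (ch in names(cfg$chrom_sizes)) {
    p <- chrom_pieces(ch, cfg$chrom_sizes[[ch]], cfg$events)
    all_pieces[[ch]] <- p
    seg_tabs[[ch]] <- pieces_segments(p, ch)
  }
  segs <- do.call(rbind, seg_tabs)
  target_sizes <- setNames(vapply(all_pieces, attr, numeric(1), "target_len"),
                           paste0(names(all_pieces), "T"))

  ## deleted source intervals (regions planted there stay unmapped)
  del <- cfg$events[cfg$events$type == "deletion", , drop = FALSE]

  classes <- c(rep("promoter", cfg$n_promoters),
               rep("enhancer", cfg$n_enhancers),
               rep("tfbs", cfg$n_tfbs))
  len_range <- list(promoter = c(150, 400), enhancer = c(250, 600),
                    tfbs = c(100, 200))
  ## special placements exercising the mapping scenarios: one enhancer in
  ## every inversion / duplication / deletion
  special <- list()
  for (g in unique(segs$group[grepl("_inv_", segs$group)]))
    special[[length(special) + 1L]] <- list(kind = "inv", group = g)
  for (g in unique(segs$group[grepl("_dup_", segs$group)]))
    special[[length(special) + 1L]] <- list(kind = "dup", group = g)
  for (i in seq_len(nrow(del)))
    special[[length(special) + 1L]] <- list(kind = "del", row = i)

  regions <- list()   # chrom, start, end, name, class, placement
  taken <- list()     # per chrom matrix of occupied intervals
  for (ch in names(cfg$chrom_sizes)) taken[[ch]] <- matrix(numeric(0), 0, 2)
  add_region <- function(ch, a, b, class, placement) {
    nm <- sprintf("%s_%03d", class, sum(vapply(regions, function(r)
      r$class == class, logical(1))) + 1L)
    regions[[length(regions) + 1L]] <<- list(chrom = ch, start = a, end = b,
                                             name = nm, class = class,
                                             placement = placement)
    taken[[ch]] <<- rbind(taken[[ch]], c(a, b))
  }
  ## specials first (consume part of the enhancer budget)
  n_special <- length(special)
  for (sp in special) {
    if (sp$kind == "del") {
      e <- del[sp$row, ]
      cont <- data.frame(s_start = e$start, s_end = e$end)
      ch <- e$chrom
    } else {
      sg <- segs[segs$group == sp$group, , drop = FALSE][1, ]
      cont <- data.frame(s_start = sg$s_start, s_end = sg$s_end)
      ch <- sg$chrom
    }
    iv <- sample_intervals(1, len_range$enhancer, cont, taken[[ch]],
                           margin = 40)
    add_region(ch, iv[1], iv[2], "enhancer", sp$kind)
  }
  ## the rest go into plain main segments
  remaining <- c(promoter = cfg$n_promoters,
                 enhancer = max(cfg$n_enhancers - n_special, 0),
                 tfbs = cfg$n_tfbs)
  for (cls in names(remaining)) {
    n_per_chrom <- table(factor(
      sample(names(cfg$chrom_sizes), remaining[[cls]], replace = TRUE),
      levels = names(cfg$chrom_sizes)))
    for (ch in names(cfg$chrom_sizes)) {
      cont <- segs[segs$chrom == ch & segs$group == "main", , drop = FALSE]
      n_here <- n_per_chrom[[ch]]
      if (n_here == 0) next
      iv <- sample_intervals(n_here, len_range[[cls]], cont, taken[[ch]])
      for (r in seq_len(n_here))
        add_region(ch, iv[r, 1], iv[r, 2], cls, "plain")
    }
  }
  reg <- do.call(rbind, lapply(regions, function(r)
    data.frame(chrom = r$chrom, start = r$start, end = r$end, name = r$name,
               class = r$class, placement = r$placement,
               stringsAsFactors = FALSE)))
  reg$active <- FALSE
  sel <- reg$class %in% c("promoter", "enhancer")
  reg$active[sel] <- runif(sum(sel)) < cfg$active_fraction
  reg$active[reg$placement == "del"] <- FALSE

  ## --- plant motifs in the source sequence ------------------------------
  plant <- function(seqs, chrom, at, motif) {
    substr(seqs[[chrom]], at + 1, at + nchar(motif)) <- motif
    seqs
  }
  motif_at <- rep(NA_real_, nrow(reg))  # source offset of planted motif
  for (i in seq_len(nrow(reg))) {
    m <- if (reg$class[i] == "tfbs") FIXTURE_MOTIF_TFBS
         else if (reg$class[i] == "enhancer" && reg$active[i])
           FIXTURE_MOTIF_ENH else NA
    if (is.na(m)) next
    at <- floor((reg$start[i] + reg$end[i] - nchar(m)) / 2)
    src <- plant(src, reg$chrom[i], at, m)
    motif_at[i] <- at
  }
  reg$motif_at <- motif_at

  ## --- build target sequences and chains --------------------------------
  tgt <- list(); chains <- list(); next_id <- 1L
  for (ch in names(cfg$chrom_sizes)) {
    parts <- vapply(all_pieces[[ch]], function(p) {
      if (p$type == "novel") random_dna(p$len)
      else {
        s <- substr(src[[ch]], p$s_start + 1, p$s_end)
        if (p$strand == "-") revcomp_chr(s) else s
      }
    }, character(1))
    tgt[[paste0(ch, "T")]] <- paste(parts, collapse = "")
    new_chains <- segments_to_chains(seg_tabs[[ch]], cfg$chrom_sizes[[ch]],
                                     target_sizes[[paste0(ch, "T")]],
                                     next_id)
    chains <- c(chains, new_chains)
    next_id <- next_id + length(new_chains)
  }
  fwd <- chain_set(chains, from_sizes = cfg$chrom_sizes,
                   to_sizes = target_sizes,
                   from_name = "source", to_name = "target")
  rev <- invert_chains(fwd)

  ## --- ground-truth manifest --------------------------------------------
  rows <- list()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    if (r$placement == "del") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = r$name, class = r$class, active = r$active,
        chrom = r$chrom, start = r$start, end = r$end,
        t_chrom = NA, t_start = NA, t_end = NA, strand = NA,
        expected_stage = "unmapped", stringsAsFactors = FALSE)
      next
    }
    sg <- segs[segs$chrom == r$chrom & segs$s_start <= r$start &
                 segs$s_end >= r$end, , drop = FALSE]
    stage <- if (any(grepl("_dup_", sg$group))) "rescue" else "primary"
    for (j in seq_len(nrow(sg))) {
      tc <- segment_project(sg[j, ], r$start, r$end)
      rows[[length(rows) + 1L]] <- data.frame(
        name = r$name, class = r$class, active = r$active,
        chrom = r$chrom, start = r$start, end = r$end,
        t_chrom = paste0(r$chrom, "T"), t_start = tc[1], t_end = tc[2],
        strand = sg$strand[j], expected_stage = stage,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)

  ## --- tracks in target coordinates -------------------------------------
  man_ok <- manifest[!is.na(manifest$t_start), , drop = FALSE]
  gr_t <- GenomicRanges::GRanges(man_ok$t_chrom,
                                 IRanges::IRanges(man_ok$t_start + 1,
                                                  man_ok$t_end))
  names(gr_t) <- make.unique(man_ok$name)
  active_t <- GenomicRanges::reduce(gr_t[man_ok$active],
                                    ignore.strand = TRUE)
  all_t <- GenomicRanges::reduce(gr_t, ignore.strand = TRUE)
  tile_start <- lapply(names(target_sizes), function(tc)
    seq(1, target_sizes[[tc]], by = 200))
  tiles <- GenomicRanges::GRanges(
    rep(names(target_sizes), lengths(tile_start)),
    IRanges::IRanges(unlist(tile_start),
                     pmin(unlist(tile_start) + 199,
                          rep(unname(target_sizes), lengths(tile_start)))))
  make_track <- function(hot, base_fun, hot_fun) {
    bg <- GenomicRanges::setdiff(tiles, hot, ignore.strand = TRUE)
    bg <- unlist(GenomicRanges::tile(bg, width = 200))
    v_bg <- base_fun(length(bg)); v_hot <- hot_fun(length(hot))
    out <- c(bg, hot)
    S4Vectors::mcols(out)$value <- c(v_bg, v_hot)
    GenomicRanges::sort(out)
  }
  fac <- cfg$enrichment_factor
  h3k27ac <- make_track(active_t,
                        function(n) round(rexp(n, 1), 3),
                        function(n) round(fac * (1 + rexp(n, 2)), 3))
  rnaseq <- make_track(active_t,
                       function(n) round(rexp(n, 1), 3),
                       function(n) round(fac * (1 + rexp(n, 2)), 3))
  conservation <- make_track(all_t,
                             function(n) round(runif(n, 0, 0.3), 4),
                             function(n) round(runif(n, 0.8, 1), 4))

  ## CAGE peaks: clustered on active promoters, sparse elsewhere
  cage_rows <- list()
  prom_t <- man_ok[man_ok$class == "promoter", , drop = FALSE]
  for (i in seq_len(nrow(prom_t))) {
    n_pk <- if (prom_t$active[i]) sample(2:3, 1) else rbinom(1, 1, 0.3)
    if (n_pk == 0) next
    w <- prom_t$t_end[i] - prom_t$t_start[i]
    at <- sort(sample.int(max(w - 20, 1), n_pk))
    cage_rows[[length(cage_rows) + 1L]] <- data.frame(
      chrom = prom_t$t_chrom[i], start = prom_t$t_start[i] + at,
      end = pmin(prom_t$t_start[i] + at + 20, prom_t$t_end[i]))
  }
  for (tc in names(target_sizes)) {   # background peaks
    n_bg <- 20
    at <- sample.int(target_sizes[[tc]] - 20, n_bg)
    cage_rows[[length(cage_rows) + 1L]] <- data.frame(
      chrom = tc, start = at, end = at + 20)
  }
  cage_df <- do.call(rbind, cage_rows)
  cage <- GenomicRanges::sort(GenomicRanges::GRanges(
    cage_df$chrom, IRanges::IRanges(cage_df$start + 1, cage_df$end)))
  names(cage) <- paste0("cage_", seq_along(cage))

  ## reference sets: half of the active regions per class
  pick_ref <- function(cls) {
    cand <- which(man_ok$class == cls & man_ok$active &
                    !duplicated(man_ok$name))
    sel <- sort(sample(cand, ceiling(length(cand) / 2)))
    gr <- GenomicRanges::GRanges(man_ok$t_chrom[sel],
                                 IRanges::IRanges(man_ok$t_start[sel] + 1,
                                                  man_ok$t_end[sel]))
    names(gr) <- paste0("ref_", man_ok$name[sel])
    gr
  }
  ref_enh <- pick_ref("enhancer")
  ref_prom <- pick_ref("promoter")

  ## PWMs for the two planted motifs
  consensus_pfm <- function(consensus, hit = 85, miss = 5) {
    b <- strsplit(consensus, "")[[1]]
    m <- matrix(miss, 4, length(b), dimnames = list(c("A", "C", "G", "T")))
    for (j in seq_along(b)) m[b[j], j] <- hit
    m
  }
  pwms <- list(ENH_MOTIF = consensus_pfm(FIXTURE_MOTIF_ENH),
               TFBS_MOTIF = consensus_pfm(FIXTURE_MOTIF_TFBS))

  ## --- SNP table (target coordinates, 1-based) --------------------------
  tgt_base <- function(tc, pos0) substr(tgt[[tc]], pos0 + 1, pos0 + 1)
  snp_rows <- list()
  enh_mot <- reg[reg$class == "enhancer" & reg$active &
                   !is.na(reg$motif_at) & reg$placement == "plain", ,
                 drop = FALSE]
  n_dis <- min(cfg$n_snp_disrupting, nrow(enh_mot))
  dis_idx <- if (n_dis > 0) sample(seq_len(nrow(enh_mot)), n_dis) else integer(0)
  for (i in dis_idx) {
    r <- enh_mot[i, ]
    sg <- segs[segs$chrom == r$chrom & segs$group == "main" &
                 segs$s_start <= r$start & segs$s_end >= r$end, ][1, ]
    off <- sample.int(nchar(FIXTURE_MOTIF_ENH), 1) - 1
    t_pos0 <- segment_project(sg, r$motif_at + off, r$motif_at + off + 1)[1]
    tc <- paste0(r$chrom, "T")
    ref_b <- tgt_base(tc, t_pos0)
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      chrom = tc, pos = t_pos0 + 1, id = sprintf("snp_dis_%03d", i),
      ref = ref_b, alt = alt_b, p = 10^-runif(1, 3, 10),
      category = "motif_disrupting", region = r$name,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_snp_neutral)) {
    tc <- sample(names(target_sizes), 1)
    t_pos0 <- sample.int(target_sizes[[tc]], 1) - 1
    ref_b <- tgt_base(tc, t_pos0)
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      chrom = tc, pos = t_pos0 + 1, id = sprintf("snp_bg_%03d", i),
      ref = ref_b, alt = sample(setdiff(c("A", "C", "G", "T"), ref_b), 1),
      p = runif(1), category = "neutral", region = NA,
      stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)

  regions_gr <- GenomicRanges::GRanges(reg$chrom,
                                       IRanges::IRanges(reg$start + 1,
                                                        reg$end))
  names(regions_gr) <- reg$name
  S4Vectors::mcols(regions_gr) <- reg[, c("class", "placement", "active",
                                          "motif_at")]

  fx <- structure(list(
    cfg = cfg,
    source_seq = Biostrings::DNAStringSet(unlist(src)),
    target_seq = Biostrings::DNAStringSet(unlist(tgt)),
    fwd = fwd, rev = rev,
    regions = regions_gr, manifest = manifest,
    cage = cage, h3k27ac = h3k27ac, rnaseq = rnaseq,
    conservation = conservation,
    ref_enh = ref_enh, ref_prom = ref_prom,
    pwms = pwms, snps = snps,
    target_sizes = target_sizes), class = "fixture")

  if (!is.null(outdir)) fx$paths <- write_fixture(fx, outdir)
  fx
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf(paste0("fixture: %d source chromosomes (%.2f Mb), ",
                     "%d chains, %d planted regions, %d SNPs\n"),
              length(x$source_seq), sum(x$cfg$chrom_sizes) / 1e6,
              length(x$fwd$chains), length(x$regions), nrow(x$snps)))
  invisible(x)
}

## Write every fixture component as standard text formats.
write_fixture <- function(fx, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  Biostrings::writeXStringSet(fx$source_seq, p("source.fa"))
  Biostrings::writeXStringSet(fx$target_seq, p("target.fa"))
  write_chain_file(fx$fwd, p("fwd.chain"))
  write_chain_file(fx$rev, p("rev.chain"))
  write_bed(fx$regions, p("regions_src.bed"))
  write_bed(fx$cage, p("cage.bed"))
  write_bedgraph(fx$h3k27ac, p("h3k27ac.bedGraph"))
  write_bedgraph(fx$rnaseq, p("rnaseq.bedGraph"))
  write_bedgraph(fx$conservation, p("conservation.bedGraph"))
  write_bed(fx$ref_enh, p("ref_enhancers.bed"))
  write_bed(fx$ref_prom, p("ref_promoters.bed"))
  con <- file(p("pwms.txt"), "w")
  for (nm in names(fx$pwms)) {
    writeLines(paste0(">", nm), con)
    m <- fx$pwms[[nm]]
    for (b in rownames(m))
      writeLines(paste0(b, " [ ", paste(m[b, ], collapse = " "), " ]"), con)
  }
  close(con)
  utils::write.table(fx$snps, p("snps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  setNames(as.list(p(c("source.fa", "target.fa", "fwd.chain", "rev.chain",
                       "regions_src.bed", "cage.bed", "h3k27ac.bedGraph",
                       "rnaseq.bedGraph", "conservation.bedGraph",
                       "ref_enhancers.bed", "ref_promoters.bed", "pwms.txt",
                       "snps.tsv", "manifest.tsv"))),
           c("source_fa", "target_fa", "fwd_chain", "rev_chain",
             "regions_src_bed", "cage_bed", "h3k27ac_bedgraph",
             "rnaseq_bedgraph", "conservation_bedgraph", "ref_enh_bed",
             "ref_prom_bed", "pwms", "snps_tsv", "manifest_tsv"))
}

#' Simulate planted-motif training sequences
#'
#' Uniform-random sequences; positives receive the motif at a random
#' offset.  The standard benchmark for the gapped k-mer classifier.
#'
#' @param n_pos,n_neg numbers of sequences.
#' @param len sequence length (default 100).
#' @param motif planted motif (default the fixture enhancer motif).
#' @param seed RNG seed.
#' @return list with `pos_seqs` and `neg_seqs`.
#' @export
simulate_motif_sequences <- function(n_pos, n_neg, len = 100,
                                     motif = FIXTURE_MOTIF_ENH, seed = 11) {
  set.seed(seed)
  w <- nchar(motif)
  pos <- vapply(seq_len(n_pos), function(i) {
    s <- random_dna(len)
    at <- sample.int(len - w + 1, 1)
    substr(s, at, at + w - 1) <- motif
    s
  }, character(1))
  neg <- vapply(seq_len(n_neg), function(i) random_dna(len), character(1))
  list(pos_seqs = pos, neg_seqs = neg)
}
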