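# Splice-site-anchored meta-event geometry: per-event position vectors with
# masking and transcript-orientation handling.

#' Map configuration
#'
#' Bundles every tunable parameter of the splicing-map pipeline.
#'
#' @param event_type event type the geometry is built for.
#' @param exon_offset nt of exon flank per window (default 50).
#' @param intron_offset nt of intron flank per window (default 300).
#' @param conf confidence used for outlier trimming: the middle
#'   `conf` fraction of values is kept at each position (default 0.95).
#' @param pseudocount_reads pseudocount, in reads, converted to RPM with the
#'   IP library size where used (default 1).
#' @param norm_method `"raw"`, `"subtraction"` or `"entropy"`; the numeric
#'   codes 0/1/2 are also accepted (default `"subtraction"`).
#' @param peak_p_max maximum raw peak p-value (default 0.001).
#' @param peak_fold_min minimum peak fold enrichment (default 8).
#' @param n_permutations bootstrap permutations (default 1000).
#' @param percentile_bounds percentiles (in percent) for the permutation
#'   confidence envelope (default `c(0.5, 99.5)`).
#' @param seed master RNG seed.
#' @param mask_mode `"boundary"` truncates each window at the far boundary of
#'   its neighbouring feature (the default; adjacent windows may then cover
#'   overlapping genomic positions when a feature is shorter than the
#'   combined flanks); `"midpoint"` truncates shared features at their
#'   midpoint so no position is covered twice within one event.
#' @param pc_per_position if `TRUE` (default) the subtraction denominator adds
#'   one pseudocount per unmasked position; if `FALSE` a single pseudocount
#'   is added once.
#' @param raw_unscaled if `TRUE`, raw mode skips the per-event
#'   unit-absolute-sum scaling (default `FALSE`).
#' @return A `map_config` object (named list).
#' @export
map_config <- function(event_type = "SE", exon_offset = 50L,
                       intron_offset = 300L, conf = 0.95,
                       pseudocount_reads = 1, norm_method = "subtraction",
                       peak_p_max = 0.001, peak_fold_min = 8,
                       n_permutations = 1000L,
                       percentile_bounds = c(0.5, 99.5), seed = 1L,
                       mask_mode = c("boundary", "midpoint"),
                       pc_per_position = TRUE, raw_unscaled = FALSE) {
  event_type <- match.arg(event_type, EVENT_TYPES)
  if (is.numeric(norm_method)) {
    norm_method <- c("raw", "subtraction", "entropy")[norm_method + 1L]
  }
  norm_method <- match.arg(norm_method, c("raw", "subtraction", "entropy"))
  mask_mode <- match.arg(mask_mode)
  exon_offset <- as.integer(exon_offset)
  intron_offset <- as.integer(intron_offset)
  stopifnot(exon_offset >= 0L, intron_offset >= 0L,
            exon_offset + intron_offset > 0L,
            conf > 0, conf <= 1, pseudocount_reads >= 0,
            length(percentile_bounds) == 2L,
            percentile_bounds[1] < percentile_bounds[2],
            n_permutations >= 1L)
  structure(list(event_type = event_type, exon_offset = exon_offset,
                 intron_offset = intron_offset, conf = conf,
                 pseudocount_reads = pseudocount_reads,
                 norm_method = norm_method, peak_p_max = peak_p_max,
                 peak_fold_min = peak_fold_min,
                 n_permutations = as.integer(n_permutations),
                 percentile_bounds = as.numeric(percentile_bounds),
                 seed = as.integer(seed), mask_mode = mask_mode,
                 pc_per_position = isTRUE(pc_per_position),
                 raw_unscaled = isTRUE(raw_unscaled)),
            class = "map_config")
}

#' Number of splice-site windows per event type
#'
#' SE uses four windows (upstream-exon 3' end, cassette 5' end, cassette
#' 3' end, downstream-exon 5' end). A3SS: flanking-exon 5' splice site and
#' the long- and short-exon 3' splice sites. A5SS: long- and short-exon 5'
#' splice sites and the flanking-exon 3' splice site. RI: the retained
#' intron's 5' and 3' splice sites. MXE: upstream-exon 3' end, both ends of
#' each mutually exclusive exon, downstream-exon 5' end.
#'
#' @param event_type event type string.
#' @return Integer number of windows.
#' @export
n_windows <- function(event_type) {
  switch(match.arg(event_type, EVENT_TYPES),
         SE = 4L, A3SS = 3L, A5SS = 3L, RI = 2L, MXE = 6L)
}

#' Total meta-region length for a configuration
#'
#' @param config a [map_config()].
#' @return `(exon_offset + intron_offset) * n_windows(event_type)`.
#' @export
region_length <- function(config) {
  (config$exon_offset + config$intron_offset) * n_windows(config$event_type)
}

# Window layout for a '+'-oriented event (anchors genomically non-decreasing,
# transcript order). Each window is one splice site with an exonic and an
# intronic flank; orient "EI" = exon then intron (3' end of an exon),
# "IE" = intron then exon (5' end of an exon). Feature ids let the midpoint
# mask detect features shared by two windows of the same event.
window_layout <- function(event_type, a) {
  iv <- function(s, e) c(s, e)
  w <- function(orient, exon, intron, exon_fid, intron_fid) {
    list(orient = orient, exon = exon, intron = intron,
         exon_fid = exon_fid, intron_fid = intron_fid)
  }
  switch(event_type,
    SE = {
      i1 <- iv(a[1, 2], a[2, 1]); i2 <- iv(a[2, 2], a[3, 1])
      list(w("EI", a[1, ], i1, "e.up", "i1"),
           w("IE", a[2, ], i1, "e.cas", "i1"),
           w("EI", a[2, ], i2, "e.cas", "i2"),
           w("IE", a[3, ], i2, "e.dn", "i2"))
    },
    A3SS = {
      # anchors: long, short, flanking; flanking exon is transcript-upstream
      il <- iv(a[3, 2], a[1, 1]); is_ <- iv(a[3, 2], a[2, 1])
      list(w("EI", a[3, ], il, "e.flank", "i.long"),
           w("IE", a[1, ], il, "e.long", "i.long"),
           w("IE", a[2, ], is_, "e.short", "i.short"))
    },
    A5SS = {
      # anchors: long, short, flanking; flanking exon is transcript-downstream
      il <- iv(a[1, 2], a[3, 1]); is_ <- iv(a[2, 2], a[3, 1])
      list(w("EI", a[1, ], il, "e.long", "i.long"),
           w("EI", a[2, ], is_, "e.short", "i.short"),
           w("IE", a[3, ], il, "e.flank", "i.long"))
    },
    RI = {
      # anchors: upstream exon, retained intron span, downstream exon
      list(w("EI", a[1, ], a[2, ], "e.up", "i.ri"),
           w("IE", a[3, ], a[2, ], "e.dn", "i.ri"))
    },
    MXE = {
      i1 <- iv(a[1, 2], a[2, 1]); i2 <- iv(a[2, 2], a[3, 1])
      i3 <- iv(a[3, 2], a[4, 1])
      list(w("EI", a[1, ], i1, "e.up", "i1"),
           w("IE", a[2, ], i1, "e.mx1", "i1"),
           w("EI", a[2, ], i2, "e.mx1", "i2"),
           w("IE", a[3, ], i2, "e.mx2", "i2"),
           w("EI", a[3, ], i3, "e.mx2", "i3"),
           w("IE", a[4, ], i3, "e.dn", "i3"))
    })
}

# How far into a feature a window may count. `anchored_left` says whether the
# window is anchored at the feature's genomic-left end. With midpoint masking
# a feature used by two windows is split; the left-anchored window takes the
# ceiling half.
feature_limit <- function(len, offset, mask_mode, shared, anchored_left) {
  lim <- len
  if (mask_mode == "midpoint" && shared) {
    lim <- if (anchored_left) ceiling(len / 2) else floor(len / 2)
  }
  min(offset, lim)
}

#' Build the splice-site-anchored position vector for one event
#'
#' Produces a `meta_region`: an ordered vector of genomic positions (0-based)
#' of fixed length `region_length(config)`, 5' to 3' in transcript
#' orientation (reversed genomic order for minus-strand events), plus a mask
#' marking positions that fall beyond a feature's boundary (signal is only
#' counted until the boundary of the neighbouring feature for exons shorter
#' than `2 * exon_offset` and introns shorter than `2 * intron_offset`) or
#' before position 0 of the chromosome.
#'
#' Minus-strand events are handled by reflecting the event to the plus
#' strand, building the vector there, and mapping positions back, which makes
#' the geometry exactly mirror-symmetric.
#'
#' @param event single-event list with fields `event_id`, `chrom`, `strand`,
#'   `anchors` (k x 2 matrix, transcript order), as stored in an
#'   [event_list()].
#' @param config a [map_config()] whose `event_type` matches the event.
#' @return A `meta_region` object with fields `event_id`, `chrom`, `strand`,
#'   `positions` (integer), `mask` (logical), `event_type`, `n_windows`,
#'   `window_size`.
#' @export
build_meta_region <- function(event, config) {
  a <- event$anchors
  if (any(a[, 2] - a[, 1] < 1L)) {
    stop("invalid event: anchor shorter than 1 nt", call. = FALSE)
  }
  if (any(a[, 2] <= a[, 1])) stop("invalid event: start >= end", call. = FALSE)
  eo <- config$exon_offset
  io <- config$intron_offset
  strand <- event$strand
  if (strand == "-") {
    M <- max(a[, 2]) + eo + io + 1L
    a <- cbind(M - a[, 2], M - a[, 1])
  }
  # after reflection anchors must be genomically non-decreasing in transcript
  # order for chain-type layouts
  wins <- window_layout(config$event_type, a)
  fid_all <- unlist(lapply(wins, function(w) c(w$exon_fid, w$intron_fid)))
  shared <- names(which(table(fid_all) > 1L))
  pos <- integer(0)
  msk <- logical(0)
  for (w in wins) {
    ex <- w$exon; intr <- w$intron
    if (intr[2] < intr[1]) stop("invalid event: features out of order", call. = FALSE)
    ex_len <- ex[2] - ex[1]
    in_len <- intr[2] - intr[1]
    if (w$orient == "EI") {
      # exon anchored at its right end; intron at its left end
      ex_lim <- feature_limit(ex_len, eo, config$mask_mode,
                              w$exon_fid %in% shared, anchored_left = FALSE)
      in_lim <- feature_limit(in_len, io, config$mask_mode,
                              w$intron_fid %in% shared, anchored_left = TRUE)
      pe <- ex[2] - eo + seq_len(eo) - 1L
      me <- (ex[2] - pe) > ex_lim
      pi_ <- intr[1] + seq_len(io) - 1L
      mi <- (pi_ - intr[1]) >= in_lim
      pos <- c(pos, pe, pi_); msk <- c(msk, me, mi)
    } else {
      in_lim <- feature_limit(in_len, io, config$mask_mode,
                              w$intron_fid %in% shared, anchored_left = FALSE)
      ex_lim <- feature_limit(ex_len, eo, config$mask_mode,
                              w$exon_fid %in% shared, anchored_left = TRUE)
      pi_ <- intr[2] - io + seq_len(io) - 1L
      mi <- (intr[2] - pi_) > in_lim
      pe <- ex[1] + seq_len(eo) - 1L
      me <- (pe - ex[1]) >= ex_lim
      pos <- c(pos, pi_, pe); msk <- c(msk, mi, me)
    }
  }
  if (strand == "-") {
    pos <- M - 1L - pos
  }
  below <- pos < 0L
  msk[below] <- TRUE
  pos[below] <- 0L
  structure(list(event_id = event$event_id, chrom = event$chrom,
                 strand = strand, positions = as.integer(pos), mask = msk,
                 event_type = config$event_type,
                 n_windows = n_windows(config$event_type),
                 window_size = eo + io),
            class = "meta_region")
}

#' @export
print.meta_region <- function(x, ...) {
  cat(sprintf("<meta_region> %s (%s%s): %d positions in %d windows, %d masked\n",
              x$event_id, x$chrom, x$strand, length(x$positions),
              x$n_windows, sum(x$mask)))
  invisible(x)
}

#' Build meta regions for every event in a list
#'
#' @param events an [event_list()].
#' @param config a [map_config()]; its `event_type` must match.
#' @return A list of `meta_region` objects.
#' @export
build_meta_regions <- function(events, config) {
  stopifnot(inherits(events, "event_list"))
  if (events$event_type != config$event_type) {
    stop(sprintf("config event_type (%s) does not match event list (%s)",
                 config$event_type, events$event_type), call. = FALSE)
  }
  df <- events$events
  lapply(seq_len(nrow(df)), function(i) {
    build_meta_region(list(event_id = df$event_id[i], chrom = df$chrom[i],
                           strand = df$strand[i], anchors = df$anchors[[i]]),
                      config)
  })
}

#' Export a meta region's unmasked runs as BED intervals
#'
#' One BED record per contiguous run of unmasked positions, for inspection in
#' a genome browser.
#'
#' @param region a `meta_region`.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open).
#' @export
meta_region_to_bed <- function(region) {
  pos <- region$positions[!region$mask]
  if (length(pos) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  }
  pos <- sort(unique(pos))
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  runs <- lapply(seq_len(length(brk) - 1L), function(i) {
    p <- pos[(brk[i] + 1L):brk[i + 1L]]
    c(p[1], p[length(p)] + 1L)
  })
  data.frame(chrom = region$chrom,
             start = vapply(runs, `[`, integer(1), 1),
             end = vapply(runs, `[`, integer(1), 2),
             name = region$event_id, score = 0L, strand = region$strand,
             stringsAsFactors = FALSE)
}
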