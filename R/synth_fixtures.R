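# Self-contained synthetic inputs: toy genome geometry, event tables,
# Poisson-noise coverage with planted positional enrichment, peak files and
# control-Psi tables.

#' Specification for synthetic fixtures
#'
#' Describes a toy skipped-exon study: `n_events` knockdown-responsive test
#' events plus a larger pool of `n_background` native-like background events
#' on one synthetic chromosome, with Poisson per-nt coverage and a
#' positionally planted IP enrichment.
#'
#' @param n_events number of test (RBP-responsive) events (default 100).
#' @param n_background number of background events; defaults to five times
#'   `n_events`, mirroring the native cassette-exon backgrounds that are
#'   several-fold larger than typical responsive sets.
#' @param exon_length_range,intron_length_range integer pairs for uniform
#'   geometry draws (defaults 100-250 nt exons, 600-1500 nt introns, long
#'   enough that default windows are unmasked).
#' @param planted_offset nt downstream of the cassette exon's 5' splice site
#'   (transcript direction, 1 = first intronic nt) at which enrichment is
#'   centred (default 67).
#' @param planted_amplitude fold enrichment over baseline at the planted
#'   centre (default 10).
#' @param planted_fraction fraction of test events carrying the planted
#'   signal (default 0.8).
#' @param baseline_rate Poisson mean reads per nt (default 1).
#' @param seed RNG seed; identical specs generate byte-identical files.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_events = 100L, n_background = 5L * n_events,
                         exon_length_range = c(100L, 250L),
                         intron_length_range = c(600L, 1500L),
                         planted_offset = 67L, planted_amplitude = 10,
                         planted_fraction = 0.8, baseline_rate = 1,
                         seed = 1L) {
  stopifnot(n_events >= 1L, n_background >= 1L,
            length(exon_length_range) == 2L, all(exon_length_range > 0L),
            exon_length_range[1] <= exon_length_range[2],
            length(intron_length_range) == 2L, all(intron_length_range > 0L),
            intron_length_range[1] <= intron_length_range[2],
            planted_fraction >= 0, planted_fraction <= 1,
            planted_amplitude >= 0, baseline_rate > 0)
  structure(list(n_events = as.integer(n_events),
                 n_background = as.integer(n_background),
                 exon_length_range = as.integer(exon_length_range),
                 intron_length_range = as.integer(intron_length_range),
                 planted_offset = as.integer(planted_offset),
                 planted_amplitude = planted_amplitude,
                 planted_fraction = planted_fraction,
                 baseline_rate = baseline_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

FIXTURE_CHROM <- "chrS"
FIXTURE_GAP <- 1000L
N_CONTROLS <- 10L

draw_len <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

place_events <- function(n, prefix, spec, cursor) {
  ue <- draw_len(n, spec$exon_length_range)
  cas <- draw_len(n, spec$exon_length_range)
  dn <- draw_len(n, spec$exon_length_range)
  i1 <- draw_len(n, spec$intron_length_range)
  i2 <- draw_len(n, spec$intron_length_range)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  anchors <- vector("list", n)
  starts <- integer(n)
  for (e in seq_len(n)) {
    s <- cursor
    A <- c(s, s + ue[e])
    B <- c(A[2] + i1[e], A[2] + i1[e] + cas[e])
    C <- c(B[2] + i2[e], B[2] + i2[e] + dn[e])
    a <- if (strand[e] == "+") rbind(A, B, C) else rbind(C, B, A)
    colnames(a) <- c("start", "end")
    rownames(a) <- NULL
    anchors[[e]] <- a
    starts[e] <- s
    cursor <- C[2] + FIXTURE_GAP
  }
  list(anchors = anchors, strand = strand,
       ids = sprintf("%s_%04d", prefix, seq_len(n)), cursor = cursor)
}

rmats_table <- function(ids, anchors, strand, ijc1, ijc2, sjc1, sjc2,
                        psi1, psi2, dpsi, pval, fdr) {
  cas <- t(vapply(anchors, function(a) a[2, ], integer(2)))
  up <- t(vapply(anchors, function(a) a[1, ], integer(2)))
  dn <- t(vapply(anchors, function(a) a[3, ], integer(2)))
  data.table(ID = ids, GeneID = paste0("G.", ids), geneSymbol = toupper(ids),
             chr = FIXTURE_CHROM, strand = strand,
             exonStart_0base = cas[, 1], exonEnd = cas[, 2],
             upstreamES = up[, 1], upstreamEE = up[, 2],
             downstreamES = dn[, 1], downstreamEE = dn[, 2],
             IJC_SAMPLE_1 = ijc1, SJC_SAMPLE_1 = sjc1,
             IJC_SAMPLE_2 = ijc2, SJC_SAMPLE_2 = sjc2,
             IncFormLen = 150L, SkipFormLen = 100L,
             PValue = pval, FDR = fdr,
             IncLevel1 = psi1, IncLevel2 = psi2, IncLevelDifference = dpsi)
}

two_rep_counts <- function(n, lambda) {
  paste(rpois(n, lambda), rpois(n, lambda), sep = ",")
}

two_rep_psi <- function(n, lo, hi) {
  paste(round(runif(n, lo, hi), 3), round(runif(n, lo, hi), 3), sep = ",")
}

#' Generate synthetic skipped-exon event tables
#'
#' Places non-overlapping SE events along a synthetic chromosome with
#' geometry drawn uniformly from the spec ranges. Test events receive
#' knockdown-excluded statistics passing the default significance filters
#' (negative delta Psi, small p and FDR); background events receive null
#' statistics plus per-control Psi values cycling through the background
#' classes (constitutive, native included / central / excluded, and
#' unclassifiable), so all five classes are non-empty. When `dir` is given,
#' rMATS-format tables and a control-Psi TSV are written and round-trip
#' through [parse_rmats()].
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory for `test_SE.txt`,
#'   `background_SE.txt` and `control_psi.tsv`.
#' @return List with `test` and `background` [event_list()]s (control Psi
#'   attached to the background list), `control_psi` (data.frame) and
#'   `files` (named character vector, when `dir` is given).
#' @export
generate_events <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  nt <- spec$n_events
  nb <- spec$n_background
  te <- place_events(nt, "test", spec, cursor = FIXTURE_GAP)
  bg <- place_events(nb, "bg", spec, cursor = te$cursor)

  test_tab <- rmats_table(te$ids, te$anchors, te$strand,
                          ijc1 = two_rep_counts(nt, 30), ijc2 = two_rep_counts(nt, 15),
                          sjc1 = two_rep_counts(nt, 10), sjc2 = two_rep_counts(nt, 25),
                          psi1 = two_rep_psi(nt, 0.6, 0.9),
                          psi2 = two_rep_psi(nt, 0.1, 0.4),
                          dpsi = -round(runif(nt, 0.1, 0.8), 3),
                          pval = signif(runif(nt, 1e-5, 0.04), 4),
                          fdr = signif(runif(nt, 1e-5, 0.09), 4))
  bg_tab <- rmats_table(bg$ids, bg$anchors, bg$strand,
                        ijc1 = two_rep_counts(nb, 25), ijc2 = two_rep_counts(nb, 25),
                        sjc1 = two_rep_counts(nb, 20), sjc2 = two_rep_counts(nb, 20),
                        psi1 = two_rep_psi(nb, 0.3, 0.7),
                        psi2 = two_rep_psi(nb, 0.3, 0.7),
                        dpsi = round(runif(nb, -0.04, 0.04), 3),
                        pval = signif(runif(nb, 0.2, 1), 4),
                        fdr = signif(runif(nb, 0.2, 1), 4))

  classes <- rep(c("native_central", "native_included", "native_excluded",
                   "constitutive", "none"),
                 length.out = nb)
  psi_mat <- t(vapply(classes, function(cl) {
    switch(cl,
           constitutive = rep(1, N_CONTROLS),
           native_included = round(runif(N_CONTROLS, 0.70, 0.93), 3),
           native_central = round(runif(N_CONTROLS, 0.35, 0.65), 3),
           native_excluded = round(runif(N_CONTROLS, 0.07, 0.30), 3),
           none = round(runif(N_CONTROLS, 0.955, 0.99), 3))
  }, numeric(N_CONTROLS)))
  control_psi <- data.frame(event_id = bg$ids, stringsAsFactors = FALSE)
  for (j in seq_len(N_CONTROLS)) {
    control_psi[[sprintf("control_%02d", j)]] <- psi_mat[, j]
  }

  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(test = file.path(dir, "test_SE.txt"),
               background = file.path(dir, "background_SE.txt"),
               control_psi = file.path(dir, "control_psi.tsv"))
    fwrite(test_tab, files[["test"]], sep = "\t", quote = FALSE)
    fwrite(bg_tab, files[["background"]], sep = "\t", quote = FALSE)
    fwrite(as.data.table(control_psi), files[["control_psi"]], sep = "\t",
           quote = FALSE)
  }

  mk_list <- function(tab, ancs, label) {
    ev <- data.frame(event_id = tab$ID, chrom = tab$chr, strand = tab$strand,
                     ijc_total = vapply(seq_len(nrow(tab)), function(i) {
                       sum_junction_counts(tab$IJC_SAMPLE_1[i],
                                           tab$IJC_SAMPLE_2[i], i + 1L, "IJC")
                     }, numeric(1)),
                     sjc_total = vapply(seq_len(nrow(tab)), function(i) {
                       sum_junction_counts(tab$SJC_SAMPLE_1[i],
                                           tab$SJC_SAMPLE_2[i], i + 1L, "SJC")
                     }, numeric(1)),
                     delta_psi = tab$IncLevelDifference, pvalue = tab$PValue,
                     fdr = tab$FDR, stringsAsFactors = FALSE)
    ev$anchors <- ancs
    ev$control_psi <- vector("list", nrow(tab))
    event_list(ev, "SE", label)
  }
  test_el <- mk_list(test_tab, te$anchors, "knockdown-excluded")
  bg_el <- attach_control_psi(mk_list(bg_tab, bg$anchors, "native-pool"),
                              control_psi)
  list(test = test_el, background = bg_el, control_psi = control_psi,
       files = files)
}

# Genomic position of the first intronic nt downstream (transcript direction)
# of the cassette exon's 5' splice site; offsets x >= 1 step further into the
# intron.
cassette_donor_positions <- function(anchors, strand, offsets) {
  cas <- anchors[2, ]
  if (strand == "+") cas[2] + offsets - 1L else cas[1] - offsets
}

# Triangular enrichment profile over a 20-nt window centred on the planted
# offset: weight 1 at the centre falling linearly to 0 at +/-10 nt.
PLANT_HALF_WIDTH <- 10L
plant_weights <- function() {
  d <- -PLANT_HALF_WIDTH:PLANT_HALF_WIDTH
  1 - abs(d) / PLANT_HALF_WIDTH
}

#' Generate synthetic coverage, peaks and tracks for fixture events
#'
#' Input coverage is Poisson(`baseline_rate`) per nt over each event's span
#' on its strand; IP coverage adds, in a `planted_fraction` subset of test
#' events, Poisson counts with a triangular profile (peak
#' `planted_amplitude * baseline_rate`, half-width 10 nt) centred
#' `planted_offset` nt downstream of the cassette 5' splice site. Peaks are
#' emitted over the planted windows of carrier events with scores passing
#' the default thresholds. Densities are RPM-scaled by the realized library
#' totals. Optionally one event receives an additional high-amplitude spike
#' (a multicopy-RNA-like artifact) for outlier-robustness experiments; spike
#' draws happen after all base draws, so runs differing only in the spike
#' share the identical base coverage.
#'
#' @param events result of [generate_events()] (or a list with `test` and
#'   `background` [event_list()]s).
#' @param spec the same [fixture_spec()].
#' @param dir optional output directory for bedGraph / BED files
#'   (`ip.pos.bedGraph`, `ip.neg.bedGraph`, `input.pos.bedGraph`,
#'   `input.neg.bedGraph`, `peaks.bed`; minus-strand files store negated
#'   values, the common convention).
#' @param spike_event index of a test event to spike, or `NULL` (default).
#' @param spike_amplitude fold over baseline for the spike (default 1000).
#' @param spike_offset nt downstream of the cassette 5' splice site for the
#'   spike centre (default 250).
#' @return List with `ip` and `input` (strand pairs of [coverage_track()]s),
#'   `peaks` (GRanges), `carriers` (test-event indices carrying the plant),
#'   `totals` and `files`.
#' @export
generate_coverage <- function(events, spec, dir = NULL, spike_event = NULL,
                              spike_amplitude = 1000, spike_offset = 250L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  all_ev <- rbind(cbind(event_spans(events$test), set = "test"),
                  cbind(event_spans(events$background), set = "bg"))
  anchors <- c(events$test$events$anchors, events$background$events$anchors)
  chromlen <- max(all_ev$end) + FIXTURE_GAP
  cov <- list(ip = list("+" = numeric(chromlen), "-" = numeric(chromlen)),
              input = list("+" = numeric(chromlen), "-" = numeric(chromlen)))
  for (i in seq_len(nrow(all_ev))) {
    s <- all_ev$start[i] + 1L
    e <- all_ev$end[i]
    len <- e - s + 1L
    st <- all_ev$strand[i]
    cov$input[[st]][s:e] <- cov$input[[st]][s:e] + rpois(len, spec$baseline_rate)
    cov$ip[[st]][s:e] <- cov$ip[[st]][s:e] + rpois(len, spec$baseline_rate)
  }
  n_test <- length(events$test)
  n_carry <- round(spec$planted_fraction * n_test)
  carriers <- if (n_carry > 0L) sort(sample.int(n_test, n_carry)) else integer(0)
  w <- plant_weights()
  offs <- spec$planted_offset + (-PLANT_HALF_WIDTH:PLANT_HALF_WIDTH)
  peak_rows <- list()
  for (e in carriers) {
    a <- events$test$events$anchors[[e]]
    st <- events$test$events$strand[e]
    g <- cassette_donor_positions(a, st, offs)
    intron_len <- if (st == "+") a[3, 1] - a[2, 2] else a[2, 1] - a[3, 2]
    if (spec$planted_offset + PLANT_HALF_WIDTH > intron_len) {
      warning("planted window exceeds intron boundary; clamped")
    }
    span <- c(all_ev$start[e], all_ev$end[e])
    ok <- g >= span[1] & g < span[2]
    extra <- rpois(sum(ok), spec$planted_amplitude * spec$baseline_rate * w[ok])
    cov$ip[[st]][g[ok] + 1L] <- cov$ip[[st]][g[ok] + 1L] + extra
    peak_rows[[length(peak_rows) + 1L]] <- data.table(
      chrom = FIXTURE_CHROM, start = min(g[ok & w > 0]),
      end = max(g[ok & w > 0]) + 1L,
      name = events$test$events$event_id[e], score = 0L, strand = st,
      log2fold = round(max(3, log2(max(spec$planted_amplitude, 1))), 3),
      neglog10p = 10)
  }
  if (!is.null(spike_event)) {
    a <- events$test$events$anchors[[spike_event]]
    st <- events$test$events$strand[spike_event]
    g <- cassette_donor_positions(a, st, spike_offset + (-PLANT_HALF_WIDTH:PLANT_HALF_WIDTH))
    ok <- g >= 0 & g < chromlen
    extra <- rpois(sum(ok), spike_amplitude * spec$baseline_rate * w[ok])
    cov$ip[[st]][g[ok] + 1L] <- cov$ip[[st]][g[ok] + 1L] + extra
  }
  totals <- list(ip = sum(cov$ip[["+"]]) + sum(cov$ip[["-"]]),
                 input = sum(cov$input[["+"]]) + sum(cov$input[["-"]]))
  mk_tracks <- function(which) {
    tot <- totals[[which]]
    lapply(setNames(c("+", "-"), c("+", "-")), function(s) {
      rpm <- cov[[which]][[s]] * 1e6 / tot
      coverage_track(setNames(list(S4Vectors::Rle(rpm)), FIXTURE_CHROM),
                     s, tot)
    })
  }
  ip_tracks <- mk_tracks("ip")
  input_tracks <- mk_tracks("input")
  peaks_dt <- if (length(peak_rows) > 0L) data.table::rbindlist(peak_rows)
              else data.table(chrom = character(0), start = integer(0),
                              end = integer(0), name = character(0),
                              score = integer(0), strand = character(0),
                              log2fold = numeric(0), neglog10p = numeric(0))
  peaks <- GenomicRanges::GRanges(
    peaks_dt$chrom,
    IRanges::IRanges(start = peaks_dt$start + 1L, end = peaks_dt$end),
    strand = peaks_dt$strand,
    p_value = 10^(-peaks_dt$neglog10p), fold_enrichment = 2^peaks_dt$log2fold)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(ip_pos = file.path(dir, "ip.pos.bedGraph"),
               ip_neg = file.path(dir, "ip.neg.bedGraph"),
               input_pos = file.path(dir, "input.pos.bedGraph"),
               input_neg = file.path(dir, "input.neg.bedGraph"),
               peaks = file.path(dir, "peaks.bed"))
    write_coverage_bedgraph(ip_tracks[["+"]], files[["ip_pos"]])
    write_coverage_bedgraph(negate_track(ip_tracks[["-"]]), files[["ip_neg"]])
    write_coverage_bedgraph(input_tracks[["+"]], files[["input_pos"]])
    write_coverage_bedgraph(negate_track(input_tracks[["-"]]), files[["input_neg"]])
    fwrite(peaks_dt, files[["peaks"]], sep = "\t", col.names = FALSE)
  }
  list(ip = ip_tracks, input = input_tracks, peaks = peaks,
       carriers = carriers, totals = totals, files = files)
}

negate_track <- function(track) {
  coverage_track(lapply(track$cov, function(r) {
    S4Vectors::Rle(-S4Vectors::runValue(r), S4Vectors::runLength(r))
  }), track$strand, track$total_reads)
}

#' Expected meta-region index of the planted enrichment centre
#'
#' For SE geometry under a given config, the planted centre (an intronic
#' offset downstream of the cassette 5' splice site) falls at 0-based index
#' `2 * (exon_offset + intron_offset) + exon_offset + planted_offset - 1`
#' (inside window 3).
#'
#' @param spec a [fixture_spec()].
#' @param config a [map_config()] for SE.
#' @return 0-based meta-region index.
#' @export
planted_index <- function(spec, config = map_config()) {
  stopifnot(config$event_type == "SE")
  2L * (config$exon_offset + config$intron_offset) + config$exon_offset +
    spec$planted_offset - 1L
}
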