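# Alternative-splicing event lists: parsing, filtering, deduplication and
# background classification.

EVENT_TYPES <- c("SE", "A3SS", "A5SS", "MXE", "RI")

# number of exon anchors per event type (transcript order)
N_ANCHORS <- c(SE = 3L, A3SS = 3L, A5SS = 3L, MXE = 4L, RI = 3L)

#' Construct an event list
#'
#' An `event_list` bundles a label with a data frame of splicing events of a
#' single type. Each row is one event; `anchors` is a list column of
#' k x 2 integer matrices (columns `start`, `end`; 0-based half-open,
#' transcript order), `control_psi` a list column of numeric vectors of
#' per-control-dataset percent-spliced-in values (or `NULL`).
#'
#' @param events data.frame with columns `event_id`, `chrom`, `strand`,
#'   `ijc_total`, `sjc_total`, `delta_psi`, `pvalue`, `fdr` and list columns
#'   `anchors` and (optionally) `control_psi`.
#' @param event_type one of `"SE"`, `"A3SS"`, `"A5SS"`, `"MXE"`, `"RI"`.
#' @param label free-text label (e.g. `"knockdown-excluded"`).
#' @return An object of class `event_list`.
#' @export
event_list <- function(events, event_type, label = "") {
  event_type <- match.arg(event_type, EVENT_TYPES)
  stopifnot(is.data.frame(events))
  if (is.null(events$control_psi)) {
    events$control_psi <- vector("list", nrow(events))
  }
  if (nrow(events) > 0L) {
    if (anyDuplicated(events$event_id)) {
      stop("event_ids must be unique within an event list", call. = FALSE)
    }
    validate_events(events, event_type)
  }
  structure(list(label = label, event_type = event_type, events = events),
            class = "event_list")
}

validate_events <- function(df, event_type) {
  k <- N_ANCHORS[[event_type]]
  for (i in seq_len(nrow(df))) {
    a <- df$anchors[[i]]
    if (!is.matrix(a) || nrow(a) != k || ncol(a) != 2L) {
      stop(sprintf("event '%s': expected %d anchor intervals", df$event_id[i], k),
           call. = FALSE)
    }
    if (any(a[, 1] >= a[, 2])) {
      stop(sprintf("event '%s': anchor interval with start >= end", df$event_id[i]),
           call. = FALSE)
    }
  }
  if (any(abs(df$delta_psi) > 1 + 1e-9, na.rm = TRUE) ||
      any(df$pvalue < 0 | df$pvalue > 1, na.rm = TRUE) ||
      any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) {
    stop("delta_psi must lie in [-1,1] and pvalue/fdr in [0,1]", call. = FALSE)
  }
  if (any(df$ijc_total < 0, na.rm = TRUE) || any(df$sjc_total < 0, na.rm = TRUE)) {
    stop("junction counts must be nonnegative", call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(df)
}

#' @export
length.event_list <- function(x) nrow(x$events)

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %s: %d %s event(s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x), x$event_type))
  invisible(x)
}

#' @export
`[.event_list` <- function(x, i) {
  ev <- x$events[i, , drop = FALSE]
  rownames(ev) <- NULL
  event_list(ev, x$event_type, x$label)
}

#' Genomic span of each event
#'
#' Full span from the minimum anchor start to the maximum anchor end.
#'
#' @param x an `event_list`.
#' @return data.frame with `event_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @export
event_spans <- function(x) {
  stopifnot(inherits(x, "event_list"))
  starts <- vapply(x$events$anchors, function(a) min(a[, 1]), numeric(1))
  ends <- vapply(x$events$anchors, function(a) max(a[, 2]), numeric(1))
  data.frame(event_id = x$events$event_id, chrom = x$events$chrom,
             strand = x$events$strand, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

rmats_coord_cols <- function(event_type) {
  switch(event_type,
    SE   = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
             "downstreamES", "downstreamEE"),
    A3SS = ,
    A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
             "flankingES", "flankingEE"),
    MXE  = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base",
             "2ndExonEnd", "upstreamES", "upstreamEE", "downstreamES",
             "downstreamEE"),
    RI   = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
             "downstreamES", "downstreamEE"))
}

RMATS_COMMON_COLS <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
                       "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                       "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen",
                       "PValue", "FDR", "IncLevel1", "IncLevel2",
                       "IncLevelDifference")

sum_junction_counts <- function(s1, s2, line_no, what) {
  vals <- unlist(strsplit(c(s1, s2), ",", fixed = TRUE))
  vals <- vals[nzchar(vals) & vals != "NA"]
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) {
    stop(sprintf("non-numeric %s count on line %d", what, line_no), call. = FALSE)
  }
  sum(num)
}

#' Parse an rMATS JunctionCountsOnly file
#'
#' Reads a tab-separated rMATS 3.x `JunctionCountsOnly.txt` table into an
#' [event_list()]. Coordinates are taken verbatim: `*Start_0base` columns are
#' 0-based and paired `*End` columns are treated as half-open ends, so all
#' internal intervals are 0-based half-open and `length = end - start`.
#' `ijc_total`/`sjc_total` sum every comma-separated replicate value over both
#' sample columns. Anchors are stored in transcript order: SE = (upstream,
#' cassette, downstream); A3SS/A5SS = (long, short, flanking); MXE =
#' (upstream, first, second, downstream); RI = (upstream, retained-intron
#' span, downstream), the retained-intron span being the gap between the two
#' flanking exons.
#'
#' @param path path to the rMATS table.
#' @param event_type one of `"SE"`, `"A3SS"`, `"A5SS"`, `"MXE"`, `"RI"`.
#' @param label label passed to the resulting [event_list()].
#' @return An [event_list()].
#' @export
parse_rmats <- function(path, event_type, label = "") {
  event_type <- match.arg(event_type, EVENT_TYPES)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # comma-separated replicate counts must never be parsed as decimal commas
  char_cols <- c("ID", "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                 "SJC_SAMPLE_2", "IncLevel1", "IncLevel2")
  dt <- fread(path, sep = "\t", header = TRUE, dec = ".",
              colClasses = list(character = char_cols),
              data.table = TRUE, showProgress = FALSE)
  needed <- c(RMATS_COMMON_COLS, rmats_coord_cols(event_type))
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols) > 0L) {
    stop(sprintf("rMATS %s format error: missing column(s) %s", event_type,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(dt)
  if (n == 0L) {
    ev <- data.frame(event_id = character(0), chrom = character(0),
                     strand = character(0), ijc_total = numeric(0),
                     sjc_total = numeric(0), delta_psi = numeric(0),
                     pvalue = numeric(0), fdr = numeric(0),
                     stringsAsFactors = FALSE)
    ev$anchors <- list()
    ev$control_psi <- list()
    return(event_list(ev, event_type, label))
  }
  cc <- rmats_coord_cols(event_type)
  for (col in cc) {
    if (!is.numeric(dt[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[col]]))))[1]
      stop(sprintf("non-numeric coordinate in column %s on line %d", col,
                   bad + 1L), call. = FALSE)
    }
  }
  anchors <- vector("list", n)
  for (i in seq_len(n)) {
    g <- function(col) as.integer(dt[[col]][i])
    a <- switch(event_type,
      SE = rbind(c(g("upstreamES"), g("upstreamEE")),
                 c(g("exonStart_0base"), g("exonEnd")),
                 c(g("downstreamES"), g("downstreamEE"))),
      A3SS = ,
      A5SS = rbind(c(g("longExonStart_0base"), g("longExonEnd")),
                   c(g("shortES"), g("shortEE")),
                   c(g("flankingES"), g("flankingEE"))),
      MXE = rbind(c(g("upstreamES"), g("upstreamEE")),
                  c(g("1stExonStart_0base"), g("1stExonEnd")),
                  c(g("2ndExonStart_0base"), g("2ndExonEnd")),
                  c(g("downstreamES"), g("downstreamEE"))),
      RI = {
        up <- c(g("upstreamES"), g("upstreamEE"))
        dn <- c(g("downstreamES"), g("downstreamEE"))
        # retained intron = genomic gap between the two flanking exons
        left <- if (up[1] <= dn[1]) up else dn
        right <- if (up[1] <= dn[1]) dn else up
        rbind(up, c(left[2], right[1]), dn)
      })
    colnames(a) <- c("start", "end")
    rownames(a) <- NULL
    anchors[[i]] <- a
  }
  ijc <- numeric(n)
  sjc <- numeric(n)
  for (i in seq_len(n)) {
    ijc[i] <- sum_junction_counts(as.character(dt$IJC_SAMPLE_1[i]),
                                  as.character(dt$IJC_SAMPLE_2[i]), i + 1L, "IJC")
    sjc[i] <- sum_junction_counts(as.character(dt$SJC_SAMPLE_1[i]),
                                  as.character(dt$SJC_SAMPLE_2[i]), i + 1L, "SJC")
  }
  ev <- data.frame(event_id = as.character(dt$ID), chrom = as.character(dt$chr),
                   strand = as.character(dt$strand), ijc_total = ijc,
                   sjc_total = sjc,
                   delta_psi = as.numeric(dt$IncLevelDifference),
                   pvalue = as.numeric(dt$PValue), fdr = as.numeric(dt$FDR),
                   stringsAsFactors = FALSE)
  ev$anchors <- anchors
  ev$control_psi <- vector("list", n)
  event_list(ev, event_type, label)
}

#' Parse MISO-style skipped-exon annotations
#'
#' Minimal converter for MISO SE event identifiers of the form
#' `chrom:start:end:strand@chrom:start:end:strand@chrom:start:end:strand`
#' (exons in transcript order: upstream, cassette, downstream; MISO
#' coordinates are 1-based inclusive and are converted to 0-based half-open).
#' One identifier per line; statistics columns are not part of the format, so
#' `delta_psi`, `pvalue` and `fdr` are set to `NA` and junction counts to 0.
#' Only the SE type is supported.
#'
#' @param path path to a text file with one MISO SE identifier per line.
#' @param label label for the resulting [event_list()].
#' @return An [event_list()] of SE events.
#' @export
parse_miso <- function(path, label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n <- length(lines)
  anchors <- vector("list", n)
  chroms <- character(n)
  strands <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i], "@", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop(sprintf("MISO SE format error on line %d: expected 3 exons", i),
           call. = FALSE)
    }
    ex <- lapply(parts, function(p) strsplit(p, ":", fixed = TRUE)[[1]])
    if (any(vapply(ex, length, integer(1)) != 4L)) {
      stop(sprintf("MISO SE format error on line %d", i), call. = FALSE)
    }
    chroms[i] <- ex[[1]][1]
    strands[i] <- ex[[1]][4]
    a <- t(vapply(ex, function(e) {
      c(as.integer(e[2]) - 1L, as.integer(e[3]))
    }, integer(2)))
    colnames(a) <- c("start", "end")
    anchors[[i]] <- a
  }
  ev <- data.frame(event_id = lines, chrom = chroms, strand = strands,
                   ijc_total = rep(0, n), sjc_total = rep(0, n),
                   delta_psi = rep(NA_real_, n), pvalue = rep(NA_real_, n),
                   fdr = rep(NA_real_, n), stringsAsFactors = FALSE)
  ev$anchors <- anchors
  ev$control_psi <- vector("list", n)
  event_list(ev, "SE", label)
}

#' Filter events for significant differential splicing
#'
#' Keeps events with `|delta_psi| >= dpsi_min`, `pvalue <= p_max` and
#' `fdr <= fdr_max`. Sign convention: positive delta Psi means the exon is
#' more included upon RBP knockdown, negative means more excluded, so
#' `direction = "included"` keeps `delta_psi > 0` and `"excluded"` keeps
#' `delta_psi < 0`.
#'
#' @param events an [event_list()].
#' @param dpsi_min minimum absolute change in percent spliced in (default 0.05).
#' @param p_max maximum p-value (default 0.05).
#' @param fdr_max maximum FDR (default 0.1).
#' @param direction `"included"`, `"excluded"` or `"both"`.
#' @return A filtered [event_list()].
#' @export
filter_significant <- function(events, dpsi_min = 0.05, p_max = 0.05,
                               fdr_max = 0.1,
                               direction = c("both", "included", "excluded")) {
  stopifnot(inherits(events, "event_list"))
  direction <- match.arg(direction)
  stopifnot(dpsi_min >= 0, dpsi_min <= 1, p_max >= 0, p_max <= 1,
            fdr_max >= 0, fdr_max <= 1)
  df <- events$events
  keep <- !is.na(df$delta_psi) & abs(df$delta_psi) >= dpsi_min &
    !is.na(df$pvalue) & df$pvalue <= p_max &
    !is.na(df$fdr) & df$fdr <= fdr_max
  keep <- switch(direction,
                 both = keep,
                 included = keep & df$delta_psi > 0,
                 excluded = keep & df$delta_psi < 0)
  events[which(keep)]
}

#' Deduplicate overlapping events
#'
#' Groups events by transitive overlap of their full genomic spans (minimum
#' anchor start to maximum anchor end) on the same chromosome and strand, and
#' keeps from each group the event with the highest total inclusion junction
#' count (`ijc_total`); ties are broken by lexicographically smallest
#' `event_id`. Output follows genomic order (chromosome, then span start).
#'
#' @param events an [event_list()].
#' @return An [event_list()] of resolved unique events.
#' @export
deduplicate_overlapping <- function(events) {
  stopifnot(inherits(events, "event_list"))
  n <- length(events)
  if (n <= 1L) return(events)
  sp <- event_spans(events)
  sp$idx <- seq_len(n)
  keep_idx <- integer(0)
  for (key in split(seq_len(n), paste(sp$chrom, sp$strand, sep = "\r"))) {
    s <- sp[key, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    grp_start <- 1L
    cur_end <- s$end[1]
    flush <- function(from, to) {
      g <- s[from:to, , drop = FALSE]
      best <- which(g$ijc_total_ == max(g$ijc_total_))
      if (length(best) > 1L) {
        best <- best[order(g$event_id[best])][1]
      }
      g$idx[best]
    }
    s$ijc_total_ <- events$events$ijc_total[s$idx]
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start[i] < cur_end) { # half-open overlap => same group
        cur_end <- max(cur_end, s$end[i])
      } else {
        keep_idx <- c(keep_idx, flush(grp_start, i - 1L))
        grp_start <- i
        cur_end <- s$end[i]
      }
    }
    keep_idx <- c(keep_idx, flush(grp_start, nrow(s)))
  }
  # genomic output order
  ksp <- sp[match(keep_idx, sp$idx), , drop = FALSE]
  keep_idx <- keep_idx[order(ksp$chrom, ksp$start, ksp$end)]
  events[keep_idx]
}

#' Classify events into background sets by control percent spliced in
#'
#' Uses per-control-dataset Psi values attached to each event
#' (`control_psi`):
#' \itemize{
#'   \item `constitutive`: Psi equal to 1 in every control (exclusion never
#'     observed);
#'   \item `native`: `0.05 < Psi < 0.95` in at least `min_fraction` of
#'     controls;
#'   \item `native_included`: native and `Psi > 0.67` in at least
#'     `min_fraction` of controls;
#'   \item `native_central`: native and `0.33 < Psi < 0.67` likewise;
#'   \item `native_excluded`: native and `Psi < 0.33` likewise.
#' }
#' The three native subsets are restricted to members of `native`, enforcing
#' the containment invariant. An event may fail all classes and appear in no
#' set. Events without any control Psi are dropped from all sets with a
#' warning.
#'
#' @param events an [event_list()] whose events carry `control_psi`.
#' @param min_fraction minimum fraction of control datasets that must satisfy
#'   a class criterion (default 0.5).
#' @return A `background_sets` object: a list with `event_list` components
#'   `constitutive`, `native`, `native_included`, `native_central`,
#'   `native_excluded`.
#' @export
classify_background <- function(events, min_fraction = 0.5) {
  stopifnot(inherits(events, "event_list"), min_fraction > 0, min_fraction <= 1)
  psi <- events$events$control_psi
  has <- vapply(psi, function(p) length(p) > 0L, logical(1))
  if (any(!has)) {
    warning(sprintf("%d event(s) without control Psi values excluded from all background sets",
                    sum(!has)))
  }
  frac <- function(fun) {
    vapply(seq_along(psi), function(i) {
      if (!has[i]) return(0)
      mean(fun(psi[[i]]))
    }, numeric(1))
  }
  constitutive <- has & vapply(seq_along(psi), function(i) {
    has[i] && all(psi[[i]] == 1)
  }, logical(1))
  native <- frac(function(p) p > 0.05 & p < 0.95) >= min_fraction & has
  included <- native & frac(function(p) p > 0.67) >= min_fraction
  central <- native & frac(function(p) p > 0.33 & p < 0.67) >= min_fraction
  excluded <- native & frac(function(p) p < 0.33) >= min_fraction
  relabel <- function(mask, lab) {
    out <- events[which(mask)]
    out$label <- lab
    out
  }
  structure(list(constitutive = relabel(constitutive, "constitutive"),
                 native = relabel(native, "native"),
                 native_included = relabel(included, "native-included"),
                 native_central = relabel(central, "native-central"),
                 native_excluded = relabel(excluded, "native-excluded")),
            class = "background_sets")
}

#' @export
print.background_sets <- function(x, ...) {
  cat("<background_sets>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %d events\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Attach control Psi values to an event list
#'
#' @param events an [event_list()].
#' @param psi_table data.frame with an `event_id` column and one numeric
#'   column per control dataset (as read by [read_control_psi()]).
#' @return The [event_list()] with `control_psi` filled in.
#' @export
attach_control_psi <- function(events, psi_table) {
  stopifnot(inherits(events, "event_list"), "event_id" %in% names(psi_table))
  m <- match(events$events$event_id, as.character(psi_table$event_id))
  num_cols <- setdiff(names(psi_table), "event_id")
  ev <- events$events
  for (i in seq_len(nrow(ev))) {
    if (!is.na(m[i])) {
      v <- as.numeric(psi_table[m[i], num_cols])
      ev$control_psi[[i]] <- v[!is.na(v)]
    }
  }
  event_list(ev, events$event_type, events$label)
}

#' Read a control Psi table
#'
#' Tab-separated table: `event_id` plus one column per control dataset.
#'
#' @param path file path.
#' @return A data.frame.
#' @export
read_control_psi <- function(path) {
  as.data.frame(fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = "event_id"),
                      showProgress = FALSE))
}

#' Write resolved events as BED6 and a TSV mirror
#'
#' BED6 columns: span (0-based half-open), event_id, `ijc_total` as score,
#' strand. The TSV mirrors all scalar event fields plus the span.
#'
#' @param events an [event_list()].
#' @param prefix output path prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_events <- function(events, prefix) {
  sp <- event_spans(events)
  bed <- data.table(chrom = sp$chrom, start = sp$start, end = sp$end,
                    name = sp$event_id, score = events$events$ijc_total,
                    strand = sp$strand)
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  tsv <- data.table(event_id = sp$event_id, event_type = events$event_type,
                    chrom = sp$chrom, strand = sp$strand, span_start = sp$start,
                    span_end = sp$end, ijc_total = events$events$ijc_total,
                    sjc_total = events$events$sjc_total,
                    delta_psi = events$events$delta_psi,
                    pvalue = events$events$pvalue, fdr = events$events$fdr)
  fwrite(tsv, tsv_path, sep = "\t")
  invisible(c(bed = bed_path, tsv = tsv_path))
}
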