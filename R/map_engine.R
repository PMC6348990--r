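# Signal matrices over meta regions: extraction, normalization, outlier
# trimming and aggregation into splicing maps.

signal_matrix <- function(event_ids, values, missing, norm_method = "raw",
                          ip_total_reads = NA_real_,
                          input_total_reads = NA_real_, event_type = "SE") {
  stopifnot(is.matrix(values), is.matrix(missing),
            all(dim(values) == dim(missing)))
  if (any(!is.finite(values[!missing]))) {
    stop("signal values must be finite where not missing", call. = FALSE)
  }
  structure(list(event_ids = event_ids, values = values, missing = missing,
                 norm_method = norm_method, ip_total_reads = ip_total_reads,
                 input_total_reads = input_total_reads,
                 event_type = event_type),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d event(s) x %d position(s), norm = %s\n",
              nrow(x$values), ncol(x$values), x$norm_method))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Extract per-event signal over meta regions
#'
#' Fills an events x positions matrix with the read density at each region
#' position on the event's strand. Masked positions become missing.
#' Chromosomes absent from the track yield zero densities with a warning.
#'
#' @param regions list of `meta_region`s of equal length (see
#'   [build_meta_regions()]).
#' @param tracks named list with `"+"` and `"-"` [coverage_track()]s.
#' @return A `signal_matrix` with `norm_method = "raw"` and `ip_total_reads`
#'   taken from the tracks.
#' @export
extract_matrix <- function(regions, tracks) {
  stopifnot(length(regions) > 0L)
  L <- length(regions[[1]]$positions)
  if (!all(vapply(regions, function(r) length(r$positions), integer(1)) == L)) {
    stop("all regions must have the same length", call. = FALSE)
  }
  n <- length(regions)
  vals <- matrix(0, n, L)
  miss <- matrix(FALSE, n, L)
  absent <- character(0)
  for (i in seq_len(n)) {
    r <- regions[[i]]
    tr <- tracks[[r$strand]]
    if (is.null(tr)) stop("missing track for strand ", r$strand, call. = FALSE)
    if (is.null(tr$cov[[r$chrom]])) absent <- union(absent, r$chrom)
    vals[i, ] <- track_values(tr, r$chrom, r$positions)
    miss[i, ] <- r$mask
  }
  if (length(absent) > 0L) {
    warning("chromosome(s) absent from track, densities set to 0: ",
            paste(absent, collapse = ", "))
  }
  vals[miss] <- NA_real_
  signal_matrix(vapply(regions, `[[`, character(1), "event_id"),
                vals, miss, "raw",
                ip_total_reads = tracks[["+"]]$total_reads,
                event_type = regions[[1]]$event_type)
}

check_matching <- function(ip, input) {
  if (!all(dim(ip$values) == dim(input$values)) ||
      !identical(ip$event_ids, input$event_ids)) {
    stop("IP and input matrices must share dimensions and event order",
         call. = FALSE)
  }
}

per_event_unit_scale <- function(d, miss, pc, pc_per_position) {
  n_unmasked <- rowSums(!miss)
  denom <- rowSums(abs(d), na.rm = TRUE) +
    if (pc_per_position) n_unmasked * pc else pc
  out <- d / denom
  out[denom == 0 & !miss] <- 0
  all_masked <- n_unmasked == 0L
  if (any(all_masked)) {
    warning(sprintf("%d event(s) fully masked; normalized rows are missing",
                    sum(all_masked)))
    out[all_masked, ] <- NA_real_
  }
  out
}

#' Background-subtraction normalization
#'
#' Per event, input read density is subtracted from IP read density and the
#' difference vector is scaled to (pseudocounted) unit absolute sum:
#' `out[i] = d[i] / (sum_j |d[j]| + n_unmasked * pc)` with
#' `pc = pseudocount_reads * 1e6 / ip_total_reads` (one pseudocount per
#' position; set `pc_per_position = FALSE` in the config to add it once).
#' This equalizes each event's contribution to the map.
#'
#' @param ip,input `signal_matrix` objects with matching dimensions and event
#'   order (RPM densities).
#' @param config a [map_config()].
#' @return A `signal_matrix` with `norm_method = "subtraction"`.
#' @export
normalize_subtraction <- function(ip, input, config = map_config()) {
  check_matching(ip, input)
  if (is.na(ip$ip_total_reads)) {
    stop("IP library size (total_reads) required for pseudocount scaling",
         call. = FALSE)
  }
  d <- ip$values - input$values
  pc <- config$pseudocount_reads * 1e6 / ip$ip_total_reads
  out <- per_event_unit_scale(d, ip$missing | input$missing, pc,
                              config$pc_per_position)
  sm <- signal_matrix(ip$event_ids, out, ip$missing | input$missing,
                      "subtraction", ip$ip_total_reads, input$ip_total_reads,
                      ip$event_type)
  sm
}

#' Raw-mode normalization
#'
#' IP density only (no input), scaled per event exactly like
#' [normalize_subtraction()] with an identically-zero input so the two modes
#' are directly comparable; `raw_unscaled = TRUE` in the config skips the
#' scaling and keeps plain RPM.
#'
#' @param ip a `signal_matrix` of IP densities.
#' @param config a [map_config()].
#' @return A `signal_matrix` with `norm_method = "raw"`.
#' @export
normalize_raw <- function(ip, config = map_config()) {
  if (config$raw_unscaled) {
    return(signal_matrix(ip$event_ids, ip$values, ip$missing, "raw",
                         ip$ip_total_reads, NA_real_, ip$event_type))
  }
  if (is.na(ip$ip_total_reads)) {
    stop("IP library size (total_reads) required for pseudocount scaling",
         call. = FALSE)
  }
  pc <- config$pseudocount_reads * 1e6 / ip$ip_total_reads
  out <- per_event_unit_scale(ip$values, ip$missing, pc, config$pc_per_position)
  signal_matrix(ip$event_ids, out, ip$missing, "raw", ip$ip_total_reads,
                NA_real_, ip$event_type)
}

#' Relative information at one position
#'
#' The per-position score `p * log2(p / q)`, an adaptation of the
#' Kullback-Leibler divergence summand, where `p` and `q` are the fractions
#' of total IP and input reads overlapping the position.
#'
#' @param p,q read probabilities in (0, 1].
#' @return `p * log2(p / q)`.
#' @export
relative_information <- function(p, q) {
  out <- p * log2(p / q)
  out[p == 0] <- 0 # x*log(x) -> 0 as x -> 0
  out
}

#' Relative-information (entropy) normalization
#'
#' Converts RPM densities back to read counts, adds a pseudocount of
#' `pseudocount_reads` to each position in both libraries, forms read
#' probabilities `p_i = (ip_count_i + pc) / (ip_total + pc)` (and `q_i`
#' analogously with the input library total), and scores each position as
#' `p_i * log2(p_i / q_i)`. No per-event renormalization is applied: events
#' with greater read density dominate the averaged map.
#'
#' @param ip,input `signal_matrix` objects with matching dimensions and event
#'   order (RPM densities).
#' @param config a [map_config()].
#' @return A `signal_matrix` with `norm_method = "entropy"`.
#' @export
normalize_entropy <- function(ip, input, config = map_config()) {
  check_matching(ip, input)
  ip_tot <- ip$ip_total_reads
  in_tot <- input$ip_total_reads
  if (is.na(ip_tot) || is.na(in_tot) || ip_tot <= 0 || in_tot <= 0) {
    stop("positive IP and input library sizes required for entropy normalization",
         call. = FALSE)
  }
  pc <- config$pseudocount_reads
  p <- (ip$values * ip_tot / 1e6 + pc) / (ip_tot + pc)
  q <- (input$values * in_tot / 1e6 + pc) / (in_tot + pc)
  out <- relative_information(p, q)
  signal_matrix(ip$event_ids, out, ip$missing | input$missing, "entropy",
                ip_tot, in_tot, ip$event_type)
}

#' Outlier-trimmed per-position means
#'
#' At each position, the `k = floor(n * (1 - conf) / 2)` largest and `k`
#' smallest of the `n` non-missing values are removed before averaging, so
#' the middle `conf` fraction of values is kept (default: middle 95%).
#' Positions where fewer than one value survives are recorded as missing.
#'
#' @param matrix a `signal_matrix` or plain numeric matrix (`NA` = missing).
#' @param conf fraction of values kept, in (0, 1].
#' @param keep_values if `TRUE` (default), also return the per-position
#'   survivor sets.
#' @return List with `mean_curve`, `n_contributing` and (optionally)
#'   `values`, a list of survivor vectors per position.
#' @export
trim_outliers <- function(matrix, conf = 0.95, keep_values = TRUE) {
  stopifnot(conf > 0, conf <= 1)
  if (inherits(matrix, "signal_matrix")) {
    x <- matrix$values
    x[matrix$missing] <- NA_real_
  } else {
    x <- matrix
  }
  st <- cpp_trimmed_col_stats(x, conf)
  out <- list(mean_curve = st$mean, n_contributing = as.integer(st$n))
  if (keep_values) {
    out$values <- lapply(seq_len(ncol(x)), function(j) {
      v <- sort(x[, j][!is.na(x[, j])])
      n <- length(v)
      k <- floor(n * (1 - conf) / 2)
      if (n - 2 * k < 1) return(numeric(0))
      v[(k + 1):(n - k)]
    })
  }
  out
}

peak_indicator_tracks <- function(peaks) {
  st <- as.character(GenomicRanges::strand(peaks))
  one <- function(s) {
    # '*' peaks match both strands
    p <- peaks[st == s | st == "*"]
    if (length(p) == 0L) return(coverage_track(list(), s))
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(p),
                                 IRanges::IRanges(GenomicRanges::start(p),
                                                  GenomicRanges::end(p)),
                                 score = rep(1, length(p)))
    cov <- granges_to_cov(gr)
    cov <- lapply(cov, function(r) {
      S4Vectors::Rle(as.numeric(S4Vectors::runValue(r) > 0),
                     S4Vectors::runLength(r))
    })
    coverage_track(cov, s)
  }
  list("+" = one("+"), "-" = one("-"))
}

#' Binary peak-overlap matrix over meta regions
#'
#' Marks each unmasked position of each event 1 if it lies within a
#' same-strand peak and 0 otherwise.
#'
#' @param regions list of `meta_region`s.
#' @param peaks a peak [GenomicRanges::GRanges] (see [load_peaks()]),
#'   pre-filtered by thresholds.
#' @return A binary `signal_matrix`.
#' @export
peak_overlap_matrix <- function(regions, peaks) {
  tracks <- peak_indicator_tracks(peaks)
  suppressWarnings(extract_matrix(regions, tracks))
}

#' Peak-fraction splicing map
#'
#' The mean curve at position i is the fraction of events whose unmasked
#' position i lies within a same-strand peak (count divided by the number of
#' events with that position unmasked).
#'
#' @param regions non-empty list of `meta_region`s of one event type.
#' @param peaks a peak [GenomicRanges::GRanges], pre-filtered by thresholds.
#' @param label condition label for the resulting map.
#' @return A `splicing_map` with one condition.
#' @export
peak_fraction_map <- function(regions, peaks, label = "events") {
  if (length(regions) == 0L) stop("empty region list", call. = FALSE)
  m <- peak_overlap_matrix(regions, peaks)
  ok <- !m$missing
  n_ok <- colSums(ok)
  hits <- colSums(m$values == 1 & ok, na.rm = TRUE)
  curve <- ifelse(n_ok > 0L, hits / n_ok, NA_real_)
  new_splicing_map(regions[[1]], conditions = setNames(list(
    list(mean_curve = curve, n_contributing = as.integer(n_ok),
         lower_bound = NULL, upper_bound = NULL, pvalues = NULL,
         n_events = length(regions))), label))
}

new_splicing_map <- function(template_region, conditions) {
  structure(list(event_type = template_region$event_type,
                 n_windows = template_region$n_windows,
                 window_size = template_region$window_size,
                 L = template_region$n_windows * template_region$window_size,
                 conditions = conditions),
            class = "splicing_map")
}

#' @export
print.splicing_map <- function(x, ...) {
  cat(sprintf("<splicing_map> %s, %d windows x %d nt\n", x$event_type,
              x$n_windows, x$window_size))
  for (nm in names(x$conditions)) {
    co <- x$conditions[[nm]]
    cat(sprintf("  %-24s n = %d, mean curve peak = %.4g at index %d\n", nm,
                co$n_events, max(co$mean_curve, na.rm = TRUE),
                which.max(co$mean_curve)))
  }
  invisible(x)
}

#' @export
as.data.frame.splicing_map <- function(x, ...) {
  do.call(rbind, lapply(names(x$conditions), function(nm) {
    co <- x$conditions[[nm]]
    data.frame(condition = nm, position = seq_along(co$mean_curve) - 1L,
               mean = co$mean_curve, n = co$n_contributing,
               lower = if (is.null(co$lower_bound)) NA_real_ else co$lower_bound,
               upper = if (is.null(co$upper_bound)) NA_real_ else co$upper_bound,
               stringsAsFactors = FALSE)
  }))
}

position_labels <- function(config) {
  ws <- config$exon_offset + config$intron_offset
  nw <- n_windows(config$event_type)
  unlist(lapply(seq_len(nw), function(w) {
    sprintf("w%d.%03d", w, seq_len(ws) - 1L)
  }))
}

write_matrix_csv <- function(m, path, labels) {
  dt <- as.data.table(m$values)
  data.table::setnames(dt, labels)
  dt <- cbind(data.table(event_id = m$event_ids), dt)
  fwrite(dt, path, na = "NA")
  invisible(path)
}

#' Build splicing maps for one or more event lists
#'
#' Orchestrates the pipeline for each event list: meta-region construction,
#' signal extraction, normalization (per `config$norm_method`: raw = IP only,
#' subtraction, entropy), outlier trimming and aggregation (density mode), or
#' binary peak-overlap fractions (peak mode). Optionally writes per-event raw
#' and normalized matrices and the mean curves as CSV.
#'
#' @param event_lists named list of [event_list()]s (all one event type).
#' @param mode `"density"` or `"peak"`.
#' @param sources list with components `ip` and (optionally) `input` (strand
#'   pairs of [coverage_track()]s, density mode) and/or `peaks` (a
#'   [GenomicRanges::GRanges], peak mode).
#' @param config a [map_config()].
#' @param out_prefix if non-`NULL`, prefix for CSV exports
#'   (`<prefix>.<label>.raw_density.csv`, `<prefix>.<label>.normed.csv`,
#'   `<prefix>.means.csv`).
#' @return List with `map` (a `splicing_map` over all conditions),
#'   `matrices` (per label: list of `raw` and `normed` `signal_matrix`), and
#'   `regions` (per label).
#' @export
build_map <- function(event_lists, mode = c("density", "peak"), sources,
                      config = map_config(), out_prefix = NULL) {
  mode <- match.arg(mode)
  if (inherits(event_lists, "event_list")) {
    event_lists <- list(event_lists)
  }
  if (is.null(names(event_lists)) || any(!nzchar(names(event_lists)))) {
    names(event_lists) <- vapply(seq_along(event_lists), function(i) {
      lab <- event_lists[[i]]$label
      if (nzchar(lab)) lab else paste0("list", i - 1L)
    }, character(1))
  }
  et <- unique(vapply(event_lists, `[[`, character(1), "event_type"))
  if (length(et) != 1L) stop("event lists must share one event type", call. = FALSE)
  if (mode == "density" && is.null(sources$ip)) {
    stop("density mode requires IP coverage tracks", call. = FALSE)
  }
  if (mode == "peak" && is.null(sources$peaks)) {
    stop("peak mode requires a peak set", call. = FALSE)
  }
  if (mode == "density" && config$norm_method %in% c("subtraction", "entropy") &&
      is.null(sources$input)) {
    stop(sprintf("%s normalization requires input tracks; use norm_method = 'raw' for IP-only maps",
                 config$norm_method), call. = FALSE)
  }
  conditions <- list()
  matrices <- list()
  regions_out <- list()
  labels <- position_labels(config)
  mean_rows <- list()
  for (nm in names(event_lists)) {
    el <- event_lists[[nm]]
    regions <- build_meta_regions(el, config)
    regions_out[[nm]] <- regions
    if (mode == "peak") {
      pm <- peak_fraction_map(regions, sources$peaks, label = nm)
      conditions[[nm]] <- pm$conditions[[nm]]
      matrices[[nm]] <- list(raw = peak_overlap_matrix(regions, sources$peaks),
                             normed = NULL)
      mean_rows[[nm]] <- conditions[[nm]]$mean_curve
      next
    }
    ip_m <- extract_matrix(regions, sources$ip)
    normed <- switch(config$norm_method,
      raw = normalize_raw(ip_m, config),
      subtraction = {
        input_m <- extract_matrix(regions, sources$input)
        normalize_subtraction(ip_m, input_m, config)
      },
      entropy = {
        input_m <- extract_matrix(regions, sources$input)
        normalize_entropy(ip_m, input_m, config)
      })
    tr <- trim_outliers(normed, conf = config$conf, keep_values = FALSE)
    conditions[[nm]] <- list(mean_curve = tr$mean_curve,
                             n_contributing = tr$n_contributing,
                             lower_bound = NULL, upper_bound = NULL,
                             pvalues = NULL, n_events = length(el))
    matrices[[nm]] <- list(raw = ip_m, normed = normed)
    mean_rows[[nm]] <- tr$mean_curve
    if (!is.null(out_prefix)) {
      write_matrix_csv(ip_m, sprintf("%s.%s.raw_density.csv", out_prefix, nm),
                       labels)
      write_matrix_csv(normed, sprintf("%s.%s.normed.csv", out_prefix, nm),
                       labels)
    }
  }
  if (!is.null(out_prefix)) {
    mdt <- as.data.table(do.call(rbind, mean_rows))
    data.table::setnames(mdt, labels)
    mdt <- cbind(data.table(condition = names(mean_rows)), mdt)
    fwrite(mdt, paste0(out_prefix, ".means.csv"), na = "NA")
  }
  template <- regions_out[[1]][[1]]
  list(map = new_splicing_map(template, conditions), matrices = matrices,
       regions = regions_out)
}
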