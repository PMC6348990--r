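# CLIP signal sources: strand-specific coverage tracks, peak interval sets
# and 5' read-end coverage.

#' Construct a coverage track
#'
#' A `coverage_track` stores strand-specific read density as one
#' run-length-encoded vector per chromosome (values in RPM; querying an
#' absent position or chromosome returns 0).
#'
#' @param cov named list of [S4Vectors::Rle] numeric vectors, one per
#'   chromosome, value at index i = density at 0-based position i - 1.
#' @param strand `"+"` or `"-"`.
#' @param total_reads library size used for RPM scaling (may be `NA` when
#'   unknown; operations that need it will then error).
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(cov, strand, total_reads = NA_real_) {
  stopifnot(strand %in% c("+", "-"), is.list(cov) || is(cov, "RleList"))
  cov <- as.list(cov)
  for (r in cov) {
    v <- S4Vectors::runValue(r)
    if (any(!is.finite(v))) stop("coverage values must be finite", call. = FALSE)
  }
  # cache run ends per chromosome so positional queries avoid re-scanning
  ends <- lapply(cov, function(r) cumsum(S4Vectors::runLength(r)))
  structure(list(strand = strand, cov = cov, ends = ends,
                 total_reads = as.numeric(total_reads)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> strand %s, %d chromosome(s), total_reads = %s\n",
              x$strand, length(x$cov),
              if (is.na(x$total_reads)) "NA" else format(x$total_reads)))
  invisible(x)
}

# value of an Rle at arbitrary 1-based indices without decoding
rle_at <- function(r, idx, ends = cumsum(S4Vectors::runLength(r))) {
  vals <- S4Vectors::runValue(r)
  out <- numeric(length(idx))
  inside <- idx >= 1L & idx <= ends[length(ends)]
  if (any(inside)) {
    k <- findInterval(idx[inside] - 0.5, ends) + 1L
    out[inside] <- vals[k]
  }
  out
}

#' Query a coverage track at 0-based genomic positions
#'
#' @param track a [coverage_track()].
#' @param chrom chromosome name.
#' @param pos0 integer vector of 0-based positions.
#' @return Numeric densities; 0 for absent chromosomes or positions.
#' @export
track_values <- function(track, chrom, pos0) {
  r <- track$cov[[chrom]]
  if (is.null(r)) return(numeric(length(pos0)))
  ends <- track$ends[[chrom]]
  if (is.null(ends)) ends <- cumsum(S4Vectors::runLength(r))
  rle_at(r, as.integer(pos0) + 1L, ends)
}

granges_to_cov <- function(gr, absolute = FALSE) {
  sc <- as.numeric(gr$score)
  if (absolute) sc <- abs(sc)
  cov <- GenomicRanges::coverage(gr, weight = sc)
  out <- as.list(cov)
  lapply(out, function(r) S4Vectors::Rle(as.numeric(S4Vectors::runValue(r)),
                                         S4Vectors::runLength(r)))
}

read_track_file <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bw", "bigwig")) {
    gr <- rtracklayer::import(path, format = "BigWig")
  } else if (ext %in% c("bedgraph", "bdg", "bg", "txt")) {
    if (file.size(path) == 0L) {
      return(GenomicRanges::GRanges(score = numeric(0)))
    }
    gr <- rtracklayer::import(path, format = "bedGraph")
  } else {
    stop("unrecognized coverage format (expect .bw/.bigWig or .bedGraph/.bdg/.bg): ",
         path, call. = FALSE)
  }
  gr
}

#' Load a strand pair of coverage tracks
#'
#' Reads bigWig or bedGraph files (dialect by extension), one per strand.
#' Values in the negative-strand file are commonly stored negated; by default
#' their absolute value is taken (`neg_values = "keep"` disables this).
#' Densities are assumed to be pre-scaled to RPM.
#'
#' @param pos_strand_file,neg_strand_file file paths.
#' @param total_reads library size used for RPM scaling; required for
#'   pseudocount accounting in normalization (stored as `NA` when absent).
#' @param neg_values `"abs"` (default) or `"keep"`.
#' @return Named list with `"+"` and `"-"` [coverage_track()]s.
#' @export
load_coverage <- function(pos_strand_file, neg_strand_file,
                          total_reads = NULL, neg_values = c("abs", "keep")) {
  neg_values <- match.arg(neg_values)
  if (missing(pos_strand_file) || missing(neg_strand_file)) {
    stop("both strand files are required", call. = FALSE)
  }
  pos_gr <- read_track_file(pos_strand_file)
  neg_gr <- read_track_file(neg_strand_file)
  if (is.null(total_reads)) total_reads <- NA_real_
  list("+" = coverage_track(granges_to_cov(pos_gr), "+", total_reads),
       "-" = coverage_track(granges_to_cov(neg_gr, absolute = neg_values == "abs"),
                            "-", total_reads))
}

#' Collapse reads to 5' terminal positions
#'
#' Each read contributes density `1e6 / total_reads` at exactly one position:
#' the interval start for `'+'` reads and `end - 1` for `'-'` reads (0-based
#' half-open), the position diagnostic of the reverse-transcriptase stop at
#' the crosslink site. Records without strand are skipped with a warning.
#'
#' @param reads a [GenomicRanges::GRanges] of read alignments, or a path to a
#'   stranded BED6 file.
#' @param total_reads library size for RPM scaling.
#' @return Named list with `"+"` and `"-"` [coverage_track()]s.
#' @export
five_prime_collapse <- function(reads, total_reads) {
  stopifnot(is.numeric(total_reads), total_reads > 0)
  if (is.character(reads)) {
    dt <- fread(reads, header = FALSE, sep = "\t", showProgress = FALSE)
    if (ncol(dt) < 6L) stop("stranded BED6 required for 5' collapse", call. = FALSE)
    reads <- GenomicRanges::GRanges(
      as.character(dt[[1]]),
      IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]]),
      strand = as.character(dt[[6]]))
  }
  st <- as.character(GenomicRanges::strand(reads))
  bad <- !(st %in% c("+", "-"))
  if (any(bad)) {
    warning(sprintf("%d read(s) without strand skipped", sum(bad)))
    reads <- reads[!bad]
    st <- st[!bad]
  }
  rpm <- 1e6 / total_reads
  one_strand <- function(s) {
    r <- reads[st == s]
    if (length(r) == 0L) {
      return(coverage_track(list(), s, total_reads))
    }
    p <- if (s == "+") GenomicRanges::start(r) else GenomicRanges::end(r)
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(r),
                                 IRanges::IRanges(start = p, width = 1L),
                                 score = rep(rpm, length(r)))
    coverage_track(granges_to_cov(gr), s, total_reads)
  }
  list("+" = one_strand("+"), "-" = one_strand("-"))
}

#' Write a coverage track as bedGraph
#'
#' Emits one line per nonzero run, 0-based half-open, tab separated. Writing
#' and re-loading reproduces every queried value exactly.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_bedgraph <- function(track, path) {
  recs <- list()
  for (chrom in names(track$cov)) {
    r <- track$cov[[chrom]]
    len <- S4Vectors::runLength(r)
    val <- S4Vectors::runValue(r)
    ends <- cumsum(len)
    starts <- ends - len
    keep <- val != 0
    if (any(keep)) {
      recs[[chrom]] <- data.table(chrom = chrom, start = starts[keep],
                                  end = ends[keep], value = val[keep])
    }
  }
  if (length(recs) == 0L) {
    file.create(path)
  } else {
    fwrite(data.table::rbindlist(recs), path, sep = "\t", col.names = FALSE,
           scipen = 50)
  }
  invisible(path)
}

#' Load and filter a peak set
#'
#' Reads a BED-derived peak file whose extra columns carry `-log10(p)` and
#' `log2(fold enrichment)` per interval (column indices configurable; the
#' default matches ENCODE-style narrow peak BED with log2 fold in column 7
#' and -log10 p in column 8). Thresholds are applied on the raw scale:
#' `p <= peak_p_max` and `fold >= peak_fold_min`.
#'
#' @param path peak file path.
#' @param config a [map_config()] supplying `peak_p_max` and `peak_fold_min`.
#' @param fold_col,p_col 1-based column indices of the `log2(fold)` and
#'   `-log10(p)` scores.
#' @return A [GenomicRanges::GRanges] with metadata columns `p_value` and
#'   `fold_enrichment`, retaining only intervals passing the thresholds.
#' @export
load_peaks <- function(path, config = map_config(), fold_col = 7L, p_col = 8L) {
  if (!file.exists(path)) stop("peak file not found: ", path, call. = FALSE)
  empty <- GenomicRanges::GRanges(p_value = numeric(0),
                                  fold_enrichment = numeric(0))
  if (file.size(path) == 0L) return(empty)
  dt <- fread(path, header = FALSE, sep = "\t", showProgress = FALSE)
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < max(fold_col, p_col, 6L)) {
    stop(sprintf("peak format error: need %d columns (have %d); score columns missing",
                 max(fold_col, p_col, 6L), ncol(dt)), call. = FALSE)
  }
  log10p <- suppressWarnings(as.numeric(dt[[p_col]]))
  log2f <- suppressWarnings(as.numeric(dt[[fold_col]]))
  if (anyNA(log10p) || anyNA(log2f)) {
    stop("peak format error: non-numeric score column", call. = FALSE)
  }
  p <- 10^(-log10p)
  fold <- 2^log2f
  keep <- p <= config$peak_p_max & fold >= config$peak_fold_min
  if (any(dt[[2]] >= dt[[3]])) {
    stop("peak format error: interval with start >= end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    as.character(dt[[1]]),
    IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]]),
    strand = as.character(dt[[6]]),
    p_value = p, fold_enrichment = fold)
  gr[keep]
}
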