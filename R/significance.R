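# Position-wise statistical comparison of test event sets against a
# background: Fisher's exact test (peak mode), Kolmogorov-Smirnov (density
# mode) and bootstrap permutation confidence bounds.

position_test_result <- function(pvalues, statistic, method) {
  structure(list(pvalues = pvalues, statistic = statistic, method = method),
            class = "position_test_result")
}

#' @export
print.position_test_result <- function(x, ...) {
  cat(sprintf("<position_test_result> %s over %d positions, min p = %.3g\n",
              x$method, length(x$pvalues), min(x$pvalues, na.rm = TRUE)))
  invisible(x)
}

#' Position-wise Fisher exact test on peak overlap
#'
#' At each position i a two-sided Fisher exact test is run on the 2 x 2 table
#' (test events with / without a peak at i; background events with / without),
#' missing entries excluded from the counts. Positions where either set has
#' no informative events get p = 1 with a warning. The reported statistic is
#' a Haldane-corrected odds ratio `((a+.5)(d+.5)) / ((b+.5)(c+.5))`.
#'
#' @param test_peaks,bg_peaks binary `signal_matrix` objects (see
#'   [peak_overlap_matrix()]) sharing the number of positions.
#' @return A `position_test_result` with `method = "fisher"`.
#' @export
fisher_positionwise <- function(test_peaks, bg_peaks) {
  tv <- test_peaks$values; tm <- test_peaks$missing
  bv <- bg_peaks$values; bm <- bg_peaks$missing
  if (ncol(tv) != ncol(bv)) {
    stop("test and background matrices must share positions", call. = FALSE)
  }
  L <- ncol(tv)
  p <- numeric(L)
  or <- numeric(L)
  cache <- new.env(parent = emptyenv())
  degenerate <- 0L
  for (i in seq_len(L)) {
    a <- sum(tv[, i] == 1 & !tm[, i], na.rm = TRUE)
    b <- sum(tv[, i] == 0 & !tm[, i], na.rm = TRUE)
    cc <- sum(bv[, i] == 1 & !bm[, i], na.rm = TRUE)
    d <- sum(bv[, i] == 0 & !bm[, i], na.rm = TRUE)
    or[i] <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    if (a + b == 0L || cc + d == 0L) {
      p[i] <- 1
      degenerate <- degenerate + 1L
      next
    }
    key <- paste(a, b, cc, d, sep = ".")
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2,
                                       byrow = TRUE))$p.value
      hit <- min(hit, 1)
      cache[[key]] <- hit
    }
    p[i] <- hit
  }
  if (degenerate > 0L) {
    warning(sprintf("%d position(s) with an empty margin; p = 1 recorded",
                    degenerate))
  }
  position_test_result(p, or, "fisher")
}

trim_vector <- function(v, conf) {
  v <- v[!is.na(v)]
  n <- length(v)
  k <- floor(n * (1 - conf) / 2)
  if (n - 2 * k < 1) return(numeric(0))
  sort(v)[(k + 1):(n - k)]
}

#' Position-wise two-sample Kolmogorov-Smirnov test
#'
#' At each position both samples are outlier-trimmed (middle `conf` fraction
#' kept, as in [trim_outliers()]) and compared by a two-sided two-sample KS
#' test with the asymptotic p-value. Positions with fewer than two survivors
#' in either sample get D = 0, p = 1 with a warning.
#'
#' @param test_matrix,bg_matrix `signal_matrix` objects normalized by the
#'   same method.
#' @param conf trimming confidence, as in [trim_outliers()].
#' @return A `position_test_result` with `method = "ks"` and the KS D as
#'   statistic.
#' @export
ks_positionwise <- function(test_matrix, bg_matrix, conf = 0.95) {
  tv <- test_matrix$values; bv <- bg_matrix$values
  if (ncol(tv) != ncol(bv)) {
    stop("test and background matrices must share positions", call. = FALSE)
  }
  if (!identical(test_matrix$norm_method, bg_matrix$norm_method)) {
    stop("matrices must be normalized by the same method", call. = FALSE)
  }
  L <- ncol(tv)
  p <- numeric(L)
  D <- numeric(L)
  thin <- 0L
  for (i in seq_len(L)) {
    x <- trim_vector(tv[, i], conf)
    y <- trim_vector(bv[, i], conf)
    if (length(x) < 2L || length(y) < 2L) {
      p[i] <- 1; D[i] <- 0; thin <- thin + 1L
      next
    }
    kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    D[i] <- unname(kt$statistic)
    p[i] <- max(min(kt$p.value, 1), .Machine$double.xmin)
  }
  if (thin > 0L) {
    warning(sprintf("%d position(s) with fewer than 2 survivors; D = 0, p = 1 recorded",
                    thin))
  }
  position_test_result(p, D, "ks")
}

#' Bootstrap permutation confidence bounds from a background matrix
#'
#' For each of `config$n_permutations` seeded draws, `n_test` background
#' events are sampled with replacement, outlier-trimmed at `config$conf` and
#' averaged per position; the bounds are the per-position percentiles
#' (default 0.5th and 99.5th) of these permutation means. Deterministic given
#' `config$seed`.
#'
#' @param bg_matrix a non-empty `signal_matrix` of normalized background
#'   events.
#' @param n_test number of events in the test condition (sample size per
#'   permutation).
#' @param config a [map_config()] supplying `n_permutations`,
#'   `percentile_bounds`, `conf` and `seed`.
#' @return A `permutation_bounds` object with `lower`, `upper`, `n_perm`,
#'   `percentiles`, `seed`.
#' @export
permutation_bounds <- function(bg_matrix, n_test, config = map_config()) {
  stopifnot(n_test >= 1L)
  x <- bg_matrix$values
  x[bg_matrix$missing] <- NA_real_
  n <- nrow(x)
  if (n == 0L) stop("empty background matrix", call. = FALSE)
  n_perm <- config$n_permutations
  set.seed(config$seed)
  draws <- matrix(sample.int(n, n_perm * n_test, replace = TRUE),
                  nrow = n_perm, ncol = n_test)
  probs <- config$percentile_bounds / 100
  b <- cpp_permutation_bounds(x, draws, config$conf, probs[1], probs[2])
  structure(list(lower = b$lower, upper = b$upper, n_perm = n_perm,
                 percentiles = config$percentile_bounds, seed = config$seed),
            class = "permutation_bounds")
}

#' @export
print.permutation_bounds <- function(x, ...) {
  cat(sprintf("<permutation_bounds> %d permutations, percentiles %.4g/%.4g, seed %d\n",
              x$n_perm, x$percentiles[1], x$percentiles[2], x$seed))
  invisible(x)
}

#' Conservatively combine bounds across conditions
#'
#' When several test conditions are displayed together, the element-wise
#' highest upper and lowest lower bound are used as the shared envelope.
#'
#' @param bounds_list non-empty list of `permutation_bounds` with equal
#'   length and percentiles.
#' @return A combined `permutation_bounds`.
#' @export
combine_condition_bounds <- function(bounds_list) {
  if (length(bounds_list) == 0L) stop("empty bounds list", call. = FALSE)
  L <- length(bounds_list[[1]]$lower)
  pct <- bounds_list[[1]]$percentiles
  for (b in bounds_list) {
    if (length(b$lower) != L || !identical(b$percentiles, pct)) {
      stop("bounds must share length and percentiles", call. = FALSE)
    }
  }
  lower <- Reduce(pmin, lapply(bounds_list, `[[`, "lower"))
  upper <- Reduce(pmax, lapply(bounds_list, `[[`, "upper"))
  structure(list(lower = lower, upper = upper,
                 n_perm = bounds_list[[1]]$n_perm, percentiles = pct,
                 seed = bounds_list[[1]]$seed),
            class = "permutation_bounds")
}

#' Write position-wise p-values and bounds as CSV
#'
#' @param result a `position_test_result` or `NULL`.
#' @param bounds a `permutation_bounds` or `NULL`.
#' @param prefix output prefix; writes `<prefix>.pvalues.csv` and/or
#'   `<prefix>.bounds.csv`.
#' @return Invisibly, the written paths.
#' @export
write_significance <- function(result = NULL, bounds = NULL, prefix) {
  paths <- character(0)
  if (!is.null(result)) {
    path <- paste0(prefix, ".pvalues.csv")
    fwrite(data.table(position = seq_along(result$pvalues) - 1L,
                      method = result$method, p = result$pvalues,
                      statistic = result$statistic), path)
    paths <- c(paths, path)
  }
  if (!is.null(bounds)) {
    path <- paste0(prefix, ".bounds.csv")
    fwrite(data.table(position = seq_along(bounds$lower) - 1L,
                      lower = bounds$lower, upper = bounds$upper), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
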