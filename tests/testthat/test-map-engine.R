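test_that("extract_matrix reads planted densities at the right cells", {
  cfg <- map_config()
  el <- se_list(se_event("a", up = c(1000, 1200), cas = c(1900, 2050),
                         dn = c(2750, 2950)),
                se_event("b", up = c(5000, 5200), cas = c(5900, 6050),
                         dn = c(6750, 6950)))
  regions <- build_meta_regions(el, cfg)
  # density 5.0 at genomic 1750, inside window 2 (intron upstream of the
  # cassette 5'ss): window-2 intronic slots cover 1600..1899, so 1750 is the
  # 151st slot => 1-based column 350 + 151 = 501
  tracks <- toy_track_pair(pos = 1750L, val = 5, len = 8000L)
  m <- extract_matrix(regions, tracks)
  expect_equal(sum(m$values == 5, na.rm = TRUE), 1L)
  expect_equal(m$values[1, 501L], 5)
  expect_true(all(m$values[2, ] == 0))
  # zero coverage everywhere -> all-zero matrix
  z <- extract_matrix(regions, toy_track_pair(len = 8000L))
  expect_true(all(z$values == 0))
  # absent chromosome warns and fills zeros
  el2 <- se_list(se_event("c", chrom = "chr9"))
  expect_warning(m9 <- extract_matrix(build_meta_regions(el2, cfg), tracks),
                 "absent")
  expect_true(all(m9$values == 0))
})

test_that("minus-strand rows are reversed copies of their mirrored twins", {
  cfg <- map_config()
  set.seed(13)
  vec <- rpois(9000L, 0.3)
  M <- 9000L
  # the minus-strand track is the reflection of the plus-strand track
  tr_fwd <- coverage_track(list(chr1 = S4Vectors::Rle(as.numeric(vec))), "+", 1e6)
  tr_rev <- coverage_track(list(chr1 = S4Vectors::Rle(as.numeric(rev(vec)))), "-", 1e6)
  tracks <- list("+" = tr_fwd, "-" = tr_rev)
  row_fwd <- se_event("f", up = c(1000, 1200), cas = c(1900, 2050),
                      dn = c(2750, 2950))
  row_rev <- mirror_event(row_fwd, M)
  row_rev$event_id <- "r"
  regions <- build_meta_regions(
    event_list(rbind(row_fwd, row_rev), "SE"), cfg)
  m <- extract_matrix(regions, tracks)
  expect_equal(m$values[2, ], m$values[1, ])
})

test_that("subtraction normalization follows the closed form", {
  cfg0 <- map_config(pseudocount_reads = 0)
  ip <- plain_matrix(matrix(c(2, 0, 0, 0), 1), "raw")
  input <- plain_matrix(matrix(0, 1, 4), "raw")
  out <- normalize_subtraction(ip, input, cfg0)
  expect_equal(out$values[1, ], c(1, 0, 0, 0))
  # pc = 0.1 RPM (0.1 reads at total 1e6): 2 / (2 + 4 * 0.1)
  cfg1 <- map_config(pseudocount_reads = 0.1)
  out1 <- normalize_subtraction(ip, input, cfg1)
  expect_equal(out1$values[1, 1], 2 / (2 + 4 * 0.1), tolerance = 1e-12)
  # single pseudocount variant
  cfg2 <- map_config(pseudocount_reads = 0.1, pc_per_position = FALSE)
  expect_equal(normalize_subtraction(ip, input, cfg2)$values[1, 1],
               2 / (2 + 0.1), tolerance = 1e-12)
  # identical IP and input -> all-zero output
  same <- normalize_subtraction(ip, ip, cfg1)
  expect_true(all(same$values == 0))
})

test_that("per-event absolute sums stay below one and approach it as pc -> 0", {
  set.seed(19)
  vals <- matrix(rpois(5 * 40, 2) - rpois(5 * 40, 2), 5, 40)
  ip <- plain_matrix(pmax(vals, 0), "raw")
  input <- plain_matrix(pmax(-vals, 0), "raw")
  for (pc in c(1, 0.1, 1e-3, 1e-8)) {
    out <- normalize_subtraction(ip, input, map_config(pseudocount_reads = pc))
    sums <- rowSums(abs(out$values))
    expect_true(all(sums >= 0 & sums < 1))
  }
  tiny <- normalize_subtraction(ip, input,
                                map_config(pseudocount_reads = 1e-10))
  nz <- rowSums(abs(vals)) > 0
  expect_equal(rowSums(abs(tiny$values))[nz], rep(1, sum(nz)),
               tolerance = 1e-6)
})

test_that("entropy normalization matches a scalar reimplementation", {
  # direct scores: p = q -> 0; p = 0.5, q = 0.25 -> 0.5
  expect_equal(relative_information(0.3, 0.3), 0)
  expect_equal(relative_information(0.5, 0.25), 0.5)
  ip_tot <- 1e6; in_tot <- 2e6
  set.seed(23)
  ip_counts <- matrix(rpois(200, 2), 4)
  in_counts <- matrix(rpois(200, 2), 4)
  ip <- plain_matrix(ip_counts * 1e6 / ip_tot, "raw", total = ip_tot)
  input <- plain_matrix(in_counts * 1e6 / in_tot, "raw", total = in_tot)
  out <- normalize_entropy(ip, input, map_config())
  scalar <- function(nip, nin) {
    p <- (nip + 1) / (ip_tot + 1)
    q <- (nin + 1) / (in_tot + 1)
    p * log2(p / q)
  }
  for (k in sample(length(ip_counts), 20)) {
    expect_equal(out$values[k], scalar(ip_counts[k], in_counts[k]),
                 tolerance = 1e-12)
  }
  # sign-diagnostic: out > 0 iff p > q, zero iff p = q
  p <- (ip_counts + 1) / (ip_tot + 1)
  q <- (in_counts + 1) / (in_tot + 1)
  expect_equal(out$values > 0, p > q)
  expect_equal(out$values == 0, p == q)
  # equal libraries give identically zero maps
  zero <- normalize_entropy(ip, plain_matrix(ip_counts, "raw", total = ip_tot),
                            map_config())
  expect_true(all(zero$values == 0))
})

test_that("trimmed means drop the extreme tails and flag empty positions", {
  x <- matrix(c(1:38, -1000, 1000), ncol = 1)
  tr <- trim_outliers(x, conf = 0.95)
  expect_equal(tr$mean_curve, 19.5) # mean of 1..38 after dropping both tails
  expect_equal(tr$n_contributing, 38L)
  expect_equal(tr$values[[1]], as.numeric(1:38))
  # conf = 1 is the plain mean
  set.seed(29)
  m <- matrix(rnorm(200), 20)
  expect_equal(trim_outliers(m, conf = 1)$mean_curve, colMeans(m))
  # robustness: one wild value does not move the trimmed mean (n = 40)
  base <- matrix(rnorm(40 * 5), 40)
  spiked <- base
  spiked[7, ] <- 1e9
  t1 <- trim_outliers(base, conf = 0.95)$mean_curve
  t2 <- trim_outliers(spiked, conf = 0.95)$mean_curve
  expect_equal(t2, apply(spiked, 2, function(v) mean(sort(v)[2:39])))
  expect_true(all(abs(t2 - t1) <= apply(base, 2, function(v) diff(range(v)))))
  # all-missing positions become missing
  na_col <- matrix(NA_real_, 5, 2)
  trna <- trim_outliers(na_col)
  expect_true(all(is.na(trna$mean_curve)))
  expect_equal(trna$n_contributing, c(0L, 0L))
})

test_that("peak fraction maps count events with a same-strand peak per position", {
  cfg <- map_config()
  mk <- function(id, base, strand = "+") {
    up <- c(base, base + 200L); cas <- c(up[2] + 700L, up[2] + 850L)
    dn <- c(cas[2] + 700L, cas[2] + 900L)
    anc <- if (strand == "+") list(up, cas, dn) else list(dn, cas, up)
    se_event(id, strand = strand, up = anc[[1]], cas = anc[[2]], dn = anc[[3]])
  }
  el <- se_list(mk("a", 1000L), mk("b", 6000L), mk("c", 11000L), mk("d", 16000L))
  regions <- build_meta_regions(el, cfg)
  # peak covering the first 20 intronic nt after the upstream exon of a and b
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1201, 6201), width = 20),
    strand = "+", p_value = 1e-6, fold_enrichment = 16)
  map <- peak_fraction_map(regions, peaks)
  curve <- map$conditions[[1]]$mean_curve
  expect_equal(curve[51], 0.5) # first intronic slot of window 1: 2 of 4 events
  expect_true(all(curve >= 0 & curve <= 1, na.rm = TRUE))
  expect_equal(sum(curve > 0), 20L)
  # no peaks -> zero curve
  zero <- peak_fraction_map(regions, peaks[0])
  expect_true(all(zero$conditions[[1]]$mean_curve == 0))
  expect_error(peak_fraction_map(list(), peaks), "empty")
  # masked positions drop out of the denominator
  el2 <- se_list(mk("a", 1000L), mk("b", 6000L), mk("c", 11000L),
                 se_event("d", up = c(16000, 16030), cas = c(16900, 17050),
                          dn = c(17750, 17950))) # 30-nt upstream exon
  regions2 <- build_meta_regions(el2, cfg)
  peaks2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1151, 1160),
                                   strand = "+", p_value = 1e-6,
                                   fold_enrichment = 16)
  map2 <- peak_fraction_map(regions2, peaks2)
  # exonic slot 1 of window 1 is masked for event d (exon < 50 nt)
  expect_equal(map2$conditions[[1]]$mean_curve[1], 1 / 3)
})

test_that("build_map orchestrates density mode and writes consistent CSVs", {
  spec <- fixture_spec(n_events = 12, n_background = 12, seed = 5,
                       planted_fraction = 1)
  ev <- generate_events(spec)
  cov <- generate_coverage(ev, spec)
  cfg <- map_config(conf = 0.95)
  prefix <- file.path(withr::local_tempdir(), "run")
  res <- build_map(list(kd = ev$test), "density",
                   sources = list(ip = cov$ip, input = cov$input),
                   config = cfg, out_prefix = prefix)
  expect_s3_class(res$map, "splicing_map")
  normed_csv <- data.table::fread(paste0(prefix, ".kd.normed.csv"))
  means_csv <- data.table::fread(paste0(prefix, ".means.csv"))
  # re-averaging the exported normalized matrix reproduces the mean curve
  mat <- as.matrix(normed_csv[, -1])
  re_mean <- trim_outliers(mat, conf = cfg$conf, keep_values = FALSE)$mean_curve
  expect_equal(unname(unlist(means_csv[1, -1])), re_mean)
  expect_equal(re_mean, res$map$conditions$kd$mean_curve)
  # determinism: a second identical run writes byte-identical CSVs
  prefix2 <- file.path(withr::local_tempdir(), "run")
  ev2 <- generate_events(spec)
  cov2 <- generate_coverage(ev2, spec)
  build_map(list(kd = ev2$test), "density",
            sources = list(ip = cov2$ip, input = cov2$input),
            config = cfg, out_prefix = prefix2)
  expect_identical(tools::md5sum(paste0(prefix, ".kd.normed.csv"))[[1]],
                   tools::md5sum(paste0(prefix2, ".kd.normed.csv"))[[1]])
})

test_that("raw mode equals subtraction against an identically zero input", {
  spec <- fixture_spec(n_events = 8, n_background = 8, seed = 9)
  ev <- generate_events(spec)
  cov <- generate_coverage(ev, spec)
  zero_tracks <- lapply(cov$input, function(tr) {
    coverage_track(lapply(tr$cov, function(r) S4Vectors::Rle(0, length(r))),
                   tr$strand, tr$total_reads)
  })
  cfg <- map_config(norm_method = "subtraction")
  sub <- build_map(list(kd = ev$test), "density",
                   sources = list(ip = cov$ip, input = zero_tracks),
                   config = cfg)
  raw <- build_map(list(kd = ev$test), "density",
                   sources = list(ip = cov$ip),
                   config = map_config(norm_method = "raw"))
  expect_equal(raw$map$conditions$kd$mean_curve,
               sub$map$conditions$kd$mean_curve)
})

test_that("build_map validates its mode and source combinations", {
  spec <- fixture_spec(n_events = 4, n_background = 4, seed = 2)
  ev <- generate_events(spec)
  cov <- generate_coverage(ev, spec)
  expect_error(build_map(list(kd = ev$test), "density", sources = list()),
               "IP")
  expect_error(build_map(list(kd = ev$test), "density",
                         sources = list(ip = cov$ip),
                         config = map_config(norm_method = "subtraction")),
               "raw")
  expect_error(build_map(list(kd = ev$test), "peak", sources = list()),
               "peak")
})
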