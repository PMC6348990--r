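test_that("parse_rmats reads toy SE tables with verbatim coordinates and summed IJC", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_rmats_se(path, list(
    toy_rmats_row("1", ijc1 = "5,7", ijc2 = "3,1"),
    toy_rmats_row("2", strand = "-", cas = c(5900, 6020), up = c(6500, 6700),
                  dn = c(5000, 5200)),
    toy_rmats_row("3", cas = c(9000, 9100), up = c(8000, 8300),
                  dn = c(9800, 9900), sjc1 = "1,0", sjc2 = "0,2")))
  el <- parse_rmats(path, "SE")
  expect_s3_class(el, "event_list")
  expect_length(el, 3L)
  expect_equal(el$events$ijc_total[1], 16) # 5+7+3+1
  expect_equal(el$events$sjc_total[3], 3)
  # every SE row carries upstream, cassette, downstream anchor exons
  expect_true(all(vapply(el$events$anchors, nrow, integer(1)) == 3L))
  a1 <- el$events$anchors[[1]]
  expect_equal(unname(a1[2, ]), c(1900, 2050)) # cassette verbatim, half-open
  expect_equal(unname(a1[1, ]), c(1000, 1200))
  # minus-strand anchors stay in transcript order (genomically decreasing)
  a2 <- el$events$anchors[[2]]
  expect_true(a2[1, 1] > a2[2, 1] && a2[2, 1] > a2[3, 1])
  expect_equal(el$events$delta_psi[1], -0.3)
})

test_that("parse_rmats handles empty input and reports format errors", {
  empty <- withr::local_tempfile(fileext = ".txt")
  write_toy_rmats_se(empty)
  expect_length(parse_rmats(empty, "SE"), 0L)

  missing <- withr::local_tempfile(fileext = ".txt")
  write_toy_rmats_se(missing, list(toy_rmats_row("1")), drop_col = "IJC_SAMPLE_1")
  expect_error(parse_rmats(missing, "SE"), "IJC_SAMPLE_1")

  badnum <- withr::local_tempfile(fileext = ".txt")
  write_toy_rmats_se(badnum, list(toy_rmats_row("1"),
                                  toy_rmats_row("2", ijc1 = "x,3")))
  expect_error(parse_rmats(badnum, "SE"), "line 3")

  expect_error(parse_rmats(withr::local_tempfile(), "SE"), "not found")
})

test_that("filter_significant applies the default splicing-change thresholds", {
  el <- se_list(
    se_event("a", dpsi = 0.2, p = 0.01, fdr = 0.05),
    se_event("b", up = c(5000, 5200), cas = c(5900, 6050), dn = c(6750, 6950),
             dpsi = 0.2, p = 0.2, fdr = 0.05),
    se_event("c", up = c(9000, 9200), cas = c(9900, 10050),
             dn = c(10750, 10950), dpsi = -0.01, p = 0.01, fdr = 0.05),
    se_event("d", up = c(13000, 13200), cas = c(13900, 14050),
             dn = c(14750, 14950), dpsi = -0.3, p = 0.001, fdr = 0.001))
  both <- filter_significant(el)
  expect_equal(both$events$event_id, c("a", "d"))
  expect_equal(filter_significant(el, direction = "included")$events$event_id, "a")
  expect_equal(filter_significant(el, direction = "excluded")$events$event_id, "d")
  # no-op thresholds are the identity
  ident <- filter_significant(el, dpsi_min = 0, p_max = 1, fdr_max = 1)
  expect_equal(ident$events$event_id, el$events$event_id)
  expect_length(filter_significant(se_list(se_event()[0, ])), 0L)
})

test_that("deduplicate_overlapping keeps the highest-IJC event per overlap group", {
  # three mutually overlapping events
  el <- se_list(
    se_event("x", ijc = 10),
    se_event("y", up = c(1050, 1250), cas = c(1950, 2100), dn = c(2800, 3000),
             ijc = 20),
    se_event("z", up = c(1100, 1300), cas = c(2000, 2150), dn = c(2850, 3050),
             ijc = 5))
  out <- deduplicate_overlapping(el)
  expect_length(out, 1L)
  expect_equal(out$events$event_id, "y")
  expect_equal(out$events$ijc_total, 20)

  # transitive chain: A overlaps B, B overlaps C, A does not overlap C
  chain <- se_list(
    se_event("A", up = c(100, 200), cas = c(500, 600), dn = c(900, 1000), ijc = 3),
    se_event("B", up = c(950, 1050), cas = c(1300, 1400), dn = c(1700, 1800),
             ijc = 9),
    se_event("C", up = c(1750, 1850), cas = c(2100, 2200), dn = c(2500, 2600),
             ijc = 6))
  out <- deduplicate_overlapping(chain)
  expect_length(out, 1L)
  expect_equal(out$events$event_id, "B")

  # ties broken by lexicographically smallest id
  tie <- se_list(se_event("m", ijc = 7), se_event("k", ijc = 7))
  expect_equal(deduplicate_overlapping(tie)$events$event_id, "k")

  # events on opposite strands never merge
  strands <- se_list(se_event("p", strand = "+", ijc = 1),
                     se_event("q", strand = "-", ijc = 2))
  expect_length(deduplicate_overlapping(strands), 2L)

  # non-overlapping input is returned unchanged (up to genomic order)
  apart <- se_list(
    se_event("u", up = c(100, 200), cas = c(500, 600), dn = c(900, 1000)),
    se_event("v", up = c(5000, 5100), cas = c(5400, 5500), dn = c(5800, 5900)))
  expect_equal(deduplicate_overlapping(apart)$events$event_id, c("u", "v"))
})

test_that("deduplication is idempotent and leaves no overlapping spans", {
  set.seed(42)
  for (rep in 1:40) {
    el <- random_se_list(sample(2:25, 1L))
    once <- deduplicate_overlapping(el)
    twice <- deduplicate_overlapping(once)
    expect_equal(twice$events$event_id, once$events$event_id)
    sp <- event_spans(once)
    if (nrow(sp) > 1L) {
      for (key in split(seq_len(nrow(sp)), paste(sp$chrom, sp$strand))) {
        s <- sp[key, , drop = FALSE]
        s <- s[order(s$start), , drop = FALSE]
        if (nrow(s) > 1L) {
          expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
        }
      }
    }
  }
})

test_that("classify_background applies the control-Psi class definitions", {
  el <- se_list(
    se_event("const", psi = rep(1, 10)),
    se_event("central", up = c(5000, 5200), cas = c(5900, 6050),
             dn = c(6750, 6950), psi = c(rep(0.5, 6), rep(0.99, 4))),
    se_event("included", up = c(9000, 9200), cas = c(9900, 10050),
             dn = c(10750, 10950), psi = rep(0.8, 10)),
    se_event("excluded", up = c(13000, 13200), cas = c(13900, 14050),
             dn = c(14750, 14950), psi = rep(0.1, 10)),
    se_event("nothing", up = c(17000, 17200), cas = c(17900, 18050),
             dn = c(18750, 18950), psi = rep(0.97, 10)))
  bs <- classify_background(el)
  expect_s3_class(bs, "background_sets")
  expect_equal(bs$constitutive$events$event_id, "const")
  expect_equal(bs$native_central$events$event_id, "central")
  expect_true("central" %in% bs$native$events$event_id)
  expect_equal(bs$native_included$events$event_id, "included")
  expect_equal(bs$native_excluded$events$event_id, "excluded")
  # an event may fail every class
  all_ids <- unlist(lapply(bs, function(s) s$events$event_id))
  expect_false("nothing" %in% all_ids)
  # native_* subsets are contained in native and pairwise disjoint
  for (nm in c("native_included", "native_central", "native_excluded")) {
    expect_true(all(bs[[nm]]$events$event_id %in% bs$native$events$event_id))
  }
  subsets <- lapply(c("native_included", "native_central", "native_excluded"),
                    function(nm) bs[[nm]]$events$event_id)
  expect_length(Reduce(intersect, subsets), 0L)
})

test_that("classify_background warns on events without control Psi", {
  el <- se_list(se_event("a", psi = rep(0.5, 4)),
                se_event("b", up = c(5000, 5200), cas = c(5900, 6050),
                         dn = c(6750, 6950), psi = NULL))
  expect_warning(bs <- classify_background(el), "without control Psi")
  expect_false("b" %in% unlist(lapply(bs, function(s) s$events$event_id)))
})

test_that("MISO SE identifiers convert to half-open skipped-exon events", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("chr1:101:200:+@chr1:301:400:+@chr1:501:600:+", path)
  el <- parse_miso(path)
  expect_length(el, 1L)
  a <- el$events$anchors[[1]]
  expect_equal(unname(a[1, ]), c(100, 200)) # 1-based inclusive -> half-open
  expect_equal(unname(a[3, ]), c(500, 600))
  expect_equal(el$event_type, "SE")
})

test_that("resolved events export as BED6 plus a TSV mirror", {
  el <- se_list(se_event("a", ijc = 12))
  prefix <- file.path(withr::local_tempdir(), "events")
  paths <- write_events(el, prefix)
  bed <- read.table(paths[["bed"]], sep = "\t")
  expect_equal(bed$V2, 1000) # span start = min anchor start
  expect_equal(bed$V3, 2950)
  expect_equal(bed$V5, 12)
  tsv <- read.delim(paths[["tsv"]])
  expect_equal(tsv$event_id, "a")
  expect_equal(tsv$ijc_total, 12)
})
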