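# In-code fixtures shared across test files.

# One SE event row; coordinates 0-based half-open, anchors transcript order.
se_event <- function(id = "e1", chrom = "chr1", strand = "+",
                     up = c(1000, 1200), cas = c(1900, 2050),
                     dn = c(2750, 2950), ijc = 10, sjc = 5, dpsi = -0.5,
                     p = 0.01, fdr = 0.01, psi = NULL) {
  a <- rbind(up, cas, dn)
  colnames(a) <- c("start", "end")
  rownames(a) <- NULL
  ev <- data.frame(event_id = id, chrom = chrom, strand = strand,
                   ijc_total = ijc, sjc_total = sjc, delta_psi = dpsi,
                   pvalue = p, fdr = fdr, stringsAsFactors = FALSE)
  ev$anchors <- list(a)
  ev$control_psi <- list(psi)
  ev
}

se_list <- function(..., label = "test") {
  event_list(do.call(rbind, list(...)), "SE", label)
}

# Reflect an SE event around coordinate M and flip its strand: the mirror
# image used by strand-symmetry checks.
mirror_event <- function(row, M) {
  a <- row$anchors[[1]]
  row$anchors[[1]] <- cbind(start = M - a[, "end"], end = M - a[, "start"])
  row$strand <- if (row$strand == "+") "-" else "+"
  row
}

# Random non-overlapping-ish SE event list (some events deliberately share
# coordinates to exercise deduplication).
random_se_list <- function(n, overlap_fraction = 0.3) {
  cursor <- 100L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1L && runif(1) < overlap_fraction) {
      # duplicate-style event: perturb the previous one but keep it overlapping
      prev <- rows[[i - 1L]]
      a <- prev$anchors[[1]]
      shift <- sample.int(40L, 1L)
      a2 <- a + shift
      rows[[i]] <- se_event(id = sprintf("ev%03d", i), strand = prev$strand,
                            up = a2[1, ], cas = a2[2, ], dn = a2[3, ],
                            ijc = sample.int(100L, 1L))
    } else {
      ue <- sample(80:200, 1L); cl <- sample(80:200, 1L); dl <- sample(80:200, 1L)
      i1 <- sample(200:700, 1L); i2 <- sample(200:700, 1L)
      s <- cursor
      strand <- sample(c("+", "-"), 1L)
      up <- c(s, s + ue); cas <- c(up[2] + i1, up[2] + i1 + cl)
      dn <- c(cas[2] + i2, cas[2] + i2 + dl)
      anc <- if (strand == "+") list(up, cas, dn) else list(dn, cas, up)
      rows[[i]] <- se_event(id = sprintf("ev%03d", i), strand = strand,
                            up = anc[[1]], cas = anc[[2]], dn = anc[[3]],
                            ijc = sample.int(100L, 1L))
      cursor <- dn[2] + sample(50:400, 1L)
    }
  }
  event_list(do.call(rbind, rows), "SE", "random")
}

# Minimal rMATS SE table writer for parser tests.
RMATS_SE_HEADER <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
                     "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
                     "downstreamES", "downstreamEE", "IJC_SAMPLE_1",
                     "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
                     "IncFormLen", "SkipFormLen", "PValue", "FDR",
                     "IncLevel1", "IncLevel2", "IncLevelDifference")

write_toy_rmats_se <- function(path, rows = list(), drop_col = NULL) {
  header <- RMATS_SE_HEADER
  if (!is.null(drop_col)) header <- setdiff(header, drop_col)
  lines <- paste(header, collapse = "\t")
  for (r in rows) {
    full <- stats::setNames(as.character(r), RMATS_SE_HEADER)
    lines <- c(lines, paste(full[header], collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

toy_rmats_row <- function(id = "1", chrom = "chr1", strand = "+",
                          cas = c(1900, 2050), up = c(1000, 1200),
                          dn = c(2750, 2950), ijc1 = "5,7", ijc2 = "3,1",
                          sjc1 = "2,2", sjc2 = "4,4", p = 0.01, fdr = 0.02,
                          dpsi = -0.3) {
  c(id, paste0("G", id), paste0("SYM", id), chrom, strand, cas[1], cas[2],
    up[1], up[2], dn[1], dn[2], ijc1, sjc1, ijc2, sjc2, 150, 100, p, fdr,
    "0.6,0.7", "0.3,0.4", dpsi)
}

# A coverage-track pair backed by explicit position/value pairs (0-based).
toy_track_pair <- function(chrom = "chr1", pos = integer(0),
                           val = numeric(0), len = 5000L,
                           total_reads = 1e6) {
  vec <- numeric(len)
  vec[pos + 1L] <- val
  mk <- function(s) coverage_track(stats::setNames(list(S4Vectors::Rle(vec)),
                                                   chrom), s, total_reads)
  list("+" = mk("+"), "-" = mk("-"))
}

# Plain signal matrix without masking.
plain_matrix <- function(values, norm = "subtraction", total = 1e6) {
  splicemapr:::signal_matrix(sprintf("e%d", seq_len(nrow(values))), values,
                             matrix(FALSE, nrow(values), ncol(values)),
                             norm, ip_total_reads = total,
                             input_total_reads = total)
}

# Independent two-sided Fisher oracle: full hypergeometric enumeration of
# all tables with the observed margins, summing probabilities of tables at
# most as probable as the observed one.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; cs <- a + c
  if (r1 == 0 || r2 == 0) return(1)
  support <- max(0, cs - r2):min(r1, cs)
  probs <- stats::dhyper(support, r1, r2, cs)
  pobs <- stats::dhyper(a, r1, r2, cs)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Independent KS D oracle via explicit empirical CDF comparison.
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}
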