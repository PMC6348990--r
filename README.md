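# splicemapr

Position-wise RNA **splicing regulatory maps** from CLIP signal and
alternative-splicing events.

RNA binding proteins (RBPs) control splice-site choice in a
position-dependent way: binding upstream of a cassette exon often has the
opposite regulatory effect of binding downstream. A splicing map makes this
visible by averaging CLIP binding signal (eCLIP read density or enriched
peaks) over hundreds of alternatively spliced events after aligning each
event to its splice sites. `splicemapr` implements the full pipeline:

* **Events** — parse rMATS `JunctionCountsOnly` tables (SE, A3SS, A5SS,
  MXE, RI), filter for significant splicing changes
  (|ΔΨ| ≥ 0.05, *P* ≤ 0.05, FDR ≤ 0.1), resolve overlapping event calls by
  keeping the highest-IJC event per overlap group, and classify events
  against control Ψ tables into constitutive / native cassette-exon
  background sets.
* **Geometry** — vectorize each event into splice-site-anchored windows
  (for SE: 50 nt of exon + 300 nt of intron around four splice sites =
  1400 positions), masking positions beyond short-feature boundaries, with
  exact mirror handling of minus-strand events.
* **Signal** — strand-specific coverage tracks (bigWig/bedGraph), 5′
  read-end collapse for crosslink-resolution maps, and peak sets filtered
  at *p* ≤ 0.001 and fold ≥ 8.
* **Maps** — raw, input-**subtraction** (per-event unit-absolute-sum
  scaling, the default) or relative-information (**entropy**,
  `p_i log2(p_i/q_i)`) normalization; per-position outlier trimming
  (middle 95% of values kept); peak-fraction maps.
* **Significance** — position-wise Fisher exact tests (peak mode),
  Kolmogorov–Smirnov tests (density mode) and a seeded bootstrap
  (1000 permutations of background events, 0.5/99.5 percentile confidence
  envelope; C++ kernel).
* **Fixtures** — a synthetic-study generator (toy genome, event tables,
  Poisson coverage with planted positional enrichment, peaks, control-Ψ
  tables) so the entire pipeline is testable offline.

The methods vignette (`vignettes/splicing-maps.Rmd`) documents the model,
parameter defaults and design decisions in detail.

## Worked example

A synthetic knockdown study: 100 knockdown-excluded cassette exons carrying
10× IP enrichment centred 67 nt downstream of the cassette 5′ splice site
in 80% of events, plus a 500-event native background pool.

```r
library(splicemapr)

spec <- fixture_spec(n_events = 100, seed = 42)
ev   <- generate_events(spec)
cov  <- generate_coverage(ev, spec)

cfg <- map_config()   # 50/300 nt flanks, subtraction norm, conf = 0.95
res <- build_map(list(`knockdown-excluded` = ev$test, native = ev$background),
                 mode = "density",
                 sources = list(ip = cov$ip, input = cov$input),
                 config = cfg, out_prefix = "demo/map")
res$map
#> <splicing_map> SE, 4 windows x 350 nt
#>   knockdown-excluded       n = 100, mean curve peak = 0.002554 at index 817
#>   native                   n = 500, mean curve peak = 6.489e-05 at index 18

b <- permutation_bounds(res$matrices$native$normed, n_test = 100, cfg)
curve <- res$map$conditions$`knockdown-excluded`$mean_curve
sum(curve < b$lower | curve > b$upper)
#> [1] 50
which.max(curve) - 1 - 750 + 1   # offset downstream of the cassette 5'ss
#> [1] 67
```

The map peaks at index 817 — exactly the planted +67 intronic position
downstream of the cassette exon's 5′ splice site (index 750 is the first
intronic position of window 3) — while the native background stays flat;
50 positions (the planted window and its shoulders) escape the native
bootstrap envelope. `build_map()` also writes per-event raw and normalized
matrices and the mean curves as CSV under the given prefix.

The same pipeline is scriptable from a shell via the installed
`exec/splicemapr` entry point (`map`, `subset-events` and `make-fixtures`
subcommands; `splicemapr --help` lists every flag, whose defaults are the
package defaults above). Every `map` run writes a JSON manifest with the
resolved configuration, input digests, seed and per-stage event counts.

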