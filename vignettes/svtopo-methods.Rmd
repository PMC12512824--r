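---
title: "How svtopo reconstructs complex SV structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How svtopo reconstructs complex SV structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svtopo)
```

This vignette walks through the model and each pipeline stage on a
simulated example with known truth.

## The break / flank model

A **break** is a 0-based genome coordinate where the sample haplotype
departs from the reference. A **junction endpoint** is a break plus a
*flank*: the side of the break on which sample sequence lies. A
soft-clipped alignment segment whose right end stops at the break
occupies the *left* flank; one whose left end starts there occupies the
*right* flank.

A split read that crosses a junction produces two segments, one per
side. Pairing the *exit* endpoint of one segment with the *entry*
endpoint of the next (in read order) yields a **junction observation**:

- exit from a `+` segment → (segment end, left flank); from a `-`
  segment → (segment start, right flank);
- entry into a `+` segment → (segment start, right flank); into a `-`
  segment → (segment end, left flank).

A junction is **inverted** exactly when its two endpoints carry the
same flank — the read turns around on the reference.

VCF breakend bracket notation maps onto the same algebra. For a
left-flank anchor, `POS` is the last retained base (`N[p[` / `]p]N`);
for a right-flank anchor, `POS` is one past the break (`[p[N`).
Symbolic alleles expand to their breakend pairs: a deletion to
(POS, left) + (END, right), a duplication to (POS, right) +
(END, left), an inversion to four endpoints.

## A worked example

```{r simulate}
spec <- category_suite(seed = 1)[["del-inv-del"]]
sim  <- simulate_rearrangement(spec, tempfile("vig"), prefix = "vig")
sim$layout   # the simulated sample haplotype
```

The simulator builds an alternate haplotype from reference blocks,
tiles it with overlapping "long reads", realigns each read back to the
reference analytically (producing primary + supplementary records with
`SA` tags and soft clips), and writes a coordinate-sorted indexed BAM
plus a breakend-style truth VCF.

### Extraction

```{r extract}
cfg <- run_config(sim$bam, sim$vcf, sample_id = "vig",
                  out_dir = tempfile("out"), verbose = FALSE)
res <- run_extract(cfg)
net <- res$networks[[1]]
net
```

Internally this stage:

1. parses the VCF into calls, expands them to break sides, and merges
   coordinates within a clustering window (default: the matching
   tolerance, 10 bp) by single linkage;
2. loads alignments near each break; a read's primary and `SA`
   segments are combined, ordered by query offset;
3. matches clipped segment ends to breaks within the tolerance
   (minimum significant clip 50 bp) — breaks with no matching
   alignments are skipped, not fatal;
4. records **spanned** connections from junction observations
   (support = number of distinct read names, counting a read's primary
   and supplementary records once) and **phased** connections between
   nearby same-chromosome groups that share an `HP:PS` phase label but
   no spanning read;
5. groups breaks into networks via graph components.

### Block ordering

The network's locus is partitioned into reference blocks `A, B, C, …`
between consecutive breaks, plus flanking margin blocks
(margin = max(10% of span, 200 bp)). Starting from the
reference-consistent entry break, a backtracking walk over the junction
graph consumes each spanned junction exactly once and emits the sample
order:

```{r chain}
chain_plot(net)
```

Here the sample haplotype is `A C' E`: block `B` and `D` deleted, `C`
inverted. Networks whose walk would exceed the block cap (default 20
rearranged blocks) keep a partial greedy ordering and are flagged
`resolved = FALSE`; they are rendered with an "incompletely resolved"
marker rather than dropped.

### Filters

```{r filters}
net$filters
```

Two independent annotators run on every network: a coverage/repeat
filter (block depth vs. the sample's weighted-median covered depth,
low-mapping-quality fraction) and an optional simple-network filter
that removes one/two-break forward same-chromosome events (plain
deletions, tandem duplications, single-ended calls) unless an inverted
block is present. Filter reasons are stored on the event — nothing is
silently discarded from the JSON.

### Rendering and the viewer

```{r render}
svg <- tempfile(fileext = ".svg")
render_network(net, plot_spec(), svg)
file.exists(svg)
```

Each image shows the sample rows (blocks with orientation arrows,
connection arcs whose thickness encodes support) above a reference
axis on which deleted blocks are greyed out. `run_viewer()` collects
all events into one self-contained HTML page with range filters on
variant count and region size, mirrored exactly by
`filter_viewer_rows()` for programmatic use.

## Determinism

All stages are deterministic: the same BAM + VCF produce byte-identical
JSON, SVG and HTML. The simulator is seed-deterministic, so fixtures
can be regenerated exactly.
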