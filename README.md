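# svtopo

Reconstruct and visualize the sample-haplotype structure of complex
germline structural variants (SVs) from phased long-read alignments.

SV callers report complex rearrangements as lists of breakends and
symbolic alleles, which makes the actual alternate-haplotype structure —
which reference blocks are retained, in what order, and in which
orientation — hard to see. `svtopo` rebuilds that structure directly
from the evidence:

1. **Parse** an SV VCF (breakend `BND` records with full bracket
   notation, plus symbolic `<DEL>`, `<DUP>`, `<INV>`, `<INS>` alleles)
   into genome break coordinates.
2. **Match** split long-read alignments (primary + `SA` supplementary
   records, `HP`/`PS` phase tags) to those breaks by their soft-clip
   positions, within a configurable tolerance (default 10 bp, minimum
   significant clip 50 bp).
3. **Connect** breaks that are spanned by the same read, or that share a
   haplotype/phase-set on the same chromosome, and group connected
   breaks into networks (complex events).
4. **Order** the reference blocks of each network into the sample
   haplotype by walking the junction graph, recording orientation
   (forward / inverted), deletions, and duplications; networks beyond a
   block cap are kept but flagged incompletely resolved.
5. **Filter** likely artifacts (abnormal coverage, low mapping quality)
   and, optionally, simple events (plain deletions, tandem
   duplications, unresolved single-ended calls) so review focuses on
   complex rearrangements.
6. **Render** each event as a block diagram (SVG/PNG/PDF): sample rows
   on top, the reference axis below, connection arcs whose thickness
   encodes read support.
7. **Browse** all events of one or more samples in a single
   self-contained HTML viewer with range filters for variant count and
   region size.

A deterministic rearrangement simulator (`simulate_rearrangement()`,
`category_suite()`) generates phased BAM + VCF fixtures with known
truth for testing and demonstration.

## Quick start (R)

```r
library(svtopo)

# simulate a deletion-inversion-deletion event with known truth
spec <- category_suite(seed = 1)[["del-inv-del"]]
sim  <- simulate_rearrangement(spec, tempfile("demo"), prefix = "demo")

cfg <- run_config(sim$bam, sim$vcf, sample_id = "demo",
                  out_dir = "svtopo_out")
res <- run_all(cfg)     # JSON + BED + images/ + images/index.html

read_sv_json(res$json)$networks[[1]]
```

Stages can be run separately: `run_extract()` writes the JSON/BED,
`run_plot()` renders images from JSON, `run_viewer()` builds the HTML
index (optionally merging several samples).

## Quick start (command line)

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/svtopo.R", package="svtopo"))')" \
    all --bam sample.bam --vcf sample.vcf --sample sample --out svtopo_out
```

Subcommands `extract`, `plot`, `viewer` and `all` mirror the R stages;
see `--help` for options (`--tolerance`, `--min-clip`, `--keep-simple`,
`--block-cap`, `--format`, ...).

## Outputs

- `{sample}.json` — full event catalog: breaks, connections (with
  per-junction read support and phase sets), ordered blocks, filter
  annotations. Round-trips losslessly through `read_sv_json()` and is
  byte-identical across runs.
- `{sample}.bed` — block annotations for genome browsers.
- `images/{sample}_{chrom}-{start}-{end}.svg` — one diagram per event.
- `images/index.html` — self-contained viewer (no network access
  needed), plus a TSV of the index table.

## Testing

```r
testthat::test_dir("tests/testthat", package = "svtopo",
                   load_package = "installed")
```

`scripts/acceptance.R --seed <int> --out <path>` recomputes the
headline accuracy metrics (structure round-trip, support counts, filter
conformance, determinism, oracle agreement) on freshly simulated data
and writes them as JSON.
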