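# Shared fixtures for the test suite. Simulated outputs are cached per
# session so each scenario's BAM/VCF is built once.

FIXTURE_SEED <- 424201L

.fix_env <- new.env(parent = emptyenv())

# simulate one category_suite() scenario (cached)
fixture <- function(name, seed = FIXTURE_SEED) {
  key <- paste0(name, "@", seed)
  if (!is.null(.fix_env[[key]])) return(.fix_env[[key]])
  spec <- category_suite(seed)[[name]]
  if (is.null(spec)) stop("unknown fixture scenario: ", name)
  dir <- file.path(tempdir(), paste0("fix_", gsub("[^A-Za-z0-9]", "_", key)))
  sim <- simulate_rearrangement(spec, dir, prefix = name)
  .fix_env[[key]] <- sim
  sim
}

# simulate an arbitrary spec (cached under a caller-chosen key)
fixture_spec <- function(key, spec) {
  if (!is.null(.fix_env[[key]])) return(.fix_env[[key]])
  dir <- file.path(tempdir(), paste0("fix_", gsub("[^A-Za-z0-9]", "_", key)))
  sim <- simulate_rearrangement(spec, dir, prefix = key)
  .fix_env[[key]] <- sim
  sim
}

# run the extract stage on a simulated fixture
extract_fixture <- function(sim, sample_id = "s", keep_simple = TRUE,
                            out_dir = tempfile("out"), ...) {
  cfg <- run_config(sim$bam, sim$vcf, sample_id = sample_id,
                    out_dir = out_dir, verbose = FALSE,
                    filter = filter_config(keep_simple = keep_simple), ...)
  run_extract(cfg)
}

# one synthetic alignment-evidence record (the shape produced by
# collect_alignment_evidence) for unit tests that need no BAM
make_evidence <- function(segments, read_name = "r1", haplotype = NA_integer_,
                          phase_set = NA_integer_) {
  list(read_name = read_name, haplotype = haplotype, phase_set = phase_set,
       segments = segments)
}

seg_row <- function(chrom, ref_start, ref_end, strand = "+",
                    clip_left = 0L, clip_right = 0L, mapq = 60L,
                    qstart = 0L) {
  data.frame(chrom = chrom, ref_start = ref_start, ref_end = ref_end,
             strand = strand, clip_left = clip_left, clip_right = clip_right,
             mapq = mapq, qstart = qstart, stringsAsFactors = FALSE)
}

# write a small VCF with given data lines and standard header
write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf"),
                           contigs = c(chr1 = 30000L, chr2 = 30000L)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"Mate ID\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"SV length\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, lines), path)
  path
}

# brute-force union-find over break indices, the oracle for component
# assembly
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- find(edges$from[i]); b <- find(edges$to[i])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# canonical partition signature for comparing component labelings
partition_signature <- function(membership) {
  groups <- split(seq_along(membership), membership)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = ";")
}
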