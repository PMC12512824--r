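# Fixture simulator: spec validation, haplotype layout, BAM/SEQ/CIGAR
# consistency oracle, depth, phasing tags and determinism.

test_that("rearrangement_spec validates its inputs", {
  chr1 <- c(chr1 = 30000L)
  blk <- data.frame(contig = "chr1", start = 1000L, end = 2000L,
                    strand = "-", stringsAsFactors = FALSE)
  expect_error(rearrangement_spec(blk, chr1), "forward")
  blk2 <- data.frame(contig = "chrX", start = 1L, end = 10L, strand = "+",
                     stringsAsFactors = FALSE)
  expect_error(rearrangement_spec(blk2, chr1), "not in contigs")
  blk3 <- data.frame(contig = "chr1", start = 29000L, end = 31000L,
                     strand = "+", stringsAsFactors = FALSE)
  expect_error(rearrangement_spec(blk3, chr1), "outside")
})

test_that("too-tight junction spacing is rejected", {
  spec <- rearrangement_spec(
    data.frame(contig = "chr1", start = c(9000L, 9980L, 10010L),
               end = c(9980L, 10010L, 11000L), strand = c("+", "-", "+"),
               stringsAsFactors = FALSE),
    contigs = c(chr1 = 30000L))
  expect_error(simulate_rearrangement(spec, tempfile()), "junctions closer")
})

test_that("contiguous blocks merge so junctions only mark real departures", {
  blocks <- data.frame(
    contig = "chr1", start = c(100L, 200L, 500L, 450L, 400L),
    end = c(200L, 300L, 600L, 500L, 450L),
    strand = c("+", "+", "-", "-", "-"), stringsAsFactors = FALSE)
  merged <- svtopo:::merge_contiguous_blocks(blocks)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$start, c(100L, 400L))
  expect_equal(merged$end, c(300L, 600L))
  expect_equal(merged$strand, c("+", "-"))
})

test_that("hap_layout places junctions at cumulative haplotype positions", {
  spec <- category_suite(FIXTURE_SEED)$inv
  lay <- svtopo:::hap_layout(spec)
  segs <- lay$segments
  expect_equal(segs$h_start[1], 0L)
  expect_equal(segs$h_end, cumsum(segs$end - segs$start))
  expect_length(lay$junctions, 2L)
  expect_equal(vapply(lay$junctions, `[[`, numeric(1), "hap_pos"),
               segs$h_end[1:2])
  j1 <- lay$junctions[[1]]
  expect_equal(j1$exit, list(chrom = "chr1", pos = 10000L, flank = "left"))
  expect_equal(j1$entry, list(chrom = "chr1", pos = 12000L, flank = "left"))
})

test_that("synthesized reference is seed-deterministic", {
  r1 <- synthesize_reference(c(a = 500L, b = 200L), seed = 42L)
  r2 <- synthesize_reference(c(a = 500L, b = 200L), seed = 42L)
  expect_identical(as.character(r1), as.character(r2))
  r3 <- synthesize_reference(c(a = 500L, b = 200L), seed = 43L)
  expect_false(identical(as.character(r1), as.character(r3)))
  expect_equal(Biostrings::width(r1), c(500L, 200L))
})

test_that("every alignment's matched bases equal the reference (oracle)", {
  for (nm in c("inv", "balanced-trans-dup")) {
    sim <- fixture(nm)
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "seq"))
    recs <- Rsamtools::scanBam(sim$bam, param = param)[[1]]
    expect_gt(length(recs$qname), 50)
    for (i in seq_along(recs$qname)) {
      cig <- recs$cigar[i]
      cl <- svtopo:::cigar_clip(cig, "left")
      m <- as.integer(sub("^([0-9]+S)?([0-9]+)M.*$", "\\2", cig))
      aligned <- substr(as.character(recs$seq[i]), cl + 1L, cl + m)
      refseq <- as.character(Biostrings::subseq(
        sim$reference[[as.character(recs$rname[i])]],
        recs$pos[i], recs$pos[i] + m - 1L))
      expect_equal(aligned, refseq,
                   info = paste(nm, recs$qname[i], cig))
    }
  }
})

test_that("SA tags list the read's other alignment segments consistently", {
  sim <- fixture("inv")
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "cigar"),
                                   tag = "SA")
  recs <- Rsamtools::scanBam(sim$bam, param = param)[[1]]
  split_reads <- names(which(table(recs$qname) > 1))
  expect_gt(length(split_reads), 5)
  for (qn in split_reads[1:5]) {
    idx <- which(recs$qname == qn)
    for (i in idx) {
      sa <- recs$tag$SA[i]
      expect_false(is.na(sa))
      listed <- length(strsplit(sa, ";", fixed = TRUE)[[1]])
      expect_equal(listed, length(idx) - 1L)
      # every other record's 1-based pos appears in this record's SA tag
      for (j in setdiff(idx, i))
        expect_match(sa, paste0(",", recs$pos[j], ","))
    }
  }
  # exactly one primary record per read
  prim <- tapply(bitwAnd(recs$flag, 2048L) == 0L, recs$qname, sum)
  expect_true(all(prim == 1L))
})

test_that("simulated depth approximates the requested coverage", {
  sim <- fixture("inv")
  d <- median_covered_depth(sim$bam)
  expect_gt(d, 15); expect_lt(d, 25)
  spec5 <- category_suite(FIXTURE_SEED)$inv
  spec5$coverage <- 5
  d5 <- median_covered_depth(fixture_spec("inv_cov5", spec5)$bam)
  expect_gt(d5, 2.5); expect_lt(d5, 7.5)
})

test_that("phase tags follow the spec and unphased_frac removes them", {
  sim <- fixture("phased-del-pair")
  param <- Rsamtools::ScanBamParam(what = "qname", tag = c("HP", "PS"))
  recs <- Rsamtools::scanBam(sim$bam, param = param)[[1]]
  expect_true(all(recs$tag$HP == 1L, na.rm = TRUE))
  expect_true(all(recs$tag$PS == 8000L, na.rm = TRUE))
  expect_true(any(!is.na(recs$tag$HP)))

  spec <- category_suite(FIXTURE_SEED)$inv
  spec$phase <- NULL
  recs2 <- Rsamtools::scanBam(fixture_spec("inv_nophase", spec)$bam,
                              param = param)[[1]]
  expect_true(is.null(recs2$tag$HP) || all(is.na(recs2$tag$HP)))
})

test_that("simulation output is byte-deterministic for a fixed seed", {
  spec <- category_suite(77001L)$`del-inv-del`
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  s1 <- simulate_rearrangement(spec, d1, prefix = "p")
  s2 <- simulate_rearrangement(spec, d2, prefix = "p")
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  expect_identical(readLines(s1$vcf), readLines(s2$vcf))
  expect_identical(s1$junctions, s2$junctions)
})

test_that("truth VCF is well-formed, sorted and mated", {
  sim <- fixture("balanced-trans-dup")
  calls <- parse_sv_vcf(sim$vcf)
  expect_true(all(calls$svtype == "BND"))
  expect_false(any(calls$single_ended))
  expect_equal(nrow(calls), nrow(sim$junctions))  # one call per junction
  lines <- readLines(sim$vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2L * nrow(sim$junctions))
})

test_that("truth networks mark over-cap structures unresolved", {
  sim <- fixture("unresolved-manyblocks")
  expect_length(sim$truth, 1L)
  expect_false(sim$truth[[1]]$resolved)
  expect_gt(nrow(sim$truth[[1]]$blocks), 20L)
})
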