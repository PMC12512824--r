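# VCF parsing, break extraction, JSON/BED round trips.

test_that("symbolic DEL/DUP/INV alleles parse to endpoint pairs", {
  vcf <- write_mini_vcf(c(
    "chr1\t1000\tdel1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=2000",
    "chr1\t5000\tdup1\tN\t<DUP:TANDEM>\t60\tPASS\tSVTYPE=DUP;END=6000",
    "chr2\t3000\tinv1\tN\t<INV>\t60\tPASS\tSVTYPE=INV;END=4000"))
  calls <- parse_sv_vcf(vcf, sample_id = "x")
  expect_equal(nrow(calls), 3L)
  del <- calls[calls$id == "del1", ]
  expect_equal(del$svtype, "DEL")
  expect_equal(c(del$pos_a, del$pos_b), c(1000L, 2000L))
  expect_equal(c(del$orient_a, del$orient_b), c("left", "right"))
  dup <- calls[calls$id == "dup1", ]
  expect_equal(dup$svtype, "DUP")   # DUP:TANDEM normalized
  expect_equal(c(dup$orient_a, dup$orient_b), c("right", "left"))
  expect_equal(calls[calls$id == "inv1", "svtype"], "INV")
  expect_true(all(calls$sample_id == "x"))
})

test_that("symbolic DEL without END falls back to SVLEN", {
  vcf <- write_mini_vcf(
    "chr1\t1000\tdel1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;SVLEN=-500")
  calls <- parse_sv_vcf(vcf)
  expect_equal(calls$pos_b, 1500L)
})

test_that("mated BND pairs collapse to one call with bracket orientations", {
  vcf <- write_mini_vcf(c(
    "chr1\t1000\tb1\tN\tN[chr2:5000[\t60\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr2\t5000\tb2\tN\t]chr1:1000]N\t60\tPASS\tSVTYPE=BND;MATEID=b1"))
  calls <- parse_sv_vcf(vcf)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$orient_a, "left")
  expect_equal(calls$orient_b, "right")
  expect_equal(calls$chrom_b, "chr2")
  expect_false(calls$single_ended)
})

test_that("all four BND bracket forms give the stated flank orientations", {
  expect_equal(svtopo:::parse_bnd_alt("N[chr2:10[")[c("orient_a", "orient_b")],
               list(orient_a = "left", orient_b = "right"))
  expect_equal(svtopo:::parse_bnd_alt("N]chr2:10]")[c("orient_a", "orient_b")],
               list(orient_a = "left", orient_b = "left"))
  expect_equal(svtopo:::parse_bnd_alt("]chr2:10]N")[c("orient_a", "orient_b")],
               list(orient_a = "right", orient_b = "left"))
  expect_equal(svtopo:::parse_bnd_alt("[chr2:10[N")[c("orient_a", "orient_b")],
               list(orient_a = "right", orient_b = "right"))
  expect_null(svtopo:::parse_bnd_alt("<DEL>"))
})

test_that("dangling MATEID warns and flags the record single-ended", {
  vcf <- write_mini_vcf(
    "chr1\t1000\tb1\tN\tN[chr2:5000[\t60\tPASS\tSVTYPE=BND;MATEID=ghost")
  expect_warning(calls <- parse_sv_vcf(vcf), "absent record")
  expect_true(calls$single_ended)
})

test_that("malformed VCF input fails with a clear error", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("this is not", "a VCF at all"), bad)
  expect_error(parse_sv_vcf(bad), "malformed VCF")
  expect_error(parse_sv_vcf(tempfile(fileext = ".vcf")), "not found")
})

test_that("extract_breaks converts endpoints to 0-based merged breaks", {
  vcf <- write_mini_vcf(c(
    "chr1\t1000\tdel1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=2000",
    # second call's endpoint 8 bp away from del1's: must merge (window 10)
    "chr1\t2008\tdel2\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=3000"))
  calls <- parse_sv_vcf(vcf)
  brk <- extract_breaks(calls, merge_window = 10L, contig_order = "chr1")
  expect_equal(nrow(brk), 3L)
  expect_equal(brk$pos, c(1000L, 2000L, 3000L))
  # merged break keeps both contributing variant ids and mixed sides -> both
  merged <- brk[brk$pos == 2000L, ]
  expect_setequal(unlist(merged$variant_id), c("del1", "del2"))
  expect_equal(merged$side, "both")
})

test_that("BND breaks use bracket-dependent position conversion", {
  vcf <- write_mini_vcf(c(
    "chr1\t1000\tb1\tN\tN[chr2:5001[\t60\tPASS\tSVTYPE=BND;MATEID=b2",
    "chr2\t5001\tb2\tN\t]chr1:1000]N\t60\tPASS\tSVTYPE=BND;MATEID=b1"))
  brk <- extract_breaks(parse_sv_vcf(vcf), contig_order = c("chr1", "chr2"))
  # left-anchored break: pos0 = POS; right-anchored: pos0 = POS - 1
  expect_equal(brk$pos[brk$chrom == "chr1"], 1000L)
  expect_equal(brk$pos[brk$chrom == "chr2"], 5000L)
  expect_equal(brk$side[brk$chrom == "chr1"], "left")
  expect_equal(brk$side[brk$chrom == "chr2"], "right")
})

test_that("JSON document round-trips networks losslessly", {
  sim <- fixture("del-inv-del")
  res <- extract_fixture(sim, sample_id = "rt")
  path <- tempfile(fileext = ".json")
  write_sv_json(res$networks, path, sample_id = "rt",
                contig_order = names(sim$contigs))
  doc <- read_sv_json(path)
  expect_equal(doc$sample_id, "rt")
  expect_equal(doc$contig_order, names(sim$contigs))
  expect_equal(length(doc$networks), length(res$networks))
  for (i in seq_along(res$networks)) {
    a <- res$networks[[i]]; b <- doc$networks[[i]]
    expect_true(networks_equivalent(a, b))
    expect_equal(a$connections$support, b$connections$support)
    expect_equal(a$connections$kind, b$connections$kind)
    expect_equal(a$variant_ids, b$variant_ids)
    expect_equal(a$filters, b$filters)
    expect_equal(a$start_break, b$start_break)
    expect_equal(a$blocks$support, b$blocks$support)
  }
  # and a second write of the re-read document is byte-identical
  path2 <- tempfile(fileext = ".json")
  write_sv_json(doc$networks, path2, sample_id = "rt",
                contig_order = doc$contig_order)
  expect_identical(readLines(path), readLines(path2))
})

test_that("BED output lists one line per block with support score", {
  sim <- fixture("inv")
  res <- extract_fixture(sim)
  path <- tempfile(fileext = ".bed")
  write_sv_bed(res$networks, path)
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bed), sum(vapply(res$networks,
                                     function(n) nrow(n$blocks), integer(1))))
  expect_true(all(bed$V3 > bed$V2))
  expect_true(any(grepl("inverted", bed$V4)))
})

test_that("read_annotation_bed skips malformed lines with a warning", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("track name=t", "# comment", "chr1\t10\t20\tgene1",
               "chr1\tnot\tnumbers", "chr2\t5\t2\tbackwards",
               "chr2\t100\t200"), path)
  expect_warning(bed <- read_annotation_bed(path), "2 malformed")
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$name, c("gene1", "."))
})
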