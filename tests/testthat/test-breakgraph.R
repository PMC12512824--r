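# Break matching, connection building, component assembly and block
# ordering.

test_that("clip-to-break matching honors the 10 bp tolerance boundary", {
  brk <- list(chrom = "chr1", pos = 5000L)
  for (off in 0:15) {
    ev <- make_evidence(seg_row("chr1", 4000L, 5000L + off,
                                clip_right = 500L))
    expect_equal(match_alignment_to_break(ev, brk, tol = 10L),
                 off <= 10L, info = paste("offset", off))
  }
})

test_that("short clips are not significant", {
  brk <- list(chrom = "chr1", pos = 5000L)
  ev49 <- make_evidence(seg_row("chr1", 4000L, 5000L, clip_right = 49L))
  ev50 <- make_evidence(seg_row("chr1", 4000L, 5000L, clip_right = 50L))
  expect_false(match_alignment_to_break(ev49, brk, min_clip = 50L))
  expect_true(match_alignment_to_break(ev50, brk, min_clip = 50L))
  # unclipped read ends never match, regardless of position
  ev0 <- make_evidence(seg_row("chr1", 4000L, 5000L))
  expect_false(match_alignment_to_break(ev0, brk))
})

test_that("left clips match via ref_start and other chromosomes never match", {
  brk <- list(chrom = "chr1", pos = 5000L)
  evl <- make_evidence(seg_row("chr1", 5003L, 6000L, clip_left = 200L))
  expect_true(match_alignment_to_break(evl, brk))
  evx <- make_evidence(seg_row("chr2", 4000L, 5000L, clip_right = 200L))
  expect_false(match_alignment_to_break(evx, brk))
})

test_that("collapse_break_sides merges by single linkage within the window", {
  bdf <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1"),
                    pos = c(100L, 108L, 116L, 300L),
                    side = c("left", "left", "left", "right"),
                    stringsAsFactors = FALSE)
  out <- svtopo:::collapse_break_sides(bdf, "chr1", window = 10L)
  # 100-108-116 chain into one break (single linkage) at the minimum pos
  expect_equal(out$pos, c(100L, 300L))
  out0 <- svtopo:::collapse_break_sides(bdf, "chr1", window = 0L)
  expect_equal(nrow(out0), 4L)
})

test_that("reference_blocks partitions the locus with flank margins", {
  brk <- data.frame(chrom = "chr1", pos = c(10000L, 12000L),
                    side = "left", stringsAsFactors = FALSE)
  blocks <- reference_blocks(brk, "chr1")
  # margin = max(round(0.1 * span), 200) = 200 for span 2000
  expect_equal(blocks$start, c(9800L, 10000L, 12000L))
  expect_equal(blocks$end, c(10000L, 12000L, 12200L))
  expect_equal(blocks$label, c("A", "B", "C"))
  expect_equal(blocks$is_flank, c(TRUE, FALSE, TRUE))
  # wide span: margin becomes 10% of span; left flank clamps at 0 and
  # collapses away when the first break sits at the chromosome start
  brk2 <- data.frame(chrom = "chr1", pos = c(0L, 10000L), side = "left",
                     stringsAsFactors = FALSE)
  blocks2 <- reference_blocks(brk2, "chr1")
  expect_equal(blocks2$start, c(0L, 10000L))
  expect_equal(blocks2$end, c(10000L, 11000L))
})

test_that("component assembly agrees with a union-find oracle", {
  set.seed(905001)
  for (trial in 1:50) {
    n <- sample(2:12, 1)
    breaks <- data.frame(chrom = "chr1", pos = seq_len(n) * 1000L,
                         stringsAsFactors = FALSE)
    m <- sample(0:(2 * n), 1)
    edges <- data.frame(from = sample(n, m, replace = TRUE),
                        to = sample(n, m, replace = TRUE))
    connections <- data.frame(
      chrom_1 = rep("chr1", m), pos_1 = breaks$pos[edges$from],
      chrom_2 = rep("chr1", m), pos_2 = breaks$pos[edges$to],
      stringsAsFactors = FALSE)
    got <- svtopo:::break_components(breaks, connections)
    want <- uf_components(n, edges)
    expect_equal(partition_signature(got), partition_signature(want),
                 info = paste("trial", trial))
  }
})

test_that("unsupported break coordinates are skipped, not fatal", {
  sim <- fixture("inv")
  # add a spurious deletion call far from any read
  vcf2 <- tempfile(fileext = ".vcf")
  lines <- readLines(sim$vcf)
  writeLines(c(lines,
               "chr1\t25000\tghost\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=25500"),
             vcf2)
  res <- extract_fixture(list(bam = sim$bam, vcf = vcf2))
  nets <- res$networks
  # the real event still reconstructs; ghost breaks appear in no network
  allpos <- unlist(lapply(nets, function(n) n$breaks$pos))
  expect_false(any(allpos %in% c(25000L, 25500L)))
  expect_true(networks_equivalent(sim$truth[[1]], nets[[1]]))
})

test_that("connect_breaks reports the skipped coordinates", {
  sim <- fixture("inv")
  contig_order <- names(sim$contigs)
  breaks <- extract_breaks(parse_sv_vcf(sim$vcf), contig_order = contig_order)
  breaks <- rbind(breaks,
                  data.frame(chrom = "chr1", pos = 25000L, side = "left",
                             variant_id = I(list("ghost")),
                             single_ended = FALSE))
  ev <- collect_alignment_evidence(sim$bam, breaks)
  conn <- connect_breaks(breaks, ev, contig_order = contig_order)
  expect_equal(conn$skipped$pos, 25000L)
  expect_false(25000L %in% conn$breaks$pos)
})

test_that("spanned connections carry inversion state and distinct-read support", {
  sim <- fixture("inv")
  res <- extract_fixture(sim)
  net <- res$networks[[1]]
  sp <- net$connections[net$connections$kind == "spanned", ]
  expect_equal(nrow(sp), 2L)
  expect_true(all(sp$inverted))
  truth <- sim$junctions
  for (i in seq_len(nrow(sp))) {
    # endpoints must match position AND flank (the two inversion junctions
    # share the same position pair and differ only in flanks)
    same <- truth$pos_1 == sp$pos_1[i] & truth$flank_1 == sp$flank_1[i] &
            truth$pos_2 == sp$pos_2[i] & truth$flank_2 == sp$flank_2[i]
    swap <- truth$pos_2 == sp$pos_1[i] & truth$flank_2 == sp$flank_1[i] &
            truth$pos_1 == sp$pos_2[i] & truth$flank_1 == sp$flank_2[i]
    hit <- which(same | swap)
    expect_length(hit, 1L)
    expect_equal(sp$support[i], truth$support[hit])
  }
})

test_that("find_start_break picks the reference-consistent entry", {
  sim <- fixture("del-inv-del")
  breaks <- extract_breaks(parse_sv_vcf(sim$vcf),
                           contig_order = names(sim$contigs))
  ev <- collect_alignment_evidence(sim$bam, breaks)
  conn <- connect_breaks(breaks, ev, contig_order = names(sim$contigs))
  net <- build_networks(conn, names(sim$contigs))[[1]]
  sb <- find_start_break(net, ev)
  expect_equal(sb$chrom, "chr1")
  expect_equal(sb$pos, 10000L)       # lowest break coordinate
  expect_equal(sb$entry_side, "left")
})

test_that("order_blocks reproduces each truth structure exactly", {
  for (nm in c("dup-del", "tandem-dup", "balanced-trans-dup")) {
    sim <- fixture(nm)
    res <- extract_fixture(sim)
    expect_equal(length(res$networks), length(sim$truth), info = nm)
    for (i in seq_along(sim$truth)) {
      eq <- networks_equivalent(sim$truth[[i]], res$networks[[i]])
      expect_true(eq, info = paste(nm, attr(eq, "reason")))
    }
  }
})

test_that("networks_equivalent detects structural differences", {
  sim <- fixture("inv")
  a <- sim$truth[[1]]
  b <- a
  b$resolved <- FALSE
  expect_false(networks_equivalent(a, b))
  expect_match(attr(networks_equivalent(a, b), "reason"), "resolved")
  c2 <- a
  c2$blocks$orientation[c2$blocks$orientation == "inverted"] <- "forward"
  expect_match(attr(networks_equivalent(a, c2), "reason"), "sample order")
  d <- a
  d$breaks$pos[1] <- d$breaks$pos[1] + 1L
  expect_match(attr(networks_equivalent(a, d), "reason"), "break sets")
})

test_that("block ordering degrades to unresolved beyond the block cap", {
  sim <- fixture("multi-block-del-inv")
  breaks <- extract_breaks(parse_sv_vcf(sim$vcf),
                           contig_order = names(sim$contigs))
  ev <- collect_alignment_evidence(sim$bam, breaks)
  conn <- connect_breaks(breaks, ev, contig_order = names(sim$contigs))
  net <- build_networks(conn, names(sim$contigs))[[1]]
  net$start_break <- find_start_break(net, ev)
  small_cap <- order_blocks(net, block_cap = 3L)
  expect_false(small_cap$resolved)
  # the partial (greedy) ordering is retained for rendering but stays
  # within the cap
  n_ordered <- sum(!is.na(small_cap$blocks$sample_order_index))
  expect_lte(n_ordered, 4L)
  full <- order_blocks(net)
  expect_true(full$resolved)
})
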