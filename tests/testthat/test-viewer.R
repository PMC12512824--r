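# Viewer index construction, filter semantics (with brute-force oracle) and
# HTML emission.

# random synthetic index for oracle tests
random_index <- function(n, seed) {
  set.seed(seed)
  data.frame(
    chrom = vapply(seq_len(n), function(i) {
      paste(sample(paste0("chr", 1:5), sample(1:2, 1)), collapse = ",")
    }, character(1)),
    start = sample.int(1e6, n),
    end = sample.int(1e6, n) + 1e6,
    region_size = sample.int(2e5, n),
    variant_ids = vapply(seq_len(n), function(i) {
      paste(paste0("v", sample.int(40, sample(1:10, 1))), collapse = ",")
    }, character(1)),
    n_variants = sample.int(10, n, replace = TRUE),
    sample_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
    image_path = sprintf("img%d.svg", seq_len(n)),
    stringsAsFactors = FALSE)
}

# brute-force per-row scan mirroring the documented semantics
oracle_filter <- function(rows, variant_id = NULL, sample_id = NULL,
                          n_variants = NULL, region_size = NULL,
                          chroms = NULL) {
  keep <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    ok <- TRUE
    if (!is.null(variant_id))
      ok <- ok && variant_id %in% strsplit(r$variant_ids, ",")[[1]]
    if (!is.null(sample_id)) ok <- ok && r$sample_id == sample_id
    if (!is.null(n_variants))
      ok <- ok && r$n_variants >= n_variants[1] && r$n_variants <= n_variants[2]
    if (!is.null(region_size))
      ok <- ok && r$region_size >= region_size[1] &&
            r$region_size <= region_size[2]
    if (!is.null(chroms))
      ok <- ok && any(strsplit(r$chrom, ",")[[1]] %in% chroms)
    keep[i] <- ok
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

test_that("filter_viewer_rows matches the brute-force oracle", {
  rows <- random_index(500, seed = 777001)
  set.seed(777002)
  for (q in 1:40) {
    args <- list(rows = rows)
    if (runif(1) < 0.4) args$variant_id <- paste0("v", sample.int(40, 1))
    if (runif(1) < 0.4) args$sample_id <- sample(c("s1", "s2", "s4"), 1)
    if (runif(1) < 0.5) args$n_variants <- sort(sample.int(10, 2))
    if (runif(1) < 0.5) args$region_size <- sort(sample.int(2e5, 2))
    if (runif(1) < 0.4) args$chroms <- sample(paste0("chr", 1:6),
                                              sample(1:3, 1))
    expect_identical(do.call(filter_viewer_rows, args),
                     do.call(oracle_filter, args), info = paste("query", q))
  }
})

test_that("the size/count filter window setting behaves inclusively", {
  rows <- random_index(500, seed = 777003)
  got <- filter_viewer_rows(rows, n_variants = c(2, 8),
                            region_size = c(8000, 90000))
  expect_identical(got, oracle_filter(rows, n_variants = c(2, 8),
                                      region_size = c(8000, 90000)))
  expect_true(all(got$n_variants >= 2 & got$n_variants <= 8))
  expect_true(all(got$region_size >= 8000 & got$region_size <= 90000))
  # boundary rows are kept
  rows2 <- rows
  rows2$n_variants[1] <- 2L; rows2$region_size[1] <- 8000L
  rows2$n_variants[2] <- 8L; rows2$region_size[2] <- 90000L
  got2 <- filter_viewer_rows(rows2, n_variants = c(2, 8),
                             region_size = c(8000, 90000))
  expect_true(all(c(rows2$image_path[1:2]) %in% got2$image_path))
})

test_that("chromosome filter keeps rows touching any selected chromosome", {
  rows <- data.frame(chrom = c("chr1", "chr1,chr5", "chr5"),
                     start = 1:3, end = 4:6, region_size = c(10L, 20L, 30L),
                     variant_ids = "v1", n_variants = 1L, sample_id = "s",
                     image_path = c("a", "b", "c"), stringsAsFactors = FALSE)
  got <- filter_viewer_rows(rows, chroms = "chr5")
  expect_equal(got$image_path, c("b", "c"))
})

test_that("build_viewer_index collates samples and skips missing images", {
  sim1 <- fixture("del-inv-del")
  sim2 <- fixture("dup-del")
  dir <- tempfile("imgs"); dir.create(dir)
  docs <- list()
  for (x in list(list(sim = sim1, id = "sampleA"),
                 list(sim = sim2, id = "sampleB"))) {
    res <- extract_fixture(x$sim, sample_id = x$id)
    jp <- file.path(tempdir(), paste0(x$id, ".json"))
    write_sv_json(res$kept, jp, sample_id = x$id,
                  contig_order = names(x$sim$contigs))
    doc <- read_sv_json(jp)
    for (net in doc$networks)
      render_network(net, plot_spec(), file.path(dir, image_filename(net)))
    docs[[length(docs) + 1L]] <- doc
  }
  idx <- build_viewer_index(docs, dir)
  expect_equal(nrow(idx), 2L)
  expect_setequal(idx$sample_id, c("sampleA", "sampleB"))
  expect_true(all(idx$n_variants >= 1))
  expect_true(all(file.exists(file.path(dir, idx$image_path))))
  # remove one image: its row is skipped with a warning
  unlink(file.path(dir, idx$image_path[1]))
  expect_warning(idx2 <- build_viewer_index(docs, dir), "row skipped")
  expect_equal(nrow(idx2), 1L)
})

test_that("emit_viewer writes a self-contained HTML plus TSV index", {
  rows <- random_index(5, seed = 777004)
  html <- tempfile(fileext = ".html")
  emit_viewer(rows, html)
  txt <- paste(readLines(html), collapse = "\n")
  expect_match(txt, "^<!DOCTYPE html>")
  expect_match(txt, "var ROWS = ")
  expect_match(txt, "function rowPasses")         # embedded filter logic
  expect_match(txt, "img1.svg", fixed = TRUE)     # data embedded
  expect_no_match(txt, "http://[^w]")             # no external resources
  tsv <- sub("\\.html$", ".tsv", html)
  expect_true(file.exists(tsv))
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$image_path, rows$image_path)
  # deterministic output
  html2 <- tempfile(fileext = ".html")
  emit_viewer(rows, html2)
  expect_identical(readLines(html), readLines(html2))
})
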