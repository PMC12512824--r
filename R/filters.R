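# Region-quality and simple-event filtering. Coverage/mapping-quality
# pruning removes likely alignment artifacts; the optional simple-network
# filter removes plain deletions, duplications and unresolved single-ended
# calls so review focuses on visually complex events.

#' Filtering configuration
#'
#' @param coverage_fold_limit drop a network when any block's mean depth
#'   exceeds this multiple of the sample's median covered depth (or falls
#'   below its inverse).
#' @param low_mapq_fraction_limit drop when more than this fraction of
#'   overlapping alignments map below `mapq_floor` (a repetitive-sequence
#'   proxy).
#' @param mapq_floor mapping-quality floor.
#' @param keep_simple keep one/two-break same-chromosome forward networks.
#' @param block_cap maximum rearranged blocks per network.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(coverage_fold_limit = 5,
                          low_mapq_fraction_limit = 0.2,
                          mapq_floor = 5L,
                          keep_simple = FALSE,
                          block_cap = 20L) {
  stopifnot(coverage_fold_limit > 0, low_mapq_fraction_limit >= 0,
            low_mapq_fraction_limit <= 1, mapq_floor >= 0, block_cap >= 2)
  structure(list(coverage_fold_limit = coverage_fold_limit,
                 low_mapq_fraction_limit = low_mapq_fraction_limit,
                 mapq_floor = as.integer(mapq_floor),
                 keep_simple = isTRUE(keep_simple),
                 block_cap = as.integer(block_cap)),
            class = "filter_config")
}

#' Median depth over covered bases of a BAM
#'
#' The background depth estimate is the weighted median of per-base coverage
#' over positions with nonzero coverage. Primary and supplementary
#' alignments both contribute (a split read covers each locus through
#' exactly one of its records), secondary alignments are excluded.
#' Restricting to covered bases keeps the estimate meaningful on targeted or
#' sparse data as well as whole genomes.
#'
#' @param bam_path indexed BAM.
#' @return numeric scalar (0 when the BAM is empty).
#' @export
median_covered_depth <- function(bam_path) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  aln <- GenomicAlignments::readGAlignments(bam_path, param = param)
  if (!length(aln)) return(0)
  cov <- GenomicAlignments::coverage(aln)
  vals <- unlist(lapply(cov, S4Vectors::runValue), use.names = FALSE)
  lens <- unlist(lapply(cov, S4Vectors::runLength), use.names = FALSE)
  keep <- vals > 0
  if (!any(keep)) return(0)
  vals <- vals[keep]; lens <- lens[keep]
  ord <- order(vals)
  vals <- vals[ord]; lens <- lens[ord]
  cum <- cumsum(as.numeric(lens))
  vals[which(cum >= cum[length(cum)] / 2)[1]]
}

block_mean_depth <- function(bam_path, chrom, start, end) {
  targets <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (!chrom %in% names(targets)) return(NA_real_)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    which = gr)
  aln <- GenomicAlignments::readGAlignments(bam_path, param = param)
  if (!length(aln)) return(0)
  ir <- IRanges::restrict(GenomicRanges::ranges(GenomicRanges::granges(aln)),
                          start + 1L, end)
  sum(as.numeric(IRanges::width(ir))) / (end - start)
}

#' Coverage and repeat (mapping-quality) filter
#'
#' Drops a network when any of its blocks shows abnormal coverage relative
#' to the sample median, or when too many overlapping alignments have low
#' mapping quality. The decision reason is recorded for the JSON output.
#'
#' @param net `sv_network` with blocks populated.
#' @param bam_path indexed BAM used for depth/mapq measurement.
#' @param cfg a [filter_config()].
#' @param median_depth optional precomputed [median_covered_depth()] value.
#' @return list(keep = logical, reasons = character vector).
#' @export
coverage_repeat_filter <- function(net, bam_path, cfg = filter_config(),
                                   median_depth = NULL) {
  if (is.null(median_depth)) median_depth <- median_covered_depth(bam_path)
  reasons <- character(0)
  blocks <- net$blocks
  if (!is.null(blocks) && nrow(blocks) && median_depth > 0) {
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      d <- block_mean_depth(bam_path, b$chrom, b$start, b$end)
      if (is.na(d)) {
        reasons <- c(reasons, sprintf("depth_unavailable:%s", b$label))
        next
      }
      # duplicated blocks legitimately carry up to ~2x depth on one
      # haplotype; flag only gross excess
      ratio <- d / median_depth
      if (ratio > cfg$coverage_fold_limit ||
          (!b$is_flank && ratio < 1 / cfg$coverage_fold_limit &&
           !is.na(b$sample_order_index)))
        reasons <- c(reasons, sprintf("abnormal_coverage:%s:%.2f", b$label,
                                      ratio))
    }
  }
  reg <- network_region(net)
  targets <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  reg <- reg[reg$chrom %in% names(targets), , drop = FALSE]
  if (nrow(reg)) {
    gr <- GenomicRanges::GRanges(reg$chrom,
                                 IRanges::IRanges(reg$start + 1L, reg$end))
    param <- Rsamtools::ScanBamParam(
      what = "mapq",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE),
      which = gr)
    mapq <- unlist(lapply(Rsamtools::scanBam(bam_path, param = param),
                          `[[`, "mapq"), use.names = FALSE)
    if (length(mapq)) {
      frac <- mean(mapq < cfg$mapq_floor, na.rm = TRUE)
      if (frac > cfg$low_mapq_fraction_limit)
        reasons <- c(reasons, sprintf("low_mapq_fraction:%.2f", frac))
    }
  }
  list(keep = !length(reasons), reasons = unique(sort(reasons)))
}

#' Simple-network filter
#'
#' When `keep_simple` is false, drops networks whose breaks are all on one
#' chromosome, forward-oriented and number at most two — unless an inverted
#' block appears within the network. This removes plain deletions and
#' duplications, and unresolved single-ended breakend calls.
#'
#' @param net `sv_network`.
#' @param cfg a [filter_config()].
#' @return list(keep = logical, reasons = character vector).
#' @export
simple_network_filter <- function(net, cfg = filter_config()) {
  if (cfg$keep_simple) return(list(keep = TRUE, reasons = character(0)))
  n_breaks <- nrow(unique(net$breaks[, c("chrom", "pos")]))
  one_chrom <- length(unique(net$breaks$chrom)) == 1L
  has_inverted <- any(net$connections$inverted) ||
    (!is.null(net$blocks) && any(net$blocks$orientation == "inverted"))
  if (one_chrom && n_breaks <= 2L && !has_inverted) {
    reason <- if (any(net$breaks$single_ended %||% FALSE) && n_breaks == 1L)
      "simple_network:single_ended" else "simple_network"
    return(list(keep = FALSE, reasons = reason))
  }
  list(keep = TRUE, reasons = character(0))
}

#' Apply all filters to a list of networks
#'
#' Both filters are evaluated on every network (they are independent and
#' order-insensitive); drop reasons accumulate on the network's `filters`
#' field. Networks are returned annotated, not removed, so that reasons are
#' preserved in JSON; use `kept_networks()` to subset.
#'
#' @param networks list of `sv_network`.
#' @param bam_path indexed BAM.
#' @param cfg a [filter_config()].
#' @return the annotated list.
#' @export
apply_filters <- function(networks, bam_path, cfg = filter_config()) {
  med <- median_covered_depth(bam_path)
  lapply(networks, function(net) {
    r1 <- coverage_repeat_filter(net, bam_path, cfg, median_depth = med)
    r2 <- simple_network_filter(net, cfg)
    net$filters <- sort(unique(c(net$filters, r1$reasons, r2$reasons)))
    net
  })
}

#' Networks that passed all filters
#' @param networks annotated list from [apply_filters()].
#' @return filtered list.
#' @export
kept_networks <- function(networks) {
  Filter(function(n) !length(n$filters), networks)
}
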