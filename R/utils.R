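# Shared helpers: contig ordering, coordinate conversion, small utilities.

#' Contig rank lookup
#'
#' Returns a function mapping contig names to integer ranks following a stated
#' contig order (normally the BAM header order). Contigs absent from the order
#' sort after all known contigs, alphabetically.
#'
#' @param contig_order character vector of contig names in rank order.
#' @return function(chrom) -> numeric rank vector.
#' @keywords internal
contig_ranker <- function(contig_order) {
  force(contig_order)
  function(chrom) {
    r <- match(chrom, contig_order)
    unknown <- is.na(r)
    if (any(unknown)) {
      extra <- sort(unique(chrom[unknown]))
      r[unknown] <- length(contig_order) + match(chrom[unknown], extra)
    }
    r
  }
}

#' Order rows by (contig rank, position)
#' @keywords internal
order_by_locus <- function(chrom, pos, contig_order) {
  rank <- contig_ranker(contig_order)(chrom)
  order(rank, pos)
}

# VCF positions are 1-based; everything internal is 0-based half-open.
vcf_to_internal_pos <- function(pos1) as.integer(pos1) - 1L
internal_to_vcf_pos <- function(pos0) as.integer(pos0) + 1L

#' Block labels in reference order: A, B, ..., Z, AA, AB, ...
#' @keywords internal
block_labels <- function(n) {
  if (n <= 0L) return(character(0))
  single <- LETTERS
  if (n <= 26L) return(single[seq_len(n)])
  double <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, double)[seq_len(n)]
}

#' Reverse-complement of a DNA string (plain character)
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

svtopo_version <- function() {
  as.character(utils::packageVersion("svtopo"))
}
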