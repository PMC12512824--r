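# Alignment evidence: reads near breaks, with each read's full segment chain
# reconstructed from its own record plus the SA tag, ordered along the read.

cigar_clip <- function(cigar, side = c("left", "right")) {
  side <- match.arg(side)
  pat <- if (side == "left") "^([0-9]+)[SH]" else "([0-9]+)[SH]$"
  m <- regmatches(cigar, regexpr(pat, cigar))
  if (!length(m)) return(0L)
  as.integer(sub("[SH]", "", m))
}

# segments table for one read from its record + SA entries; read-forward
# query start is the left clip for forward segments, the right clip for
# reverse ones
read_segments <- function(chrom, pos1, strand, cigar, mapq, sa) {
  seg1 <- data.frame(chrom = chrom, pos1 = pos1, strand = strand,
                     cigar = cigar, mapq = as.integer(mapq),
                     stringsAsFactors = FALSE)
  if (!is.na(sa) && nzchar(sa)) {
    parts <- strsplit(sa, ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    sa_df <- do.call(rbind, lapply(parts, function(p) {
      f <- strsplit(p, ",", fixed = TRUE)[[1]]
      data.frame(chrom = f[1], pos1 = as.integer(f[2]), strand = f[3],
                 cigar = f[4], mapq = as.integer(f[5]),
                 stringsAsFactors = FALSE)
    }))
    seg1 <- rbind(seg1, sa_df)
  }
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(seg1$cigar)
  cl <- vapply(seg1$cigar, cigar_clip, integer(1), side = "left")
  cr <- vapply(seg1$cigar, cigar_clip, integer(1), side = "right")
  out <- data.frame(
    chrom = seg1$chrom,
    ref_start = seg1$pos1 - 1L,
    ref_end = seg1$pos1 - 1L + ref_w,
    strand = seg1$strand,
    clip_left = unname(cl), clip_right = unname(cr),
    mapq = seg1$mapq,
    qstart = ifelse(seg1$strand == "+", cl, cr),
    stringsAsFactors = FALSE)
  out <- out[order(out$qstart, out$chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collect alignment evidence around breaks
#'
#' Fetches reads overlapping a window around each break and reconstructs
#' every read's full alignment-segment chain from its SA tag, recording
#' haplotype (HP) and phase set (PS) tags when present. A read fetched at
#' several breaks, or via both primary and supplementary records, is
#' returned once.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param breaks data.frame with `chrom`, `pos` (0-based).
#' @param window fetch window half-width in bp around each break.
#' @return list of evidence records: each a list with `read_name`,
#'   `haplotype`, `phase_set` and a `segments` data.frame (`chrom`,
#'   `ref_start`, `ref_end` 0-based half-open, `strand`, `clip_left`,
#'   `clip_right`, `mapq`, `qstart`) ordered by position in the read.
#' @export
collect_alignment_evidence <- function(bam_path, breaks, window = 1000L) {
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path)))
    stop("BAM index (.bai) not found for ", bam_path)
  targets <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  known <- breaks$chrom %in% names(targets)
  if (any(!known)) {
    warning("break contig(s) absent from BAM header, skipped: ",
            paste(unique(breaks$chrom[!known]), collapse = ", "))
    breaks <- breaks[known, , drop = FALSE]
  }
  if (!nrow(breaks)) return(list())
  gr <- GenomicRanges::GRanges(
    breaks$chrom,
    IRanges::IRanges(pmax(1L, breaks$pos - window + 1L),
                     pmin(unname(targets[breaks$chrom]), breaks$pos + window)))
  gr <- GenomicRanges::reduce(gr)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq"),
    tag = c("SA", "HP", "PS"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    which = gr)
  res <- Rsamtools::scanBam(bam_path, param = param)
  recs <- list()
  for (r in res) {
    n <- length(r$qname)
    if (!n) next
    sa <- r$tag$SA %||% rep(NA_character_, n)
    hp <- r$tag$HP %||% rep(NA_integer_, n)
    ps <- r$tag$PS %||% rep(NA_integer_, n)
    for (i in seq_len(n)) {
      recs[[length(recs) + 1L]] <- list(
        qname = r$qname[i], flag = r$flag[i],
        chrom = as.character(r$rname[i]), pos1 = r$pos[i],
        strand = as.character(r$strand[i]), cigar = r$cigar[i],
        mapq = r$mapq[i], sa = sa[i],
        hp = if (is.na(hp[i])) NA_integer_ else as.integer(hp[i]),
        ps = if (is.na(ps[i])) NA_integer_ else as.integer(ps[i]))
    }
  }
  if (!length(recs)) return(list())
  qnames <- vapply(recs, `[[`, character(1), "qname")
  out <- list()
  for (qn in sort(unique(qnames))) {
    idx <- which(qnames == qn)
    # prefer the primary record: its SA tag lists the full chain
    flags <- vapply(recs[idx], `[[`, integer(1), "flag")
    pick <- idx[order(bitwAnd(flags, 2048L) != 0L)][1]
    r <- recs[[pick]]
    out[[length(out) + 1L]] <- list(
      read_name = qn,
      haplotype = r$hp, phase_set = r$ps,
      segments = read_segments(r$chrom, r$pos1, r$strand, r$cigar, r$mapq,
                               r$sa))
  }
  out
}
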