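# SV VCF input: breakend (BND) records with bracket-notation mates, and
# symbolic DEL/DUP/INV/INS alleles. VCF positions are 1-based; breaks are
# converted to the package's 0-based convention in extract_breaks().

# parse one BND ALT string; returns NULL when not bracket notation
parse_bnd_alt <- function(alt) {
  m <- regmatches(alt, regexec(
    "^([ACGTNacgtn.]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([ACGTNacgtn.]*)$",
    alt, perl = TRUE))[[1]]
  if (!length(m)) return(NULL)
  anchored_left <- nzchar(m[2])   # base precedes bracket: left flank retained
  bracket <- m[3]
  list(chrom_b = m[4], pos_b = as.integer(m[5]),
       orient_a = if (anchored_left) "left" else "right",
       orient_b = if (bracket == "[") "right" else "left")
}

#' Parse an SV VCF into SV calls
#'
#' Breakend records are paired with their mates via MATEID; each mated pair
#' yields one call. Symbolic DEL/DUP/INV/INS alleles are converted to
#' endpoint pairs using END. BND records without a resolvable mate are
#' retained and flagged single-ended.
#'
#' @param vcf_path path to a VCF (plain or bgzipped).
#' @param sample_id sample name recorded on every call.
#' @return data.frame of SV calls: `id`, `svtype`, `chrom_a`, `pos_a`
#'   (1-based, as read), `chrom_b`, `pos_b`, `orient_a`, `orient_b`
#'   (`"left"`/`"right"`: which flank of the break continues in reference
#'   orientation), `mate_id`, `single_ended`, `sample_id`.
#' @export
parse_sv_vcf <- function(vcf_path, sample_id = "sample") {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcf_path, genome = "unknown")),
    error = function(e) stop("malformed VCF '", vcf_path, "': ",
                             conditionMessage(e)))
  n <- length(vcf)
  empty <- data.frame(id = character(0), svtype = character(0),
                      chrom_a = character(0), pos_a = integer(0),
                      chrom_b = character(0), pos_b = integer(0),
                      orient_a = character(0), orient_b = character(0),
                      mate_id = character(0), single_ended = logical(0),
                      sample_id = character(0), stringsAsFactors = FALSE)
  if (!n) return(empty)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  info <- VariantAnnotation::info(vcf)
  getv <- function(field) {
    if (!field %in% colnames(info)) return(rep(NA, n))
    v <- info[[field]]
    if (methods::is(v, "List") || is.list(v)) {
      vapply(v, function(x) {
        if (length(x)) as.character(as.vector(x)[1]) else NA_character_
      }, character(1))
    } else as.vector(v)
  }
  svtype <- as.character(getv("SVTYPE"))
  mateid <- as.character(getv("MATEID"))
  endpos <- suppressWarnings(as.integer(getv("END")))
  alts <- vapply(seq_len(n), function(i) {
    a <- VariantAnnotation::alt(vcf)[[i]]
    if (length(a)) as.character(a)[1] else ""
  }, character(1))
  sym <- sub("^<(.+)>$", "\\1", alts)
  sym_type <- sub("[:].*$", "", sym)   # e.g. DUP:TANDEM -> DUP
  svtype <- ifelse(is.na(svtype) & alts != sym, sym_type, svtype)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ty <- svtype[i]
    if (is.na(ty)) next
    if (ty == "BND") {
      bnd <- parse_bnd_alt(alts[i])
      if (is.null(bnd)) {
        rows[[i]] <- data.frame(
          id = ids[i], svtype = "BND", chrom_a = chrom[i], pos_a = pos[i],
          chrom_b = NA_character_, pos_b = NA_integer_,
          orient_a = if (grepl("^[ACGTNacgtn]", alts[i])) "left" else "right",
          orient_b = NA_character_, mate_id = NA_character_,
          single_ended = TRUE, sample_id = sample_id,
          stringsAsFactors = FALSE)
      } else {
        rows[[i]] <- data.frame(
          id = ids[i], svtype = "BND", chrom_a = chrom[i], pos_a = pos[i],
          chrom_b = bnd$chrom_b, pos_b = bnd$pos_b,
          orient_a = bnd$orient_a, orient_b = bnd$orient_b,
          mate_id = mateid[i], single_ended = FALSE, sample_id = sample_id,
          stringsAsFactors = FALSE)
      }
    } else if (ty %in% c("DEL", "DUP", "INV", "INS")) {
      e <- endpos[i]
      if (is.na(e)) {
        svlen <- suppressWarnings(abs(as.integer(getv("SVLEN")[i])))
        e <- if (ty == "INS" || is.na(svlen)) pos[i] else pos[i] + svlen
      }
      orients <- switch(ty,
        DEL = c("left", "right"), DUP = c("right", "left"),
        INV = c("both", "both"), INS = c("both", "both"))
      rows[[i]] <- data.frame(
        id = ids[i], svtype = ty, chrom_a = chrom[i], pos_a = pos[i],
        chrom_b = chrom[i], pos_b = as.integer(e),
        orient_a = orients[1], orient_b = orients[2],
        mate_id = NA_character_, single_ended = FALSE, sample_id = sample_id,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls)) return(empty)

  # resolve BND mates: warn on dangling MATEID, drop the mate's duplicate row
  is_bnd <- calls$svtype == "BND" & !calls$single_ended
  has_mate_field <- is_bnd & !is.na(calls$mate_id)
  dangling <- has_mate_field & !(calls$mate_id %in% calls$id)
  if (any(dangling)) {
    warning("MATEID references absent record(s): ",
            paste(calls$id[dangling], collapse = ", "),
            "; treating as single-ended")
    calls$single_ended[dangling] <- TRUE
  }
  keep <- rep(TRUE, nrow(calls))
  seen <- character(0)
  for (i in seq_len(nrow(calls))) {
    if (!is_bnd[i] || calls$single_ended[i]) next
    mid <- calls$mate_id[i]
    if (!is.na(mid) && mid %in% seen) keep[i] <- FALSE
    seen <- c(seen, calls$id[i])
  }
  calls <- calls[keep, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Extract breaks from SV calls
#'
#' Each call endpoint yields one break at a 0-based coordinate; endpoints of
#' different calls within the merge window collapse into a single break.
#' Symbolic INV calls contribute breakends on both sides of each endpoint
#' (the two inverted junctions).
#'
#' @param calls data.frame from [parse_sv_vcf()].
#' @param merge_window clustering radius in bp (default 10, the alignment
#'   matching tolerance).
#' @param contig_order chromosome rank order (default: sorted names seen).
#' @return data.frame of breaks: `chrom`, `pos` (0-based), `side`,
#'   `variant_id` (list column of contributing call IDs), `single_ended`.
#' @export
extract_breaks <- function(calls, merge_window = 10L, contig_order = NULL) {
  if (is.null(contig_order))
    contig_order <- sort(unique(c(calls$chrom_a, calls$chrom_b)))
  rows <- list()
  add <- function(chrom, pos0, side, id, single_ended = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = as.integer(pos0), side = side,
      variant_id = I(list(id)), single_ended = single_ended,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$svtype == "BND") {
      # flank "left": POS anchors the last retained base, break = POS (0-based)
      pa <- if (identical(cl$orient_a, "right")) cl$pos_a - 1L else cl$pos_a
      add(cl$chrom_a, pa, cl$orient_a, cl$id, cl$single_ended)
      if (!is.na(cl$chrom_b)) {
        pb <- if (identical(cl$orient_b, "right")) cl$pos_b - 1L else cl$pos_b
        add(cl$chrom_b, pb, cl$orient_b, cl$id, cl$single_ended)
      }
    } else if (cl$svtype == "DEL") {
      add(cl$chrom_a, cl$pos_a, "left", cl$id)
      add(cl$chrom_b, cl$pos_b, "right", cl$id)
    } else if (cl$svtype == "DUP") {
      add(cl$chrom_a, cl$pos_a, "right", cl$id)
      add(cl$chrom_b, cl$pos_b, "left", cl$id)
    } else if (cl$svtype == "INV") {
      add(cl$chrom_a, cl$pos_a, "left", cl$id)
      add(cl$chrom_a, cl$pos_a, "right", cl$id)
      add(cl$chrom_b, cl$pos_b, "left", cl$id)
      add(cl$chrom_b, cl$pos_b, "right", cl$id)
    } else if (cl$svtype == "INS") {
      add(cl$chrom_a, cl$pos_a, "left", cl$id)
      add(cl$chrom_a, cl$pos_a, "right", cl$id)
    }
  }
  bdf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), side = character(0),
               variant_id = I(list()), single_ended = logical(0))
  collapse_break_sides(bdf, contig_order, window = merge_window)
}
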