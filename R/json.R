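# Per-sample JSON and BED output. The JSON document round-trips losslessly
# and serializes with deterministic field order, so identical runs produce
# byte-identical files.

event_to_list <- function(net) {
  reg <- network_region(net)
  breaks <- data.frame(
    chrom = net$breaks$chrom, pos = as.integer(net$breaks$pos),
    side = net$breaks$side,
    single_ended = net$breaks$single_ended %||% rep(FALSE, nrow(net$breaks)),
    variant_ids = vapply(net$breaks$variant_id,
                         function(v) paste(unlist(v), collapse = ","),
                         character(1)),
    stringsAsFactors = FALSE)
  cn <- net$connections
  connections <- data.frame(
    chrom_1 = cn$chrom_1, pos_1 = as.integer(cn$pos_1), flank_1 = cn$flank_1,
    chrom_2 = cn$chrom_2, pos_2 = as.integer(cn$pos_2), flank_2 = cn$flank_2,
    kind = cn$kind, inverted = cn$inverted,
    support = as.integer(cn$support), phase_set = as.integer(cn$phase_set),
    stringsAsFactors = FALSE)
  blocks <- NULL
  if (!is.null(net$blocks)) {
    b <- net$blocks
    blocks <- data.frame(
      chrom = b$chrom, start = as.integer(b$start), end = as.integer(b$end),
      label = b$label, orientation = b$orientation,
      sample_order_index = as.integer(b$sample_order_index),
      is_flank = b$is_flank,
      support = as.integer(b$support %||% rep(0L, nrow(b))),
      stringsAsFactors = FALSE)
  }
  list(
    region = data.frame(chrom = reg$chrom, start = as.integer(reg$start),
                        end = as.integer(reg$end), stringsAsFactors = FALSE),
    variant_ids = as.character(net$variant_ids),
    resolved = isTRUE(net$resolved),
    filters = as.character(net$filters),
    start_break = if (is.null(net$start_break)) NULL else
      list(chrom = net$start_break$chrom,
           pos = as.integer(net$start_break$pos),
           entry_side = net$start_break$entry_side),
    breaks = breaks,
    connections = connections,
    blocks = blocks)
}

#' Write networks of one sample to JSON
#'
#' @param networks list of `sv_network` objects.
#' @param path output file.
#' @param sample_id sample name for the document header.
#' @param contig_order chromosome rank order stored with the document.
#' @return `path`, invisibly.
#' @export
write_sv_json <- function(networks, path, sample_id = "sample",
                          contig_order = NULL) {
  if (is.null(contig_order))
    contig_order <- if (length(networks)) networks[[1]]$contig_order else character(0)
  doc <- list(sample_id = sample_id,
              svtopo_version = svtopo_version(),
              contig_order = as.character(contig_order),
              events = unname(lapply(networks, event_to_list)))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

# one column from a list of JSON record objects; nulls become NA
rec_col <- function(recs, field, coerce) {
  coerce(unlist(lapply(recs, function(r) {
    v <- r[[field]]
    if (is.null(v)) NA else v
  })))
}

#' Read a per-sample JSON document back into networks
#'
#' @param path JSON file written by [write_sv_json()].
#' @return list with `sample_id`, `svtopo_version`, `contig_order` and
#'   `networks` (list of `sv_network` objects).
#' @export
read_sv_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  contig_order <- as.character(unlist(doc$contig_order))
  nets <- list()
  for (ev in doc$events) {
    bx <- ev$breaks
    breaks <- data.frame(
      chrom = rec_col(bx, "chrom", as.character),
      pos = rec_col(bx, "pos", as.integer),
      side = rec_col(bx, "side", as.character),
      single_ended = rec_col(bx, "single_ended", as.logical),
      stringsAsFactors = FALSE)
    breaks$variant_id <- I(lapply(rec_col(bx, "variant_ids", as.character),
                                  function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else strsplit(s, ",", fixed = TRUE)[[1]]
    }))
    cx <- ev$connections
    connections <- if (length(cx)) {
      cn <- data.frame(
        chrom_1 = rec_col(cx, "chrom_1", as.character),
        pos_1 = rec_col(cx, "pos_1", as.integer),
        flank_1 = rec_col(cx, "flank_1", as.character),
        chrom_2 = rec_col(cx, "chrom_2", as.character),
        pos_2 = rec_col(cx, "pos_2", as.integer),
        flank_2 = rec_col(cx, "flank_2", as.character),
        kind = rec_col(cx, "kind", as.character),
        inverted = rec_col(cx, "inverted", as.logical),
        support = rec_col(cx, "support", as.integer),
        phase_set = rec_col(cx, "phase_set", as.integer),
        stringsAsFactors = FALSE)
      cn$read_names <- I(replicate(nrow(cn), character(0), simplify = FALSE))
      cn
    } else empty_connections()
    blocks <- NULL
    if (length(ev$blocks)) {
      bl <- ev$blocks
      blocks <- data.frame(
        chrom = rec_col(bl, "chrom", as.character),
        start = rec_col(bl, "start", as.integer),
        end = rec_col(bl, "end", as.integer),
        label = rec_col(bl, "label", as.character),
        is_flank = rec_col(bl, "is_flank", as.logical),
        sample_order_index = rec_col(bl, "sample_order_index", as.integer),
        orientation = rec_col(bl, "orientation", as.character),
        support = rec_col(bl, "support", as.integer),
        stringsAsFactors = FALSE)
    }
    sb <- ev$start_break
    start_break <- if (is.null(sb)) NULL else
      list(chrom = as.character(sb$chrom), pos = as.integer(sb$pos),
           entry_side = as.character(sb$entry_side))
    nets[[length(nets) + 1L]] <- sv_network(
      breaks = breaks, connections = connections, blocks = blocks,
      start_break = start_break, resolved = isTRUE(ev$resolved),
      variant_ids = as.character(unlist(ev$variant_ids)),
      sample_id = as.character(doc$sample_id),
      contig_order = contig_order,
      filters = as.character(unlist(ev$filters)))
  }
  list(sample_id = as.character(doc$sample_id),
       svtopo_version = as.character(doc$svtopo_version),
       contig_order = contig_order, networks = nets)
}

#' Write event blocks as BED annotations
#'
#' One line per block: name encodes event index, label, orientation and
#' sample-order index; score is the block's alignment support.
#'
#' @param networks list of `sv_network` objects with blocks populated.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_sv_bed <- function(networks, path) {
  lines <- character(0)
  for (i in seq_along(networks)) {
    b <- networks[[i]]$blocks
    if (is.null(b) || !nrow(b)) next
    name <- sprintf("event%d_%s_%s_%s", i, b$label, b$orientation,
                    ifelse(is.na(b$sample_order_index), "deleted",
                           b$sample_order_index))
    sup <- b$support %||% rep(0L, nrow(b))
    lines <- c(lines, paste(b$chrom, b$start, b$end, name, sup, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation BED file
#'
#' BED 3+ with optional name in column 4. Malformed lines are skipped with a
#' warning.
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end`, `name`.
#' @export
read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  out <- list()
  bad <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (length(f) < 3L || is.na(s) || is.na(e) || e < s) {
      bad <- bad + 1L
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = f[1], start = s, end = e,
      name = if (length(f) >= 4L) f[4] else ".", stringsAsFactors = FALSE)
  }
  if (bad) warning(bad, " malformed BED line(s) skipped in ", path)
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  }
  do.call(rbind, out)
}
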