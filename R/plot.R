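# Block-diagram rendering. The layout follows the standard presentation for
# complex rearrangements: blocks ordered left-to-right as in the reference
# and top-to-bottom as in the sample haplotype, thickness scaled by
# alignment support, dotted lines connecting consecutive sample blocks, a
# reference axis showing all blocks (deleted ones included), a chain-plot
# track, and optional annotation tracks. SVG is the canonical format and is
# byte-deterministic; PNG and PDF are drawn from the same scene.

#' Plot specification
#'
#' @param image_format one of `"svg"`, `"png"`, `"pdf"`.
#' @param show_labels draw orientation and region-name labels.
#' @param annotation_tracks named list of BED file paths drawn as extra
#'   tracks.
#' @param thickness_range row thickness in px at support 0 and at/after
#'   `support_cap` (piecewise linear, saturating).
#' @param support_cap support count at which thickness saturates.
#' @param width image width in px.
#' @param dpi raster resolution (PNG only).
#' @return list of class `plot_spec`.
#' @export
plot_spec <- function(image_format = c("svg", "png", "pdf"),
                      show_labels = TRUE,
                      annotation_tracks = list(),
                      thickness_range = c(4, 16),
                      support_cap = 30L,
                      width = 900L,
                      dpi = 96L) {
  image_format <- match.arg(image_format)
  stopifnot(length(thickness_range) == 2,
            diff(thickness_range) >= 0, support_cap > 0)
  structure(list(image_format = image_format, show_labels = show_labels,
                 annotation_tracks = annotation_tracks,
                 thickness_range = thickness_range,
                 support_cap = as.integer(support_cap),
                 width = as.integer(width), dpi = as.integer(dpi)),
            class = "plot_spec")
}

# monotone, saturating support -> thickness mapping
support_thickness <- function(support, spec) {
  s <- pmin(pmax(support, 0), spec$support_cap)
  spec$thickness_range[1] +
    (spec$thickness_range[2] - spec$thickness_range[1]) * s / spec$support_cap
}

# x scale: one panel per chromosome, widths proportional to span with a
# minimum share, fixed gaps
panel_scale <- function(blocks, contig_order, width, pad = 40, gap = 30,
                        min_share = 0.15) {
  chroms <- unique(blocks$chrom[order_by_locus(blocks$chrom, blocks$start,
                                               contig_order)])
  spans <- vapply(chroms, function(ch) {
    b <- blocks[blocks$chrom == ch, ]
    max(b$end) - min(b$start)
  }, numeric(1))
  share <- pmax(spans / sum(spans), min_share)
  share <- share / sum(share)
  avail <- width - 2 * pad - gap * (length(chroms) - 1)
  px <- share * avail
  x0 <- pad + c(0, cumsum(px + gap))[seq_along(chroms)]
  panels <- lapply(seq_along(chroms), function(i) {
    b <- blocks[blocks$chrom == chroms[i], ]
    list(chrom = chroms[i], gstart = min(b$start), gend = max(b$end),
         x0 = x0[i], x1 = x0[i] + px[i])
  })
  names(panels) <- chroms
  panels
}

panel_x <- function(panels, chrom, gpos) {
  p <- panels[[chrom]]
  p$x0 + (gpos - p$gstart) / (p$gend - p$gstart) * (p$x1 - p$x0)
}

# ---- scene construction --------------------------------------------------

scene_add <- function(scene, kind, ...) {
  scene[[length(scene) + 1L]] <- c(list(kind = kind), list(...))
  scene
}

#' Build the drawing scene for a network
#'
#' Exposed mainly for tests; [render_network()] is the user entry point.
#'
#' @param net resolved or unresolved `sv_network` with blocks populated.
#' @param spec a [plot_spec()].
#' @return list(scene = primitive list, width, height).
#' @keywords internal
build_scene <- function(net, spec) {
  blocks <- net$blocks
  if (is.null(blocks) || !nrow(blocks)) stop("network has no blocks to draw")
  ord <- blocks[!is.na(blocks$sample_order_index), , drop = FALSE]
  ord <- ord[order(ord$sample_order_index), , drop = FALSE]
  panels <- panel_scale(blocks, net$contig_order, spec$width)
  row_h <- 26
  top <- 48
  n_rows <- max(1L, nrow(ord))
  axis_y <- top + n_rows * row_h + 24
  chain_y <- axis_y + 46
  ann_h <- 24 * length(spec$annotation_tracks)
  height <- chain_y + 30 + ann_h + 10
  sc <- list()

  reg <- network_region(net)
  title <- paste0(net$sample_id, "  ",
                  paste(sprintf("%s:%d-%d", reg$chrom, reg$start, reg$end),
                        collapse = "  "))
  sc <- scene_add(sc, "text", x = 12, y = 20, text = title, size = 13,
                  anchor = "start", color = "#222222")
  if (!net$resolved) {
    sc <- scene_add(sc, "text", x = spec$width - 12, y = 20,
                    text = "incompletely resolved", size = 12,
                    anchor = "end", color = "#b00020")
  }

  stroke_dash <- if (net$resolved) "" else "4,3"
  # sample rows, one per sample-order step
  prev_exit <- NULL
  for (k in seq_len(nrow(ord))) {
    b <- ord[k, ]
    y <- top + (k - 1) * row_h + row_h / 2
    x1 <- panel_x(panels, b$chrom, b$start)
    x2 <- panel_x(panels, b$chrom, b$end)
    th <- support_thickness(b$support %||% 0L, spec)
    sc <- scene_add(sc, "rect", x = x1, y = y - th / 2, w = x2 - x1, h = th,
                    fill = "#2b2b2b", dash = stroke_dash)
    inv <- b$orientation == "inverted"
    if (spec$show_labels) {
      # orientation arrowhead at the block's leading edge
      ax <- if (inv) x1 else x2
      dx <- if (inv) 6 else -6
      sc <- scene_add(sc, "poly",
                      xs = c(ax, ax + dx, ax + dx),
                      ys = c(y, y - 5, y + 5), fill = "#f0f0f0")
    }
    entry_x <- if (inv) x2 else x1
    exit_x <- if (inv) x1 else x2
    if (!is.null(prev_exit)) {
      sc <- scene_add(sc, "line", x1 = prev_exit$x, y1 = prev_exit$y,
                      x2 = entry_x, y2 = y, color = "#555555", dash = "3,3",
                      lwd = 1)
    }
    prev_exit <- list(x = exit_x, y = y)
  }

  # reference axis: every block, deleted ones included
  for (p in panels) {
    sc <- scene_add(sc, "line", x1 = p$x0, y1 = axis_y, x2 = p$x1,
                    y2 = axis_y, color = "#888888", dash = "", lwd = 1)
    sc <- scene_add(sc, "text", x = (p$x0 + p$x1) / 2, y = axis_y + 30,
                    text = sprintf("%s:%d-%d", p$chrom, p$gstart, p$gend),
                    size = 10, anchor = "middle", color = "#666666")
  }
  ref <- blocks[order_by_locus(blocks$chrom, blocks$start, net$contig_order), ]
  ref <- unique(ref[, c("chrom", "start", "end", "label",
                        "sample_order_index")])
  for (lab in unique(ref$label)) {
    b <- ref[ref$label == lab, ][1, ]
    x1 <- panel_x(panels, b$chrom, b$start)
    x2 <- panel_x(panels, b$chrom, b$end)
    present <- lab %in% ord$label
    sc <- scene_add(sc, "rect", x = x1, y = axis_y - 6, w = x2 - x1, h = 12,
                    fill = if (present) "#9ecae1" else "#f2f2f2",
                    stroke = "#666666", dash = "")
    sc <- scene_add(sc, "text", x = (x1 + x2) / 2, y = axis_y - 10,
                    text = lab, size = 10, anchor = "middle",
                    color = "#333333")
  }

  # chain plot: blocks in reference order, then in sample order/orientation
  ref_chain <- paste(unique(ref$label), collapse = " ")
  smp_chain <- paste0(ord$label,
                      ifelse(ord$orientation == "inverted", "'", ""),
                      collapse = " ")
  sc <- scene_add(sc, "text", x = 12, y = chain_y, size = 11,
                  text = paste0("reference: ", ref_chain), anchor = "start",
                  color = "#222222")
  sc <- scene_add(sc, "text", x = 12, y = chain_y + 16, size = 11,
                  text = paste0("sample:    ", smp_chain), anchor = "start",
                  color = "#222222")

  # annotation tracks
  ty <- chain_y + 34
  for (nm in names(spec$annotation_tracks)) {
    ann <- read_annotation_bed(spec$annotation_tracks[[nm]])
    sc <- scene_add(sc, "text", x = 12, y = ty + 9, text = nm, size = 10,
                    anchor = "start", color = "#444444")
    for (i in seq_len(nrow(ann))) {
      a <- ann[i, ]
      if (!a$chrom %in% names(panels)) next
      p <- panels[[a$chrom]]
      s <- max(a$start, p$gstart); e <- min(a$end, p$gend)
      if (e <= s) next
      x1 <- panel_x(panels, a$chrom, s)
      x2 <- panel_x(panels, a$chrom, e)
      sc <- scene_add(sc, "rect", x = x1, y = ty + 2, w = x2 - x1, h = 10,
                      fill = "#a1d99b", stroke = "#31a354", dash = "")
      if (spec$show_labels && a$name != ".") {
        sc <- scene_add(sc, "text", x = (x1 + x2) / 2, y = ty + 11,
                        text = a$name, size = 9, anchor = "middle",
                        color = "#1a5e20")
      }
    }
    ty <- ty + 24
  }
  list(scene = sc, width = spec$width, height = height)
}

# ---- backends ------------------------------------------------------------

fmt_num <- function(x) {
  s <- sprintf("%.2f", x)
  sub("\\.00$", "", s)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

scene_to_svg <- function(sc, width, height) {
  out <- c(sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                          "width=\"%d\" height=\"%s\" viewBox=\"0 0 %d %s\">"),
                   width, fmt_num(height), width, fmt_num(height)),
           "<rect width=\"100%\" height=\"100%\" fill=\"#ffffff\"/>")
  for (el in sc) {
    out <- c(out, switch(el$kind,
      rect = {
        dashed <- !is.null(el$dash) && nzchar(el$dash)
        stroke <- el$stroke %||% (if (dashed) "#555555" else NULL)
        sprintf(
          "<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"%s%s/>",
          fmt_num(el$x), fmt_num(el$y), fmt_num(el$w), fmt_num(el$h), el$fill,
          if (!is.null(stroke)) sprintf(" stroke=\"%s\"", stroke) else "",
          if (dashed) sprintf(" stroke-dasharray=\"%s\"", el$dash) else "")
      },
      line = sprintf(
        paste0("<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
               "stroke=\"%s\" stroke-width=\"%s\"%s/>"),
        fmt_num(el$x1), fmt_num(el$y1), fmt_num(el$x2), fmt_num(el$y2),
        el$color, fmt_num(el$lwd),
        if (nzchar(el$dash)) sprintf(" stroke-dasharray=\"%s\"", el$dash)
        else ""),
      poly = sprintf(
        "<polygon points=\"%s\" fill=\"%s\"/>",
        paste(paste0(fmt_num(el$xs), ",", fmt_num(el$ys)), collapse = " "),
        el$fill),
      text = sprintf(
        paste0("<text x=\"%s\" y=\"%s\" font-size=\"%s\" ",
               "font-family=\"monospace\" text-anchor=\"%s\" ",
               "fill=\"%s\">%s</text>"),
        fmt_num(el$x), fmt_num(el$y), fmt_num(el$size),
        el$anchor, el$color, xml_escape(el$text))))
  }
  c(out, "</svg>")
}

scene_to_device <- function(sc, width, height) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, width), ylim = c(height, 0))
  for (el in sc) {
    switch(el$kind,
      rect = graphics::rect(el$x, el$y + el$h, el$x + el$w, el$y,
                            col = el$fill,
                            border = el$stroke %||% NA),
      line = graphics::segments(el$x1, el$y1, el$x2, el$y2, col = el$color,
                                lwd = el$lwd,
                                lty = if (nzchar(el$dash)) 2 else 1),
      poly = graphics::polygon(el$xs, el$ys, col = el$fill, border = NA),
      text = graphics::text(el$x, el$y, labels = el$text,
                            cex = el$size / 12, col = el$color,
                            adj = switch(el$anchor, start = 0,
                                         middle = 0.5, end = 1)))
  }
}

#' Render a network as a block-diagram image
#'
#' One row per sample-order step with the row's filled segment spanning the
#' block's reference extent; inverted blocks carry a reversed direction
#' marker; dotted lines connect consecutive sample blocks; deleted blocks
#' appear on the reference axis only. Unresolved networks are drawn with
#' dashed block borders and an "incompletely resolved" banner. SVG output is
#' byte-identical across runs for identical input.
#'
#' @param net `sv_network` with blocks populated.
#' @param spec a [plot_spec()].
#' @param out_path output image path (extension independent of format).
#' @return `out_path`, invisibly.
#' @export
render_network <- function(net, spec = plot_spec(), out_path) {
  sn <- build_scene(net, spec)
  if (spec$image_format == "svg") {
    writeLines(scene_to_svg(sn$scene, sn$width, sn$height), out_path,
               useBytes = TRUE)
  } else if (spec$image_format == "png") {
    grDevices::png(out_path, width = sn$width, height = ceiling(sn$height),
                   res = spec$dpi)
    on.exit(grDevices::dev.off())
    scene_to_device(sn$scene, sn$width, sn$height)
  } else {
    grDevices::pdf(out_path, width = sn$width / 72,
                   height = ceiling(sn$height) / 72)
    on.exit(grDevices::dev.off())
    scene_to_device(sn$scene, sn$width, sn$height)
  }
  invisible(out_path)
}

#' Chain-plot strings for a network
#'
#' Returns the two label sequences drawn in the chain track: blocks in
#' reference order, and in sample order with a prime mark on inverted
#' blocks (deleted blocks absent, duplicated blocks repeated).
#'
#' @param net `sv_network` with blocks populated.
#' @return list(reference = character, sample = character).
#' @export
chain_plot <- function(net) {
  blocks <- net$blocks
  ref <- blocks[order_by_locus(blocks$chrom, blocks$start, net$contig_order), ]
  ord <- blocks[!is.na(blocks$sample_order_index), , drop = FALSE]
  ord <- ord[order(ord$sample_order_index), , drop = FALSE]
  list(reference = unique(ref$label),
       sample = paste0(ord$label,
                       ifelse(ord$orientation == "inverted", "'", "")))
}

#' Default image file name for an event
#' @param net `sv_network`.
#' @param ext file extension.
#' @return file name `{sample}_{chrom}-{start}-{end}.{ext}`.
#' @export
image_filename <- function(net, ext = "svg") {
  reg <- network_region(net)
  sprintf("%s_%s-%d-%d.%s", net$sample_id, reg$chrom[1], reg$start[1],
          reg$end[1], ext)
}
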