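# Staged pipeline: extract (VCF+BAM -> JSON+BED), plot (JSON -> images),
# viewer (JSON+images -> HTML). Stages are separable so events can be
# re-plotted without re-extraction.

#' Pipeline run configuration
#'
#' @param bam indexed BAM of phased, aligned long reads.
#' @param vcf SV VCF.
#' @param sample_id sample name (used in outputs and file names).
#' @param out_dir output directory.
#' @param tolerance clip-to-break matching tolerance bp (default 10).
#' @param min_clip minimum significant soft-clip bp (default 50).
#' @param merge_window break clustering radius bp (default: `tolerance`).
#' @param window evidence fetch half-width bp around breaks.
#' @param phase_gap maximum gap bridged by a phased connection, bp.
#' @param filter a [filter_config()].
#' @param plot a [plot_spec()].
#' @param block_cap maximum rearranged blocks per network.
#' @param margin_frac,margin_min flanking block margin rule.
#' @param verbose emit per-stage progress messages.
#' @return list of class `run_config`.
#' @export
run_config <- function(bam, vcf, sample_id = "sample",
                       out_dir = "svtopo_out",
                       tolerance = 10L, min_clip = 50L,
                       merge_window = tolerance, window = 1000L,
                       phase_gap = 5e5,
                       filter = filter_config(),
                       plot = plot_spec(),
                       block_cap = 20L,
                       margin_frac = 0.1, margin_min = 200L,
                       verbose = TRUE) {
  cfg <- list(bam = bam, vcf = vcf, sample_id = sample_id, out_dir = out_dir,
              tolerance = as.integer(tolerance),
              min_clip = as.integer(min_clip),
              merge_window = as.integer(merge_window),
              window = as.integer(window), phase_gap = phase_gap,
              filter = filter, plot = plot, block_cap = as.integer(block_cap),
              margin_frac = margin_frac, margin_min = as.integer(margin_min),
              verbose = isTRUE(verbose))
  class(cfg) <- "run_config"
  cfg
}

cfg_msg <- function(cfg, ...) if (cfg$verbose) message(sprintf(...))

#' Extract and reconstruct SV networks
#'
#' Runs parse -> breaks -> evidence -> connect -> networks -> start break ->
#' block order -> support -> filters, then writes the per-sample JSON and
#' BED. All networks (kept and filtered, with reasons) are serialized.
#'
#' @param cfg a [run_config()].
#' @return invisibly, list(json, bed, networks, kept).
#' @export
run_extract <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!file.exists(cfg$bam)) stop("BAM not found: ", cfg$bam)
  if (!file.exists(cfg$vcf)) stop("VCF not found: ", cfg$vcf)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  contig_order <- names(Rsamtools::scanBamHeader(cfg$bam)[[1]]$targets)

  calls <- parse_sv_vcf(cfg$vcf, sample_id = cfg$sample_id)
  cfg_msg(cfg, "parsed %d SV call(s)", nrow(calls))
  breaks <- extract_breaks(calls, merge_window = cfg$merge_window,
                           contig_order = contig_order)
  cfg_msg(cfg, "extracted %d break(s)", nrow(breaks))
  evidence <- collect_alignment_evidence(cfg$bam, breaks,
                                         window = cfg$window)
  cfg_msg(cfg, "collected evidence from %d read(s)", length(evidence))
  conn <- connect_breaks(breaks, evidence, tol = cfg$tolerance,
                         min_clip = cfg$min_clip,
                         contig_order = contig_order,
                         phase_gap = cfg$phase_gap)
  cfg_msg(cfg, "%d connection(s); %d break(s) skipped (no alignment support)",
          nrow(conn$connections), nrow(conn$skipped))
  nets <- build_networks(conn, contig_order, sample_id = cfg$sample_id)
  cfg_msg(cfg, "%d network(s)", length(nets))
  nets <- lapply(nets, function(net) {
    net$start_break <- find_start_break(net, evidence, tol = cfg$tolerance,
                                        min_clip = cfg$min_clip)
    net <- order_blocks(net, block_cap = cfg$block_cap,
                        margin_frac = cfg$margin_frac,
                        margin_min = cfg$margin_min)
    count_support(net, evidence, tol = cfg$tolerance,
                  min_clip = cfg$min_clip)
  })
  nets <- apply_filters(nets, cfg$bam, cfg$filter)
  kept <- kept_networks(nets)
  cfg_msg(cfg, "%d network(s) kept after filters (%d resolved)",
          length(kept), sum(vapply(kept, `[[`, logical(1), "resolved")))

  json_path <- file.path(cfg$out_dir, paste0(cfg$sample_id, ".json"))
  bed_path <- file.path(cfg$out_dir, paste0(cfg$sample_id, ".bed"))
  write_sv_json(nets, json_path, sample_id = cfg$sample_id,
                contig_order = contig_order)
  write_sv_bed(nets, bed_path)
  invisible(list(json = json_path, bed = bed_path, networks = nets,
                 kept = kept))
}

#' Render images for extracted events
#'
#' One image per kept network, named `{sample}_{chrom}-{start}-{end}.{ext}`.
#'
#' @param cfg a [run_config()].
#' @param json_paths JSON files written by [run_extract()].
#' @return invisibly, character vector of image paths.
#' @export
run_plot <- function(cfg, json_paths) {
  image_dir <- file.path(cfg$out_dir, "images")
  dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (jp in json_paths) {
    doc <- read_sv_json(jp)
    for (net in doc$networks) {
      if (length(net$filters)) next
      fn <- file.path(image_dir, image_filename(net, cfg$plot$image_format))
      render_network(net, cfg$plot, fn)
      paths <- c(paths, fn)
    }
  }
  cfg_msg(cfg, "rendered %d image(s)", length(paths))
  invisible(paths)
}

#' Build the HTML viewer over one or more samples
#'
#' @param cfg a [run_config()].
#' @param json_paths JSON files of all samples to merge into one index.
#' @param image_dir directory of rendered images (default: the pipeline's).
#' @return invisibly, the HTML path.
#' @export
run_viewer <- function(cfg, json_paths, image_dir = NULL) {
  if (is.null(image_dir)) image_dir <- file.path(cfg$out_dir, "images")
  docs <- lapply(json_paths, read_sv_json)
  docs <- lapply(docs, function(d) {
    d$networks <- Filter(function(n) !length(n$filters), d$networks)
    d
  })
  rows <- build_viewer_index(docs, image_dir, ext = cfg$plot$image_format)
  html <- file.path(image_dir, "index.html")
  emit_viewer(rows, html)
  cfg_msg(cfg, "viewer with %d row(s): %s", nrow(rows), html)
  invisible(html)
}

#' Run extract, plot and viewer in sequence
#' @param cfg a [run_config()].
#' @return invisibly, list(json, bed, images, html).
#' @export
run_all <- function(cfg) {
  ex <- run_extract(cfg)
  imgs <- run_plot(cfg, ex$json)
  html <- run_viewer(cfg, ex$json)
  invisible(list(json = ex$json, bed = ex$bed, images = imgs, html = html))
}
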