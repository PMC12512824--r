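# Serverless HTML table viewer: one row per rendered event, click-to-filter
# on variant ID / variant count / sample, and a filter window for region
# size ranges and chromosomes. The filter semantics live in
# filter_viewer_rows(), mirrored verbatim by the embedded JavaScript.

#' Build the viewer index
#'
#' One row per rendered event across one or more samples, sorted by
#' (chromosome rank, start). Events whose image file is missing are skipped
#' with a warning.
#'
#' @param docs list of documents as returned by [read_sv_json()] (or the
#'   in-memory equivalent: list(sample_id, contig_order, networks)).
#' @param image_dir directory holding the rendered images.
#' @param ext image extension used at render time.
#' @return data.frame: `chrom` (comma-joined when an event spans several),
#'   `start`, `end`, `region_size`, `variant_ids`, `n_variants`,
#'   `sample_id`, `image_path` (relative to the viewer's directory).
#' @export
build_viewer_index <- function(docs, image_dir, ext = "svg") {
  rows <- list()
  contig_order <- character(0)
  for (doc in docs) {
    contig_order <- unique(c(contig_order, doc$contig_order))
    for (net in doc$networks) {
      reg <- network_region(net)
      fn <- image_filename(net, ext)
      if (!file.exists(file.path(image_dir, fn))) {
        warning("no image for event ", fn, "; row skipped")
        next
      }
      size <- sum(reg$end - reg$start)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = paste(reg$chrom, collapse = ","),
        start = reg$start[1], end = reg$end[1],
        region_size = size,
        variant_ids = paste(net$variant_ids, collapse = ","),
        n_variants = length(net$variant_ids),
        sample_id = net$sample_id,
        image_path = fn,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_size = integer(0),
                      variant_ids = character(0), n_variants = integer(0),
                      sample_id = character(0), image_path = character(0)))
  }
  idx <- do.call(rbind, rows)
  first_chrom <- sub(",.*$", "", idx$chrom)
  idx <- idx[order_by_locus(first_chrom, idx$start, contig_order), ,
             drop = FALSE]
  rownames(idx) <- NULL
  idx
}

#' Filter viewer index rows
#'
#' The reference implementation of the viewer's filter logic: all bounds
#' inclusive; a chromosome filter keeps rows touching any selected
#' chromosome (so translocations stay visible); NULL means no constraint.
#'
#' @param rows index data.frame from [build_viewer_index()].
#' @param variant_id keep rows whose variant-ID list contains this ID.
#' @param sample_id keep rows with this sample.
#' @param n_variants length-2 inclusive range of variant counts.
#' @param region_size length-2 inclusive range of region sizes in bp.
#' @param chroms character vector of chromosomes.
#' @return the filtered data.frame.
#' @export
filter_viewer_rows <- function(rows, variant_id = NULL, sample_id = NULL,
                               n_variants = NULL, region_size = NULL,
                               chroms = NULL) {
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(variant_id)) {
    keep <- keep & vapply(strsplit(rows$variant_ids, ",", fixed = TRUE),
                          function(v) variant_id %in% v, logical(1))
  }
  if (!is.null(sample_id)) keep <- keep & rows$sample_id == sample_id
  if (!is.null(n_variants)) {
    keep <- keep & rows$n_variants >= n_variants[1] &
            rows$n_variants <= n_variants[2]
  }
  if (!is.null(region_size)) {
    keep <- keep & rows$region_size >= region_size[1] &
            rows$region_size <= region_size[2]
  }
  if (!is.null(chroms)) {
    keep <- keep & vapply(strsplit(rows$chrom, ",", fixed = TRUE),
                          function(v) any(v %in% chroms), logical(1))
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the self-contained HTML viewer
#'
#' A single file working from the local filesystem with no server: a table
#' of events; clicking a row displays its image; clicking a variant ID,
#' variant-count or sample cell filters on that value; a filter window
#' offers variant-ID/sample text filters, variant-count and region-size
#' ranges, and chromosome selection. Image paths are relative to the output
#' directory. A machine-readable TSV of the index is written alongside.
#'
#' @param rows index data.frame from [build_viewer_index()].
#' @param out_path output HTML file.
#' @return `out_path`, invisibly.
#' @export
emit_viewer <- function(rows, out_path) {
  data_json <- jsonlite::toJSON(rows, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA)
  html <- c(
"<!DOCTYPE html>",
"<html><head><meta charset=\"utf-8\"><title>SV image browser</title>",
"<style>",
"body{font-family:sans-serif;margin:16px;}",
"table{border-collapse:collapse;width:100%;}",
"th,td{border:1px solid #ccc;padding:4px 8px;font-size:13px;}",
"tr.evt:hover{background:#eef;} tr.sel{background:#dde8ff;}",
"td.click{cursor:pointer;color:#1a0dab;}",
"#filters{border:1px solid #aaa;padding:8px;margin-bottom:12px;}",
"#filters label{margin-right:12px;font-size:13px;}",
"#filters input{width:90px;}",
"#img{margin-top:12px;} #img img{max-width:100%;border:1px solid #ddd;}",
"</style></head><body>",
"<h2>SV image browser</h2>",
"<div id=\"filters\">",
"<label>variant ID <input id=\"f_vid\"></label>",
"<label>sample <input id=\"f_sample\"></label>",
"<label>variants <input id=\"f_nmin\" size=\"4\">&ndash;<input id=\"f_nmax\" size=\"4\"></label>",
"<label>size (bp) <input id=\"f_smin\">&ndash;<input id=\"f_smax\"></label>",
"<label>chromosomes <input id=\"f_chroms\" placeholder=\"all\"></label>",
"<button onclick=\"refresh()\">apply</button>",
"<button onclick=\"clearFilters()\">clear</button>",
"</div>",
"<table id=\"tbl\"><thead><tr>",
"<th>chromosome</th><th>start</th><th>end</th><th>region size</th>",
"<th>variant IDs</th><th>n variants</th><th>sample</th>",
"</tr></thead><tbody></tbody></table>",
"<div id=\"img\"></div>",
"<script>",
paste0("var ROWS = ", data_json, ";"),
"function getFilters(){",
"  var num=function(id){var v=document.getElementById(id).value;",
"    return v===''?null:Number(v);};",
"  var txt=function(id){var v=document.getElementById(id).value.trim();",
"    return v===''?null:v;};",
"  var ch=txt('f_chroms');",
"  return {variant_id:txt('f_vid'), sample_id:txt('f_sample'),",
"    n_min:num('f_nmin'), n_max:num('f_nmax'),",
"    s_min:num('f_smin'), s_max:num('f_smax'),",
"    chroms: ch===null?null:ch.split(',').map(function(s){return s.trim();})};",
"}",
"// mirrors the package's filter_viewer_rows(): inclusive bounds; a",
"// chromosome filter keeps rows touching any selected chromosome",
"function rowPasses(r,f){",
"  if(f.variant_id!==null &&",
"     r.variant_ids.split(',').indexOf(f.variant_id)<0) return false;",
"  if(f.sample_id!==null && r.sample_id!==f.sample_id) return false;",
"  if(f.n_min!==null && r.n_variants<f.n_min) return false;",
"  if(f.n_max!==null && r.n_variants>f.n_max) return false;",
"  if(f.s_min!==null && r.region_size<f.s_min) return false;",
"  if(f.s_max!==null && r.region_size>f.s_max) return false;",
"  if(f.chroms!==null){",
"    var touch=r.chrom.split(',');",
"    if(!touch.some(function(c){return f.chroms.indexOf(c)>=0;}))",
"      return false;",
"  }",
"  return true;",
"}",
"function setFilter(id,val){document.getElementById(id).value=val;refresh();}",
"function clearFilters(){",
"  ['f_vid','f_sample','f_nmin','f_nmax','f_smin','f_smax','f_chroms']",
"    .forEach(function(id){document.getElementById(id).value='';});",
"  refresh();",
"}",
"function showImage(tr,path){",
"  var sel=document.querySelectorAll('tr.sel');",
"  for(var i=0;i<sel.length;i++) sel[i].classList.remove('sel');",
"  tr.classList.add('sel');",
"  document.getElementById('img').innerHTML=",
"    '<img src=\"'+path+'\" alt=\"'+path+'\">';",
"}",
"function refresh(){",
"  var f=getFilters();",
"  var tb=document.querySelector('#tbl tbody');",
"  tb.innerHTML='';",
"  ROWS.filter(function(r){return rowPasses(r,f);}).forEach(function(r){",
"    var tr=document.createElement('tr');",
"    tr.className='evt';",
"    tr.onclick=function(){showImage(tr,r.image_path);};",
"    function td(v,cls,fn){var d=document.createElement('td');",
"      d.textContent=v;if(cls)d.className=cls;",
"      if(fn)d.onclick=function(e){e.stopPropagation();fn();};",
"      tr.appendChild(d);}",
"    td(r.chrom); td(r.start); td(r.end); td(r.region_size);",
"    td(r.variant_ids,'click',function(){",
"      setFilter('f_vid',r.variant_ids.split(',')[0]);});",
"    td(r.n_variants,'click',function(){",
"      setFilter('f_nmin',r.n_variants);setFilter('f_nmax',r.n_variants);});",
"    td(r.sample_id,'click',function(){setFilter('f_sample',r.sample_id);});",
"    tb.appendChild(tr);",
"  });",
"}",
"refresh();",
"</script></body></html>")
  writeLines(html, out_path, useBytes = TRUE)
  tsv <- sub("\\.html?$", ".tsv", out_path)
  if (tsv == out_path) tsv <- paste0(out_path, ".tsv")
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}
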