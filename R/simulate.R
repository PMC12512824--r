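# Synthetic rearrangement fixtures: seeded reference, phased split-read
# alignments (BAM), truth VCF (mated BNDs) and the expected reconstruction.
# Every pipeline stage is testable against these without external data.

#' Describe a scripted rearrangement
#'
#' A rearrangement is described as the ordered list of reference intervals
#' making up the sample haplotype, left to right. Adjacent blocks that are
#' reference-contiguous (same contig, same strand, abutting) are merged, so a
#' junction exists exactly where the haplotype departs from the reference.
#' The first and last blocks must be forward-oriented: they carry the
#' reference-consistent flanking sequence through which reads enter and leave
#' the event.
#'
#' @param blocks data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open) and `strand` (`"+"` or `"-"`), in sample-haplotype order.
#' @param contigs named integer vector of contig lengths for the synthetic
#'   reference; names define the contig order used throughout.
#' @param flanks bp of extra reference-consistent sequence simulated on each
#'   side of the outermost blocks.
#' @param coverage target mean read depth over the sample haplotype.
#' @param read_length numeric of length 2: mean and sd of read length (bp).
#' @param seed integer seed; the same spec and seed always produce identical
#'   output files.
#' @param phase optional list(hp =, ps =): haplotype and phase-set tags given
#'   to simulated reads. `NULL` leaves all reads unphased.
#' @param jitter clip-position jitter in bp applied at junctions, emulating
#'   small alignment ambiguity (default 2, well inside the 10 bp matching
#'   tolerance).
#' @param unphased_frac fraction of reads left untagged even when `phase` is
#'   set.
#' @param mapq mapping quality written for every alignment record.
#' @return an object of class `rearrangement_spec`.
#' @export
rearrangement_spec <- function(blocks, contigs,
                               flanks = 2000L,
                               coverage = 20,
                               read_length = c(2000, 150),
                               seed = 1L,
                               phase = list(hp = 1L, ps = 1L),
                               jitter = 2L,
                               unphased_frac = 0,
                               mapq = 60L) {
  blocks <- as.data.frame(blocks, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "start", "end", "strand") %in% names(blocks)),
            nrow(blocks) >= 1L,
            all(blocks$strand %in% c("+", "-")),
            all(blocks$end > blocks$start),
            !is.null(names(contigs)), all(contigs > 0))
  if (blocks$strand[1] != "+" || blocks$strand[nrow(blocks)] != "+")
    stop("first and last blocks must be forward (reference-consistent flanks)")
  bad <- !(blocks$contig %in% names(contigs))
  if (any(bad)) stop("block contig not in contigs: ", blocks$contig[bad][1])
  if (any(blocks$start < 0) ||
      any(blocks$end > contigs[blocks$contig]))
    stop("block interval outside its contig")
  spec <- list(blocks = blocks, contigs = contigs, flanks = as.integer(flanks),
               coverage = coverage, read_length = read_length,
               seed = as.integer(seed), phase = phase,
               jitter = as.integer(jitter), unphased_frac = unphased_frac,
               mapq = as.integer(mapq))
  class(spec) <- "rearrangement_spec"
  spec
}

# run code with a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a random reference genome
#'
#' @param contigs named integer vector of contig lengths.
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] with one entry per contig.
#' @export
synthesize_reference <- function(contigs, seed = 1L) {
  with_seed(seed, {
    seqs <- vapply(contigs, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs, names(contigs)))
  })
}

# merge reference-contiguous adjacent haplotype blocks
merge_contiguous_blocks <- function(blocks) {
  out <- blocks[1, , drop = FALSE]
  for (i in seq_len(nrow(blocks))[-1]) {
    a <- out[nrow(out), ]
    b <- blocks[i, ]
    contig_ok <- a$contig == b$contig && a$strand == b$strand
    if (contig_ok && a$strand == "+" && a$end == b$start) {
      out$end[nrow(out)] <- b$end
    } else if (contig_ok && a$strand == "-" && a$start == b$end) {
      out$start[nrow(out)] <- b$start
    } else {
      out <- rbind(out, b)
    }
  }
  rownames(out) <- NULL
  out
}

# breakend of the junction side where the haplotype leaves segment `seg`
# (exit) or enters it (entry); flank = side of the break occupied by the
# sample sequence adjacent to the junction
junction_exit <- function(seg) {
  if (seg$strand == "+") list(chrom = seg$contig, pos = seg$end, flank = "left")
  else list(chrom = seg$contig, pos = seg$start, flank = "right")
}
junction_entry <- function(seg) {
  if (seg$strand == "+") list(chrom = seg$contig, pos = seg$start, flank = "right")
  else list(chrom = seg$contig, pos = seg$end, flank = "left")
}

# haplotype segments (merged blocks + extended outer flanks) and junctions
hap_layout <- function(spec) {
  blocks <- merge_contiguous_blocks(spec$blocks)
  n <- nrow(blocks)
  blocks$start[1] <- max(0L, blocks$start[1] - spec$flanks)
  blocks$end[n] <- min(unname(spec$contigs[blocks$contig[n]]),
                       blocks$end[n] + spec$flanks)
  blocks$h_start <- c(0L, cumsum(blocks$end - blocks$start))[seq_len(n)]
  blocks$h_end <- blocks$h_start + (blocks$end - blocks$start)
  juncs <- NULL
  if (n > 1L) {
    juncs <- lapply(seq_len(n - 1L), function(i) {
      e <- junction_exit(blocks[i, ])
      s <- junction_entry(blocks[i + 1L, ])
      list(exit = e, entry = s, hap_pos = blocks$h_end[i])
    })
  }
  list(segments = blocks, junctions = juncs)
}

#' Simulate reads, truth VCF and expected reconstruction for a rearrangement
#'
#' Reads are sampled uniformly along the sample haplotype and decomposed into
#' reference-space alignment segments: boundaries fall at rearrangement
#' junctions (with small jitter), producing primary plus supplementary records
#' with consistent SA tags, soft-clip lengths equal to the off-segment
#' remainder of the read, and strand flips across inverted blocks. About half
#' of the reads are simulated as sequenced from the reverse strand.
#'
#' @param spec a [rearrangement_spec()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the BAM/VCF written.
#' @param reference optional pre-built [Biostrings::DNAStringSet]; synthesized
#'   from `spec$contigs` and `spec$seed` when `NULL`.
#' @param min_seg minimum aligned-part length (bp); shorter terminal read
#'   parts stay soft-clipped rather than aligned, as an aligner would leave
#'   them.
#' @return list with `bam`, `vcf`, `sam`, `reference`, `truth` (list of
#'   expected [sv_network] objects), `layout` (per-read aligned-part table),
#'   `junctions` (truth junction table with spanning-read support counts) and
#'   `contigs`.
#' @export
simulate_rearrangement <- function(spec, dir = tempfile("sim"),
                                   prefix = "sim", reference = NULL,
                                   min_seg = 50L) {
  stopifnot(inherits(spec, "rearrangement_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(reference)) reference <- synthesize_reference(spec$contigs, spec$seed)
  lay <- hap_layout(spec)
  segs <- lay$segments
  L <- sum(segs$end - segs$start)
  rl_mean <- spec$read_length[1]
  rl_sd <- spec$read_length[2]
  if (length(lay$junctions)) {
    jp <- vapply(lay$junctions, `[[`, numeric(1), "hap_pos")
    if (any(diff(sort(c(0, jp, L))) < min_seg + spec$jitter + 1))
      stop("junctions closer than read-segment constraints permit")
  }

  reads <- with_seed(spec$seed, {
    n <- max(1L, as.integer(round(spec$coverage * L / rl_mean)))
    lens <- pmax(300L, pmin(as.integer(L),
                            as.integer(round(stats::rnorm(n, rl_mean, rl_sd)))))
    starts <- as.integer(floor(stats::runif(n, 0, L - lens + 1)))
    rc <- stats::runif(n) < 0.5
    phased <- if (is.null(spec$phase)) rep(FALSE, n)
              else stats::runif(n) >= spec$unphased_frac
    jit <- lapply(seq_len(n), function(i) {
      as.integer(round(stats::runif(length(lay$junctions),
                                    -spec$jitter, spec$jitter)))
    })
    list(n = n, lens = lens, starts = starts, rc = rc, phased = phased,
         jit = jit)
  })

  hap_seq <- paste(vapply(seq_len(nrow(segs)), function(i) {
    s <- Biostrings::subseq(reference[[segs$contig[i]]],
                            segs$start[i] + 1L, segs$end[i])
    if (segs$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)), collapse = "")

  layout <- list()
  sam_records <- character(0)
  jn <- length(lay$junctions)
  junction_support <- integer(jn)
  # reads (by index) whose aligned parts span each junction
  junction_reads <- replicate(jn, character(0), simplify = FALSE)
  read_names <- sprintf("read_%05d", seq_len(reads$n))

  for (ri in seq_len(reads$n)) {
    s <- reads$starts[ri]
    e <- s + reads$lens[ri]
    # split the read interval at (jittered) junction positions
    bounds <- s
    seg_idx <- integer(0)
    for (j in seq_len(jn)) {
      jpos <- lay$junctions[[j]]$hap_pos + reads$jit[[ri]][j]
      if (jpos > s && jpos < e) {
        bounds <- c(bounds, jpos)
        seg_idx <- c(seg_idx, j)         # part before this bound is in seg j
      }
    }
    bounds <- c(bounds, e)
    nparts <- length(bounds) - 1L
    # junction j separates haplotype segments j and j+1, so the part before
    # the first internal boundary lies in that boundary's segment
    part_seg <- if (nparts == 1L) max(which(segs$h_start <= s))
                else c(seg_idx[1], seg_idx + 1L)
    keep <- rep(TRUE, nparts)
    part_len <- diff(bounds)
    # terminal parts too short to align remain soft-clipped
    if (nparts > 1L) {
      if (part_len[1] < min_seg) keep[1] <- FALSE
      if (part_len[nparts] < min_seg) keep[nparts] <- FALSE
    }
    kept <- which(keep)
    if (!length(kept)) next
    parts <- lapply(kept, function(p) {
      sg <- segs[part_seg[p], ]
      ps <- bounds[p]; pe <- bounds[p + 1L]
      off1 <- ps - sg$h_start; off2 <- pe - sg$h_start
      # clamp: jitter may push a boundary marginally past the segment edge;
      # the clamped-off bases stay soft-clipped, so query offsets follow
      off1 <- max(0L, min(off1, sg$end - sg$start))
      off2 <- max(off1, min(off2, sg$end - sg$start))
      ps2 <- sg$h_start + off1; pe2 <- sg$h_start + off2
      if (sg$strand == "+") {
        rs <- sg$start + off1; re <- sg$start + off2; strand <- "+"
      } else {
        rs <- sg$end - off2; re <- sg$end - off1; strand <- "-"
      }
      if (reads$rc[ri]) strand <- if (strand == "+") "-" else "+"
      list(seg = part_seg[p], h_start = ps2, h_end = pe2, chrom = sg$contig,
           ref_start = as.integer(rs), ref_end = as.integer(re),
           strand = strand, q0 = ps2 - s, q1 = pe2 - s)
    })
    parts <- Filter(function(p) p$ref_end > p$ref_start, parts)
    if (!length(parts)) next
    # junction support: consecutive kept parts in consecutive segments
    if (length(parts) > 1L) {
      for (k in seq_len(length(parts) - 1L)) {
        if (parts[[k + 1L]]$seg == parts[[k]]$seg + 1L) {
          jid <- parts[[k]]$seg  # junction between segment seg and seg+1
          junction_support[jid] <- junction_support[jid] + 1L
          junction_reads[[jid]] <- c(junction_reads[[jid]], read_names[ri])
        }
      }
    }
    read_len <- reads$lens[ri]
    read_seq <- substr(hap_seq, s + 1L, e)
    if (reads$rc[ri]) read_seq <- revcomp(read_seq)
    plens <- vapply(parts, function(p) p$q1 - p$q0, numeric(1))
    primary <- which.max(plens)
    # q0/q1 are haplotype-forward; reverse-sequenced reads mirror them, and
    # the clip sides in reference orientation follow from the (already
    # flipped) segment strand
    cigars <- vapply(seq_along(parts), function(k) {
      p <- parts[[k]]
      m <- p$ref_end - p$ref_start
      q0 <- if (reads$rc[ri]) read_len - p$q1 else p$q0
      q1 <- if (reads$rc[ri]) read_len - p$q0 else p$q1
      if (p$strand == "+") { cl <- q0; cr <- read_len - q1 }
      else { cl <- read_len - q1; cr <- q0 }
      paste0(if (cl > 0) paste0(cl, "S") else "", m, "M",
             if (cr > 0) paste0(cr, "S") else "")
    }, character(1))
    sa_of <- function(k) {
      others <- setdiff(seq_along(parts), k)
      if (!length(others)) return(NULL)
      paste0(vapply(others, function(o) {
        p <- parts[[o]]
        paste0(p$chrom, ",", p$ref_start + 1L, ",", p$strand, ",",
               cigars[o], ",", spec$mapq, ",0;")
      }, character(1)), collapse = "")
    }
    for (k in seq_along(parts)) {
      p <- parts[[k]]
      flag <- 0L
      if (p$strand == "-") flag <- flag + 16L
      if (k != primary) flag <- flag + 2048L
      seq_out <- if (p$strand == "-") revcomp(read_seq) else read_seq
      tags <- character(0)
      sa <- sa_of(k)
      if (!is.null(sa)) tags <- c(tags, paste0("SA:Z:", sa))
      if (reads$phased[ri] && !is.null(spec$phase)) {
        tags <- c(tags, paste0("HP:i:", spec$phase$hp),
                  paste0("PS:i:", spec$phase$ps))
      }
      sam_records <- c(sam_records, paste(c(
        read_names[ri], flag, p$chrom, p$ref_start + 1L, spec$mapq,
        cigars[k], "*", 0L, 0L, seq_out, "*", tags), collapse = "\t"))
      layout[[length(layout) + 1L]] <- data.frame(
        read_name = read_names[ri], part = k, n_parts = length(parts),
        h_start = p$h_start, h_end = p$h_end, hap_offset = s,
        chrom = p$chrom, ref_start = p$ref_start, ref_end = p$ref_end,
        strand = p$strand, primary = (k == primary), seg = p$seg,
        stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, layout)

  sam_path <- file.path(dir, paste0(prefix, ".sam"))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(spec$contigs),
                      as.integer(spec$contigs)))
  writeLines(c(header, sam_records), sam_path)
  bam0 <- Rsamtools::asBam(sam_path,
                           destination = file.path(dir, paste0(prefix, "_u")),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, prefix))
  Rsamtools::indexBam(bam)
  unlink(bam0)

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  write_truth_vcf(lay$junctions, spec$contigs, vcf_path)

  truth <- truth_networks(spec, lay, junction_reads,
                          sample_id = prefix)

  list(bam = unname(bam), vcf = vcf_path, sam = sam_path,
       reference = reference, truth = truth, layout = layout,
       junctions = truth_junction_table(lay$junctions, junction_support),
       contigs = spec$contigs)
}

truth_junction_table <- function(junctions, support) {
  if (!length(junctions)) {
    return(data.frame(chrom_1 = character(0), pos_1 = integer(0),
                      flank_1 = character(0), chrom_2 = character(0),
                      pos_2 = integer(0), flank_2 = character(0),
                      support = integer(0)))
  }
  do.call(rbind, lapply(seq_along(junctions), function(i) {
    j <- junctions[[i]]
    data.frame(chrom_1 = j$exit$chrom, pos_1 = j$exit$pos,
               flank_1 = j$exit$flank, chrom_2 = j$entry$chrom,
               pos_2 = j$entry$pos, flank_2 = j$entry$flank,
               support = support[i], stringsAsFactors = FALSE)
  }))
}

# mated BND records per junction, VCF 4.2 bracket semantics.
# flank "left" at 0-based break b anchors 1-based POS = b (last retained
# base); flank "right" anchors POS = b + 1 (first retained base).
bnd_pair <- function(exit, entry, id_base) {
  fmt <- function(this, other, this_first) {
    if (this$flank == "left") {
      pos <- this$pos
      alt <- if (other$flank == "right") {
        sprintf("N[%s:%d[", other$chrom, other$pos + 1L)
      } else sprintf("N]%s:%d]", other$chrom, other$pos)
    } else {
      pos <- this$pos + 1L
      alt <- if (other$flank == "left") {
        sprintf("]%s:%d]N", other$chrom, other$pos)
      } else sprintf("[%s:%d[N", other$chrom, other$pos + 1L)
    }
    list(chrom = this$chrom, pos = pos, alt = alt)
  }
  a <- fmt(exit, entry); b <- fmt(entry, exit)
  ida <- paste0(id_base, "_a"); idb <- paste0(id_base, "_b")
  list(
    list(chrom = a$chrom, pos = a$pos, id = ida, alt = a$alt, mate = idb),
    list(chrom = b$chrom, pos = b$pos, id = idb, alt = b$alt, mate = ida))
}

write_truth_vcf <- function(junctions, contigs, path) {
  recs <- list()
  for (i in seq_along(junctions)) {
    j <- junctions[[i]]
    recs <- c(recs, bnd_pair(j$exit, j$entry, sprintf("jct_%d", i)))
  }
  lines <- vapply(recs, function(r) {
    paste(r$chrom, r$pos, r$id, "N", r$alt, 60, "PASS",
          sprintf("SVTYPE=BND;MATEID=%s", r$mate), sep = "\t")
  }, character(1))
  chrom <- vapply(recs, `[[`, character(1), "chrom")
  pos <- vapply(recs, `[[`, numeric(1), "pos")
  ord <- order_by_locus(chrom, pos, names(contigs))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)),
              "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
              "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"Mate breakend ID\">",
              "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
              "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"SV length\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, lines[ord]), path)
  invisible(path)
}

# expected reconstruction: per junction-connectivity component, the labeled
# reference blocks plus sample-order traversal implied by the haplotype spec
truth_networks <- function(spec, lay, junction_reads, sample_id,
                           block_cap = 20L, margin_frac = 0.1,
                           margin_min = 200L) {
  segs <- lay$segments
  junctions <- lay$junctions
  if (!length(junctions)) return(list())
  nseg <- nrow(segs)
  # junction components: consecutive junctions linked by a shared spanning
  # read or by phasing of the whole event
  linked <- rep(FALSE, length(junctions) - 1L)
  if (length(junctions) > 1L) {
    for (i in seq_len(length(junctions) - 1L)) {
      shared <- length(intersect(junction_reads[[i]],
                                 junction_reads[[i + 1L]])) > 0
      linked[i] <- shared || !is.null(spec$phase)
    }
  }
  comp <- cumsum(c(1L, !linked))
  nets <- list()
  for (ci in unique(comp)) {
    jidx <- which(comp == ci)
    seg_idx <- min(jidx):(max(jidx) + 1L)
    sub_segs <- segs[seg_idx, , drop = FALSE]
    sub_juncs <- junctions[jidx]
    ends <- lapply(sub_juncs, function(j) list(j$exit, j$entry))
    ends <- do.call(c, ends)
    bdf <- data.frame(chrom = vapply(ends, `[[`, character(1), "chrom"),
                      pos = vapply(ends, `[[`, numeric(1), "pos"),
                      side = vapply(ends, `[[`, character(1), "flank"),
                      stringsAsFactors = FALSE)
    breaks <- collapse_break_sides(bdf, names(spec$contigs))
    blocks <- reference_blocks(breaks, names(spec$contigs),
                               margin_frac = margin_frac,
                               margin_min = margin_min)
    # clip outer flank segments to the margin boundaries, cut at breaks
    order_rows <- list()
    for (si in seq_len(nrow(sub_segs))) {
      sg <- sub_segs[si, ]
      s0 <- sg$start; e0 <- sg$end
      onb <- blocks[blocks$chrom == sg$contig, , drop = FALSE]
      if (si == 1L) s0 <- max(s0, min(onb$start))
      if (si == nrow(sub_segs)) e0 <- min(e0, max(onb$end))
      hit <- onb[onb$start < e0 & onb$end > s0, , drop = FALSE]
      hit <- hit[order(hit$start), , drop = FALSE]
      if (sg$strand == "-") hit <- hit[rev(seq_len(nrow(hit))), , drop = FALSE]
      for (bi in seq_len(nrow(hit))) {
        order_rows[[length(order_rows) + 1L]] <-
          data.frame(label = hit$label[bi],
                     orientation = if (sg$strand == "+") "forward" else "inverted",
                     stringsAsFactors = FALSE)
      }
    }
    sample_order <- do.call(rbind, order_rows)
    resolved <- nrow(blocks) <= block_cap
    blocks$sample_order_index <- NA_integer_
    blocks$orientation <- "forward"
    if (resolved) {
      expanded <- blocks[0, ]
      for (k in seq_len(nrow(sample_order))) {
        row <- blocks[blocks$label == sample_order$label[k], , drop = FALSE][1, ]
        row$sample_order_index <- k - 1L
        row$orientation <- sample_order$orientation[k]
        expanded <- rbind(expanded, row)
      }
      missing <- blocks[!(blocks$label %in% sample_order$label), , drop = FALSE]
      blocks <- rbind(expanded, missing)
      blocks <- blocks[order_by_locus(blocks$chrom, blocks$start,
                                      names(spec$contigs)), , drop = FALSE]
      rownames(blocks) <- NULL
    }
    cons <- do.call(rbind, lapply(sub_juncs, function(j) {
      e1 <- list(j$exit, j$entry)
      normalize_connection(e1[[1]], e1[[2]], names(spec$contigs),
                           kind = "spanned",
                           inverted = (j$exit$flank == j$entry$flank),
                           support = NA_integer_)
    }))
    nets[[length(nets) + 1L]] <- sv_network(
      breaks = breaks, connections = cons, blocks = blocks,
      resolved = resolved, sample_id = sample_id,
      variant_ids = character(0), contig_order = names(spec$contigs))
  }
  nets
}

#' Named suite of scripted rearrangement scenarios
#'
#' One spec per fixture scenario covering the canonical complex-SV classes:
#' balanced inversion, inversion with one or two flanking deletions (the
#' del-inv-del fixture uses the literal 716/284/38 bp size triple), non-tandem
#' duplication plus deletion, inverted non-tandem duplication plus deletion,
#' balanced translocation with flanking duplication, tandem duplication,
#' phase-linked deletion pair, a multi-block deletion/inversion combination,
#' and an over-the-block-cap chain expected to stay unresolved.
#'
#' @param seed base seed; each scenario derives its own offset seed.
#' @return named list of [rearrangement_spec()] objects.
#' @export
category_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  chr1 <- c(chr1 = 30000L)
  blk <- function(contig, start, end, strand = "+") {
    data.frame(contig = contig, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  }
  specs <- list()

  specs$inv <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 10000L), blk("chr1", 10000L, 12000L, "-"),
          blk("chr1", 12000L, 13000L)),
    contigs = chr1, seed = seed + 101L)

  specs$`inv-del` <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 10000L), blk("chr1", 10716L, 11716L, "-"),
          blk("chr1", 11716L, 12716L)),
    contigs = chr1, seed = seed + 102L)

  # literal size triple: 716 bp deletion, 284 bp inversion, 38 bp deletion
  specs$`del-inv-del` <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 10000L), blk("chr1", 10716L, 11000L, "-"),
          blk("chr1", 11038L, 12038L)),
    contigs = chr1, seed = seed + 103L, read_length = c(1500, 100))

  # non-tandem duplication of C inserted between A and B, deletion of D
  specs$`dup-del` <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 10000L), blk("chr1", 11000L, 12000L),
          blk("chr1", 10000L, 12000L), blk("chr1", 13000L, 14000L)),
    contigs = chr1, seed = seed + 104L)

  # inverted non-tandem duplication of C, deletion of D
  specs$`nontandem-inv-del` <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 10000L), blk("chr1", 11000L, 12000L, "-"),
          blk("chr1", 10000L, 12000L), blk("chr1", 13000L, 14000L)),
    contigs = chr1, seed = seed + 105L)

  # two chr12 blocks (one inverted) inserted into chr2 with duplication of
  # the short chr2 region at the insertion site
  specs$`balanced-trans-dup` <- rearrangement_spec(
    rbind(blk("chr2", 9000L, 10400L), blk("chr12", 20000L, 22000L),
          blk("chr12", 22000L, 23000L, "-"), blk("chr2", 10000L, 10400L),
          blk("chr2", 10400L, 11400L)),
    contigs = c(chr2 = 20000L, chr12 = 30000L), seed = seed + 106L)

  specs$`tandem-dup` <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 11000L), blk("chr1", 10000L, 11000L),
          blk("chr1", 11000L, 12000L)),
    contigs = chr1, seed = seed + 107L)

  # two deletions too far apart for one read, linked only by phase tags
  specs$`phased-del-pair` <- rearrangement_spec(
    rbind(blk("chr1", 8000L, 10000L), blk("chr1", 10500L, 18000L),
          blk("chr1", 18700L, 20500L)),
    contigs = chr1, seed = seed + 108L,
    phase = list(hp = 1L, ps = 8000L))

  # the multi-block combination: B, D, F, H deleted; C, E, G reordered with
  # C and G inverted
  specs$`multi-block-del-inv` <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 10000L), blk("chr1", 15000L, 16000L, "-"),
          blk("chr1", 13000L, 14000L), blk("chr1", 11000L, 12000L, "-"),
          blk("chr1", 17000L, 18000L)),
    contigs = chr1, seed = seed + 109L)

  # 25 small deletions in a chain: 50 breaks / 51 blocks, past the cap of 20
  kept <- lapply(0:24, function(k) {
    blk("chr1", 10400L + 1500L * k, 10000L + 1500L * (k + 1L))
  })
  specs$`unresolved-manyblocks` <- rearrangement_spec(
    rbind(blk("chr1", 9000L, 10000L), do.call(rbind, kept)),
    contigs = c(chr1 = 60000L), seed = seed + 110L)

  specs
}
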