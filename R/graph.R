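# Break-connection graph: match alignment clips to SV breaks, connect breaks
# via spanning reads or shared phase blocks, assemble networks, and
# reconstruct the ordered, oriented sample-haplotype blocks.

# ---- shared low-level helpers -------------------------------------------

# collapse breakends at (near-)identical positions into single breaks;
# single-linkage clustering per chromosome with radius `window`
collapse_break_sides <- function(bdf, contig_order, window = 0L) {
  if (!nrow(bdf)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      side = character(0),
                      variant_id = I(list()), single_ended = logical(0)))
  }
  if (is.null(bdf$variant_id)) bdf$variant_id <- replicate(nrow(bdf), character(0), simplify = FALSE)
  if (is.null(bdf$single_ended)) bdf$single_ended <- FALSE
  out <- list()
  for (ch in unique(bdf$chrom)) {
    sub <- bdf[bdf$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    cl <- cumsum(c(1L, diff(sub$pos) > window))
    for (g in unique(cl)) {
      rows <- sub[cl == g, , drop = FALSE]
      side <- unique(rows$side)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = min(rows$pos),
        side = if (length(side) == 1L) side else "both",
        variant_id = I(list(sort(unique(unlist(rows$variant_id))))),
        single_ended = all(rows$single_ended),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order_by_locus(out$chrom, out$pos, contig_order), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition the event window into labeled reference blocks
#'
#' Breaks cut each involved chromosome into reference intervals; one
#' reference-consistent flanking block is added on each side (margin a
#' fraction of the per-chromosome break span, with a floor). Labels A, B, C…
#' follow reference order across chromosomes.
#'
#' @param breaks data.frame with `chrom`, `pos` (0-based).
#' @param contig_order character vector giving chromosome rank.
#' @param margin_frac,margin_min flank margin as fraction of span / floor bp.
#' @return data.frame `chrom`, `start`, `end`, `label`, `is_flank`.
#' @export
reference_blocks <- function(breaks, contig_order,
                             margin_frac = 0.1, margin_min = 200L) {
  stopifnot(nrow(breaks) >= 1L)
  out <- list()
  for (ch in unique(breaks$chrom)) {
    pos <- sort(unique(breaks$pos[breaks$chrom == ch]))
    span <- max(pos) - min(pos)
    margin <- max(as.integer(round(margin_frac * span)), as.integer(margin_min))
    bounds <- c(max(0L, min(pos) - margin), pos, max(pos) + margin)
    bounds <- unique(bounds)
    n <- length(bounds) - 1L
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = bounds[seq_len(n)], end = bounds[-1L],
      is_flank = seq_len(n) %in% c(1L, n), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order_by_locus(out$chrom, out$start, contig_order), , drop = FALSE]
  out$label <- block_labels(nrow(out))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "label", "is_flank")]
}

# one connection row with endpoints in canonical (contig rank, pos, flank)
# order
normalize_connection <- function(e1, e2, contig_order, kind, inverted,
                                 support, phase_set = NA_integer_,
                                 reads = character(0)) {
  rank <- contig_ranker(contig_order)
  k1 <- c(rank(e1$chrom), e1$pos, match(e1$flank, c("left", "right"), nomatch = 3L))
  k2 <- c(rank(e2$chrom), e2$pos, match(e2$flank, c("left", "right"), nomatch = 3L))
  if (isTRUE(all(k1 == k2)) || !isTRUE(any(k1 != k2))) {
    swap <- FALSE
  } else {
    d <- which(k1 != k2)[1]
    swap <- k1[d] > k2[d]
  }
  if (swap) { tmp <- e1; e1 <- e2; e2 <- tmp }
  data.frame(chrom_1 = e1$chrom, pos_1 = as.integer(e1$pos),
             flank_1 = as.character(e1$flank),
             chrom_2 = e2$chrom, pos_2 = as.integer(e2$pos),
             flank_2 = as.character(e2$flank),
             kind = kind, inverted = inverted,
             support = as.integer(support),
             phase_set = as.integer(phase_set),
             read_names = I(list(sort(unique(reads)))),
             stringsAsFactors = FALSE)
}

empty_connections <- function() {
  data.frame(chrom_1 = character(0), pos_1 = integer(0), flank_1 = character(0),
             chrom_2 = character(0), pos_2 = integer(0), flank_2 = character(0),
             kind = character(0), inverted = logical(0), support = integer(0),
             phase_set = integer(0), read_names = I(list()),
             stringsAsFactors = FALSE)
}

#' Construct an SV network object
#'
#' A connected set of breaks, evidence-backed connections and (after
#' ordering) labeled genomic blocks representing one rearrangement event.
#'
#' @param breaks,connections,blocks data.frames (see package vignette).
#' @param start_break list(chrom, pos, entry_side) or NULL.
#' @param resolved logical: a single traversal from the start break explains
#'   every junction.
#' @param variant_ids contributing VCF record IDs.
#' @param sample_id sample name.
#' @param contig_order chromosome rank order.
#' @param filters reasons recorded by filtering steps (empty when kept).
#' @return object of class `sv_network`.
#' @export
sv_network <- function(breaks, connections = empty_connections(),
                       blocks = NULL, start_break = NULL, resolved = FALSE,
                       variant_ids = character(0), sample_id = "sample",
                       contig_order = unique(breaks$chrom),
                       filters = character(0)) {
  net <- list(breaks = breaks, connections = connections, blocks = blocks,
              start_break = start_break, resolved = resolved,
              variant_ids = variant_ids, sample_id = sample_id,
              contig_order = contig_order, filters = filters)
  class(net) <- "sv_network"
  net
}

#' @export
print.sv_network <- function(x, ...) {
  cat(sprintf("sv_network: %d breaks, %d connections, %s, sample %s\n",
              nrow(x$breaks), nrow(x$connections),
              if (x$resolved) "resolved" else "unresolved", x$sample_id))
  if (!is.null(x$blocks)) {
    ord <- x$blocks[!is.na(x$blocks$sample_order_index), , drop = FALSE]
    ord <- ord[order(ord$sample_order_index), , drop = FALSE]
    cat("sample order:",
        paste0(ord$label, ifelse(ord$orientation == "inverted", "'", ""),
               collapse = " "), "\n")
  }
  invisible(x)
}

#' Per-chromosome span of an SV network
#' @param net an `sv_network`.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
network_region <- function(net) {
  src <- if (!is.null(net$blocks)) net$blocks[, c("chrom", "start", "end")]
         else data.frame(chrom = net$breaks$chrom, start = net$breaks$pos,
                         end = net$breaks$pos)
  agg <- lapply(split(src, src$chrom), function(d) {
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order_by_locus(out$chrom, out$start, net$contig_order), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- matching and connecting --------------------------------------------

#' Does a read's alignment support a break?
#'
#' True when some alignment segment of the read carries significant
#' soft-clipping (>= `min_clip` bp) whose clipped reference coordinate falls
#' within `tol` bp of the break position.
#'
#' @param ev one alignment-evidence record (see [collect_alignment_evidence()]).
#' @param brk list or one-row data.frame with `chrom` and `pos` (0-based).
#' @param tol matching tolerance in bp (default 10).
#' @param min_clip minimum clip length considered significant (default 50).
#' @return logical scalar.
#' @export
match_alignment_to_break <- function(ev, brk, tol = 10L, min_clip = 50L) {
  seg <- ev$segments
  any(seg$chrom == brk$chrom &
      ((seg$clip_left >= min_clip & abs(seg$ref_start - brk$pos) <= tol) |
       (seg$clip_right >= min_clip & abs(seg$ref_end - brk$pos) <= tol)))
}

# junction observations of one read: adjacent segment pairs with significant
# clips on both junction sides, described as two (chrom, pos, flank)
# endpoints. `flank` is the side of the break occupied by sample sequence
# adjacent to the junction.
read_junction_obs <- function(ev, min_clip = 50L) {
  seg <- ev$segments
  n <- nrow(seg)
  if (n < 2L) return(NULL)
  obs <- list()
  for (i in seq_len(n - 1L)) {
    a <- seg[i, ]; b <- seg[i + 1L, ]
    if (a$strand == "+") {
      exit <- list(chrom = a$chrom, pos = a$ref_end, flank = "left")
      exit_clip <- a$clip_right
    } else {
      exit <- list(chrom = a$chrom, pos = a$ref_start, flank = "right")
      exit_clip <- a$clip_left
    }
    if (b$strand == "+") {
      entry <- list(chrom = b$chrom, pos = b$ref_start, flank = "right")
      entry_clip <- b$clip_left
    } else {
      entry <- list(chrom = b$chrom, pos = b$ref_end, flank = "left")
      entry_clip <- b$clip_right
    }
    if (exit_clip < min_clip || entry_clip < min_clip) next
    obs[[length(obs) + 1L]] <- list(exit = exit, entry = entry,
                                    inverted = a$strand != b$strand)
  }
  obs
}

# nearest break row index within tol, or NA
match_break_index <- function(breaks, chrom, pos, tol) {
  cand <- which(breaks$chrom == chrom & abs(breaks$pos - pos) <= tol)
  if (!length(cand)) return(NA_integer_)
  cand[order(abs(breaks$pos[cand] - pos), breaks$pos[cand])][1]
}

#' Connect breaks using alignment and phase evidence
#'
#' Breaks without any supporting alignment are skipped. Spanned connections
#' join two breaks matched by the adjacent alignment segments of a single
#' read; phased connections join break groups whose supporting reads share a
#' haplotype and phase set without any single spanning read, within a gap
#' limit.
#'
#' @param breaks data.frame from [extract_breaks()].
#' @param evidence list from [collect_alignment_evidence()].
#' @param tol clip-to-break matching tolerance bp.
#' @param min_clip minimum significant clip length bp.
#' @param contig_order chromosome rank order.
#' @param phase_gap maximum reference gap bridged by a phased connection.
#' @return list with `connections` (data.frame), `breaks` (supported breaks),
#'   `skipped` (unsupported breaks) and `break_reads` (supporting read names
#'   per kept break).
#' @export
connect_breaks <- function(breaks, evidence, tol = 10L, min_clip = 50L,
                           contig_order = unique(breaks$chrom),
                           phase_gap = 5e5) {
  if (!nrow(breaks) || !length(evidence)) {
    return(list(connections = empty_connections(),
                breaks = breaks[0, , drop = FALSE], skipped = breaks,
                break_reads = list()))
  }
  support <- replicate(nrow(breaks), character(0), simplify = FALSE)
  phase_keys <- replicate(nrow(breaks), character(0), simplify = FALSE)
  for (ev in evidence) {
    seg <- ev$segments
    for (i in seq_len(nrow(breaks))) {
      if (match_alignment_to_break(ev, breaks[i, ], tol, min_clip)) {
        support[[i]] <- c(support[[i]], ev$read_name)
        if (!is.na(ev$haplotype) && !is.na(ev$phase_set)) {
          phase_keys[[i]] <- c(phase_keys[[i]],
                               paste0(ev$haplotype, ":", ev$phase_set))
        }
      }
    }
  }
  kept <- which(lengths(support) > 0L)
  skipped <- breaks[setdiff(seq_len(nrow(breaks)), kept), , drop = FALSE]
  breaks_kept <- breaks[kept, , drop = FALSE]
  rownames(breaks_kept) <- NULL
  support <- support[kept]
  phase_keys <- phase_keys[kept]

  # spanned connections from per-read junction observations
  conn_map <- new.env(parent = emptyenv())
  for (ev in evidence) {
    for (ob in read_junction_obs(ev, min_clip)) {
      i1 <- match_break_index(breaks_kept, ob$exit$chrom, ob$exit$pos, tol)
      i2 <- match_break_index(breaks_kept, ob$entry$chrom, ob$entry$pos, tol)
      if (is.na(i1) || is.na(i2) || i1 == i2) next
      e1 <- list(chrom = breaks_kept$chrom[i1], pos = breaks_kept$pos[i1],
                 flank = ob$exit$flank)
      e2 <- list(chrom = breaks_kept$chrom[i2], pos = breaks_kept$pos[i2],
                 flank = ob$entry$flank)
      row <- normalize_connection(e1, e2, contig_order, "spanned",
                                  ob$inverted, 0L)
      key <- paste(row$chrom_1, row$pos_1, row$flank_1, row$chrom_2,
                   row$pos_2, row$flank_2, row$inverted, sep = "|")
      cur <- if (exists(key, envir = conn_map)) get(key, envir = conn_map)
             else list(row = row, reads = character(0))
      cur$reads <- c(cur$reads, ev$read_name)
      assign(key, cur, envir = conn_map)
    }
  }
  conns <- list()
  for (key in sort(ls(conn_map))) {
    cur <- get(key, envir = conn_map)
    row <- cur$row
    row$support <- length(unique(cur$reads))
    row$read_names <- I(list(sort(unique(cur$reads))))
    conns[[length(conns) + 1L]] <- row
  }
  connections <- if (length(conns)) do.call(rbind, conns) else empty_connections()

  # phased connections: link adjacent spanned components sharing HP:PS
  comp <- break_components(breaks_kept, connections)
  comp_order <- order(vapply(split(seq_len(nrow(breaks_kept)), comp), function(idx) {
    rank <- contig_ranker(contig_order)(breaks_kept$chrom[idx])
    min(rank * 1e9 + breaks_kept$pos[idx])
  }, numeric(1)))
  comp_ids <- names(split(seq_len(nrow(breaks_kept)), comp))[comp_order]
  if (length(comp_ids) > 1L) {
    groups <- split(seq_len(nrow(breaks_kept)), comp)
    for (g in seq_len(length(comp_ids) - 1L)) {
      ia <- groups[[comp_ids[g]]]; ib <- groups[[comp_ids[g + 1L]]]
      keys_a <- unique(unlist(phase_keys[ia]))
      keys_b <- unique(unlist(phase_keys[ib]))
      shared <- intersect(keys_a, keys_b)
      if (!length(shared)) next
      # nearest same-chromosome break pair between the two components
      best <- NULL
      for (x in ia) for (y in ib) {
        if (breaks_kept$chrom[x] != breaks_kept$chrom[y]) next
        d <- abs(breaks_kept$pos[x] - breaks_kept$pos[y])
        if (is.null(best) || d < best$d) best <- list(x = x, y = y, d = d)
      }
      if (is.null(best) || best$d > phase_gap) next
      key <- sort(shared)[1]
      ps <- as.integer(strsplit(key, ":", fixed = TRUE)[[1]][2])
      rd <- unique(c(
        support[[best$x]][phase_reads_match(evidence, support[[best$x]], key)],
        support[[best$y]][phase_reads_match(evidence, support[[best$y]], key)]))
      e1 <- list(chrom = breaks_kept$chrom[best$x], pos = breaks_kept$pos[best$x],
                 flank = NA_character_)
      e2 <- list(chrom = breaks_kept$chrom[best$y], pos = breaks_kept$pos[best$y],
                 flank = NA_character_)
      row <- normalize_connection(e1, e2, contig_order, "phased", FALSE,
                                  length(rd), phase_set = ps, reads = rd)
      connections <- rbind(connections, row)
    }
  }
  rownames(connections) <- NULL
  nm <- if (nrow(breaks_kept)) {
    paste0(breaks_kept$chrom, ":", breaks_kept$pos)
  } else character(0)
  list(connections = connections, breaks = breaks_kept, skipped = skipped,
       break_reads = stats::setNames(support, nm))
}

# which of `reads` carry phase key `key`
phase_reads_match <- function(evidence, reads, key) {
  keys <- vapply(evidence, function(ev) {
    if (is.na(ev$haplotype) || is.na(ev$phase_set)) ""
    else paste0(ev$haplotype, ":", ev$phase_set)
  }, character(1))
  names(keys) <- vapply(evidence, `[[`, character(1), "read_name")
  keys[reads] == key
}

# component id per break row (igraph connected components; isolated
# supported breaks form their own singleton components)
break_components <- function(breaks, connections) {
  n <- nrow(breaks)
  if (!n) return(integer(0))
  key <- paste0(breaks$chrom, ":", breaks$pos)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(connections)) {
    v1 <- match(paste0(connections$chrom_1, ":", connections$pos_1), key)
    v2 <- match(paste0(connections$chrom_2, ":", connections$pos_2), key)
    ok <- !is.na(v1) & !is.na(v2)
    g <- igraph::add_edges(g, rbind(v1[ok], v2[ok]))
  }
  igraph::components(g)$membership
}

#' Assemble connected SV networks
#'
#' Networks are the connected components of the break-connection graph,
#' ordered deterministically by their first break. Supported breaks with no
#' connection become singleton (unresolvable) networks so that single-ended
#' calls stay visible until the simple-network filter.
#'
#' @param conn result of [connect_breaks()].
#' @param contig_order chromosome rank order.
#' @param sample_id sample name attached to each network.
#' @return list of [sv_network] objects.
#' @export
build_networks <- function(conn, contig_order, sample_id = "sample") {
  breaks <- conn$breaks
  if (!nrow(breaks)) return(list())
  comp <- break_components(breaks, conn$connections)
  rank <- contig_ranker(contig_order)
  nets <- lapply(split(seq_len(nrow(breaks)), comp), function(idx) {
    b <- breaks[idx, , drop = FALSE]
    rownames(b) <- NULL
    key <- paste0(b$chrom, ":", b$pos)
    cn <- conn$connections
    cn <- cn[paste0(cn$chrom_1, ":", cn$pos_1) %in% key &
             paste0(cn$chrom_2, ":", cn$pos_2) %in% key, , drop = FALSE]
    rownames(cn) <- NULL
    sv_network(breaks = b, connections = cn,
               variant_ids = sort(unique(unlist(b$variant_id))),
               sample_id = sample_id, contig_order = contig_order)
  })
  first <- vapply(nets, function(n) {
    min(rank(n$breaks$chrom) * 1e9 + n$breaks$pos)
  }, numeric(1))
  unname(nets[order(first)])
}

# ---- start break and traversal ------------------------------------------

#' Identify the start break of a network
#'
#' The start break is the break where reads enter the event from
#' reference-consistent flanking sequence: a clipped segment matches the
#' break while its other end runs, unclipped, into sequence beyond the
#' network's outermost break on that chromosome. Among candidates the break
#' with the smallest position on the lowest-ranked chromosome wins; the side
#' of entry is recorded for traversal.
#'
#' @param net an `sv_network`.
#' @param evidence alignment evidence list.
#' @param tol,min_clip matching parameters.
#' @return list(chrom, pos, entry_side) or NULL when no unambiguous
#'   reference-consistent entry exists.
#' @export
find_start_break <- function(net, evidence, tol = 10L, min_clip = 50L) {
  breaks <- net$breaks
  lims <- lapply(split(breaks$pos, breaks$chrom), range)
  cands <- list()
  for (ev in evidence) {
    seg <- ev$segments
    for (i in seq_len(nrow(seg))) {
      ch <- seg$chrom[i]
      if (is.null(lims[[ch]])) next
      # entry from the left: clipped at its right end onto a break, free and
      # extending into flank on its left
      if (seg$clip_right[i] >= min_clip && seg$clip_left[i] < min_clip &&
          seg$ref_start[i] <= lims[[ch]][1] - min_clip) {
        b <- match_break_index(breaks, ch, seg$ref_end[i], tol)
        if (!is.na(b)) cands[[length(cands) + 1L]] <-
            list(chrom = breaks$chrom[b], pos = breaks$pos[b], entry_side = "left")
      }
      # entry from the right
      if (seg$clip_left[i] >= min_clip && seg$clip_right[i] < min_clip &&
          seg$ref_end[i] >= lims[[ch]][2] + min_clip) {
        b <- match_break_index(breaks, ch, seg$ref_start[i], tol)
        if (!is.na(b)) cands[[length(cands) + 1L]] <-
            list(chrom = breaks$chrom[b], pos = breaks$pos[b], entry_side = "right")
      }
    }
  }
  if (!length(cands)) return(NULL)
  rank <- contig_ranker(net$contig_order)
  keys <- vapply(cands, function(cd) {
    rank(cd$chrom) * 1e10 + cd$pos * 4 + (cd$entry_side == "right")
  }, numeric(1))
  cands[[which.min(keys)]]
}

#' Order blocks by traversal from the start break
#'
#' The reference interval between each pair of adjacent breaks (plus a
#' flanking margin block on each side) becomes a labeled block. Starting in
#' the flank adjacent to the start break, the traversal walks along the
#' reference, taking each spanned junction exactly once (backtracking where
#' several traversals are locally possible), and assigns sample order and
#' orientation to every visited block. Blocks never visited carry no sample
#' order index (deleted); blocks visited twice appear twice. Traversals that
#' cannot consume every junction, or that exceed the block cap, leave the
#' network unresolved with a partial (greedy) ordering.
#'
#' @param net `sv_network` with `start_break` set (may be NULL: unresolved).
#' @param block_cap maximum number of sample-order blocks (default 20).
#' @param margin_frac,margin_min flanking block margin rule.
#' @return the network with `blocks` populated and `resolved` set.
#' @export
order_blocks <- function(net, block_cap = 20L, margin_frac = 0.1,
                         margin_min = 200L) {
  blocks <- reference_blocks(net$breaks, net$contig_order,
                             margin_frac = margin_frac,
                             margin_min = margin_min)
  blocks$sample_order_index <- NA_integer_
  blocks$orientation <- "forward"
  net$blocks <- blocks
  net$resolved <- FALSE
  if (is.null(net$start_break)) return(net)

  juncs <- net$connections[net$connections$kind == "spanned", , drop = FALSE]
  res <- traverse_blocks(blocks, juncs, net$start_break, block_cap)
  if (is.null(res$path)) return(net)

  path <- res$path
  if (net$start_break$entry_side == "right") {
    # traversed backwards: reverse and flip orientations to present the
    # haplotype left-to-right
    path <- rev(path)
    path <- lapply(path, function(p) {
      p$inverted <- !p$inverted
      p
    })
  }
  visited <- blocks[0, ]
  for (k in seq_along(path)) {
    p <- path[[k]]
    row <- blocks[blocks$chrom == p$chrom & blocks$start == p$start &
                  blocks$end == p$end, , drop = FALSE][1, ]
    row$sample_order_index <- k - 1L
    row$orientation <- if (p$inverted) "inverted" else "forward"
    visited <- rbind(visited, row)
  }
  unvisited <- blocks[!(blocks$label %in% visited$label), , drop = FALSE]
  out <- rbind(visited, unvisited)
  out <- out[order_by_locus(out$chrom, out$start, net$contig_order), , drop = FALSE]
  rownames(out) <- NULL
  net$blocks <- out
  net$resolved <- res$complete
  net
}

# depth-first traversal consuming each junction once; returns the first
# complete walk (all junctions used, ends in a flank) or, failing that, the
# greedy partial walk. Junction endpoints are (chrom, pos, flank) pairs;
# state is (chrom, break pos, occupied flank).
traverse_blocks <- function(blocks, juncs, start_break, block_cap) {
  njunc <- nrow(juncs)
  bounds <- split(blocks, blocks$chrom)
  # break positions per chromosome = interior block boundaries
  brk_pos <- lapply(bounds, function(b) sort(unique(c(b$start[-1]))))

  block_at <- function(chrom, lo, hi) list(chrom = chrom, start = lo, end = hi)

  # endpoints of unused junctions at state (chrom, pos, flank)
  ends_at <- function(chrom, pos, flank, used) {
    hits <- list()
    for (j in seq_len(njunc)) {
      if (used[j]) next
      if (juncs$chrom_1[j] == chrom && juncs$pos_1[j] == pos &&
          juncs$flank_1[j] == flank) {
        hits[[length(hits) + 1L]] <-
          list(j = j, chrom = juncs$chrom_2[j], pos = juncs$pos_2[j],
               flank = juncs$flank_2[j])
      }
      if (juncs$chrom_2[j] == chrom && juncs$pos_2[j] == pos &&
          juncs$flank_2[j] == flank) {
        hits[[length(hits) + 1L]] <-
          list(j = j, chrom = juncs$chrom_1[j], pos = juncs$pos_1[j],
               flank = juncs$flank_1[j])
      }
    }
    if (length(hits) > 1L) {
      key <- vapply(hits, function(h) paste(h$chrom, sprintf("%012d", h$pos),
                                            h$flank), character(1))
      hits <- hits[order(key)]
    }
    hits
  }

  # advance from break `pos` over flank `side`; returns the emitted block and
  # either the next state or terminal
  step_over <- function(chrom, pos, side) {
    bp <- brk_pos[[chrom]]
    cb <- bounds[[chrom]]
    if (side == "right") {
      nxt <- bp[bp > pos]
      hi <- if (length(nxt)) min(nxt) else max(cb$end)
      list(block = block_at(chrom, pos, hi), inverted = FALSE,
           terminal = !length(nxt),
           state = list(chrom = chrom, pos = if (length(nxt)) min(nxt) else NA,
                        flank = "left"))
    } else {
      prv <- bp[bp < pos]
      lo <- if (length(prv)) max(prv) else min(cb$start)
      list(block = block_at(chrom, lo, pos), inverted = TRUE,
           terminal = !length(prv),
           state = list(chrom = chrom, pos = if (length(prv)) max(prv) else NA,
                        flank = "right"))
    }
  }

  best_partial <- NULL
  dfs <- function(state, used, path, greedy) {
    if (length(path) > block_cap) return(NULL)
    if (is.null(best_partial) || length(path) > length(best_partial))
      best_partial <<- path
    opts <- ends_at(state$chrom, state$pos, state$flank, used)
    for (op in opts) {
      used2 <- used
      used2[op$j] <- TRUE
      # continue away from the far break over its occupied flank
      mv <- step_over(op$chrom, op$pos, op$flank)
      path2 <- c(path, list(c(mv$block, list(inverted = mv$inverted))))
      if (mv$terminal) {
        if (all(used2)) return(path2)
        if (greedy) return(NULL)
        next
      }
      r <- dfs(mv$state, used2, path2, greedy)
      if (!is.null(r)) return(r)
      if (greedy) return(NULL)
    }
    # pass through the break, keeping direction
    side <- if (state$flank == "left") "right" else "left"
    mv <- step_over(state$chrom, state$pos, side)
    path2 <- c(path, list(c(mv$block, list(inverted = mv$inverted))))
    if (mv$terminal) {
      if (all(used)) return(path2)
      return(NULL)
    }
    dfs(mv$state, used, path2, greedy)
  }

  sb <- start_break
  bp <- brk_pos[[sb$chrom]]
  cb <- bounds[[sb$chrom]]
  if (sb$entry_side == "left") {
    first <- list(block = block_at(sb$chrom, min(cb$start), min(bp)),
                  inverted = FALSE)
    state0 <- list(chrom = sb$chrom, pos = min(bp), flank = "left")
  } else {
    first <- list(block = block_at(sb$chrom, max(bp), max(cb$end)),
                  inverted = TRUE)
    state0 <- list(chrom = sb$chrom, pos = max(bp), flank = "right")
  }
  path0 <- list(c(first$block, list(inverted = first$inverted)))
  used0 <- rep(FALSE, njunc)
  full <- dfs(state0, used0, path0, greedy = FALSE)
  if (!is.null(full)) return(list(path = full, complete = TRUE))
  greedy <- dfs(state0, used0, path0, greedy = TRUE)
  partial <- if (!is.null(greedy)) greedy else best_partial
  list(path = partial, complete = FALSE)
}

#' Fill support counts on connections and blocks
#'
#' Connection support is the number of distinct read names whose alignments
#' satisfy the matching rule at both of its breaks (a read contributing
#' primary and supplementary records counts once). Block support is the
#' maximum over its bounding connections.
#'
#' @param net `sv_network` with blocks populated.
#' @param evidence alignment evidence list.
#' @param tol,min_clip matching parameters.
#' @return the network with supports filled (`support` columns).
#' @export
count_support <- function(net, evidence, tol = 10L, min_clip = 50L) {
  cn <- net$connections
  if (nrow(cn)) {
    cn$support <- vapply(seq_len(nrow(cn)), function(i) {
      reads <- unlist(cn$read_names[[i]])
      if (!length(reads) && length(evidence)) {
        b1 <- list(chrom = cn$chrom_1[i], pos = cn$pos_1[i])
        b2 <- list(chrom = cn$chrom_2[i], pos = cn$pos_2[i])
        reads <- vapply(evidence, function(ev) {
          if (match_alignment_to_break(ev, b1, tol, min_clip) &&
              match_alignment_to_break(ev, b2, tol, min_clip)) ev$read_name
          else NA_character_
        }, character(1))
        reads <- reads[!is.na(reads)]
      }
      length(unique(reads))
    }, integer(1))
    net$connections <- cn
  }
  if (!is.null(net$blocks) && nrow(net$blocks)) {
    net$blocks$support <- vapply(seq_len(nrow(net$blocks)), function(i) {
      b <- net$blocks[i, ]
      touch <- (cn$chrom_1 == b$chrom & cn$pos_1 %in% c(b$start, b$end)) |
               (cn$chrom_2 == b$chrom & cn$pos_2 %in% c(b$start, b$end))
      if (any(touch)) max(cn$support[touch]) else 0L
    }, integer(1))
  }
  net
}

#' Structural equality of two networks
#'
#' Compares break positions, the labeled block partition, the sample-order
#' block sequence with orientations, and the resolved flag. Support counts
#' and evidence bookkeeping are not compared.
#'
#' @param a,b `sv_network` objects.
#' @return TRUE, or FALSE with a `reason` attribute.
#' @export
networks_equivalent <- function(a, b) {
  fail <- function(why) structure(FALSE, reason = why)
  key <- function(n) paste0(n$breaks$chrom, ":", n$breaks$pos)
  if (!setequal(key(a), key(b))) return(fail("break sets differ"))
  if (!identical(a$resolved, b$resolved)) return(fail("resolved flag differs"))
  blk <- function(n) {
    d <- unique(n$blocks[, c("chrom", "start", "end", "label")])
    d[order(d$label), ]
  }
  ba <- blk(a); bb <- blk(b)
  if (!identical(unname(as.matrix(ba)), unname(as.matrix(bb))))
    return(fail("block partitions differ"))
  ord <- function(n) {
    d <- n$blocks[!is.na(n$blocks$sample_order_index), , drop = FALSE]
    d <- d[order(d$sample_order_index), , drop = FALSE]
    paste0(d$label, ifelse(d$orientation == "inverted", "'", ""))
  }
  if (a$resolved && !identical(ord(a), ord(b)))
    return(fail(sprintf("sample order differs: %s vs %s",
                        paste(ord(a), collapse = " "),
                        paste(ord(b), collapse = " "))))
  TRUE
}
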