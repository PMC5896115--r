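#' Arrangements of genome segments
#'
#' An arrangement is a permutation of segments together with a per-segment
#' orientation bit. \code{forward = TRUE} means the segment's head comes
#' first (reference strand); the orientation function value of the head is 1
#' and of the tail is 0, and flipping a segment swaps them. The *reference
#' arrangement* is the identity order with every segment forward.
#'
#' @param ids integer segment ids.
#' @param rank integer ranks (a permutation of \code{seq_along(ids)}); rank 1
#'   is the leftmost segment of the rearranged genome.
#' @param forward logical; \code{TRUE} = head-first.
#' @return object of class \code{arrangement}.
#' @export
arrangement <- function(ids, rank = seq_along(ids), forward = rep(TRUE, length(ids))) {
  ids <- as.integer(ids)
  rank <- as.integer(rank)
  stopifnot(length(rank) == length(ids), length(forward) == length(ids))
  if (!setequal(rank, seq_along(ids))) stop("rank must be a permutation of 1..n")
  structure(list(ids = ids, rank = rank, forward = as.logical(forward)),
            class = "arrangement")
}

#' @rdname arrangement
#' @export
reference_arrangement <- function(ids) {
  ids <- sort(as.integer(ids))
  arrangement(ids)
}

#' Reverse-complement an arrangement
#'
#' Reverses the permutation and flips every orientation bit; by the
#' reverse-complement symmetry of genome spelling this preserves the
#' compatibility of every edge.
#'
#' @param arr an [arrangement()].
#' @export
reverse_arrangement <- function(arr) {
  arrangement(arr$ids, length(arr$rank) + 1L - arr$rank, !arr$forward)
}

#' @export
print.arrangement <- function(x, ...) {
  ord <- order(x$rank)
  cat("<arrangement> ",
      paste0(ifelse(x$forward[ord], "", "-"), x$ids[ord], collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Edge compatibility with an arrangement
#'
#' An edge between segment ends \eqn{(u_i, v_j)} is compatible with an
#' arrangement \eqn{(\pi, f)} iff \eqn{1 - f(v_j) = 1[\pi(v) < \pi(u)] =
#' f(u_i)}: it must connect the trailing end of the earlier segment to the
#' leading end of the later one in the rearranged genome. Vectorized over
#' edges.
#'
#' @param a_id,b_id integer segment ids of the two endpoints.
#' @param a_side,b_side \code{"head"} or \code{"tail"}.
#' @param arr an [arrangement()] covering all mentioned segments.
#' @return logical vector.
#' @export
compatible <- function(a_id, a_side, b_id, b_side, arr) {
  ia <- match(a_id, arr$ids); ib <- match(b_id, arr$ids)
  if (anyNA(ia) || anyNA(ib)) stop("edge references a segment absent from the arrangement")
  # f value of an endpoint: head -> forward, tail -> !forward
  f_a <- ifelse(a_side == "head", arr$forward[ia], !arr$forward[ia])
  f_b <- ifelse(b_side == "head", arr$forward[ib], !arr$forward[ib])
  b_before_a <- arr$rank[ib] < arr$rank[ia]
  (f_a == b_before_a) & (f_b == !b_before_a)
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

#' Reference concordance of an edge
#'
#' An edge is concordant with the reference genome when it is compatible
#' with the reference arrangement *and* both segments lie on one
#' chromosome: the reference spells each chromosome separately, so a
#' tail--head adjacency across chromosomes is never realized by it, even
#' though a single concatenated sequence would satisfy the ordering
#' condition. With this chromosome-aware definition, the concordance of a
#' paired-end alignment and the reference concordance of its edge are
#' equivalent. Compatibility with *rearranged* arrangements remains
#' chromosome-blind (the rearranged genome is a new sequence), which is how
#' inter-chromosomal TSVs become satisfiable.
#'
#' @param a_id,a_side,b_id,b_side edge endpoints (vectorized).
#' @param segments segment tiling (provides chromosome labels).
#' @return logical vector.
#' @export
edge_reference_concordant <- function(a_id, a_side, b_id, b_side, segments) {
  segments <- as.data.table(segments)
  ref <- reference_arrangement(segments$id)
  same_chrom <- segments$chrom[match(a_id, segments$id)] ==
    segments$chrom[match(b_id, segments$id)]
  same_chrom & compatible(a_id, a_side, b_id, b_side, ref)
}

#' Segment-end connection implied by two consecutive parts of a fragment
#'
#' Given two aligned parts that are consecutive in read layout (\code{part_a}
#' from the first mate's last split part or an earlier split part,
#' \code{part_b} interpreted in mate-2 convention, i.e. pointing back toward
#' \code{part_a}), returns the pair of segment ends whose junction would make
#' the two parts concordant when the segments are traversed along the edge.
#' With both parts forward-recorded this is a tail--tail connection; a proper
#' (+,-) pair yields tail--head, (-,-) head--head and (-,+) head--tail.
#' Parts falling in the same segment produce no edge (\code{NULL}).
#'
#' @param part_a,part_b single-row aligned parts (recorded orientations).
#' @param segments segment tiling from [partition_genome()].
#' @return list with \code{a_id}, \code{a_side}, \code{b_id}, \code{b_side},
#'   \code{a_coord}, \code{b_coord} (junction-abutting genome coordinates),
#'   canonically ordered, or \code{NULL}.
#' @export
edge_for_connection <- function(part_a, part_b, segments) {
  la <- as.character(part_a$orient)            # layout orientation of out-part
  lb <- flip_orient(as.character(part_b$orient)) # mate-2 convention flips
  con <- connection_endpoints(
    data.table(chrom = c(part_a$chrom, part_b$chrom),
               start = as.integer(c(part_a$start, part_b$start)),
               end = as.integer(c(part_a$end, part_b$end)),
               layout_ori = c(la, lb),
               role = c("out", "in")),
    segments
  )
  if (con$a_id == con$b_id) return(NULL)
  canonical_connection(con)
}

# endpoints for one (out-part, in-part) connection given layout orientations
connection_endpoints <- function(two, segments) {
  o <- two[two$role == "out"]
  i <- two[two$role == "in"]
  a_side <- if (o$layout_ori == "+") "tail" else "head"
  a_coord <- if (o$layout_ori == "+") o$end else o$start
  a_base <- if (o$layout_ori == "+") o$end - 1L else o$start
  b_side <- if (i$layout_ori == "+") "head" else "tail"
  b_coord <- if (i$layout_ori == "+") i$start else i$end
  b_base <- if (i$layout_ori == "+") i$start else i$end - 1L
  list(a_id = segment_of_base(segments, o$chrom, a_base), a_side = a_side,
       b_id = segment_of_base(segments, i$chrom, b_base), b_side = b_side,
       a_coord = a_coord, b_coord = b_coord)
}

canonical_connection <- function(con) {
  if (con$a_id > con$b_id ||
      (con$a_id == con$b_id && con$a_side > con$b_side)) {
    con <- list(a_id = con$b_id, a_side = con$b_side,
                b_id = con$a_id, b_side = con$a_side,
                a_coord = con$b_coord, b_coord = con$a_coord)
  }
  con
}

#' Segment-end connections generated by one read pair
#'
#' Lays the pair out as a single fragment traversal (first end's parts in
#' read order, then the second end's parts in reverse-complement layout) and
#' emits one connection per consecutive part pair: one per split within each
#' end plus one mate connection. Connections within one segment are dropped.
#'
#' @param first,second aligned-part tables of the two ends.
#' @param segments segment tiling.
#' @return list of connections as in [edge_for_connection()].
#' @export
edges_from_pair <- function(first, second, segments) {
  first <- as.data.table(first); second <- as.data.table(second)
  pid <- if (nrow(first)) first$pair_id[1L] else 1L
  if (is.null(pid)) pid <- 1L
  first$pair_id <- pid; second$pair_id <- pid
  first$mate <- 1L; second$mate <- 2L
  cons <- connections_table(rbind(
    first[, list(pair_id, mate, chrom, start, end, orient, qoff)],
    second[, list(pair_id, mate, chrom, start, end, orient, qoff)]
  ), segments)
  if (nrow(cons) == 0L) return(list())
  lapply(seq_len(nrow(cons)), function(k) as.list(cons[k]))
}

# Vectorized: all connections for a full parts table.
# Returns canonical connection rows with supporting pair_id and junction
# coordinates.
connections_table <- function(parts, segments) {
  pt <- as.data.table(parts)
  if (nrow(pt) == 0L) {
    return(data.table(pair_id = integer(), a_id = integer(), a_side = character(),
                      b_id = integer(), b_side = character(),
                      a_coord = integer(), b_coord = integer()))
  }
  # fragment layout: mate 1 parts by qoff, then mate 2 parts by -qoff flipped
  pt[, layout_ori := ifelse(mate == 1L, orient, flip_orient(orient))]
  pt[, okey := ifelse(mate == 1L, qoff, -qoff)]
  setorder(pt, pair_id, mate, okey)
  pt[, idx := seq_len(.N), by = pair_id]
  nxt <- pt[, list(pair_id, idx = idx - 1L, n_chrom = chrom, n_start = start,
                   n_end = end, n_ori = layout_ori)]
  con <- pt[nxt, on = list(pair_id, idx), nomatch = NULL]
  if (nrow(con) == 0L) return(connections_table(empty_parts(), segments))
  # out endpoint from current part, in endpoint from next part
  con[, `:=`(
    a_side = ifelse(layout_ori == "+", "tail", "head"),
    a_coord = ifelse(layout_ori == "+", end, start),
    a_base = ifelse(layout_ori == "+", end - 1L, start),
    b_side = ifelse(n_ori == "+", "head", "tail"),
    b_coord = ifelse(n_ori == "+", n_start, n_end),
    b_base = ifelse(n_ori == "+", n_start, n_end - 1L)
  )]
  con[, a_id := segment_of_base(segments, chrom, a_base)]
  con[, b_id := segment_of_base(segments, n_chrom, b_base)]
  con <- con[a_id != b_id]
  if (nrow(con) == 0L) return(connections_table(empty_parts(), segments))
  # canonicalize endpoint order
  swap <- con$a_id > con$b_id | (con$a_id == con$b_id & con$a_side > con$b_side)
  out <- data.table(
    pair_id = con$pair_id,
    a_id = ifelse(swap, con$b_id, con$a_id),
    a_side = ifelse(swap, con$b_side, con$a_side),
    b_id = ifelse(swap, con$a_id, con$b_id),
    b_side = ifelse(swap, con$a_side, con$b_side),
    a_coord = as.integer(ifelse(swap, con$b_coord, con$a_coord)),
    b_coord = as.integer(ifelse(swap, con$a_coord, con$b_coord))
  )
  out
}

#' Build the weighted genome segment graph
#'
#' Aggregates the connections of all read pairs into canonical weighted
#' edges. \code{raw_count} is the number of supporting connections;
#' reference-discordant edges have their weight multiplied by the discordant
#' edge weight coefficient \code{alpha} (the assumed normal/tumor transcript
#' ratio), concordant edges keep weight = count.
#'
#' @param pairs a [pair_alignments()] object (or a parts table).
#' @param segments segment tiling from [partition_genome()].
#' @param alpha discordant edge weight coefficient, >= 1. Default 1.
#' @return object of class \code{segment_graph}: list with \code{segments},
#'   \code{edges}, \code{connections}, \code{alpha}.
#' @export
build_graph <- function(pairs, segments, alpha = 1) {
  stopifnot(alpha >= 1)
  parts <- if (inherits(pairs, "pair_alignments")) pairs$parts else as.data.table(pairs)
  segments <- as.data.table(segments)
  cons <- connections_table(parts, segments)
  edges <- cons[, list(raw_count = .N),
                by = list(a_id, a_side, b_id, b_side)]
  if (nrow(edges)) {
    edges[, concordant := edge_reference_concordant(a_id, a_side, b_id, b_side,
                                                    segments)]
    edges[, weight := raw_count * ifelse(concordant, 1, alpha)]
    setorder(edges, a_id, a_side, b_id, b_side)
  } else {
    edges <- data.table(a_id = integer(), a_side = character(),
                        b_id = integer(), b_side = character(),
                        raw_count = integer(), concordant = logical(),
                        weight = numeric())
  }
  structure(list(segments = segments, edges = edges, connections = cons,
                 alpha = alpha),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat(sprintf(
    "<segment_graph> %d segments, %d edges (%d discordant), alpha = %g\n",
    nrow(x$segments), nrow(x$edges), sum(!x$edges$concordant), x$alpha
  ))
  invisible(x)
}

#' Filter obvious false-positive edges from a segment graph
#'
#' Applies, in order: (1) the edge weight threshold \code{theta} -- edges
#' supported by fewer than \code{theta} read alignments are removed; (2) the
#' segment degree threshold \code{gamma} -- segments connected by discordant
#' edges to more than \code{gamma} distinct other segments (low-mappability
#' artifacts) lose all their discordant edges; (3) the interleaving filter --
#' when the discordant edges between two runs of genome-consecutive segments
#' imply that each run must be spliced into the interior of the other at two
#' or more distinct places (an exon-interleaving pattern typical of
#' alignment error rather than a single structural variant), all discordant
#' edges between the two runs are removed. The filter is monotone and
#' idempotent; concordant backbone edges are never removed by (2) or (3).
#'
#' @param g a [build_graph()] result.
#' @param theta minimum supporting read count per edge (strict: count <
#'   theta is removed). Default 5.
#' @param gamma maximum number of distinct discordant neighbor segments.
#'   Default 5.
#' @return filtered \code{segment_graph}.
#' @export
filter_graph <- function(g, theta = 5, gamma = 5) {
  stopifnot(theta >= 0, gamma >= 1)
  e <- copy(g$edges)
  # (1) weight threshold on raw support
  e <- e[raw_count >= theta]
  # (2) degree filter via discordant edges
  if (nrow(e)) {
    de <- e[concordant == FALSE]
    deg <- rbind(de[, list(seg = a_id, nb = b_id)],
                 de[, list(seg = b_id, nb = a_id)])
    deg <- deg[, list(n = length(unique(nb))), by = seg]
    bad <- deg[n > gamma, seg]
    if (length(bad)) {
      e <- e[concordant == TRUE | (!(a_id %in% bad) & !(b_id %in% bad))]
    }
  }
  # (3) interleaving filter between concordant backbone runs
  if (nrow(e)) {
    runs <- backbone_runs(g$segments, e)
    de <- e[concordant == FALSE]
    if (nrow(de)) {
      de[, `:=`(run_a = runs$run[match(a_id, runs$id)],
                run_b = runs$run[match(b_id, runs$id)])]
      de[, `:=`(
        att_a = runs$pos[match(a_id, runs$id)] + ifelse(a_side == "tail", 0.5, -0.5),
        att_b = runs$pos[match(b_id, runs$id)] + ifelse(b_side == "tail", 0.5, -0.5)
      )]
      de[, `:=`(len_a = runs$runlen[match(a_id, runs$id)],
                len_b = runs$runlen[match(b_id, runs$id)])]
      de[, `:=`(int_a = att_a > 0 & att_a < len_a - 1,
                int_b = att_b > 0 & att_b < len_b - 1)]
      offenders <- de[run_a != run_b, {
        g1 <- length(unique(att_a[int_a]))
        g2 <- length(unique(att_b[int_b]))
        list(drop = g1 >= 2L && g2 >= 2L)
      }, by = list(run_a, run_b)][drop == TRUE]
      if (nrow(offenders)) {
        doomed <- de[offenders, on = list(run_a, run_b), nomatch = NULL,
                     list(a_id, a_side, b_id, b_side)]
        doomed$kill <- TRUE
        e <- doomed[e, on = list(a_id, a_side, b_id, b_side)]
        e <- e[concordant == TRUE | is.na(kill)]
        e[, kill := NULL]
      }
    }
  }
  structure(list(segments = g$segments, edges = e, connections = g$connections,
                 alpha = g$alpha),
            class = "segment_graph")
}

# Maximal runs of genome-consecutive segments linked by concordant edges.
# Returns per-segment run id, position within run, and run length.
backbone_runs <- function(segments, edges) {
  seg <- as.data.table(segments)
  setorder(seg, id)
  ce <- edges[concordant == TRUE]
  linked <- rep(FALSE, nrow(seg)) # linked[i]: seg i and i+1 in one run
  if (nrow(ce)) {
    adj <- ce[abs(a_id - b_id) == 1L]
    if (nrow(adj)) {
      lo <- pmin(adj$a_id, adj$b_id)
      same_chrom <- seg$chrom[lo] == seg$chrom[lo + 1L]
      linked[lo[same_chrom]] <- TRUE
    }
  }
  run <- cumsum(c(TRUE, !linked[-nrow(seg)]))
  pos <- stats::ave(seq_len(nrow(seg)), run, FUN = function(i) seq_along(i) - 1L)
  runlen <- stats::ave(seq_len(nrow(seg)), run, FUN = length)
  data.table(id = seg$id, run = run, pos = pos, runlen = runlen)
}

#' Serialize a segment graph to TSV (one edge per line)
#' @param g segment graph.
#' @param file output path.
#' @export
write_graph_tsv <- function(g, file) {
  df <- g$edges[, list(seg_a = a_id, side_a = a_side, seg_b = b_id,
                       side_b = b_side, raw_count, weight,
                       concordant_flag = as.integer(concordant))]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
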