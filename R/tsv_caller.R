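#' Call TSVs from optimal component arrangements
#'
#' A TSV is an edge that is discordant in the reference arrangement but
#' compatible with its component's optimal arrangement: the rearrangement
#' realizes the adjacency the discordant reads support. Each such edge
#' yields one call with two oriented breakpoints, refined to exact
#' coordinates where enough supporting alignments agree
#' (see [refine_breakpoint()]).
#'
#' @param g the (filtered) segment graph the solutions were computed on.
#' @param solutions list of per-component solutions from [solve_graph()].
#' @return data.table of calls: \code{chrom1}, \code{pos1}, \code{side1},
#'   \code{chrom2}, \code{pos2}, \code{side2}, \code{support},
#'   \code{component_id}. \code{side} is \code{"tail"} when the retained
#'   sequence lies upstream (left) of the breakpoint and \code{"head"} when
#'   it lies downstream.
#' @export
call_tsvs <- function(g, solutions) {
  comps <- components(g)
  stopifnot(length(comps) == length(solutions))
  calls <- list()
  for (k in seq_along(comps)) {
    gc <- comps[[k]]
    sol <- solutions[[k]]
    if (nrow(gc$edges) == 0L) next
    hit <- !gc$edges$concordant & sol$satisfied
    if (!any(hit)) next
    e <- gc$edges[hit]
    for (j in seq_len(nrow(e))) {
      edge <- e[j]
      pos <- refine_breakpoint(edge, gc$connections, gc$segments)
      seg_a <- gc$segments[id == edge$a_id]
      seg_b <- gc$segments[id == edge$b_id]
      calls[[length(calls) + 1L]] <- data.table(
        chrom1 = seg_a$chrom, pos1 = pos[1L], side1 = edge$a_side,
        chrom2 = seg_b$chrom, pos2 = pos[2L], side2 = edge$b_side,
        support = edge$raw_count, component_id = k
      )
    }
  }
  if (length(calls) == 0L) {
    return(data.table(chrom1 = character(), pos1 = integer(), side1 = character(),
                      chrom2 = character(), pos2 = integer(), side2 = character(),
                      support = integer(), component_id = integer()))
  }
  out <- rbindlist(calls)
  out <- canonical_calls(out)
  setorder(out, chrom1, pos1, chrom2, pos2, side1, side2)
  out[]
}

# order the two breakpoints of each call lexicographically
canonical_calls <- function(calls) {
  sw <- calls$chrom2 < calls$chrom1 |
    (calls$chrom2 == calls$chrom1 & calls$pos2 < calls$pos1)
  flip <- function(a, b) list(ifelse(sw, b, a), ifelse(sw, a, b))
  c1 <- flip(calls$chrom1, calls$chrom2)
  p1 <- flip(calls$pos1, calls$pos2)
  s1 <- flip(calls$side1, calls$side2)
  data.table(chrom1 = c1[[1]], pos1 = p1[[1]], side1 = s1[[1]],
             chrom2 = c1[[2]], pos2 = p1[[2]], side2 = s1[[2]],
             support = calls$support, component_id = calls$component_id)
}

#' Refine TSV breakpoint coordinates from supporting alignments
#'
#' For each side of a TSV edge, the junction-abutting coordinates of the
#' supporting alignment parts are examined (part end for a tail side, part
#' start for a head side). If at least \code{min_share} supporting
#' alignments share one coordinate (the discordant alignment plus two others
#' that start or end in the same position), that coordinate is the exact
#' breakpoint; otherwise the corresponding segment boundary is reported
#' (tail: segment end, head: segment start). Ties go to the higher count,
#' then the smaller coordinate.
#'
#' @param edge single edge (row with \code{a_id}, \code{a_side}, \code{b_id},
#'   \code{b_side}).
#' @param connections connection table carried by the segment graph
#'   (junction coordinates of every supporting alignment).
#' @param segments segment tiling.
#' @param min_share minimum number of alignments sharing a coordinate.
#'   Default 3.
#' @return numeric length-2 vector: refined positions for the two sides.
#' @export
refine_breakpoint <- function(edge, connections, segments, min_share = 3) {
  segments <- as.data.table(segments)
  sup <- connections[a_id == edge$a_id & a_side == edge$a_side &
                       b_id == edge$b_id & b_side == edge$b_side]
  pick <- function(coords, side, seg) {
    boundary <- if (side == "tail") seg$end else seg$start
    if (length(coords) == 0L) return(boundary)
    tab <- sort(table(coords), decreasing = TRUE)
    best_n <- tab[1L]
    if (best_n < min_share) return(boundary)
    cand <- as.integer(names(tab)[tab == best_n])
    min(cand)
  }
  c(pick(sup$a_coord, edge$a_side, segments[id == edge$a_id]),
    pick(sup$b_coord, edge$b_side, segments[id == edge$b_id]))
}

#' Write TSV calls as BEDPE
#'
#' 0-based half-open BEDPE with columns chrom1 start1 end1 chrom2 start2
#' end2 name score strand1 strand2. Strand \code{+} means the retained
#' sequence lies upstream of the breakpoint (tail side; the feature interval
#' is the base left of the junction), \code{-} downstream (head side; the
#' base right of the junction). Score is the supporting read count. Output
#' is deterministically sorted.
#'
#' @param calls call table from [call_tsvs()] (or [true_tsvs()]).
#' @param file output path.
#' @export
write_predictions <- function(calls, file) {
  header <- paste("#chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "name", "score", "strand1", "strand2", sep = "\t")
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) {
    writeLines(header, file)
    return(invisible(file))
  }
  calls <- canonical_calls(calls)
  setorder(calls, chrom1, pos1, chrom2, pos2, side1, side2)
  bed <- calls[, list(
    chrom1,
    start1 = ifelse(side1 == "tail", pos1 - 1L, pos1),
    end1 = ifelse(side1 == "tail", pos1, pos1 + 1L),
    chrom2,
    start2 = ifelse(side2 == "tail", pos2 - 1L, pos2),
    end2 = ifelse(side2 == "tail", pos2, pos2 + 1L),
    name = paste0("TSV", seq_len(.N)),
    score = support,
    strand1 = ifelse(side1 == "tail", "+", "-"),
    strand2 = ifelse(side2 == "tail", "+", "-")
  )]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read BEDPE TSV calls written by [write_predictions()]
#' @param file BEDPE path.
#' @return call table with the [call_tsvs()] columns.
#' @export
read_predictions <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.table(chrom1 = character(), pos1 = integer(), side1 = character(),
                      chrom2 = character(), pos2 = integer(), side2 = character(),
                      support = integer(), component_id = integer()))
  }
  df <- as.data.table(read.table(text = lines, sep = "\t",
                                 stringsAsFactors = FALSE))
  names(df) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                 "name", "score", "strand1", "strand2")[seq_len(ncol(df))]
  data.table(
    chrom1 = as.character(df$chrom1),
    pos1 = as.integer(ifelse(df$strand1 == "+", df$end1, df$start1)),
    side1 = ifelse(df$strand1 == "+", "tail", "head"),
    chrom2 = as.character(df$chrom2),
    pos2 = as.integer(ifelse(df$strand2 == "+", df$end2, df$start2)),
    side2 = ifelse(df$strand2 == "+", "tail", "head"),
    support = as.integer(df$score),
    component_id = NA_integer_
  )
}
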