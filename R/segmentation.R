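#' Merge overlapping discordant alignment intervals
#'
#' Computes maximal intervals of strictly overlapping aligned-part spans of
#' discordant read pairs, per chromosome. Book-ended spans (\code{[100,200)}
#' and \code{[200,300)}) are not merged.
#'
#' @param discordant_parts aligned-parts table restricted to discordant pairs.
#' @return data.table with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), sorted by genome position.
#' @export
merge_discordant_intervals <- function(discordant_parts) {
  dp <- as.data.table(discordant_parts)
  if (nrow(dp) == 0L) {
    return(data.table(chrom = character(), start = integer(), end = integer()))
  }
  out <- dp[, {
    ir <- IRanges::IRanges(start = start + 1L, end = end) # 1-based closed
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    list(start = IRanges::start(red) - 1L, end = IRanges::end(red))
  }, by = chrom]
  setorder(out, chrom, start)
  out[]
}

#' Choose genome breakpoints from discordant pileups and zero-coverage gaps
#'
#' The breakpoint set is the union of (1) the start and end of every interval
#' of overlapping discordant alignments and (2) the starting point of every
#' maximal zero-coverage run, where coverage counts all aligned parts
#' (concordant and discordant); spliced reads contribute coverage only where
#' their parts align. Positions 0 and the chromosome length are implicit
#' boundaries and never returned.
#'
#' @param all_parts aligned-parts table of every pair.
#' @param discordant_intervals output of [merge_discordant_intervals()].
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return named list (per chromosome) of sorted breakpoint positions.
#' @export
find_breakpoints <- function(all_parts, discordant_intervals, chrom_lengths) {
  ap <- as.data.table(all_parts)
  di <- as.data.table(discordant_intervals)
  if (nrow(ap)) {
    unknown <- setdiff(unique(ap$chrom), names(chrom_lengths))
    if (length(unknown)) {
      stop("parts on chromosome(s) absent from header: ",
           paste(unknown, collapse = ", "))
    }
    over <- ap[end > chrom_lengths[chrom]]
    if (nrow(over)) stop("aligned part beyond chromosome length (bad header?)")
  }
  bp <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    cov_parts <- ap[chrom == cn]
    zero_starts <- integer()
    if (nrow(cov_parts)) {
      covered <- IRanges::reduce(
        IRanges::IRanges(cov_parts$start + 1L, cov_parts$end)
      )
      gaps <- IRanges::gaps(covered, start = 1L, end = len)
      zero_starts <- IRanges::start(gaps) - 1L
    } else {
      zero_starts <- 0L
    }
    d <- di[chrom == cn]
    pos <- sort(unique(c(zero_starts, d$start, d$end)))
    pos[pos > 0L & pos < len]
  })
  names(bp) <- names(chrom_lengths)
  bp
}

#' Partition the genome into segments
#'
#' Consecutive breakpoints (with 0 and the chromosome length added) delimit
#' segments; ids are assigned in (chromosome, start) order and every base
#' belongs to exactly one segment. Duplicate breakpoints are deduplicated
#' silently.
#'
#' @param breakpoints named list of per-chromosome breakpoint positions.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return data.table with columns \code{id}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open tiling).
#' @export
partition_genome <- function(breakpoints, chrom_lengths) {
  segs <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    bp <- sort(unique(breakpoints[[cn]]))
    bp <- bp[bp > 0L & bp < len]
    bounds <- c(0L, bp, len)
    data.table(chrom = cn, start = head(bounds, -1L), end = tail(bounds, -1L))
  })
  out <- rbindlist(segs)
  setorder(out, chrom, start)
  out[, id := seq_len(.N)]
  out[, list(id, chrom, start, end)]
}

#' Export segments as BED (0-based half-open)
#' @param segments segment table from [partition_genome()].
#' @param file output path.
#' @export
write_segments_bed <- function(segments, file) {
  df <- as.data.table(segments)[, list(chrom, start, end, name = paste0("seg", id))]
  write.table(df, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

# Locate the segment containing base `pos` (0-based) on `chrom`.
# segments must tile each chromosome. Vectorized; returns segment ids.
segment_of_base <- function(segments, chrom, pos) {
  seg <- as.data.table(segments)
  setorderv(seg, c("chrom", "start"))
  out <- integer(length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    sc <- seg[seg$chrom == cn]
    if (nrow(sc) == 0L) stop("no segments on chromosome ", cn)
    idx <- findInterval(pos[sel], sc$start)
    if (any(idx < 1L) || any(pos[sel] >= sc$end[pmax(idx, 1L)])) {
      stop("position outside segment tiling on ", cn)
    }
    out[sel] <- sc$id[idx]
  }
  out
}
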