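#' Aligned parts and read-pair alignments
#'
#' The package represents read alignments as a flat table of *aligned parts*.
#' Each part is one contiguously aligned stretch of one read end: a spliced or
#' split end contributes several parts. Columns:
#'
#' \describe{
#'   \item{pair_id}{integer identifier of the read pair}
#'   \item{read_name}{read name}
#'   \item{mate}{1 or 2, which end of the pair}
#'   \item{chrom}{chromosome name}
#'   \item{start,end}{0-based half-open genome interval of the part}
#'   \item{orient}{alignment orientation, \code{"+"} or \code{"-"}}
#'   \item{qoff}{offset of the part within the original read sequence; parts of
#'     one end are ordered by \code{qoff}}
#' }
#'
#' @param parts data.frame of aligned parts as described above.
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return An object of class \code{pair_alignments}: a list with elements
#'   \code{parts} (the validated parts table) and \code{pairs} (one row per
#'   read pair with its derived concordance status).
#' @seealso [split_concordant()], [pair_concordant()], [read_alignment_groups()]
#' @export
pair_alignments <- function(parts, chrom_lengths = NULL) {
  parts <- validate_parts(parts)
  pairs <- classify_pairs(parts)
  structure(
    list(parts = parts, pairs = pairs),
    chrom_lengths = chrom_lengths,
    class = "pair_alignments"
  )
}

#' @export
print.pair_alignments <- function(x, ...) {
  cat(sprintf(
    "<pair_alignments> %d pairs (%d concordant, %d discordant), %d aligned parts\n",
    nrow(x$pairs), sum(x$pairs$concordant, na.rm = TRUE),
    sum(!x$pairs$concordant, na.rm = TRUE), nrow(x$parts)
  ))
  invisible(x)
}

validate_parts <- function(parts) {
  parts <- as.data.table(parts)
  needed <- c("pair_id", "mate", "chrom", "start", "end", "orient", "qoff")
  missing <- setdiff(needed, names(parts))
  if (length(missing)) {
    stop("parts table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!"read_name" %in% names(parts)) parts$read_name <- as.character(parts$pair_id)
  if (any(parts$start >= parts$end)) stop("aligned parts must satisfy start < end")
  if (!all(parts$orient %in% c("+", "-"))) stop("orient must be '+' or '-'")
  if (!all(parts$mate %in% c(1L, 2L))) stop("mate must be 1 or 2")
  setorder(parts, pair_id, mate, qoff, start)
  parts[]
}

#' Split-alignment concordance of one read end
#'
#' A split-aligned end is concordant when all its parts share one chromosome
#' and one orientation, and genome start positions are strictly increasing in
#' read order for forward parts or strictly decreasing for reverse parts.
#' A single-part end is always concordant.
#'
#' @param parts data.frame of aligned parts of a single read end, ordered by
#'   (or orderable by) \code{qoff}.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
split_concordant <- function(parts) {
  parts <- as.data.table(parts)
  if (nrow(parts) == 0L) stop("empty read end")
  parts <- parts[order(qoff)]
  if (nrow(parts) == 1L) return(TRUE)
  if (length(unique(parts$chrom)) != 1L) return(FALSE)
  if (length(unique(parts$orient)) != 1L) return(FALSE)
  d <- diff(parts$start)
  if (parts$orient[1L] == "+") all(d > 0) else all(d < 0)
}

#' Pair-level concordance of a paired-end alignment
#'
#' A paired-end alignment is concordant when both ends are individually
#' split-concordant, all parts of both ends lie on one chromosome, the two
#' ends align to opposite strands, and the leftmost part of the forward end
#' starts at or before the leftmost part of the reverse end (ends may
#' overlap).
#'
#' @param first,second data.frames of aligned parts of the two read ends.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
pair_concordant <- function(first, second) {
  first <- as.data.table(first); second <- as.data.table(second)
  if (!split_concordant(first) || !split_concordant(second)) return(FALSE)
  if (length(unique(c(first$chrom, second$chrom))) != 1L) return(FALSE)
  o1 <- first$orient[1L]; o2 <- second$orient[1L]
  if (o1 == o2) return(FALSE)
  fwd <- if (o1 == "+") first else second
  rev <- if (o1 == "+") second else first
  min(fwd$start) <= min(rev$start)
}

#' Classify every read pair as concordant or discordant
#'
#' Vectorized over a full parts table; one row per pair is returned. Pairs
#' with only one aligned end get \code{NA}.
#'
#' @param parts aligned-parts table (see [pair_alignments()]).
#' @return data.table with columns \code{pair_id}, \code{read_name},
#'   \code{concordant}.
#' @export
classify_pairs <- function(parts) {
  pt <- as.data.table(parts)
  setorder(pt, pair_id, mate, qoff, start)
  ends <- pt[, {
    ok <- if (.N == 1L) TRUE else {
      if (length(unique(chrom)) != 1L || length(unique(orient)) != 1L) FALSE
      else if (orient[1L] == "+") all(diff(start) > 0)
      else all(diff(start) < 0)
    }
    list(split_ok = ok, ori = orient[1L], minstart = min(start),
         chrom1 = chrom[1L], nchrom = length(unique(chrom)))
  }, by = list(pair_id, mate)]
  pairs <- ends[, {
    if (.N < 2L) list(concordant = NA) else {
      both_split <- all(split_ok)
      same_chrom <- length(unique(chrom1)) == 1L && all(nchrom == 1L)
      opposite <- ori[1L] != ori[2L]
      order_ok <- if (!opposite) FALSE else {
        fwd <- which(ori == "+"); rev <- which(ori == "-")
        minstart[fwd] <= minstart[rev]
      }
      list(concordant = both_split && same_chrom && opposite && order_ok)
    }
  }, by = pair_id]
  nm <- unique(pt[, list(pair_id, read_name)])
  out <- nm[pairs, on = "pair_id"]
  setorder(out, pair_id)
  out[]
}

sam_flag_bit <- function(flag, bit) bitwAnd(flag, bit) > 0L

#' Read paired-end and split alignments from SAM/BAM
#'
#' Reads SAM-convention records (split alignments as primary plus
#' supplementary records sharing the read name and mate flag), splits each
#' record at N (intron skip) CIGAR operations into aligned parts, converts
#' 1-based inclusive positions to 0-based half-open, derives query offsets
#' from clipping (strand adjusted, so parts are ordered by their position in
#' the original read), and groups parts into read pairs. Unmapped, secondary,
#' and unpaired records are dropped; pairs with only one mapped end are
#' excluded.
#'
#' @param file path to a SAM or BAM file (SAM is converted on the fly).
#' @param min_mapq minimum mapping quality; records below are skipped.
#'   Default 0 (off).
#' @param include_duplicates,include_qcfail keep records flagged as PCR/optical
#'   duplicate or QC fail. Default \code{FALSE}.
#' @return A [pair_alignments()] object; chromosome lengths from the header
#'   are attached as the \code{chrom_lengths} attribute.
#' @export
read_alignment_groups <- function(file, min_mapq = 0,
                                  include_duplicates = FALSE,
                                  include_qcfail = FALSE) {
  if (!file.exists(file)) stop("no such file: ", file)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  chrom_lengths <- setNames(as.integer(hdr), names(hdr))

  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  rec <- data.table(
    qname = rec$qname, flag = rec$flag, chrom = as.character(rec$rname),
    pos = rec$pos, mapq = rec$mapq, cigar = rec$cigar
  )
  bad <- is.na(rec$pos) | is.na(rec$cigar) | rec$cigar == "*" | is.na(rec$chrom)
  if (any(bad)) {
    warning(sum(bad), " malformed or unaligned record(s) skipped")
    rec <- rec[!bad]
  }
  rec <- rec[!sam_flag_bit(flag, 0x4L)]
  if (!include_duplicates) rec <- rec[!sam_flag_bit(flag, 0x400L)]
  if (!include_qcfail) rec <- rec[!sam_flag_bit(flag, 0x200L)]
  if (min_mapq > 0) rec <- rec[!is.na(mapq) & mapq >= min_mapq]
  unpaired <- !sam_flag_bit(rec$flag, 0x1L) |
    (!sam_flag_bit(rec$flag, 0x40L) & !sam_flag_bit(rec$flag, 0x80L))
  if (any(unpaired)) {
    warning(sum(unpaired), " unpaired record(s) skipped")
    rec <- rec[!unpaired]
  }
  if (nrow(rec) == 0L) {
    return(pair_alignments(empty_parts(), chrom_lengths))
  }
  rec$mate <- ifelse(sam_flag_bit(rec$flag, 0x40L), 1L, 2L)
  rec$orient <- ifelse(sam_flag_bit(rec$flag, 0x10L), "-", "+")
  parts <- cigar_to_parts(rec)

  # keep only pairs with both ends mapped
  both <- parts[, list(nm = length(unique(mate))), by = "qname"][nm == 2L]
  parts <- parts[both[, list(qname)], on = "qname"]
  if (nrow(parts) == 0L) {
    return(pair_alignments(empty_parts(), chrom_lengths))
  }
  parts[, pair_id := as.integer(factor(qname, levels = unique(qname)))]
  out <- parts[, list(pair_id, read_name = qname, mate, chrom, start, end,
                      orient, qoff)]
  pair_alignments(out, chrom_lengths)
}

empty_parts <- function() {
  data.table(pair_id = integer(), read_name = character(), mate = integer(),
             chrom = character(), start = integer(), end = integer(),
             orient = character(), qoff = integer())
}

# Explode CIGAR strings and emit one aligned part per run of
# reference-aligned operations, splitting at N. Query offsets count from the
# start of the original read (hard/soft clips included, strand adjusted).
cigar_to_parts <- function(rec) {
  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
  nop <- lengths(ops)
  dt <- data.table(
    rid = rep(seq_len(nrow(rec)), nop),
    op = unlist(ops), len = unlist(lens)
  )
  dt[, consq := as.integer(op %in% c("M", "I", "S", "H", "=", "X")) * len]
  dt[, consr := as.integer(op %in% c("M", "D", "N", "=", "X")) * len]
  dt[, q_end := cumsum(consq), by = rid]
  dt[, q_start := q_end - consq]
  dt[, r_end := cumsum(consr), by = rid]
  dt[, r_start := r_end - consr]
  dt[, part := cumsum(op == "N"), by = rid]
  dt[, qlen_total := sum(consq), by = rid]

  ali <- dt[op %in% c("M", "=", "X", "D")]
  parts <- ali[, list(
    r0 = min(r_start), r1 = max(r_end),
    q0 = min(q_start[op != "D"]), q1 = max(q_end[op != "D"]),
    qlen = qlen_total[1L]
  ), by = list(rid, part)]
  parts <- parts[r1 > r0]
  parts[, `:=`(
    chrom = rec$chrom[rid],
    start = rec$pos[rid] - 1L + r0,
    end = rec$pos[rid] - 1L + r1,
    orient = rec$orient[rid],
    mate = rec$mate[rid],
    qname = rec$qname[rid]
  )]
  parts[, qoff := ifelse(orient == "+", q0, qlen - q1)]
  parts[, list(qname, mate, chrom, start, end, orient, qoff)]
}
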