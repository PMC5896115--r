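#' Write a genome as FASTA
#' @param x a [make_genome()] or [plant_svs()] result (its \code{seq} is used).
#' @param file output path.
#' @export
write_genome_fasta <- function(x, file) {
  seqs <- Biostrings::DNAStringSet(x$seq)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' Write gene models as GTF (1-based inclusive)
#' @param genome a [make_genome()] result.
#' @param file output path.
#' @export
write_annotation_gtf <- function(genome, file) {
  ex <- as.data.table(genome$exons)
  ge <- as.data.table(genome$genes)
  ex <- ge[, list(gene_id, strand)][ex, on = "gene_id"]
  lines <- c(
    ge[, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
                 chrom, start + 1L, end, strand, gene_id)],
    ex[, sprintf(paste0("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                        "transcript_id \"%s.t1\"; exon_number \"%d\";"),
                 chrom, start + 1L, end, strand, gene_id, gene_id, rank)]
  )
  writeLines(lines, file)
  invisible(file)
}

#' Write paired-end alignments as SAM
#'
#' Consecutive parts of one end that continue on the same chromosome and
#' strand are emitted as a single record with N (skip) CIGAR operations,
#' as a spliced aligner would; parts that jump chromosome or strand become
#' supplementary records. Sequences are omitted (\code{*}).
#'
#' @param aln a [pair_alignments()] object.
#' @param file output path.
#' @param chrom_lengths named lengths for the header; defaults to the
#'   object's attribute.
#' @param read_len read length used to compute clipping; defaults to the
#'   maximum extent seen per mate.
#' @export
write_sam <- function(aln, file, chrom_lengths = attr(aln, "chrom_lengths"),
                      read_len = NULL) {
  if (is.null(chrom_lengths)) stop("chrom_lengths required for the SAM header")
  pt <- copy(aln$parts)
  setorder(pt, pair_id, mate, qoff)
  if (is.null(read_len)) read_len <- max(pt$qoff + (pt$end - pt$start))
  # split each end into spliced runs
  pt[, gap_ok := {
    n <- .N
    if (n == 1L) TRUE else {
      nx_chrom <- c(chrom[-1L], NA); nx_start <- c(start[-1L], NA)
      nx_end <- c(end[-1L], NA); nx_or <- c(orient[-1L], NA)
      ok <- chrom == nx_chrom & orient == nx_or &
        ifelse(orient == "+", nx_start >= end, nx_end <= start)
      c(TRUE, head(ok, n - 1L))
    }
  }, by = list(pair_id, mate)]
  pt[, run := cumsum(!gap_ok), by = list(pair_id, mate)]

  recs <- pt[, {
    # reference blocks are written in increasing genome order on both strands
    ord <- order(start)
    s <- start[ord]; e <- end[ord]
    q0 <- min(qoff); q1 <- max(qoff + (end - start))
    lead <- if (orient[1L] == "+") q0 else read_len - q1
    trail <- read_len - lead - sum(e - s)
    op_len <- integer(0); op_chr <- character(0)
    push <- function(len, op) {
      if (len <= 0) return()
      n <- length(op_chr)
      if (n > 0L && op_chr[n] == op) {
        op_len[n] <<- op_len[n] + len
      } else {
        op_len <<- c(op_len, len); op_chr <<- c(op_chr, op)
      }
    }
    push(lead, "S")
    for (i in seq_along(s)) {
      push(e[i] - s[i], "M")
      if (i < length(s)) push(s[i + 1L] - e[i], "N")
    }
    push(trail, "S")
    cigar <- paste0(op_len, op_chr, collapse = "")
    list(chrom = chrom[1L], pos = min(s) + 1L, orient = orient[1L],
         cigar = cigar, minq = q0)
  }, by = list(pair_id, read_name, mate, run)]
  recs[, primary := minq == min(minq), by = list(pair_id, mate)]
  recs[, flag := 1L + ifelse(mate == 1L, 64L, 128L) +
         ifelse(orient == "-", 16L, 0L) + ifelse(primary, 0L, 2048L)]

  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- recs[, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                         read_name, flag, chrom, pos, cigar)]
  writeLines(c(hdr, body), file)
  invisible(file)
}
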