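#' Match predicted TSVs against ground truth
#'
#' A prediction is a true positive when some truth record pairs its two
#' breakpoints (in either orientation of the pairing) on the same
#' chromosomes, with both positions within \code{window_bp} and both
#' side/orientation labels agreeing. Matching is greedy nearest-first on the
#' summed breakpoint distance; each truth record and each prediction is
#' consumed at most once. With no predictions, precision is 1 by convention.
#'
#' @param pred,truth call tables ([call_tsvs()] format).
#' @param window_bp matching window per breakpoint (bp). Default 30000.
#' @return list with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{sensitivity}, and the matched index pairs.
#' @export
match_tsvs <- function(pred, truth, window_bp = 30000) {
  stopifnot(window_bp >= 0)
  pred <- canonical_calls(as.data.table(pred))
  truth <- canonical_calls(as.data.table(truth))
  np <- nrow(pred); nt <- nrow(truth)
  cand <- list()
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      # direct pairing
      d <- pair_distance(pred[i], truth[j], window_bp, crossed = FALSE)
      dx <- pair_distance(pred[i], truth[j], window_bp, crossed = TRUE)
      d <- min(d, dx)
      if (is.finite(d)) {
        cand[[length(cand) + 1L]] <- data.table(i = i, j = j, d = d)
      }
    }
  }
  matched <- data.table(i = integer(), j = integer(), d = numeric())
  if (length(cand)) {
    cand <- rbindlist(cand)
    setorder(cand, d, i, j)
    used_i <- logical(np); used_j <- logical(nt)
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        matched <- rbind(matched, cand[k])
      }
    }
  }
  tp <- nrow(matched)
  fp <- np - tp
  fn <- nt - tp
  list(
    tp = tp, fp = fp, fn = fn,
    precision = if (np == 0L) 1 else tp / np,
    sensitivity = if (nt == 0L) 1 else tp / nt,
    matches = matched
  )
}

pair_distance <- function(p, t, window_bp, crossed = FALSE) {
  t1 <- if (crossed) list(chrom = t$chrom2, pos = t$pos2, side = t$side2)
        else list(chrom = t$chrom1, pos = t$pos1, side = t$side1)
  t2 <- if (crossed) list(chrom = t$chrom1, pos = t$pos1, side = t$side1)
        else list(chrom = t$chrom2, pos = t$pos2, side = t$side2)
  if (p$chrom1 != t1$chrom || p$chrom2 != t2$chrom) return(Inf)
  if (p$side1 != t1$side || p$side2 != t2$side) return(Inf)
  d1 <- abs(p$pos1 - t1$pos); d2 <- abs(p$pos2 - t2$pos)
  if (d1 > window_bp || d2 > window_bp) return(Inf)
  d1 + d2
}

#' Breakpoint-partner entropy of recurrent breakpoints
#'
#' Breakpoints are binned by coordinate; for every binned breakpoint
#' occurring at least \code{min_recurrence} times across the calls, the
#' Shannon entropy of the empirical distribution of its junction partners
#' (also binned) is computed. Entropy 0 means the breakpoint always rejoins
#' the same partner; higher values mean promiscuous partnering.
#'
#' @param calls call table ([call_tsvs()] format), typically pooled across
#'   samples.
#' @param min_recurrence minimum occurrences of a breakpoint. Default 3.
#' @param bin_bp coordinate bin width for breakpoint identity. Default 10000.
#' @param base logarithm base for the entropy. Default 2 (bits).
#' @return data.table with one row per qualifying breakpoint: \code{chrom},
#'   \code{bin}, \code{n}, \code{entropy}.
#' @export
partner_entropy <- function(calls, min_recurrence = 3, bin_bp = 10000,
                            base = 2) {
  stopifnot(min_recurrence >= 1)
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) {
    return(data.table(chrom = character(), bin = integer(), n = integer(),
                      entropy = numeric()))
  }
  bp <- rbind(
    calls[, list(chrom = chrom1, bin = pos1 %/% as.integer(bin_bp),
                 p_chrom = chrom2, p_bin = pos2 %/% as.integer(bin_bp))],
    calls[, list(chrom = chrom2, bin = pos2 %/% as.integer(bin_bp),
                 p_chrom = chrom1, p_bin = pos1 %/% as.integer(bin_bp))]
  )
  out <- bp[, {
    partners <- paste(p_chrom, p_bin)
    p <- as.numeric(table(partners)) / .N
    list(n = .N, entropy = -sum(p * log(p, base = base)))
  }, by = list(chrom, bin)]
  out <- out[n >= min_recurrence]
  setorder(out, chrom, bin)
  out[]
}

#' Tag calls as fusion-gene or non-fusion-gene TSVs
#'
#' Reporting-only classification: a call is a fusion-gene TSV when both
#' breakpoints lie inside annotated genes and the joined pieces are
#' transcribed in a consistent sense (the strand implied by each breakpoint
#' side either matches both gene strands or is opposite to both). All other
#' calls -- intergenic breakpoints or anti-sense joins -- are non-fusion-gene
#' TSVs.
#'
#' @param calls call table.
#' @param genes gene table with \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end} (e.g. from [make_genome()]).
#' @return the call table with added columns \code{gene1}, \code{gene2},
#'   \code{fusion_gene}.
#' @export
tag_fusion_genes <- function(calls, genes) {
  calls <- as.data.table(calls)
  genes <- as.data.table(genes)
  find_gene <- function(chrom, pos) {
    out <- rep(NA_character_, length(pos))
    strand <- rep(NA_character_, length(pos))
    for (k in seq_len(nrow(genes))) {
      hit <- chrom == genes$chrom[k] & pos >= genes$start[k] & pos <= genes$end[k]
      out[hit] <- genes$gene_id[k]
      strand[hit] <- genes$strand[k]
    }
    list(gene = out, strand = strand)
  }
  g1 <- find_gene(calls$chrom1, calls$pos1)
  g2 <- find_gene(calls$chrom2, calls$pos2)
  eff1 <- ifelse(calls$side1 == "tail", "+", "-")
  eff2 <- ifelse(calls$side2 == "head", "+", "-")
  sense_ok <- (eff1 == g1$strand) == (eff2 == g2$strand)
  calls$gene1 <- g1$gene
  calls$gene2 <- g2$gene
  calls$fusion_gene <- !is.na(g1$gene) & !is.na(g2$gene) & sense_ok
  calls
}
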