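#' Detect transcriptomic structural variants from RNA-seq alignments
#'
#' End-to-end pipeline: classify read pairs as concordant or discordant,
#' choose genome breakpoints from discordant pileups and zero-coverage gaps,
#' partition the genome into segments, build and filter the weighted genome
#' segment graph, rearrange each connected component to maximize compatible
#' edge weight, and report initially-discordant edges made compatible as TSV
#' breakpoint pairs.
#'
#' @param input path to a SAM/BAM file, or a [pair_alignments()] object.
#' @param alpha discordant edge weight coefficient (assumed normal/tumor
#'   transcript ratio), >= 1. Default 1.
#' @param theta minimum supporting read count per edge. Default 5.
#' @param gamma maximum distinct discordant neighbor segments. Default 5.
#' @param max_component largest component solved exactly; larger components
#'   are skipped with a warning. Default 14.
#' @param min_mapq minimum mapping quality when reading alignments. Default 0.
#' @param chrom_lengths named integer vector; required when \code{input}
#'   carries no header information.
#' @param verbose log component-level progress to stderr.
#' @return object of class \code{tsv_result}: list with \code{calls},
#'   \code{graph} (filtered), \code{solutions}, \code{segments},
#'   \code{alignments}.
#' @examples
#' sim <- simulate_dataset(seed = 1)
#' res <- detect_tsvs(sim$alignments, theta = 3)
#' res$calls
#' @export
detect_tsvs <- function(input, alpha = 1, theta = 5, gamma = 5,
                        max_component = 14, min_mapq = 0,
                        chrom_lengths = NULL, verbose = FALSE) {
  aln <- if (inherits(input, "pair_alignments")) input
         else read_alignment_groups(input, min_mapq = min_mapq)
  if (is.null(chrom_lengths)) chrom_lengths <- attr(aln, "chrom_lengths")
  if (is.null(chrom_lengths)) {
    stop("chrom_lengths must be supplied when input carries no header")
  }
  parts <- aln$parts
  disc_ids <- aln$pairs$pair_id[!is.na(aln$pairs$concordant) & !aln$pairs$concordant]
  disc_parts <- parts[pair_id %in% disc_ids]

  di <- merge_discordant_intervals(disc_parts)
  bp <- find_breakpoints(parts, di, chrom_lengths)
  segments <- partition_genome(bp, chrom_lengths)
  if (verbose) {
    message(sprintf("%d segments, %d discordant pairs", nrow(segments),
                    length(disc_ids)))
  }
  g <- build_graph(aln, segments, alpha = alpha)
  g <- filter_graph(g, theta = theta, gamma = gamma)
  comps <- components(g)
  sols <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    sols[[k]] <- optimize_component(comps[[k]], max_size = max_component)
    if (verbose && nrow(comps[[k]]$edges)) {
      message(sprintf("component %d/%d: %d segments, %d edges, objective %.6g",
                      k, length(comps), nrow(comps[[k]]$segments),
                      nrow(comps[[k]]$edges), sols[[k]]$objective))
    }
  }
  calls <- call_tsvs(g, sols)
  structure(list(calls = calls, graph = g, solutions = sols,
                 segments = segments, alignments = aln),
            class = "tsv_result")
}

#' @export
print.tsv_result <- function(x, ...) {
  cat(sprintf("<tsv_result> %d TSV call(s) over %d segments\n",
              nrow(x$calls), nrow(x$segments)))
  if (nrow(x$calls)) print(x$calls)
  invisible(x)
}
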