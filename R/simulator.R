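#' Generate a small multi-chromosome genome with gene models
#'
#' Random genome for desk-scale simulation: genes with a fixed number of
#' exons are packed onto each chromosome, separated by untranscribed gaps so
#' that distinct genes never share expressed sequence. Deterministic under
#' \code{seed}.
#'
#' @param n_chroms number of chromosomes. Default 4.
#' @param chrom_len length of each chromosome (bp). Default 50000.
#' @param n_genes total genes, distributed across chromosomes. Default 20.
#' @param exon_geometry list with \code{n_exons} (exons per gene),
#'   \code{exon_len} and \code{intron_len} (min/max ranges, bp).
#' @param gap range of intergenic gap lengths (bp).
#' @param seed optional RNG seed.
#' @return object of class \code{sim_genome}: list with \code{seq} (named
#'   character vector of chromosome sequences), \code{genes} and
#'   \code{exons} tables (0-based half-open coordinates; \code{rank} is the
#'   exon's transcript order), and \code{chrom_lengths}.
#' @export
make_genome <- function(n_chroms = 4, chrom_len = 50000, n_genes = 20,
                        exon_geometry = list(n_exons = 3L,
                                             exon_len = c(200L, 300L),
                                             intron_len = c(450L, 550L)),
                        gap = c(900L, 1500L), seed = NULL) {
  stopifnot(n_chroms >= 1, chrom_len >= 1000, n_genes >= 0)
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chroms))
    seqs <- vapply(chroms, function(cn) {
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = "")
    }, character(1))
    genes <- list(); exons <- list()
    if (n_genes > 0) {
      per_chrom <- tabulate(rep(seq_len(n_chroms), length.out = n_genes),
                            nbins = n_chroms)
      gid <- 0L
      for (ci in seq_len(n_chroms)) {
        cursor <- 0L
        for (k in seq_len(per_chrom[ci])) {
          gid <- gid + 1L
          cursor <- cursor + rint(gap[1], gap[2])
          ne <- exon_geometry$n_exons
          elens <- rint(exon_geometry$exon_len[1], exon_geometry$exon_len[2], ne)
          ilens <- if (ne > 1) {
            rint(exon_geometry$intron_len[1], exon_geometry$intron_len[2], ne - 1L)
          } else integer()
          glen <- sum(elens) + sum(ilens)
          if (cursor + glen > chrom_len - 200L) {
            stop("infeasible packing: gene ", gid, " does not fit on ",
                 chroms[ci])
          }
          strand <- sample(c("+", "-"), 1L)
          gene_id <- sprintf("gene%02d", gid)
          estarts <- cursor + cumsum(c(0L, head(elens, -1L) + ilens))
          genes[[gid]] <- data.table(
            gene_id = gene_id, chrom = chroms[ci], strand = strand,
            start = cursor, end = cursor + glen
          )
          rk <- if (strand == "+") seq_len(ne) else rev(seq_len(ne))
          exons[[gid]] <- data.table(
            gene_id = gene_id, chrom = chroms[ci], rank = rk,
            start = estarts, end = estarts + elens
          )
          cursor <- cursor + glen
        }
      }
    }
    structure(list(
      seq = seqs,
      genes = if (length(genes)) rbindlist(genes) else
        data.table(gene_id = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer()),
      exons = if (length(exons)) rbindlist(exons) else
        data.table(gene_id = character(), chrom = character(), rank = integer(),
                   start = integer(), end = integer()),
      chrom_lengths = setNames(rep(as.integer(chrom_len), n_chroms), chroms)
    ), class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosome(s), %d gene(s)\n",
              length(x$seq), nrow(x$genes)))
  invisible(x)
}

sv_types <- c("deletion", "insertion", "duplication", "inversion", "translocation")

#' Plant structural variants into a genome
#'
#' Introduces SVs of five types -- deletion, inversion, insertion (novel
#' sequence), tandem duplication, and reciprocal inter-chromosomal
#' translocation -- producing a rearranged genome together with a base-level
#' coordinate map between the original and rearranged genomes (a bijection
#' on retained bases). SVs are placed in distinct genes so that their
#' discordant read pileups cannot overlap, matching the pileup assumption of
#' the segment construction.
#'
#' @param genome a [make_genome()] result.
#' @param counts named integer vector over
#'   \code{c("deletion","insertion","duplication","inversion","translocation")}.
#' @param seed optional RNG seed.
#' @param sv_len length of deleted/duplicated material (bp).
#' @return object of class \code{planted_genome}: list with \code{blocks}
#'   (ordered source blocks of each rearranged chromosome, with destination
#'   coordinates), \code{svs} (SV records), \code{chrom_lengths} of the
#'   rearranged genome, \code{seq} (rearranged sequences), and the original
#'   \code{genome}.
#' @export
plant_svs <- function(genome,
                      counts = c(deletion = 1, insertion = 1, duplication = 1,
                                 inversion = 2, translocation = 1),
                      seed = NULL, sv_len = 400L) {
  stopifnot(all(names(counts) %in% sv_types))
  with_seed(seed, {
    bl <- lapply(names(genome$chrom_lengths), function(cn) {
      data.table(src_chrom = cn, src_start = 0L,
                 src_end = genome$chrom_lengths[[cn]],
                 strand = "+", primary = TRUE, novel_len = 0L)
    })
    names(bl) <- names(genome$chrom_lengths)

    exons <- as.data.table(genome$exons)
    used <- character()
    pick_gene <- function(min_exons = 2L, not_chrom = character()) {
      cand <- genome$genes[!(genome$genes$gene_id %in% used) &
                             !(genome$genes$chrom %in% not_chrom), ]
      nex <- vapply(cand$gene_id, function(g) sum(exons$gene_id == g), integer(1))
      cand <- cand[nex >= min_exons, ]
      if (nrow(cand) == 0L) stop("cannot place SV: no unused gene available")
      g <- cand[sample.int(nrow(cand), 1L), ]
      used <<- c(used, g$gene_id)
      g
    }
    gene_exons <- function(g) {
      e <- exons[gene_id == g$gene_id]
      setorder(e, start)
      e
    }

    svs <- list()
    add_sv <- function(type, chrom1, start1, end1, chrom2 = NA_character_,
                       pos2 = NA_integer_) {
      svs[[length(svs) + 1L]] <<- data.table(
        sv_id = sprintf("sv%02d", length(svs) + 1L), type = type,
        chrom1 = chrom1, start1 = as.integer(start1), end1 = as.integer(end1),
        chrom2 = chrom2, pos2 = as.integer(pos2)
      )
    }

    # local SVs first (block edits keyed by original coordinates),
    # translocations last (they exchange whole chromosome suffixes)
    for (k in seq_len(counts["inversion"] %||na% 0)) {
      g <- pick_gene(min_exons = 3L)
      e <- gene_exons(g)
      ne <- nrow(e)
      s <- rint(e$end[1L] + 20L, e$end[1L] + 120L)
      en <- rint(e$start[ne] - 120L, e$start[ne] - 20L)
      bl <- apply_local_sv(bl, "inversion", g$chrom, s, en)
      add_sv("inversion", g$chrom, s, en)
    }
    for (k in seq_len(counts["deletion"] %||na% 0)) {
      g <- pick_gene()
      e <- gene_exons(g)
      s <- e$start[2L] - 150L
      bl <- apply_local_sv(bl, "deletion", g$chrom, s, s + sv_len)
      add_sv("deletion", g$chrom, s, s + sv_len)
    }
    for (k in seq_len(counts["duplication"] %||na% 0)) {
      g <- pick_gene()
      e <- gene_exons(g)
      s <- e$start[2L] - 150L
      bl <- apply_local_sv(bl, "duplication", g$chrom, s, s + sv_len)
      add_sv("duplication", g$chrom, s, s + sv_len)
    }
    for (k in seq_len(counts["insertion"] %||na% 0)) {
      g <- pick_gene()
      e <- gene_exons(g)
      p <- e$start[2L] + 100L
      bl <- apply_local_sv(bl, "insertion", g$chrom, p, p, novel_len = 500L)
      add_sv("insertion", g$chrom, p, p)
    }
    trans_pairs <- list()
    for (k in seq_len(counts["translocation"] %||na% 0)) {
      gA <- pick_gene(min_exons = 2L)
      gB <- pick_gene(min_exons = 2L, not_chrom = gA$chrom)
      eA <- gene_exons(gA); eB <- gene_exons(gB)
      p1 <- as.integer((eA$end[1L] + eA$start[2L]) %/% 2L)
      p2 <- as.integer((eB$end[1L] + eB$start[2L]) %/% 2L)
      bl <- apply_translocation(bl, gA$chrom, p1, gB$chrom, p2)
      add_sv("translocation", gA$chrom, p1, p1, gB$chrom, p2)
    }

    blocks <- finalize_blocks(bl)
    seq <- spell_blocks(blocks, genome$seq)
    chrom_lengths <- vapply(split(blocks, blocks$chrom), function(b) {
      as.integer(sum(b$len))
    }, integer(1))[names(bl)]
    structure(list(blocks = blocks, svs = rbindlist(svs),
                   chrom_lengths = chrom_lengths, seq = seq, genome = genome),
              class = "planted_genome")
  })
}

`%||na%` <- function(x, default) {
  if (length(x) == 0L || is.na(x)) default else as.integer(x)
}

#' @export
print.planted_genome <- function(x, ...) {
  cat(sprintf("<planted_genome> %d SV(s): %s\n", nrow(x$svs),
              paste(x$svs$type, collapse = ", ")))
  invisible(x)
}

# --- block-list surgery -----------------------------------------------------

# find (chrom list name, row index) of the primary forward block containing
# original span [s, e) of src chromosome `chrom`
locate_block <- function(bl, chrom, s, e) {
  for (cn in names(bl)) {
    b <- bl[[cn]]
    i <- which(b$primary & b$strand == "+" & !is.na(b$src_chrom) &
                 b$src_chrom == chrom & b$src_start <= s & b$src_end >= e &
                 b$novel_len == 0L)
    if (length(i)) return(list(chrom = cn, i = i[1L]))
  }
  stop("cannot place SV: original span ", chrom, ":", s, "-", e,
       " is not intact (overlapping SVs?)")
}

split_row <- function(b, i, s, e) {
  row <- b[i]
  pieces <- list()
  if (s > row$src_start) {
    pieces[[length(pieces) + 1L]] <- data.table(
      src_chrom = row$src_chrom, src_start = row$src_start, src_end = s,
      strand = "+", primary = TRUE, novel_len = 0L)
  }
  mid_idx <- length(pieces) + 1L
  if (e > s) {
    pieces[[mid_idx]] <- data.table(
      src_chrom = row$src_chrom, src_start = s, src_end = e,
      strand = "+", primary = TRUE, novel_len = 0L)
  }
  if (e < row$src_end) {
    pieces[[length(pieces) + 1L]] <- data.table(
      src_chrom = row$src_chrom, src_start = e, src_end = row$src_end,
      strand = "+", primary = TRUE, novel_len = 0L)
  }
  list(before = if (i > 1L) b[seq_len(i - 1L)] else NULL,
       pieces = rbindlist(pieces),
       after = if (i < nrow(b)) b[(i + 1L):nrow(b)] else NULL,
       mid = if (e > s) mid_idx else NA_integer_,
       n_before_mid = mid_idx - 1L)
}

apply_local_sv <- function(bl, type, chrom, s, e, novel_len = 0L) {
  loc <- locate_block(bl, chrom, s, max(e, s))
  b <- bl[[loc$chrom]]
  sp <- split_row(b, loc$i, s, e)
  pieces <- sp$pieces
  if (type == "deletion") {
    pieces <- pieces[-sp$mid]
  } else if (type == "inversion") {
    pieces$strand[sp$mid] <- "-"
  } else if (type == "duplication") {
    copy_row <- copy(pieces[sp$mid])
    copy_row$primary <- FALSE
    pieces <- rbindlist(list(
      pieces[seq_len(sp$mid)], copy_row,
      if (sp$mid < nrow(pieces)) pieces[(sp$mid + 1L):nrow(pieces)]
    ))
  } else if (type == "insertion") {
    novel <- data.table(src_chrom = NA_character_, src_start = 0L,
                        src_end = 0L, strand = "+", primary = TRUE,
                        novel_len = as.integer(novel_len))
    pieces <- rbindlist(list(
      if (sp$n_before_mid > 0L) pieces[seq_len(sp$n_before_mid)], novel,
      if (sp$n_before_mid < nrow(pieces))
        pieces[(sp$n_before_mid + 1L):nrow(pieces)]
    ))
  } else stop("unknown local SV type: ", type)
  bl[[loc$chrom]] <- rbindlist(list(sp$before, pieces, sp$after))
  bl
}

apply_translocation <- function(bl, chromA, p1, chromB, p2) {
  locA <- locate_block(bl, chromA, p1, p1)
  spA <- split_row(bl[[locA$chrom]], locA$i, p1, p1)
  bl[[locA$chrom]] <- rbindlist(list(spA$before, spA$pieces, spA$after))
  # rows up to (excluding) original position p1 stay on this chromosome
  cutA <- (if (is.null(spA$before)) 0L else nrow(spA$before)) + spA$n_before_mid
  locB <- locate_block(bl, chromB, p2, p2)
  spB <- split_row(bl[[locB$chrom]], locB$i, p2, p2)
  bl[[locB$chrom]] <- rbindlist(list(spB$before, spB$pieces, spB$after))
  cutB <- (if (is.null(spB$before)) 0L else nrow(spB$before)) + spB$n_before_mid
  if (locA$chrom == locB$chrom) {
    stop("translocation breakpoints resolve to the same rearranged chromosome")
  }
  A <- bl[[locA$chrom]]; B <- bl[[locB$chrom]]
  headA <- A[seq_len(cutA)]; tailA <- if (cutA < nrow(A)) A[(cutA + 1L):nrow(A)] else NULL
  headB <- B[seq_len(cutB)]; tailB <- if (cutB < nrow(B)) B[(cutB + 1L):nrow(B)] else NULL
  bl[[locA$chrom]] <- rbindlist(list(headA, tailB))
  bl[[locB$chrom]] <- rbindlist(list(headB, tailA))
  bl
}

finalize_blocks <- function(bl) {
  out <- rbindlist(lapply(names(bl), function(cn) {
    b <- copy(bl[[cn]])
    b <- b[(b$src_end > b$src_start) | b$novel_len > 0L]
    b$chrom <- cn
    b$len <- ifelse(b$novel_len > 0L, b$novel_len, b$src_end - b$src_start)
    b$dest_start <- cumsum(c(0L, head(b$len, -1L)))
    b
  }))
  out[, list(chrom, dest_start, len, src_chrom, src_start, src_end, strand,
             primary, novel_len)]
}

spell_blocks <- function(blocks, seqs) {
  out <- vapply(split(blocks, blocks$chrom), function(b) {
    setorder(b, dest_start)
    pieces <- vapply(seq_len(nrow(b)), function(i) {
      r <- b[i]
      if (r$novel_len > 0L) {
        paste(sample(c("A", "C", "G", "T"), r$novel_len, replace = TRUE),
              collapse = "")
      } else {
        s <- substr(seqs[[r$src_chrom]], r$src_start + 1L, r$src_end)
        if (r$strand == "-") {
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        } else s
      }
    }, character(1))
    paste(pieces, collapse = "")
  }, character(1))
  out[unique(blocks$chrom)]
}

# --- coordinate maps --------------------------------------------------------

# map original-genome positions to the rearranged genome (primary image).
# Returns data.table(dest_chrom, dest_pos, strand); NA rows for deleted bases.
map_positions <- function(planted, chrom, pos) {
  mp <- planted$blocks[primary == TRUE & novel_len == 0L]
  n <- length(pos)
  dest_chrom <- rep(NA_character_, n)
  dest_pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  for (sc in unique(chrom)) {
    sel <- which(chrom == sc)
    mb <- mp[src_chrom == sc]
    setorder(mb, src_start)
    if (nrow(mb) == 0L) next
    idx <- findInterval(pos[sel], mb$src_start)
    ok <- idx >= 1L & idx <= nrow(mb)
    ok[ok] <- pos[sel][ok] < mb$src_end[idx[ok]]
    i <- idx[ok]; p <- pos[sel][ok]
    dest_chrom[sel[ok]] <- mb$chrom[i]
    dest_pos[sel[ok]] <- as.integer(ifelse(
      mb$strand[i] == "+",
      mb$dest_start[i] + (p - mb$src_start[i]),
      mb$dest_start[i] + (mb$src_end[i] - 1L - p)
    ))
    strand[sel[ok]] <- mb$strand[i]
  }
  data.table(dest_chrom = dest_chrom, dest_pos = dest_pos, strand = strand)
}

# Piecewise map from transcript coordinates of each gene to the rearranged
# genome. Rows: gene_id, tstart, tend, chrom, rstart, rend, strand;
# transcript positions whose bases were deleted have no row.
transcript_maps <- function(planted) {
  genome <- planted$genome
  mp <- planted$blocks[primary == TRUE & novel_len == 0L]
  exons <- as.data.table(genome$exons)
  out <- list()
  for (gi in seq_len(nrow(genome$genes))) {
    g <- genome$genes[gi, ]
    e <- exons[gene_id == g$gene_id]
    if (g$strand == "+") setorder(e, start) else setorder(e, -start)
    tcur <- 0L
    for (k in seq_len(nrow(e))) {
      gs <- e$start[k]; ge <- e$end[k]
      d <- g$strand
      mb <- mp[src_chrom == g$chrom & src_end > gs & src_start < ge]
      if (nrow(mb)) {
        if (d == "+") setorder(mb, src_start) else setorder(mb, -src_start)
        for (j in seq_len(nrow(mb))) {
          os <- max(gs, mb$src_start[j]); oe <- min(ge, mb$src_end[j])
          t0 <- if (d == "+") tcur + (os - gs) else tcur + (ge - oe)
          t1 <- t0 + (oe - os)
          sigma <- if (d == mb$strand[j]) "+" else "-"
          dest <- function(p) {
            if (mb$strand[j] == "+") mb$dest_start[j] + (p - mb$src_start[j])
            else mb$dest_start[j] + (mb$src_end[j] - 1L - p)
          }
          r_ends <- c(dest(os), dest(oe - 1L))
          out[[length(out) + 1L]] <- data.table(
            gene_id = g$gene_id, tstart = as.integer(t0), tend = as.integer(t1),
            chrom = mb$chrom[j], rstart = as.integer(min(r_ends)),
            rend = as.integer(max(r_ends) + 1L), strand = sigma
          )
        }
      }
      tcur <- tcur + (ge - gs)
    }
  }
  if (length(out) == 0L) {
    return(data.table(gene_id = character(), tstart = integer(),
                      tend = integer(), chrom = character(), rstart = integer(),
                      rend = integer(), strand = character()))
  }
  res <- rbindlist(out)
  setorder(res, gene_id, tstart)
  res
}

#' Derive ground-truth TSVs from planted SVs
#'
#' Walks each gene's transcript and finds pairs of nucleotides that are
#' adjacent in the transcript but whose images in the rearranged genome are
#' not reference-adjacent (different chromosome, opposite strands, or
#' reversed order): exactly the junctions observable as discordant RNA-seq
#' alignments. A breakpoint falling inside an exon yields the two
#' consecutive exonic bases; a breakpoint in an intron yields the flanking
#' exon endpoints. Junctions whose images read forward on one chromosome
#' (intron-like skips, as left by deletions, novel insertions, and tandem
#' duplications) are concordant and produce no record. Coordinates are in
#' the rearranged (alignment reference) genome.
#'
#' @param planted a [plant_svs()] result.
#' @return call table in [call_tsvs()] format (support is \code{NA}).
#' @export
true_tsvs <- function(planted) {
  tm <- transcript_maps(planted)
  calls <- list()
  for (g in unique(tm$gene_id)) {
    b <- tm[gene_id == g]
    setorder(b, tstart)
    if (nrow(b) < 2L) next
    for (k in seq_len(nrow(b) - 1L)) {
      b1 <- b[k]; b2 <- b[k + 1L]
      if (b2$tstart != b1$tend) next # deleted bases between: no mapped junction
      r1 <- if (b1$strand == "+") b1$rend - 1L else b1$rstart
      r2 <- if (b2$strand == "+") b2$rstart else b2$rend - 1L
      splice_like <- b1$chrom == b2$chrom && b1$strand == b2$strand &&
        (if (b1$strand == "+") r2 > r1 else r2 < r1)
      if (splice_like) next
      calls[[length(calls) + 1L]] <- data.table(
        chrom1 = b1$chrom,
        pos1 = if (b1$strand == "+") r1 + 1L else r1,
        side1 = if (b1$strand == "+") "tail" else "head",
        chrom2 = b2$chrom,
        pos2 = if (b2$strand == "+") r2 else r2 + 1L,
        side2 = if (b2$strand == "+") "head" else "tail",
        support = NA_integer_, component_id = NA_integer_
      )
    }
  }
  if (length(calls) == 0L) {
    return(data.table(chrom1 = character(), pos1 = integer(), side1 = character(),
                      chrom2 = character(), pos2 = integer(), side2 = character(),
                      support = integer(), component_id = integer()))
  }
  out <- canonical_calls(rbindlist(calls))
  out <- unique(out, by = c("chrom1", "pos1", "side1", "chrom2", "pos2", "side2"))
  setorder(out, chrom1, pos1, chrom2, pos2)
  out[]
}

#' Emit paired-end alignments of transcriptome reads to the rearranged genome
#'
#' Fragments are sampled uniformly from the spliced transcripts of the
#' original genome; each read end's alignment to the rearranged genome is
#' computed exactly through the SV coordinate maps, splitting parts at exon
#' junctions and SV junctions. Parts shorter than \code{min_part} (an
#' aligner's minimum anchor) are dropped, as are pairs with an unmappable
#' end. Optional uniform random noise pairs exercise the graph filters.
#'
#' @param planted a [plant_svs()] result.
#' @param read_len read length (bp), 51-100 typical. Default 76.
#' @param frag_len fragment length (bp). Default 300.
#' @param coverage mean transcriptome coverage. Default 30.
#' @param noise_rate noise pairs per real pair. Default 0.
#' @param min_part minimum aligned part length (bp). Default 12.
#' @param seed optional RNG seed.
#' @return a [pair_alignments()] object with rearranged-genome chromosome
#'   lengths attached.
#' @export
emit_alignments <- function(planted, read_len = 76, frag_len = 300,
                            coverage = 30, noise_rate = 0, min_part = 12,
                            seed = NULL) {
  stopifnot(read_len < frag_len, coverage > 0)
  with_seed(seed, {
    tm <- transcript_maps(planted)
    tm[, tend1 := tend - 1L] # closed interval bound for overlap joins
    all_parts <- list()
    pid0 <- 0L
    for (g in unique(tm$gene_id)) {
      b <- tm[gene_id == g]
      tlen <- {
        ex <- planted$genome$exons[planted$genome$exons$gene_id == g, ]
        sum(ex$end - ex$start)
      }
      if (tlen < frag_len) next
      n_frag <- max(0L, as.integer(round(coverage * tlen / (2 * read_len))))
      if (n_frag == 0L) next
      a <- sample.int(tlen - frag_len + 1L, n_frag, replace = TRUE) - 1L
      mates <- data.table(
        fid = rep(seq_len(n_frag), 2L),
        mate = rep(c(1L, 2L), each = n_frag),
        ts = c(a, a + frag_len - read_len),
        te = c(a + read_len, a + frag_len),
        a = rep(a, 2L)
      )
      mates[, te1 := te - 1L]
      setkey(b, tstart, tend1)
      ov <- data.table::foverlaps(mates, b, by.x = c("ts", "te1"),
                                  by.y = c("tstart", "tend1"), nomatch = NULL)
      if (nrow(ov) == 0L) next
      ov[, `:=`(t0 = pmax(ts, tstart), t1 = pmin(te, tend))]
      ov <- ov[t1 - t0 >= min_part]
      if (nrow(ov) == 0L) next
      ov[, `:=`(
        pstart = as.integer(ifelse(strand == "+", rstart + (t0 - tstart),
                                   rstart + (tend - t1))),
        pend = as.integer(ifelse(strand == "+", rstart + (t1 - tstart),
                                 rstart + (tend - t0))),
        orient = ifelse(mate == 1L, strand, flip_orient(strand)),
        qoff = as.integer(ifelse(mate == 1L, t0 - a, (a + frag_len) - t1))
      )]
      # keep only fragments with both ends mapped
      good <- ov[, list(nm = length(unique(mate))), by = fid][nm == 2L, fid]
      ov <- ov[fid %in% good]
      if (nrow(ov) == 0L) next
      parts <- ov[, list(
        pair_id = pid0 + fid,
        read_name = sprintf("%s_frag%06d", g, fid),
        mate, chrom, start = pstart, end = pend, orient, qoff
      )]
      pid0 <- pid0 + n_frag
      all_parts[[length(all_parts) + 1L]] <- parts
    }
    parts <- if (length(all_parts)) rbindlist(all_parts) else empty_parts()
    # renumber pair ids densely
    if (nrow(parts)) {
      parts[, pair_id := as.integer(factor(pair_id, levels = unique(pair_id)))]
    }
    n_real <- if (nrow(parts)) max(parts$pair_id) else 0L
    n_noise <- as.integer(round(noise_rate * n_real))
    if (n_noise > 0L) {
      cls <- planted$chrom_lengths
      mk <- function(mate, i) {
        cn <- sample(names(cls), n_noise, replace = TRUE)
        st <- vapply(cn, function(x) sample.int(cls[[x]] - read_len, 1L),
                     integer(1))
        data.table(pair_id = n_real + seq_len(n_noise),
                   read_name = sprintf("noise%06d", seq_len(n_noise)),
                   mate = mate, chrom = cn, start = st,
                   end = st + as.integer(read_len),
                   orient = sample(c("+", "-"), n_noise, replace = TRUE),
                   qoff = 0L)
      }
      parts <- rbindlist(list(parts, mk(1L), mk(2L)))
    }
    pair_alignments(parts, chrom_lengths = planted$chrom_lengths)
  })
}

#' Simulate a complete rearranged-genome RNA-seq dataset
#'
#' Convenience wrapper chaining [make_genome()], [plant_svs()],
#' [true_tsvs()], and [emit_alignments()] with one master seed. The
#' rearranged genome plays the role of the alignment reference and reads
#' come from the original genome's transcripts, so planted SVs appear as
#' discordant alignments.
#'
#' @param seed master RNG seed.
#' @param counts SV counts per type (see [plant_svs()]).
#' @param coverage,read_len,frag_len,noise_rate see [emit_alignments()].
#' @param ... further arguments to [make_genome()].
#' @return list with \code{genome}, \code{planted}, \code{truth},
#'   \code{alignments}.
#' @export
simulate_dataset <- function(seed = NULL,
                             counts = c(deletion = 1, insertion = 1,
                                        duplication = 1, inversion = 2,
                                        translocation = 1),
                             coverage = 30, read_len = 76, frag_len = 300,
                             noise_rate = 0, ...) {
  with_seed(seed, {
    genome <- make_genome(...)
    planted <- plant_svs(genome, counts = counts)
    truth <- true_tsvs(planted)
    aln <- emit_alignments(planted, read_len = read_len, frag_len = frag_len,
                           coverage = coverage, noise_rate = noise_rate)
    list(genome = genome, planted = planted, truth = truth, alignments = aln)
  })
}
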