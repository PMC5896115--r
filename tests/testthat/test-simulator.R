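test_that("genome generation is deterministic and respects geometry", {
  g1 <- make_genome(seed = 101)
  g2 <- make_genome(seed = 101)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$exons, g2$exons)
  g3 <- make_genome(seed = 102)
  expect_false(identical(g1$seq, g3$seq))

  # no genes: empty annotation
  g0 <- make_genome(n_genes = 0, seed = 101)
  expect_equal(nrow(g0$genes), 0L)

  # exon lengths honor the requested geometry
  geom <- list(n_exons = 3L, exon_len = c(250L, 250L), intron_len = c(500L, 500L))
  g4 <- make_genome(exon_geometry = geom, seed = 103)
  expect_true(all(g4$exons$end - g4$exons$start == 250L))
  expect_equal(sum(g4$exons$end - g4$exons$start), 250L * 3L * nrow(g4$genes))
  # genes are disjoint and separated on each chromosome
  for (cn in unique(g4$genes$chrom)) {
    gg <- g4$genes[g4$genes$chrom == cn, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
})

test_that("an inversion reverse-complements exactly its interval", {
  g <- make_genome(seed = 104)
  p <- plant_svs(g, counts = c(inversion = 1), seed = 105)
  sv <- p$svs
  expect_equal(sv$type, "inversion")
  cn <- sv$chrom1
  s <- sv$start1; e <- sv$end1
  orig <- g$seq[[cn]]
  new <- p$seq[[cn]]
  expect_equal(nchar(new), nchar(orig))
  # outside the interval: unchanged
  expect_equal(substr(new, 1, s), substr(orig, 1, s))
  expect_equal(substr(new, e + 1, nchar(new)), substr(orig, e + 1, nchar(orig)))
  # inside: reverse complement
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(orig, s + 1, e))))
  expect_equal(substr(new, s + 1, e), rc)
})

test_that("deletions shorten and insertions/duplications lengthen the chromosome", {
  g <- make_genome(seed = 106)
  pd <- plant_svs(g, counts = c(deletion = 1), seed = 107, sv_len = 400L)
  cn <- pd$svs$chrom1
  expect_equal(pd$chrom_lengths[[cn]], g$chrom_lengths[[cn]] - 400L)
  pi <- plant_svs(g, counts = c(insertion = 1), seed = 108)
  expect_equal(pi$chrom_lengths[[pi$svs$chrom1]],
               g$chrom_lengths[[pi$svs$chrom1]] + 500L)
  pu <- plant_svs(g, counts = c(duplication = 1), seed = 109, sv_len = 400L)
  expect_equal(pu$chrom_lengths[[pu$svs$chrom1]],
               g$chrom_lengths[[pu$svs$chrom1]] + 400L)
  pt <- plant_svs(g, counts = c(translocation = 1), seed = 110)
  expect_equal(sum(pt$chrom_lengths), sum(g$chrom_lengths))
})

test_that("the coordinate map is a base-faithful bijection on retained bases", {
  g <- make_genome(n_chroms = 2, chrom_len = 20000, n_genes = 4, seed = 111)
  p <- plant_svs(g, counts = c(deletion = 1, inversion = 1, translocation = 1),
                 seed = 112)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  images <- character(0)
  for (cn in names(g$chrom_lengths)) {
    pos <- 0:(g$chrom_lengths[[cn]] - 1L)
    m <- tsvgraph:::map_positions(p, rep(cn, length(pos)), pos)
    mapped <- !is.na(m$dest_pos)
    images <- c(images, paste(m$dest_chrom[mapped], m$dest_pos[mapped]))
    # spot-check base identity of 500 mapped positions
    idx <- which(mapped)[seq(1, sum(mapped), length.out = 500)]
    for (i in idx) {
      orig_base <- substr(g$seq[[cn]], pos[i] + 1, pos[i] + 1)
      new_base <- substr(p$seq[[m$dest_chrom[i]]], m$dest_pos[i] + 1,
                         m$dest_pos[i] + 1)
      want <- if (m$strand[i] == "-") comp[[orig_base]] else orig_base
      expect_equal(new_base, want)
    }
  }
  expect_false(any(duplicated(images))) # injective
})

test_that("ground-truth TSVs arise from inversions and translocations only", {
  sim <- simulate_dataset(seed = 113)
  types <- sim$planted$svs$type
  expect_setequal(unique(types), sv_types <- c("deletion", "insertion",
                                               "duplication", "inversion",
                                               "translocation"))
  # two inversions give four junctions, one translocation gives two
  expect_equal(nrow(sim$truth), 6L)
  # every truth junction is reference-discordant by construction: sides are
  # never a forward tail-head pair on one chromosome
  same_chrom_th <- sim$truth$chrom1 == sim$truth$chrom2 &
    sim$truth$side1 == "tail" & sim$truth$side2 == "head" &
    sim$truth$pos1 < sim$truth$pos2
  expect_false(any(same_chrom_th))

  # intergenic-only SVs contribute nothing
  g <- make_genome(seed = 114)
  p <- plant_svs(g, counts = c(deletion = 1), seed = 115)
  expect_equal(nrow(true_tsvs(p)), 0L)
})

test_that("alignments from an unrearranged genome are all concordant and counted", {
  g <- make_genome(n_chroms = 2, chrom_len = 30000, n_genes = 6, seed = 116)
  p <- plant_svs(g, counts = c(deletion = 0), seed = 117)
  aln <- emit_alignments(p, coverage = 10, seed = 118)
  expect_true(all(aln$pairs$concordant))
  # expected pair count: coverage x transcriptome length / (2 read length)
  tlen <- sum(g$exons$end - g$exons$start)
  expect_equal(nrow(aln$pairs),
               sum(vapply(split(g$exons, g$exons$gene_id), function(e) {
                 round(10 * sum(e$end - e$start) / (2 * 76))
               }, numeric(1))))
  expect_lt(abs(nrow(aln$pairs) - 10 * tlen / (2 * 76)),
            3 * sqrt(10 * tlen / (2 * 76)))
})

test_that("fragments straddling an SV junction classify discordant", {
  sim <- small_sim(seed = 119)
  aln <- sim$alignments
  expect_gt(sum(!aln$pairs$concordant), 0L)
  # discordant parts abut the truth junction coordinates
  disc <- aln$parts[aln$parts$pair_id %in%
                      aln$pairs$pair_id[!aln$pairs$concordant], ]
  near_truth <- function(chrom, pos) {
    any(disc$chrom == chrom & abs(disc$end - pos) <= 1) ||
      any(disc$chrom == chrom & abs(disc$start - pos) <= 1)
  }
  for (k in seq_len(nrow(sim$truth))) {
    expect_true(near_truth(sim$truth$chrom1[k], sim$truth$pos1[k]))
    expect_true(near_truth(sim$truth$chrom2[k], sim$truth$pos2[k]))
  }
})

test_that("emitted alignments are deterministic under a fixed seed", {
  a1 <- simulate_dataset(seed = 120)
  a2 <- simulate_dataset(seed = 120)
  expect_identical(a1$alignments$parts, a2$alignments$parts)
  expect_identical(a1$truth, a2$truth)
})

test_that("noise pairs are generated at the requested rate", {
  g <- make_genome(n_chroms = 2, chrom_len = 30000, n_genes = 6, seed = 121)
  p <- plant_svs(g, counts = c(inversion = 1), seed = 122)
  aln <- emit_alignments(p, coverage = 10, noise_rate = 0.1, seed = 123)
  n_noise <- sum(grepl("^noise", aln$pairs$read_name))
  expect_equal(n_noise, round(0.1 * (nrow(aln$pairs) - n_noise)))
})

test_that("longer reads never hurt recovery of planted junctions", {
  prec_sens <- function(read_len) {
    sim <- simulate_dataset(seed = 124, read_len = read_len)
    res <- detect_tsvs(sim$alignments, theta = 3)
    match_tsvs(res$calls, sim$truth)$sensitivity
  }
  expect_gte(prec_sens(100), prec_sens(51))
})

test_that("FASTA and GTF exports are well-formed", {
  g <- make_genome(n_chroms = 2, chrom_len = 20000, n_genes = 4, seed = 125)
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), 2L)
  expect_equal(unname(Biostrings::width(seqs)), unname(g$chrom_lengths))

  gtf <- tempfile(fileext = ".gtf")
  write_annotation_gtf(g, gtf)
  lines <- readLines(gtf)
  expect_equal(sum(grepl("\tgene\t", lines)), nrow(g$genes))
  expect_equal(sum(grepl("\texon\t", lines)), nrow(g$exons))
})
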