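test_that("split-alignment concordance follows the chromosome/orientation/order rules", {
  # unsplit end is always concordant
  expect_true(split_concordant(one_part("chr1", 100, 150, "+")))
  # forward spliced end with increasing starts
  expect_true(split_concordant(rbind(
    one_part("chr1", 100, 150, "+", qoff = 0),
    one_part("chr1", 5000, 5050, "+", qoff = 50)
  )))
  # chromosome jump breaks concordance
  expect_false(split_concordant(rbind(
    one_part("chr1", 100, 150, "+", qoff = 0),
    one_part("chr2", 100, 150, "+", qoff = 50)
  )))
  # reverse-strand end: starts must decrease in read order
  expect_true(split_concordant(rbind(
    one_part("chr1", 5000, 5050, "-", qoff = 0),
    one_part("chr1", 100, 150, "-", qoff = 50)
  )))
  expect_false(split_concordant(rbind(
    one_part("chr1", 100, 150, "-", qoff = 0),
    one_part("chr1", 5000, 5050, "-", qoff = 50)
  )))
  # mixed orientations within one end are discordant
  expect_false(split_concordant(rbind(
    one_part("chr1", 100, 150, "+", qoff = 0),
    one_part("chr1", 5000, 5050, "-", qoff = 50)
  )))
})

test_that("pair-level concordance requires opposite strands in forward-reverse order", {
  expect_true(pair_concordant(one_part("chr1", 100, 150, "+"),
                              one_part("chr1", 400, 450, "-", mate = 2)))
  # both ends forward
  expect_false(pair_concordant(one_part("chr1", 100, 150, "+"),
                               one_part("chr1", 400, 450, "+", mate = 2)))
  # forward end starts after the reverse end
  expect_false(pair_concordant(one_part("chr1", 400, 450, "+"),
                               one_part("chr1", 100, 150, "-", mate = 2)))
  # fully overlapping short fragment is allowed
  expect_true(pair_concordant(one_part("chr1", 100, 150, "+"),
                              one_part("chr1", 100, 150, "-", mate = 2)))
  # different chromosomes
  expect_false(pair_concordant(one_part("chr1", 100, 150, "+"),
                               one_part("chr2", 400, 450, "-", mate = 2)))
})

test_that("strand symmetry: reversing part order and flipping orientations preserves end concordance", {
  set.seed(11)
  for (k in 1:50) {
    np <- sample(1:4, 1)
    starts <- sample.int(100000, np)
    end <- one_part("chr1", starts[1], starts[1] + 50,
                    sample(c("+", "-"), 1), qoff = 0)
    if (np > 1) {
      for (j in 2:np) {
        end <- rbind(end, one_part("chr1", starts[j], starts[j] + 50,
                                   end$orient[1], qoff = (j - 1) * 50))
      }
    }
    flipped <- end
    flipped$orient <- ifelse(end$orient == "+", "-", "+")
    flipped$qoff <- max(end$qoff) - end$qoff
    expect_identical(split_concordant(end), split_concordant(flipped))
  }
})

test_that("pair concordance is symmetric in the two ends", {
  set.seed(12)
  segs <- make_segments_2chrom()
  for (k in 1:50) {
    p <- random_single_part_pair(segs)
    expect_identical(pair_concordant(p$first, p$second),
                     pair_concordant(p$second, p$first))
  }
})

test_that("vectorized pair classification agrees with the scalar predicates", {
  set.seed(13)
  segs <- make_segments_2chrom()
  parts <- list()
  expected <- logical(0)
  for (k in 1:80) {
    p <- random_single_part_pair(segs)
    p$first$pair_id <- k; p$second$pair_id <- k
    parts[[k]] <- rbind(p$first, p$second)
    expected[k] <- pair_concordant(p$first, p$second)
  }
  cls <- classify_pairs(data.table::rbindlist(parts))
  expect_identical(cls$concordant, expected)
})

test_that("SAM round trip preserves parts and pair classification", {
  sim <- small_sim(seed = 301)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$alignments, sam, read_len = 76)
  back <- read_alignment_groups(sam)
  expect_equal(nrow(back$pairs), nrow(sim$alignments$pairs))
  expect_equal(sum(back$pairs$concordant), sum(sim$alignments$pairs$concordant))
  # compare the multiset of aligned parts (pair ids are renumbered on read)
  key <- function(p) sort(paste(p$read_name, p$mate, p$chrom, p$start, p$end,
                                p$orient, p$qoff))
  expect_identical(key(back$parts), key(sim$alignments$parts))
  # header lengths survive
  expect_identical(attr(back, "chrom_lengths"),
                   attr(sim$alignments, "chrom_lengths"))
})

test_that("reader drops pairs with an unmapped end and unpaired records", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    # complete pair
    "p1\t99\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
    "p1\t147\tchr1\t401\t60\t50M\t*\t0\t0\t*\t*",
    # mate 2 unmapped: only one mapped end
    "p2\t73\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
    # split end: primary plus supplementary
    "p3\t99\tchr1\t101\t60\t25M25S\t*\t0\t0\t*\t*",
    "p3\t2147\tchr1\t2001\t60\t25S25M\t*\t0\t0\t*\t*",
    "p3\t147\tchr1\t2401\t60\t50M\t*\t0\t0\t*\t*"
  ), sam)
  aln <- read_alignment_groups(sam)
  expect_setequal(unique(aln$parts$read_name), c("p1", "p3"))
  p3_first <- aln$parts[aln$parts$read_name == "p3" & aln$parts$mate == 1L, ]
  expect_equal(nrow(p3_first), 2L)
  expect_equal(p3_first$qoff, c(0L, 25L))
  expect_equal(p3_first$start, c(100L, 2000L))
})

test_that("spliced N records are split into parts with correct query offsets", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@SQ\tSN:chr1\tLN:10000",
    "s1\t99\tchr1\t101\t60\t30M500N46M\t*\t0\t0\t*\t*",
    "s1\t147\tchr1\t1901\t60\t76M\t*\t0\t0\t*\t*",
    # reverse-strand spliced record: leading clip is at the read's 3' end
    "s2\t83\tchr1\t101\t60\t10S30M100N36M\t*\t0\t0\t*\t*",
    "s2\t163\tchr1\t51\t60\t76M\t*\t0\t0\t*\t*"
  ), sam)
  aln <- read_alignment_groups(sam)
  s1 <- aln$parts[aln$parts$read_name == "s1" & aln$parts$mate == 1L, ]
  expect_equal(s1$start, c(100L, 630L))
  expect_equal(s1$end, c(130L, 676L))
  expect_equal(s1$qoff, c(0L, 30L))
  s2 <- aln$parts[aln$parts$read_name == "s2" & aln$parts$mate == 1L, ]
  # strand-adjusted offsets: genome-later part comes first in the read
  expect_equal(s2$qoff[order(s2$start)], c(36L, 0L))
})
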