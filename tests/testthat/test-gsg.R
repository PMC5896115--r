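segs2 <- make_segments(2L) # u = 1, v = 2

test_that("edge construction follows the four orientation cases", {
  u_part <- function(orient) one_part("chr1", 100, 175, orient)
  v_part <- function(orient) one_part("chr1", 1400, 1475, orient, mate = 2)
  cases <- list(
    list(o = c("+", "-"), want = c("tail", "head")),
    list(o = c("+", "+"), want = c("tail", "tail")),
    list(o = c("-", "-"), want = c("head", "head")),
    list(o = c("-", "+"), want = c("head", "tail"))
  )
  for (cs in cases) {
    e <- edge_for_connection(u_part(cs$o[1]), v_part(cs$o[2]), segs2)
    expect_equal(e$a_id, 1L)
    expect_equal(e$b_id, 2L)
    expect_equal(c(e$a_side, e$b_side), cs$want)
  }
})

test_that("parts in one segment give no edge", {
  e <- edge_for_connection(one_part("chr1", 100, 175, "+"),
                           one_part("chr1", 400, 475, "-", mate = 2), segs2)
  expect_null(e)
})

test_that("a pair yields one connection per split plus the mate connection", {
  segs3 <- make_segments(3L)
  # unsplit concordant pair spanning segments 1 and 2
  cons <- edges_from_pair(one_part("chr1", 800, 875, "+"),
                          one_part("chr1", 1100, 1175, "-", mate = 2), segs3)
  expect_length(cons, 1L)
  expect_equal(c(cons[[1]]$a_side, cons[[1]]$b_side), c("tail", "head"))

  # mate 1 split across segments 1 and 3, mate 2 in segment 2 (reverse)
  first <- rbind(one_part("chr1", 100, 140, "+", qoff = 0),
                 one_part("chr1", 2100, 2135, "+", qoff = 40))
  second <- one_part("chr1", 1500, 1575, "-", mate = 2)
  cons2 <- edges_from_pair(first, second, segs3)
  expect_length(cons2, 2L)
  ids <- lapply(cons2, function(x) c(x$a_id, x$b_id))
  expect_true(any(vapply(ids, function(v) setequal(v, c(1L, 3L)), logical(1))))
  expect_true(any(vapply(ids, function(v) setequal(v, c(2L, 3L)), logical(1))))

  # pair entirely inside one segment
  expect_length(edges_from_pair(one_part("chr1", 100, 175, "+"),
                                one_part("chr1", 400, 475, "-", mate = 2),
                                make_segments(1L, w = 1000L)), 0L)
})

test_that("edge compatibility implements the orientation-function condition", {
  ref <- reference_arrangement(1:2)
  expect_true(compatible(1L, "tail", 2L, "head", ref))
  expect_false(compatible(1L, "tail", 2L, "tail", ref))
  # flipping v's orientation makes the tail-tail edge compatible
  inv_v <- arrangement(1:2, rank = 1:2, forward = c(TRUE, FALSE))
  expect_true(compatible(1L, "tail", 2L, "tail", inv_v))
  # head-tail edge with v placed before u, both forward
  v_first <- arrangement(1:2, rank = c(2L, 1L), forward = c(TRUE, TRUE))
  expect_true(compatible(1L, "head", 2L, "tail", v_first))
  expect_error(compatible(1L, "tail", 9L, "head", ref), "absent")
})

test_that("alignment concordance and reference edge concordance are equivalent", {
  set.seed(21)
  segs <- make_segments_2chrom()
  for (k in 1:200) {
    p <- random_single_part_pair(segs)
    e <- edge_for_connection(p$first, p$second, segs)
    expect_identical(
      pair_concordant(p$first, p$second),
      edge_reference_concordant(e$a_id, e$a_side, e$b_id, e$b_side, segs),
      info = sprintf("case %d", k)
    )
  }
})

test_that("graph aggregation counts support and applies alpha to discordant edges", {
  # 5 identical discordant pairs (both ends forward), alpha = 2
  parts <- data.table::rbindlist(lapply(1:5, function(i) {
    rbind(one_part("chr1", 100, 175, "+", pair_id = i),
          one_part("chr1", 1400, 1475, "+", mate = 2, pair_id = i))
  }))
  g <- build_graph(parts, segs2, alpha = 2)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$raw_count, 5L)
  expect_false(g$edges$concordant)
  expect_equal(g$edges$weight, 10)

  # 7 concordant pairs over adjacent segments keep weight = count
  parts2 <- data.table::rbindlist(lapply(1:7, function(i) {
    rbind(one_part("chr1", 800, 875, "+", pair_id = i),
          one_part("chr1", 1100, 1175, "-", mate = 2, pair_id = i))
  }))
  g2 <- build_graph(parts2, segs2, alpha = 2)
  expect_equal(g2$edges$weight, 7)
  expect_true(g2$edges$concordant)

  # pairs within one segment produce no edges
  g3 <- build_graph(one_part("chr1", 100, 175, "+"),
                    make_segments(1L), alpha = 1)
  expect_equal(nrow(g3$edges), 0L)

  # aggregation conservation: raw counts sum to the connection count
  sim <- small_sim(seed = 402)
  res <- detect_tsvs(sim$alignments, theta = 1)
  g4 <- build_graph(sim$alignments, res$segments)
  expect_equal(sum(g4$edges$raw_count), nrow(g4$connections))
})

test_that("theta removes low-support edges strictly below threshold", {
  parts <- data.table::rbindlist(c(
    lapply(1:2, function(i) rbind(
      one_part("chr1", 100, 175, "+", pair_id = i),
      one_part("chr1", 1400, 1475, "+", mate = 2, pair_id = i))),
    lapply(3:5, function(i) rbind(
      one_part("chr1", 300, 375, "-", pair_id = i),
      one_part("chr1", 1600, 1675, "-", mate = 2, pair_id = i)))
  ))
  g <- build_graph(parts, segs2)
  gf <- filter_graph(g, theta = 3, gamma = 5)
  expect_equal(nrow(gf$edges), 1L) # count-2 edge removed, count-3 kept
  expect_equal(gf$edges$raw_count, 3L)
})

test_that("gamma drops discordant edges of promiscuous segments", {
  segs4 <- make_segments(4L)
  # segment 1 discordantly connected to 2, 3, 4
  parts <- data.table::rbindlist(lapply(1:3, function(i) {
    rbind(one_part("chr1", 100, 175, "+", pair_id = i),
          one_part("chr1", i * 1000 + 400, i * 1000 + 475, "+",
                   mate = 2, pair_id = i))
  }))
  g <- build_graph(parts, segs4)
  expect_equal(nrow(g$edges), 3L)
  gf <- filter_graph(g, theta = 1, gamma = 2)
  expect_equal(nrow(gf$edges), 0L)
  # with a permissive gamma nothing changes and filtering is idempotent
  gk <- filter_graph(g, theta = 1, gamma = 5)
  expect_equal(gk$edges, g$edges)
  expect_equal(filter_graph(gk, theta = 1, gamma = 5)$edges, gk$edges)
})

test_that("interleaving discordant edges between two exon runs are removed", {
  # two backbone runs (1,2,3) and (5,6,7) on one chromosome, plus a ladder of
  # discordant edges attaching at two interior points on both sides
  segs8 <- make_segments(8L)
  mk_pair <- function(i, s1, s2) {
    rbind(one_part("chr1", s1, s1 + 75, "+", pair_id = i),
          one_part("chr1", s2, s2 + 75, "+", mate = 2, pair_id = i))
  }
  conc_pair <- function(i, s1, s2) {
    rbind(one_part("chr1", s1, s1 + 75, "+", pair_id = i),
          one_part("chr1", s2, s2 + 75, "-", mate = 2, pair_id = i))
  }
  parts <- data.table::rbindlist(list(
    conc_pair(1, 900, 1100), conc_pair(2, 1900, 2100),   # run 1-2-3
    conc_pair(3, 4900, 5100), conc_pair(4, 5900, 6100),  # run 5-6-7
    mk_pair(5, 500, 4500), mk_pair(6, 1500, 5500)        # interleaving ladder
  ))
  g <- build_graph(parts, segs8)
  gf <- filter_graph(g, theta = 1, gamma = 5)
  expect_equal(sum(!gf$edges$concordant), 0L)
  expect_equal(sum(gf$edges$concordant), 4L)

  # a single-junction connection between two runs survives
  parts2 <- data.table::rbindlist(list(
    conc_pair(1, 900, 1100), conc_pair(2, 1900, 2100),
    conc_pair(3, 4900, 5100), conc_pair(4, 5900, 6100),
    mk_pair(5, 1500, 5500)
  ))
  g2 <- filter_graph(build_graph(parts2, segs8), theta = 1, gamma = 5)
  expect_equal(sum(!g2$edges$concordant), 1L)
})

test_that("filtering is monotone on simulated graphs", {
  sim <- small_sim(seed = 403)
  res <- detect_tsvs(sim$alignments, theta = 1)
  g <- build_graph(sim$alignments, res$segments)
  key <- function(e) paste(e$a_id, e$a_side, e$b_id, e$b_side)
  gf <- filter_graph(g, theta = 4, gamma = 3)
  expect_true(all(key(gf$edges) %in% key(g$edges)))
})

test_that("reversal symmetry: compatibility is invariant under reverse-complement", {
  set.seed(22)
  for (k in 1:30) {
    gc <- random_component()
    n <- nrow(gc$segments)
    arr <- arrangement(gc$segments$id, sample.int(n),
                       sample(c(TRUE, FALSE), n, replace = TRUE))
    rev_arr <- reverse_arrangement(arr)
    expect_identical(
      compatible(gc$edges$a_id, gc$edges$a_side, gc$edges$b_id,
                 gc$edges$b_side, arr),
      compatible(gc$edges$a_id, gc$edges$a_side, gc$edges$b_id,
                 gc$edges$b_side, rev_arr)
    )
  }
})

test_that("graph TSV serialization round-trips edge fields", {
  sim <- small_sim(seed = 404)
  res <- detect_tsvs(sim$alignments, theta = 3)
  f <- tempfile(fileext = ".tsv")
  write_graph_tsv(res$graph, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(res$graph$edges))
  expect_equal(sum(back$raw_count), sum(res$graph$edges$raw_count))
})
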