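# fixtures are built in code; nothing is read from disk

# a simple tiling: n segments of width `w` on one chromosome
make_segments <- function(n, w = 1000L, chrom = "chr1") {
  data.table::data.table(
    id = seq_len(n), chrom = chrom,
    start = (seq_len(n) - 1L) * w, end = seq_len(n) * w
  )
}

# two-chromosome tiling used for cross-chromosome cases
make_segments_2chrom <- function(n_per = 3L, w = 1000L) {
  s1 <- make_segments(n_per, w, "chr1")
  s2 <- make_segments(n_per, w, "chr2")
  s2$id <- s2$id + n_per
  rbind(s1, s2)
}

one_part <- function(chrom, start, end, orient, qoff = 0L, mate = 1L,
                     pair_id = 1L) {
  data.table::data.table(pair_id = pair_id, read_name = paste0("r", pair_id),
                         mate = mate, chrom = chrom, start = as.integer(start),
                         end = as.integer(end), orient = orient,
                         qoff = as.integer(qoff))
}

# random single-part read pair over a fixed two-chromosome tiling;
# ends are placed in distinct segments so exactly one mate connection arises
random_single_part_pair <- function(segments, read_len = 75L) {
  repeat {
    i <- sample.int(nrow(segments), 2L)
    if (i[1L] != i[2L]) break
  }
  mk <- function(seg, mate) {
    s <- segments$start[seg] + sample.int(segments$end[seg] -
                                            segments$start[seg] - read_len, 1L)
    one_part(segments$chrom[seg], s, s + read_len,
             sample(c("+", "-"), 1L), mate = mate)
  }
  first <- mk(i[1L], 1L)
  second <- mk(i[2L], 2L)
  second$pair_id <- first$pair_id
  list(first = first, second = second)
}

# random small component for solver-oracle comparisons: n segments,
# deduplicated random edges with mixed endpoint sides and integer weights
random_component <- function(n_max = 6L, e_max = 10L, w_max = 10L) {
  n <- sample(2:n_max, 1L)
  segments <- make_segments(n)
  m <- sample.int(e_max, 1L)
  e <- data.table::data.table(
    a_id = sample.int(n, m, replace = TRUE),
    a_side = sample(c("head", "tail"), m, replace = TRUE),
    b_id = sample.int(n, m, replace = TRUE),
    b_side = sample(c("head", "tail"), m, replace = TRUE)
  )
  e <- e[e$a_id != e$b_id]
  swap <- e$a_id > e$b_id
  tmp_id <- e$a_id[swap]; tmp_side <- e$a_side[swap]
  e$a_id[swap] <- e$b_id[swap]; e$a_side[swap] <- e$b_side[swap]
  e$b_id[swap] <- tmp_id; e$b_side[swap] <- tmp_side
  e <- unique(e)
  if (nrow(e) == 0L) return(random_component(n_max, e_max, w_max))
  e$raw_count <- sample.int(w_max, nrow(e), replace = TRUE)
  e$concordant <- edge_reference_concordant(e$a_id, e$a_side, e$b_id, e$b_side,
                                            segments)
  e$weight <- as.numeric(e$raw_count)
  list(segments = segments, edges = e,
       connections = data.table::data.table(
         pair_id = integer(), a_id = integer(), a_side = character(),
         b_id = integer(), b_side = character(), a_coord = integer(),
         b_coord = integer()),
       alpha = 1)
}

# evaluate an arrangement's total satisfied weight directly from compatible()
satisfied_weight <- function(gc, arr) {
  if (nrow(gc$edges) == 0L) return(0)
  sat <- compatible(gc$edges$a_id, gc$edges$a_side,
                    gc$edges$b_id, gc$edges$b_side, arr)
  sum(gc$edges$weight[sat])
}

# tiny two-gene dataset for fast end-to-end checks
small_sim <- function(seed, counts = c(inversion = 1), n_genes = 6) {
  simulate_dataset(seed = seed, counts = counts, n_chroms = 2,
                   chrom_len = 30000, n_genes = n_genes)
}
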