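#' Connected components of a segment graph
#'
#' Segments are partitioned by edge connectivity; each component keeps every
#' edge among its segments. Segments without edges become singleton
#' components. The optimal rearrangement of one component is independent of
#' all others, so each can be solved separately.
#'
#' @param g a [build_graph()] (optionally [filter_graph()]ed) result.
#' @return list of \code{segment_graph} objects, ordered by smallest segment
#'   id; each carries its \code{component_id}.
#' @export
components <- function(g) {
  seg <- g$segments
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$edges$a_id),
                   to = as.character(g$edges$b_id)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seg$id))
  )
  memb <- igraph::components(ig)$membership
  memb <- memb[as.character(seg$id)]
  split_ids <- split(seg$id, memb)
  split_ids <- split_ids[order(vapply(split_ids, min, numeric(1)))]
  out <- lapply(seq_along(split_ids), function(k) {
    ids <- split_ids[[k]]
    e <- g$edges[a_id %in% ids & b_id %in% ids]
    cons <- g$connections[a_id %in% ids & b_id %in% ids]
    structure(list(segments = seg[id %in% ids], edges = e, connections = cons,
                   alpha = g$alpha, component_id = k),
              class = "segment_graph")
  })
  out
}

new_solution <- function(gc, arr, objective, tie_concordant, tie_forward) {
  sat <- if (nrow(gc$edges)) {
    compatible(gc$edges$a_id, gc$edges$a_side, gc$edges$b_id, gc$edges$b_side, arr)
  } else logical(0)
  structure(list(arrangement = arr, objective = objective,
                 satisfied = sat, tie_concordant = tie_concordant,
                 tie_forward = tie_forward,
                 component_id = gc$component_id %||% NA_integer_),
            class = "gsg_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gsg_solution <- function(x, ...) {
  cat(sprintf("<gsg_solution> objective %.6g, %d/%d edges satisfied\n",
              x$objective, sum(x$satisfied), length(x$satisfied)))
  invisible(x)
}

identity_solution <- function(gc) {
  arr <- reference_arrangement(gc$segments$id)
  obj <- if (nrow(gc$edges)) sum(gc$edges$weight[gc$edges$concordant]) else 0
  conc <- if (nrow(gc$edges)) sum(gc$edges$concordant) else 0L
  new_solution(gc, arr, obj, as.integer(conc), length(arr$ids))
}

#' Optimal rearrangement of one connected component
#'
#' Finds a permutation and orientation of the component's segments that
#' maximizes the total weight of compatible edges (exactly). Components
#' whose edges are all reference-concordant are short-circuited to the
#' identity arrangement, which is provably optimal there. Ties are broken
#' lexicographically: first maximize the number of satisfied
#' reference-concordant edges, then minimize the number of inverted
#' segments.
#'
#' Components larger than \code{max_size} segments are not solved: a warning
#' is emitted and the identity arrangement returned (their discordant edges
#' then yield no TSV calls).
#'
#' @param gc one component from [components()].
#' @param max_size largest component solved exactly. Default 14; the solver's
#'   state space grows as \eqn{3^n}.
#' @return object of class \code{gsg_solution} with the \code{arrangement},
#'   the \code{objective} (sum of satisfied edge weights), and per-edge
#'   \code{satisfied} flags.
#' @export
optimize_component <- function(gc, max_size = 14) {
  ids <- sort(gc$segments$id)
  n <- length(ids)
  if (nrow(gc$edges) == 0L || all(gc$edges$concordant)) {
    return(identity_solution(gc))
  }
  if (n > max_size) {
    warning("component with ", n, " segments exceeds max_size = ", max_size,
            "; returning identity arrangement")
    return(identity_solution(gc))
  }
  e <- gc$edges
  res <- .dp_arrange(
    n,
    match(e$a_id, ids) - 1L, match(e$b_id, ids) - 1L,
    e$a_side == "head", e$b_side == "head",
    as.numeric(e$weight), e$concordant
  )
  arr <- arrangement(ids, res$rank, res$forward)
  sol <- new_solution(gc, arr, res$objective, res$tie_concordant, res$tie_forward)
  stopifnot(abs(sum(e$weight[sol$satisfied]) - sol$objective) < 1e-6)
  sol
}

#' Exhaustive oracle for the component rearrangement optimum
#'
#' Enumerates all \eqn{|S|! \cdot 2^{|S|}} arrangements of a component and
#' returns the best under the same lexicographic objective as
#' [optimize_component()]. Intended as an independent verification oracle
#' for small components.
#'
#' @param gc component with at most 8 segments.
#' @return a \code{gsg_solution}.
#' @export
brute_force_optimum <- function(gc) {
  ids <- sort(gc$segments$id)
  n <- length(ids)
  if (n > 8L) stop("brute force limited to components of at most 8 segments")
  e <- gc$edges
  if (nrow(e) == 0L) return(identity_solution(gc))
  ea <- match(e$a_id, ids); eb <- match(e$b_id, ids)
  w <- as.numeric(e$weight); conc <- e$concordant
  m <- nrow(e)

  # all orientation assignments (rows) x f-values per edge endpoint
  Y <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n)))[, seq_len(n), drop = FALSE]
  FA <- matrix(FALSE, nrow(Y), m); FB <- matrix(FALSE, nrow(Y), m)
  for (k in seq_len(m)) {
    FA[, k] <- if (e$a_side[k] == "head") Y[, ea[k]] else !Y[, ea[k]]
    FB[, k] <- if (e$b_side[k] == "head") Y[, eb[k]] else !Y[, eb[k]]
  }
  fwd_cnt <- rowSums(Y)

  best <- list(obj = -Inf, conc = -1L, fwd = -1L, rank = NULL, forward = NULL)
  for (p in all_permutations(n)) {
    rank <- integer(n); rank[p] <- seq_len(n)
    b_before_a <- rank[eb] < rank[ea]
    sat <- sweep(FA, 2L, b_before_a, `==`) & sweep(FB, 2L, !b_before_a, `==`)
    obj <- as.numeric(sat %*% w)
    cc <- as.integer(sat %*% conc)
    better <- obj > best$obj |
      (obj == best$obj & (cc > best$conc | (cc == best$conc & fwd_cnt > best$fwd)))
    if (any(better)) {
      i <- which(better)[
        order(-obj[better], -cc[better], -fwd_cnt[better])][1L]
      best <- list(obj = obj[i], conc = cc[i], fwd = fwd_cnt[i],
                   rank = rank, forward = Y[i, ])
    }
  }
  arr <- arrangement(ids, best$rank, best$forward)
  new_solution(gc, arr, best$obj, best$conc, as.integer(best$fwd))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Solve every component of a segment graph
#'
#' @param g filtered segment graph.
#' @param max_size passed to [optimize_component()].
#' @return list of \code{gsg_solution}, one per component (in
#'   [components()] order).
#' @export
solve_graph <- function(g, max_size = 14) {
  lapply(components(g), optimize_component, max_size = max_size)
}
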