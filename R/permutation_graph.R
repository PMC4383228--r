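# The permutation graph G_pi: vertices are the elements of pi, edges are the
# inversion pairs. Its connected components occupy consecutive position
# intervals whose absolute values are exactly that integer interval (minimal
# complete substrings), so a single left-to-right scan decomposes the graph.
# A component is odd when it contains an odd number of negative elements;
# the count of odd components is the 1-reversal cleanup cost of sorting by
# super short operations.

#' Component decomposition of the permutation graph
#'
#' Scans positions left to right, closing a component whenever the positions
#' seen so far form a minimal complete substring (the running maximum of the
#' absolute values equals the current position). The result equals the
#' connected components of the graph whose edges are the inversion pairs.
#'
#' @param p A signed permutation.
#' @return A data.frame of class `component_decomposition` with one row per
#'   component, columns `start`, `end` (position interval), `vertices`,
#'   `negatives` (count of negative elements) and `odd` (logical parity).
#'   Intervals are consecutive and partition `1..n`.
#' @examples
#' graph_components(parse_permutation("+2 -1 -3"))
#' @export
graph_components <- function(p) {
  x <- as_perm_vec(p)
  n <- length(x)
  a <- abs(x)
  start <- integer(0); end <- integer(0)
  s <- 1L
  running_max <- 0L
  for (t in seq_len(n)) {
    if (a[t] > running_max) running_max <- a[t]
    if (running_max == t) {       # minimal complete substring closes here
      start <- c(start, s)
      end <- c(end, t)
      s <- t + 1L
      running_max <- t
    }
  }
  negatives <- mapply(function(s, e) sum(x[s:e] < 0L), start, end)
  out <- data.frame(start = start, end = end,
                    vertices = end - start + 1L,
                    negatives = as.integer(negatives),
                    odd = as.integer(negatives) %% 2L == 1L)
  class(out) <- c("component_decomposition", "data.frame")
  out
}

#' Odd component counts
#'
#' @param p A signed permutation.
#' @return List with `c_odd` (number of components containing an odd number
#'   of negative elements), and `c1_odd`, `c2_odd` (odd components with
#'   exactly 1 and exactly 2 vertices), which drive the short-operation
#'   upper bound.
#' @examples
#' odd_components(signed_perm(c(-1, -2, 3)))  # c_odd 2, both singletons
#' @export
odd_components <- function(p) {
  comps <- graph_components(p)
  list(c_odd = sum(comps$odd),
       c1_odd = sum(comps$odd & comps$vertices == 1L),
       c2_odd = sum(comps$odd & comps$vertices == 2L))
}

# Positions of the component containing position i, as interval c(start, end).
component_interval_at <- function(comps, i) {
  row <- which(comps$start <= i & comps$end >= i)
  c(comps$start[row], comps$end[row])
}

#' Cut-edge analysis of an adjacent edge
#'
#' Examines the potential edge `e = (pi_i, pi_(i+1))`: it exists when the
#' adjacent pair is an inversion. When it exists, reports whether deleting it
#' disconnects its component (a cut edge), and if so the vertex counts and
#' parities of the two resulting sides. This is the case analysis the
#' super-short and short operation sorters use to decide between an adjacent
#' swap (transposition, signs kept) and a 2-reversal (signs flipped).
#'
#' @param p A signed permutation.
#' @param i Position with `1 <= i < n`.
#' @return List with `exists_edge`; when the edge exists, `is_cut`; when it
#'   is a cut edge, `side_a` and `side_b`, each a list with `vertex_count`
#'   and `odd` (parity of its negative count). `side_a` contains position
#'   `i`. Sides are `NULL` when the edge is absent or not a cut edge.
#' @export
cut_edge_split <- function(p, i) {
  x <- as_perm_vec(p)
  n <- length(x)
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i >= n) {
    stop("need a position 1 <= i < n", call. = FALSE)
  }
  a <- abs(x)
  if (a[i] <= a[i + 1L]) {
    return(list(exists_edge = FALSE, is_cut = NA, side_a = NULL, side_b = NULL))
  }
  comps <- graph_components(x)
  iv <- component_interval_at(comps, i)
  pos <- iv[1]:iv[2]
  # adjacency among component positions, with edge (i, i+1) removed
  adj <- lapply(pos, function(u) {
    nb <- pos[(pos < u & a[pos] > a[u]) | (pos > u & a[pos] < a[u])]
    nb[!((u == i & nb == i + 1L) | (u == i + 1L & nb == i))]
  })
  names(adj) <- as.character(pos)
  reach <- rep(FALSE, length(pos))
  names(reach) <- as.character(pos)
  queue <- i
  reach[as.character(i)] <- TRUE
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (v in adj[[as.character(u)]]) {
      if (!reach[as.character(v)]) {
        reach[as.character(v)] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  if (reach[as.character(i + 1L)]) {
    return(list(exists_edge = TRUE, is_cut = FALSE, side_a = NULL, side_b = NULL))
  }
  side_a_pos <- pos[reach]
  side_b_pos <- pos[!reach]
  side_info <- function(ps) {
    list(vertex_count = length(ps), odd = sum(x[ps] < 0L) %% 2L == 1L)
  }
  list(exists_edge = TRUE, is_cut = TRUE,
       side_a = side_info(side_a_pos), side_b = side_info(side_b_pos))
}

#' Extract a component as a standalone permutation
#'
#' A component occupying interval `[start, end]` holds exactly the absolute
#' values `start..end`; shifting them down by `start - 1` (keeping signs)
#' yields a signed permutation of size `end - start + 1` whose permutation
#' graph is isomorphic to the component, edges and signs preserved. The
#' short-operation sorter extracts small components this way, sorts them via
#' a precomputed table, and translates the operations back.
#'
#' @param p A signed permutation.
#' @param interval Integer vector `c(start, end)`; must be a component
#'   interval of `graph_components(p)`.
#' @return A `signed_perm` of size `end - start + 1`.
#' @examples
#' extract_component(parse_permutation("+1 -3 -4 -2 +5"), c(2, 4))  # (-2 -3 -1)
#' @export
extract_component <- function(p, interval) {
  x <- as_perm_vec(p)
  interval <- as.integer(interval)
  stopifnot(length(interval) == 2L)
  comps <- graph_components(x)
  if (!any(comps$start == interval[1] & comps$end == interval[2])) {
    stop(sprintf("[%d, %d] is not a component interval",
                 interval[1], interval[2]), call. = FALSE)
  }
  offset <- interval[1] - 1L
  seg <- x[interval[1]:interval[2]]
  structure(ifelse(seg > 0L, seg - offset, seg + offset), class = "signed_perm")
}
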