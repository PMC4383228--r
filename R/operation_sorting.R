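# Sorting by bounded signed operations (reversals and transpositions).
#
# Super short operations (span <= 2): exact distance Inv(pi) + c_odd(pi).
# Removing an adjacent inversion costs one operation either way; the choice
# between the adjacent-swap transposition (signs kept) and the 2-reversal
# (both signs flipped) is made so the number of odd components never grows,
# leaving exactly c_odd(pi) sign flips for the 1-reversal cleanup.
#
# Short operations (span <= 3): exact distance is open. The sorter removes
# inversions while keeping c2_odd + c1_odd from growing, dispatching on the
# size of the component containing the leftmost adjacent inversion; 3- and
# 4-vertex components are handled by replaying BFS-shortest sequences from a
# precomputed table. The count is within a factor 3 of optimal (tight).

#' Exact distance under super short operations
#'
#' Closed form: `Inv(pi) + c_odd(pi)` -- one operation per inversion plus one
#' 1-reversal per component containing an odd number of negative elements.
#'
#' @param p A signed permutation.
#' @return Nonnegative integer distance.
#' @examples
#' ssso_distance(signed_perm(c(-3, -2, -1)))  # 4
#' @export
ssso_distance <- function(p) {
  x <- as_perm_vec(p)
  inv_count(x) + odd_components(x)$c_odd
}

#' Optimal sort by super short operations
#'
#' While inversions remain, acts at the leftmost adjacent inversion `i`: if
#' the edge `(pi_i, pi_(i+1))` is not a cut edge of its component, or the two
#' sides it separates are not both odd, applies the adjacent-swap
#' transposition; if both sides are odd, applies the 2-reversal, which turns
#' both sides even. Then 1-reversals at the remaining negative positions in
#' ascending order. The scenario length always equals [ssso_distance()].
#'
#' @param p A signed permutation.
#' @return A `sorting_scenario` with family `"SSSO"`.
#' @export
ssso_sort <- function(p) {
  start <- as_signed_perm(p)
  x <- as_perm_vec(start)
  ops <- list()
  repeat {
    i <- leftmost_adjacent_inversion(x)
    if (is.null(i)) break
    split <- cut_edge_split(x, i)
    op <- if (isTRUE(split$is_cut) && split$side_a$odd && split$side_b$odd) {
      reversal(i, i + 1L)
    } else {
      transposition(i, i + 1L, i + 2L)
    }
    ops[[length(ops) + 1L]] <- op
    x <- apply_op_vec(x, op)
  }
  for (i in which(x < 0L)) {
    ops[[length(ops) + 1L]] <- reversal(i, i)
    x[i] <- -x[i]
  }
  sorting_scenario(start, ops, "SSSO")
}

# Greedy shortest sorting sequence read off a BFS distance table: at each
# state take the first operation, in canonical order, that steps one unit
# closer to the identity. Deterministic given the canonical order.
greedy_table_sort <- function(x, family) {
  n <- length(x)
  tab <- build_distance_table(n, family)
  maps <- op_maps(n, enumerate_operations(n, family))
  ops_all <- enumerate_operations(n, family)
  ops <- list()
  d <- tab$dist[[perm_key(x)]]
  while (d > 0L) {
    advanced <- FALSE
    for (o in seq_along(maps)) {
      q <- maps[[o]]$sgn * x[maps[[o]]$idx]
      if (tab$dist[[perm_key(q)]] == d - 1L) {
        ops[[length(ops) + 1L]] <- ops_all[[o]]
        x <- q
        d <- d - 1L
        advanced <- TRUE
        break
      }
    }
    stopifnot(advanced)
  }
  ops
}

#' Shortest short-operation sorts for small single-component permutations
#'
#' For every signed permutation of size `m` whose permutation graph is a
#' single component, a shortest sorting sequence under the short-operation
#' family, found by BFS with the canonical operation order as the only
#' tie-break. Every stored sequence has length at most the permutation's
#' inversion count, which is what makes the component-replay step of
#' [sso_sort()] pay for itself. Built lazily once per process and cached.
#'
#' @param m Component size, 3 or 4.
#' @return A named list mapping the permutation key (its space-separated
#'   elements) to a list of `rearr_op`.
#' @export
small_component_table <- function(m) {
  m <- as.integer(m)
  if (!(m %in% c(3L, 4L))) {
    stop("small-component tables exist for m = 3 or 4 only", call. = FALSE)
  }
  key <- sprintf("small_%d", m)
  cached <- .table_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- list()
  for (p in all_signed_permutations(m)) {
    if (nrow(graph_components(p)) == 1L) {
      out[[perm_key(p)]] <- greedy_table_sort(as_perm_vec(p), "SSO")
    }
  }
  .table_cache[[key]] <- out
  out
}

# Shift an operation's positions by a fixed offset.
translate_op <- function(op, offset) {
  if (op$kind == "reversal") reversal(op$i + offset, op$j + offset)
  else transposition(op$i + offset, op$j + offset, op$k + offset)
}

#' Sort by short operations (3-approximation)
#'
#' While inversions remain, acts at the leftmost adjacent inversion `i`,
#' dispatching on the component `C` containing it (`m` vertices):
#' * `m >= 5`: if the edge `(pi_i, pi_(i+1))` is not a cut edge, or both
#'   sides of `C - e` have at least 3 vertices, apply the adjacent-swap
#'   transposition; otherwise the unique side with at most 2 vertices
#'   decides -- transposition if it is even, 2-reversal if odd.
#' * `m = 3` or `4`: extract the component, replay the BFS-shortest sequence
#'   from [small_component_table()] translated to the component's interval.
#' * `m = 2`: 2-reversal when both elements are negative, otherwise the
#'   adjacent-swap transposition.
#'
#' Then 1-reversals at the remaining negative positions in ascending order.
#' The count is at most `Inv(pi) + c2_odd(pi) + c1_odd(pi)` and within a
#' factor 3 of the exact short-operation distance (a tight factor).
#'
#' @param p A signed permutation.
#' @return A `sorting_scenario` with family `"SSO"`.
#' @examples
#' sso_sort(parse_permutation("-3 -2 -5 -4 +1"))  # 6 operations, optimum is 2
#' @export
sso_sort <- function(p) {
  start <- as_signed_perm(p)
  x <- as_perm_vec(start)
  ops <- list()
  repeat {
    i <- leftmost_adjacent_inversion(x)
    if (is.null(i)) break
    comps <- graph_components(x)
    iv <- component_interval_at(comps, i)
    m <- iv[2] - iv[1] + 1L
    if (m >= 5L) {
      split <- cut_edge_split(x, i)
      op <- if (!isTRUE(split$is_cut)) {
        transposition(i, i + 1L, i + 2L)
      } else {
        # sides partition the component, so with m >= 5 at most one is small
        stopifnot(split$side_a$vertex_count + split$side_b$vertex_count == m)
        small <- if (split$side_a$vertex_count <= 2L) split$side_a
                 else if (split$side_b$vertex_count <= 2L) split$side_b
                 else NULL
        if (is.null(small)) {
          transposition(i, i + 1L, i + 2L)        # both sides >= 3 vertices
        } else if (small$odd) {
          reversal(i, i + 1L)
        } else {
          transposition(i, i + 1L, i + 2L)
        }
      }
      ops[[length(ops) + 1L]] <- op
      x <- apply_op_vec(x, op)
    } else if (m >= 3L) {
      sigma <- extract_component(x, iv)
      seq_ops <- small_component_table(m)[[perm_key(sigma)]]
      offset <- iv[1] - 1L
      for (op in seq_ops) {
        op <- translate_op(op, offset)
        ops[[length(ops) + 1L]] <- op
        x <- apply_op_vec(x, op)
      }
    } else {  # m == 2
      op <- if (x[i] < 0L && x[i + 1L] < 0L) reversal(i, i + 1L)
            else transposition(i, i + 1L, i + 2L)
      ops[[length(ops) + 1L]] <- op
      x <- apply_op_vec(x, op)
    }
  }
  for (i in which(x < 0L)) {
    ops[[length(ops) + 1L]] <- reversal(i, i)
    x[i] <- -x[i]
  }
  sorting_scenario(start, ops, "SSO")
}

#' Lower bound on the short-operation distance
#'
#' The larger of two potential-function bounds: a short operation decreases
#' `Inv + c_odd` by at most 4, and `Inv + c2_odd + c1_odd` by at most 3.
#'
#' @param p A signed permutation.
#' @return Nonnegative integer, never exceeding the exact distance.
#' @export
sso_lower_bound <- function(p) {
  x <- as_perm_vec(p)
  oc <- odd_components(x)
  inv <- inv_count(x)
  b1 <- ceiling((inv + oc$c_odd) / 4)
  b2 <- ceiling((inv + oc$c2_odd + oc$c1_odd) / 3)
  as.integer(max(b1, b2))
}
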