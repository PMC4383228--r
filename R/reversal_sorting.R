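# Sorting by bounded signed reversals.
#
# Super short reversals (length <= 2): the distance has a closed form,
# Inv(pi) + |V^even-| + |V^odd+|, realized by removing adjacent inversions
# with 2-reversals and then flipping the leftover negative signs with
# 1-reversals.
#
# Short reversals (length <= 3): exact distance is open; the sorter repeatedly
# swaps a vector-opposite pair via the short-reversal ladder until no element
# is displaced, then cleans up signs. Its count is within a factor 5 of
# optimal, and within 3 when Vec(pi) = 0 or Vec(pi) >= 4n.

#' Exact distance under super short reversals
#'
#' Closed form: `Inv(pi) + |V^even-| + |V^odd+|`. Each 2-reversal removes at
#' most one inversion and flips two length-parities in the vector diagram;
#' the two subset sizes count exactly the elements still negative after the
#' inversion phase, each costing one 1-reversal.
#'
#' @param p A signed permutation.
#' @return Nonnegative integer distance.
#' @examples
#' sssr_distance(signed_perm(c(-3, -2, -1)))  # 6
#' @export
sssr_distance <- function(p) {
  x <- as_perm_vec(p)
  sub <- vector_subset_sizes(x)
  inv_count(x) + sub$even_neg + sub$odd_pos
}

#' Optimal sort by super short reversals
#'
#' While inversions remain, applies the 2-reversal at the leftmost adjacent
#' inversion; then applies 1-reversals at the remaining negative positions in
#' ascending order. The scenario length always equals [sssr_distance()].
#'
#' @param p A signed permutation.
#' @return A `sorting_scenario` with family `"SSSR"`.
#' @export
sssr_sort <- function(p) {
  start <- as_signed_perm(p)
  x <- as_perm_vec(start)
  ops <- list()
  repeat {
    i <- leftmost_adjacent_inversion(x)
    if (is.null(i)) break
    op <- reversal(i, i + 1L)
    ops[[length(ops) + 1L]] <- op
    x <- apply_op_vec(x, op)
  }
  for (i in which(x < 0L)) {
    ops[[length(ops) + 1L]] <- reversal(i, i)
    x[i] <- -x[i]
  }
  sorting_scenario(start, ops, "SSSR")
}

#' Sort by short reversals (5-approximation)
#'
#' Two phases. Phase one: while some element is displaced, find a
#' vector-opposite pair with [find_vector_opposite_pair()] and apply the
#' [swap_sequence()] ladder, which strictly decreases the total vector
#' length. Phase two: apply 1-reversals at the remaining negative positions
#' in ascending order. The count is at most 5 times the exact
#' short-reversal distance, and at most 3 times when the permutation starts
#' with `vec_total` zero or at least `4n`.
#'
#' @param p A signed permutation.
#' @return A `sorting_scenario` with family `"SSR"`.
#' @examples
#' ssr_sort(parse_permutation("+3 +4 -1 -2"))  # 6 operations, optimum is 2
#' @export
ssr_sort <- function(p) {
  start <- as_signed_perm(p)
  x <- as_perm_vec(start)
  ops <- list()
  repeat {
    pair <- find_vector_opposite_pair(x)
    if (is.null(pair)) break
    seq_ops <- swap_sequence(x, pair[1], pair[2])
    for (op in seq_ops) {
      ops[[length(ops) + 1L]] <- op
      x <- apply_op_vec(x, op)
    }
  }
  for (i in which(x < 0L)) {
    ops[[length(ops) + 1L]] <- reversal(i, i)
    x[i] <- -x[i]
  }
  sorting_scenario(start, ops, "SSR")
}

#' Lower bound on the short-reversal distance
#'
#' The larger of two potential-function bounds: a short reversal can decrease
#' `Inv + |V^even-| + |V^odd+|` by at most 6, and `Vec + |V^odd| + |V^0-|`
#' by at most 5. Taking the maximum strengthens either bound alone.
#'
#' @param p A signed permutation.
#' @return Nonnegative integer, never exceeding the exact distance.
#' @export
ssr_lower_bound <- function(p) {
  x <- as_perm_vec(p)
  sub <- vector_subset_sizes(x)
  inv <- inv_count(x)
  b1 <- ceiling((inv + sub$even_neg + sub$odd_pos) / 6)
  b2 <- ceiling((vec_total(x) + sub$odd + sub$zero_neg) / 5)
  as.integer(max(b1, b2))
}
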