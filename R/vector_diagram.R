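# The vector diagram: each element pi_i gets a vector of length ||pi_i| - i|
# pointing toward its home position (right if the target lies ahead, left if
# behind). Zero-length vectors keep the element's sign (zero+ when pi_i = i,
# zero- when pi_i = -i). The total length Vec(pi) is the displacement mass a
# bounded-length sorting procedure must move.

#' Vector diagram of a signed permutation
#'
#' @param p A signed permutation.
#' @return An object of class `vector_diagram`: a list with `table` (a
#'   data.frame with columns `position`, `element`, `length`, `direction`
#'   where direction is one of `"right"`, `"left"`, `"zero+"`, `"zero-"`)
#'   and `vec_total`, the sum of all vector lengths.
#' @examples
#' vector_diagram(parse_permutation("+3 -4 +6 -1 +5 -2"))$vec_total  # 14
#' @export
vector_diagram <- function(p) {
  x <- as_perm_vec(p)
  n <- length(x)
  disp <- abs(x) - seq_len(n)
  len <- abs(disp)
  direction <- ifelse(disp > 0, "right",
                      ifelse(disp < 0, "left",
                             ifelse(x > 0, "zero+", "zero-")))
  structure(list(
    table = data.frame(position = seq_len(n), element = x,
                       length = len, direction = direction,
                       stringsAsFactors = FALSE),
    vec_total = sum(len)
  ), class = "vector_diagram")
}

#' @export
print.vector_diagram <- function(x, ...) {
  cat(sprintf("vector diagram (Vec = %d)\n", x$vec_total))
  elems <- ifelse(x$table$element > 0, paste0("+", x$table$element),
                  as.character(x$table$element))
  arrows <- ifelse(x$table$direction == "right",
                   paste0(x$table$length, ">"),
                   ifelse(x$table$direction == "left",
                          paste0("<", x$table$length),
                          x$table$direction))
  w <- max(nchar(elems), nchar(arrows))
  cat(" ", paste(formatC(elems, width = w), collapse = " "), "\n")
  cat(" ", paste(formatC(arrows, width = w), collapse = " "), "\n")
  invisible(x)
}

#' Total vector length Vec
#'
#' @param p A signed permutation.
#' @return Sum over positions of `||pi_i| - i|`; zero exactly when every
#'   element sits at its home position (whatever its sign).
#' @export
vec_total <- function(p) {
  x <- as_perm_vec(p)
  sum(abs(abs(x) - seq_along(x)))
}

#' Sizes of the four vector subsets
#'
#' The subsets drive the distance formulas and lower bounds:
#' * `even_neg`: negative elements with even vector length -- exactly the
#'   elements still negative after all inversions are removed by 2-reversals,
#'   hence the 1-reversal cleanup cost of the super-short-reversal solver.
#' * `odd_pos`: positive elements with odd vector length (same role).
#' * `odd`: elements with odd vector length (a parity obstruction for
#'   3-reversals, which preserve length parities).
#' * `zero_neg`: elements parked at home with flipped sign (`pi_i = -i`).
#'
#' @param p A signed permutation.
#' @return List with integer fields `even_neg`, `odd_pos`, `odd`, `zero_neg`.
#' @export
vector_subset_sizes <- function(p) {
  x <- as_perm_vec(p)
  len <- abs(abs(x) - seq_along(x))
  odd_len <- len %% 2L == 1L
  list(even_neg = sum(x < 0 & !odd_len),
       odd_pos  = sum(x > 0 & odd_len),
       odd      = sum(odd_len),
       zero_neg = sum(x == -seq_along(x)))
}

#' Are two elements vector-opposite?
#'
#' Elements at positions `i < j` are vector-opposite when their vectors point
#' toward each other (one right, one left) and each is long enough to reach
#' the other's position: both lengths at least `m = j - i`. Such a pair can
#' be swapped by a short-reversal ladder that decreases Vec by exactly `2m`.
#'
#' @param p A signed permutation.
#' @param i,j Positions with `i < j`.
#' @return Logical, with attribute `m` giving `j - i`.
#' @export
are_vector_opposite <- function(p, i, j) {
  x <- as_perm_vec(p)
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(c(i, j)) || i < 1L || j > length(x) || i >= j) {
    stop("need positions 1 <= i < j <= n", call. = FALSE)
  }
  m <- j - i
  di <- abs(x[i]) - i
  dj <- abs(x[j]) - j
  ans <- (di > 0L) && (dj < 0L) && (di >= m) && (-dj >= m)
  # "differ in direction" for i < j can only mean right at i, left at j when
  # both must reach across the window.
  structure(ans, m = m)
}

#' Find a vector-opposite pair
#'
#' Pinned pair-finding procedure used by the short-reversal sorter. Let `i`
#' be the position of the rightmost right vector and `k = |pi_i|`; let `j` be
#' the smallest position in `(i, k]` carrying a left vector. If `j = i + 1`
#' but positions `(i, i + 2)` are 2-vector-opposite, return `(i, i + 2)`;
#' otherwise return `(i, j)`. Whenever the permutation is displaced at all
#' (`vec_total > 0`) this returns a genuine vector-opposite pair, and when it
#' returns an adjacent pair, `(i, i + 2)` is guaranteed not 2-vector-opposite
#' -- the guarantee the approximation analysis leans on.
#'
#' @param p A signed permutation.
#' @return Integer vector `c(i, j)`, or `NULL` when `vec_total(p) == 0`.
#' @export
find_vector_opposite_pair <- function(p) {
  x <- as_perm_vec(p)
  n <- length(x)
  disp <- abs(x) - seq_len(n)
  rights <- which(disp > 0L)
  if (length(rights) == 0L) return(NULL)  # Vec == 0 (no displacement)
  i <- rights[length(rights)]
  k <- abs(x[i])
  window <- (i + 1L):k
  lefts <- window[disp[window] < 0L]
  j <- lefts[1L]
  if (j == i + 1L && i + 2L <= n && isTRUE(c(are_vector_opposite(x, i, i + 2L)))) {
    return(c(i, i + 2L))
  }
  c(i, j)
}

#' Swap ladder for a vector-opposite pair
#'
#' For an `m`-vector-opposite pair at positions `(i, j)`, builds the sequence
#' of short reversals that exchanges the absolute values at `i` and `j` while
#' leaving all other absolute values in place, using `2*ceiling(m/2) - 1`
#' operations: an up-ladder of 3-reversals, for odd `m` a middle 2-reversal,
#' then the mirrored down-ladder. For even `m` the element left at position
#' `j - 1` has its sign flipped; for odd `m` all other elements are unchanged.
#' Applying the ladder decreases `vec_total` by exactly `2 * m`.
#'
#' @param p A signed permutation.
#' @param i,j A vector-opposite pair of positions.
#' @return List of `rearr_op` (all reversals of length 2 or 3).
#' @export
swap_sequence <- function(p, i, j) {
  x <- as_perm_vec(p)
  i <- as.integer(i); j <- as.integer(j)
  if (!isTRUE(c(are_vector_opposite(x, i, j)))) {
    stop(sprintf("positions (%d, %d) are not vector-opposite", i, j),
         call. = FALSE)
  }
  m <- j - i
  ops <- list()
  if (m %% 2L == 0L) {
    up <- seq(i, j - 2L, by = 2L)
    for (s in up) ops[[length(ops) + 1L]] <- reversal(s, s + 2L)
    down <- rev(up)[-1L]
    for (s in down) ops[[length(ops) + 1L]] <- reversal(s, s + 2L)
  } else {
    up <- if (m > 1L) seq(i, j - 3L, by = 2L) else integer(0)
    for (s in up) ops[[length(ops) + 1L]] <- reversal(s, s + 2L)
    ops[[length(ops) + 1L]] <- reversal(j - 1L, j)
    for (s in rev(up)) ops[[length(ops) + 1L]] <- reversal(s, s + 2L)
  }
  ops
}
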