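# Length-bounded rearrangement operations and the four operation families.
#
# A signed reversal rho(i, j) reverses the block at positions i..j and flips
# every sign in it; a transposition rho(i, j, k) exchanges the adjacent blocks
# at positions i..j-1 and j..k-1 without touching signs. Families:
#   SSSR  reversals of length <= 2
#   SSR   reversals of length <= 3
#   SSSO  SSSR plus (1,1)-transpositions (adjacent swaps)
#   SSO   SSR plus transpositions with block lengths x + y <= 3
# All positions are 1-based; a transposition's upper index k may equal n + 1.

OPERATION_FAMILIES <- c("SSSR", "SSR", "SSSO", "SSO")

#' Signed reversal operation
#'
#' @param i,j Positions with `1 <= i <= j`; the reversal spans `j - i + 1`
#'   elements (its length).
#' @return An object of class `rearr_op`.
#' @examples
#' reversal(2, 4)
#' @export
reversal <- function(i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(c(i, j)) || i < 1L || j < i) {
    stop("reversal needs positions 1 <= i <= j", call. = FALSE)
  }
  structure(list(kind = "reversal", i = i, j = j), class = "rearr_op")
}

#' Transposition operation
#'
#' @param i,j,k Positions with `1 <= i < j < k`; the blocks at `i..j-1` and
#'   `j..k-1` exchange places. Its profile is `(x, y) = (j - i, k - j)`.
#' @return An object of class `rearr_op`.
#' @examples
#' transposition(1, 2, 3)  # swap of two adjacent elements, signs kept
#' @export
transposition <- function(i, j, k) {
  i <- as.integer(i); j <- as.integer(j); k <- as.integer(k)
  if (anyNA(c(i, j, k)) || i < 1L || j <= i || k <= j) {
    stop("transposition needs positions 1 <= i < j < k", call. = FALSE)
  }
  structure(list(kind = "transposition", i = i, j = j, k = k),
            class = "rearr_op")
}

#' @export
print.rearr_op <- function(x, ...) {
  cat(format_operation(x), "\n")
  invisible(x)
}

#' Format an operation in rho-notation
#'
#' @param op A `rearr_op`.
#' @return `"rho(i,j)"` for a reversal, `"rho(i,j,k)"` for a transposition.
#' @export
format_operation <- function(op) {
  stopifnot(inherits(op, "rearr_op"))
  if (op$kind == "reversal") {
    sprintf("rho(%d,%d)", op$i, op$j)
  } else {
    sprintf("rho(%d,%d,%d)", op$i, op$j, op$k)
  }
}

#' Format a list of operations as a scenario string
#'
#' @param ops List of `rearr_op`.
#' @return Semicolon-separated rho-terms, e.g. `"rho(2,4);rho(1,3);rho(1,1)"`.
#' @export
format_operations <- function(ops) {
  paste(vapply(ops, format_operation, character(1)), collapse = ";")
}

#' Parse a semicolon-separated list of rho-terms
#'
#' @param text e.g. `"rho(2,4);rho(1,3);rho(1,1)"`. Two indices make a
#'   reversal, three a transposition.
#' @return List of `rearr_op`.
#' @export
parse_operations <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  terms <- strsplit(trimws(text), ";")[[1]]
  terms <- trimws(terms[nzchar(trimws(terms))])
  lapply(terms, function(term) {
    m <- regmatches(term, regexec(
      "^rho\\(\\s*([0-9]+)\\s*,\\s*([0-9]+)\\s*(?:,\\s*([0-9]+)\\s*)?\\)$",
      term))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("cannot parse operation term '%s'", term), call. = FALSE)
    }
    idx <- as.integer(m[-1][nzchar(m[-1])])
    if (length(idx) == 2L) reversal(idx[1], idx[2])
    else transposition(idx[1], idx[2], idx[3])
  })
}

op_valid_for_n <- function(op, n) {
  if (op$kind == "reversal") op$j <= n else op$k <= n + 1L
}

# Span length: reversal length, or x + y for a transposition.
op_span <- function(op) {
  if (op$kind == "reversal") op$j - op$i + 1L else op$k - op$i
}

#' Family membership of an operation
#'
#' @param op A `rearr_op`.
#' @param family One of `"SSSR"`, `"SSR"`, `"SSSO"`, `"SSO"`.
#' @param n Permutation size the operation must fit in.
#' @return Logical.
#' @export
op_in_family <- function(op, family, n) {
  stopifnot(inherits(op, "rearr_op"))
  family <- match.arg(family, OPERATION_FAMILIES)
  if (!op_valid_for_n(op, n)) return(FALSE)
  if (op$kind == "reversal") {
    len <- op$j - op$i + 1L
    switch(family,
           SSSR = len <= 2L, SSSO = len <= 2L,
           SSR = len <= 3L, SSO = len <= 3L)
  } else {
    xy <- op$k - op$i
    switch(family,
           SSSR = FALSE, SSR = FALSE,
           SSSO = xy == 2L,
           SSO = xy <= 3L)
  }
}

# Fast internal application to a bare integer vector; callers guarantee
# index validity.
apply_op_vec <- function(x, op) {
  if (op$kind == "reversal") {
    idx <- op$i:op$j
    x[idx] <- -rev(x[idx])
  } else {
    x[op$i:(op$k - 1L)] <- x[c(op$j:(op$k - 1L), op$i:(op$j - 1L))]
  }
  x
}

#' Apply an operation to a signed permutation
#'
#' A reversal `rho(i,j)` reverses the block at positions `i..j` and negates
#' every element in it; a transposition `rho(i,j,k)` exchanges the blocks at
#' positions `i..j-1` and `j..k-1`, signs untouched. Elements outside the
#' affected range are unchanged and a new permutation is returned.
#'
#' @param p A signed permutation.
#' @param op A `rearr_op` whose indices fit `length(p)`.
#' @return A new `signed_perm`.
#' @examples
#' apply_operation(signed_perm(c(-3, -2, -1)), reversal(1, 3))  # identity
#' @export
apply_operation <- function(p, op) {
  x <- as_perm_vec(p)
  stopifnot(inherits(op, "rearr_op"))
  if (!op_valid_for_n(op, length(x))) {
    stop(sprintf("operation %s out of range for permutation of size %d",
                 format_operation(op), length(x)), call. = FALSE)
  }
  structure(apply_op_vec(x, op), class = "signed_perm")
}

#' Inverse of an operation
#'
#' Reversals are involutions; the inverse of transposition `rho(i,j,k)` is
#' `rho(i, i+k-j, k)` (the two blocks swap back). The inverse of a family
#' member is always in the same family, which is what lets the BFS oracle
#' measure distance *to* the identity by searching *from* it.
#'
#' @param op A `rearr_op`.
#' @return A `rearr_op`.
#' @export
inverse_operation <- function(op) {
  stopifnot(inherits(op, "rearr_op"))
  if (op$kind == "reversal") op
  else transposition(op$i, op$i + op$k - op$j, op$k)
}

#' Enumerate every operation of a family for size n
#'
#' Deterministic canonical order: reversals by ascending `(i, j)`, then
#' transpositions by ascending `(i, j, k)`. This order is the single
#' tie-break source for the BFS oracle and the small-component lookup tables;
#' it never varies.
#'
#' @param n Positive integer permutation size.
#' @param family One of `"SSSR"`, `"SSR"`, `"SSSO"`, `"SSO"`.
#' @return List of `rearr_op`.
#' @examples
#' length(enumerate_operations(3, "SSSR"))  # 5: three 1-reversals, two 2-reversals
#' @export
enumerate_operations <- function(n, family) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("n must be a positive integer", call. = FALSE)
  }
  family <- match.arg(family, OPERATION_FAMILIES)
  max_len <- if (family %in% c("SSSR", "SSSO")) 2L else 3L
  ops <- list()
  for (i in seq_len(n)) {
    for (j in i:min(n, i + max_len - 1L)) {
      ops[[length(ops) + 1L]] <- reversal(i, j)
    }
  }
  if (family %in% c("SSSO", "SSO")) {
    max_span <- if (family == "SSSO") 2L else 3L
    for (i in seq_len(n)) {
      for (j in (i + 1L):(i + max_span - 1L)) {
        for (k in (j + 1L):(i + max_span)) {
          if (j > i && k > j && k <= n + 1L && (k - i) <= max_span) {
            ops[[length(ops) + 1L]] <- transposition(i, j, k)
          }
        }
      }
    }
  }
  ops
}
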