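# Signed permutations: construction, parsing, printing, inversions, and
# seeded random generation. A signed permutation models a gene order with
# orientations: an ordering of 1..n where each element carries a + or - sign.

#' Construct a signed permutation
#'
#' A signed permutation of size `n` is an ordering of the integers `1..n` in
#' which every element carries a sign. It models a unichromosomal genome:
#' elements are genes, signs are gene orientations.
#'
#' @param elements Integer vector of signed nonzero integers whose absolute
#'   values are exactly `1..length(elements)`.
#' @return An object of class `signed_perm` (an integer vector with a class
#'   attribute). Operations never modify a permutation in place; they return
#'   new values.
#' @examples
#' signed_perm(c(3, -4, 6, -1, 5, -2))
#' @export
signed_perm <- function(elements) {
  x <- suppressWarnings(as.integer(elements))
  if (length(x) == 0L || anyNA(x)) {
    stop("a signed permutation needs at least one integer element", call. = FALSE)
  }
  if (any(x == 0L)) {
    stop("element 0 is not allowed in a signed permutation", call. = FALSE)
  }
  a <- sort(abs(x))
  n <- length(x)
  if (anyDuplicated(abs(x))) {
    dup <- abs(x)[duplicated(abs(x))][1L]
    stop(sprintf("duplicate absolute value %d in signed permutation", dup),
         call. = FALSE)
  }
  if (!identical(a, seq_len(n))) {
    missing_v <- setdiff(seq_len(n), a)[1L]
    stop(sprintf("absolute values must be exactly 1..%d (missing %d)", n, missing_v),
         call. = FALSE)
  }
  structure(x, class = "signed_perm")
}

#' @export
print.signed_perm <- function(x, ...) {
  cat("signed permutation (n = ", length(x), "): ",
      format_permutation(x), "\n", sep = "")
  invisible(x)
}

as_perm_vec <- function(p) {
  if (inherits(p, "signed_perm")) return(unclass(p))
  unclass(signed_perm(p))
}

#' Coerce to a signed permutation
#'
#' @param p A `signed_perm`, an integer vector, or a character string in the
#'   text format accepted by [parse_permutation()].
#' @return A `signed_perm`.
#' @export
as_signed_perm <- function(p) {
  if (inherits(p, "signed_perm")) return(p)
  if (is.character(p)) return(parse_permutation(p))
  signed_perm(p)
}

#' Parse a signed permutation from text
#'
#' Accepts whitespace- or comma-separated signed integers; the `+` sign on
#' positive elements is optional. For example `"+3 -4 +6 -1 +5 -2"`.
#'
#' @param text A character string.
#' @return A `signed_perm`.
#' @examples
#' parse_permutation("+3 -4 +6 -1 +5 -2")
#' @export
parse_permutation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "[,[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("empty permutation text", call. = FALSE)
  }
  bad <- !grepl("^[+-]?[0-9]+$", tokens)
  if (any(bad)) {
    stop(sprintf("non-integer token '%s' in permutation text", tokens[bad][1L]),
         call. = FALSE)
  }
  signed_perm(as.integer(tokens))
}

#' Format a signed permutation as text
#'
#' Prints explicit `+` signs on positive elements, e.g. `"+3 -4 +6 -1 +5 -2"`.
#' `parse_permutation(format_permutation(p))` round-trips.
#'
#' @param p A signed permutation.
#' @return A character string.
#' @export
format_permutation <- function(p) {
  x <- as_perm_vec(p)
  paste(ifelse(x > 0, paste0("+", x), as.character(x)), collapse = " ")
}

#' The identity permutation
#'
#' @param n Positive integer size.
#' @return The signed permutation `(+1, +2, ..., +n)`, the sorting target of
#'   every algorithm in this package.
#' @export
identity_permutation <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("n must be a positive integer", call. = FALSE)
  }
  structure(seq_len(n), class = "signed_perm")
}

is_identity <- function(p) {
  x <- as_perm_vec(p)
  all(x == seq_along(x))
}

# Fast internal inversion count on a bare integer vector (O(n^2) pair scan;
# permutations handled here are desk-scale).
inv_count <- function(x) {
  n <- length(x)
  if (n < 2L) return(0L)
  a <- abs(x)
  total <- 0L
  for (i in seq_len(n - 1L)) {
    total <- total + sum(a[i] > a[(i + 1L):n])
  }
  as.integer(total)
}

#' Inversions of a signed permutation
#'
#' An inversion is a pair of positions `i < j` with `|pi_i| > |pi_j|`. The
#' inversion count is the number of adjacent swaps any bounded-length sorting
#' procedure must pay for, and the edge set of the permutation graph.
#'
#' @param p A signed permutation.
#' @return A list with `count` (nonnegative integer) and `pairs` (two-column
#'   integer matrix of positions, in lexicographic order; zero rows when there
#'   are no inversions).
#' @examples
#' inversions(signed_perm(c(-3, -2, -1)))$count  # 3
#' @export
inversions <- function(p) {
  x <- as_perm_vec(p)
  n <- length(x)
  a <- abs(x)
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (n >= 2L) {
    rows <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      js <- which(a[(i + 1L):n] < a[i]) + i
      if (length(js)) rows[[i]] <- cbind(i = i, j = js)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) pairs <- do.call(rbind, rows)
  }
  list(count = nrow(pairs), pairs = pairs)
}

#' Leftmost adjacent inversion
#'
#' The smallest position `i` with `|pi_i| > |pi_(i+1)|`, or `NULL` if the
#' permutation has no inversions. Whenever any inversion exists, an adjacent
#' one exists, so this is `NULL` exactly when `inversions(p)$count == 0`.
#' Every sorting algorithm in the package uses this position as its single,
#' reproducible choice of where to act.
#'
#' @param p A signed permutation.
#' @return Integer position or `NULL`.
#' @export
leftmost_adjacent_inversion <- function(p) {
  x <- as_perm_vec(p)
  n <- length(x)
  if (n < 2L) return(NULL)
  a <- abs(x)
  w <- which(a[-n] > a[-1L])
  if (length(w) == 0L) NULL else w[1L]
}

#' Uniform random signed permutation
#'
#' Draws uniformly over all `n! * 2^n` signed permutations of size `n`: a
#' uniform shuffle of the values `1..n` with an independent fair sign on each
#' element. This is the random-genome model used for the expected-behaviour
#' experiments.
#'
#' @param n Positive integer size.
#' @param seed Optional integer. When given, the draw is a pure function of
#'   `(n, seed)` and the caller's RNG state is left untouched.
#' @return A `signed_perm`.
#' @export
random_permutation <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  vals <- sample.int(n)
  signs <- sample(c(-1L, 1L), n, replace = TRUE)
  structure(vals * signs, class = "signed_perm")
}

# All permutations of 1..n as an (n!, n) integer matrix, in a deterministic
# order (recursive insertion of n into every gap).
all_unsigned_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_unsigned_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (s in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[s, ], n, after = pos - 1L)
    }
  }
  out
}

#' Enumerate all signed permutations of size n
#'
#' @param n Positive integer (kept small: the state space has `n! * 2^n`
#'   members, 46080 already at `n = 6`).
#' @return A list of `signed_perm` objects in a deterministic order.
#' @export
all_signed_permutations <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (n > 7L) {
    stop("refusing to enumerate all signed permutations for n > 7", call. = FALSE)
  }
  perms <- all_unsigned_perms(n)
  signs <- unname(as.matrix(expand.grid(rep(list(c(1L, -1L)), n),
                                        KEEP.OUT.ATTRS = FALSE)))
  out <- vector("list", nrow(perms) * nrow(signs))
  k <- 0L
  for (i in seq_len(nrow(perms))) {
    base <- perms[i, ]
    for (j in seq_len(nrow(signs))) {
      k <- k + 1L
      out[[k]] <- structure(base * signs[j, ], class = "signed_perm")
    }
  }
  out
}

# Canonical string key for hashing a permutation state.
perm_key <- function(x) paste(unclass(x), collapse = " ")
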