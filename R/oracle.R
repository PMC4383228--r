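# Exhaustive BFS distance oracle. Every family contains all 1- and
# 2-reversals, which generate the whole group of signed permutations, and is
# closed under operation inverses, so breadth-first search outward from the
# identity assigns each of the n! * 2^n states its exact distance to the
# identity. Tables are cached per (n, family) for the lifetime of the
# process; sizes above the cap are refused rather than allowed to thrash.

.table_cache <- new.env(parent = emptyenv())

# Precompute each operation as an index map plus sign mask so BFS expansion
# is a single subset-and-multiply.
op_maps <- function(n, ops) {
  lapply(ops, function(op) {
    idx <- seq_len(n)
    sgn <- rep(1L, n)
    if (op$kind == "reversal") {
      idx[op$i:op$j] <- op$j:op$i
      sgn[op$i:op$j] <- -1L
    } else {
      idx[op$i:(op$k - 1L)] <- c(op$j:(op$k - 1L), op$i:(op$j - 1L))
    }
    list(idx = idx, sgn = sgn)
  })
}

#' Build the exact-distance table for a family
#'
#' Breadth-first search from the identity over the family's operations in
#' canonical order. Because each family is closed under
#' [inverse_operation()], the depth at which a state is first reached equals
#' its sorting distance.
#'
#' @param n Permutation size; refused above `cap`.
#' @param family One of `"SSSR"`, `"SSR"`, `"SSSO"`, `"SSO"`.
#' @param cap Resource guard (default 7, i.e. at most 645120 states); raise
#'   explicitly to go further.
#' @return An object of class `distance_table` with fields `n`, `family`,
#'   `dist` (an environment mapping permutation keys to distances) and
#'   `n_states`.
#' @export
build_distance_table <- function(n, family, cap = 7L) {
  n <- as.integer(n)
  family <- match.arg(family, OPERATION_FAMILIES)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("n must be a positive integer", call. = FALSE)
  }
  if (n > cap) {
    stop(sprintf(paste0("n = %d exceeds the distance-table cap (%d); ",
                        "pass a larger `cap` explicitly to allow it"), n, cap),
         call. = FALSE)
  }
  key <- sprintf("%s_%d", family, n)
  cached <- .table_cache[[key]]
  if (!is.null(cached)) return(cached)

  maps <- op_maps(n, enumerate_operations(n, family))
  dist <- new.env(hash = TRUE, parent = emptyenv(),
                  size = max(64L, 2L * factorial(n) * 2L^n))
  id <- seq_len(n)
  assign(perm_key(id), 0L, envir = dist)
  frontier <- list(id)
  d <- 0L
  n_states <- 1L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- vector("list", length(frontier) * length(maps))
    cnt <- 0L
    for (pvec in frontier) {
      for (mp in maps) {
        q <- mp$sgn * pvec[mp$idx]
        k <- perm_key(q)
        if (is.null(dist[[k]])) {
          assign(k, d, envir = dist)
          cnt <- cnt + 1L
          nxt[[cnt]] <- q
        }
      }
    }
    n_states <- n_states + cnt
    frontier <- if (cnt) nxt[seq_len(cnt)] else list()
  }
  expected <- factorial(n) * 2^n
  stopifnot(n_states == expected)  # 1- and 2-reversals generate the group
  tab <- structure(list(n = n, family = family, dist = dist,
                        n_states = n_states),
                   class = "distance_table")
  .table_cache[[key]] <- tab
  tab
}

#' @export
print.distance_table <- function(x, ...) {
  cat("distance table: family ", x$family, ", n = ", x$n,
      " (", x$n_states, " states)\n", sep = "")
  invisible(x)
}

#' Exact sorting distance by table lookup
#'
#' @param p A signed permutation.
#' @param family One of `"SSSR"`, `"SSR"`, `"SSSO"`, `"SSO"`.
#' @param cap Passed to [build_distance_table()].
#' @return The exact distance of `p` to the identity under the family.
#' @examples
#' exact_distance(parse_permutation("+3 +4 -1 -2"), "SSR")  # 2
#' @export
exact_distance <- function(p, family, cap = 7L) {
  x <- as_perm_vec(p)
  tab <- build_distance_table(length(x), family, cap = cap)
  tab$dist[[perm_key(x)]]
}

#' Dump a distance table as a data.frame
#'
#' @param tab A `distance_table`.
#' @return data.frame with columns `permutation` (text) and `distance`,
#'   ordered by the deterministic enumeration of
#'   [all_signed_permutations()].
#' @export
distance_table_frame <- function(tab) {
  stopifnot(inherits(tab, "distance_table"))
  perms <- all_signed_permutations(tab$n)
  data.frame(
    permutation = vapply(perms, format_permutation, character(1)),
    distance = vapply(perms, function(p) tab$dist[[perm_key(p)]], integer(1))
  )
}
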