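# Exhaustive audit of the approximation sorters against the BFS oracle, plus
# the random-permutation experiments on the expected vector-length mass.

# lcm over a vector of small positive integers
int_lcm <- function(v) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  Reduce(function(a, b) a / g(a, b) * b, v, accumulate = FALSE)
}

#' Round half-up to a number of decimals
#'
#' Presentation rounding for audit rows (R's `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Exhaustive audit of a sorter against exact distances
#'
#' Enumerates all `n! * 2^n` signed permutations of size `n`, runs the
#' chosen approximation sorter on each, and compares its operation count with
#' the exact distance from the BFS oracle under the matching family (SSR for
#' the short-reversal sorter, SSO for the short-operation sorter). The ratio
#' is defined as 1 when the exact distance is 0, so the identity counts as
#' exact. Aggregation is in exact rational arithmetic (integer numerators
#' over a common denominator, all well below 2^53); rounding half-up to two
#' decimals happens only at presentation.
#'
#' @param algorithm `"ssr"` or `"sso"`.
#' @param n Permutation size (the full enumeration grows as `n! * 2^n`;
#'   sizes above 7 are refused by the oracle cap).
#' @param cap Passed to [build_distance_table()].
#' @return A list of class `audit_row`: `n`, `avg_ratio`, `max_ratio`,
#'   `exact_pct` (rounded for presentation) plus `avg_ratio_raw` and
#'   `n_permutations`.
#' @examples
#' \donttest{
#' audit("sso", 3)  # avg 1.04, max 1.50, exact 91.67%
#' }
#' @export
audit <- function(algorithm = c("ssr", "sso"), n, cap = 7L) {
  algorithm <- match.arg(algorithm)
  family <- if (algorithm == "ssr") "SSR" else "SSO"
  sorter <- if (algorithm == "ssr") ssr_sort else sso_sort
  tab <- build_distance_table(n, family, cap = cap)
  perms <- all_signed_permutations(n)
  lens <- integer(length(perms))
  dists <- integer(length(perms))
  for (idx in seq_along(perms)) {
    lens[idx] <- sorter(perms[[idx]])$length
    dists[idx] <- tab$dist[[perm_key(perms[[idx]])]]
  }
  N <- length(perms)
  denom <- pmax(dists, 1L)           # ratio := 1 when the distance is 0
  numer <- ifelse(dists == 0L, 1L, lens)
  L <- int_lcm(sort(unique(denom)))
  total <- sum(as.numeric(numer) * (L / denom))  # exact: integers < 2^53
  avg_raw <- total / (N * L)
  structure(list(
    n = n,
    avg_ratio = round_half_up(avg_raw, 2),
    max_ratio = round_half_up(max(numer / denom), 2),
    exact_pct = round_half_up(100 * sum(lens == dists) / N, 2),
    avg_ratio_raw = avg_raw,
    n_permutations = N,
    algorithm = algorithm
  ), class = "audit_row")
}

#' @export
print.audit_row <- function(x, ...) {
  cat(sprintf("audit of %s sorter, n = %d (%d permutations)\n",
              x$algorithm, x$n, x$n_permutations))
  cat(sprintf("  avg ratio %.2f   max ratio %.2f   exact %.2f%%\n",
              x$avg_ratio, x$max_ratio, x$exact_pct))
  invisible(x)
}

#' Mean total vector length of random signed permutations
#'
#' The expected value of `vec_total` over a uniform signed permutation of
#' size `n` is `(n^2 - 1) / 3`. With `exact = TRUE` (requires `n <= 7`) the
#' mean is computed over the full enumeration and matches the closed form
#' exactly; otherwise a seeded Monte-Carlo mean is returned with its
#' standard error.
#'
#' @param n Permutation size.
#' @param samples Monte-Carlo sample count (ignored when exact).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param exact Enumerate instead of sampling.
#' @return List with `mean`, `theoretical`, and for Monte-Carlo `se`.
#' @export
expected_vec_experiment <- function(n, samples = 10000L, seed = 1L,
                                    exact = FALSE) {
  theoretical <- (n^2 - 1) / 3
  if (exact) {
    vals <- vapply(all_signed_permutations(n), vec_total, numeric(1))
    return(list(mean = mean(vals), theoretical = theoretical))
  }
  stopifnot(samples >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  vals <- numeric(samples)
  for (s in seq_len(samples)) {
    vals[s] <- vec_total(random_permutation(n))
  }
  list(mean = mean(vals), theoretical = theoretical,
       se = stats::sd(vals) / sqrt(samples))
}

#' Distribution of vector lengths under the uniform model
#'
#' For each length `j` in `1..n-1`, the sum over positions of the
#' probability that the vector at that position has length `j` equals
#' `2(n - j) / n`. Computed here by exhaustive enumeration; the `j = 0`
#' column is excluded (the identity holds for `j >= 1`).
#'
#' @param n Permutation size (enumeration; keep small).
#' @return data.frame with columns `j`, `empirical` (enumerated expectation
#'   of the count of vectors of length `j`) and `formula` (`2(n - j)/n`).
#' @export
vector_length_distribution_check <- function(n) {
  stopifnot(n >= 2L, n <= 7L)
  perms <- all_signed_permutations(n)
  counts <- numeric(n - 1L)
  for (p in perms) {
    len <- abs(abs(as_perm_vec(p)) - seq_len(n))
    for (j in seq_len(n - 1L)) counts[j] <- counts[j] + sum(len == j)
  }
  data.frame(j = seq_len(n - 1L),
             empirical = counts / length(perms),
             formula = 2 * (n - seq_len(n - 1L)) / n)
}
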