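# Independent brute-force oracles, deliberately naive so they cannot share a
# bug with the implementation they check.

perm_key_chr <- function(p) paste(as.integer(unclass(p)), collapse = " ")

# inversion count by explicit pair enumeration
brute_inversions <- function(p) {
  x <- abs(as.integer(unclass(p)))
  n <- length(x)
  cnt <- 0L
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (x[i] > x[j]) cnt <- cnt + 1L
    }
  }
  cnt
}

# connected components of the inversion-edge graph by depth-first search,
# returned as a list of sorted position vectors ordered by first position
brute_components <- function(p) {
  x <- abs(as.integer(unclass(p)))
  n <- length(x)
  pos <- seq_len(n)
  adj <- lapply(pos, function(u) {
    which((pos < u & x > x[u]) | (pos > u & x < x[u]))
  })
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    stack <- s
    comp <- integer(0)
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[u]) next
      seen[u] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, adj[[u]][!seen[adj[[u]]]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# total vector length computed straight from the definition
brute_vec <- function(p) {
  x <- as.integer(unclass(p))
  s <- 0L
  for (i in seq_along(x)) s <- s + abs(abs(x[i]) - i)
  s
}

# every vector-opposite pair of positions, by definition
brute_vector_opposite_pairs <- function(p) {
  x <- as.integer(unclass(p))
  n <- length(x)
  out <- list()
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      di <- abs(x[i]) - i
      dj <- abs(x[j]) - j
      m <- j - i
      if (di > 0 && dj < 0 && di >= m && -dj >= m) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  out
}
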