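figure_perm <- parse_permutation("+3 -4 +6 -1 +5 -2")

test_that("vector diagram lengths, directions and total follow the definition", {
  vd <- vector_diagram(figure_perm)
  expect_equal(vd$vec_total, 14)
  expect_equal(vd$table$direction[2], "right")   # |-4| - 2 = 2 > 0
  expect_equal(vd$table$length[2], 2L)

  vd_id <- vector_diagram(identity_permutation(5))
  expect_true(all(vd_id$table$direction == "zero+"))
  expect_equal(vd_id$vec_total, 0)

  expect_equal(vector_diagram(signed_perm(c(1, -2, 3)))$table$direction[2], "zero-")

  for (n in c(3L, 8L, 12L)) {
    p <- random_permutation(n, seed = 100 + n)
    expect_equal(vec_total(p), brute_vec(p))
    expect_equal(vector_diagram(p)$vec_total, brute_vec(p))
  }
})

test_that("vector subset sizes count the sign/parity classes", {
  s <- vector_subset_sizes(signed_perm(c(-3, -2, -1)))
  expect_equal(s, list(even_neg = 3L, odd_pos = 0L, odd = 0L, zero_neg = 1L))
  expect_equal(vector_subset_sizes(identity_permutation(4)),
               list(even_neg = 0L, odd_pos = 0L, odd = 0L, zero_neg = 0L))
  expect_equal(vector_subset_sizes(signed_perm(c(2, 1)))$odd_pos, 2L)
  # a zero-length vector is even: odd and zero_neg classes are disjoint
  for (p in all_signed_permutations(4)) {
    s <- vector_subset_sizes(p)
    x <- unclass(p)
    len <- abs(abs(x) - seq_along(x))
    expect_equal(s$odd + s$zero_neg,
                 sum(len %% 2 == 1) + sum(x == -seq_along(x)))
  }
})

test_that("vector-opposite test matches the definition", {
  expect_true(c(are_vector_opposite(figure_perm, 2, 4)))
  expect_equal(attr(are_vector_opposite(figure_perm, 2, 4), "m"), 2L)
  expect_false(c(are_vector_opposite(identity_permutation(4), 1, 3)))
  expect_false(c(are_vector_opposite(signed_perm(c(-3, 1, 2)), 1, 3)))
  expect_error(are_vector_opposite(figure_perm, 4, 2), "i < j")
})

test_that("pair finding returns a genuine pair and honours its guarantee", {
  expect_equal(find_vector_opposite_pair(signed_perm(c(3, 4, -1, -2))), c(2L, 4L))
  expect_equal(find_vector_opposite_pair(signed_perm(c(-3, 1, 2))), c(1L, 2L))
  expect_null(find_vector_opposite_pair(identity_permutation(4)))

  # exhaustive over size 5: whenever inversions exist, the returned pair is
  # vector-opposite, and an adjacent return implies (i, i+2) is not
  # 2-vector-opposite
  for (p in all_signed_permutations(5)) {
    pair <- find_vector_opposite_pair(p)
    if (inversions(p)$count == 0L) {
      if (vec_total(p) == 0) expect_null(pair)
      next
    }
    expect_false(is.null(pair))
    expect_true(c(are_vector_opposite(p, pair[1], pair[2])))
    if (pair[2] == pair[1] + 1L && pair[1] + 2L <= 5L) {
      expect_false(c(are_vector_opposite(p, pair[1], pair[1] + 2L)))
    }
  }
})

test_that("swap ladders have the stated shape and element-exchange effect", {
  # adjacent pair degenerates to the single 2-reversal
  expect_equal(swap_sequence(signed_perm(c(2, 1)), 1, 2), list(reversal(1, 2)))
  expect_equal(swap_sequence(signed_perm(c(3, 4, -1, -2)), 2, 4),
               list(reversal(2, 4)))
  expect_equal(swap_sequence(signed_perm(c(4, 2, 3, -1)), 1, 4),
               list(reversal(1, 3), reversal(3, 4), reversal(1, 3)))
  expect_error(swap_sequence(identity_permutation(3), 1, 3),
               "not vector-opposite")

  # exhaustive at n = 4, plus larger random cases: the ladder swaps the two
  # absolute values, fixes all other absolute values, uses 2*ceiling(m/2)-1
  # short reversals, and decreases Vec by exactly 2m
  check_ladder <- function(p) {
    for (pair in brute_vector_opposite_pairs(p)) {
      i <- pair[1]; j <- pair[2]; m <- j - i
      ops <- swap_sequence(p, i, j)
      expect_length(ops, 2L * ceiling(m / 2) - 1L)
      expect_true(all(vapply(ops, function(o) {
        o$kind == "reversal" && (o$j - o$i + 1L) %in% c(2L, 3L)
      }, logical(1))))
      q <- apply_operations(p, ops)
      expect_equal(abs(q[i]), abs(p[j]))
      expect_equal(abs(q[j]), abs(p[i]))
      others <- setdiff(seq_along(p), c(i, j))
      expect_equal(abs(unclass(q)[others]), abs(unclass(p)[others]))
      if (m %% 2 == 1) expect_equal(unclass(q)[others], unclass(p)[others])
      expect_equal(vec_total(p) - vec_total(q), 2 * m)
    }
  }
  for (p in all_signed_permutations(4)) check_ladder(p)
  for (s in 1:5) check_ladder(random_permutation(12, seed = s))
})

test_that("short reversals move Vec by at most their reach", {
  # exhaustive ledger at n = 4: 0 for 1-reversals, |delta| <= 2 for
  # 2-reversals, <= 4 for 3-reversals
  perms <- all_signed_permutations(4)
  for (op in enumerate_operations(4, "SSR")) {
    len <- op$j - op$i + 1L
    bound <- c(0L, 2L, 4L)[len]
    for (p in perms) {
      delta <- vec_total(p) - vec_total(apply_operation(p, op))
      expect_lte(abs(delta), bound)
    }
  }
})

test_that("2-reversals preserve the even-negative + odd-positive tally", {
  perms <- all_signed_permutations(4)
  two_revs <- Filter(function(o) o$j - o$i + 1L == 2L,
                     enumerate_operations(4, "SSSR"))
  for (p in perms) {
    s <- vector_subset_sizes(p)
    before <- s$even_neg + s$odd_pos
    for (op in two_revs) {
      s2 <- vector_subset_sizes(apply_operation(p, op))
      expect_equal(s2$even_neg + s2$odd_pos, before)
    }
  }
})
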