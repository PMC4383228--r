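test_that("component scan equals DFS over the inversion-edge graph", {
  comps <- graph_components(identity_permutation(4))
  expect_equal(nrow(comps), 4L)
  expect_true(all(!comps$odd))

  comps <- graph_components(parse_permutation("+3 -4 +6 -1 +5 -2"))
  expect_equal(nrow(comps), 1L)
  expect_equal(comps$start, 1L)
  expect_equal(comps$end, 6L)
  expect_equal(comps$negatives, 3L)
  expect_true(comps$odd)

  comps <- graph_components(signed_perm(c(2, -1, -3)))
  expect_equal(comps$start, c(1L, 3L))
  expect_equal(comps$end, c(2L, 3L))
  expect_equal(comps$odd, c(TRUE, TRUE))

  check_against_dfs <- function(p) {
    comps <- graph_components(p)
    got <- mapply(function(s, e) s:e, comps$start, comps$end, SIMPLIFY = FALSE)
    expect_equal(got, brute_components(p))
    # intervals partition 1..n and hold exactly their own absolute values
    expect_equal(unlist(got), seq_along(p))
    for (r in seq_len(nrow(comps))) {
      expect_setequal(abs(unclass(p)[comps$start[r]:comps$end[r]]),
                      comps$start[r]:comps$end[r])
    }
  }
  for (p in all_signed_permutations(5)) check_against_dfs(p)
  for (s in 1:3) check_against_dfs(random_permutation(40, seed = s))
})

test_that("odd component counts split by component size", {
  expect_equal(odd_components(signed_perm(c(-3, -2, -1))),
               list(c_odd = 1L, c1_odd = 0L, c2_odd = 0L))
  expect_equal(odd_components(identity_permutation(3)),
               list(c_odd = 0L, c1_odd = 0L, c2_odd = 0L))
  expect_equal(odd_components(signed_perm(c(-1, -2, 3))),
               list(c_odd = 2L, c1_odd = 2L, c2_odd = 0L))
})

test_that("cut-edge analysis reports existence, cut status and side parities", {
  split <- cut_edge_split(signed_perm(c(-2, -3, -4, -5, 1)), 4)
  expect_true(split$exists_edge)
  expect_true(split$is_cut)
  sizes <- sort(c(split$side_a$vertex_count, split$side_b$vertex_count))
  expect_equal(sizes, c(1L, 4L))
  expect_true(split$side_a$odd)
  expect_true(split$side_b$odd)
  # side_a contains position 4, isolated once the star edge to position 5 goes
  expect_equal(split$side_a$vertex_count, 1L)

  split <- cut_edge_split(signed_perm(c(-3, -2, -5, -4, 1)), 1)
  expect_true(split$exists_edge)
  expect_false(split$is_cut)

  split <- cut_edge_split(identity_permutation(4), 2)
  expect_false(split$exists_edge)

  expect_error(cut_edge_split(identity_permutation(4), 4), "1 <= i < n")

  # cross-check cut status against a DFS recount on every adjacent edge, n = 4
  for (p in all_signed_permutations(4)) {
    for (i in 1:3) {
      split <- cut_edge_split(p, i)
      expect_equal(split$exists_edge, abs(p[i]) > abs(p[i + 1L]))
      if (!split$exists_edge) next
      # removing the edge via a transposition of the two elements changes the
      # component count iff the edge was a cut edge
      before <- length(brute_components(p))
      q <- apply_operation(p, transposition(i, i + 1L, i + 2L))
      after <- length(brute_components(q))
      expect_equal(split$is_cut, after == before + 1L)
      if (split$is_cut) {
        comp_of_i <- Filter(function(cc) i %in% cc, brute_components(p))[[1]]
        expect_equal(split$side_a$vertex_count + split$side_b$vertex_count,
                     length(comp_of_i))
      }
    }
  }
})

test_that("component extraction shifts values, keeps signs, and reconstructs", {
  expect_equal(unclass(extract_component(signed_perm(c(-2, -3, -4, -1, 5)),
                                         c(1, 4))),
               c(-2L, -3L, -4L, -1L))
  expect_equal(unclass(extract_component(signed_perm(c(1, -3, -4, -2, 5)),
                                         c(2, 4))),
               c(-2L, -3L, -1L))
  expect_equal(unclass(extract_component(identity_permutation(5), c(2, 2))), 1L)
  expect_error(extract_component(identity_permutation(5), c(1, 2)),
               "not a component")

  # concatenating extracted components and re-offsetting reconstructs the
  # permutation, and each extract has an isomorphic edge set
  for (p in all_signed_permutations(5)) {
    comps <- graph_components(p)
    rebuilt <- integer(0)
    for (r in seq_len(nrow(comps))) {
      sigma <- extract_component(p, c(comps$start[r], comps$end[r]))
      # isomorphism: inversion pairs translate position-for-position
      seg_pairs <- inversions(sigma)$pairs + comps$start[r] - 1L
      all_pairs <- inversions(p)$pairs
      in_seg <- all_pairs[, 1] >= comps$start[r] & all_pairs[, 2] <= comps$end[r]
      expect_equal(unname(seg_pairs), unname(all_pairs[in_seg, , drop = FALSE]))
      off <- comps$start[r] - 1L
      rebuilt <- c(rebuilt, ifelse(unclass(sigma) > 0, unclass(sigma) + off,
                                   unclass(sigma) - off))
    }
    expect_equal(rebuilt, as.integer(unclass(p)))
  }
})

test_that("super short and short operations drop the graph potential boundedly", {
  # Inv + c_odd falls by at most 1 per super short operation and at most 4
  # per short operation, exhaustively at n = 4
  perms <- all_signed_permutations(4)
  pot <- function(p) inversions(p)$count + odd_components(p)$c_odd
  ops_ssso <- enumerate_operations(4, "SSSO")
  ops_sso <- enumerate_operations(4, "SSO")
  sso_only <- Filter(function(o) {
    span <- if (o$kind == "reversal") o$j - o$i + 1L else o$k - o$i
    span == 3L
  }, ops_sso)
  for (p in perms) {
    before <- pot(p)
    for (op in ops_ssso) {
      expect_gte(pot(apply_operation(p, op)), before - 1L)
    }
    for (op in sso_only) {
      expect_gte(pot(apply_operation(p, op)), before - 4L)
    }
  }
})
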