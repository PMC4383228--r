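---
title: "Sorting signed permutations by length-bounded operations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting signed permutations by length-bounded operations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shortrear)
```

## The model

A unichromosomal genome with `n` genes, each with an orientation, is modelled
as a *signed permutation*: an ordering of `1..n` where every element carries a
`+` or `-` sign. Two kinds of rearrangement event act on it:

* a **signed reversal** `rho(i, j)` reverses the block at positions `i..j` and
  flips every sign in it (a `k`-reversal spans `k = j - i + 1` elements);
* a **transposition** `rho(i, j, k)` exchanges the adjacent blocks at
  positions `i..j-1` and `j..k-1` without touching signs (an
  `(x, y)`-transposition has block lengths `x = j - i`, `y = k - j`; the upper
  index may be `n + 1`).

Observations on bacterial and lower-eukaryote genomes suggest that events
affecting only one or a few neighbouring genes dominate, so this package
restricts attention to four *length-bounded* families:

| family | operations |
|--------|------------|
| `SSSR` | reversals of length at most 2 |
| `SSR`  | reversals of length at most 3 |
| `SSSO` | `SSSR` plus `(1,1)`-transpositions (adjacent swaps) |
| `SSO`  | `SSR` plus transpositions with `x + y <= 3` |

The *distance* of a permutation under a family is the minimum number of its
operations transforming the permutation into the identity `(+1 +2 ... +n)`.
For the two super short families the distance has a closed form that the
package evaluates exactly; for the two short families no polynomial exact
algorithm is known, and the package provides sorters whose operation counts
are provably within factors 5 (`SSR`) and 3 (`SSO`, tight) of optimal.

## Invariants driving the closed forms

**Inversions.** A pair of positions `i < j` with `|pi_i| > |pi_j|` is an
inversion; `Inv(pi)` counts them. A super short operation changes `Inv` by at
most 1, a short transposition by at most 2, a short reversal by at most 3
(verified exhaustively in the test suite at `n = 4`).

**The vector diagram.** Each element gets a vector of length `||pi_i| - i|`
pointing toward its home position; `Vec(pi)` is the total length. Two subsets
control sign cleanup under 2-reversals: negative elements with even vector
length and positive elements with odd vector length are exactly the elements
that end up negative after all inversions are removed, because a 2-reversal
flips two signs together with the parities of the two vector lengths. Hence
the exact super-short-reversal distance

```
d_sssr(pi) = Inv(pi) + |V^even-| + |V^odd+|
```

computed by `sssr_distance()` and realized constructively by `sssr_sort()`.

**The permutation graph.** Vertices are the elements, edges the inversion
pairs. Its components occupy consecutive position intervals holding exactly
that interval of absolute values (minimal complete substrings), so
`graph_components()` finds them in one linear scan. A component is *odd* if
it contains an odd number of negative elements. A super short operation can
remove an inversion either by an adjacent-swap transposition (signs kept) or
a 2-reversal (both signs flipped); choosing between them so that the number
of odd components never grows yields the exact distance

```
d_ssso(pi) = Inv(pi) + c_odd(pi)
```

(`ssso_distance()`, `ssso_sort()`). The choice is decided by cut-edge
analysis (`cut_edge_split()`): the 2-reversal is used exactly when the
adjacent edge is a cut edge whose two sides are both odd.

## The approximation sorters

**Short reversals (`ssr_sort()`).** While any element is displaced, the
sorter finds a *vector-opposite* pair — two vectors pointing toward each
other, each long enough to reach the other's position — and swaps their
absolute values with a ladder of 3-reversals (plus one 2-reversal when the
distance `m` is odd), `2*ceiling(m/2) - 1` operations that remove exactly
`2m` units of `Vec`. When `Vec` reaches zero, leftover negative signs are
flipped by 1-reversals. Against the lower bound
`(Vec + |V^odd| + |V^0-|) / 5` this gives a 5-approximation; when the start
has `Vec = 0` or `Vec >= 4n` the ratio is at most 3. Since the expected
`Vec` of a uniform random signed permutation is `(n^2 - 1)/3 >= 4n` for
`n >= 13`, the *expected* ratio is at most 3 for such sizes — the package
checks the distributional inputs to that argument (the per-length identity
`sum_i Pr(|v(pi_i)| = j) = 2(n - j)/n` and the mean) by enumeration and by a
seeded Monte-Carlo run at `n = 13`.

**Short operations (`sso_sort()`).** Acting always at the leftmost adjacent
inversion, the sorter dispatches on the size `m` of the component containing
it. For `m >= 5` a cut-edge analysis picks an adjacent swap or a 2-reversal
so that `Inv + c2_odd + c1_odd` falls by one per operation. Components of
size 3 or 4 are extracted (`extract_component()`), matched against a
precomputed table of shortest short-operation sorts
(`small_component_table()`), and the table sequence is replayed translated
to the component's interval; every such sequence has length at most the
component's inversion count. Two-vertex components take one operation.
Together with the lower bound `(Inv + c2_odd + c1_odd) / 3` this yields a
3-approximation, and the witness `(-3 -2 -5 -4 +1)` (ratio exactly 3) shows
the factor is tight.

## Numerical and design choices

* **Positions are 1-based** throughout the public interface, and output
  prints explicit `+` signs, matching the field's notation.
* **Tie-breaks are pinned.** Wherever a choice is theoretically free it is
  fixed so scenarios are reproducible: sorters act at the *leftmost* adjacent
  inversion; cleanup 1-reversals run in ascending position order; the
  vector-opposite pair finder takes the rightmost right vector, then the
  leftmost left vector in its reach window `(i, |pi_i|]`, with one override —
  if that yields an adjacent pair while `(i, i+2)` is 2-vector-opposite, the
  wider pair is returned (this guarantee is what the 5-approximation's
  worst-subcase analysis needs). Operations are enumerated in a single
  canonical order (reversals by ascending `(i, j)`, then transpositions by
  ascending `(i, j, k)`), which is the only tie-break in the BFS oracle and
  the small-component tables: table sequences are read off greedily by taking
  the first canonical operation that steps one unit closer to the identity.
  With these choices the exhaustive audits are bit-reproducible, and the
  audit rows for all `n <= 5` agree with the published exhaustive audit of
  both approximation algorithms to every printed digit.
* **The BFS oracle** (`build_distance_table()`) searches outward from the
  identity; families are closed under operation inverses, so first-visit
  depth equals sorting distance. States are keyed by their space-separated
  element string in a hashed environment; tables are cached per process.
  Sizes above `n = 7` (645120 states) are refused unless the cap is raised
  explicitly — refusal beats silent thrashing.
* **Audit aggregation is exact.** Ratios `count / distance` are averaged as
  integer numerators over a common denominator (the lcm of the observed
  distances), all far below 2^53, so the mean is exact; the ratio is defined
  as 1 when the exact distance is 0, which makes the identity count as
  "exact" and reproduces the 100% rows at `n = 1, 2`. Rounding is half-up to
  two decimals, applied only at presentation.
* **Lower bounds.** `ssr_lower_bound()` and `sso_lower_bound()` take the
  maximum of their two potential-function bounds (e.g. `/6` on
  `Inv + |V^even-| + |V^odd+|` and `/5` on `Vec + |V^odd| + |V^0-|`). The
  underlying analyses never combine the two; the maximum is a strengthening
  this package adopts, valid since each is individually a lower bound.

## The random model and what the tests cover

`random_permutation()` draws uniformly over all `n! * 2^n` signed
permutations: a uniform shuffle of values with an independent fair sign per
element. This is the neutral-evolution null model behind the expected-ratio
analysis; it does not emulate features of real gene orders such as
hot-spot reversals, length-biased event rates, or conserved clusters, so the
expected-ratio and distribution checks say nothing about such structure —
they validate the mathematics, not a biological fit.

Exhaustive verification is performed at deliberate desk scale: closed forms
against BFS for every permutation up to `n = 5` (3840 states), bounded-change
ledgers and swap-ladder properties at `n = 4`, audits up to `n = 5` (the
`n = 5` audits take seconds; the published audits extend to `n = 10`, about
`3.7e9` states, which is out of scope here and covered instead by the proven
ratio caps of 5 and 3 that hold at every size). The Monte-Carlo check of the
mean vector mass uses `10^4` seeded samples at `n = 13` with a 3-standard-
error acceptance band.

## Worked example

```{r}
p <- parse_permutation("+3 -4 +6 -1 +5 -2")
vec_total(p)        # total vector length: 14
inversions(p)$count # 8
sssr_distance(p)    # 8 inversions + 3 cleanup 1-reversals
ssso_distance(p)    # 8 inversions + 1 odd component
ssso_sort(p)
```

```{r}
audit("sso", 3)
```

## Limitations

* Exact distances for the short families come only from the BFS oracle, so
  they are available for `n <= 7`; polynomial exact algorithms are open
  problems.
* Linear (not circular) permutations only; sorting circular permutations by
  short operations is a genuinely different problem. Weighted-length
  operation models are likewise out of scope.
* The package computes distances; it does not build phylogenies from the
  resulting distance matrices.
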