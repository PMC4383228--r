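Package: shortrear
Title: Sorting Signed Permutations by Short Reversals and Transpositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome rearrangement distances and sorting algorithms for signed
    permutations under length-bounded operations. Implements exact
    polynomial-time solvers for sorting by super short reversals (reversals of
    length at most 2) and by super short operations (also allowing swaps of
    adjacent elements), a 5-approximation for sorting by short reversals
    (length at most 3), and a 3-approximation for sorting by short operations
    (reversals and transpositions spanning at most 3 elements). Includes the
    vector diagram and permutation graph machinery behind the bounds, an
    exhaustive breadth-first-search distance oracle over all signed
    permutations of small size, and an audit harness comparing algorithm
    output against exact distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
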