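# Sorting scenarios: validated operation sequences that realize a sort.

#' Construct a sorting scenario
#'
#' A sorting scenario is an explicit certificate: an ordered list of
#' operations, all drawn from one family, whose sequential application
#' transforms the start permutation into the identity. Construction fails if
#' any operation is outside the family or the sequence does not sort.
#'
#' @param start A signed permutation.
#' @param ops List of `rearr_op`.
#' @param family One of `"SSSR"`, `"SSR"`, `"SSSO"`, `"SSO"`.
#' @return An object of class `sorting_scenario` with fields `start`, `ops`,
#'   `family` and `length` (the operation count).
#' @export
sorting_scenario <- function(start, ops, family) {
  start <- as_signed_perm(start)
  family <- match.arg(family, OPERATION_FAMILIES)
  check <- verify_scenario(start, ops, family)
  if (!check$valid) {
    stop(sprintf("invalid scenario at step %d: %s", check$failed_step,
                 check$reason), call. = FALSE)
  }
  structure(list(start = start, ops = ops, family = family,
                 length = length(ops)),
            class = "sorting_scenario")
}

#' Verify an operation sequence against a permutation
#'
#' Checks, step by step, that every operation belongs to the family and is in
#' range, and that the final permutation is the identity. Unlike
#' [sorting_scenario()] this never errors; it reports the first failing step.
#'
#' @param p A signed permutation.
#' @param ops List of `rearr_op` (or a scenario string for
#'   [parse_operations()]).
#' @param family One of `"SSSR"`, `"SSR"`, `"SSSO"`, `"SSO"`.
#' @return List with `valid` (logical), `failed_step` (integer or `NA`;
#'   `length(ops) + 1` means the sequence ran but did not reach the
#'   identity), `reason` (character) and `result` (the final permutation).
#' @export
verify_scenario <- function(p, ops, family) {
  x <- as_perm_vec(p)
  if (is.character(ops)) ops <- parse_operations(ops)
  family <- match.arg(family, OPERATION_FAMILIES)
  n <- length(x)
  for (s in seq_along(ops)) {
    op <- ops[[s]]
    if (!inherits(op, "rearr_op")) {
      return(list(valid = FALSE, failed_step = s,
                  reason = "not an operation", result = NULL))
    }
    if (!op_valid_for_n(op, n)) {
      return(list(valid = FALSE, failed_step = s,
                  reason = sprintf("%s out of range for n = %d",
                                   format_operation(op), n),
                  result = NULL))
    }
    if (!op_in_family(op, family, n)) {
      return(list(valid = FALSE, failed_step = s,
                  reason = sprintf("%s not in family %s",
                                   format_operation(op), family),
                  result = NULL))
    }
    x <- apply_op_vec(x, op)
  }
  final <- structure(x, class = "signed_perm")
  if (!all(x == seq_len(n))) {
    return(list(valid = FALSE, failed_step = length(ops) + 1L,
                reason = "sequence does not reach the identity",
                result = final))
  }
  list(valid = TRUE, failed_step = NA_integer_, reason = "ok", result = final)
}

#' Apply a sequence of operations
#'
#' @param p A signed permutation.
#' @param ops List of `rearr_op`.
#' @return The resulting `signed_perm`.
#' @export
apply_operations <- function(p, ops) {
  x <- as_perm_vec(p)
  for (op in ops) {
    if (!op_valid_for_n(op, length(x))) {
      stop(sprintf("operation %s out of range", format_operation(op)),
           call. = FALSE)
    }
    x <- apply_op_vec(x, op)
  }
  structure(x, class = "signed_perm")
}

#' @export
print.sorting_scenario <- function(x, ...) {
  cat("sorting scenario (", x$family, ", ", x$length, " operation",
      if (x$length == 1L) "" else "s", ")\n", sep = "")
  cat("  start: ", format_permutation(x$start), "\n", sep = "")
  if (x$length > 0L) {
    cat("  ops:   ", format_operations(x$ops), "\n", sep = "")
  }
  invisible(x)
}
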