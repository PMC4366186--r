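#' Binary screening test specifications
#'
#' Constructors for the index tests evaluated by the screening pipeline. A
#' leaf test is positive when its marker is at or above the cutoff
#' (`>=` semantics for both the FINDRISC score and HbA1c). Two tests can be
#' combined in parallel (simultaneous testing: positive on *either* test) or
#' in series (sequential testing: positive on *both* tests).
#'
#' @param threshold Positivity cutoff: FINDRISC score units for
#'   [findrisc_test()], percent HbA1c for [hba1c_test()].
#' @param a,b Two `screening_test` objects to combine.
#'
#' @return An object of class `screening_test`.
#' @examples
#' combined <- parallel_or(findrisc_test(9), hba1c_test(6.5))
#' format(combined)
#' @name screening_test
NULL

new_screening_test <- function(kind, threshold = NULL, operands = NULL) {
  structure(
    list(kind = kind, threshold = threshold, operands = operands),
    class = "screening_test"
  )
}

#' @rdname screening_test
#' @export
findrisc_test <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold)) {
    abort("`threshold` must be a single FINDRISC score value.")
  }
  new_screening_test("findrisc_ge", threshold = threshold)
}

#' @rdname screening_test
#' @export
hba1c_test <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0) {
    abort("`threshold` must be a single positive HbA1c percentage.")
  }
  new_screening_test("hba1c_ge", threshold = threshold)
}

#' @rdname screening_test
#' @export
parallel_or <- function(a, b) {
  stopifnot(inherits(a, "screening_test"), inherits(b, "screening_test"))
  new_screening_test("parallel_or", operands = list(a, b))
}

#' @rdname screening_test
#' @export
serial_and <- function(a, b) {
  stopifnot(inherits(a, "screening_test"), inherits(b, "screening_test"))
  new_screening_test("serial_and", operands = list(a, b))
}

#' @export
format.screening_test <- function(x, ...) {
  switch(x$kind,
    findrisc_ge = sprintf("FINDRISC >= %g", x$threshold),
    hba1c_ge = sprintf("HbA1c >= %g%%", x$threshold),
    parallel_or = sprintf("(%s) OR (%s)", format(x$operands[[1]]),
                          format(x$operands[[2]])),
    serial_and = sprintf("(%s) AND (%s)", format(x$operands[[1]]),
                         format(x$operands[[2]]))
  )
}

#' @export
print.screening_test <- function(x, ...) {
  cat("<screening_test> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Apply a screening test to a cohort
#'
#' Evaluates a [screening_test] on every row of a scored cohort. Leaf tests
#' compare `findrisc_total` or `hba1c` against the cutoff with `>=`;
#' combinations apply logical OR (parallel / simultaneous testing) or AND
#' (serial / sequential testing) to their operands.
#'
#' @param spec A `screening_test`.
#' @param data Cohort tibble; must carry `findrisc_total` and/or `hba1c` as
#'   required by the test's leaves, with no missing values in the columns
#'   actually used.
#'
#' @return Logical vector of per-participant test positivity.
#' @export
apply_test <- function(spec, data) {
  stopifnot(inherits(spec, "screening_test"))
  data <- as_tibble(data)
  leaf <- function(col, thr, label) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` required by test %s is absent.", col, label))
    }
    x <- data[[col]]
    if (any(is.na(x))) {
      abort(sprintf("Column `%s` required by test %s has missing values.",
                    col, label))
    }
    x >= thr
  }
  switch(spec$kind,
    findrisc_ge = leaf("findrisc_total", spec$threshold, format(spec)),
    hba1c_ge = leaf("hba1c", spec$threshold, format(spec)),
    parallel_or = apply_test(spec$operands[[1]], data) |
      apply_test(spec$operands[[2]], data),
    serial_and = apply_test(spec$operands[[1]], data) &
      apply_test(spec$operands[[2]], data)
  )
}
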