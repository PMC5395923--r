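#' @keywords internal
fk_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "freekappa_error")))
}

check_count <- function(x, name, class = "freekappa_invalid_count") {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    fk_stop(sprintf("'%s' must be a single finite number", name), class)
  }
  if (x < 0 || x != round(x)) {
    fk_stop(sprintf(
      "'%s' must be a nonnegative integer count (got %s); counts are tallies of findings and are not rounded",
      name, format(x)
    ), class)
  }
  as.numeric(x)
}

#' Full 2x2 contingency table of matched ratings
#'
#' Holds the four cells of a two-rater dichotomous agreement table:
#' `a` double negatives, `b` positives reported by rater 2 only, `c` positives
#' reported by rater 1 only, `d` concordant positives.  All cells must be
#' nonnegative integers and the total `N = a + b + c + d` must be positive.
#'
#' @param a Count of findings rated negative by both raters.
#' @param b Count rated negative by rater 1 and positive by rater 2.
#' @param c Count rated positive by rater 1 and negative by rater 2.
#' @param d Count rated positive by both raters.
#' @return An object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d` and the derived total `N`.
#' @examples
#' contingency_table(a = 26, b = 1, c = 2, d = 55)
#' @export
contingency_table <- function(a, b, c, d) {
  a <- check_count(a, "a")
  b <- check_count(b, "b")
  c <- check_count(c, "c")
  d <- check_count(d, "d")
  if (a + b + c + d <= 0) {
    fk_stop("contingency table is empty: a + b + c + d must be > 0",
            "freekappa_empty_table")
  }
  structure(list(a = a, b = b, c = c, d = d, N = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 contingency table (N =", format(x$N), ")\n")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(`rater 1` = c("negative", "positive"),
                              `rater 2` = c("negative", "positive")))
  print(m)
  invisible(x)
}

#' Positive-finding counts from a free-response assessment
#'
#' In the free-response paradigm raters report only positive findings, so the
#' double-negative cell of the 2x2 table is unknown (effectively very large).
#' The observable data reduce to `b` (rater-2-only), `c` (rater-1-only) and
#' `d` (concordant-positive) counts.  At least one positive finding is
#' required.
#'
#' @param b Count of positives reported by rater 2 only.
#' @param c Count of positives reported by rater 1 only.
#' @param d Count of concordant positive findings.
#' @return An object of class `positive_counts`.
#' @examples
#' positive_counts(b = 19, c = 57, d = 173)
#' @export
positive_counts <- function(b, c, d) {
  b <- check_count(b, "b")
  c <- check_count(c, "c")
  d <- check_count(d, "d")
  if (b + c + d < 1) {
    fk_stop("no positive findings: b + c + d must be at least 1",
            "freekappa_no_positives")
  }
  structure(list(b = b, c = c, d = d), class = "positive_counts")
}

#' @export
print.positive_counts <- function(x, ...) {
  cat(sprintf("positive-finding counts: b = %s, c = %s, d = %s  (n = %s)\n",
              format(x$b), format(x$c), format(x$d),
              format(x$b + x$c + x$d)))
  invisible(x)
}

#' Coerce to positive-finding counts
#'
#' Accepts a `positive_counts` object, a numeric vector of length 3 in the
#' order `(b, c, d)`, or a list/data.frame row with components named `b`,
#' `c`, `d`.
#'
#' @param x Object to coerce.
#' @return A `positive_counts` object.
#' @export
as_positive_counts <- function(x) {
  if (inherits(x, "positive_counts")) return(x)
  if (is.numeric(x) && length(x) == 3L && is.null(names(x))) {
    return(positive_counts(x[[1L]], x[[2L]], x[[3L]]))
  }
  if ((is.list(x) || is.numeric(x)) && all(c("b", "c", "d") %in% names(x))) {
    return(positive_counts(x[["b"]], x[["c"]], x[["d"]]))
  }
  fk_stop("cannot interpret input as positive counts (need b, c, d)",
          "freekappa_bad_input")
}

#' Coerce to a 2x2 contingency table
#'
#' Accepts a `contingency_table`, a numeric vector of length 4 in the order
#' `(a, b, c, d)`, or a list with components named `a`, `b`, `c`, `d`.
#'
#' @param x Object to coerce.
#' @return A `contingency_table` object.
#' @export
as_contingency_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.numeric(x) && length(x) == 4L && is.null(names(x))) {
    return(contingency_table(x[[1L]], x[[2L]], x[[3L]], x[[4L]]))
  }
  if ((is.list(x) || is.numeric(x)) &&
      all(c("a", "b", "c", "d") %in% names(x))) {
    return(contingency_table(x[["a"]], x[["b"]], x[["c"]], x[["d"]]))
  }
  fk_stop("cannot interpret input as a 2x2 table (need a, b, c, d)",
          "freekappa_bad_input")
}

#' Per-patient positive-finding counts
#'
#' Clustered free-response data: each patient (cluster) `k` contributes
#' counts `b_k`, `c_k`, `d_k` of rater-2-only, rater-1-only and concordant
#' positive findings.  Patients without any positive finding are allowed:
#' they carry zero weight in the pooled estimate but belong in the
#' resampling frame of the cluster bootstrap.  Double negatives are not
#' representable, by design of the paradigm.
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param b,c,d Integer vectors of per-patient counts, same length as
#'   `patient_id`.
#' @return An object of classes `clustered_findings` and `data.frame` with
#'   columns `patient_id`, `b`, `c`, `d`.
#' @examples
#' clustered_findings(c("p1", "p2"), b = c(1, 0), c = c(0, 1), d = c(2, 3))
#' @export
clustered_findings <- function(patient_id, b, c, d) {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  if (n < 1L) {
    fk_stop("at least one patient is required", "freekappa_empty_input")
  }
  if (anyDuplicated(patient_id)) {
    fk_stop("patient identifiers must be unique", "freekappa_duplicate_id")
  }
  if (length(b) != n || length(c) != n || length(d) != n) {
    fk_stop("patient_id, b, c, d must have equal length", "freekappa_bad_input")
  }
  for (i in seq_len(n)) {
    check_count(b[[i]], sprintf("b[%d]", i))
    check_count(c[[i]], sprintf("c[%d]", i))
    check_count(d[[i]], sprintf("d[%d]", i))
  }
  out <- data.frame(patient_id = patient_id, b = as.numeric(b),
                    c = as.numeric(c), d = as.numeric(d),
                    stringsAsFactors = FALSE)
  class(out) <- c("clustered_findings", "data.frame")
  out
}

#' @export
print.clustered_findings <- function(x, ...) {
  cat(sprintf("clustered free-response findings: %d patients, pooled b = %s, c = %s, d = %s\n",
              nrow(x), format(sum(x$b)), format(sum(x$c)), format(sum(x$d))))
  NextMethod()
}

#' Interval estimate for the free-response kappa
#'
#' Container for a point estimate with confidence bounds on the kappa scale.
#'
#' @param point Point estimate in `[0, 1]`.
#' @param lower,upper Confidence bounds, `lower <= point <= upper`.
#' @param level Confidence level, strictly between 0 and 1.
#' @param method One of `"logit_delta"`, `"agresti_coull"`,
#'   `"clopper_pearson"`, `"cluster_bootstrap"`.
#' @param n_effective Number of positive pairs `b + c + d`, or the retained
#'   replicate count for the bootstrap.
#' @param extra Optional named list of method-specific details (e.g. dropped
#'   bootstrap replicates, seed used).
#' @return An object of class `interval_estimate`.
#' @export
interval_estimate <- function(point, lower, upper, level, method,
                              n_effective, extra = list()) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  method <- match.arg(method, c("logit_delta", "agresti_coull",
                                "clopper_pearson", "cluster_bootstrap"))
  point <- unname(point); lower <- unname(lower); upper <- unname(upper)
  if (!(lower <= point + 1e-12 && point <= upper + 1e-12)) {
    fk_stop("interval must satisfy lower <= point <= upper",
            "freekappa_bad_interval")
  }
  structure(list(point = point, lower = lower, upper = upper, level = level,
                 method = method, n_effective = n_effective, extra = extra),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("free-response kappa: %.3f  (%g%% CI %.3f to %.3f, %s, n = %s)\n",
              x$point, 100 * x$level, x$lower, x$upper,
              gsub("_", " ", x$method), format(x$n_effective)))
  invisible(x)
}
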