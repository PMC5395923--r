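#' Read clustered free-response findings from CSV
#'
#' Two dialects are supported.  `"long"` has one row per distinct
#' (adjudicated) finding with columns `patient_id, finding_id, rater1,
#' rater2` and 0/1 calls; rows with both raters positive count towards
#' `d_k`, rater-1-only towards `c_k`, rater-2-only towards `b_k`.  A row
#' with both raters negative is invalid — free-response data contain no
#' double negatives — and is reported by row number.  `"counts"` has one
#' row per patient with columns `patient_id, b, c, d`.
#'
#' Patients appearing only through findings are inferred from the long
#' dialect; all-negative patients can only be carried by the counts dialect
#' (rows with `b = c = d = 0`).
#'
#' @param path Path to a CSV file with a header.
#' @param dialect `"long"` or `"counts"`.
#' @return A [clustered_findings()] object.
#' @export
read_findings <- function(path, dialect = c("counts", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    fk_stop(sprintf("file not found: %s", path), "freekappa_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "counts") {
    need <- c("patient_id", "b", "c", "d")
    if (!all(need %in% names(df))) {
      fk_stop(sprintf("counts dialect requires columns %s",
                      paste(need, collapse = ", ")), "freekappa_io_error")
    }
    return(clustered_findings(df$patient_id, df$b, df$c, df$d))
  }
  need <- c("patient_id", "finding_id", "rater1", "rater2")
  if (!all(need %in% names(df))) {
    fk_stop(sprintf("long dialect requires columns %s",
                    paste(need, collapse = ", ")), "freekappa_io_error")
  }
  bad <- which(!(df$rater1 %in% c(0, 1)) | !(df$rater2 %in% c(0, 1)))
  if (length(bad)) {
    fk_stop(sprintf("non-binary rater value in row %d", bad[1]),
            "freekappa_validation_error")
  }
  dn <- which(df$rater1 == 0 & df$rater2 == 0)
  if (length(dn)) {
    fk_stop(sprintf(
      "row %d has both raters negative; free-response data record positive findings only",
      dn[1]), "freekappa_validation_error")
  }
  key <- paste(df$patient_id, df$finding_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    fk_stop(sprintf("duplicate finding '%s' for patient '%s'",
                    dup$finding_id, dup$patient_id),
            "freekappa_validation_error")
  }
  ids <- unique(df$patient_id)
  agg <- function(cond) {
    tab <- tapply(as.numeric(cond), df$patient_id, sum)
    as.numeric(tab[ids])
  }
  clustered_findings(ids,
                     b = agg(df$rater1 == 0 & df$rater2 == 1),
                     c = agg(df$rater1 == 1 & df$rater2 == 0),
                     d = agg(df$rater1 == 1 & df$rater2 == 1))
}

#' Write clustered findings to CSV
#'
#' Inverse of [read_findings()].  The counts dialect writes one row per
#' patient; the long dialect expands each patient's counts into one row per
#' finding with synthetic finding identifiers (all-negative patients are
#' silently droppable only in this dialect, so a warning notes them).
#'
#' @param clusters A [clustered_findings()] object.
#' @param path Output CSV path.
#' @param dialect `"counts"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_findings <- function(clusters, path, dialect = c("counts", "long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(clusters, "clustered_findings"))
  if (dialect == "counts") {
    utils::write.csv(as.data.frame(unclass(clusters))[
      , c("patient_id", "b", "c", "d")], path, row.names = FALSE,
      quote = FALSE)
    return(invisible(path))
  }
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    n <- clusters$b[i] + clusters$c[i] + clusters$d[i]
    if (n == 0) return(NULL)
    data.frame(
      patient_id = clusters$patient_id[i],
      finding_id = sprintf("F%03d", seq_len(n)),
      rater1 = rep(c(0, 1, 1), c(clusters$b[i], clusters$c[i], clusters$d[i])),
      rater2 = rep(c(1, 0, 1), c(clusters$b[i], clusters$c[i], clusters$d[i])),
      stringsAsFactors = FALSE)
  })
  n_dropped <- sum(vapply(rows, is.null, logical(1)))
  if (n_dropped > 0) {
    warning(sprintf(
      "%d all-negative patient(s) cannot be represented in the long dialect and were omitted",
      n_dropped))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
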