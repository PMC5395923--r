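#' Generative model of a clustered free-response rating study
#'
#' Describes a study in which each patient carries a Poisson number of true
#' lesions, each rater detects each lesion independently with a per-lesion
#' sensitivity, and each rater additionally produces a Poisson number of
#' false-positive findings per patient.  False positives never match between
#' raters (a conservative simplification: matching of spurious findings is
#' rater-protocol-specific), and lesion matching by the adjudicator is
#' assumed error-free.
#'
#' With no false positives, a lesion seen by at least one rater is seen by
#' both with probability `s1*s2 / (s1 + s2 - s1*s2)`, so the pooled
#' free-response kappa converges to the harmonic-mean form
#' `2*s1*s2 / (s1 + s2)` as the study grows — and to `s` itself when both
#' sensitivities equal `s`.
#'
#' @param n_patients Number of patients.
#' @param lesion_rate Mean number of true lesions per patient (Poisson).
#' @param sens1,sens2 Per-lesion detection probability of each rater, in
#'   `[0, 1]`.
#' @param fp1,fp2 Mean false-positive findings per patient per rater
#'   (Poisson).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `study_model`.
#' @export
study_model <- function(n_patients, lesion_rate, sens1, sens2,
                        fp1 = 0, fp2 = 0, seed = NULL) {
  n_patients <- check_count(n_patients, "n_patients")
  stopifnot(n_patients >= 1, lesion_rate >= 0,
            sens1 >= 0, sens1 <= 1, sens2 >= 0, sens2 <= 1,
            fp1 >= 0, fp2 >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 lesion_rate = lesion_rate, sens1 = sens1, sens2 = sens2,
                 fp1 = fp1, fp2 = fp2, seed = seed),
            class = "study_model")
}

#' Simulate a clustered free-response study
#'
#' Draws per-patient findings under a [study_model()]: true lesions are
#' Poisson, each rater detects each lesion independently, lesions detected
#' by both raters become concordant positives (`d_k`), lesions detected by
#' exactly one become discordant (`c_k` for rater 1 only, `b_k` for rater 2
#' only), and lesions missed by both are never recorded — the free-response
#' paradigm has no double negatives.  Rater false positives add to the
#' discordant counts.
#'
#' @param model A [study_model()].
#' @return A [clustered_findings()] object with `n_patients` rows.
#' @examples
#' m <- study_model(50, lesion_rate = 3, sens1 = 0.8, sens2 = 0.8, seed = 1)
#' free_response_kappa(pooled_counts(generate_study(m)))
#' @export
generate_study <- function(model) {
  stopifnot(inherits(model, "study_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  np <- model$n_patients
  lesions <- stats::rpois(np, model$lesion_rate)
  b <- c <- d <- numeric(np)
  for (k in seq_len(np)) {
    L <- lesions[k]
    if (L > 0) {
      seen1 <- stats::runif(L) < model$sens1
      seen2 <- stats::runif(L) < model$sens2
      d[k] <- sum(seen1 & seen2)
      c[k] <- sum(seen1 & !seen2)
      b[k] <- sum(!seen1 & seen2)
    }
    # false positives never match between raters: rater 1's go to c, rater 2's to b
  }
  c <- c + stats::rpois(np, model$fp1)
  b <- b + stats::rpois(np, model$fp2)
  clustered_findings(sprintf("P%04d", seq_len(np)), b = b, c = c, d = d)
}

#' Matched-rating tables from the paediatric whole-body MRI study
#'
#' The embedded case study: 84 children underwent full-body MRI, two
#' radiologists independently reported all lesions, and a third radiologist
#' matched the reports, identifying 249 distinct lesions in 58 children.
#' Returns the pooled lesion-level positive counts and the three
#' region-of-interest aggregations (patient level, 9 regions per patient,
#' 95 regions per patient) as complete 2x2 tables.
#'
#' @return A named list:
#' \describe{
#'   \item{lesion_counts}{[positive_counts()] `(b = 19, c = 57, d = 173)`.}
#'   \item{patient_table}{[contingency_table()] `(26, 1, 2, 55)`, N = 84.}
#'   \item{intermediate_table}{[contingency_table()] `(640, 8, 21, 87)`,
#'     N = 756 (9 regions per patient).}
#'   \item{detailed_table}{[contingency_table()] `(7743, 18, 53, 166)`,
#'     N = 7980 (95 regions per patient).}
#'   \item{metadata}{list with `n_patients = 84`,
#'     `n_patients_with_lesions = 58`, `n_distinct_lesions = 249`,
#'     `max_lesions_per_patient = 17`, `n_distinct_lesion_sites = 95`.}
#' }
#' @examples
#' fx <- case_study_fixtures()
#' free_response_kappa(fx$lesion_counts)        # 0.820
#' cohen_kappa(fx$patient_table)                # 0.919
#' @export
case_study_fixtures <- function() {
  list(
    lesion_counts = positive_counts(b = 19, c = 57, d = 173),
    patient_table = contingency_table(a = 26, b = 1, c = 2, d = 55),
    intermediate_table = contingency_table(a = 640, b = 8, c = 21, d = 87),
    detailed_table = contingency_table(a = 7743, b = 18, c = 53, d = 166),
    metadata = list(n_patients = 84L, n_patients_with_lesions = 58L,
                    n_distinct_lesions = 249L,
                    max_lesions_per_patient = 17L,
                    n_distinct_lesion_sites = 95L)
  )
}
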