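#' Cohen's kappa for two raters from a 2x2 table
#'
#' Chance-corrected agreement \eqn{(P_o - P_e)/(1 - P_e)} for two raters and
#' a dichotomous rating, computed in closed form from the table cells as
#' \deqn{K = \frac{2(ad - bc)}{(b + c)N + 2(ad - bc)}.}
#'
#' @param table A [contingency_table()], or anything accepted by
#'   [as_contingency_table()].
#' @return Cohen's kappa, a number in `[-1, 1]`.
#' @section Errors: Signals a `freekappa_undefined_kappa` error when the
#'   denominator is exactly zero (e.g. `b = c = 0` with `ad = bc`), where
#'   chance-corrected agreement is undefined.
#' @examples
#' cohen_kappa(contingency_table(a = 26, b = 1, c = 2, d = 55))  # 0.919
#' @export
cohen_kappa <- function(table) {
  t <- as_contingency_table(table)
  num <- 2 * (t$a * t$d - t$b * t$c)
  den <- (t$b + t$c) * t$N + num
  if (den == 0) {
    fk_stop(paste0(
      "Cohen's kappa is undefined for this table: the denominator ",
      "(b+c)N + 2(ad-bc) is zero, so expected agreement equals 1 and no ",
      "chance correction is possible"), "freekappa_undefined_kappa")
  }
  num / den
}

#' Free-response kappa
#'
#' Agreement beyond chance when only positive findings are recorded.  It is
#' the limit of Cohen's kappa as the (unknown) number of double-negative
#' observations grows without bound:
#' \deqn{K_{FR} = \frac{2d}{b + c + 2d},}
#' the proportion of confirmed positive individual ratings (\eqn{2d}) among
#' all positive individual ratings made by the two raters (\eqn{b + c + 2d}).
#'
#' `d = 0` cleanly gives 0 (no confirmed positives) and `b = c = 0` gives 1
#' (every positive confirmed); only the all-zero case is an error.
#'
#' @param counts A [positive_counts()] object, a numeric vector `(b, c, d)`,
#'   or anything accepted by [as_positive_counts()].
#' @return The free-response kappa, a number in `[0, 1]`.
#' @examples
#' free_response_kappa(positive_counts(b = 19, c = 57, d = 173))  # 0.820
#' @export
free_response_kappa <- function(counts) {
  k <- as_positive_counts(counts)
  2 * k$d / (k$b + k$c + 2 * k$d)
}

#' Proportion of congruent positive pairs and its kappa transform
#'
#' The free-response kappa is a monotone transform of the proportion
#' \eqn{p = d/(b + c + d)} of congruent pairs among all positive pairs:
#' \eqn{K_{FR} = 2p/(1 + p)}, with inverse \eqn{p = K/(2 - K)}.  These two
#' helpers apply the transform and its inverse elementwise.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param kappa Kappa value(s) in `[0, 1]`.
#' @return Numeric vector of the same length.
#' @examples
#' p_to_kappa(1 / 3)   # 0.5
#' kappa_to_p(0.5)     # 1/3
#' @export
p_to_kappa <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p / (1 + p)
}

#' @rdname p_to_kappa
#' @export
kappa_to_p <- function(kappa) {
  stopifnot(is.numeric(kappa), all(kappa >= 0 & kappa <= 1, na.rm = TRUE))
  kappa / (2 - kappa)
}

#' Cohen's kappa as a function of the double-negative count
#'
#' Completes the free-response counts `(b, c, d)` with each candidate
#' double-negative total `a` and evaluates Cohen's kappa on the resulting
#' 2x2 table.  Kappa increases monotonically in `a` and converges to the
#' free-response kappa, so the curve shows how far a finite enumeration of
#' negatives understates agreement.
#'
#' `a_values` are totals over the whole study.  When negatives are more
#' naturally counted as potential finding sites per patient, use
#' `sites_per_patient` together with `n_patients`: the double-negative total
#' is then `n_patients * sites_per_patient - (b + c + d)`.
#'
#' @param counts Positive-finding counts (see [as_positive_counts()]).
#' @param a_values Nonnegative numbers of double-negative observations.
#' @param sites_per_patient Alternative to `a_values`: potential finding
#'   sites per patient.
#' @param n_patients Number of patients; required with `sites_per_patient`.
#' @return A data.frame with columns `a` and `kappa` (plus
#'   `sites_per_patient` when that interface is used).
#' @examples
#' kappa_curve(positive_counts(19, 57, 173), a_values = c(1179, 7731))
#' kappa_curve(positive_counts(19, 57, 173),
#'             sites_per_patient = c(17, 95), n_patients = 84)
#' @export
kappa_curve <- function(counts, a_values = NULL, sites_per_patient = NULL,
                        n_patients = NULL) {
  k <- as_positive_counts(counts)
  sites <- NULL
  if (is.null(a_values)) {
    if (is.null(sites_per_patient) || is.null(n_patients)) {
      fk_stop("supply a_values, or sites_per_patient with n_patients",
              "freekappa_bad_input")
    }
    n_patients <- check_count(n_patients, "n_patients")
    sites <- sites_per_patient
    a_values <- n_patients * sites_per_patient - (k$b + k$c + k$d)
    if (any(a_values < 0)) {
      fk_stop("sites_per_patient * n_patients must be at least b + c + d",
              "freekappa_bad_input")
    }
  }
  kap <- vapply(a_values, function(a) {
    cohen_kappa(contingency_table(a, k$b, k$c, k$d))
  }, numeric(1))
  out <- data.frame(a = as.numeric(a_values), kappa = kap)
  if (!is.null(sites)) out <- cbind(sites_per_patient = sites, out)
  out
}

#' Pool per-patient counts into study totals
#'
#' Collapses the per-patient 2x2 tables of a clustered study into the single
#' table of pooled positive counts.  Because patients without positive
#' findings contribute zeros, pooling is invariant to their presence.
#'
#' @param clusters A [clustered_findings()] object.
#' @return A [positive_counts()] object with `b`, `c`, `d` summed over
#'   patients.
#' @export
pooled_counts <- function(clusters) {
  if (!inherits(clusters, "clustered_findings")) {
    fk_stop("expected a clustered_findings object", "freekappa_bad_input")
  }
  if (nrow(clusters) < 1L) {
    fk_stop("no patients in input", "freekappa_empty_input")
  }
  positive_counts(sum(clusters$b), sum(clusters$c), sum(clusters$d))
}

#' Decompose the pooled free-response kappa over patients
#'
#' The pooled free-response kappa is exactly a weighted average of
#' per-patient free-response kappas, with weight
#' \eqn{\nu_k = (b_k + c_k + 2d_k)/(b + c + 2d)} — each patient's share of
#' all positive individual ratings.  Patients without positive findings get
#' weight 0 and an undefined (NA) per-patient kappa.  The decomposition
#' holds for any partition of the data, so the same weights serve to compare
#' agreement across subgroups.
#'
#' @param clusters A [clustered_findings()] object with at least one
#'   positive finding overall.
#' @return A data.frame with columns `patient_id`, `weight`, `kappa`; the
#'   weights sum to 1 and `sum(weight * kappa)` (over positive patients)
#'   equals the pooled free-response kappa.
#' @examples
#' cl <- clustered_findings(c("p1", "p2"), b = c(0, 1), c = c(0, 1),
#'                          d = c(1, 0))
#' cluster_decomposition(cl)  # weights 0.5/0.5, kappas 1/0, pooled 0.5
#' @export
cluster_decomposition <- function(clusters) {
  pooled <- pooled_counts(clusters)  # validates, errors if all zero
  tot <- pooled$b + pooled$c + 2 * pooled$d
  per <- clusters$b + clusters$c + 2 * clusters$d
  weight <- per / tot
  kappa <- ifelse(per > 0, 2 * clusters$d / per, NA_real_)
  data.frame(patient_id = clusters$patient_id, weight = weight,
             kappa = kappa, stringsAsFactors = FALSE)
}
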