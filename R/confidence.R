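#' Delta-method variance of the logit free-response kappa
#'
#' Because the free-response kappa is bounded by 0 and 1, interval
#' estimation works on the logit scale.  For independent positive pairs the
#' delta-method variance is
#' \deqn{Var(logit\,K_{FR}) = \frac{b + c + d}{(b + c)\,d}.}
#'
#' @param counts Positive-finding counts (see [as_positive_counts()]).
#' @return The variance, a positive number.
#' @section Errors: Signals `freekappa_degenerate_counts` when `d = 0` or
#'   `b + c = 0`: the logit of 0 or 1 is undefined and the method does not
#'   apply.
#' @examples
#' logit_variance(positive_counts(19, 57, 173))  # 249/13148
#' @export
logit_variance <- function(counts) {
  k <- as_positive_counts(counts)
  if (k$d < 1 || k$b + k$c < 1) {
    fk_stop(paste0(
      "logit delta method not applicable: requires d >= 1 and b + c >= 1 ",
      "(the logit of a kappa of exactly 0 or 1 is undefined)"),
      "freekappa_degenerate_counts")
  }
  (k$b + k$c + k$d) / ((k$b + k$c) * k$d)
}

#' Logit delta-method confidence interval
#'
#' Builds a normal interval for `logit(K_FR)` using [logit_variance()] and
#' back-transforms the bounds to the kappa scale.  Bounds are strictly
#' inside (0, 1).
#'
#' @param counts Positive-finding counts with `d >= 1` and `b + c >= 1`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return An [interval_estimate()] with method `"logit_delta"`.
#' @examples
#' logit_delta_ci(positive_counts(19, 57, 173))
#' @export
logit_delta_ci <- function(counts, level = 0.95) {
  k <- as_positive_counts(counts)
  v <- logit_variance(k)
  est <- free_response_kappa(k)
  z <- stats::qnorm((1 + level) / 2)
  logit_est <- log(est / (1 - est))
  lower <- stats::plogis(logit_est - z * sqrt(v))
  upper <- stats::plogis(logit_est + z * sqrt(v))
  interval_estimate(est, lower, upper, level, "logit_delta",
                    n_effective = k$b + k$c + k$d)
}

#' Map an interval for p onto the kappa scale
#'
#' The transform \eqn{K = 2p/(1+p)} linking the congruent-pair proportion
#' `p = d/(b+c+d)` to the free-response kappa is monotone increasing, so a
#' confidence interval for the binomial proportion `p` maps endpoint-by-
#' endpoint to an interval for kappa.
#'
#' @param p_lower,p_upper Bounds for `p`, with
#'   `0 <= p_lower <= p_upper <= 1`.
#' @return Numeric vector `c(kappa_lower, kappa_upper)`.
#' @examples
#' p_interval_to_kappa(1 / 3, 3 / 5)  # c(0.5, 0.75)
#' @export
p_interval_to_kappa <- function(p_lower, p_upper) {
  stopifnot(is.numeric(p_lower), is.numeric(p_upper),
            p_lower >= 0, p_upper <= 1, p_lower <= p_upper)
  c(p_to_kappa(p_lower), p_to_kappa(p_upper))
}

# Agresti-Coull bounds for x successes in n trials, clipped to [0, 1].
# Vectorised over x; used both by the user-facing CI and the simulation.
ac_bounds <- function(x, n, level) {
  z <- stats::qnorm((1 + level) / 2)
  ntilde <- n + z^2
  ptilde <- (x + z^2 / 2) / ntilde
  half <- z * sqrt(ptilde * (1 - ptilde) / ntilde)
  cbind(lower = pmax(0, ptilde - half), upper = pmin(1, ptilde + half))
}

# Clopper-Pearson (exact beta-quantile) bounds, vectorised over x.
cp_bounds <- function(x, n, level) {
  alpha <- 1 - level
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

#' Agresti-Coull confidence interval for the free-response kappa
#'
#' Treats the concordant count `d` as `x` successes in `n = b + c + d`
#' binomial trials for the congruent-pair proportion `p`, forms the
#' Agresti-Coull add-z-squared interval for `p` (clipped to `[0, 1]`, since
#' the method can overshoot at the extremes), and maps it to the kappa
#' scale via [p_interval_to_kappa()].  Well-defined for `d = 0` and
#' `d = n`, unlike the logit method.
#'
#' @inheritParams logit_delta_ci
#' @return An [interval_estimate()] with method `"agresti_coull"`.
#' @examples
#' agresti_coull_ci(positive_counts(19, 57, 173))
#' @export
agresti_coull_ci <- function(counts, level = 0.95) {
  k <- as_positive_counts(counts)
  n <- k$b + k$c + k$d
  bounds <- ac_bounds(k$d, n, level)
  kap <- p_interval_to_kappa(bounds[1, "lower"], bounds[1, "upper"])
  interval_estimate(free_response_kappa(k), kap[1], kap[2], level,
                    "agresti_coull", n_effective = n)
}

#' Clopper-Pearson confidence interval for the free-response kappa
#'
#' Exact beta-quantile interval for the congruent-pair proportion `p` with
#' `x = d` successes in `n = b + c + d` trials, mapped to the kappa scale.
#' The lower bound is exactly 0 when `d = 0` and the upper bound exactly 1
#' when `d = n`.  Coverage is guaranteed at or above the nominal level, at
#' the cost of wider intervals than the other methods.
#'
#' @inheritParams logit_delta_ci
#' @return An [interval_estimate()] with method `"clopper_pearson"`.
#' @examples
#' clopper_pearson_ci(positive_counts(19, 57, 173))
#' @export
clopper_pearson_ci <- function(counts, level = 0.95) {
  k <- as_positive_counts(counts)
  n <- k$b + k$c + k$d
  bounds <- cp_bounds(k$d, n, level)
  kap <- p_interval_to_kappa(bounds[1, "lower"], bounds[1, "upper"])
  interval_estimate(free_response_kappa(k), kap[1], kap[2], level,
                    "clopper_pearson", n_effective = n)
}

#' Cluster-bootstrap confidence interval for clustered studies
#'
#' When patients contribute several findings, positive pairs are not
#' independent and the closed-form variance is biased.  This interval
#' resamples whole patients with replacement (a patient is the random
#' factor; findings within a patient travel together), pools the counts of
#' each resample, and computes the free-response kappa per replicate.
#' All-negative patients stay in the resampling frame: they carry zero
#' weight in any replicate but keep the sampling honest.
#'
#' Replicates in which the resample contains no positive finding at all are
#' dropped and counted; a warning is emitted when more than 1% are dropped,
#' and an error when none remain.
#'
#' @param clusters A [clustered_findings()] object with at least one
#'   positive finding.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param replicates Number of bootstrap resamples; default 10000.
#' @param seed Integer seed for reproducibility.  When `NULL`, a seed is
#'   drawn from R's RNG and reported in a message so the run can be
#'   repeated.
#' @param type `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, with a leave-one-patient-out jackknife for the
#'   acceleration).
#' @return An [interval_estimate()] with method `"cluster_bootstrap"`;
#'   `n_effective` is the number of retained replicates and
#'   `$extra` records the seed, dropped-replicate count and interval type.
#' @examples
#' cl <- clustered_findings(paste0("p", 1:4), b = c(1, 0, 2, 0),
#'                          c = c(0, 1, 0, 0), d = c(3, 2, 4, 1))
#' cluster_bootstrap_ci(cl, replicates = 500, seed = 7)
#' @export
cluster_bootstrap_ci <- function(clusters, level = 0.95, replicates = 10000,
                                 seed = NULL,
                                 type = c("percentile", "bca")) {
  type <- match.arg(type)
  stopifnot(replicates >= 1)
  pooled <- pooled_counts(clusters)  # errors if no positives anywhere
  est <- free_response_kappa(pooled)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("cluster_bootstrap_ci: no seed supplied; using entropy-derived seed ",
            seed)
  }
  nk <- nrow(clusters)
  boot <- local({
    set.seed(seed)
    idx <- matrix(sample.int(nk, nk * replicates, replace = TRUE),
                  nrow = replicates)
    bs <- matrix(clusters$b[idx], nrow = replicates)
    cs <- matrix(clusters$c[idx], nrow = replicates)
    ds <- matrix(clusters$d[idx], nrow = replicates)
    b <- rowSums(bs); c <- rowSums(cs); d <- rowSums(ds)
    list(kappa = 2 * d / (b + c + 2 * d), total = b + c + 2 * d)
  })
  ok <- boot$total > 0
  dropped <- sum(!ok)
  if (!any(ok)) {
    fk_stop("all bootstrap replicates were degenerate (no positive findings)",
            "freekappa_bootstrap_failure")
  }
  if (dropped / replicates > 0.01) {
    warning(sprintf(
      "%d of %d bootstrap replicates (%.1f%%) had no positive findings and were dropped",
      dropped, replicates, 100 * dropped / replicates))
  }
  kb <- boot$kappa[ok]
  alpha <- 1 - level
  if (type == "percentile") {
    qs <- stats::quantile(kb, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          type = 7)
  } else {
    z0 <- stats::qnorm(pmin(pmax(mean(kb < est) + 0.5 * mean(kb == est),
                                 1 / (2 * length(kb))),
                            1 - 1 / (2 * length(kb))))
    # leave-one-patient-out jackknife for the acceleration constant
    tb <- sum(clusters$b); tc <- sum(clusters$c); td <- sum(clusters$d)
    jack <- vapply(seq_len(nk), function(i) {
      b <- tb - clusters$b[i]; c <- tc - clusters$c[i]; d <- td - clusters$d[i]
      if (b + c + 2 * d == 0) return(NA_real_)
      2 * d / (b + c + 2 * d)
    }, numeric(1))
    jack <- jack[is.finite(jack)]
    dev <- mean(jack) - jack
    denom <- 6 * sum(dev^2)^1.5
    a <- if (denom > 0) sum(dev^3) / denom else 0
    zlo <- stats::qnorm(alpha / 2); zhi <- stats::qnorm(1 - alpha / 2)
    adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
    qs <- stats::quantile(kb, c(adj(zlo), adj(zhi)), names = FALSE, type = 7)
  }
  interval_estimate(est, min(qs[1], est), max(qs[2], est), level,
                    "cluster_bootstrap", n_effective = sum(ok),
                    extra = list(seed = seed, replicates = replicates,
                                 dropped = dropped, type = type))
}
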