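test_that("logit variance evaluates (b+c+d)/((b+c)d) and rejects degenerate counts", {
  expect_equal(logit_variance(positive_counts(19, 57, 173)), 249 / 13148)
  expect_equal(logit_variance(positive_counts(1, 1, 2)), 1)
  expect_error(logit_variance(positive_counts(0, 0, 5)),
               class = "freekappa_degenerate_counts")
  expect_error(logit_variance(positive_counts(3, 2, 0)),
               class = "freekappa_degenerate_counts")
})

test_that("logit variance matches an independent numeric delta-method computation", {
  # oracle: K_FR = g(p) with g(p) = 2p/(1+p) on the logit scale is
  # logit(g(p)) = log(2p/(1-p)); differentiate numerically and apply the
  # delta method to Var(p_hat) = p(1-p)/n
  set.seed(606)
  for (i in 1:50) {
    k <- random_nondegenerate_counts()
    n <- k$b + k$c + k$d
    p <- k$d / n
    h <- 1e-6
    g <- function(p) log(2 * p / (1 - p))
    grad <- (g(p + h) - g(p - h)) / (2 * h)
    oracle <- grad^2 * p * (1 - p) / n
    expect_equal(logit_variance(k), oracle, tolerance = 1e-6)
  }
})

test_that("logit delta interval brackets the estimate and narrows with more data", {
  ci <- logit_delta_ci(positive_counts(19, 57, 173), 0.95)
  expect_lt(ci$lower, ci$point)
  expect_gt(ci$upper, ci$point)
  expect_equal(ci$point, 0.820, tolerance = 5e-4)
  # width on the logit scale is 2z*sqrt(Var)
  z <- qnorm(0.975)
  v <- 249 / 13148
  logit_width <- log(ci$upper / (1 - ci$upper)) - log(ci$lower / (1 - ci$lower))
  expect_equal(logit_width, 2 * z * sqrt(v), tolerance = 1e-10)
  # doubling every count roughly halves the variance: strictly narrower CI
  ci2 <- logit_delta_ci(positive_counts(38, 114, 346), 0.95)
  expect_lt(ci2$upper - ci2$lower, ci$upper - ci$lower)
  expect_equal(ci2$point, ci$point)
})

test_that("p-scale intervals map monotonically onto the kappa scale", {
  expect_equal(p_interval_to_kappa(0, 1), c(0, 1))
  expect_equal(p_interval_to_kappa(0.5, 0.5), c(2 / 3, 2 / 3))
  expect_equal(p_interval_to_kappa(1 / 3, 3 / 5), c(0.5, 0.75))
  set.seed(707)
  for (i in 1:20) {
    p <- sort(runif(2))
    out <- p_interval_to_kappa(p[1], p[2])
    expect_true(out[1] <= out[2])
  }
})

test_that("Agresti-Coull interval matches an independently coded formula", {
  # oracle written out from the add-z^2/2-successes definition
  ac_oracle <- function(x, n, level) {
    z <- qnorm((1 + level) / 2)
    nt <- n + z^2
    pt <- (x + z^2 / 2) / nt
    se <- sqrt(pt * (1 - pt) / nt)
    c(max(0, pt - z * se), min(1, pt + z * se))
  }
  set.seed(808)
  for (i in 1:50) {
    k <- random_positive_counts()
    n <- k$b + k$c + k$d
    ci <- agresti_coull_ci(k, 0.9)
    oracle <- p_interval_to_kappa(ac_oracle(k$d, n, 0.9)[1],
                                  ac_oracle(k$d, n, 0.9)[2])
    expect_equal(c(ci$lower, ci$upper), oracle, tolerance = 1e-12)
    expect_true(ci$lower <= ci$point && ci$point <= ci$upper)
  }
  # boundary: all positives concordant -> upper bound clipped to 1
  ci <- agresti_coull_ci(positive_counts(0, 0, 20), 0.95)
  expect_equal(ci$upper, 1)
  expect_lt(ci$lower, 1)
})

test_that("Agresti-Coull width shrinks like 1/sqrt(n) at fixed proportion", {
  widths <- vapply(c(1, 4, 16, 64), function(m) {
    ci <- agresti_coull_ci(positive_counts(5 * m, 5 * m, 10 * m), 0.95)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.15)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.1)
})

test_that("Clopper-Pearson interval agrees with binom.test and is exact at the edges", {
  set.seed(909)
  for (i in 1:50) {
    k <- random_positive_counts()
    n <- k$b + k$c + k$d
    ci <- clopper_pearson_ci(k, 0.95)
    oracle <- as.numeric(binom.test(k$d, n)$conf.int)  # independent CP source
    expect_equal(c(ci$lower, ci$upper),
                 p_interval_to_kappa(oracle[1], oracle[2]), tolerance = 1e-9)
  }
  expect_equal(clopper_pearson_ci(positive_counts(5, 5, 0), 0.95)$lower, 0)
  expect_equal(clopper_pearson_ci(positive_counts(0, 0, 10), 0.95)$upper, 1)
})

test_that("cluster bootstrap is deterministic given a seed and collapses without between-patient variance", {
  same <- clustered_findings(paste0("p", 1:10), b = rep(1, 10), c = rep(1, 10),
                             d = rep(1, 10))
  ci <- cluster_bootstrap_ci(same, replicates = 500, seed = 11)
  expect_equal(ci$lower, 0.5)
  expect_equal(ci$upper, 0.5)
  expect_equal(ci$point, 0.5)

  single <- clustered_findings("p1", b = 2, c = 1, d = 5)
  ci1 <- cluster_bootstrap_ci(single, replicates = 200, seed = 3)
  expect_equal(ci1$lower, ci1$point)
  expect_equal(ci1$upper, ci1$point)

  set.seed(1010)
  cl <- random_clusters(n_patients = 12)
  a <- cluster_bootstrap_ci(cl, replicates = 2000, seed = 99)
  b <- cluster_bootstrap_ci(cl, replicates = 2000, seed = 99)
  expect_identical(a[c("point", "lower", "upper")],
                   b[c("point", "lower", "upper")])
  c <- cluster_bootstrap_ci(cl, replicates = 2000, seed = 100)
  expect_false(identical(a[c("lower", "upper")], c[c("lower", "upper")]))
})

test_that("cluster bootstrap reports degenerate replicates and supports BCa", {
  # one positive patient among many all-negative ones: many resamples miss it
  sparse <- clustered_findings(paste0("p", 1:50),
                               b = c(1, rep(0, 49)), c = c(1, rep(0, 49)),
                               d = c(2, rep(0, 49)))
  expect_warning(
    ci <- cluster_bootstrap_ci(sparse, replicates = 200, seed = 5),
    "dropped")
  expect_lt(ci$n_effective, 200)
  expect_equal(ci$extra$dropped + ci$n_effective, 200)

  set.seed(1111)
  cl <- random_clusters(n_patients = 15)
  bca <- cluster_bootstrap_ci(cl, replicates = 2000, seed = 21, type = "bca")
  expect_true(bca$lower <= bca$point && bca$point <= bca$upper)
  expect_identical(bca$extra$type, "bca")
})

test_that("interval containers validate their invariants", {
  expect_error(interval_estimate(0.5, 0.6, 0.9, 0.95, "logit_delta", 10),
               class = "freekappa_bad_interval")
  expect_error(interval_estimate(0.5, 0.4, 0.9, 1.5, "logit_delta", 10))
})
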