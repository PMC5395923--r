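#' Configuration for one coverage-simulation cell
#'
#' One cell of the coverage study: samples of `n` positive pairs are drawn
#' with concordant count `d ~ Binomial(n, p)` where
#' `p = kappa_target / (2 - kappa_target)`, and the requested interval
#' methods are evaluated against the true kappa.
#'
#' @param n Positive pairs per sample (`n = b + c + d`).
#' @param kappa_target True free-response kappa in (0, 1).
#' @param replicates Number of Monte-Carlo replicates.
#' @param level Confidence level; default 0.95.
#' @param seed Integer seed for the cell.
#' @param methods Subset of `c("logit_delta", "agresti_coull",
#'   "clopper_pearson")`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n, kappa_target, replicates = 50000,
                              level = 0.95, seed = 1L,
                              methods = c("logit_delta", "agresti_coull",
                                          "clopper_pearson")) {
  n <- check_count(n, "n")
  stopifnot(n >= 1, replicates >= 1,
            kappa_target > 0, kappa_target < 1,
            level > 0, level < 1)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("logit_delta", "agresti_coull",
                                   "clopper_pearson"))
  structure(list(n = as.integer(n), kappa_target = kappa_target,
                 replicates = as.integer(replicates), level = level,
                 seed = as.integer(seed), methods = methods),
            class = "simulation_config")
}

#' Draw free-response samples under a target kappa
#'
#' Inverts `K = 2p/(1+p)` to `p = K/(2-K)` and draws the concordant count
#' `d ~ Binomial(n, p)`; the remaining `n - d` discordant pairs are assigned
#' to `b` (the b/c split is statistically inert: every implemented statistic
#' depends on `b + c` only).  Uses the current RNG state; call `set.seed()`
#' for reproducibility.
#'
#' @param n Positive pairs per sample.
#' @param kappa_target True kappa in (0, 1).
#' @param size Number of samples to draw.
#' @return A data.frame with columns `d`, `b` (= `n - d`) and `c` (= 0).
#' @export
draw_sample <- function(n, kappa_target, size = 1) {
  stopifnot(n >= 1, kappa_target > 0, kappa_target < 1, size >= 1)
  p <- kappa_to_p(kappa_target)
  d <- stats::rbinom(size, n, p)
  data.frame(d = d, b = n - d, c = 0L)
}

#' Run one coverage-simulation cell
#'
#' For each replicate, draws `d ~ Binomial(n, p)`, computes the observed
#' free-response kappa `2d/(n + d)` and the requested confidence intervals,
#' and tallies coverage of the true kappa and interval widths (on the kappa
#' scale).  Degenerate samples (`d = 0` or `d = n`), where the logit-scale
#' interval is undefined, are counted as non-coverage for the logit method
#' and excluded from its mean width; the Agresti-Coull and Clopper-Pearson
#' intervals are always computable and use every replicate.  The coverage of
#' the logit method restricted to non-degenerate samples is also reported.
#'
#' @param config A [simulation_config()].
#' @return A data.frame with one row per method and columns `n`,
#'   `kappa_target`, `mean_kappa`, `degenerate_frac`, `method`, `coverage`,
#'   `coverage_excl_degenerate` (logit method only, NA otherwise),
#'   `mean_width`, `replicates`, `seed`.
#' @examples
#' run_cell(simulation_config(20, 0.3, replicates = 2000, seed = 42))
#' @export
run_cell <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  p <- kappa_to_p(config$kappa_target)
  set.seed(config$seed)
  d <- stats::rbinom(config$replicates, n, p)

  kappa_hat <- 2 * d / (n + d)         # b + c = n - d, so denominator n + d
  degenerate <- d == 0L | d == n
  target <- config$kappa_target

  rows <- lapply(config$methods, function(m) {
    if (m == "logit_delta") {
      ok <- !degenerate
      v <- n / ((n - d[ok]) * d[ok])   # (b+c+d)/((b+c) d) with b+c+d = n
      z <- stats::qnorm((1 + config$level) / 2)
      logit_k <- log(kappa_hat[ok] / (1 - kappa_hat[ok]))
      lower <- stats::plogis(logit_k - z * sqrt(v))
      upper <- stats::plogis(logit_k + z * sqrt(v))
      covered <- lower <= target & target <= upper
      data.frame(method = m,
                 coverage = sum(covered) / config$replicates,
                 coverage_excl_degenerate = mean(covered),
                 mean_width = mean(upper - lower))
    } else {
      bounds <- if (m == "agresti_coull") {
        ac_bounds(d, n, config$level)
      } else {
        cp_bounds(d, n, config$level)
      }
      lower <- p_to_kappa(bounds[, "lower"])
      upper <- p_to_kappa(bounds[, "upper"])
      data.frame(method = m,
                 coverage = mean(lower <= target & target <= upper),
                 coverage_excl_degenerate = NA_real_,
                 mean_width = mean(upper - lower))
    }
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(n = n, kappa_target = target,
                   mean_kappa = mean(kappa_hat),
                   degenerate_frac = mean(degenerate)),
        out,
        data.frame(replicates = config$replicates, seed = config$seed))
}

# Stable per-cell seed so cells are independent and order-insensitive.
cell_seed <- function(master_seed, n, kappa_target) {
  h <- (as.numeric(master_seed) * 2654435761 + n * 40503 +
          round(kappa_target * 1000) * 2246822519) %% (2^31 - 1)
  as.integer(h)
}

#' Run a grid of coverage-simulation cells
#'
#' Runs every cell and stacks the tidy per-method rows.  The default grid is
#' `n` in 20, 50, 100, 200 crossed with kappa in 0.3, 0.5, 0.7, 0.9 at the
#' 95% level.  Per-cell seeds are derived from `seed` by a stable hash of
#' `(n, kappa_target)`, so cells are reproducible independently of grid
#' order.
#'
#' @param configs Optional list of [simulation_config()] objects; when
#'   omitted, the default grid is built from the remaining arguments.
#' @param n,kappa_target Grid values used when `configs` is missing.
#' @param replicates Replicates per cell.
#' @param level Confidence level.
#' @param seed Master seed.
#' @param quiet Suppress per-cell progress messages.
#' @return A data.frame, one row per (cell, method), with the columns of
#'   [run_cell()].
#' @examples
#' run_table(n = 20, kappa_target = c(0.3, 0.9), replicates = 1000, seed = 1)
#' @export
run_table <- function(configs = NULL, n = c(20, 50, 100, 200),
                      kappa_target = c(0.3, 0.5, 0.7, 0.9),
                      replicates = 50000, level = 0.95, seed = 1L,
                      quiet = FALSE) {
  if (is.null(configs)) {
    grid <- expand.grid(kappa_target = kappa_target, n = n)
    configs <- lapply(seq_len(nrow(grid)), function(i) {
      simulation_config(grid$n[i], grid$kappa_target[i], replicates,
                        level, seed = cell_seed(seed, grid$n[i],
                                                grid$kappa_target[i]))
    })
  }
  stopifnot(length(configs) >= 1)
  rows <- lapply(configs, function(cfg) {
    if (!quiet) {
      message(sprintf("simulating n = %d, kappa = %.2f (%d replicates)",
                      cfg$n, cfg$kappa_target, cfg$replicates))
    }
    run_cell(cfg)
  })
  do.call(rbind, rows)
}
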