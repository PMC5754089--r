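#' Likelihood-ratio statistic for the strict clock
#'
#' `2*DeltaL = -2 (L1 - L0)` where `L0` is the log-likelihood of the
#' clock-constrained consensus tree and `L1` that of the unconstrained one.
#' The log-likelihoods are computed upstream (e.g. by the sampler); this
#' module only performs the comparison.
#'
#' @param l0 log-likelihood under the clock model.
#' @param l1 log-likelihood under the non-clock model.
#' @return the statistic `-2 * (l1 - l0)`.
#' @export
lr_statistic <- function(l0, l1) {
  -2 * (l1 - l0)
}

#' Chi-square critical value
#'
#' Upper-`alpha` quantile of the chi-square distribution with `df` degrees of
#' freedom; the clock constraint removes `S - 2` free parameters on a tree
#' with `S` species.
#'
#' @param df degrees of freedom, `>= 1`.
#' @param alpha significance level in `(0, 1)`.
#' @return the critical value.
#' @export
chi2_critical <- function(df, alpha = 0.01) {
  df <- as.integer(df)
  if (is.na(df) || df < 1L) stop("'df' must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Run the likelihood-ratio strict-clock test
#'
#' @param l0,l1 log-likelihoods under the clock and non-clock models.
#' @param n_taxa number of species `S`, `>= 3`; degrees of freedom are
#'   `S - 2`.
#' @param alpha significance level.
#' @return an `lr_result` with fields `l0`, `l1`, `two_delta_l`, `df`,
#'   `chi2_critical`, `alpha`, `reject`.
#' @export
run_lr_test <- function(l0, l1, n_taxa, alpha = 0.01) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 3L) stop("'n_taxa' must be at least 3")
  df <- n_taxa - 2L
  stat <- lr_statistic(l0, l1)
  crit <- chi2_critical(df, alpha)
  structure(list(l0 = l0, l1 = l1, two_delta_l = stat, df = df,
                 chi2_critical = crit, alpha = alpha,
                 reject = stat > crit),
            class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat("Likelihood-ratio strict-clock test\n")
  cat(sprintf("  L0 = %.2f   L1 = %.2f   2*DeltaL = %.2f\n",
              x$l0, x$l1, x$two_delta_l))
  cat(sprintf("  chi-square crit(%.0f%%, df = %d) = %.2f\n",
              100 * x$alpha, x$df, x$chi2_critical))
  cat("  Decision:", if (x$reject) "REJECT strict clock"
      else "do not reject", "\n")
  invisible(x)
}
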