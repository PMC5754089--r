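## Smirnov coefficient c(alpha) = sqrt(-log(alpha/2)/2); c(0.01) ~ 1.6276.
ks_coefficient <- function(alpha) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  sqrt(-log(alpha / 2) / 2)
}

#' Two-sample KS statistic
#'
#' `D(N, M) = sup |F_N(x) - G_M(x)|`, computed exactly over the union of the
#' two samples' jump points. Branch lengths enter as real values (not
#' discretized); ties between the samples are handled by the `<=` convention
#' at the distinct pooled points, which leaves the exact supremum unaffected.
#'
#' @param a,b `branch_sample` objects or non-empty numeric vectors.
#' @return the statistic, in `[0, 1]`.
#' @export
ks2_statistic <- function(a, b) {
  if (inherits(a, "branch_sample")) a <- a$values
  if (inherits(b, "branch_sample")) b <- b$values
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  sa <- sort(a)
  sb <- sort(b)
  z <- sort(unique(c(sa, sb)))
  Fa <- findInterval(z, sa) / length(sa)
  Fb <- findInterval(z, sb) / length(sb)
  max(abs(Fa - Fb))
}

#' Asymptotic two-sample KS critical value
#'
#' `D_alpha = c(alpha) * sqrt((n + m) / (n * m))` with
#' `c(alpha) = sqrt(-ln(alpha/2) / 2)` (Smirnov). Use the
#' autocorrelation-adjusted sizes.
#'
#' @param n_adj,m_adj adjusted sample sizes, `>= 1`.
#' @param alpha significance level in `(0, 1)`.
#' @return the critical value.
#' @export
ks2_critical_value <- function(n_adj, m_adj, alpha = 0.01) {
  if (n_adj < 1 || m_adj < 1) stop("sample sizes must be at least 1")
  ks_coefficient(alpha) * sqrt((n_adj + m_adj) / (n_adj * m_adj))
}

#' Asymptotic two-sample KS p-value
#'
#' Kolmogorov tail probability `Q(t) = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)`
#' evaluated at `t = d * sqrt(n m / (n + m))`; the series is truncated when a
#' term drops below 1e-10 and the result clamped to `[0, 1]`.
#'
#' @param d observed statistic, in `[0, 1]`.
#' @param n_adj,m_adj adjusted sample sizes.
#' @return p-value in `[0, 1]`.
#' @export
ks2_p_value <- function(d, n_adj, m_adj) {
  if (d < 0 || d > 1) stop("'d' must be in [0, 1]")
  t <- d * sqrt(n_adj * m_adj / (n_adj + m_adj))
  if (t == 0) return(1)
  p <- 0
  for (k in 1:1000) {
    term <- 2 * (-1)^(k - 1) * exp(-2 * k^2 * t^2)
    p <- p + term
    if (abs(term) < 1e-10) break
  }
  min(max(p, 0), 1)
}

#' Run the full two-sample KS clock test
#'
#' Compares the continuous branch-length distribution of an unconstrained
#' ensemble with that of a clock-constrained ensemble (strict or relaxed):
#' burn-in both, choose a common tau by the prefix-scan rule (smallest tau at
#' least the taxon count minimizing the two-sample statistic; or the full
#' ensembles with `tau_rule = "all"`), compute `D(N, M)` on the unadjusted
#' pooled samples, adjust each size by the autocorrelation coefficient of its
#' own tree-length trace, and evaluate the asymptotic critical value and
#' p-value at the adjusted sizes. Rejection means the clock model under test
#' does not fit.
#'
#' @param ens_u unconstrained (non-clock) [tree_ensemble()].
#' @param ens_c clock-constrained [tree_ensemble()] (strict or relaxed).
#' @param alpha significance level.
#' @param burnin burn-in fraction applied to both ensembles.
#' @param tau_rule `"min-d"` (prefix scan, default) or `"all"` (pool every
#'   post burn-in tree).
#' @param ess_override_u,ess_override_c optional externally computed effective
#'   sample sizes for the two tree-length traces.
#' @param labels character pair naming the two ensembles in the report.
#' @return a `ks2_result` with fields `d`, `tau`, `n_unadjusted`,
#'   `m_unadjusted`, `n_adjusted`, `m_adjusted`, `k_u`, `k_c`, `alpha`,
#'   `d_critical`, `p_value`, `reject`, `labels`.
#' @export
run_ks2_test <- function(ens_u, ens_c, alpha = 0.01, burnin = 0.25,
                         tau_rule = c("min-d", "all"),
                         ess_override_u = NULL, ess_override_c = NULL,
                         labels = c("unconstrained", "clock")) {
  stopifnot(inherits(ens_u, "tree_ensemble"), inherits(ens_c, "tree_ensemble"))
  tau_rule <- match.arg(tau_rule)
  ens_u <- apply_burnin(ens_u, burnin)
  ens_c <- apply_burnin(ens_c, burnin)
  ntaxa <- max(length(ens_u$taxa), length(ens_c$taxa))
  T_min <- min(length(ens_u), length(ens_c))
  if (T_min < ntaxa)
    stop("ensembles (", T_min, " trees) smaller than the taxon count (",
         ntaxa, ")")
  vals_u <- lapply(unclass(ens_u$trees), function(tr) tr$edge.length)
  vals_c <- lapply(unclass(ens_c$trees), function(tr) tr$edge.length)
  .check_equal_b <- function(v, who) {
    if (length(unique(lengths(v))) != 1L)
      stop(who, " ensemble has unequal edge counts across trees")
  }
  .check_equal_b(vals_u, "unconstrained")
  .check_equal_b(vals_c, "clock-constrained")
  if (tau_rule == "all") {
    tau <- T_min
    d <- ks2_statistic(unlist(vals_u[seq_len(tau)], use.names = FALSE),
                       unlist(vals_c[seq_len(tau)], use.names = FALSE))
  } else {
    best_tau <- NA_integer_
    best_d <- Inf
    for (tau in ntaxa:T_min) {
      d_tau <- ks2_statistic(unlist(vals_u[seq_len(tau)], use.names = FALSE),
                             unlist(vals_c[seq_len(tau)], use.names = FALSE))
      if (d_tau < best_d) {
        best_d <- d_tau
        best_tau <- tau
      }
    }
    tau <- best_tau
    d <- best_d
  }
  n <- tau * lengths(vals_u)[1L]
  m <- tau * lengths(vals_c)[1L]
  adj_u <- ess_coefficient(tree_length_trace(ens_u), ess_override_u)
  adj_c <- ess_coefficient(tree_length_trace(ens_c), ess_override_c)
  n_adj <- adjust_sample_size(n, adj_u)
  m_adj <- adjust_sample_size(m, adj_c)
  d_critical <- ks2_critical_value(n_adj, m_adj, alpha)
  structure(list(
    d = d,
    tau = tau,
    n_unadjusted = n,
    m_unadjusted = m,
    n_adjusted = n_adj,
    m_adjusted = m_adj,
    k_u = adj_u$k,
    k_c = adj_c$k,
    alpha = alpha,
    d_critical = d_critical,
    p_value = ks2_p_value(d, n_adj, m_adj),
    reject = d > d_critical,
    labels = labels
  ), class = "ks2_result")
}

#' @export
print.ks2_result <- function(x, ...) {
  cat("Two-sample KS clock test (", x$labels[1L], " vs ", x$labels[2L],
      ")\n", sep = "")
  cat(sprintf("  D(N,M) = %.4f   tau = %d\n", x$d, x$tau))
  cat(sprintf("  N = %d -> N_adj = %d (k = %.3f)   M = %d -> M_adj = %d (k = %.3f)\n",
              x$n_unadjusted, x$n_adjusted, x$k_u,
              x$m_unadjusted, x$m_adjusted, x$k_c))
  cat(sprintf("  D_crit(%.0f%%) = %.4f   p = %.4g\n",
              100 * x$alpha, x$d_critical, x$p_value))
  cat("  Decision:", if (x$reject) "REJECT (not clock-like)"
      else "do not reject (clock-like)", "\n")
  invisible(x)
}

#' Non-parametric coverage band around an empirical CDF
#'
#' `U(x) = min(F(x) + D_alpha, 1)`, `L(x) = max(F(x) - D_alpha, 0)` with the
#' one-sample asymptotic halfwidth `D_alpha = c(alpha) / sqrt(n_adj)`. The
#' pair `(L, U)` contains the true CDF with probability at least `1 - alpha`.
#'
#' @param f a `step_cdf` (usually the unconstrained ensemble's ECD).
#' @param n_adj adjusted sample size behind `f`.
#' @param alpha significance level.
#' @return a `coverage_band`: list with `center` (the `step_cdf`),
#'   `halfwidth`, `level` (= 1 - alpha) and `n_adj`.
#' @export
coverage_band <- function(f, n_adj, alpha = 0.01) {
  stopifnot(inherits(f, "step_cdf"))
  if (n_adj < 1) stop("'n_adj' must be at least 1")
  structure(list(center = f,
                 halfwidth = ks_coefficient(alpha) / sqrt(n_adj),
                 level = 1 - alpha,
                 n_adj = as.integer(n_adj)),
            class = "coverage_band")
}

#' Evaluate a coverage band
#'
#' @param band a [coverage_band()].
#' @param q numeric evaluation points.
#' @return data frame with columns `x`, `L`, `F`, `U`.
#' @export
band_at <- function(band, q) {
  stopifnot(inherits(band, "coverage_band"))
  Fq <- cdf_at(band$center, q)
  data.frame(x = q,
             L = pmax(Fq - band$halfwidth, 0),
             F = Fq,
             U = pmin(Fq + band$halfwidth, 1))
}

#' Export a coverage band as TSV
#'
#' Three columns (`x`, `L`, `U`) plus the central ECD, evaluated at the jump
#' points of the central CDF.
#'
#' @param band a [coverage_band()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_tsv <- function(band, path) {
  stopifnot(inherits(band, "coverage_band"))
  utils::write.table(band_at(band, band$center$x), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
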