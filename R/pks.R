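## Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

#' Estimate the Poisson mean from discretized branch lengths
#'
#' The strict-clock null takes the Poisson parameter as the arithmetic mean of
#' the pooled integer substitution counts, the same set of branches used for
#' the empirical CDF.
#'
#' @param sample a `discrete_branch_sample` (from [discretize()]) or an
#'   integer vector of counts.
#' @return the mean count, a non-negative real.
#' @export
estimate_lambda <- function(sample) {
  counts <- if (inherits(sample, "discrete_branch_sample")) sample$counts
            else as.numeric(sample)
  if (length(counts) == 0L) stop("empty sample")
  mean(counts)
}

#' One-sample PKS statistic
#'
#' `D_PKS = sup |F_N(x) - P(x, lambda)|`, the supremum distance between the
#' empirical CDF of the discretized branch lengths and the Poisson CDF with
#' the given mean.
#'
#' @param sample a `discrete_branch_sample` or integer vector of counts.
#' @param lam Poisson mean, `>= 0`.
#' @return the statistic, in `[0, 1]`.
#' @export
pks_statistic <- function(sample, lam) {
  counts <- if (inherits(sample, "discrete_branch_sample")) sample$counts
            else as.numeric(sample)
  sup_distance(step_ecdf(counts), poisson_model(lam))
}

## Fast exact D for integer counts: both CDFs jump only at integers, so the
## sup is attained among the right-hand values on 0..K.
.pks_d_counts <- function(counts, lam, K) {
  n <- length(counts)
  ecd <- cumsum(tabulate(counts + 1L, nbins = K + 1L)) / n
  max(abs(ecd - stats::ppois(0:K, lam)))
}

## Parametric bootstrap null sample of D_PKS with lambda re-estimated per
## replicate (Lilliefors-style).
pks_null_distribution <- function(lam, n, reps, seed = NULL) {
  if (n < 1L) stop("'n' must be at least 1")
  if (lam < 0) stop("'lam' must be non-negative")
  if (lam == 0) return(numeric(reps))
  with_seed(seed, {
    K <- max(stats::qpois(1e-12, 2 * lam + 10, lower.tail = FALSE) + 1, 10)
    D <- numeric(reps)
    for (r in seq_len(reps)) {
      x <- stats::rpois(n, lam)
      D[r] <- .pks_d_counts(x, mean(x), max(K, max(x)))
    }
    D
  })
}

#' Bootstrap critical value of the PKS test
#'
#' Simulates `reps` samples of size `n` from Poisson(`lam`); for each, the
#' mean is re-estimated from the simulated sample and the PKS statistic
#' computed against the Poisson CDF at the estimate. Returns the empirical
#' `(1 - alpha)` quantile of the null distribution.
#'
#' @param lam Poisson mean used to simulate (typically the estimate from the
#'   observed sample).
#' @param n sample size (use the autocorrelation-adjusted size `N_adj`).
#' @param alpha significance level in `(0, 1)`.
#' @param reps number of bootstrap replicates, `>= 1000`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return the critical value `D_alpha`.
#' @export
pks_critical_value <- function(lam, n, alpha = 0.01, reps = 10000,
                               seed = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (reps < 1000) stop("'reps' must be at least 1000")
  if (lam == 0) return(0)
  D <- pks_null_distribution(lam, n, reps, seed)
  unname(stats::quantile(D, 1 - alpha, type = 7))
}

#' Bootstrap p-value of the PKS test
#'
#' Fraction of bootstrap replicates with `D >= d_obs`, with a
#' `+1/(reps + 1)` continuity correction so the p-value is never exactly 0.
#'
#' @param d_obs observed statistic.
#' @inheritParams pks_critical_value
#' @return p-value in `(0, 1]`.
#' @export
pks_p_value <- function(d_obs, lam, n, reps = 10000, seed = NULL) {
  if (reps < 1000) stop("'reps' must be at least 1000")
  D <- pks_null_distribution(lam, n, reps, seed)
  (sum(D >= d_obs) + 1) / (reps + 1)
}

#' Select the number of trees to pool (tau)
#'
#' Scans prefixes of the post burn-in ensemble in chain order, pooling the
#' discretized branch lengths of the first tau trees, re-estimating the
#' Poisson mean and computing the PKS statistic for each tau. Returns the
#' smallest tau, with tau at least the number of taxa, attaining the minimal
#' statistic: the best possible fit of the empirical CDF, so that enlarging
#' the sample cannot artificially force (or revert) a rejection.
#'
#' @param ens a post burn-in [tree_ensemble()] with fixed topology.
#' @param alignment_length alignment length for discretization.
#' @return list with `tau` and `d_at_tau`.
#' @export
select_tree_count <- function(ens, alignment_length) {
  stopifnot(inherits(ens, "tree_ensemble"))
  T_len <- length(ens)
  ntaxa <- length(ens$taxa)
  if (T_len < ntaxa)
    stop("ensemble (", T_len, " trees) smaller than the taxon count (",
         ntaxa, ")")
  counts_list <- lapply(unclass(ens$trees), function(tr)
    as.integer(floor(tr$edge.length * alignment_length + 0.5)))
  B <- lengths(counts_list)
  if (length(unique(B)) != 1L)
    stop("trees have unequal edge counts (offending trees: ",
         paste(which(B != B[1L]), collapse = ", "), ")")
  B <- B[1L]
  Kdata <- max(unlist(counts_list, use.names = FALSE))
  lam_hi <- max(cumsum(vapply(counts_list, sum, numeric(1))) /
                (seq_len(T_len) * B))
  K <- max(Kdata, stats::qpois(1e-12, lam_hi, lower.tail = FALSE) + 1)
  pk_grid <- 0:K
  tab <- integer(K + 1L)
  total <- 0
  best_tau <- NA_integer_
  best_d <- Inf
  for (tau in seq_len(T_len)) {
    cts <- counts_list[[tau]]
    tab <- tab + tabulate(cts + 1L, nbins = K + 1L)
    total <- total + sum(cts)
    if (tau < ntaxa) next
    lam <- total / (tau * B)
    d <- max(abs(cumsum(tab) / (tau * B) - stats::ppois(pk_grid, lam)))
    if (d < best_d) {
      best_d <- d
      best_tau <- tau
    }
  }
  list(tau = best_tau, d_at_tau = best_d)
}

#' Lower bound on the power of the PKS test
#'
#' A Dvoretzky-Kiefer-Wolfowitz-type bound: if the true CDF is at supremum
#' distance `delta` from the hypothesized Poisson CDF and `delta` exceeds the
#' critical value, the rejection probability is at least
#' `1 - 2 exp(-2 n (delta - d_critical)^2)`. The bound is conservative for
#' discrete data.
#'
#' @param d_critical critical value of the test.
#' @param delta supremum distance between the hypothesized CDF and the
#'   alternative CDF, `>= 0`.
#' @param n sample size.
#' @return lower bound on power, in `[0, 1]`.
#' @export
power_lower_bound <- function(d_critical, delta, n) {
  if (delta < 0) stop("'delta' must be non-negative")
  if (delta <= d_critical) return(0)
  max(0, 1 - 2 * exp(-2 * n * (delta - d_critical)^2))
}

#' Run the full PKS strict-clock test
#'
#' Executes the complete procedure on an ensemble of unconstrained trees:
#' burn-in, optional outgroup pruning, tau selection, discretization, Poisson
#' mean estimation and PKS statistic on the unadjusted pooled sample of size
#' `N = tau * B`, autocorrelation coefficient `k` from the tree-length trace
#' (or a supplied ESS), adjusted size `N_adj = round(k * N)`, and a seeded
#' parametric-bootstrap critical value and p-value at size `N_adj`. The null
#' (clock-like) hypothesis is rejected when `D_PKS > D_alpha`.
#'
#' The reported power lower bound is the DKW-type bound of
#' [power_lower_bound()] evaluated at the plug-in alternative `delta = D_PKS`
#' (the empirical CDF taken as the alternative distribution).
#'
#' @param ens a [tree_ensemble()].
#' @param alignment_length alignment length for discretization, `>= 1`.
#' @param alpha significance level.
#' @param burnin burn-in fraction in `[0, 1)`.
#' @param outgroup optional outgroup taxon label, pruned before testing.
#' @param reps bootstrap replicates.
#' @param seed optional integer seed for the bootstrap.
#' @param ess_override optional externally computed effective sample size of
#'   the tree-length trace (e.g. sampler-reported).
#' @return a `pks_result` with fields `lambda_hat`, `d_pks`, `tau`,
#'   `branches_per_tree`, `n_unadjusted`, `n_adjusted`, `k`, `t_ess`, `alpha`,
#'   `d_critical`, `p_value`, `reject`, `power_lower_bound`, `reps`, `seed`.
#' @export
run_pks_test <- function(ens, alignment_length, alpha = 0.01, burnin = 0.25,
                         outgroup = NULL, reps = 10000, seed = NULL,
                         ess_override = NULL) {
  stopifnot(inherits(ens, "tree_ensemble"))
  ens <- apply_burnin(ens, burnin)
  if (!is.null(outgroup)) ens <- prune_outgroup(ens, outgroup)
  sel <- select_tree_count(ens, alignment_length)
  sample <- pooled_branch_lengths(ens, tau = sel$tau)
  disc <- discretize(sample, alignment_length)
  lambda_hat <- estimate_lambda(disc)
  d_pks <- pks_statistic(disc, lambda_hat)
  adj <- ess_coefficient(tree_length_trace(ens), ess_override)
  n_adj <- adjust_sample_size(sample$n, adj)
  boot <- pks_null_distribution(lambda_hat, n_adj, reps, seed)
  d_critical <- if (lambda_hat == 0) 0 else
    unname(stats::quantile(boot, 1 - alpha, type = 7))
  p_value <- (sum(boot >= d_pks) + 1) / (reps + 1)
  structure(list(
    lambda_hat = lambda_hat,
    d_pks = d_pks,
    tau = sample$tau,
    branches_per_tree = sample$branches_per_tree,
    n_unadjusted = sample$n,
    n_adjusted = n_adj,
    k = adj$k,
    t_ess = adj$T_ess,
    alpha = alpha,
    d_critical = d_critical,
    p_value = p_value,
    reject = d_pks > d_critical,
    power_lower_bound = power_lower_bound(d_critical, d_pks, n_adj),
    reps = reps,
    seed = seed
  ), class = "pks_result")
}

#' @export
print.pks_result <- function(x, ...) {
  cat("Poisson-Kolmogorov-Smirnov strict-clock test\n")
  cat(sprintf("  lambda = %.4g   D_PKS = %.4f\n", x$lambda_hat, x$d_pks))
  cat(sprintf("  tau = %d (B = %d)   N = %d   N_adj = %d (k = %.3f)\n",
              x$tau, x$branches_per_tree, x$n_unadjusted, x$n_adjusted, x$k))
  cat(sprintf("  D_crit(%.0f%%) = %.4f   p = %.4g\n",
              100 * x$alpha, x$d_critical, x$p_value))
  cat("  Decision:", if (x$reject) "REJECT strict clock (not clock-like)"
      else "do not reject (clock-like)", "\n")
  invisible(x)
}
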