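#' Effective sample size of an MCMC scalar trace
#'
#' Estimates the size of a hypothetical IID sample carrying the same
#' information as the autocorrelated trace: `T / (1 + 2 * sum(rho_t))`, where
#' the empirical autocorrelations are summed by the initial-positive-sequence
#' rule (truncate at the first lag with `rho_t <= 0`), the convention used by
#' common MCMC diagnostics. The result is clamped to `(1, T]`.
#'
#' @param trace numeric trace of length `>= 10` (e.g. from
#'   [tree_length_trace()]); must not be constant.
#' @return the effective sample size, a real in `(1, T]`.
#' @export
effective_sample_size <- function(trace) {
  trace <- as.numeric(trace)
  T_len <- length(trace)
  if (T_len < 10L) stop("trace must have at least 10 entries")
  if (stats::var(trace) == 0)
    stop("constant trace: autocorrelation undefined")
  lag_max <- min(T_len - 1L, 2000L)
  rho <- stats::acf(trace, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  neg <- which(rho <= 0)
  keep <- if (length(neg)) rho[seq_len(neg[1L] - 1L)] else rho
  ess <- T_len / (1 + 2 * sum(keep))
  min(max(ess, 1 + .Machine$double.eps), T_len)
}

#' Autocorrelation adjustment for KS sample sizes
#'
#' The coefficient `k = T_ess / T` rescales the nominal pooled sample sizes
#' (N = tau * B) so that the critical values and p-values reflect the
#' information actually carried by the autocorrelated chain.
#'
#' @param T post burn-in ensemble size.
#' @param T_ess effective sample size, `1 < T_ess <= T` (computed by
#'   [effective_sample_size()] or supplied externally, e.g. sampler-reported).
#' @return an `ess_adjustment`: list with `T`, `T_ess` and `k` in `(0, 1]`.
#' @export
ess_adjustment <- function(T, T_ess) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("'T' must be a positive integer")
  if (!is.numeric(T_ess) || length(T_ess) != 1L || is.na(T_ess) ||
      T_ess <= 0 || T_ess > T)
    stop("'T_ess' must be a real in (0, T]")
  structure(list(T = T, T_ess = as.numeric(T_ess), k = as.numeric(T_ess) / T),
            class = "ess_adjustment")
}

#' @export
print.ess_adjustment <- function(x, ...) {
  cat(sprintf("ESS adjustment: T = %d, T_ess = %.1f, k = %.3f\n",
              x$T, x$T_ess, x$k))
  invisible(x)
}

## Adjustment coefficient from a trace, or from a user-supplied ESS override.
ess_coefficient <- function(trace, ess_override = NULL) {
  T_len <- length(trace)
  T_ess <- if (is.null(ess_override)) effective_sample_size(trace)
           else min(as.numeric(ess_override), T_len)
  ess_adjustment(T_len, T_ess)
}

#' Adjust a pooled sample size for autocorrelation
#'
#' `N_adj = round(k * N)`, at least 1, where `k` is the autocorrelation
#' coefficient of the ensemble the sample was pooled from.
#'
#' @param n_unadjusted unadjusted sample size N = tau * B, `>= 1`.
#' @param adj an [ess_adjustment()].
#' @return the adjusted sample size, an integer `>= 1`.
#' @export
adjust_sample_size <- function(n_unadjusted, adj) {
  stopifnot(inherits(adj, "ess_adjustment"))
  n_unadjusted <- as.integer(n_unadjusted)
  if (is.na(n_unadjusted) || n_unadjusted < 1L)
    stop("'n_unadjusted' must be a positive integer")
  max(1L, as.integer(round(adj$k * n_unadjusted)))
}

#' Read a one-column plain-text trace file
#'
#' Alternative to computing tree lengths from trees: a text file with one
#' numeric value per line (comment lines starting with `#` are skipped).
#'
#' @param path file path.
#' @return numeric vector.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- x[!grepl("^\\s*(#|$)", x)]
  as.numeric(x)
}
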