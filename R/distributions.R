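#' Step cumulative distribution functions
#'
#' A `step_cdf` is a right-continuous step function with values in `[0, 1]`:
#' jump points `x` (sorted, distinct) and cumulative values `y` (the value on
#' `[x[i], x[i+1])`). Evaluation left of the first jump is 0.
#'
#' @param x sorted distinct jump points.
#' @param y non-decreasing cumulative values in `[0, 1]`, one per jump point.
#' @return an object of class `step_cdf`.
#' @export
step_cdf <- function(x, y) {
  if (length(x) != length(y) || length(x) == 0L)
    stop("'x' and 'y' must be non-empty and of equal length")
  if (is.unsorted(x, strictly = TRUE)) stop("'x' must be strictly increasing")
  if (is.unsorted(y)) stop("'y' must be non-decreasing")
  if (y[1L] < 0 || y[length(y)] > 1 + 1e-12)
    stop("'y' must lie in [0, 1]")
  structure(list(x = as.numeric(x), y = pmin(as.numeric(y), 1)),
            class = "step_cdf")
}

#' Empirical cumulative distribution of a sample
#'
#' F(x) = (number of sample values <= x) / N, as a [step_cdf()] with jumps at
#' the distinct sample values.
#'
#' @param values non-empty numeric sample (a `branch_sample` is also accepted).
#' @return a `step_cdf`.
#' @export
step_ecdf <- function(values) {
  if (inherits(values, "branch_sample")) values <- values$values
  if (inherits(values, "discrete_branch_sample")) values <- values$counts
  if (length(values) == 0L) stop("empty sample")
  if (anyNA(values)) stop("sample contains NA")
  tab <- table(values)
  x <- as.numeric(names(tab))
  step_cdf(x, cumsum(as.numeric(tab)) / length(values))
}

#' Evaluate a CDF (right-continuously) at given points
#'
#' Generic evaluator shared by empirical step CDFs and the Poisson and
#' Poisson-mixture expected CDFs.
#'
#' @param f a `step_cdf`, `poisson_model` or `poisson_mixture`.
#' @param q numeric vector of evaluation points.
#' @return numeric vector of CDF values in `[0, 1]`.
#' @export
cdf_at <- function(f, q) UseMethod("cdf_at")

#' @export
cdf_at.step_cdf <- function(f, q) {
  i <- findInterval(q, f$x)
  ifelse(i == 0L, 0, f$y[pmax(i, 1L)])
}

## Left limit F(x-) of a step CDF.
cdf_left <- function(f, q) UseMethod("cdf_left")

#' @export
cdf_left.step_cdf <- function(f, q) {
  i <- findInterval(q, f$x, left.open = TRUE)
  ifelse(i == 0L, 0, f$y[pmax(i, 1L)])
}

#' Poisson branch-count model
#'
#' Expected distribution of discretized branch lengths under a strict clock:
#' a single Poisson law with mean `lambda` substitutions per branch.
#'
#' @param lambda mean substitution count, `>= 0`.
#' @return an object of class `poisson_model`.
#' @export
poisson_model <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0)
    stop("'lambda' must be a single non-negative number")
  structure(list(lambda = as.numeric(lambda)), class = "poisson_model")
}

#' @export
cdf_at.poisson_model <- function(f, q) {
  ifelse(q < 0, 0, stats::ppois(floor(q), f$lambda))
}

#' @export
cdf_left.poisson_model <- function(f, q) {
  ## P(X <= ceiling(q) - 1) just below q; equals cdf_at off the integers
  ifelse(q <= 0, 0, stats::ppois(ceiling(q) - 1, f$lambda))
}

#' Poisson mixture model
#'
#' Weighted mixture of Poisson laws, the expected branch-count distribution
#' when an unbalanced topology yields groups of systematically longer and
#' shorter branches.
#'
#' @param lambda numeric vector of component means, all `>= 0`.
#' @param weights numeric vector of component weights, summing to 1.
#' @return an object of class `poisson_mixture`.
#' @export
poisson_mixture <- function(lambda, weights) {
  if (length(lambda) < 1L || length(lambda) != length(weights))
    stop("'lambda' and 'weights' must be non-empty and of equal length")
  if (any(lambda < 0)) stop("component means must be non-negative")
  if (any(weights < 0) || any(weights > 1))
    stop("weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("weights must sum to 1 (tolerance 1e-12)")
  structure(list(lambda = as.numeric(lambda),
                 weights = as.numeric(weights)),
            class = "poisson_mixture")
}

#' @export
cdf_at.poisson_mixture <- function(f, q) {
  k <- floor(q)
  out <- numeric(length(q))
  for (i in seq_along(f$lambda))
    out <- out + f$weights[i] * stats::ppois(k, f$lambda[i])
  ifelse(q < 0, 0, out)
}

#' @export
cdf_left.poisson_mixture <- function(f, q) {
  k <- ceiling(q) - 1
  out <- numeric(length(q))
  for (i in seq_along(f$lambda))
    out <- out + f$weights[i] * stats::ppois(k, f$lambda[i])
  ifelse(q <= 0, 0, out)
}

#' Mean of a Poisson or Poisson-mixture model
#'
#' @param model a `poisson_model` or `poisson_mixture`.
#' @return the model mean, `sum(w_i * lambda_i)`.
#' @export
mixture_mean <- function(model) {
  if (inherits(model, "poisson_model")) return(model$lambda)
  stopifnot(inherits(model, "poisson_mixture"))
  sum(model$weights * model$lambda)
}

## Jump points relevant for sup evaluation: integers up to the tail cutoff,
## the smallest m with 1 - CDF(m) < 1e-12.
model_jump_points <- function(f) {
  lam_max <- max(f$lambda)
  m <- stats::qpois(1e-12, lam_max, lower.tail = FALSE) + 1
  0:max(m, 1)
}

#' Discretize branch lengths to substitution counts
#'
#' Each branch length (expected substitutions per site) is multiplied by the
#' alignment length and rounded half-up to a non-negative integer count.
#'
#' @param lengths a `branch_sample` (from [pooled_branch_lengths()]) or a
#'   numeric vector of non-negative branch lengths.
#' @param alignment_length number of sites in the alignment, `>= 1`.
#' @return a `discrete_branch_sample`: list with integer `counts`,
#'   `alignment_length` and the source sample sizes (`tau`,
#'   `branches_per_tree`, `n`).
#' @export
discretize <- function(lengths, alignment_length) {
  alignment_length <- as.integer(alignment_length)
  if (is.na(alignment_length) || alignment_length < 1L)
    stop("'alignment_length' must be a positive integer")
  if (inherits(lengths, "branch_sample")) {
    values <- lengths$values
    src <- lengths[c("tau", "branches_per_tree", "n", "label")]
  } else {
    values <- as.numeric(lengths)
    src <- list(tau = NA_integer_, branches_per_tree = NA_integer_,
                n = length(values), label = NA_character_)
  }
  if (any(values < 0)) stop("branch lengths must be non-negative")
  counts <- as.integer(floor(values * alignment_length + 0.5))
  structure(c(list(counts = counts, alignment_length = alignment_length), src),
            class = "discrete_branch_sample")
}

#' Supremum distance between two cumulative distribution functions
#'
#' Computes `sup |F(x) - G(x)|` exactly by evaluating both one-sided limits at
#' the union of the jump points of both functions (for a Poisson or mixture
#' CDF, at every integer up to the point where the upper tail drops below
#' 1e-12, plus all empirical jump points). The supremum of a difference of
#' step functions can occur just before a jump, hence the left limits.
#'
#' @param f,g each a `step_cdf`, `poisson_model` or `poisson_mixture`.
#' @return the supremum distance, in `[0, 1]`.
#' @export
sup_distance <- function(f, g) {
  pts <- sort(unique(c(.jumps_of(f), .jumps_of(g))))
  if (length(pts) == 0L) return(0)
  d_right <- abs(cdf_at(f, pts) - cdf_at(g, pts))
  d_left <- abs(cdf_left(f, pts) - cdf_left(g, pts))
  max(d_right, d_left)
}

.jumps_of <- function(f) {
  if (inherits(f, "step_cdf")) f$x else model_jump_points(f)
}

#' Export a step CDF as two-column TSV
#'
#' @param f a `step_cdf`.
#' @param path output path; columns `x` and `F`.
#' @return `path`, invisibly.
#' @export
write_cdf_tsv <- function(f, path) {
  stopifnot(inherits(f, "step_cdf"))
  utils::write.table(data.frame(x = f$x, F = f$y), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
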