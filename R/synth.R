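#' Configuration for synthetic posterior-like ensembles
#'
#' Describes a fixed-topology ensemble whose discretized branch lengths have a
#' controlled marginal distribution and a controlled between-tree
#' autocorrelation, emulating the posterior tree sample of an MCMC run.
#' Simulation operates directly on edge substitution counts (the quantity the
#' tests consume); edge lengths are counts divided by the alignment length.
#'
#' @param n_taxa number of leaves when `topology` is generated.
#' @param topology `NULL` to generate a shape, a Newick string, or a `phylo`
#'   tree. Generated shapes are unrooted binary trees with `2 * n_taxa - 3`
#'   edges.
#' @param shape `"balanced"` or `"caterpillar"` generated shape.
#' @param alignment_length alignment length used to convert counts to branch
#'   lengths (and back).
#' @param branch_model list describing the marginal law of each edge count:
#'   `list(kind = "poisson", lambda = )`,
#'   `list(kind = "mixture", lambda = c(l1, l2))` (component assignment is by
#'   edge, see [simulate_mixture_ensemble()]), or
#'   `list(kind = "overdispersed", lambda = , dispersion = )` with
#'   variance-to-mean ratio `dispersion > 1` (negative-binomial marginal).
#' @param n_trees ensemble size.
#' @param rho lag-1 between-tree autocorrelation in `[0, 1)`; implemented by
#'   INAR(1) binomial thinning, which preserves the Poisson marginal exactly.
#'   Over-dispersed ensembles require `rho = 0`.
#' @param seed integer seed; the same configuration always yields the same
#'   ensemble.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_taxa = 9, topology = NULL,
                         shape = c("balanced", "caterpillar"),
                         alignment_length = 1000,
                         branch_model = list(kind = "poisson", lambda = 6),
                         n_trees = 1000, rho = 0, seed = 1) {
  shape <- match.arg(shape)
  if (rho < 0 || rho >= 1) stop("'rho' must be in [0, 1)")
  if (n_trees < 1) stop("'n_trees' must be at least 1")
  if (is.null(branch_model$kind) ||
      !branch_model$kind %in% c("poisson", "mixture", "overdispersed"))
    stop("'branch_model$kind' must be poisson, mixture or overdispersed")
  if (branch_model$kind == "overdispersed") {
    if (is.null(branch_model$dispersion) || branch_model$dispersion <= 1)
      stop("over-dispersed model needs dispersion > 1")
    if (rho != 0)
      stop("autocorrelation is only supported for the Poisson marginal")
  }
  if (any(branch_model$lambda < 0)) stop("'lambda' must be non-negative")
  tree <- .resolve_topology(topology, n_taxa, shape)
  structure(list(tree = tree, alignment_length = as.integer(alignment_length),
                 branch_model = branch_model, n_trees = as.integer(n_trees),
                 rho = rho, seed = as.integer(seed)),
            class = "synth_config")
}

.resolve_topology <- function(topology, n_taxa, shape) {
  if (is.null(topology)) {
    if (n_taxa < 3) stop("'n_taxa' must be at least 3")
    nwk <- if (shape == "balanced") .balanced_newick(seq_len(n_taxa))
           else .caterpillar_newick(n_taxa)
    tree <- ape::unroot(ape::read.tree(text = paste0(nwk, ";")))
  } else if (inherits(topology, "phylo")) {
    tree <- topology
  } else {
    tree <- ape::read.tree(text = topology)
  }
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  tree
}

.balanced_newick <- function(idx) {
  if (length(idx) == 1L) return(paste0("t", idx))
  half <- ceiling(length(idx) / 2)
  paste0("(", .balanced_newick(idx[seq_len(half)]), ",",
         .balanced_newick(idx[-seq_len(half)]), ")")
}

.caterpillar_newick <- function(n) {
  out <- paste0("(t", n - 1L, ",t", n, ")")
  for (i in rev(seq_len(n - 2L))) out <- paste0("(t", i, ",", out, ")")
  out
}

## INAR(1) count chains: one column per edge, Poisson(lambda[e]) marginal,
## lag-1 autocorrelation rho via binomial thinning plus Poisson innovation.
.inar1_counts <- function(n_trees, lambda, rho) {
  E <- length(lambda)
  out <- matrix(0L, nrow = n_trees, ncol = E)
  x <- stats::rpois(E, lambda)
  out[1L, ] <- x
  if (n_trees > 1L) {
    for (t in 2:n_trees) {
      x <- stats::rbinom(E, x, rho) + stats::rpois(E, (1 - rho) * lambda)
      out[t, ] <- x
    }
  }
  out
}

.counts_to_ensemble <- function(cfg, counts) {
  trees <- vector("list", cfg$n_trees)
  base <- cfg$tree
  for (t in seq_len(cfg$n_trees)) {
    tr <- base
    tr$edge.length <- counts[t, ] / cfg$alignment_length
    trees[[t]] <- tr
  }
  tree_ensemble(trees)
}

#' Simulate a strict-clock (or over-dispersed) ensemble
#'
#' Under the Poisson model every edge count has a Poisson(`lambda`) stationary
#' marginal and the between-tree dependence of each edge is a stationary
#' INAR(1) chain with lag-1 autocorrelation `rho` (binomial thinning keeps the
#' marginal exactly Poisson). Under the over-dispersed model edge counts are
#' IID negative-binomial draws with the stated variance-to-mean ratio, the
#' standard alternative when the substitution process is over-dispersed.
#'
#' @param cfg a [synth_config()] with a `poisson` or `overdispersed` branch
#'   model.
#' @return a [tree_ensemble()].
#' @export
simulate_clock_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  kind <- cfg$branch_model$kind
  if (!kind %in% c("poisson", "overdispersed"))
    stop("use simulate_mixture_ensemble() for mixture models")
  E <- nrow(cfg$tree$edge)
  with_seed(cfg$seed, {
    counts <- if (kind == "poisson") {
      .inar1_counts(cfg$n_trees, rep(cfg$branch_model$lambda, E), cfg$rho)
    } else {
      lam <- cfg$branch_model$lambda
      size <- lam / (cfg$branch_model$dispersion - 1)
      matrix(stats::rnbinom(cfg$n_trees * E, size = size, mu = lam),
             nrow = cfg$n_trees)
    }
    .counts_to_ensemble(cfg, counts)
  })
}

#' Simulate a Poisson-mixture ensemble
#'
#' Designated "long" edges draw their counts from the second (large-mean)
#' Poisson component, all remaining edges from the first, so the pooled
#' marginal across edges is the weighted mixture with weights given by the
#' edge proportions - the situation produced by an unbalanced topology such
#' as an ingroup plus a long outgroup branch.
#'
#' @param cfg a [synth_config()] whose `branch_model` is
#'   `list(kind = "mixture", lambda = c(lambda_short, lambda_long))`.
#' @param long_edges integer indices (into the tree's edge set) of the edges
#'   drawing from the second component; non-empty.
#' @return a [tree_ensemble()].
#' @export
simulate_mixture_ensemble <- function(cfg, long_edges) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$branch_model$kind != "mixture")
    stop("'cfg' must carry a mixture branch model")
  if (length(cfg$branch_model$lambda) != 2L)
    stop("the mixture branch model takes exactly two component means")
  E <- nrow(cfg$tree$edge)
  long_edges <- as.integer(long_edges)
  if (length(long_edges) == 0L) stop("'long_edges' must be non-empty")
  if (any(long_edges < 1L | long_edges > E))
    stop("'long_edges' indices outside the tree's ", E, " edges")
  lam <- rep(cfg$branch_model$lambda[1L], E)
  lam[long_edges] <- cfg$branch_model$lambda[2L]
  with_seed(cfg$seed,
            .counts_to_ensemble(cfg, .inar1_counts(cfg$n_trees, lam, cfg$rho)))
}
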