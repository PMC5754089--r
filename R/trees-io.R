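#' Tree ensembles
#'
#' A `tree_ensemble` is an ordered collection of equally-weighted phylogenetic
#' trees sharing a common taxon set, typically the post burn-in sample of a
#' Bayesian MCMC run. Branch lengths are expected substitutions per site.
#'
#' @param trees a `multiPhylo` object or a list of `phylo` objects, all with
#'   edge lengths and identical leaf-label sets.
#' @param generations optional integer vector of MCMC generation indices, one
#'   per tree, strictly increasing.
#' @return an object of class `tree_ensemble`: a list with elements `trees`
#'   (`multiPhylo`), `taxa` (sorted character vector) and `generations`.
#' @export
tree_ensemble <- function(trees, generations = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("ensemble must contain at least one tree")
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!inherits(tr, "phylo")) stop("element ", i, " is not a 'phylo' tree")
    if (is.null(tr$edge.length))
      stop("tree ", i, " has no branch lengths")
    if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
      stop("tree ", i, " has negative or missing branch lengths")
  }
  taxa <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), taxa))
      stop("tree ", i, " has a different taxon set than tree 1")
  }
  if (!is.null(generations)) {
    generations <- as.integer(generations)
    if (length(generations) != length(trees))
      stop("'generations' must have one entry per tree")
    if (any(diff(generations) <= 0))
      stop("'generations' must be strictly increasing")
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, taxa = taxa, generations = generations),
            class = "tree_ensemble")
}

#' @export
length.tree_ensemble <- function(x) length(x$trees)

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("Tree ensemble:", length(x), "trees,", length(x$taxa), "taxa\n")
  cat("Taxa:", paste(utils::head(x$taxa, 8L), collapse = ", "),
      if (length(x$taxa) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Read a multi-tree file into an ensemble
#'
#' Reads MrBayes-style Nexus tree files (`begin trees;` block with an optional
#' `translate` table, `[&U]`/`[&R]` rooting flags and bracketed `[&...]`
#' metacomments, all stripped before parsing) or plain Newick files (one tree
#' per line or semicolon-separated).
#'
#' @param path path to the tree file.
#' @param format `"auto"` (sniff for `#NEXUS`), `"nexus"` or `"newick"`.
#' @return a [tree_ensemble()].
#' @export
read_tree_ensemble <- function(path, format = c("auto", "nexus", "newick")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE))
      "nexus" else "newick"
  }
  trees <- if (format == "nexus") .read_nexus_trees(path) else
    .read_newick_trees(path)
  tree_ensemble(trees)
}

## MrBayes .t dialect: strip [&...] comments anywhere, then hand to ape.
.read_nexus_trees <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[&[^]]*\\]", "", txt)
  tmp <- tempfile(fileext = ".nex")
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  trees <- ape::read.nexus(tmp)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees
}

.read_newick_trees <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[&[^]]*\\]", "", txt)
  pieces <- strsplit(txt, ";")[[1L]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0L) stop("no trees found in ", path)
  trees <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    tr <- tryCatch(ape::read.tree(text = paste0(pieces[i], ";")),
                   error = function(e) NULL)
    if (is.null(tr)) stop("malformed Newick at tree ", i, " of ", path)
    trees[[i]] <- tr
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Write an ensemble to Newick or Nexus
#'
#' Nexus output contains a translate block with all taxa; branch lengths are
#' written with 10 significant digits so a write/read round trip preserves
#' them at reporting precision.
#'
#' @param ens a [tree_ensemble()].
#' @param path output file path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(ens, "tree_ensemble"))
  if (format == "newick") {
    ape::write.tree(ens$trees, file = path, digits = 10)
  } else {
    ape::write.nexus(ens$trees, file = path, translate = TRUE, digits = 10)
  }
  invisible(path)
}

#' Discard an initial burn-in fraction of an ensemble
#'
#' Removes the first `ceiling(fraction * T)` trees, preserving order. Bayesian
#' practice discards at least 25% so that the retained trees are statistically
#' equivalent draws from the posterior.
#'
#' @param ens a [tree_ensemble()].
#' @param fraction fraction in `[0, 1)` of leading trees to discard.
#' @return the truncated [tree_ensemble()].
#' @export
apply_burnin <- function(ens, fraction) {
  stopifnot(inherits(ens, "tree_ensemble"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction >= 1)
    stop("'fraction' must be a single number in [0, 1)")
  ndrop <- ceiling(fraction * length(ens))
  keep <- seq_len(length(ens)) > ndrop
  if (!any(keep)) stop("burn-in removes every tree")
  tree_ensemble(ens$trees[keep],
                generations = if (!is.null(ens$generations))
                  ens$generations[keep])
}

#' Remove the outgroup branch from every tree
#'
#' Deletes the terminal edge leading to the outgroup leaf in each tree; its
#' length is discarded, not merged into neighbouring edges, and the attachment
#' node is retained (the ingroup is effectively rooted there). For a tree with
#' B edges this leaves B - 1 edges.
#'
#' @param ens a [tree_ensemble()].
#' @param outgroup taxon label to remove.
#' @return the pruned [tree_ensemble()].
#' @export
prune_outgroup <- function(ens, outgroup) {
  stopifnot(inherits(ens, "tree_ensemble"))
  if (!outgroup %in% ens$taxa)
    stop("outgroup '", outgroup, "' is not in the taxon set")
  pruned <- lapply(unclass(ens$trees), function(tr)
    ape::drop.tip(tr, outgroup, collapse.singles = FALSE))
  tree_ensemble(pruned, generations = ens$generations)
}

#' Pool branch lengths from the first tau trees
#'
#' Concatenates all edge lengths of the first `tau` trees of the ensemble,
#' giving the unadjusted sample of size N = tau * B used by both clock tests.
#' All trees must share the same edge count B (fixed topology).
#'
#' @param ens a [tree_ensemble()].
#' @param tau number of trees to pool; defaults to the whole ensemble.
#' @param label sample provenance label, one of `"unconstrained"`,
#'   `"strict_clock"`, `"relaxed_clock"`.
#' @return a `branch_sample`: list with `values`, `tau`, `branches_per_tree`,
#'   `n` (= tau * B) and `label`.
#' @export
pooled_branch_lengths <- function(ens, tau = length(ens),
                                  label = c("unconstrained", "strict_clock",
                                            "relaxed_clock")) {
  stopifnot(inherits(ens, "tree_ensemble"))
  label <- match.arg(label)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) stop("'tau' must be a positive integer")
  if (tau > length(ens)) stop("'tau' exceeds the ensemble size")
  counts <- vapply(unclass(ens$trees), function(tr) length(tr$edge.length),
                   integer(1))
  if (length(unique(counts)) != 1L)
    stop("trees have unequal edge counts (offending trees: ",
         paste(which(counts != counts[1L]), collapse = ", "), ")")
  B <- counts[1L]
  values <- unlist(lapply(unclass(ens$trees)[seq_len(tau)],
                          function(tr) tr$edge.length), use.names = FALSE)
  structure(list(values = values, tau = tau, branches_per_tree = B,
                 n = tau * B, label = label),
            class = "branch_sample")
}

#' @export
print.branch_sample <- function(x, ...) {
  cat("Branch sample (", x$label, "): N = ", x$n, " = ", x$tau, " trees x ",
      x$branches_per_tree, " branches\n", sep = "")
  invisible(x)
}

#' Tree-length trace of an ensemble
#'
#' The tree length (TL) of a tree is the sum of all its branch lengths; the
#' trace across the ensemble is the scalar MCMC diagnostic whose effective
#' sample size drives the autocorrelation adjustment.
#'
#' @param ens a [tree_ensemble()].
#' @return numeric vector of tree lengths, one per tree.
#' @export
tree_length_trace <- function(ens) {
  stopifnot(inherits(ens, "tree_ensemble"))
  vapply(unclass(ens$trees), function(tr) sum(tr$edge.length), numeric(1))
}
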