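# Shared helpers: tiny ensembles built in code, and brute-force oracles for
# the supremum-distance computations.

toy_ensemble <- function(newicks) {
  trees <- lapply(newicks, function(s) ape::read.tree(text = s))
  tree_ensemble(trees)
}

# Nine-taxon-style unrooted shape: ingroup of 8 plus outgroup O (15 edges).
nine_taxon_newick <- function() {
  paste0("(((S1:0.005,S2:0.006):0.004,(S3:0.007,S4:0.005):0.003):0.002,",
         "((S5:0.006,S6:0.004):0.005,(S7:0.005,S8:0.007):0.004):0.003,",
         "O:0.025);")
}

# Brute-force sup|F - G| oracle: evaluates both CDFs on a dense grid plus the
# jump points of both and just below each jump.
brute_sup <- function(f, g, lo, hi) {
  jumps <- c(
    if (inherits(f, "step_cdf")) f$x else 0:ceiling(hi),
    if (inherits(g, "step_cdf")) g$x else 0:ceiling(hi)
  )
  grid <- sort(unique(c(seq(lo, hi, length.out = 20001),
                        jumps, jumps - 1e-9, jumps + 1e-9)))
  max(abs(cdf_at(f, grid) - cdf_at(g, grid)))
}

# O(N*M)-style two-sample oracle over a dense grid plus sample points.
brute_ks2 <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  grid <- sort(unique(c(pts, pts - 1e-9, pts + 1e-9,
                        seq(min(pts) - 1, max(pts) + 1, length.out = 10001))))
  Fa <- vapply(grid, function(z) mean(a <= z), numeric(1))
  Fb <- vapply(grid, function(z) mean(b <= z), numeric(1))
  max(abs(Fa - Fb))
}
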