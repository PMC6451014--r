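# shared fixtures, all built in code

# one model instance for the whole suite (construction is cheap but
# there is no reason to re-parse the constants in every test)
DAYHOFF <- dayhoff_model()

toy_msa <- function() {
  protein_msa(c(Alpha = "AAC-D", Beta = "AACXD", Gamma = "TTCCD"))
}

# evodist from a named lower-triangle spec, e.g. ab = 3, ac = 5 ...
dist_from_pairs <- function(labels, ...) {
  v <- list(...)
  d <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (nm in names(v)) {
    i <- substr(nm, 1, 1); j <- substr(nm, 2, 2)
    if (!i %in% labels) { i <- toupper(i); j <- toupper(j) }
    d[i, j] <- d[j, i] <- v[[nm]]
  }
  evodist(d, labels)
}

# random tree with edge lengths in [lo, hi]; unrooted, for NJ tests
random_additive_tree <- function(n, seed, lo = 0.1, hi = 2) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = FALSE, br = NULL)
  tree$edge.length <- runif(nrow(tree$edge), lo, hi)
  tree
}

# random k-dim rotation (det +1) for rigid-motion properties
random_rotation <- function(k, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(k * k), k, k))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# simulate one aligned pair at divergence t (two-leaf tree)
simulated_pair <- function(t, n_sites, seed, model = DAYHOFF) {
  tr <- read_newick(sprintf("(a:%g,b:%g);", t / 2, t / 2))
  fam <- evolve_sequences(tr, model, n_sites, seed = seed)
  fam$msa$seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
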