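# deterministic per-stream seed derivation (stays below 2^31)
.derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 9973) %%
               2147483629)
}

#' Evolve protein sequences along a tree
#'
#' Forward simulation under a [dayhoff_model()]-style reversible Markov
#' process: the root sequence is drawn site-independently from the
#' stationary frequencies \eqn{\pi}; along each branch of length \eqn{t}
#' every site makes one categorical draw from the corresponding row of
#' \eqn{P(t \cdot m)}, where \eqn{m} is that branch's rate multiplier.
#' Sites are independent and no gaps are generated. Each branch uses its
#' own derived random stream, so edits to one part of the topology do not
#' perturb the sequences of unrelated subtrees, and regeneration from the
#' same `(tree, model, n_sites, seed)` is bit-identical.
#'
#' @param tree a `phylo` with complete branch lengths (substitutions per
#'   site).
#' @param model a [dayhoff_model()].
#' @param n_sites number of alignment columns.
#' @param seed integer seed.
#' @param rate_multipliers optional positive numeric vector, one entry per
#'   edge of `tree` (in `tree$edge` order); defaults to 1 everywhere.
#' @return an object of class `simulated_family`: `tree`, `msa`
#'   (leaf sequences as a [protein_msa()]), `model_name`, `seed`,
#'   `rate_multipliers`.
#' @export
evolve_sequences <- function(tree, model, n_sites, seed = 1,
                             rate_multipliers = NULL) {
  stopifnot(inherits(tree, "phylo"),
            inherits(model, "substitution_model"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    ps_stop("tree has missing branch lengths")
  if (n_sites < 1) ps_stop("n_sites must be >= 1")
  nedge <- nrow(tree$edge)
  if (is.null(rate_multipliers)) rate_multipliers <- rep(1, nedge)
  if (length(rate_multipliers) != nedge)
    ps_stop("need one rate multiplier per edge (", nedge, ")")
  if (any(!is.finite(rate_multipliers) | rate_multipliers <= 0))
    ps_stop("rate multipliers must be positive")

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  set.seed(.derive_seed(seed, 0L))
  states[[root]] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$pi)
  # parent-before-child order
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    par <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    t_eff <- tree$edge.length[e] * rate_multipliers[e]
    P <- transition_matrix(model, t_eff)
    parent_states <- states[[par]]
    child <- integer(n_sites)
    set.seed(.derive_seed(seed, e))
    for (a in sort(unique(parent_states))) {
      idx <- which(parent_states == a)
      child[idx] <- sample.int(20L, length(idx), replace = TRUE,
                               prob = P[a, ])
    }
    states[[ch]] <- child
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(AA20[states[[i]]], collapse = ""), character(1))
  msa <- protein_msa(seqs, tree$tip.label)
  structure(list(tree = tree, msa = msa, model_name = model$name,
                 seed = seed, rate_multipliers = rate_multipliers),
            class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("simulated_family:", length(x$msa$taxa), "taxa,", x$msa$n_sites,
      "sites under the", x$model_name, "model (seed", x$seed, ")\n")
  invisible(x)
}

#' Plant a low-dimensional point configuration
#'
#' Draws `n` points from a seeded spherical Gaussian in `k` dimensions and
#' returns them together with their exact Euclidean distance matrix — a
#' configuration that is embeddable in `k` dimensions with zero stress,
#' which makes it the natural oracle for [sammon_map()].
#'
#' @param n number of points (`n > k`).
#' @param k dimension.
#' @param seed integer seed.
#' @param scale standard deviation of the point cloud.
#' @return list with `X` (n x k, rownames `p01`, `p02`, ...) and `dm`
#'   (an [evodist()]).
#' @export
planted_configuration <- function(n, k, seed = 1, scale = 1) {
  if (n <= k) ps_stop("need n > k points, got n = ", n, ", k = ", k)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(.derive_seed(seed, 1L))
  X <- matrix(rnorm(n * k, sd = scale), n, k)
  rownames(X) <- sprintf("p%02d", seq_len(n))
  colnames(X) <- c("x", "y", "z")[seq_len(min(k, 3))]
  list(X = X, dm = evodist(as.matrix(dist(X)), rownames(X)))
}

# balanced binary clade as a newick fragment; total root-to-tip length
# = depth (for power-of-two sizes; uneven splits give shorter paths)
.balanced_clade <- function(labels, depth) {
  levels <- max(1, ceiling(log2(length(labels))))
  el <- depth / levels
  build <- function(lab) {
    if (length(lab) == 1) return(sprintf("%s:%.17g", lab, el))
    h <- ceiling(length(lab) / 2)
    sprintf("(%s,%s):%.17g", build(lab[seq_len(h)]),
            build(lab[-seq_len(h)]), el)
  }
  if (length(labels) == 1) return(sprintf("%s:%.17g", labels, depth))
  h <- ceiling(length(labels) / 2)
  sprintf("(%s,%s)", build(labels[seq_len(h)]), build(labels[-seq_len(h)]))
}

#' Simulate a two-group family with contrasting evolutionary rates
#'
#' Generates the compact-versus-spread scenario end to end: a rooted,
#' balanced two-clade tree in which every branch of the second clade is
#' scaled by `rate_ratio`, emulating a lineage with a much higher
#' mutational rate, then evolves sequences along it. The companion
#' annotation labels the clades `"slow"` and `"fast"`. With
#' `rate_ratio = 1` the clades are exchangeable.
#'
#' Defaults describe a realistic single-domain protein family: 8 taxa per
#' clade, 0.5 substitutions per site from the clade root to its tips plus
#' a 0.25 stem per clade, and 300 alignment columns.
#'
#' @param n_per_group taxa per clade.
#' @param rate_ratio branch-rate scaling of the fast clade (>= 1).
#' @param depth root-to-tip path length within each clade,
#'   substitutions per site.
#' @param n_sites alignment columns.
#' @param seed integer seed.
#' @param model a [dayhoff_model()].
#' @return list with `family` (a [evolve_sequences()] result),
#'   `annotation` (a [group_annotation()]) and `tree`.
#' @export
two_group_family <- function(n_per_group = 8, rate_ratio = 5, depth = 0.5,
                             n_sites = 300, seed = 1,
                             model = dayhoff_model()) {
  if (n_per_group < 2) ps_stop("need at least 2 taxa per group")
  if (rate_ratio < 1) ps_stop("rate_ratio must be >= 1")
  slow <- sprintf("slow_%02d", seq_len(n_per_group))
  fast <- sprintf("fast_%02d", seq_len(n_per_group))
  stem <- depth / 2
  nwk <- sprintf("(%s:%.17g,%s:%.17g);",
                 .balanced_clade(slow, depth), stem,
                 .balanced_clade(fast, depth), stem)
  tree <- ape::read.tree(text = nwk)
  # fast clade = every edge whose child subtends only fast_* tips
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(ntip + tree$Nnode), "tips")
  is_fast_node <- vapply(desc, function(tp)
    all(startsWith(tree$tip.label[tp], "fast_")), logical(1))
  mult <- ifelse(is_fast_node[tree$edge[, 2]], rate_ratio, 1)
  fam <- evolve_sequences(tree, model, n_sites, seed = seed,
                          rate_multipliers = mult)
  ann <- group_annotation(data.frame(
    taxon = c(slow, fast),
    group = rep(c("slow", "fast"), each = n_per_group)))
  list(family = fam, annotation = ann, tree = tree)
}
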