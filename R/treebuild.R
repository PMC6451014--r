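#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor-joining: repeatedly join the pair minimizing
#' \eqn{Q(i,j) = (n-2)d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}}, with the
#' usual branch-length formulas. On an additive (tree-like) matrix the
#' generating topology and branch lengths are recovered exactly. Two
#' departures from the bare algorithm make the output total and
#' deterministic: a negative estimated branch length is clamped to zero
#' and its deficit transferred to the sibling branch (so path lengths are
#' preserved), and ties in \eqn{Q} are broken by the lexicographically
#' lowest pair of cluster representatives (the smallest leaf label in each
#' cluster).
#'
#' @param dm an [evodist()] with at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @examples
#' d <- matrix(c(0, .4, .6, .4, 0, .8, .6, .8, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' neighbor_joining(evodist(d))
#' @export
neighbor_joining <- function(dm) {
  stopifnot(inherits(dm, "evodist"))
  d <- dm$d
  n <- nrow(d)
  if (n < 3) ps_stop("neighbor-joining needs at least 3 taxa")
  if (any(!is.finite(d))) ps_stop("non-finite distances")
  # cluster state: newick fragment and representative (min leaf label)
  frag <- dm$labels
  rep_ <- dm$labels
  clamped <- 0L
  while (nrow(d) > 3) {
    m <- nrow(d)
    rs <- rowSums(d)
    Q <- (m - 2) * d - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(r) {
      pr <- sort(c(rep_[cand[r, 1]], rep_[cand[r, 2]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0; clamped <- clamped + 1L }
    if (bj < 0) { bi <- bi + bj; bj <- 0; clamped <- clamped + 1L }
    newfrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], bi, frag[j], bj)
    newrep <- min(rep_[i], rep_[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_ <- c(rep_[keep], newrep)
    d <- d2
  }
  # final three clusters joined at one internal node
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  for (v in c("ba", "bb", "bc"))
    if (get(v) < 0) { assign(v, 0); clamped <- clamped + 1L }
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], ba, frag[2], bb, frag[3], bc)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped_branches") <- clamped
  if (clamped > 0)
    warning(clamped, " negative NJ branch(es) clamped to zero",
            call. = FALSE)
  tree
}

#' Patristic distances on a tree
#'
#' Sum of branch lengths along the unique path between nodes.
#'
#' @param tree a `phylo` with complete branch lengths.
#' @param include_internal also return distances involving internal nodes
#'   (labelled by their node labels, or `node<k>` when unlabelled).
#' @return an [evodist()].
#' @export
patristic_distances <- function(tree, include_internal = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    ps_stop("tree has missing branch lengths")
  if (!include_internal) {
    d <- ape::cophenetic.phylo(tree)
    d <- d[tree$tip.label, tree$tip.label]
    return(evodist(d, tree$tip.label))
  }
  d <- ape::dist.nodes(tree)
  ntip <- length(tree$tip.label)
  ilab <- tree$node.label
  if (is.null(ilab) || any(!nzchar(ilab)))
    ilab <- paste0("node", seq_len(tree$Nnode) + ntip)
  labels <- c(tree$tip.label, ilab)
  evodist(d, labels)
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the longest leaf-to-leaf path.
#'
#' @param tree an unrooted `phylo` with branch lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    ps_stop("tree has missing branch lengths")
  if (sum(tree$edge.length) <= 0) ps_stop("tree has zero total length")
  if (length(tree$tip.label) == 2) {
    half <- sum(tree$edge.length) / 2
    t2 <- ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                        tree$tip.label[1], half,
                                        tree$tip.label[2], half))
    return(t2)
  }
  phangorn::midpoint(tree)
}
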