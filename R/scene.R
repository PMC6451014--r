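#' Orthogonal Procrustes superposition
#'
#' Finds the translation plus rotation (and optionally reflection) of `Y`
#' that minimizes the root-mean-square deviation from `X`. Because MDS
#' axes are arbitrary — every rotation and symmetry of a map is an equally
#' valid map — this is the correct way to compare two embeddings of the
#' same taxa (restarts, reruns, figures). No scaling is fitted: Sammon
#' output units approximate substitutions per site and are meaningful.
#'
#' @param X,Y n x k coordinate matrices with matching rows.
#' @param allow_reflection also allow an improper rotation (reflection).
#' @return list with `Y_aligned`, `rotation`, `translation` and `rmsd`,
#'   class `procrustes_align`.
#' @export
procrustes_align <- function(X, Y, allow_reflection = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)))
    ps_stop("configurations differ in shape (", nrow(X), "x", ncol(X),
            " vs ", nrow(Y), "x", ncol(Y), ")")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  Yr <- Yc %*% R
  rmsd <- sqrt(mean(rowSums((Xc - Yr)^2)))
  Ya <- sweep(Yr, 2, cx, "+")
  rownames(Ya) <- rownames(X)
  structure(list(Y_aligned = Ya, rotation = R,
                 translation = cx - as.vector(cy %*% R), rmsd = rmsd),
            class = "procrustes_align")
}

#' @export
print.procrustes_align <- function(x, ...) {
  cat(sprintf("Procrustes superposition: rmsd = %.6g (det R = %+.0f)\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

# fixed display convention: first (reference/slow/monofunctional) group
# blue, second (fast/bifunctional) red, further groups from a palette
.group_colors <- function(groups) {
  groups <- as.character(groups)
  cols <- character(length(groups))
  blue_like <- c("monofunctional", "slow", "unikont")
  red_like <- c("bifunctional", "fast", "bikont")
  cols[tolower(groups) %in% blue_like] <- "blue"
  cols[tolower(groups) %in% red_like] <- "red"
  rest <- which(!nzchar(cols))
  if (length(rest))
    cols[rest] <- hcl.colors(max(length(rest), 2), "Dark 3")[seq_along(rest)]
  stats::setNames(cols, groups)
}

#' Overlay a phylogenetic tree on an embedding
#'
#' Produces the combined figure object: the embedded leaf points with the
#' tree's edges drawn over them, so one scene carries both the
#' distance-based map and the (possibly externally inferred) phylogeny.
#' Leaf coordinates are taken from the embedding unchanged — the overlay
#' never moves data points. Internal vertices are positioned either at
#' the unweighted mean of their descendant leaves (`"centroid"`,
#' deterministic and parameter-free) or by Sammon-embedding an augmented
#' distance matrix whose entries involving internal nodes are patristic
#' distances, with the leaves frozen in place (`"joint"`).
#'
#' @param emb a [sammon_map()] fit.
#' @param tree a `phylo` whose leaf labels all occur in the embedding.
#' @param method `"centroid"` (default) or `"joint"`.
#' @param groups optional [group_annotation()].
#' @return an object of class `overlay_scene`: `nodes` (data.frame: id,
#'   label, type, coordinates, group, color, saturated), `edges`
#'   (data.frame: from, to, length, support) and `provenance`.
#' @export
overlay_tree <- function(emb, tree, method = c("centroid", "joint"),
                         groups = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(emb, "sammon_map"), inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, emb$labels)
  if (length(missing))
    ps_stop("tree leaves absent from embedding: ",
            paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  k <- emb$k
  leafX <- emb$X[match(tree$tip.label, emb$labels), , drop = FALSE]

  desc <- phangorn::Descendants(tree, seq_len(ntip + nnode), type = "tips")
  centroids <- t(vapply(seq_len(nnode) + ntip, function(nd)
    colMeans(leafX[desc[[nd]], , drop = FALSE]), numeric(k)))

  if (method == "centroid") {
    intX <- centroids
  } else {
    pat <- patristic_distances(tree, include_internal = TRUE)
    D <- pat$d
    # leaf-leaf block keeps the original-space distances the map was
    # fitted to; only pairs involving an internal node are patristic
    dm0 <- emb$dm$d[match(tree$tip.label, emb$dm$labels),
                    match(tree$tip.label, emb$dm$labels)]
    D[seq_len(ntip), seq_len(ntip)] <- dm0
    X0 <- rbind(leafX, centroids)
    pos <- D[upper.tri(D)]
    if (any(pos == 0)) {               # guard zero-length branches
      D[D == 0] <- min(pos[pos > 0]) * 1e-3
      diag(D) <- 0
    }
    fit <- .sammon_descent(D, X0, free = c(rep(FALSE, ntip),
                                           rep(TRUE, nnode)))
    intX <- fit$X[seq_len(nnode) + ntip, , drop = FALSE]
  }

  ids <- c(paste0("leaf:", tree$tip.label),
           paste0("internal:", seq_len(nnode) + ntip))
  labs <- c(tree$tip.label,
            if (!is.null(tree$node.label)) tree$node.label
            else rep("", nnode))
  grp <- rep(NA_character_, ntip + nnode)
  col <- rep("grey30", ntip + nnode)
  if (!is.null(groups)) {
    groups <- group_annotation(groups)
    unknown <- setdiff(groups$taxon, emb$labels)
    if (length(unknown))
      ps_stop("annotation references unknown taxa: ",
              paste(unknown, collapse = ", "))
    gi <- match(tree$tip.label, groups$taxon)
    grp[seq_len(ntip)] <- groups$group[gi]
    pal <- if ("color" %in% names(groups))
      stats::setNames(groups$color[!duplicated(groups$group)],
                      groups$group[!duplicated(groups$group)])
    else .group_colors(unique(groups$group))
    col[seq_len(ntip)] <- pal[grp[seq_len(ntip)]]
  }
  sat <- rep(FALSE, ntip + nnode)
  if (!is.null(emb$dm$saturated) && nrow(emb$dm$saturated) > 0)
    sat[seq_len(ntip)] <- tree$tip.label %in% c(emb$dm$saturated)

  coords <- rbind(leafX, intX)
  colnames(coords) <- c("x", "y", "z")[seq_len(k)]
  rownames(coords) <- NULL
  nodes <- data.frame(id = ids, label = labs,
                      type = rep(c("leaf", "internal"), c(ntip, nnode)),
                      coords, group = grp, color = col, saturated = sat,
                      stringsAsFactors = FALSE, row.names = NULL)
  sup <- tree_supports(tree)
  edge_support <- rep(NA_real_, nrow(tree$edge))
  if (!is.null(sup)) {
    int_child <- tree$edge[, 2] > ntip
    edge_support[int_child] <- sup[tree$edge[int_child, 2] - ntip]
  }
  edges <- data.frame(from = ids[tree$edge[, 1]], to = ids[tree$edge[, 2]],
                      length = tree$edge.length %||%
                        rep(NA_real_, nrow(tree$edge)),
                      support = edge_support, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 provenance = list(package = "protspace",
                                   version = as.character(
                                     utils::packageVersion("protspace")),
                                   overlay_method = method,
                                   embedding_seed = emb$seed,
                                   embedding_stress = emb$stress,
                                   k = k,
                                   schema_version = "1.0")),
            class = "overlay_scene")
}

#' @export
print.overlay_scene <- function(x, ...) {
  cat("overlay_scene:", sum(x$nodes$type == "leaf"), "leaves +",
      sum(x$nodes$type == "internal"), "internal vertices,",
      nrow(x$edges), "edges (", x$provenance$overlay_method, "overlay )\n")
  invisible(x)
}

#' Per-group spread of an embedding
#'
#' Quantifies the "compact versus widely spread" reading of a sequence
#' space map: for each group the root-mean-square of pairwise embedded
#' distances within the group, and its ratio to the global RMS over all
#' pairs (the relative spread, invariant to rigid motion and global
#' scaling of the map). Singleton groups are reported with `NA` spread
#' and flagged, never dropped.
#'
#' @param emb a [sammon_map()] fit or a coordinate matrix with rownames.
#' @param ann a [group_annotation()].
#' @return data.frame (class `spread_report`) with one row per group:
#'   `group`, `n`, `spread`, `rel_spread`, `singleton`; the global RMS is
#'   attached as attribute `global_rms`.
#' @export
group_spread <- function(emb, ann) {
  if (inherits(emb, "sammon_map")) {
    X <- emb$X
    labels <- emb$labels
  } else {
    X <- as.matrix(emb)
    labels <- rownames(X)
  }
  ann <- group_annotation(ann)
  unknown <- setdiff(ann$taxon, labels)
  if (length(unknown))
    ps_stop("annotation references unknown taxa: ",
            paste(unknown, collapse = ", "))
  dmat <- as.matrix(dist(X))
  rms <- function(v) sqrt(mean(v^2))
  global_rms <- rms(dmat[upper.tri(dmat)])
  groups <- unique(ann$group)
  rows <- lapply(groups, function(g) {
    idx <- match(ann$taxon[ann$group == g], labels)
    n_g <- length(idx)
    if (n_g < 2)
      return(data.frame(group = g, n = n_g, spread = NA_real_,
                        rel_spread = NA_real_, singleton = TRUE))
    sub <- dmat[idx, idx]
    sp <- rms(sub[upper.tri(sub)])
    data.frame(group = g, n = n_g, spread = sp,
               rel_spread = sp / global_rms, singleton = FALSE)
  })
  if (all(vapply(rows, function(r) r$singleton, logical(1))))
    ps_stop("need at least one group with >= 2 taxa")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "global_rms") <- global_rms
  class(out) <- c("spread_report", "data.frame")
  out
}

#' @export
print.spread_report <- function(x, ...) {
  cat("group spread (global RMS pairwise distance =",
      format(signif(attr(x, "global_rms"), 6)), ")\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
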