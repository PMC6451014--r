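# small helper: embedding-like object with known coordinates
fake_fit <- function(X, labels = rownames(X)) {
  dm <- evodist(as.matrix(dist(X)), labels)
  structure(list(labels = labels, X = `rownames<-`(as.matrix(X), labels),
                 k = ncol(X), stress = 0, seed = 1, dm = dm,
                 merged_duplicates = 0),
            class = "sammon_map")
}

test_that("centroid overlay places internal vertices at descendant means", {
  X <- rbind(A = c(0, 0, 0), B = c(2, 0, 0))
  fit <- fake_fit(X)
  tree <- read_newick("(A:1,B:1);")
  sc <- overlay_tree(fit, tree, "centroid")
  int <- sc$nodes[sc$nodes$type == "internal", ]
  expect_equal(unlist(int[, c("x", "y", "z")]), c(x = 1, y = 0, z = 0))

  # 3-leaf star: root at the triangle's centroid
  tri <- rbind(A = c(0, 0), B = c(1, 0), C = c(0.5, sqrt(3) / 2))
  sc2 <- overlay_tree(fake_fit(tri), read_newick("(A:1,B:1,C:1);"),
                      "centroid")
  int2 <- sc2$nodes[sc2$nodes$type == "internal", ]
  expect_equal(unlist(int2[, c("x", "y")]),
               c(x = 0.5, y = sqrt(3) / 6), tolerance = 1e-12)
})

test_that("overlay never moves the embedded leaf points", {
  pc <- planted_configuration(8, 3, seed = 12)
  fit <- sammon_map(pc$dm, k = 3, seed = 1, restarts = 2)
  tree <- neighbor_joining(pc$dm)
  for (method in c("centroid", "joint")) {
    sc <- overlay_tree(fit, tree, method)
    leaf <- sc$nodes[sc$nodes$type == "leaf", ]
    got <- as.matrix(leaf[, c("x", "y", "z")])
    want <- fit$X[match(leaf$label, fit$labels), ]
    dimnames(got) <- dimnames(want) <- NULL
    expect_identical(got, want)          # bit-exact
    # the edge list is exactly the tree's edge set
    expect_equal(nrow(sc$edges), nrow(tree$edge))
    expect_true(all(sc$edges$to %in% sc$nodes$id))
  }
  expect_error(overlay_tree(fit, read_newick("(p01:1,zzz:1);")),
               "absent from embedding: zzz")
})

test_that("centroid overlay commutes with rigid motions", {
  pc <- planted_configuration(6, 3, seed = 3)
  fit <- sammon_map(pc$dm, k = 3, seed = 1, restarts = 1)
  tree <- neighbor_joining(pc$dm)
  sc <- overlay_tree(fit, tree, "centroid")
  R <- random_rotation(3, 5)
  cshift <- c(0.3, -1, 2)
  fit2 <- fit
  fit2$X <- fit$X %*% R + matrix(cshift, nrow(fit$X), 3, byrow = TRUE)
  sc2 <- overlay_tree(fit2, tree, "centroid")
  M <- as.matrix(sc$nodes[, c("x", "y", "z")])
  M2 <- as.matrix(sc2$nodes[, c("x", "y", "z")])
  expect_equal(M2, M %*% R + matrix(cshift, nrow(M), 3, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group spread matches hand-computed values", {
  # two points at distance 2
  X <- rbind(a = c(0, 0), b = c(2, 0), c = c(9, 9), d = c(9, 10))
  ann <- group_annotation(data.frame(taxon = c("a", "b", "c", "d"),
                                     group = c("g1", "g1", "g2", "g2")))
  sp <- group_spread(X, ann)
  expect_equal(sp$spread[sp$group == "g1"], 2)

  # unit square: RMS of {1,1,1,1,sqrt2,sqrt2} = sqrt(8/6)
  sq <- rbind(p = c(0, 0), q = c(1, 0), r = c(1, 1), s = c(0, 1))
  ann2 <- group_annotation(data.frame(taxon = rownames(sq), group = "sq"))
  sp2 <- group_spread(sq, ann2)
  expect_equal(sp2$spread, sqrt(8 / 6))
  expect_equal(sp2$rel_spread, 1)        # only group = global

  # coincident points spread 0
  z <- rbind(u = c(1, 1), v = c(1, 1), w = c(5, 5))
  annz <- group_annotation(data.frame(taxon = c("u", "v", "w"),
                                      group = c("z", "z", "far")))
  spz <- group_spread(z, annz)
  expect_equal(spz$spread[spz$group == "z"], 0)
  expect_true(spz$singleton[spz$group == "far"])
  expect_true(is.na(spz$spread[spz$group == "far"]))

  expect_error(group_spread(X, group_annotation(
    data.frame(taxon = "nope", group = "g"))), "unknown taxa")
})

test_that("relative spread is scale- and rigid-motion invariant", {
  set.seed(21)
  X <- matrix(rnorm(12 * 3), 12)
  rownames(X) <- paste0("t", 1:12)
  ann <- group_annotation(data.frame(taxon = rownames(X),
                                     group = rep(c("g1", "g2"), each = 6)))
  sp <- group_spread(X, ann)
  sp_scaled <- group_spread(X * 7.3, ann)
  expect_equal(sp_scaled$rel_spread, sp$rel_spread, tolerance = 1e-12)
  R <- random_rotation(3, 2)
  sp_rot <- group_spread(X %*% R + 5, ann)
  expect_equal(sp_rot$rel_spread, sp$rel_spread, tolerance = 1e-10)
  # absolute spread scales linearly
  expect_equal(sp_scaled$spread, sp$spread * 7.3, tolerance = 1e-12)
})

test_that("procrustes superposition undoes rigid motions", {
  set.seed(8)
  X <- matrix(rnorm(10 * 3), 10)
  R <- random_rotation(3, 1)
  Y <- X %*% R + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  expect_lt(procrustes_align(X, Y)$rmsd, 1e-10)

  # mirrored copy: only recoverable when reflection is allowed
  Ym <- X %*% diag(c(-1, 1, 1))
  expect_lt(procrustes_align(X, Ym, allow_reflection = TRUE)$rmsd, 1e-10)
  expect_gt(procrustes_align(X, Ym, allow_reflection = FALSE)$rmsd, 0.1)
  expect_error(procrustes_align(X, Y[1:5, ]), "shape")
})

test_that("procrustes rmsd matches a brute-force rotation search", {
  # unit square vs its doubled copy; no scaling is fitted, so the
  # residual is real. Oracle: exhaustive search over 2D rotations.
  X <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  Y <- X * 2
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  angles <- seq(0, 2 * pi, length.out = 100001)
  rmsd_at <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    sqrt(mean(rowSums((Xc - Yc %*% R)^2)))
  }, numeric(1))
  expect_equal(procrustes_align(X, Y)$rmsd, min(rmsd_at),
               tolerance = 1e-6)
})

test_that("procrustes agrees with an independent implementation", {
  set.seed(5)
  X <- matrix(rnorm(8 * 3), 8)
  Y <- matrix(rnorm(8 * 3), 8)
  ours <- procrustes_align(X, Y, allow_reflection = TRUE)
  veg <- vegan::procrustes(X, Y, scale = FALSE)
  expect_equal(ours$rmsd, sqrt(veg$ss / nrow(X)), tolerance = 1e-8)
})

test_that("scene export formats round-trip and enumerate all nodes", {
  pc <- planted_configuration(7, 3, seed = 6)
  fit <- sammon_map(pc$dm, k = 3, seed = 1, restarts = 2)
  tree <- neighbor_joining(pc$dm)
  ann <- group_annotation(data.frame(
    taxon = pc$dm$labels,
    group = rep(c("monofunctional", "bifunctional"), c(3, 4))))
  sc <- overlay_tree(fit, tree, "centroid", ann)

  f <- withr::local_tempfile(fileext = ".json")
  export_scene(sc, f, "json")
  back <- read_scene(f)
  expect_identical(back$nodes$x, sc$nodes$x)
  expect_identical(back$nodes$id, sc$nodes$id)
  expect_identical(back$edges, sc$edges)

  d <- withr::local_tempdir()
  export_scene(sc, d, "tsv_bundle")
  pts <- read.delim(file.path(d, "points.tsv"))
  expect_equal(nrow(pts), 7 + tree$Nnode)   # one row per tree node
  expect_true(file.exists(file.path(d, "edges.tsv")))
  grp <- read.delim(file.path(d, "groups.tsv"))
  # the paper-style convention: blue monofunctional, red bifunctional
  expect_equal(grp$color[grp$group == "monofunctional"], "blue")
  expect_equal(grp$color[grp$group == "bifunctional"], "red")

  h <- withr::local_tempfile(fileext = ".html")
  export_scene(sc, h, "html3d")
  expect_gt(file.size(h), 1000)

  # no annotation: a single default group
  sc0 <- overlay_tree(fit, tree, "centroid")
  d0 <- withr::local_tempdir()
  export_scene(sc0, d0, "tsv_bundle")
  expect_equal(nrow(read.delim(file.path(d0, "groups.tsv"))), 1)
})
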