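test_that("stress formula reproduces hand-computed values", {
  tri <- dist_from_pairs(c("a", "b", "c"), ab = 1, ac = 1, bc = 1)
  # all points coincident: E = (1/3) * 3 * (1-0)^2/1 = 1
  expect_equal(sammon_stress(matrix(0, 3, 2), tri), 1)
  # two points at embedded distance 2 for d* = 1: E = (1-2)^2/1 = 1
  two <- dist_from_pairs(c("u", "v"), uv = 1)
  expect_equal(sammon_stress(rbind(c(0, 0), c(2, 0)), two), 1)
  # exact reproduction: E = 0
  X <- rbind(c(0, 0), c(0, 1))
  expect_equal(sammon_stress(X, dist_from_pairs(c("u", "v"), uv = 1)), 0)
  expect_error(sammon_stress(matrix(Inf, 2, 2), two), "non-finite")
  dup <- evodist(matrix(c(0, 0, 0, 0), 2), c("x", "y"))
  expect_error(sammon_stress(matrix(0, 2, 2), dup), "merge duplicate")
})

test_that("perfectly embeddable configurations reach zero stress", {
  # equilateral triangle of side 1 in the plane
  tri <- dist_from_pairs(c("a", "b", "c"), ab = 1, ac = 1, bc = 1)
  fit <- sammon_map(tri, k = 2, seed = 1, restarts = 2)
  expect_lt(fit$stress, 1e-6)
  expect_equal(as.vector(dist(fit$X)), rep(1, 3), tolerance = 1e-4)

  # unit square: four sides 1, two diagonals sqrt(2)
  sq <- dist_from_pairs(c("a", "b", "c", "d"),
                        ab = 1, bc = 1, cd = 1, ad = 1,
                        ac = sqrt(2), bd = sqrt(2))
  expect_lt(sammon_map(sq, k = 2, seed = 1, restarts = 2)$stress, 1e-6)

  # planted 3D cloud
  pc <- planted_configuration(12, 3, seed = 5)
  fit3 <- sammon_map(pc$dm, k = 3, seed = 1, restarts = 3)
  expect_lt(fit3$stress, 1e-6)
  expect_lt(procrustes_align(pc$X, fit3$X,
                             allow_reflection = TRUE)$rmsd, 1e-3)
})

test_that("reported stress is the stress of the returned coordinates", {
  pc <- planted_configuration(9, 3, seed = 2)
  fit <- sammon_map(pc$dm, k = 2, seed = 3, restarts = 4)
  expect_equal(fit$stress, sammon_stress(fit$X, pc$dm), tolerance = 1e-12)
  expect_equal(fit$stress, min(fit$restart_stresses))
})

test_that("stress descent is monotone in every restart", {
  pc <- planted_configuration(10, 3, seed = 8)
  fit <- sammon_map(pc$dm, k = 2, seed = 1, restarts = 5)
  for (tr in fit$traces)
    expect_true(all(diff(tr) <= 0))
})

test_that("stress is invariant under rigid motions of the map", {
  pc <- planted_configuration(8, 3, seed = 4)
  fit <- sammon_map(pc$dm, k = 3, seed = 1, restarts = 1)
  E0 <- sammon_stress(fit$X, pc$dm)
  for (seed in 1:5) {
    R <- random_rotation(3, seed)
    shift <- matrix(rnorm(3), nrow(fit$X), 3, byrow = TRUE)
    expect_equal(sammon_stress(fit$X %*% R + shift, pc$dm), E0,
                 tolerance = 1e-12)
    # reflection too: symmetry is admissible
    M <- diag(c(-1, 1, 1))
    expect_equal(sammon_stress(fit$X %*% M, pc$dm), E0, tolerance = 1e-12)
  }
})

test_that("three dimensions never fit worse than two", {
  set.seed(31)
  X <- matrix(rnorm(10 * 5), 10)   # intrinsically 5-dimensional
  dm <- evodist(as.matrix(dist(X)), paste0("t", 1:10))
  f2 <- sammon_map(dm, k = 2, seed = 6, restarts = 4)
  f3 <- sammon_map(dm, k = 3, seed = 6, restarts = 4)
  expect_lte(f3$stress, f2$stress)
  expect_gt(f2$stress, 0)          # genuinely not embeddable in 2D
})

test_that("identical inputs give bit-identical embeddings", {
  pc <- planted_configuration(7, 3, seed = 10)
  f1 <- sammon_map(pc$dm, k = 2, seed = 5, restarts = 3)
  f2 <- sammon_map(pc$dm, k = 2, seed = 5, restarts = 3)
  expect_identical(f1$X, f2$X)
  expect_identical(f1$restart_stresses, f2$restart_stresses)
  # and the caller's RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(sammon_map(pc$dm, k = 2, seed = 5, restarts = 1))
  expect_identical(rnorm(1), before)
})

test_that("duplicate taxa are merged and re-attached at one point", {
  X <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(X[c(1, 1, 2, 3, 4), ]))   # taxon 2 duplicates 1
  dm <- evodist(d, paste0("s", 1:5))
  expect_warning(fit <- sammon_map(dm, k = 2, seed = 1, restarts = 2),
                 "duplicate")
  expect_identical(fit$X["s1", ], fit$X["s2", ])
  expect_equal(fit$merged_duplicates, 1)
})

test_that("random initialization also descends to a valid map", {
  pc <- planted_configuration(8, 2, seed = 3)
  fit <- sammon_map(pc$dm, k = 2, seed = 2, restarts = 3, init = "random")
  expect_lt(fit$stress, 0.01)
  for (tr in fit$traces) expect_true(all(diff(tr) <= 0))
})

test_that("our minimizer matches the classical implementation's criterion", {
  # MASS::sammon optimizes the same stress; its reported value must equal
  # our formula evaluated on its output, and our optimum should not be
  # worse than its
  set.seed(77)
  X <- matrix(rnorm(9 * 5), 9)
  dm <- evodist(as.matrix(dist(X)), paste0("t", 1:9))
  ms <- MASS::sammon(as.dist(dm), k = 2, trace = FALSE)
  expect_equal(sammon_stress(ms$points, dm), ms$stress, tolerance = 1e-6)
  ours <- sammon_map(dm, k = 2, seed = 1, restarts = 5)
  expect_lte(ours$stress, ms$stress + 1e-6)
})

test_that("shepard data enumerate every unordered pair", {
  pc <- planted_configuration(6, 2, seed = 1)
  fit <- sammon_map(pc$dm, k = 2, seed = 1, restarts = 1)
  sh <- shepard_data(fit)
  expect_equal(nrow(sh), 6 * 5 / 2)
  # perfect embedding: all points on the diagonal
  expect_lt(max(abs(sh$dstar - sh$d)), 1e-4)
  # collapsed configuration: all embedded distances zero
  sh0 <- shepard_data(matrix(0, 6, 2), pc$dm)
  expect_true(all(sh0$d == 0))
  # residuals are d* - d
  expect_equal(unname(residuals(fit)), sh$dstar - sh$d)
})

test_that("fit methods print and plot without error", {
  pc <- planted_configuration(6, 2, seed = 1)
  fit <- sammon_map(pc$dm, k = 2, seed = 1, restarts = 2)
  expect_output(print(fit), "Sammon map")
  expect_output(print(summary(fit)), "distance correlation")
  expect_identical(coef(fit), fit$X)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, type = "shepard"))
})
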