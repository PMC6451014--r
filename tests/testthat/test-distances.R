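test_that("observed difference fractions follow the site-count rules", {
  expect_equal(p_distance("AAAA", "AAAA")$p, 0)
  s <- p_distance("AAAA", "AATA")
  expect_equal(s$p, 0.25)
  expect_equal(s$n_compared, 4)
  g <- p_distance("A-CD", "AVCD")      # gap column dropped
  expect_equal(g$n_compared, 3)
  expect_equal(g$p, 0)
  g2 <- p_distance("AXCD", "AVCD")     # X treated as missing, like a gap
  expect_equal(g2$n_compared, 3)
  expect_equal(g2$p, 0)
  expect_error(p_distance("---", "AAA"), "no comparable")
  expect_error(p_distance("AA", "AAA"), "length")
})

test_that("poisson correction matches its closed form and caps saturation", {
  expect_equal(as.numeric(poisson_distance(0)), 0)
  expect_equal(as.numeric(poisson_distance(0.25)), -log(0.75))
  expect_equal(round(as.numeric(poisson_distance(0.25)), 6), 0.287682)
  d <- poisson_distance(0.999999999)
  expect_equal(as.numeric(d), 10)
  expect_true(attr(d, "saturated"))
  expect_error(poisson_distance(1.2), "\\[0,1\\]")
})

test_that("ML distance maximizes the likelihood it claims to maximize", {
  # identical sequences: boundary maximum at t = 0
  fit <- pam_ml_distance("ACDEFGHIKL", "ACDEFGHIKL", DAYHOFF)
  expect_equal(fit$t_hat, 0)

  # grid-search oracle on simulated 100-site pairs (finer check with
  # more pairs lives in the acceptance suite)
  grid <- seq(0.001, 10, by = 0.001)
  for (seed in 1:5) {
    t_true <- c(0.1, 0.3, 0.8, 1.5, 2.5)[seed]
    sq <- simulated_pair(t_true, 100, seed + 100)
    N <- protspace:::.pair_counts(sq[1], sq[2])
    ll <- vapply(grid, function(t)
      protspace:::.pair_loglik(N, DAYHOFF, t), numeric(1))
    t_grid <- grid[which.max(ll)]
    fit <- pam_ml_distance(sq[1], sq[2], DAYHOFF)
    expect_lt(abs(fit$t_hat - t_grid), 0.001 + 1e-9)
    expect_gte(fit$logL + 1e-9, max(ll))
  }
})

test_that("ML distance recovers the divergence it was simulated at", {
  sq <- simulated_pair(0.5, 10000, seed = 7)
  fit <- pam_ml_distance(sq[1], sq[2], DAYHOFF)
  expect_lt(abs(fit$t_hat - 0.5), 0.05)
})

test_that("likelihood distance is invariant to column order", {
  sq <- simulated_pair(0.7, 200, seed = 3)
  set.seed(9)
  perm <- sample(nchar(sq[1]))
  shuffle <- function(s) paste(strsplit(s, "")[[1]][perm], collapse = "")
  f1 <- pam_ml_distance(sq[1], sq[2], DAYHOFF)
  f2 <- pam_ml_distance(shuffle(sq[1]), shuffle(sq[2]), DAYHOFF)
  expect_equal(f1$t_hat, f2$t_hat)
  expect_equal(f1$logL, f2$logL)
})

test_that("poisson and ML distances agree in the weak-divergence limit", {
  rel <- vapply(1:5, function(seed) {
    sq <- simulated_pair(0.1, 5000, seed = seed + 20)
    p <- p_distance(sq[1], sq[2])$p
    dp <- as.numeric(poisson_distance(p))
    dm <- pam_ml_distance(sq[1], sq[2], DAYHOFF)$t_hat
    abs(dp - dm) / dm
  }, numeric(1))
  expect_lt(mean(rel), 0.15)
})

test_that("distance matrices assemble per-pair results symmetrically", {
  msa <- protein_msa(c(A = "ACDEF", B = "ACDEF"))
  dm <- distance_matrix(msa, "dayhoff_ml", model = DAYHOFF)
  expect_equal(unname(dm$d), matrix(0, 2, 2))

  msa3 <- protein_msa(c(A = "ACDEFGHIKL", B = "ACDEFGHIKV",
                        C = "TCDEFGHIKV"))
  dm3 <- distance_matrix(msa3, "poisson")
  expect_equal(dm3$d["A", "B"],
               as.numeric(poisson_distance(p_distance(
                 msa3$seqs["A"], msa3$seqs["B"])$p)))
  expect_identical(dm3$d, t(dm3$d))

  # permuting taxa permutes the matrix, values unchanged
  msa3p <- protein_msa(msa3$seqs[c(3, 1, 2)])
  dm3p <- distance_matrix(msa3p, "poisson")
  expect_equal(dm3p$d[msa3$taxa, msa3$taxa], dm3$d)

  # a pair with no shared columns is an error naming the pair
  msag <- protein_msa(c(A = "AC--", B = "--DE", C = "ACDE"))
  expect_error(distance_matrix(msag, "p"), "'A', 'B'")
})

test_that("complete deletion removes columns with any gap or X", {
  msa <- protein_msa(c(A = "ACD-F", B = "ACDEF", C = "TCDEX"))
  dm <- distance_matrix(msa, "p", gap_policy = "complete_deletion")
  # columns 4 and 5 drop for every pair; A vs C differ at 1 of 3
  expect_equal(dm$d["A", "C"], 1 / 3)
  expect_equal(dm$d["A", "B"], 0)
})

test_that("saturated pairs are capped and flagged, not dropped", {
  # two maximally different repeats saturate the poisson correction
  msa <- protein_msa(c(A = strrep("AC", 40), B = strrep("CA", 40),
                       C = strrep("AC", 40)))
  dm <- distance_matrix(msa, "poisson")
  expect_equal(dm$d["A", "B"], 10)
  expect_true(!is.null(dm$saturated))
  expect_true(any(apply(dm$saturated, 1, setequal, c("A", "B"))))
})
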