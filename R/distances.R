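#' Observed difference fraction between two aligned rows
#'
#' Columns where either sequence carries a gap (`-`) or the ambiguity code
#' `X` are excluded (pairwise deletion). The building block for corrected
#' evolutionary distances.
#'
#' @param a,b aligned amino-acid strings of equal length.
#' @return list with `n_compared`, `n_diff` and `p = n_diff/n_compared`.
#' @examples
#' p_distance("AAAA", "AATA")$p   # 0.25
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    ps_stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ia <- match(ca, AA20)
  ib <- match(cb, AA20)
  keep <- !is.na(ia) & !is.na(ib)
  n_compared <- sum(keep)
  if (n_compared == 0)
    ps_stop("no comparable columns (all gap or ambiguous)")
  n_diff <- sum(ia[keep] != ib[keep])
  list(n_compared = n_compared, n_diff = n_diff, p = n_diff / n_compared)
}

#' Poisson-corrected distance
#'
#' \eqn{d = -\ln(1 - p)} substitutions per site, the correction that
#' assumes all replacements equally likely. Differences so extensive that
#' `p` is within `1e-9` of 1 no longer constrain the distance; such pairs
#' are capped at `d_max` and flagged as saturated (attribute
#' `"saturated"`).
#'
#' @param p observed difference fraction in `[0, 1]`.
#' @param d_max saturation cap, substitutions per site.
#' @return numeric distance with logical attribute `saturated`.
#' @export
poisson_distance <- function(p, d_max = 10) {
  if (!is.finite(p) || p < 0 || p > 1)
    ps_stop("difference fraction must be in [0,1], got ", p)
  if (p >= 1 - 1e-9)
    return(structure(d_max, saturated = TRUE))
  d <- min(-log(1 - p), d_max)
  structure(d, saturated = d >= d_max)
}

# 20x20 matrix of pair counts over comparable columns
.pair_counts <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ia <- match(ca, AA20)
  ib <- match(cb, AA20)
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) return(NULL)
  matrix(tabulate((ia[keep] - 1L) * 20L + ib[keep], nbins = 400L),
         20, 20, byrow = TRUE, dimnames = list(AA20, AA20))
}

# log-likelihood of a pair at divergence t given a count matrix N:
# l(t) = sum_ab N_ab log(pi_a P_ab(t))
.pair_loglik <- function(N, model, t) {
  P <- transition_matrix(model, t)
  lp <- log(pmax(model$pi * P, 1e-300))
  sum(N * lp)
}

#' Maximum-likelihood pairwise distance under the Dayhoff model
#'
#' Finds the divergence \eqn{\hat t} maximizing
#' \eqn{\ell(t) = \sum_{\mathrm{sites}} \ln(\pi_{a} P_{ab}(t))} over the
#' comparable columns of an aligned pair — the model-based distance the
#' classic protdist program computes in its Dayhoff-PAM mode. The search
#' is a bounded one-dimensional maximization on \eqn{[0, d_{max}]}: a
#' coarse scan (including the Poisson estimate as a candidate) brackets
#' the optimum, which is then refined by golden-section/parabolic search.
#'
#' @param a,b aligned amino-acid strings.
#' @param model a [dayhoff_model()].
#' @param d_max upper bound on the distance, substitutions per site.
#' @param tol absolute tolerance on \eqn{\hat t}.
#' @return list with `t_hat`, `logL` and `saturated` (TRUE when the
#'   estimate hit `d_max`).
#' @export
pam_ml_distance <- function(a, b, model = dayhoff_model(), d_max = 10,
                            tol = 1e-6) {
  N <- .pair_counts(a, b)
  if (is.null(N)) ps_stop("no comparable columns (all gap or ambiguous)")
  if (sum(N) == sum(diag(N)))                       # identical overlap
    return(list(t_hat = 0, logL = .pair_loglik(N, model, 0),
                saturated = FALSE))
  psum <- p_distance(a, b)
  seed <- as.numeric(poisson_distance(psum$p, d_max))
  grid <- sort(unique(pmin(pmax(
    c(seq(0.005, d_max, length.out = 40), seed), 1e-8), d_max)))
  ll <- vapply(grid, function(t) .pair_loglik(N, model, t), numeric(1))
  i <- which.max(ll)
  lo <- if (i > 1) grid[i - 1] else 1e-9
  hi <- if (i < length(grid)) grid[i + 1] else d_max
  opt <- optimize(function(t) .pair_loglik(N, model, t),
                  interval = c(lo, hi), maximum = TRUE, tol = tol)
  t_hat <- opt$maximum
  logL <- opt$objective
  ll_cap <- .pair_loglik(N, model, d_max)
  if (ll_cap > logL) { t_hat <- d_max; logL <- ll_cap }
  list(t_hat = t_hat, logL = logL, saturated = t_hat >= d_max - tol)
}

#' Pairwise distance matrix of an alignment
#'
#' All \eqn{n(n-1)/2} pairs are computed independently. Under
#' `"pairwise_deletion"` (the protdist behavior and the default) each pair
#' uses every column where neither member has a gap or `X`; under
#' `"complete_deletion"` any column containing a gap or `X` in any row is
#' removed first.
#'
#' @param msa a [protein_msa()].
#' @param method `"dayhoff_ml"` (maximum likelihood under the Dayhoff
#'   model, default), `"poisson"`, or `"p"` (uncorrected).
#' @param gap_policy `"pairwise_deletion"` or `"complete_deletion"`.
#' @param d_max saturation cap, substitutions per site.
#' @param model substitution model for `"dayhoff_ml"`.
#' @return an [evodist()] with saturated pairs flagged.
#' @export
distance_matrix <- function(msa,
                            method = c("dayhoff_ml", "poisson", "p"),
                            gap_policy = c("pairwise_deletion",
                                           "complete_deletion"),
                            d_max = 10,
                            model = NULL) {
  method <- match.arg(method)
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(msa, "protein_msa"))
  n <- length(msa$taxa)
  if (n < 2) ps_stop("need at least 2 taxa")
  seqs <- msa$seqs
  if (gap_policy == "complete_deletion") {
    m <- as.matrix(msa)
    keep <- colSums(!matrix(m %in% AA20, nrow(m))) == 0
    if (!any(keep)) ps_stop("no columns survive complete deletion")
    seqs <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  }
  if (method == "dayhoff_ml" && is.null(model)) model <- dayhoff_model()
  d <- matrix(0, n, n)
  sat <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    res <- tryCatch({
      switch(method,
        p = {
          s <- p_distance(seqs[i], seqs[j])
          structure(s$p, saturated = FALSE)
        },
        poisson = {
          s <- p_distance(seqs[i], seqs[j])
          poisson_distance(s$p, d_max)
        },
        dayhoff_ml = {
          f <- pam_ml_distance(seqs[i], seqs[j], model, d_max)
          structure(f$t_hat, saturated = f$saturated)
        })
    }, protspace_validation_error = function(e)
      ps_stop("pair ('", msa$taxa[i], "', '", msa$taxa[j], "'): ",
              conditionMessage(e)))
    d[i, j] <- d[j, i] <- as.numeric(res)
    if (isTRUE(attr(res, "saturated")))
      sat <- rbind(sat, c(msa$taxa[i], msa$taxa[j]))
  }
  evodist(d, msa$taxa, saturated = sat)
}
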