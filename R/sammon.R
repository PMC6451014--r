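#' Sammon stress of a configuration
#'
#' \deqn{E = \frac{1}{\sum_{i<j} d^*_{ij}} \sum_{i<j}
#'       \frac{(d^*_{ij} - d_{ij})^2}{d^*_{ij}}}
#' where \eqn{d^*_{ij}} are the original-space distances and \eqn{d_{ij}}
#' the Euclidean distances of the embedded points. The \eqn{1/d^*}
#' weighting is what makes the mapping favor the preservation of short
#' distances, so local structure survives the projection. \eqn{E = 0}
#' exactly when the configuration reproduces every original distance.
#'
#' @param X n x k coordinate matrix.
#' @param dm an [evodist()] with strictly positive off-diagonal entries
#'   (merge duplicate taxa first; see [sammon_map()]).
#' @return the stress, a non-negative scalar.
#' @export
sammon_stress <- function(X, dm) {
  stopifnot(inherits(dm, "evodist"))
  X <- as.matrix(X)
  if (any(!is.finite(X))) ps_stop("non-finite coordinates")
  dstar <- as.dist(dm)
  if (any(dstar <= 0))
    ps_stop("zero off-diagonal distance; merge duplicate taxa first")
  if (nrow(X) != length(dm$labels))
    ps_stop("coordinate rows do not match distance labels")
  d <- dist(X)
  sum((dstar - d)^2 / dstar) / sum(dstar)
}

# One monotone Sammon descent from a given start.
# D: full matrix with positive off-diagonals; X: start; free: logical,
# points allowed to move (frozen points anchor the rest, used by the
# joint overlay). Returns list(X, stress, trace, n_iter, converged).
.sammon_descent <- function(D, X, alpha = 0.3, tol = 1e-9, max_iter = 500,
                            free = NULL) {
  n <- nrow(D)
  k <- ncol(X)
  if (is.null(free)) free <- rep(TRUE, n)
  csum <- sum(D[upper.tri(D)])
  eps <- 1e-12
  stress_of <- function(X) {
    dm <- as.matrix(dist(X))
    sum(((D - dm)[upper.tri(D)])^2 / D[upper.tri(D)]) / csum
  }
  E <- stress_of(X)
  trace <- E
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    dm <- as.matrix(dist(X))
    dm[dm < eps] <- eps
    diag(dm) <- 1                     # excluded via zeroed weights below
    Dg <- D; diag(Dg) <- 1
    W1 <- (D - dm) / (Dg * dm)        # (d* - d)/(d* d)
    diag(W1) <- 0
    G <- matrix(0, n, k)
    H <- matrix(0, n, k)
    for (q in seq_len(k)) {
      dx <- outer(X[, q], X[, q], "-")
      G[, q] <- rowSums(W1 * dx)
      T2 <- ((D - dm) - dx^2 / dm * (1 + (D - dm) / dm)) / (Dg * dm)
      diag(T2) <- 0
      H[, q] <- rowSums(T2)
    }
    G <- -2 / csum * G
    H <- -2 / csum * H
    step <- G / pmax(abs(H), eps)
    step[!free, ] <- 0
    # step halving guarantees monotone descent
    a <- alpha
    ok <- FALSE
    for (h in 0:20) {
      Xn <- X - a * step
      En <- stress_of(Xn)
      if (En <= E) { ok <- TRUE; break }
      a <- a / 2
    }
    if (!ok) { converged <- TRUE; break }
    rel <- (E - En) / max(E, eps)
    X <- Xn
    E <- En
    trace <- c(trace, E)
    if (rel < tol || E < 1e-16) { converged <- TRUE; break }
  }
  list(X = X, stress = E, trace = trace, n_iter = iter,
       converged = converged)
}

# partition labels into groups of identical taxa (zero distance)
.zero_groups <- function(D) {
  n <- nrow(D)
  rep_of <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] == 0 && rep_of[j] == j) rep_of[j] <- rep_of[i]
  rep_of
}

#' Fit a Sammon map of a distance matrix
#'
#' The central fitting function of the package: embeds the original-space
#' distances into `k` Euclidean dimensions by iteratively minimizing the
#' Sammon stress (see [sammon_stress()]), using Sammon's diagonal-Newton
#' update \eqn{x \leftarrow x - \alpha\,
#' (\partial E/\partial x)/|\partial^2 E/\partial x^2|} with step halving
#' on any stress increase, so the recorded stress trace is non-increasing.
#' The first start is the classical (Torgerson) metric MDS configuration;
#' the remaining `restarts - 1` starts are seeded random configurations.
#' The best start (lowest final stress) is returned. Axes of the result
#' are arbitrary: any rotation, reflection or translation of the
#' configuration is an equally valid map, so only inter-point distances
#' carry meaning (compare configurations with [procrustes_align()]).
#'
#' Duplicate taxa (zero original distance, where the \eqn{1/d^*} weight is
#' undefined) are merged onto one representative point before fitting and
#' re-attached at its coordinates afterwards.
#'
#' @param dm an [evodist()].
#' @param k target dimension, 2 or 3.
#' @param seed integer seed controlling the random restarts.
#' @param restarts number of independent starts (>= 1).
#' @param max_iter iteration cap per start.
#' @param tol relative stress-change convergence threshold.
#' @param alpha Sammon's step ("magic") factor, in (0, 1].
#' @param init `"classical"` (Torgerson MDS, default) or `"random"` for
#'   the first start.
#' @return an object of class `sammon_map` with elements `labels`, `X`
#'   (n x k coordinates), `stress`, `n_iter`, `converged`,
#'   `restart_stresses`, `trace`, `seed`, `config` and `dm`.
#' @examples
#' pc <- planted_configuration(10, 2, seed = 1)
#' fit <- sammon_map(pc$dm, k = 2, seed = 1, restarts = 2)
#' fit$stress
#' @export
sammon_map <- function(dm, k = 3, seed = 1, restarts = 10, max_iter = 500,
                       tol = 1e-9, alpha = 0.3,
                       init = c("classical", "random")) {
  init <- match.arg(init)
  stopifnot(inherits(dm, "evodist"))
  if (!k %in% 2:3) ps_stop("k must be 2 or 3")
  if (restarts < 1) ps_stop("restarts must be >= 1")
  if (alpha <= 0 || alpha > 1) ps_stop("alpha must be in (0, 1]")
  if (tol <= 0) ps_stop("tol must be > 0")
  n_all <- length(dm$labels)
  if (n_all <= k) ps_stop("need more than k = ", k, " taxa, got ", n_all)

  rep_of <- .zero_groups(dm$d)
  reps <- sort(unique(rep_of))
  merged <- n_all - length(reps)
  D <- dm$d[reps, reps, drop = FALSE]
  n <- nrow(D)
  if (n <= k)
    ps_stop("after merging duplicates only ", n,
            " distinct points remain; need more than k = ", k)

  # restore caller RNG state afterwards
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })

  scale0 <- mean(D[upper.tri(D)])
  best <- NULL
  restart_stresses <- numeric(restarts)
  traces <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    set.seed(as.integer((seed + 7919 * (r - 1)) %% 2147483647L))
    if (r == 1 && init == "classical") {
      X0 <- suppressWarnings(cmdscale(D, k = k))
      if (ncol(X0) < k)
        X0 <- cbind(X0, matrix(0, n, k - ncol(X0)))
    } else {
      X0 <- matrix(rnorm(n * k, sd = scale0 / 2), n, k)
    }
    fit <- .sammon_descent(D, X0, alpha = alpha, tol = tol,
                           max_iter = max_iter)
    restart_stresses[r] <- fit$stress
    traces[[r]] <- fit$trace
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }

  # re-attach merged duplicates at their representative's coordinates
  X <- best$X[match(rep_of, reps), , drop = FALSE]
  rownames(X) <- dm$labels
  colnames(X) <- c("x", "y", "z")[seq_len(k)]
  stress <- if (merged == 0) sammon_stress(X, dm) else best$stress
  if (merged > 0)
    warning(merged, " duplicate taxa merged before embedding",
            call. = FALSE)
  structure(list(labels = dm$labels, X = X, k = k, stress = stress,
                 n_iter = best$n_iter, converged = best$converged,
                 restart_stresses = restart_stresses, trace = best$trace,
                 traces = traces,
                 seed = seed, merged_duplicates = merged,
                 config = list(k = k, seed = seed, restarts = restarts,
                               max_iter = max_iter, tol = tol,
                               alpha = alpha, init = init),
                 dm = dm),
            class = "sammon_map")
}

#' @export
print.sammon_map <- function(x, ...) {
  cat("Sammon map:", length(x$labels), "taxa in", x$k, "dimensions\n")
  cat(sprintf("  stress: %.6g  (best of %d restart%s)\n", x$stress,
              length(x$restart_stresses),
              if (length(x$restart_stresses) > 1) "s" else ""))
  cat("  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  invisible(x)
}

#' @export
summary.sammon_map <- function(object, ...) {
  sh <- shepard_data(object)
  out <- list(n = length(object$labels), k = object$k,
              stress = object$stress,
              restart_stresses = object$restart_stresses,
              distance_correlation = stats::cor(sh$dstar, sh$d),
              merged_duplicates = object$merged_duplicates,
              converged = object$converged)
  class(out) <- "summary.sammon_map"
  out
}

#' @export
print.summary.sammon_map <- function(x, ...) {
  cat("Sammon map summary\n")
  cat("  taxa:", x$n, " dimensions:", x$k, "\n")
  cat(sprintf("  stress: %.6g\n", x$stress))
  cat(sprintf("  restart stresses: %s\n",
              paste(signif(x$restart_stresses, 4), collapse = " ")))
  cat(sprintf("  original/embedded distance correlation: %.4f\n",
              x$distance_correlation))
  if (x$merged_duplicates > 0)
    cat("  duplicate taxa merged:", x$merged_duplicates, "\n")
  invisible(x)
}

#' @export
coef.sammon_map <- function(object, ...) object$X

#' Residuals of a Sammon map
#'
#' One residual \eqn{d^*_{ij} - d_{ij}} per unordered taxon pair: the
#' amount by which the map stretches (negative) or shrinks (positive)
#' each original distance.
#'
#' @param object a [sammon_map()] fit.
#' @param ... unused.
#' @export
residuals.sammon_map <- function(object, ...) {
  sh <- shepard_data(object)
  stats::setNames(sh$dstar - sh$d, paste(sh$taxon_i, sh$taxon_j, sep = ":"))
}

#' Plot a Sammon map
#'
#' `type = "map"` draws the embedded points (first two axes); `type =
#' "shepard"` draws the Shepard diagram of embedded versus original
#' distances, whose scatter around the diagonal visualizes the distortion
#' the stress summarizes.
#'
#' @param x a [sammon_map()] fit.
#' @param type `"map"` or `"shepard"`.
#' @param groups optional [group_annotation()] used to color points.
#' @param ... passed to [plot()].
#' @export
plot.sammon_map <- function(x, type = c("map", "shepard"), groups = NULL,
                            ...) {
  type <- match.arg(type)
  if (type == "shepard") {
    sh <- shepard_data(x)
    plot(sh$dstar, sh$d, xlab = "original distance d*",
         ylab = "embedded distance d",
         main = sprintf("Shepard diagram (stress %.4g)", x$stress), ...)
    abline(0, 1, lty = 2)
    return(invisible(x))
  }
  col <- "black"
  if (!is.null(groups)) {
    g <- groups$group[match(x$labels, groups$taxon)]
    col <- .group_colors(unique(g[!is.na(g)]))[g]
    col[is.na(col)] <- "grey50"
  }
  plot(x$X[, 1], x$X[, 2], col = col, pch = 19,
       xlab = colnames(x$X)[1], ylab = colnames(x$X)[2],
       main = "sequence space map", asp = 1, ...)
  text(x$X[, 1], x$X[, 2], x$labels, pos = 3, cex = 0.6, col = col)
  invisible(x)
}

#' Shepard data of an embedding
#'
#' One `(d*, d)` pair per unordered taxon pair, for distortion
#' diagnostics.
#'
#' @param x a [sammon_map()] fit, or an n x k coordinate matrix.
#' @param dm the [evodist()] of original distances (taken from the fit
#'   when `x` is a `sammon_map`).
#' @return data.frame with columns `taxon_i`, `taxon_j`, `dstar`, `d`.
#' @export
shepard_data <- function(x, dm = NULL) {
  if (inherits(x, "sammon_map")) {
    dm <- dm %||% x$dm
    X <- x$X
  } else X <- as.matrix(x)
  stopifnot(inherits(dm, "evodist"))
  n <- length(dm$labels)
  ij <- which(upper.tri(dm$d), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  dmat <- as.matrix(dist(X))
  data.frame(taxon_i = dm$labels[ij[, 1]],
             taxon_j = dm$labels[ij[, 2]],
             dstar = dm$d[ij],
             d = dmat[ij])
}
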