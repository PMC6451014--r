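#' The empirical Dayhoff (PAM) amino-acid replacement model
#'
#' Builds the reversible continuous-time Markov model of amino-acid
#' replacement from the classic Dayhoff exchangeability/frequency table
#' (shipped with the package as a text resource in the PAML `dayhoff.dat`
#' layout). Off-diagonal rates are \eqn{Q_{ab} = s\,S_{ab}\pi_b}, the
#' diagonal makes rows sum to zero, and the scale \eqn{s} is chosen so the
#' mean rate at stationarity is one: \eqn{-\sum_a \pi_a Q_{aa} = 1}.
#' Divergences are then in expected substitutions per site, the scale on
#' which PAM distances and tree branch lengths live (PAM250 is the point
#' of this same process at 250 accepted mutations per 100 residues).
#'
#' The spectral decomposition of the \eqn{\pi}-symmetrized rate matrix is
#' cached on the object, making [transition_matrix()] exact and stable at
#' any divergence.
#'
#' @return an object of class `substitution_model` with elements `name`,
#'   `Q`, `pi`, `S`, `scale` and the cached eigensystem.
#' @examples
#' m <- dayhoff_model()
#' max(abs(rowSums(m$Q)))            # rows of Q sum to 0
#' -sum(m$pi * diag(m$Q))            # unit mean rate
#' @export
dayhoff_model <- function() {
  path <- system.file("extdata", "dayhoff.dat", package = "protspace")
  if (!nzchar(path)) ps_stop("model constant table not found")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tri <- lapply(lines[1:19], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  pi <- as.numeric(strsplit(trimws(lines[20]), "\\s+")[[1]])
  # checksum on the embedded constants
  if (length(unlist(tri)) != 190 || length(pi) != 20 ||
      anyNA(unlist(tri)) || anyNA(pi) || any(unlist(tri) < 0) ||
      any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    ps_stop("model constant table corrupted")
  pi <- pi / sum(pi)
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (i in 2:20) S[i, seq_len(i - 1)] <- tri[[i - 1]]
  S <- S + t(S)
  Q <- S * rep(pi, each = 20)          # Q_ab = S_ab * pi_b, a != b
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # eigensystem of the symmetrized generator B = D^{1/2} Q D^{-1/2}
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  structure(list(name = "dayhoff", Q = Q, pi = stats::setNames(pi, AA20),
                 S = S, scale = 1 / scale,
                 eig = list(values = e$values,
                            U = (1 / sq) * e$vectors,
                            W = t(sq * e$vectors))),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("substitution_model:", x$name, "\n")
  cat("  mean rate at stationarity:", format(-sum(x$pi * diag(x$Q))), "\n")
  cat("  frequencies:", paste(names(x$pi)[1:5], round(x$pi[1:5], 3),
                              collapse = " "), "...\n")
  invisible(x)
}

#' Transition probabilities P(t) = exp(Qt)
#'
#' Computed through the cached eigendecomposition of the symmetrized rate
#' matrix (exact for a reversible model). Tiny negative entries arising
#' from round-off (never below `-1e-12`) are clamped to zero.
#'
#' @param model a [dayhoff_model()].
#' @param t divergence in expected substitutions per site, `t >= 0`.
#' @return 20x20 row-stochastic matrix, rows = source amino acid.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.finite(t) || t < 0)
    ps_stop("divergence must be finite and >= 0, got ", t)
  if (t == 0) {
    P <- diag(20)
    dimnames(P) <- list(AA20, AA20)
    return(P)
  }
  e <- model$eig
  P <- e$U %*% (exp(e$values * t) * e$W)
  P[P < 0] <- 0
  dimnames(P) <- list(AA20, AA20)
  P
}
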