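#' General time-reversible substitution model with discrete gamma rates
#'
#' Constructs a GTR+Gamma model: base frequencies `pi`, six exchangeability
#' rates in the order AC, AG, AT, CG, CT, GT, and a discrete gamma
#' distribution of site rates with `ncat` categories. The rate matrix is
#' scaled so that the mean substitution rate at stationarity is 1, so branch
#' lengths are expected substitutions per site. No invariant-sites class is
#' offered: rate heterogeneity is modelled by the gamma distribution alone.
#'
#' @param pi numeric(4), base frequencies for A, C, G, T; must sum to 1.
#' @param exch numeric(6), positive exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param alpha positive gamma shape; large values approach rate homogeneity.
#' @param ncat number of discrete gamma categories.
#' @return An object of class `gtr_model` with elements `pi`, `exch`,
#'   `alpha`, `ncat`, the scaled rate matrix `Q`, its eigendecomposition
#'   (`U`, `Uinv`, `lambda`), and the category rates `rates` (mean 1).
#' @examples
#' m <- gtr_model(alpha = 0.8)
#' rowSums(m$Q)  # zero
#' @export
gtr_model <- function(pi = rep(0.25, 4),
                      exch = rep(1, 6),
                      alpha = 1,
                      ncat = 4L) {
  stopifnot(length(pi) == 4, length(exch) == 6)
  if (abs(sum(pi) - 1) > 1e-12) stop("'pi' must sum to 1")
  if (any(pi <= 0)) stop("'pi' must be positive")
  if (any(exch <= 0)) stop("exchangeabilities must be positive")
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  pi <- as.numeric(pi)
  exch <- as.numeric(exch)
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- exch[k] * pi[j]
    Q[j, i] <- exch[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # mean rate at stationarity
  Q <- Q / mu
  # reversible eigendecomposition via the symmetrized matrix
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(sp)
  structure(list(pi = pi, exch = exch, alpha = alpha, ncat = as.integer(ncat),
                 Q = Q, U = U, Uinv = Uinv, lambda = eig$values,
                 rates = discrete_gamma_rates(alpha, ncat)),
            class = "gtr_model")
}

#' Discrete gamma category rates
#'
#' Category rates are the gamma quantiles at category midpoints
#' ((2i - 1) / 2k), normalized to mean 1.
#'
#' @param alpha gamma shape (> 0).
#' @param ncat number of categories.
#' @return numeric(ncat) rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L) {
  stopifnot(alpha > 0, ncat >= 1)
  r <- stats::qgamma((2 * seq_len(ncat) - 1) / (2 * ncat),
                     shape = alpha, rate = alpha)
  r / mean(r)
}

#' Transition probability matrix of a `gtr_model`
#'
#' @param model a `gtr_model`.
#' @param t branch length (expected substitutions per site; >= 0).
#' @return 4 x 4 matrix of probabilities `P[a, b] = P(b at end | a at start)`.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "gtr_model"), t >= 0)
  P <- model$U %*% diag(exp(model$lambda * t)) %*% model$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+G substitution model\n")
  cat("  pi   :", format(round(x$pi, 4)), "\n")
  cat("  exch :", format(round(x$exch, 4)), "(AC AG AT CG CT GT)\n")
  cat("  alpha:", format(x$alpha), " (", x$ncat, "categories )\n")
  invisible(x)
}

#' Insertion/deletion process parameters
#'
#' Indel events arise along branches as Poisson processes with per-site
#' rates; fragment lengths are geometric with parameter `len_p`, so the
#' expected fragment length is `1 / len_p`.
#'
#' @param ins_rate insertions per site per unit branch length (>= 0).
#' @param del_rate deletions per site per unit branch length (>= 0).
#' @param len_p geometric length parameter in (0, 1].
#' @return An object of class `indel_model`.
#' @examples
#' indel_model(0.02, 0.02, 0.5)  # mean fragment length 2
#' @export
indel_model <- function(ins_rate = 0.02, del_rate = 0.02, len_p = 0.5) {
  if (ins_rate < 0 || del_rate < 0) stop("indel rates must be >= 0")
  if (len_p <= 0 || len_p > 1) stop("'len_p' must be in (0, 1]")
  structure(list(ins_rate = ins_rate, del_rate = del_rate, len_p = len_p),
            class = "indel_model")
}

#' @export
print.indel_model <- function(x, ...) {
  cat("Indel model: ins", x$ins_rate, "del", x$del_rate,
      "per site per unit length; mean fragment", 1 / x$len_p, "\n")
  invisible(x)
}
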