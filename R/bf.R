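# Configuration-specific Bayes factors under the two-level normal prior on
# standardized effects.
#
# For a configuration gamma and grid point (phi, omega), the model for the
# active tissues' standardized effects is b_s ~ N(bbar, phi^2),
# bbar ~ N(0, omega^2); the BF compares this alternative against b = 0 with
# diffuse priors on the per-tissue intercept and residual variance.
#
# With independent individuals the nuisance integrals factor by tissue and,
# after integrating the intercept (flat prior), the effect vector (normal
# prior) and the residual precision (scale-invariant prior), the BF reduces
# to
#   |I + D Omega|^{-1/2} * E_u[ exp( t' M u u' M t / 2) ]   (schematically)
# with D = diag(d_s), d_s the centered genotype sum of squares scaled by the
# residual variance, M = Omega (I + D Omega)^{-1}, and u_s the per-tissue
# residual precision. The per-tissue (diagonal) part of that expectation is
# available in closed form,
#   (1 - M_ss * c_s^2 / a_s)^{-(n_s - 1)/2},
# the score-statistic form; the cross-tissue terms are evaluated by a tilted
# plug-in for u_s. Everything is computed in log space and vectorized over
# units (gene-SNP pairs or permutations) via Sherman-Morrison identities for
# the diagonal-plus-rank-one prior.

# sufficient statistics for the BF from regression summaries
# returns list of S x K matrices: n, d (= sxx / sigmahat^2 inverse-variance of
# bhat), cc (= betahat * d), a (= total centered SS of y)
.bf_suff <- function(n, betahat, se, sigmahat) {
  d <- (sigmahat / se)^2
  cc <- betahat * d
  a <- sigmahat^2 * (n - 2) + betahat^2 * d
  list(n = n, d = d, cc = cc, a = a)
}

.suff_from_summaries <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("n", "betahat", "se", "sigmahat") %in% names(summaries)))
  if (any(summaries$se <= 0) || any(summaries$sigmahat <= 0)) {
    stop("standard errors and residual SDs must be positive")
  }
  with(summaries, .bf_suff(matrix(n), matrix(betahat), matrix(se), matrix(sigmahat)))
}

# log BFs for all configurations x grid points, independent-individuals path.
# n, d, cc, a: S x K matrices; configs: nc x S 0/1 matrix; grid: tibble.
# Returns array dim (K, nc, L).
.lbf_array <- function(suff, configs, grid) {
  S <- nrow(suff$d); K <- ncol(suff$d)
  nc <- nrow(configs); L <- nrow(grid)
  rho2 <- suff$cc^2 / (suff$a * suff$d)
  if (any(rho2 >= 1)) stop("degenerate perfect fit encountered")
  out <- array(0, dim = c(K, nc, L))
  amat <- suff$a; ccm <- suff$cc; dm <- suff$d; nm <- suff$n
  if (length(nm) == S) nm <- matrix(nm, S, K)
  for (l in seq_len(L)) {
    phi <- grid$phi[l]; omega <- grid$omega[l]
    if (phi == 0 && omega == 0) next
    if (phi > 0) {
      f <- dm + 1 / phi^2           # S x K
      invf <- 1 / f
      logf <- log(f)
    }
    for (ci in seq_len(nc)) {
      A <- which(configs[ci, ] == 1L)
      q <- length(A)
      if (phi > 0) {
        kap <- omega^2 / (phi^2 * (phi^2 + q * omega^2))
        S1 <- .colsum(invf, A)                        # K
        denom <- 1 - kap * S1
        ldet <- (q - 1) * 2 * log(phi) + log(phi^2 + q * omega^2) +
          .colsum(logf, A) + log(denom)
        Mss <- invf[A, , drop = FALSE] *
          (1 + kap * sweep(invf[A, , drop = FALSE], 2, denom, "/"))
      } else {
        sumd <- .colsum(dm, A)
        ldet <- log1p(omega^2 * sumd)
        mbar <- omega^2 / (1 + omega^2 * sumd)        # K
        Mss <- matrix(mbar, q, K, byrow = TRUE)
      }
      aA <- amat[A, , drop = FALSE]; ccA <- ccm[A, , drop = FALSE]
      nA <- nm[A, , drop = FALSE]
      h <- Mss * ccA^2 / aA                           # in [0, rho2)
      diagterm <- -(nA - 1) / 2 * log1p(-h)
      tt <- ccA * sqrt((nA - 1) / (aA - Mss * ccA^2)) # tilted plug-in
      if (phi > 0) {
        tf <- tt * invf[A, , drop = FALSE]
        cross <- 0.5 * kap / denom *
          (.colsum2(tf)^2 - .colsum2(tf^2))
      } else {
        cross <- 0.5 * mbar * (.colsum2(tt)^2 - .colsum2(tt^2))
      }
      out[, ci, l] <- -0.5 * ldet + .colsum2(diagterm) + cross
    }
  }
  out
}

.colsum <- function(m, rows) {
  x <- m[rows, , drop = FALSE]
  if (nrow(x) == 1L) x[1L, ] else colSums(x)
}
.colsum2 <- function(x) if (nrow(x) == 1L) x[1L, ] else colSums(x)

# correlated-residuals path: multivariate normal density ratio on score-scale
# standardized summaries, V_ij = rcorr_ij * se0_i * se0_j. One unit.
.lbf_matrix_corr <- function(suff, rcorr, configs, grid) {
  S <- nrow(suff$d)
  stopifnot(nrow(rcorr) == S, ncol(rcorr) == S)
  sigma0 <- sqrt(suff$a / (suff$n - 1))             # null residual SD
  bhat0 <- drop(suff$cc / suff$d) / drop(sigma0)
  se0 <- 1 / sqrt(drop(suff$d))
  V <- rcorr * tcrossprod(se0)
  cv <- chol(V)
  ld0 <- 2 * sum(log(diag(cv)))
  q0 <- sum(backsolve(cv, bhat0, transpose = TRUE)^2)
  nc <- nrow(configs); L <- nrow(grid)
  out <- matrix(0, nc, L)
  for (l in seq_len(L)) {
    phi <- grid$phi[l]; omega <- grid$omega[l]
    if (phi == 0 && omega == 0) next
    for (ci in seq_len(nc)) {
      act <- configs[ci, ] == 1L
      P <- matrix(0, S, S)
      P[act, act] <- omega^2
      diag(P)[act] <- diag(P)[act] + phi^2
      c1 <- chol(V + P)
      ld1 <- 2 * sum(log(diag(c1)))
      q1 <- sum(backsolve(c1, bhat0, transpose = TRUE)^2)
      out[ci, l] <- 0.5 * (ld0 - ld1) + 0.5 * (q0 - q1)
    }
  }
  out
}

.as_config_matrix <- function(gamma, S) {
  if (is.matrix(gamma)) gamma else matrix(as.integer(gamma), 1L, S)
}

#' Bayes factor for one configuration at one grid point
#'
#' Computes the approximate Bayes factor comparing "eQTL active in the
#' tissues flagged by `gamma`, with standardized effects drawn from the
#' two-level normal prior at `(phi, omega)`" against the global null of no
#' effect in any tissue. With `rcorr = NULL` individuals are treated as
#' independent across tissues and inactive tissues contribute nothing; with
#' a residual correlation matrix (same individuals in all tissues, see
#' [estimate_residual_correlation()]) the error covariance couples tissues.
#'
#' @param summaries Data frame of per-tissue regression summaries, one row
#'   per tissue in tissue order, as returned by [fit_tissue_regression()]
#'   (columns `n`, `betahat`, `se`, `sigmahat`).
#' @param gamma Binary activity vector of length S (at least one 1).
#' @param phi,omega Prior SDs: `phi` for the between-tissue deviation of
#'   effects, `omega` for the shared mean effect. `phi = omega = 0`
#'   represents the null point and gives BF = 1.
#' @param rcorr Optional S x S residual correlation matrix.
#' @param log Return the natural-log BF instead.
#' @return Scalar Bayes factor (or its log).
#' @export
bf_config_gridpoint <- function(summaries, gamma, phi, omega, rcorr = NULL,
                                log = FALSE) {
  S <- nrow(summaries)
  gamma <- .as_config_matrix(gamma, S)
  stopifnot(ncol(gamma) == S, phi >= 0, omega >= 0)
  if (sum(gamma) == 0L) stop("gamma must activate at least one tissue")
  suff <- .suff_from_summaries(summaries)
  grid1 <- tibble::tibble(phi = phi, omega = omega, weight = 1)
  lbf <- if (is.null(rcorr)) {
    .lbf_array(suff, gamma, grid1)[1L, 1L, 1L]
  } else {
    .lbf_matrix_corr(suff, rcorr, gamma, grid1)[1L, 1L]
  }
  if (log) lbf else exp(lbf)
}

#' Grid-averaged Bayes factor for one configuration
#'
#' Weighted average of [bf_config_gridpoint()] over the grid points, using
#' the grid weights.
#'
#' @inheritParams bf_config_gridpoint
#' @param grid Grid tibble from [build_grid()].
#' @return Scalar Bayes factor (or its log).
#' @export
bf_config <- function(summaries, gamma, grid, rcorr = NULL, log = FALSE) {
  validate_grid(grid)
  S <- nrow(summaries)
  gamma <- .as_config_matrix(gamma, S)
  suff <- .suff_from_summaries(summaries)
  lbf <- if (is.null(rcorr)) {
    .lbf_array(suff, gamma, grid)[1L, 1L, ]
  } else {
    .lbf_matrix_corr(suff, rcorr, gamma, grid)[1L, ]
  }
  out <- logsumexp(lbf + log(grid$weight))
  if (log) out else exp(out)
}

#' Numeric-integration Bayes factor oracle
#'
#' Evaluates the configuration Bayes factor by direct numerical integration
#' from the raw data: Gauss-Hermite quadrature over the shared mean `bbar`
#' and the per-tissue effects `b_s`, with the per-tissue marginal likelihood
#' under diffuse intercept/variance priors obtained by adaptive 1-D
#' quadrature over the residual precision. Exact up to quadrature error but
#' slow; intended for validating the analytic approximation on small
#' instances (S <= 3, n <= a few hundred), not for production use.
#'
#' @param ys List of expression vectors, one per active-or-not tissue
#'   (length S).
#' @param g Genotype dosage vector (same individuals in all tissues).
#' @param gamma Binary activity vector of length S.
#' @param phi,omega Prior SDs as in [bf_config_gridpoint()].
#' @param nodes Number of Gauss-Hermite nodes per dimension.
#' @param log Return the natural-log BF.
#' @return Scalar Bayes factor (or its log).
#' @export
bf_exact_oracle <- function(ys, g, gamma, phi, omega, nodes = 31L, log = FALSE) {
  stopifnot(is.list(ys), length(gamma) == length(ys), phi >= 0, omega >= 0)
  if (length(ys) > 3L) stop("oracle supports S <= 3 only")
  act <- which(as.integer(gamma) == 1L)
  if (length(act) == 0L) stop("gamma must activate at least one tissue")
  if (phi == 0 && omega == 0) return(if (log) 0 else 1)
  gq <- .gauss_hermite(nodes)
  lse <- logsumexp
  # per-tissue log marginal-likelihood ratio m(b)/m(0) under diffuse priors
  log_r <- function(b, y) {
    n <- length(y)
    stopifnot(n == length(g))
    yc <- y - mean(y); gc <- g - mean(g)
    a <- sum(yc^2); cc <- sum(yc * gc); d <- sum(gc^2)
    li <- function(bb) {
      # log int_0^inf u^{n-2} exp(-a u^2/2 + bb*cc*u) du, u = 1/sigma
      ustar <- (bb * cc + sqrt(bb^2 * cc^2 + 4 * a * (n - 2))) / (2 * a)
      M <- (n - 2) * base::log(ustar) - a * ustar^2 / 2 + bb * cc * ustar
      f <- function(u) exp((n - 2) * base::log(u) - a * u^2 / 2 + bb * cc * u - M)
      M + base::log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
    }
    l0 <- li(0)
    vapply(b, function(bb) -bb^2 * d / 2 + li(bb) - l0, numeric(1))
  }
  if (omega > 0) {
    bbar <- sqrt(2) * omega * gq$x
    lw_out <- base::log(gq$w) - 0.5 * base::log(pi)
  } else {
    bbar <- 0
    lw_out <- 0
  }
  terms <- numeric(length(bbar))
  lw_in <- base::log(gq$w) - 0.5 * base::log(pi)
  for (j in seq_along(bbar)) {
    lt <- 0
    for (s in act) {
      if (phi > 0) {
        bs <- bbar[j] + sqrt(2) * phi * gq$x
        lt <- lt + lse(lw_in + log_r(bs, ys[[s]]))
      } else {
        lt <- lt + log_r(bbar[j], ys[[s]])
      }
    }
    terms[j] <- lw_out[j] + lt
  }
  out <- lse(terms)
  if (log) out else exp(out)
}

# Gauss-Hermite nodes/weights (physicists'), Golub-Welsch
.gauss_hermite <- function(K) {
  i <- seq_len(K - 1L)
  J <- matrix(0, K, K)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1L, ord])^2 * sqrt(pi))
}
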