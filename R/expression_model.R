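#' Inclusion prior as a function of regulatory-interaction potential
#'
#' `phi(theta) = pi^theta (pi/rho)^(1-theta)`: the prior probability that a
#' SNP-gene pair is an expression-regulator is `pi` inside an
#' interacting-regulator locus (`theta = 1`) and `pi/rho` outside
#' (`theta = 0`). Fractional theta interpolates geometrically between the
#' endpoints.
#'
#' @param theta indicator or probability in \[0, 1\].
#' @param pi expression-regulator prior inside regulator loci, in (0, 1).
#' @param rho amplification factor, >= 1 (default 100).
#' @export
phi <- function(theta, pi, rho = 100) {
  stopifnot(all(theta >= 0), all(theta <= 1), pi > 0, pi < 1, rho >= 1)
  pi^theta * (pi / rho)^(1 - theta)
}

#' Marginal inclusion prior with theta integrated out
#'
#' `E[phi(theta) | q] = q pi + (1 - q) pi / rho`: the exact prior inclusion
#' probability of a pair whose potential is q, used by the sampler's
#' gamma updates (a Rao-Blackwellization of theta). As `rho -> Inf` this
#' tends to `q * pi` — the two-level sparsity product of the
#' interacting-regulator fraction and the expression-regulator fraction.
#' @param q regulatory-interaction potential(s) in \[0, 1\].
#' @inheritParams phi
#' @export
phi_marginal <- function(q, pi, rho = 100) {
  stopifnot(all(q >= 0), all(q <= 1), pi > 0, pi < 1, rho >= 1)
  q * pi + (1 - q) * pi / rho
}

gene_gram <- function(y, x) {
  x <- as.matrix(x)
  n <- length(y)
  stopifnot(nrow(x) == n)
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  list(gram = crossprod(xc), xty = as.vector(crossprod(xc, yc)),
       yty = sum(yc^2), n = n, xc = xc, yc = yc)
}

#' Log marginal likelihood under the Zellner g-prior
#'
#' Closed-form evidence of a gene's expression on the included SNP design
#' with coefficients and noise variance integrated out: intercept under a
#' flat prior, `beta | sigma^2 ~ N(0, g sigma^2 (X'X)^-1)`,
#' `p(sigma^2) ~ 1/sigma^2`. Collinear columns are handled by a
#' rank-revealing pseudo-solve (with a warning), so duplicated predictors do
#' not change the evidence.
#'
#' @param y expression vector (standardized or not; centered internally).
#' @param x included-SNP dosage matrix (`NULL` or zero columns gives the
#'   null-model evidence, a function of n and y'y only).
#' @param g g-prior scale (default `length(y)`, the unit-information prior).
#' @return log marginal likelihood (natural log), including constants.
#' @export
log_marginal <- function(y, x = NULL, g = length(y)) {
  n <- length(y)
  k <- if (is.null(x)) 0L else ncol(as.matrix(x))
  if (k >= n - 2) stop("|gamma| must be smaller than n - 2")
  yc <- y - mean(y)
  yty <- sum(yc^2)
  const <- lgamma((n - 1) / 2) - ((n - 1) / 2) * log(pi) - 0.5 * log(n) -
    ((n - 1) / 2) * log(yty)
  if (k == 0L) return(const)
  d <- gene_gram(y, x)
  fit <- cpp_log_marginal(d$gram, d$xty, d$yty, n, g,
                          seq_len(k) - 1L)
  if (fit$rank < k)
    warning("rank-deficient design (rank ", fit$rank, " < ", k,
            "): collinear columns dropped by pseudo-solve")
  const + fit$logev
}

#' One Gibbs sweep over the inclusion indicators of a SNP set
#'
#' Sweeps the listed SNPs in random order; each indicator is resampled from
#' its exact conditional, the g-prior evidence ratio times the prior odds
#' `prior_incl/(1 - prior_incl)`. Leaves the per-gene posterior invariant.
#'
#' When `blocks` is supplied the sweep is the restricted kernel used inside
#' the hierarchical sampler: a SNP that is the only included member of its
#' LD block is left untouched (block deactivation is the job of
#' [block_move()], whose proposals carry the correct reverse-move
#' probability; letting the sweep empty a block would make the sweep's own
#' coordinate selection depend on the value being resampled and bias the
#' chain).
#'
#' @param y expression vector.
#' @param x dosage matrix of all candidate SNPs (centered internally).
#' @param gamma current 0/1 inclusion vector.
#' @param prior_incl per-SNP prior inclusion probabilities (phi values).
#' @param g g-prior scale.
#' @param sweep SNP indices to sweep (default: all).
#' @param kmax maximum model size (default `n - 3`).
#' @param blocks optional integer block index per SNP; activates the
#'   last-SNP protection described above.
#' @return updated 0/1 gamma vector.
#' @export
gamma_gibbs_step <- function(y, x, gamma, prior_incl, g = length(y),
                             sweep = seq_len(ncol(x)), kmax = length(y) - 3,
                             blocks = NULL) {
  d <- gene_gram(y, x)
  lpo <- qlogis(pmin(pmax(prior_incl, 0), 1))
  blk <- if (is.null(blocks)) integer(0) else
    as.integer(as.integer(factor(blocks)) - 1L)
  cpp_gibbs_sweep(d$gram, d$xty, d$yty, d$n, g, as.integer(gamma), lpo,
                  as.integer(sweep - 1L), as.integer(kmax), blk)
}

#' Rao-Blackwellized conditional inclusion probabilities
#'
#' For every SNP, the exact probability that its indicator is 1 given all
#' other indicators, the data and the priors — the quantity whose average
#' over iterations is the Rao-Blackwellized posterior inclusion
#' probability.
#' @inheritParams gamma_gibbs_step
#' @export
conditional_inclusion <- function(y, x, gamma, prior_incl, g = length(y),
                                  kmax = length(y) - 3) {
  d <- gene_gram(y, x)
  lpo <- qlogis(pmin(pmax(prior_incl, 0), 1))
  cpp_rb_probs(d$gram, d$xty, d$yty, d$n, g, as.integer(gamma), lpo,
               as.integer(kmax))
}

#' Hierarchical LD-block Metropolis-Hastings moves
#'
#' Proposes activating an inactive LD block through its single best SNP,
#' deactivating an active block by dropping all its SNPs, or swapping an
#' active block for an inactive one (mix 0.4/0.4/0.2). Acceptance uses the
#' exact evidence and prior ratios with the proposal correction; proposals
#' whose deterministic reverse could not reconstruct the current state are
#' rejected, so the chain stays invariant for the target posterior.
#'
#' @inheritParams gamma_gibbs_step
#' @param blocks integer block index per SNP.
#' @param n_moves number of proposals.
#' @return updated 0/1 gamma vector.
#' @export
block_move <- function(y, x, gamma, prior_incl, blocks, g = length(y),
                       n_moves = 1, kmax = length(y) - 3) {
  d <- gene_gram(y, x)
  lpo <- qlogis(pmin(pmax(prior_incl, 0), 1))
  blocks0 <- as.integer(as.integer(factor(blocks)) - 1L)
  cpp_block_moves(d$gram, d$xty, d$yty, d$n, g, as.integer(gamma), lpo,
                  blocks0, as.integer(n_moves), as.integer(kmax))
}

#' Sample (or fix) the expression-regulator prior probability pi
#'
#' In `"fixed"` mode (the default) returns `m/e`, the minimum expected
#' regulator count over the candidate count. In `"sampled"` mode draws pi
#' from its conditional under a uniform prior on `(m/e, M/e)` given the
#' current binary indicators: pairs with `theta = 1` contribute
#' Bernoulli(pi) terms and pairs with `theta = 0` Bernoulli(pi/rho) terms
#' (grid inverse-CDF draw on the truncated support).
#'
#' @param gamma,theta 0/1 vectors over pairs (ignored in fixed mode).
#' @param m,M minimum and maximum expected expression-regulator counts.
#' @param e expected number of interacting-regulators among the
#'   candidates (the paper's `e`, e.g. 1% of the candidate count).
#' @param rho amplification factor.
#' @param mode `"fixed"` or `"sampled"`.
#' @param grid_n grid resolution for the sampled mode.
#' @export
sample_pi <- function(gamma = NULL, theta = NULL, m = 2, M = NULL, e,
                      rho = 100, mode = c("fixed", "sampled"),
                      grid_n = 2048) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(m / e)
  if (is.null(M) || m >= M) stop("sampled mode requires m < M")
  lo <- m / e
  hi <- M / e
  grid <- seq(lo, hi, length.out = grid_n + 1)[-1] - (hi - lo) / (2 * grid_n)
  if (is.null(gamma) || length(gamma) == 0L) {
    ll <- rep(0, length(grid))
  } else {
    stopifnot(length(gamma) == length(theta))
    s1 <- sum(gamma == 1 & theta == 1); n1 <- sum(theta == 1)
    s0 <- sum(gamma == 1 & theta == 0); n0 <- sum(theta == 0)
    ll <- s1 * log(grid) + (n1 - s1) * log1p(-grid) +
      s0 * log(grid / rho) + (n0 - s0) * log1p(-grid / rho)
  }
  w <- exp(ll - max(ll))
  grid[sample.int(length(grid), 1L, prob = w)]
}

#' Draw effect sizes and noise variance given the included set
#'
#' Conjugate draws under the g-prior: `sigma^2` from its inverse-gamma-form
#' conditional with beta integrated out, then `beta` from the normal
#' conditional with mean `g/(1+g)` times the least-squares solution and
#' covariance `sigma^2 g/(1+g) (X'X)^-1`.
#'
#' @param y expression vector.
#' @param x candidate dosage matrix.
#' @param gamma 0/1 inclusion vector (empty model allowed: beta empty,
#'   sigma^2 from the null conditional).
#' @param g g-prior scale.
#' @return list `beta` (named, included SNPs only) and `sigma2`.
#' @export
sample_beta_sigma <- function(y, x, gamma, g = length(y)) {
  n <- length(y)
  act <- which(gamma == 1)
  if (length(act) >= n - 2) stop("|gamma| must be smaller than n - 2")
  yc <- y - mean(y)
  if (!length(act)) {
    sig2 <- (sum(yc^2) / 2) / rgamma(1, (n - 1) / 2)
    return(list(beta = numeric(0), sigma2 = sig2))
  }
  xs <- as.matrix(x)[, act, drop = FALSE]
  xc <- sweep(xs, 2, colMeans(xs))
  S <- crossprod(xc)
  b <- as.vector(crossprod(xc, yc))
  bhat <- solve(S, b)
  shrink <- g / (1 + g)
  Q <- sum(yc^2) - shrink * sum(b * bhat)
  sig2 <- (Q / 2) / rgamma(1, (n - 1) / 2)
  cov <- sig2 * shrink * solve(S)
  L <- chol(cov)
  beta <- shrink * bhat + as.vector(t(L) %*% rnorm(length(act)))
  names(beta) <- colnames(xs)
  list(beta = beta, sigma2 = sig2)
}
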