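#' Regulatory-interaction potential of a feature vector
#'
#' The logistic-regression potential `logistic(alpha . f)`: the probability
#' that a SNP-gene pair is an interacting-regulator given its epigenetic and
#' interaction features. `f` must carry the leading constant-1 bias entry
#' matching the bias weight `alpha[1]`.
#'
#' @param alpha weight vector (bias first).
#' @param f feature vector of the same length.
#' @return probability in (0, 1).
#' @export
potential <- function(alpha, f) {
  if (!all(is.finite(f))) stop("non-finite feature value")
  stopifnot(length(alpha) == length(f))
  plogis(sum(alpha * f))
}

#' Bias prior that encodes an expected regulator count
#'
#' `b0 = log(e / (p - e))`, the logistic-regression intercept prior mean
#' under which the prior regulator fraction is `e / p` (e.g. 1% gives
#' `log(1/99)`).
#' @param e expected number of interacting-regulators.
#' @param p number of candidate loci.
#' @export
bias_prior <- function(e, p) {
  stopifnot(e > 0, e < p)
  log(e / (p - e))
}

#' Posterior probability that a pair is an interacting-regulator
#'
#' Rao-Blackwell update of the latent indicator theta given the pair's
#' expression-model inclusion indicator gamma and its prior potential q:
#' `P(theta = 1 | gamma) = q B(gamma; pi) / (q B(gamma; pi) +
#' (1 - q) B(gamma; pi / rho))` with `B(gamma; x) = x^gamma
#' (1 - x)^(1 - gamma)`. Inclusion (`gamma = 1`) pulls theta up because the
#' expression-regulator prior is `rho`-fold larger inside
#' interacting-regulator loci; with `rho = 1`, gamma carries no information
#' and the posterior equals q.
#'
#' @param gamma inclusion indicator(s) in \{0, 1\}.
#' @param q prior potential(s) in \[0, 1\] (from [potential()]).
#' @param pi expression-regulator prior probability inside regulator loci.
#' @param rho amplification factor, >= 1.
#' @return posterior probability(ies) in \[0, 1\].
#' @export
theta_posterior <- function(gamma, q, pi, rho) {
  stopifnot(all(gamma %in% c(0, 1)), all(q >= 0), all(q <= 1),
            pi > 0, pi < 1, rho >= 1)
  pi0 <- pi / rho
  lik1 <- ifelse(gamma == 1, pi, 1 - pi)
  lik0 <- ifelse(gamma == 1, pi0, 1 - pi0)
  num <- q * lik1
  num / (num + (1 - q) * lik0)
}

#' Sample the interacting-regulator indicator
#'
#' Bernoulli draw with probability [theta_posterior()].
#' @inheritParams theta_posterior
#' @export
sample_theta <- function(gamma, q, pi, rho) {
  p <- theta_posterior(gamma, q, pi, rho)
  rbinom(length(p), 1L, p)
}

#' Polya-Gamma PG(1, z) random draws
#'
#' Exact draws from the Polya-Gamma distribution with shape 1 and tilt `z`
#' (Devroye-type alternating-series rejection sampler). Used for the
#' logistic-regression augmentation; exported because its moments
#' (`E = tanh(z/2)/(2z)`) make it directly testable.
#' @param n number of draws.
#' @param z tilt parameter(s), recycled.
#' @export
rpolyagamma <- function(n, z = 0) {
  cpp_rpolyagamma(as.integer(n), as.numeric(z))
}

#' Draw regulatory-model weights by Polya-Gamma Gibbs
#'
#' One (or more) draws from the conditional posterior of the logistic
#' weights alpha given the current interacting-regulator labels theta,
#' under a `N(b, prior_var I)` prior, via Polya-Gamma data augmentation.
#' The proper prior keeps the draw defined even under complete separation
#' (a warning is logged when the labels are degenerate).
#'
#' @param f_matrix pair feature matrix (rows = SNP-gene pairs, bias column
#'   first).
#' @param theta 0/1 labels, one per row.
#' @param b prior mean vector (all zero except possibly the bias, see
#'   [bias_prior()]).
#' @param prior_var prior variance of the non-degenerate components
#'   (scalar or per-weight vector).
#' With `select_features = TRUE` the non-bias weights additionally carry
#' spike-and-slab indicators (point mass at zero vs the normal slab,
#' prior inclusion `select_prior`), giving Bayesian selection of the
#' informative epigenetic/interaction factors; the returned draws then
#' have exact zeros for excluded features. Off by default.
#'
#' @param n_draws number of successive Gibbs draws to return.
#' @param init starting value (defaults to `b`).
#' @param select_features enable spike-and-slab selection on non-bias
#'   weights.
#' @param select_prior prior inclusion probability of each feature under
#'   selection (default 0.5).
#' @return matrix `n_draws` x `ncol(f_matrix)` of posterior draws.
#' @export
sample_alpha <- function(f_matrix, theta, b, prior_var = 1, n_draws = 1,
                         init = b, select_features = FALSE,
                         select_prior = 0.5) {
  f_matrix <- as.matrix(f_matrix)
  stopifnot(nrow(f_matrix) == length(theta), ncol(f_matrix) == length(b),
            all(prior_var > 0))
  if (all(theta == theta[1]))
    warning("degenerate labels (all ", theta[1],
            "): posterior driven by the prior; possible separability")
  prior_prec <- rep(1 / prior_var, length.out = length(b))
  if (!select_features) {
    draws <- cpp_logistic_gibbs(f_matrix, as.numeric(theta), as.numeric(b),
                                prior_prec, as.integer(n_draws),
                                as.numeric(init))
    colnames(draws) <- colnames(f_matrix)
    return(draws)
  }
  # spike-and-slab variant: given the Polya-Gamma draws the model is a
  # Gaussian regression z ~ N(F alpha, Omega^-1) with z = kappa/omega,
  # so per-component indicators have conjugate conditional odds
  d <- ncol(f_matrix)
  kappa <- theta - 0.5
  alpha <- as.numeric(init)
  tau <- rep(prior_var, length.out = d)
  out <- matrix(0, n_draws, d, dimnames = list(NULL, colnames(f_matrix)))
  for (it in seq_len(n_draws)) {
    om <- cpp_rpolyagamma(nrow(f_matrix), as.vector(f_matrix %*% alpha))
    for (k in seq_len(d)) {
      xk <- f_matrix[, k]
      r <- kappa - om * as.vector(f_matrix[, -k, drop = FALSE] %*%
                                    alpha[-k]) # Omega-weighted residual
      prec <- sum(om * xk^2) + 1 / tau[k]
      m <- (sum(xk * r) + b[k] / tau[k]) / prec
      if (k == 1L) { # bias is never selected out
        alpha[1] <- rnorm(1, m, sqrt(1 / prec))
        next
      }
      # log Bayes factor slab (mean-zero) vs spike at 0
      lbf <- 0.5 * (log(1 / tau[k]) - log(prec)) + 0.5 * m^2 * prec
      p_in <- plogis(lbf + qlogis(select_prior))
      alpha[k] <- if (runif(1) < p_in) rnorm(1, m, sqrt(1 / prec)) else 0
    }
    out[it, ] <- alpha
  }
  out
}

#' Rank features by posterior importance
#'
#' Orders features by `|posterior mean| / posterior sd` of their weights,
#' ties broken by feature name. Requires at least 100 retained draws.
#' Near-duplicate features are flagged: their weight draws are strongly
#' anti-correlated and the importance splits between them.
#'
#' @param draws matrix of posterior alpha draws (draw x feature).
#' @param feature_names labels (default column names).
#' @return data.frame `feature`, `mean`, `sd`, `importance`, ordered by
#'   decreasing importance.
#' @export
rank_features <- function(draws, feature_names = colnames(draws)) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 100)
    stop("need >= 100 retained draws to rank features; run a longer chain")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(draws)))
  m <- colMeans(draws)
  s <- apply(draws, 2, sd)
  if (ncol(draws) > 1) {
    cc <- suppressWarnings(cor(draws))
    diag(cc) <- 0
    if (any(cc < -0.9, na.rm = TRUE))
      warning("strongly anti-correlated weight draws: collinear features, ",
              "importance is split between them")
  }
  out <- data.frame(feature = feature_names, mean = m, sd = s,
                    importance = abs(m) / s, stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}
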