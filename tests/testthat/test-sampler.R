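make_tiny_problem <- function(n = 80, p = 8, seed = 3,
                              blocks = rep(1:2, each = 4),
                              beta = c(3, 0.9, 7, 0.6), noise = 0.8) {
  set.seed(seed)
  dos <- matrix(rbinom(n * p, 2, 0.3), n, p)
  g <- genotype_matrix(dos, chrom = "c1",
                       pos = seq(1000, by = 1000, length.out = p),
                       block = blocks)
  attr(g, "genes") <- data.frame(gene_id = "gA", chrom = "c1",
                                 tss = as.integer(1000 * p / 2),
                                 stringsAsFactors = FALSE)
  y <- rep(0, n)
  if (length(beta))
    for (i in seq(1, length(beta), by = 2))
      y <- y + scale(dos[, beta[i]])[, 1] * beta[i + 1]
  y <- y + rnorm(n) * noise
  e <- expression_matrix(matrix(y, 1, n), chrom = "c1",
                         tss = as.integer(1000 * p / 2), gene_id = "gA")
  ft <- toy_features(g)
  list(g = g, e = normalize_expression(e), ft = ft)
}

test_that("coupled fit matches enumeration under uninformative features", {
  tp <- make_tiny_problem()
  ctl <- eqtel_control(burn_in = 500, n_iter = 4000, fix_alpha = TRUE,
                       seed = 11, m_expected = 2, regulator_fraction = 0.25)
  fits <- lapply(c(11, 12, 13), function(s) {
    ctl$seed <- s
    suppressWarnings(eqtel_fit(tp$g, tp$e, tp$ft, ctl))
  })
  # oracle: enumeration with the theta-marginalized prior at alpha = b
  p <- 8
  b0 <- bias_prior(0.25 * p, p)
  Fm <- cbind(1, tp$ft$epigenetic, tp$ft$interaction$i1)
  q <- plogis(Fm %*% c(b0, 0, 0, 0))[, 1]
  pi1 <- min(2 / (0.25 * p), 0.9)
  pibar <- q * pi1 + (1 - q) * pi1 / 100
  oracle <- enumerate_pip(tp$e$values[1, ], tp$g$dosages, pibar, 80)
  pips <- vapply(fits, function(f) f$pairs$pip, numeric(p))
  mc_sd <- apply(pips, 1, sd) / sqrt(3)
  err <- abs(rowMeans(pips) - oracle$pip)
  expect_true(all(err < pmax(3 * mc_sd, 0.02)))
})

test_that("fits are byte-identical under identical config and seed", {
  tp <- make_tiny_problem()
  ctl <- eqtel_control(burn_in = 200, n_iter = 600, seed = 5)
  f1 <- eqtel_fit(tp$g, tp$e, tp$ft, ctl)
  f2 <- eqtel_fit(tp$g, tp$e, tp$ft, ctl)
  expect_identical(f1$pairs, f2$pairs)
  expect_identical(f1$alpha_draws, f2$alpha_draws)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$beta_draws, f2$beta_draws)
})

test_that("configuration is validated", {
  expect_error(eqtel_control(n_iter = 0), "at least one sampling iteration")
  tp <- make_tiny_problem()
  ctl <- eqtel_control(burn_in = 10, n_iter = 20, seed = 1)
  bad_e <- tp$e
  bad_e$values <- bad_e$values[, 1:10]
  expect_error(eqtel_fit(tp$g, structure(list(), class = "list"), tp$ft, ctl))
})

test_that("rao_blackwell_pip averages conditional probabilities", {
  expect_equal(rao_blackwell_pip(rep(0.7, 25)), 0.7)
  m <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  expect_equal(rao_blackwell_pip(m), c(0.3, 0.7))
  expect_equal(rao_blackwell_pip(matrix(c(0.37, 0.9), 1, 2)), c(0.37, 0.9))
})

test_that("RB estimator beats indicator frequencies in replicate variance", {
  set.seed(21)
  n <- 60
  x <- cbind(rnorm(n), rnorm(n))
  y <- 0.5 * x[, 1] + rnorm(n)
  pri <- c(0.2, 0.2)
  est <- t(vapply(1:50, function(r) {
    set.seed(100 + r)
    gm <- c(0L, 0L)
    rb <- fr <- numeric(2)
    for (i in 1:120) {
      gm <- gamma_gibbs_step(y, x, gm, pri)
      rb <- rb + conditional_inclusion(y, x, gm, pri)
      fr <- fr + gm
    }
    c(rb / 120, fr / 120)
  }, numeric(4)))
  sd_rb <- apply(est[, 1:2], 2, sd)
  sd_fr <- apply(est[, 3:4], 2, sd)
  expect_true(all(sd_rb <= sd_fr))
})

test_that("convergence diagnostics behave on canonical traces", {
  expect_true(check_convergence(rep(5, 500))$converged)       # constant
  expect_false(check_convergence(seq(0, 10, length.out = 500))$converged)
  expect_error(check_convergence(c(1, 2)), "too short")
  # white-noise trace flagged converged at about the nominal level
  set.seed(22)
  flags <- vapply(1:40, function(i)
    check_convergence(rnorm(2000))$converged, logical(1))
  expect_gt(mean(flags), 0.8)
})

test_that("joint chain matches discrete-theta/gamma enumeration with alpha quadrature", {
  set.seed(23)
  n <- 100
  p <- 5
  dos <- matrix(rbinom(n * p, 2, 0.35), n, p)
  g <- genotype_matrix(dos, chrom = "c1",
                       pos = seq(1000, by = 1000, length.out = p),
                       block = c(1, 1, 1, 2, 2))
  y <- scale(dos[, 2])[, 1] * 0.8 + rnorm(n) * 0.9
  e <- normalize_expression(
    expression_matrix(matrix(y, 1, n), chrom = "c1", tss = 3000L,
                      gene_id = "gA"))
  set.seed(24)
  ep <- matrix(rnorm(p * 1), p, 1,
               dimnames = list(g$snp_info$snp_id, "e1"))
  inter <- data.frame(snp_id = g$snp_info$snp_id, gene_id = "gA",
                      i1 = rnorm(p))
  ft <- standardize_feature_table(feature_table(ep, inter))
  rf <- 0.2
  ctl <- eqtel_control(burn_in = 1000, n_iter = 8000, seed = 31,
                       m_expected = 1, regulator_fraction = rf,
                       prior_var = 1)
  fits <- lapply(c(31, 32, 33), function(s) {
    ctl$seed <- s
    suppressWarnings(eqtel_fit(g, e, ft, ctl))
  })

  # oracle: sum over gamma configs, theta summed out, alpha by
  # Gauss-Hermite quadrature over its 3-dimensional prior
  Fm <- cbind(1, ft$epigenetic, ft$interaction$i1)
  b <- c(bias_prior(rf * p, p), 0, 0)
  pi1 <- min(1 / (rf * p), 0.9)
  pi0 <- pi1 / 100
  gh <- gauss_hermite_prob(9)
  nodes <- as.matrix(expand.grid(gh$nodes, gh$nodes, gh$nodes))
  wts <- apply(as.matrix(expand.grid(gh$weights, gh$weights, gh$weights)),
               1, prod)
  alphas <- sweep(nodes, 2, b, "+") # prior sd 1 on every component
  qmat <- plogis(Fm %*% t(alphas)) # p x n_nodes
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  ev <- apply(configs, 1, function(gm) {
    act <- which(gm == 1)
    if (length(act))
      suppressWarnings(log_marginal(e$values[1, ], dos[, act, drop = FALSE],
                                    n))
    else log_marginal(e$values[1, ], NULL, n)
  })
  pip_num <- numeric(p)
  th_num <- numeric(p)
  Z <- 0
  for (ci in seq_len(nrow(configs))) {
    gm <- configs[ci, ]
    lik1 <- ifelse(gm == 1, pi1, 1 - pi1)
    lik0 <- ifelse(gm == 1, pi0, 1 - pi0)
    m <- qmat * lik1 + (1 - qmat) * lik0       # p x nodes
    w_nodes <- exp(ev[ci] - max(ev)) * wts * apply(m, 2, prod)
    tpost <- qmat * lik1 / m                   # p x nodes
    Z <- Z + sum(w_nodes)
    pip_num <- pip_num + gm * sum(w_nodes)
    th_num <- th_num + as.vector(tpost %*% w_nodes)
  }
  pip_oracle <- pip_num / Z
  th_oracle <- th_num / Z

  pips <- vapply(fits, function(f) f$pairs$pip, numeric(p))
  ths <- vapply(fits, function(f) f$pairs$theta_hat, numeric(p))
  expect_true(all(abs(rowMeans(pips) - pip_oracle) <
                    pmax(3 * apply(pips, 1, sd) / sqrt(3), 0.025)))
  expect_true(all(abs(rowMeans(ths) - th_oracle) <
                    pmax(3 * apply(ths, 1, sd) / sqrt(3), 0.04)))
})

test_that("prediction recovers noiseless genes and collapses under permutation", {
  tp <- make_tiny_problem(n = 120, beta = c(2, 1.0, 6, -0.8), noise = 0.02)
  ctl <- eqtel_control(burn_in = 300, n_iter = 1500, seed = 7,
                       regulator_fraction = 0.25)
  fit <- suppressWarnings(eqtel_fit(tp$g, tp$e, tp$ft, ctl))
  ph <- predict(fit, tp$g)
  # compare against the true linear predictor (the rank-normal transform
  # of y is monotone but not linear in it)
  truth_pred <- scale(tp$g$dosages[, 2])[, 1] * 1.0 +
    scale(tp$g$dosages[, 6])[, 1] * -0.8
  expect_gt(cor(ph$mean[1, ], truth_pred), 0.99)
  expect_false(is.null(ph$draws[[1]])) # per-draw predictions available
  # permuted sample labels: correlation collapses
  gperm <- tp$g
  set.seed(8)
  gperm$dosages <- gperm$dosages[sample(nrow(gperm$dosages)), ]
  php <- predict(fit, gperm)
  expect_lt(abs(cor(php$mean[1, ], tp$e$values[1, ])), 0.3)
  # SNP-id mismatch is an error
  gbad <- tp$g
  gbad$snp_info$snp_id <- paste0("other_", gbad$snp_info$snp_id)
  expect_error(predict(fit, gbad), "not found")
})
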