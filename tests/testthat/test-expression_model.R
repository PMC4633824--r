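test_that("phi interpolates geometrically between its endpoints", {
  expect_identical(phi(1, 0.01, 100), 0.01)
  expect_equal(phi(0, 0.01, 100), 1e-4)
  expect_equal(phi(0.5, 0.01, 100), 1e-3) # geometric mean of the endpoints
  expect_error(phi(0.5, 1.2, 100))
  expect_error(phi(-0.1, 0.5, 100))
})

test_that("two-level sparsity factorizes for large rho", {
  # the theta-marginalized inclusion mass E[phi(theta)] tends to
  # E[theta] * pi as rho -> Inf: overall sparsity is the product of the
  # interacting-regulator fraction and the expression-regulator fraction
  pi1 <- 0.01
  for (etheta in c(0.1, 0.5, 0.9)) {
    gap <- vapply(c(1e2, 1e4, 1e8), function(rho)
      abs(log(phi_marginal(etheta, pi1, rho)) - (log(etheta) + log(pi1))),
      numeric(1))
    expect_true(all(diff(gap) < 0))           # monotone approach
    expect_lt(gap[3], 1e-5)                   # limit attained
  }
})

test_that("g-prior evidence matches 2-D quadrature on a small fixed case", {
  set.seed(7)
  n <- 8
  x <- matrix(rnorm(n), n, 1)
  y <- 0.8 * x[, 1] + rnorm(n)
  g <- n
  got <- log_marginal(y, x, g)
  yc <- y - mean(y)
  xc <- x - mean(x)
  Sxx <- sum(xc^2)
  f <- function(beta, s2) {
    (2 * pi * s2)^(-(n - 1) / 2) * n^(-1 / 2) *
      exp(-sum((yc - xc * beta)^2) / (2 * s2)) *
      dnorm(beta, 0, sqrt(g * s2 / Sxx)) / s2
  }
  inner <- Vectorize(function(s2)
    integrate(function(b) vapply(b, f, numeric(1), s2 = s2), -10, 10,
              rel.tol = 1e-10)$value)
  oracle <- log(integrate(inner, 1e-4, 60, rel.tol = 1e-10)$value)
  expect_equal(got, oracle, tolerance = 1e-6)

  # empty model: a function of n and y'y only
  y2 <- y * 2
  expect_equal(log_marginal(y2, NULL),
               log_marginal(y, NULL) - (n - 1) * log(2), tolerance = 1e-10)

  # duplicating an included column leaves the evidence unchanged
  expect_warning(dup <- log_marginal(y, cbind(x, x), g), "rank-deficient")
  expect_equal(dup, got, tolerance = 1e-10)
})

test_that("evidence is invariant to sample and SNP permutations", {
  set.seed(8)
  n <- 40
  x <- matrix(rbinom(3 * n, 2, 0.3), n, 3)
  y <- rnorm(n)
  base <- log_marginal(y, x)
  perm <- sample(n)
  expect_equal(log_marginal(y[perm], x[perm, ], n), base, tolerance = 1e-10)
  expect_equal(log_marginal(y, x[, c(3, 1, 2)], n), base, tolerance = 1e-10)
})

test_that("Gibbs sweep respects zero priors and splits correlated SNPs", {
  set.seed(9)
  n <- 100
  x1 <- rnorm(n)
  x <- cbind(x1, x1, rnorm(n)) # SNPs 1 and 2 perfectly correlated
  y <- x1 + 0.5 * rnorm(n)

  # phi = 0 means never included
  gm <- rep(0L, 3)
  for (i in 1:50)
    gm <- gamma_gibbs_step(y, x, gm, c(0, 0.5, 0.01))
  expect_equal(gm[1], 0L)

  # equal priors: inclusion mass splits between the twins
  run_freq <- function(pri, iters = 4000) {
    gm <- rep(0L, 3)
    acc <- numeric(3)
    for (i in seq_len(iters)) {
      gm <- gamma_gibbs_step(y, x, gm, pri)
      acc <- acc + gm
    }
    acc / iters
  }
  set.seed(10)
  f_eq <- run_freq(c(0.3, 0.3, 0.01))
  expect_lt(abs(f_eq[1] - f_eq[2]), 0.12)
  expect_gt(f_eq[1] + f_eq[2], 0.8)
  # 10x larger prior pulls the mass onto the favoured twin
  set.seed(11)
  f_hi <- run_freq(c(0.3, 0.03, 0.01))
  expect_gt(f_hi[1], 5 * f_hi[2])
})

test_that("null data includes about sum(phi) SNPs on average", {
  set.seed(12)
  n <- 80
  p <- 20
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  pri <- rep(0.01, p)
  gm <- rep(0L, p)
  tot <- 0
  iters <- 3000
  for (i in seq_len(iters)) {
    gm <- gamma_gibbs_step(y, x, gm, pri)
    tot <- tot + sum(gm)
  }
  mean_inc <- tot / iters
  # null inclusion rate approximately sum(phi) (evidence ratio ~ 1)
  expect_lt(abs(mean_inc - sum(pri)), 3 * sqrt(sum(pri) / iters) * 10)
})

test_that("single-block genome reduces block moves to add/remove", {
  set.seed(13)
  n <- 70
  x <- matrix(rnorm(n), n, 1)
  y <- 0.45 * x[, 1] + rnorm(n)
  pri <- 0.2
  # exact 2-model posterior of the occupancy
  l1 <- log_marginal(y, x, n) + log(pri)
  l0 <- log_marginal(y, NULL, n) + log(1 - pri)
  p_occ <- exp(l1) / (exp(l1) + exp(l0))
  gm <- 0L
  occ <- 0
  iters <- 8000
  for (i in seq_len(iters)) {
    gm <- block_move(y, x, gm, pri, blocks = 1, n_moves = 1)
    occ <- occ + gm
  }
  expect_lt(abs(occ / iters - p_occ), 0.03)
})

test_that("two-block instance matches the 16-configuration enumeration", {
  set.seed(14)
  n <- 90
  x <- matrix(rnorm(n * 4), n, 4)
  y <- 0.8 * x[, 2] + rnorm(n) # causal in block A; block B is decoy
  pri <- rep(0.1, 4)
  blocks <- c(1, 1, 2, 2)
  oracle <- enumerate_pip(y, x, pri, n)
  gm <- rep(0L, 4)
  acc <- numeric(4)
  occA <- occB <- 0
  iters <- 6000
  for (i in seq_len(iters)) {
    gm <- block_move(y, x, gm, pri, blocks, n_moves = 2)
    sw <- which(blocks %in% blocks[gm == 1])
    if (length(sw)) gm <- gamma_gibbs_step(y, x, gm, pri, sweep = sw, blocks = blocks)
    acc <- acc + conditional_inclusion(y, x, gm, pri)
    occA <- occA + any(gm[1:2] == 1)
    occB <- occB + any(gm[3:4] == 1)
  }
  expect_lt(max(abs(acc / iters - oracle$pip)), 0.03)
  expect_gt(occA, occB) # causal block occupied more than the decoy
})

test_that("pi is fixed or sampled on its truncated support", {
  expect_identical(sample_pi(m = 2, e = 200, mode = "fixed"), 0.01)
  # prior sampling with no data is uniform on (m/e, M/e)
  set.seed(15)
  draws <- replicate(400, sample_pi(gamma = NULL, theta = NULL, m = 1, M = 4,
                                    e = 200, mode = "sampled"))
  expect_gt(suppressWarnings( # grid draws carry occasional ties
    ks.test(draws, "punif", 1 / 200, 4 / 200))$p.value, 0.01)
  # strong data keeps draws inside the support
  set.seed(16)
  gm <- rbinom(2000, 1, 0.01)
  th <- rep(1, 2000)
  d2 <- replicate(200, sample_pi(gm, th, m = 1, M = 4, e = 200, rho = 100,
                                 mode = "sampled"))
  expect_true(all(d2 > 1 / 200 & d2 < 4 / 200))
  expect_error(sample_pi(gm, th, m = 4, M = 1, e = 200, mode = "sampled"),
               "m < M")
})

test_that("beta and sigma draws match the conjugate closed form", {
  set.seed(17)
  n <- 60
  x <- matrix(rnorm(n * 3), n, 3)
  y <- x %*% c(1, -0.5, 0) + rnorm(n)
  gamma <- c(1L, 1L, 0L)
  g <- n
  xc <- sweep(x[, 1:2], 2, colMeans(x[, 1:2]))
  yc <- y - mean(y)
  bls <- solve(crossprod(xc), crossprod(xc, yc))[, 1]
  draws <- replicate(4000, sample_beta_sigma(y, x, gamma, g)$beta)
  pm <- rowMeans(draws)
  mcse <- apply(draws, 1, sd) / sqrt(4000)
  expect_true(all(abs(pm - g / (1 + g) * bls) < 4 * mcse))

  # g -> Inf limit: posterior mean equals least squares
  dinf <- replicate(2000, sample_beta_sigma(y, x, gamma, g = 1e12)$beta)
  expect_equal(rowMeans(dinf), bls, tolerance = 0.05)

  # empty gamma: beta empty, sigma2 from the null conditional
  set.seed(18)
  out <- sample_beta_sigma(y, x, c(0L, 0L, 0L), g)
  expect_length(out$beta, 0)
  s2 <- replicate(4000, sample_beta_sigma(y, x, c(0L, 0L, 0L), g)$sigma2)
  expect_equal(mean(s2), sum(yc^2) / (n - 3), tolerance = 0.1)
})

test_that("sampler pip matches exact enumeration on p <= 12 instances", {
  set.seed(19)
  n <- 70
  p <- 8
  x <- matrix(rnorm(n * p), n, p)
  x[, 2] <- x[, 1] * 0.9 + sqrt(1 - 0.81) * rnorm(n)
  y <- x[, 1] - 0.6 * x[, 6] + rnorm(n)
  pri <- c(0.15, 0.05, 0.02, 0.02, 0.02, 0.2, 0.02, 0.02)
  oracle <- enumerate_pip(y, x, pri, n)
  blocks <- rep(1:2, each = 4)
  run <- function(seed) {
    set.seed(seed)
    gm <- rep(0L, p)
    acc <- numeric(p)
    for (i in 1:5000) {
      gm <- block_move(y, x, gm, pri, blocks, n_moves = 3)
      sw <- which(blocks %in% blocks[gm == 1])
      if (length(sw)) gm <- gamma_gibbs_step(y, x, gm, pri, sweep = sw, blocks = blocks)
      if (i > 500) acc <- acc + conditional_inclusion(y, x, gm, pri)
    }
    acc / 4500
  }
  reps <- vapply(1:3, run, numeric(p))
  mc_sd <- apply(reps, 1, sd) / sqrt(3)
  err <- abs(rowMeans(reps) - oracle$pip)
  expect_true(all(err < pmax(3 * mc_sd, 0.02)))
})

test_that("model-size guard rejects oversized inclusions", {
  y <- rnorm(10)
  x <- matrix(rnorm(10 * 9), 10, 9)
  expect_error(log_marginal(y, x), "n - 2")
  expect_error(sample_beta_sigma(y, x, rep(1L, 9)), "n - 2")
})
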