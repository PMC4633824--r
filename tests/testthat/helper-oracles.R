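# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: enumeration, recurrences and
# quadrature only.

# exact posterior inclusion probabilities by 2^p model enumeration
enumerate_pip <- function(y, x, prior_incl, g = length(y)) {
  p <- ncol(x)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  lp <- apply(configs, 1, function(gm) {
    act <- which(gm == 1)
    lm <- if (length(act))
      suppressWarnings(log_marginal(y, x[, act, drop = FALSE], g))
    else log_marginal(y, NULL, g)
    lm + sum(gm * log(prior_incl) + (1 - gm) * log(1 - prior_incl))
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(pip = colSums(configs * w), configs = configs, post = w)
}

# HWE exact P by the heterozygote-count probability recurrence
# (independent of the package's direct log-factorial evaluation)
hwe_recurrence_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * min(n_aa, n_bb) + n_ab
  n2 <- 2 * n - n1
  hs <- seq.int(n1 %% 2, min(n1, n2), by = 2)
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i] # P(h+2)/P(h) = 4 hom1 hom2 / ((h+1)(h+2))
      hom1 <- (n1 - h) / 2
      hom2 <- (n2 - h) / 2
      pr[i + 1] <- pr[i] * 4 * hom1 * hom2 / ((h + 1) * (h + 2))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hs)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# exact two-sided Wilcoxon rank-sum P by enumeration of all label
# assignments (no ties assumed)
wilcox_enum_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(x) + length(y), nx)
  Ws <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# random-walk Metropolis reference sampler for Bayesian logistic regression
metropolis_logistic <- function(X, y, b, prior_var, n_iter, step = 0.15,
                                init = b) {
  lpost <- function(a) {
    eta <- as.vector(X %*% a)
    sum(y * eta - log1p(exp(eta))) - sum((a - b)^2) / (2 * prior_var)
  }
  d <- length(b)
  out <- matrix(NA_real_, n_iter, d)
  cur <- init
  lp <- lpost(cur)
  for (it in seq_len(n_iter)) {
    prop <- cur + rnorm(d, 0, step)
    lpp <- lpost(prop)
    if (log(runif(1)) < lpp - lp) {
      cur <- prop
      lp <- lpp
    }
    out[it, ] <- cur
  }
  out
}

# brute-force PWM match P over all 4^w background words
pwm_bruteforce_p <- function(pwm, score, background = rep(0.25, 4),
                             pseudocount = 0.01) {
  lom <- eqtel:::pwm_log_odds(pwm, background, pseudocount)
  w <- ncol(lom)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- numeric(nrow(words))
  for (i in seq_len(nrow(words))) {
    s <- 0
    q <- 1
    for (j in seq_len(w)) {
      s <- s + lom[words[i, j], j]
      q <- q * background[words[i, j]]
    }
    sc[i] <- s
    pr[i] <- q
  }
  sum(pr[sc >= score - 1e-9])
}

# probabilists' Gauss-Hermite rule (Golub-Welsch); weights sum to 1, so
# sum(w * f(nodes)) approximates E[f(Z)], Z ~ N(0,1)
gauss_hermite_prob <- function(k) {
  J <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    J[i, i + 1] <- sqrt(i)
    J[i + 1, i] <- sqrt(i)
  }
  ev <- eigen(J, symmetric = TRUE)
  list(nodes = ev$values, weights = ev$vectors[1, ]^2)
}

# small genotype fixture: independent SNPs, two blocks
toy_genotypes <- function(n = 80, p = 8, seed = 3, maf = 0.3,
                          blocks = rep(1:2, each = p / 2)) {
  set.seed(seed)
  dos <- matrix(rbinom(n * p, 2, maf), n, p)
  g <- genotype_matrix(dos, chrom = "c1",
                       pos = seq(1000, by = 1000, length.out = p),
                       block = blocks)
  attr(g, "genes") <- data.frame(gene_id = "gA", chrom = "c1",
                                 tss = as.integer(1000 * (p / 2)),
                                 stringsAsFactors = FALSE)
  g
}

toy_features <- function(g, gene_id = "gA", n_epi = 2, seed = 5) {
  set.seed(seed)
  p <- ncol(g$dosages)
  ep <- matrix(rnorm(p * n_epi), p, n_epi,
               dimnames = list(g$snp_info$snp_id,
                               paste0("e", seq_len(n_epi))))
  inter <- data.frame(snp_id = g$snp_info$snp_id, gene_id = gene_id,
                      i1 = rnorm(p), stringsAsFactors = FALSE)
  standardize_feature_table(feature_table(ep, inter))
}
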