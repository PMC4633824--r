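#' Sampler configuration
#'
#' Collects every tunable of the coupled sampler. Defaults follow the
#' method's standard operating point: unit-information g-prior (`g = n`),
#' amplification `rho = 100`, fixed `pi = m_expected / (cis candidates)`,
#' 2,000 burn-in + 8,000 sampling iterations, one regulatory-model sweep
#' per outer iteration, and the "equal priors" start (gamma all zero,
#' alpha at its prior mean, so every SNP starts at the same potential).
#'
#' @param burn_in,n_iter,thin outer MCMC schedule.
#' @param g g-prior scale; `NULL` means the sample size.
#' @param rho amplification factor between inside/outside-regulator priors.
#' @param m_expected expected expression-regulators per gene. The fixed
#'   expression-regulator prior is `pi = m_expected / e` with `e` the
#'   expected number of interacting-regulators among the gene's candidates
#'   (`regulator_fraction` times the candidate count) — the two-level
#'   sparsity split: 1% of SNPs are interacting-regulators, and of those a
#'   fraction pi are expression-regulators.
#' @param regulator_fraction prior fraction of SNPs that are
#'   interacting-regulators (default 0.01); sets both the bias prior and
#'   the per-gene `e`.
#' @param pi_fixed optional explicit value overriding the `m_expected / e`
#'   rule (useful for small test instances where `e < m`).
#' @param prior_var prior variance of non-bias regulatory weights.
#' @param bias_e expected interacting-regulator count for the bias prior;
#'   `NULL` means 1% of candidate pairs.
#' @param alpha_sweeps regulatory-model Gibbs sweeps per outer iteration.
#' @param n_block_moves LD-block MH proposals per gene per iteration;
#'   `NULL` means `max(10, ceiling(blocks/4))`.
#' @param kmax model-size cap per gene; `NULL` means `min(n - 3, 25)`.
#' @param window_bp cis window for SNP-gene pairing.
#' @param store_draw_thin keep a joint (gamma, beta) draw every this many
#'   retained iterations (0 disables).
#' @param fix_alpha freeze the regulatory weights at their prior mean
#'   (uninformative-feature mode; used by exactness checks).
#' @param seed master seed for the fit.
#' @return list of class `eqtel_control`.
#' @export
eqtel_control <- function(burn_in = 2000, n_iter = 8000, thin = 1, g = NULL,
                          rho = 100, m_expected = 2,
                          regulator_fraction = 0.01, pi_fixed = NULL,
                          prior_var = 1, bias_e = NULL, alpha_sweeps = 1,
                          n_block_moves = NULL, kmax = NULL, window_bp = 1e6,
                          store_draw_thin = 10, fix_alpha = FALSE, seed = 1) {
  if (n_iter < 1) stop("at least one sampling iteration is required")
  stopifnot(burn_in >= 0, thin >= 1, rho >= 1)
  structure(as.list(environment()), class = "eqtel_control")
}

#' Fit the coupled eQTeL model
#'
#' Runs the alternating MCMC: per-gene inclusion updates under the current
#' regulatory potentials (hierarchical LD-block proposals plus within-block
#' Gibbs), interacting-regulator indicator draws given the inclusions and
#' weights, and a Polya-Gamma draw of the shared regulatory weights given
#' the indicators. Posterior inclusion probabilities are Rao-Blackwellized:
#' averages of exact per-iteration conditional probabilities rather than
#' indicator frequencies. Identical inputs, config and seed give an
#' identical summary.
#'
#' @param genotypes a [genotype_matrix()] (post-QC: complete dosages).
#' @param expression an [expression_matrix()]; rank-normalized on the fly
#'   when not already normalized.
#' @param features a standardized [feature_table()] covering every cis pair.
#' @param control an [eqtel_control()].
#' @param genes optional data.frame (`gene_id`, `chrom`, `tss`) restricting
#'   or ordering the genes to fit; defaults to all genes in `expression`.
#' @return object of class `eqtel_fit`: `pairs` (data.frame `gene_id`,
#'   `snp_id`, `pip`, `theta_hat`, `beta_mean`, `incl_freq`), `alpha_draws`,
#'   `alpha_mean`, `alpha_sd`, `per_gene` (posterior mean explained
#'   variance and convergence flags), `trace` (per-gene joint log-posterior
#'   traces), sparse joint draws for prediction, and the configuration.
#' @export
eqtel_fit <- function(genotypes, expression, features,
                      control = eqtel_control(), genes = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(expression, "expression_matrix"),
            inherits(features, "feature_table"),
            inherits(control, "eqtel_control"))
  if (anyNA(genotypes$dosages))
    stop("genotypes contain missing dosages; run qc_filter() first")
  if (!isTRUE(attr(expression, "normalized")))
    expression <- normalize_expression(expression)
  if (is.null(genes)) genes <- expression$gene_info
  set.seed(control$seed)

  n <- nrow(genotypes$dosages)
  g_scale <- if (is.null(control$g)) n else control$g
  kmax <- if (is.null(control$kmax)) min(n - 3, 25) else control$kmax

  snp_info <- genotypes$snp_info
  ep <- features$epigenetic
  inter <- features$interaction
  icols <- setdiff(names(inter), c("snp_id", "gene_id"))
  ikey <- paste(inter$gene_id, inter$snp_id)

  gene_list <- list()
  Frows <- list()
  pair_rows <- list()
  offset <- 0L
  nb_max <- 0L
  for (j in seq_len(nrow(genes))) {
    gid <- genes$gene_id[j]
    cis <- which(snp_info$chrom == genes$chrom[j] &
                   abs(snp_info$pos - genes$tss[j]) <= control$window_bp)
    if (!length(cis)) {
      warning("gene ", gid, " has no cis SNP; skipped")
      next
    }
    yrow <- match(gid, expression$gene_info$gene_id)
    if (is.na(yrow)) stop("gene ", gid, " not present in expression")
    y <- expression$values[yrow, ]
    x <- genotypes$dosages[, cis, drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    blocks <- as.integer(factor(snp_info$block[cis])) - 1L
    nb_max <- max(nb_max, max(blocks) + 1L)
    sid <- snp_info$snp_id[cis]
    em <- ep[match(sid, rownames(ep)), , drop = FALSE]
    if (anyNA(em[, 1])) stop("missing epigenetic features for gene ", gid)
    irow <- match(paste(gid, sid), ikey)
    if (anyNA(irow)) stop("missing interaction features for gene ", gid)
    im <- as.matrix(inter[irow, icols, drop = FALSE])
    gene_list[[length(gene_list) + 1L]] <- list(
      gram = crossprod(xc), xty = as.vector(crossprod(xc, y - mean(y))),
      yty = sum((y - mean(y))^2), block = blocks, offset = offset,
      gene_id = gid, snp_index = cis, centers = colMeans(x))
    Frows[[length(Frows) + 1L]] <- cbind(1, em, im)
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(gene_id = gid, snp_id = sid, stringsAsFactors = FALSE)
    offset <- offset + length(cis)
  }
  if (!length(gene_list)) stop("no gene with cis SNPs to fit")

  Fmat <- do.call(rbind, Frows)
  colnames(Fmat) <- c("bias", colnames(ep), icols)
  d <- ncol(Fmat)
  pairs <- do.call(rbind, pair_rows)

  e_bias <- if (is.null(control$bias_e))
    control$regulator_fraction * nrow(Fmat) else control$bias_e
  b <- c(bias_prior(e_bias, nrow(Fmat)), rep(0, d - 1L))
  prior_prec <- c(1, rep(1 / control$prior_var, d - 1L))
  pig <- vapply(gene_list, function(gl) {
    if (!is.null(control$pi_fixed)) return(control$pi_fixed)
    e_j <- control$regulator_fraction * length(gl$xty)
    min(control$m_expected / e_j, 0.9)
  }, numeric(1))
  nbm <- if (is.null(control$n_block_moves))
    max(10L, ceiling(nb_max / 4)) else control$n_block_moves

  res <- cpp_fit_coupled(gene_list, Fmat, b, prior_prec, n, g_scale, pig,
                         control$rho, as.integer(control$burn_in),
                         as.integer(control$n_iter), as.integer(control$thin),
                         as.integer(nbm), as.integer(kmax),
                         isTRUE(control$fix_alpha),
                         as.integer(control$alpha_sweeps),
                         as.integer(control$store_draw_thin))

  pairs$pip <- res$pip
  pairs$theta_hat <- res$theta_hat
  pairs$beta_mean <- res$beta_mean
  pairs$incl_freq <- res$incl_freq
  colnames(res$alpha_draws) <- colnames(Fmat)

  conv <- check_convergence_core(res$trace, res$pip_half1, res$pip_half2,
                                 lapply(gene_list, function(gl)
                                   gl$offset + seq_along(gl$xty)))
  per_gene <- data.frame(
    gene_id = vapply(gene_list, `[[`, character(1), "gene_id"),
    r2 = res$r2, geweke_z = conv$geweke_z, max_dpip = conv$max_dpip,
    converged = conv$converged, stringsAsFactors = FALSE)
  if (any(!per_gene$converged))
    warning(sum(!per_gene$converged), " gene(s) show non-converged chains; ",
            "summaries returned anyway (see per_gene$converged)")

  structure(list(
    pairs = pairs, alpha_draws = res$alpha_draws,
    alpha_mean = colMeans(res$alpha_draws),
    alpha_sd = apply(res$alpha_draws, 2, sd),
    per_gene = per_gene, trace = res$trace,
    beta_draws = data.frame(iter = res$beta_draw_iter,
                            pair = res$beta_draw_pair + 1L,
                            value = res$beta_draw_value),
    gene_meta = lapply(gene_list, function(gl)
      gl[c("gene_id", "snp_index", "offset", "centers")]),
    n = n, g = g_scale, control = control), class = "eqtel_fit")
}

#' @export
print.eqtel_fit <- function(x, ...) {
  cat(sprintf(paste0("eqtel_fit: %d genes, %d SNP-gene pairs, %d kept ",
                     "iterations\n  eeSNP pairs (pip > 0.5): %d; converged ",
                     "genes: %d/%d\n"),
              nrow(x$per_gene), nrow(x$pairs), nrow(x$alpha_draws),
              sum(x$pairs$pip > 0.5), sum(x$per_gene$converged),
              nrow(x$per_gene)))
  invisible(x)
}

#' Rao-Blackwellized posterior inclusion probability
#'
#' Averages exact per-iteration conditional inclusion probabilities. By the
#' Rao-Blackwell inequality this estimator has variance no larger than the
#' raw indicator-frequency estimator computed from the same chain.
#' @param p matrix (iterations x pairs) or vector of per-iteration
#'   conditional inclusion probabilities.
#' @return pip per pair.
#' @export
rao_blackwell_pip <- function(p) {
  if (is.matrix(p)) colMeans(p) else mean(p)
}

geweke_z <- function(trace, frac1 = 0.1, frac2 = 0.5) {
  m <- length(trace)
  a <- trace[seq_len(max(2, floor(frac1 * m)))]
  b <- trace[seq.int(m - max(2, floor(frac2 * m)) + 1, m)]
  s0 <- function(x) { # spectral density at zero via AR fit
    if (var(x) == 0) return(0)
    fit <- try(ar(x, aic = TRUE, order.max = min(10, length(x) %/% 5)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !length(fit$ar))
      return(var(x))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  va <- s0(a) / length(a)
  vb <- s0(b) / length(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

check_convergence_core <- function(trace, pip1, pip2, gene_pair_idx) {
  gz <- apply(trace, 2, geweke_z)
  dp <- vapply(gene_pair_idx, function(ix) max(abs(pip1[ix] - pip2[ix])),
               numeric(1))
  list(geweke_z = gz, max_dpip = dp,
       converged = abs(gz) < 2 & dp < 0.02)
}

#' Chain convergence diagnostics
#'
#' Per gene: a Geweke z-score on the joint log-posterior trace (|z| < 2)
#' and the maximum absolute PIP difference between the two chain halves
#' (< 0.02). Both must hold for the gene to be flagged converged.
#' @param fit an [eqtel_fit()], or a numeric trace vector.
#' @param z_threshold,dpip_threshold thresholds.
#' @return for a fit: the `per_gene` data.frame re-evaluated at the given
#'   thresholds; for a trace vector: a one-row data.frame.
#' @export
check_convergence <- function(fit, z_threshold = 2, dpip_threshold = 0.02) {
  if (is.numeric(fit)) {
    if (length(fit) < 4) stop("trace too short for convergence assessment")
    z <- geweke_z(fit)
    return(data.frame(geweke_z = z, converged = abs(z) < z_threshold))
  }
  stopifnot(inherits(fit, "eqtel_fit"))
  pg <- fit$per_gene
  pg$converged <- abs(pg$geweke_z) < z_threshold & pg$max_dpip < dpip_threshold
  pg
}

#' Predict expression from a fitted model
#'
#' Posterior-mean prediction: new dosages (centered at the training means)
#' times the Rao-Blackwellized posterior-mean effects. Per-draw predictions
#' from the stored joint (gamma, beta) draws are returned alongside.
#'
#' @param object an [eqtel_fit()].
#' @param genotypes a [genotype_matrix()] with the same SNPs as training.
#' @param ... unused.
#' @return list: `mean` (matrix genes x new samples) and `draws` (list per
#'   gene of matrices draws x samples; `NULL` when no draws were stored).
#' @export
predict.eqtel_fit <- function(object, genotypes, ...) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ng <- length(object$gene_meta)
  nnew <- nrow(genotypes$dosages)
  out <- matrix(0, ng, nnew,
                dimnames = list(vapply(object$gene_meta, `[[`, character(1),
                                       "gene_id"),
                                rownames(genotypes$dosages)))
  draws <- vector("list", ng)
  bd <- object$beta_draws
  for (j in seq_len(ng)) {
    gm <- object$gene_meta[[j]]
    ids <- object$pairs$snp_id[gm$offset + seq_along(gm$centers)]
    col <- match(ids, genotypes$snp_info$snp_id)
    if (anyNA(col)) stop("SNP ids of gene ", gm$gene_id,
                         " not found in new genotypes")
    xnew <- sweep(genotypes$dosages[, col, drop = FALSE], 2, gm$centers)
    beta <- object$pairs$beta_mean[gm$offset + seq_along(gm$centers)]
    out[j, ] <- as.vector(xnew %*% beta)
    prange <- gm$offset + seq_along(gm$centers)
    sub <- bd[bd$pair %in% prange, , drop = FALSE]
    if (nrow(sub)) {
      its <- sort(unique(bd$iter))
      dm <- matrix(0, length(its), nnew)
      for (r in seq_len(nrow(sub)))
        dm[match(sub$iter[r], its), ] <- dm[match(sub$iter[r], its), ] +
          xnew[, sub$pair[r] - gm$offset] * sub$value[r]
      draws[[j]] <- dm
    }
  }
  list(mean = out, draws = draws)
}
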