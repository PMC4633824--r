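#' Precision-recall curve of causal-pair recovery
#'
#' Ranks SNP-gene pairs by PIP (or any score) against the simulation truth
#' and sweeps the threshold. Tied scores are collapsed into a single
#' threshold step, so the reported precision at a tie is the expected
#' precision over random orderings of the tied pairs. A called pair is a
#' true positive iff it is a truth expression-regulator pair
#' (`level = "pair"`); `level = "snp"` scores SNPs by their best pair.
#'
#' @param pairs data.frame with `gene_id`, `snp_id` and a score column
#'   (default `pip`), e.g. the `pairs` element of an [eqtel_fit()].
#' @param truth a `simulation_truth`.
#' @param score name of the score column.
#' @param level `"pair"` or `"snp"`.
#' @return data.frame of class `pr_curve` with `threshold`, `n_called`,
#'   `recall` (non-decreasing), `precision`.
#' @export
precision_recall <- function(pairs, truth, score = "pip",
                             level = c("pair", "snp")) {
  level <- match.arg(level)
  sc <- pairs[[score]]
  if (level == "pair") {
    lab <- paste(pairs$gene_id, pairs$snp_id) %in%
      paste(truth$regulators$gene_id, truth$regulators$snp_id)
  } else {
    agg <- tapply(sc, pairs$snp_id, max)
    sc <- as.vector(agg)
    lab <- names(agg) %in% truth$regulators$snp_id
  }
  npos <- sum(lab)
  if (npos == 0) stop("truth contains zero positive pairs")
  o <- order(-sc)
  sc <- sc[o]; lab <- lab[o]
  grp <- cumsum(!duplicated(sc)) # tie groups share one threshold
  tp <- tapply(lab, grp, sum)
  nn <- tapply(lab, grp, length)
  ctp <- cumsum(tp)
  cn <- cumsum(nn)
  out <- data.frame(threshold = sc[!duplicated(sc)], n_called = as.vector(cn),
                    recall = as.vector(ctp) / npos,
                    precision = as.vector(ctp) / as.vector(cn))
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Precision interpolated at a target recall
#'
#' Linear interpolation of the precision-recall curve at recall `r`.
#' @param pr a [precision_recall()] curve.
#' @param r target recall(s) in (0, 1].
#' @export
precision_at <- function(pr, r) {
  x <- c(0, pr$recall)
  y <- c(if (nrow(pr)) pr$precision[1] else 1, pr$precision)
  vapply(r, function(ri) {
    if (ri > max(x)) return(NA_real_)
    stats::approx(x, y, xout = ri, ties = "ordered")$y
  }, numeric(1))
}

#' Ordinary and cross-validated explained variance
#'
#' Least-squares R^2 of a gene's expression on the selected SNP dosages.
#' With `cv = TRUE`, out-of-sample R^2 over `k` folds (1 - PRESS/TSS).
#'
#' @param y expression vector.
#' @param x_selected dosage matrix of the selected SNPs (zero columns or
#'   `NULL` gives R^2 = 0).
#' @param cv logical; cross-validated variant.
#' @param k folds for the CV variant.
#' @return R^2 (CV variant may be negative).
#' @export
explained_variance <- function(y, x_selected, cv = FALSE, k = 5) {
  n <- length(y)
  if (is.null(x_selected) || NCOL(x_selected) == 0) return(0)
  x <- as.matrix(x_selected)
  if (ncol(x) > n - 2) stop("more selected SNPs than samples - 2")
  if (!cv) {
    fit <- lm.fit(cbind(1, x), y)
    return(1 - sum(fit$residuals^2) / sum((y - mean(y))^2))
  }
  fold <- rep(seq_len(k), length.out = n)[sample.int(n)]
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- lm.fit(cbind(1, x[tr, , drop = FALSE]), y[tr])
    pred[!tr] <- cbind(1, x[!tr, , drop = FALSE]) %*% fit$coefficients
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Cross-validated expression predictability
#'
#' Per gene: refit the coupled model on k-1 folds of samples, predict the
#' held-out fold, pool the held-out predictions, and report the Pearson
#' correlation with the observed (normalized) expression; then the mean and
#' sd over genes. Fold fits default to shorter chains than a headline fit
#' (posterior-mean predictions stabilize much faster than PIP rankings).
#'
#' @param genotypes,expression,features as in [eqtel_fit()].
#' @param k_folds number of folds (>= 2); every fold must keep >= 3
#'   samples.
#' @param seed fold-assignment seed; fold fits use `seed + fold`.
#' @param control an [eqtel_control()] for the fold fits (default: 500
#'   burn-in + 2,500 sampling iterations).
#' @return list: `mean_r`, `sd_r`, `per_gene` (data.frame `gene_id`, `r`),
#'   `predictions` (genes x samples, pooled held-out).
#' @export
cv_predictability <- function(genotypes, expression, features, k_folds = 5,
                              seed = 1,
                              control = eqtel_control(burn_in = 500,
                                                      n_iter = 2500)) {
  stopifnot(k_folds >= 2)
  if (!isTRUE(attr(expression, "normalized")))
    expression <- normalize_expression(expression)
  n <- nrow(genotypes$dosages)
  set.seed(seed)
  fold <- rep(seq_len(k_folds), length.out = n)[sample.int(n)]
  if (min(table(fold)) < 3) stop("a fold has fewer than 3 samples")
  preds <- matrix(NA_real_, nrow(expression$values), n,
                  dimnames = dimnames(expression$values))
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    gtr <- subset_samples(genotypes, tr)
    etr <- expression
    etr$values <- expression$values[, tr, drop = FALSE]
    attr(etr, "normalized") <- TRUE # keep the full-data normalization
    ctl <- control
    ctl$seed <- seed + f
    fit <- suppressWarnings(eqtel_fit(gtr, etr, features, ctl))
    ph <- predict(fit, subset_samples(genotypes, te))
    preds[rownames(ph$mean), te] <- ph$mean
  }
  rr <- vapply(seq_len(nrow(preds)), function(j) {
    if (sd(preds[j, ]) == 0) return(0)
    cor(preds[j, ], expression$values[j, ])
  }, numeric(1))
  list(mean_r = mean(rr), sd_r = sd(rr),
       per_gene = data.frame(gene_id = rownames(preds), r = rr,
                             stringsAsFactors = FALSE),
       predictions = preds)
}

#' Detection power stratified by MAF and regulatory potential
#'
#' Among truth expression-regulator pairs, the fraction called, per MAF bin
#' and per potential stratum (high: `theta_hat >= high`; low:
#' `theta_hat < low`; the rest are middle).
#'
#' @param pairs fitted pairs (with `pip`, `theta_hat`).
#' @param truth a `simulation_truth`.
#' @param maf named per-SNP MAF vector (e.g. from `snp_info`).
#' @param bins MAF bin breaks; default deciles of the regulators' MAF.
#' @param pip_threshold call threshold (default 0.5, the eeSNP rule).
#' @param low,high potential-stratum cutoffs (default < 0.1 and >= 0.9).
#' @return data.frame `maf_bin`, `stratum`, `n`, `rate` (`NA` where the bin
#'   is empty).
#' @export
power_by_maf <- function(pairs, truth, maf, bins = NULL, pip_threshold = 0.5,
                         low = 0.1, high = 0.9) {
  key <- paste(pairs$gene_id, pairs$snp_id)
  tkey <- paste(truth$regulators$gene_id, truth$regulators$snp_id)
  ix <- match(tkey, key)
  if (anyNA(ix)) stop("truth pairs missing from fitted pairs")
  called <- pairs$pip[ix] > pip_threshold
  th <- pairs$theta_hat[ix]
  mf <- maf[truth$regulators$snp_id]
  if (is.null(bins)) bins <- unique(quantile(mf, seq(0, 1, 0.1)))
  bin <- cut(mf, bins, include.lowest = TRUE)
  stratum <- ifelse(th >= high, "high", ifelse(th < low, "low", "mid"))
  out <- expand.grid(maf_bin = levels(bin),
                     stratum = c("high", "mid", "low"),
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(b, s) sum(bin == b & stratum == s),
                  out$maf_bin, out$stratum)
  out$rate <- mapply(function(b, s) {
    sel <- bin == b & stratum == s
    if (!any(sel)) return(NA_real_)
    mean(called[sel])
  }, out$maf_bin, out$stratum)
  out
}
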