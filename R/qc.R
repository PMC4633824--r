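#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on the heterozygote count conditional on the allele
#' counts: the P value is the total probability of all heterozygote
#' configurations no more probable than the observed one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote). Vectorized.
#' @return exact P value(s) in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n == 0L) return(1)
    n1 <- 2L * min(aa, bb) + ab # minor allele count
    n2 <- 2L * n - n1
    hmax <- min(n1, n2)
    h <- seq.int(n1 %% 2L, hmax, by = 2L)
    logp <- h * log(2) - lfactorial((n1 - h) / 2) - lfactorial(h) -
      lfactorial((n2 - h) / 2)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    obs <- pr[match(ab, h)]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }, n_aa, n_ab, n_bb)
}

#' Genotype quality-control filter
#'
#' Removes SNPs failing any of three criteria, each computed on the observed
#' (pre-imputation) genotypes so the result does not depend on the order the
#' filters are applied in: call rate below `call_rate_min`, minor-allele
#' frequency below `maf_min`, or exact-test Hardy-Weinberg P below
#' `hwe_p_min`. Missing dosages of surviving SNPs are then mean-imputed
#' (which preserves each SNP's allele frequency).
#'
#' @param g a [genotype_matrix()].
#' @param call_rate_min,maf_min,hwe_p_min thresholds in (0, 1). Defaults:
#'   call rate 0.95, MAF 0.15, HWE P 1e-6.
#' @return a list with `genotypes` (the filtered, complete
#'   [genotype_matrix()]) and `report` (a data.frame counting SNPs removed
#'   per criterion, plus the total removed; criteria overlap, so the per-
#'   criterion counts need not sum to the total).
#' @export
qc_filter <- function(g, call_rate_min = 0.95, maf_min = 0.15,
                      hwe_p_min = 1e-6) {
  stopifnot(call_rate_min > 0, call_rate_min < 1,
            maf_min > 0, maf_min < 1, hwe_p_min > 0, hwe_p_min < 1)
  dos <- g$dosages
  n <- nrow(dos)
  call_rate <- 1 - colSums(is.na(dos)) / n
  maf <- maf_from_dosages(dos)
  cnt <- function(v) colSums(dos == v, na.rm = TRUE)
  n0 <- cnt(0); n1 <- cnt(1); n2 <- cnt(2)
  hwe_p <- hwe_exact_test(pmax(n0, n2), n1, pmin(n0, n2))

  fail_cr <- call_rate < call_rate_min
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep))
    stop("all SNPs removed by QC (call rate >= ", call_rate_min,
         ", MAF >= ", maf_min, ", HWE P >= ", hwe_p_min, ")")

  dos <- dos[, keep, drop = FALSE]
  # mean-impute remaining missing entries per SNP
  nas <- which(colSums(is.na(dos)) > 0L)
  for (j in nas) {
    m <- mean(dos[, j], na.rm = TRUE)
    dos[is.na(dos[, j]), j] <- m
  }
  out <- g
  out$dosages <- dos
  out$snp_info <- g$snp_info[keep, , drop = FALSE]
  out$snp_info$maf <- maf_from_dosages(dos)
  rownames(out$snp_info) <- NULL
  attr(out, "genes") <- attr(g, "genes")
  list(genotypes = out,
       report = data.frame(
         criterion = c("call_rate", "maf", "hwe", "total"),
         n_removed = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe),
                       sum(!keep))))
}
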