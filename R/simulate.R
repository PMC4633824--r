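#' Zero-truncated Poisson draws
#' @param n number of draws.
#' @param lambda Poisson rate before truncation at zero.
#' @export
rztpois <- function(n, lambda) {
  qpois(runif(n, dpois(0, lambda), 1), lambda)
}

#' Simulate block-LD genotypes
#'
#' Generates diploid dosages with LD-block structure by a Gaussian-copula
#' threshold scheme: within each block the two latent haplotype fields share
#' an equicorrelated Gaussian factor with correlation `within_block_r`, and
#' each SNP's latent values are thresholded at its MAF quantile, so every
#' SNP is in Hardy-Weinberg proportions at its target frequency while
#' within-block dosages are correlated and across-block dosages are
#' independent. Block sizes are geometric with the given mean. Each gene's
#' SNPs are laid out on a private contig at 1-kb spacing with the TSS at the
#' centre, so the default 1-Mb cis window pairs each gene with exactly its
#' own SNPs.
#'
#' @param n_samples,n_genes,snps_per_gene design dimensions (defaults 313,
#'   200, 874: the benchmark's full scale, 174,800 SNPs in total).
#' @param maf_range minor-allele frequencies drawn uniformly from this
#'   interval (default (0.15, 0.5), i.e. the post-QC spectrum).
#' @param block_size_mean mean LD-block size in SNPs (default 20).
#' @param within_block_r target latent correlation within a block, in
#'   [0, 1) (default 0.9).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return a [genotype_matrix()] with per-SNP block ids and an attached
#'   `genes` attribute (data.frame `gene_id`, `chrom`, `tss`).
#' @export
simulate_genotypes <- function(n_samples = 313, n_genes = 200,
                               snps_per_gene = 874,
                               maf_range = c(0.15, 0.5),
                               block_size_mean = 20, within_block_r = 0.9,
                               seed = NULL) {
  if (within_block_r < 0 || within_block_r >= 1)
    stop("within_block_r must lie in [0, 1)")
  stopifnot(block_size_mean >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- n_genes * snps_per_gene
  dos <- matrix(0L, n_samples, p)
  maf <- runif(p, maf_range[1], maf_range[2])
  block <- integer(p)
  chrom <- character(p)
  pos <- integer(p)
  nextblock <- 1L
  r <- within_block_r
  for (gi in seq_len(n_genes)) {
    off <- (gi - 1L) * snps_per_gene
    chrom[off + seq_len(snps_per_gene)] <- paste0("sim", gi)
    pos[off + seq_len(snps_per_gene)] <- 10000L +
      (seq_len(snps_per_gene) - 1L) * 1000L
    done <- 0L
    while (done < snps_per_gene) {
      m <- min(1L + rgeom(1, 1 / block_size_mean), snps_per_gene - done)
      idx <- off + done + seq_len(m)
      # two latent haplotype fields sharing a per-haplotype block factor
      w <- rnorm(2L * n_samples)
      z <- sqrt(r) * w + sqrt(1 - r) *
        matrix(rnorm(2L * n_samples * m), 2L * n_samples, m)
      thr <- qnorm(maf[idx])
      hap <- sweep(z, 2, thr, "<")
      dos[, idx] <- hap[seq_len(n_samples), , drop = FALSE] +
        hap[n_samples + seq_len(n_samples), , drop = FALSE]
      block[idx] <- nextblock
      nextblock <- nextblock + 1L
      done <- done + m
    }
  }
  storage.mode(dos) <- "integer"
  rownames(dos) <- paste0("sample", seq_len(n_samples))
  g <- genotype_matrix(dos, chrom = chrom, pos = pos,
                       snp_id = paste0("snp", seq_len(p)), block = block)
  attr(g, "genes") <- data.frame(
    gene_id = paste0("gene", seq_len(n_genes)),
    chrom = paste0("sim", seq_len(n_genes)),
    tss = 10000L + as.integer(round((snps_per_gene - 1) / 2) * 1000L),
    stringsAsFactors = FALSE)
  g
}

#' Declare a fraction of SNPs as interacting-regulator loci
#'
#' Draws exactly `round(fraction * p)` loci uniformly without replacement.
#' @param g a [genotype_matrix()].
#' @param fraction proportion of SNPs to flag, in (0, 1) (default 0.01).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return named logical vector over SNPs (`TRUE` = regulator locus).
#' @export
assign_regulators <- function(g, fraction = 0.01, seed = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in the open interval (0, 1)")
  p <- ncol(g$dosages)
  k <- round(fraction * p)
  if (k < 1) stop("fraction * p < 1: no regulator loci possible")
  if (!is.null(seed)) set.seed(seed)
  flags <- rep(FALSE, p)
  flags[sample.int(p, k)] <- TRUE
  names(flags) <- g$snp_info$snp_id
  flags
}

#' Cis SNP-gene candidate pairs
#'
#' Pairs every gene with the SNPs within `window_bp` of its TSS (distance
#' from transcription start; strand ignored).
#' @param g a [genotype_matrix()].
#' @param genes data.frame `gene_id`, `chrom`, `tss`; defaults to the
#'   `genes` attribute a simulated genotype matrix carries.
#' @param window_bp cis window (default 1e6).
#' @return data.frame `gene_id`, `snp_id`, `snp_index`.
#' @export
cis_pairs <- function(g, genes = attr(g, "genes"), window_bp = 1e6) {
  if (is.null(genes)) stop("no gene coordinates supplied")
  out <- lapply(seq_len(nrow(genes)), function(j) {
    cis <- which(g$snp_info$chrom == genes$chrom[j] &
                   abs(g$snp_info$pos - genes$tss[j]) <= window_bp)
    if (!length(cis)) return(NULL)
    data.frame(gene_id = genes$gene_id[j], snp_id = g$snp_info$snp_id[cis],
               snp_index = cis, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate gene expression from flagged regulator loci
#'
#' Per gene, draws a causal count k from `count_dist`, picks k
#' expression-regulators among the gene's regulator-flagged cis SNPs, draws
#' effect sizes on standardized dosages, and adds Gaussian noise calibrated
#' so that on the realized genotypes var(predictor) / (var(predictor) +
#' noise_sd^2) equals the gene's drawn target explained variance exactly.
#'
#' @param g a [genotype_matrix()].
#' @param flags regulator flags from [assign_regulators()].
#' @param count_dist function(n) drawing per-gene causal counts on
#'   \{1, 2, ...\} (default zero-truncated Poisson(2)).
#' @param effect_dist function(n) drawing nonzero effect sizes (default
#'   standard normal; exact zeros are redrawn).
#' @param r2_dist function(n) drawing per-gene target explained variance in
#'   (0, 1) (default Beta with mean 0.09, shape1 = 2).
#' @param genes,window_bp cis pairing, as in [cis_pairs()].
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return list with `expression` (an [expression_matrix()], raw scale) and
#'   `truth` (class `simulation_truth`: `regulator_flags`, `regulators`
#'   data.frame (`gene_id`, `snp_id`, `effect`), `genes` data.frame
#'   (`gene_id`, `target_r2`, `noise_sd`)).
#' @export
simulate_expression <- function(g, flags,
                                count_dist = function(n) rztpois(n, 2),
                                effect_dist = function(n) rnorm(n),
                                r2_dist = function(n) rbeta(n, 2, 2 * (1 / 0.09 - 1)),
                                genes = attr(g, "genes"), window_bp = 1e6,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) stop("no gene coordinates supplied")
  n <- nrow(g$dosages)
  ng <- nrow(genes)
  xstd <- scale(g$dosages)
  vals <- matrix(NA_real_, ng, n, dimnames = list(genes$gene_id, rownames(g$dosages)))
  regl <- vector("list", ng)
  target_r2 <- noise_sd <- numeric(ng)
  for (j in seq_len(ng)) {
    cis <- which(g$snp_info$chrom == genes$chrom[j] &
                   abs(g$snp_info$pos - genes$tss[j]) <= window_bp)
    cand <- cis[flags[cis]]
    if (!length(cand))
      stop("gene ", genes$gene_id[j], " has no regulator-flagged cis SNP")
    k <- count_dist(1L)
    tries <- 0L
    while (k > length(cand)) {
      if (tries == 0L)
        warning("gene ", genes$gene_id[j], ": drawn causal count ", k,
                " exceeds ", length(cand), " flagged cis SNPs; redrawing")
      k <- count_dist(1L)
      tries <- tries + 1L
      if (tries > 1000L) stop("cannot draw a feasible causal count")
    }
    picked <- if (length(cand) == 1L) cand else sample(cand, k)
    eff <- effect_dist(k)
    while (any(eff == 0)) eff[eff == 0] <- effect_dist(sum(eff == 0))
    pred <- as.vector(xstd[, picked, drop = FALSE] %*% eff)
    v <- var(pred)
    r2 <- r2_dist(1L)
    noise_sd[j] <- sqrt(v * (1 - r2) / r2)
    target_r2[j] <- r2
    vals[j, ] <- pred + rnorm(n, 0, noise_sd[j])
    regl[[j]] <- data.frame(gene_id = genes$gene_id[j],
                            snp_id = g$snp_info$snp_id[picked],
                            effect = eff, stringsAsFactors = FALSE)
  }
  truth <- structure(list(
    regulator_flags = flags,
    regulators = do.call(rbind, regl),
    genes = data.frame(gene_id = genes$gene_id, target_r2 = target_r2,
                       noise_sd = noise_sd, stringsAsFactors = FALSE)),
    class = "simulation_truth")
  list(expression = expression_matrix(vals, chrom = genes$chrom,
                                      tss = genes$tss,
                                      gene_id = genes$gene_id),
       truth = truth)
}

#' Default epigenetic mark names and enhancer mean shifts
#'
#' Seven heart-enhancer marks; activating marks shift positive at regulator
#' loci, repressive marks negative. The 3-sd magnitude abstracts validated
#' enhancers as a two-population mean shift.
#' @export
default_epigenetic_marks <- function() {
  c(DNase = 3, H3K4me1 = 3, H3K4me3 = 3, P300 = 3, H3K27me3 = -3,
    H3K36me3 = 3, H3K9me3 = -3)
}

#' Simulate epigenetic and interaction features
#'
#' Background SNPs draw each epigenetic feature from a standard normal;
#' regulator-flagged SNPs draw from a normal with mean `enhancer_shift`
#' (sign per mark). Interaction features are standard normal except that
#' true expression-regulator pairs (when `truth` is supplied) are shifted by
#' `interaction_shift`, emulating weakly informative correlation-derived
#' interaction evidence. All columns are standardized afterwards.
#'
#' @param flags regulator flags from [assign_regulators()] (named by SNP).
#' @param pairs candidate pairs from [cis_pairs()].
#' @param truth optional `simulation_truth`; names the true pairs whose
#'   interaction features are elevated.
#' @param n_epigenetic number of epigenetic features (default 7).
#' @param enhancer_shift signed mean-shift per epigenetic feature at
#'   regulator loci; length must equal `n_epigenetic`.
#' @param n_interaction,interaction_shift number of interaction features and
#'   the mean shift of true pairs (defaults 2 and 1).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @return a standardized [feature_table()].
#' @export
simulate_features <- function(flags, pairs, truth = NULL, n_epigenetic = 7,
                              enhancer_shift = default_epigenetic_marks(),
                              n_interaction = 2, interaction_shift = 1,
                              seed = NULL) {
  if (length(enhancer_shift) != n_epigenetic)
    stop("enhancer_shift must have length n_epigenetic (", n_epigenetic, ")")
  if (!is.null(seed)) set.seed(seed)
  p <- length(flags)
  nm <- names(enhancer_shift)
  if (is.null(nm)) nm <- paste0("epi", seq_len(n_epigenetic))
  ep <- matrix(rnorm(p * n_epigenetic), p, n_epigenetic,
               dimnames = list(names(flags), nm))
  ep[flags, ] <- sweep(ep[flags, , drop = FALSE], 2, enhancer_shift, "+")
  npair <- nrow(pairs)
  im <- matrix(rnorm(npair * n_interaction), npair, n_interaction)
  colnames(im) <- paste0("inter", seq_len(n_interaction))
  if (!is.null(truth)) {
    key <- paste(pairs$gene_id, pairs$snp_id)
    hit <- key %in% paste(truth$regulators$gene_id, truth$regulators$snp_id)
    im[hit, ] <- im[hit, , drop = FALSE] + interaction_shift
  }
  inter <- data.frame(snp_id = pairs$snp_id, gene_id = pairs$gene_id,
                      im, stringsAsFactors = FALSE)
  standardize_feature_table(feature_table(ep, inter))
}

#' Generate a complete semi-synthetic benchmark dataset
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [assign_regulators()], [simulate_expression()] and
#' [simulate_features()], all driven by one seed. The defaults reproduce
#' the benchmark design: 313 samples, 874 candidate SNPs per gene, 1%
#' regulator loci, 7 enhancer-shifted epigenetic marks, noise calibrated to
#' the target explained-variance distribution.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulate_expression
#' @inheritParams simulate_features
#' @param regulator_fraction fraction of SNPs flagged as regulator loci.
#' @param seed master seed driving every stage.
#' @return list: `genotypes`, `expression` (raw), `features`, `truth`,
#'   `pairs`.
#' @export
simulate_eqtel_data <- function(n_samples = 313, n_genes = 200,
                                snps_per_gene = 874,
                                maf_range = c(0.15, 0.5),
                                block_size_mean = 20, within_block_r = 0.9,
                                regulator_fraction = 0.01,
                                count_dist = function(n) rztpois(n, 2),
                                effect_dist = function(n) rnorm(n),
                                r2_dist = function(n) rbeta(n, 2, 2 * (1 / 0.09 - 1)),
                                n_epigenetic = 7,
                                enhancer_shift = default_epigenetic_marks(),
                                n_interaction = 2, interaction_shift = 1,
                                seed = 1) {
  set.seed(seed)
  g <- simulate_genotypes(n_samples, n_genes, snps_per_gene, maf_range,
                          block_size_mean, within_block_r, seed = NULL)
  flags <- assign_regulators(g, regulator_fraction, seed = NULL)
  sim <- simulate_expression(g, flags, count_dist, effect_dist, r2_dist,
                             seed = NULL)
  pairs <- cis_pairs(g)
  ft <- simulate_features(flags, pairs, truth = sim$truth, n_epigenetic,
                          enhancer_shift, n_interaction, interaction_shift,
                          seed = NULL)
  list(genotypes = g, expression = sim$expression, features = ft,
       truth = sim$truth, pairs = pairs)
}

#' Serialize or load simulation ground truth
#'
#' Writes `<prefix>_truth_pairs.tsv` (snp_id, gene_id, effect,
#' regulator_flag for every flagged or causal SNP-gene record),
#' `<prefix>_truth_flags.tsv` and `<prefix>_truth_genes.tsv`, so that
#' evaluation can always join predictions to truth by SNP and gene id.
#' @param truth a `simulation_truth`.
#' @param prefix path prefix.
#' @export
write_truth <- function(truth, prefix) {
  reg <- truth$regulators
  reg$regulator_flag <- TRUE
  data.table::fwrite(reg, paste0(prefix, "_truth_pairs.tsv"), sep = "\t")
  data.table::fwrite(
    data.table::data.table(snp_id = names(truth$regulator_flags),
                           regulator_flag = truth$regulator_flags),
    paste0(prefix, "_truth_flags.tsv"), sep = "\t")
  data.table::fwrite(truth$genes, paste0(prefix, "_truth_genes.tsv"),
                     sep = "\t")
  invisible(prefix)
}

#' @rdname write_truth
#' @export
read_truth <- function(prefix) {
  reg <- as.data.frame(data.table::fread(
    paste0(prefix, "_truth_pairs.tsv"), sep = "\t"))
  flg <- data.table::fread(paste0(prefix, "_truth_flags.tsv"), sep = "\t")
  genes <- as.data.frame(data.table::fread(
    paste0(prefix, "_truth_genes.tsv"), sep = "\t"))
  structure(list(
    regulator_flags = setNames(flg$regulator_flag, flg$snp_id),
    regulators = reg[c("gene_id", "snp_id", "effect")],
    genes = genes), class = "simulation_truth")
}
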