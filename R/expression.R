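#' Construct an expression matrix
#'
#' @param values numeric matrix, genes x samples; row names are gene ids
#'   unless `gene_id` is given.
#' @param chrom,tss chromosome and transcription-start coordinate per gene,
#'   used for cis-window pairing.
#' @param gene_id gene identifiers.
#' @return an object of class `expression_matrix`: list with `values`
#'   (genes x samples) and `gene_info` (`gene_id`, `chrom`, `tss`).
#' @export
expression_matrix <- function(values, chrom, tss, gene_id = rownames(values)) {
  values <- as.matrix(values)
  ng <- nrow(values)
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_len(ng))
  if (length(chrom) == 1L) chrom <- rep(chrom, ng)
  stopifnot(length(gene_id) == ng, length(chrom) == ng, length(tss) == ng)
  rownames(values) <- gene_id
  structure(list(values = values,
                 gene_info = data.frame(gene_id = as.character(gene_id),
                                        chrom = as.character(chrom),
                                        tss = as.integer(tss),
                                        stringsAsFactors = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  invisible(x)
}

#' Rank-based inverse-normal transform of expression
#'
#' Per gene, ranks across samples (ties averaged) are mapped through the
#' normal quantile function with Blom offsets, (rank - 3/8)/(n + 1/4), and
#' the result is rescaled to exactly zero mean and unit variance. The
#' transform is idempotent: reapplying it returns the same values.
#'
#' @param e an [expression_matrix()].
#' @return the normalized [expression_matrix()] (attribute `normalized`).
#' @export
normalize_expression <- function(e) {
  v <- e$values
  n <- ncol(v)
  out <- t(apply(v, 1, function(y) {
    qnorm((rank(y, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  }))
  const <- apply(v, 1, function(y) all(y == y[1]))
  if (any(const))
    stop("constant expression row cannot be normalized: gene ",
         e$gene_info$gene_id[which(const)[1]])
  out <- out - rowMeans(out)
  out <- out / sqrt(rowSums(out^2) / (n - 1))
  e$values <- out
  attr(e, "normalized") <- TRUE
  e
}

#' Univariate cis-eQTL gene screen
#'
#' Simple-linear-regression association of each gene with every SNP within
#' `window_bp` of its transcription start; P values are pooled across all
#' gene-SNP tests and Benjamini-Hochberg adjusted. A gene is retained when
#' at least one cis SNP has adjusted P below `fdr`. Genes with no cis SNP
#' are excluded with a warning.
#'
#' @param g a [genotype_matrix()].
#' @param e an [expression_matrix()] (normalized or not; association is
#'   scale-invariant).
#' @param window_bp cis window around the TSS (default 1e6).
#' @param fdr Benjamini-Hochberg threshold (default 1e-6).
#' @return character vector of retained gene ids; the full per-pair
#'   association table is attached as attribute `"screen"`.
#' @export
univariate_screen <- function(g, e, window_bp = 1e6, fdr = 1e-6) {
  n <- nrow(g$dosages)
  stopifnot(n == ncol(e$values))
  res <- vector("list", nrow(e$gene_info))
  for (j in seq_len(nrow(e$gene_info))) {
    gi <- e$gene_info[j, ]
    cis <- which(g$snp_info$chrom == gi$chrom &
                   abs(g$snp_info$pos - gi$tss) <= window_bp)
    if (!length(cis)) {
      warning("gene ", gi$gene_id, " has no cis SNP within ", window_bp,
              " bp; excluded from screen")
      next
    }
    y <- e$values[j, ]
    r <- suppressWarnings(as.vector(cor(g$dosages[, cis, drop = FALSE], y)))
    r[is.na(r)] <- 0
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    res[[j]] <- data.frame(gene_id = gi$gene_id,
                           snp_id = g$snp_info$snp_id[cis], p = p)
  }
  tab <- do.call(rbind, res)
  if (is.null(tab)) return(character(0))
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  genes <- unique(tab$gene_id[tab$p_adj <= fdr])
  structure(genes, screen = tab)
}

#' Read or write expression in the package TSV dialect
#'
#' One row per gene: `gene_id`, `chrom`, `tss`, then one column per sample.
#' @param path file path.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("gene_id", "chrom")))
  samples <- setdiff(names(dt), c("gene_id", "chrom", "tss"))
  v <- as.matrix(dt[, samples, with = FALSE])
  rownames(v) <- dt$gene_id
  expression_matrix(v, chrom = dt$chrom, tss = dt$tss, gene_id = dt$gene_id)
}

#' @rdname read_expression
#' @param e an [expression_matrix()].
#' @export
write_expression <- function(e, path) {
  samp <- colnames(e$values)
  if (is.null(samp)) samp <- paste0("sample", seq_len(ncol(e$values)))
  dt <- data.table::as.data.table(
    c(e$gene_info, as.data.frame(e$values, col.names = samp)))
  data.table::setnames(dt, c("gene_id", "chrom", "tss", samp))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
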