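#' Construct a feature table
#'
#' Holds the per-SNP epigenetic features and the per-SNP-gene-pair
#' interaction features that together form the regulatory model's input.
#' Feature columns are expected standardized (mean 0, sd 1) over the
#' candidate universe; use [standardize_feature_table()].
#'
#' @param epigenetic numeric matrix, SNPs x features, with SNP ids as row
#'   names.
#' @param interaction data.frame with `snp_id`, `gene_id` and one numeric
#'   column per interaction feature.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(epigenetic, interaction) {
  epigenetic <- as.matrix(epigenetic)
  if (is.null(rownames(epigenetic)))
    stop("epigenetic feature matrix needs SNP ids as row names")
  stopifnot(all(c("snp_id", "gene_id") %in% names(interaction)))
  structure(list(epigenetic = epigenetic,
                 interaction = as.data.frame(interaction)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d SNPs x %d epigenetic, %d pairs x %d interaction\n",
              nrow(x$epigenetic), ncol(x$epigenetic),
              nrow(x$interaction), ncol(x$interaction) - 2L))
  invisible(x)
}

#' Standardize feature columns to mean 0 and unit sd
#'
#' Epigenetic columns are standardized over the SNP universe, interaction
#' columns over all pairs.
#' @param ft a [feature_table()].
#' @export
standardize_feature_table <- function(ft) {
  std <- function(x) {
    s <- sd(x)
    if (s == 0) stop("constant feature column cannot be standardized")
    (x - mean(x)) / s
  }
  ft$epigenetic <- apply(ft$epigenetic, 2, std)
  for (cl in setdiff(names(ft$interaction), c("snp_id", "gene_id")))
    ft$interaction[[cl]] <- std(ft$interaction[[cl]])
  attr(ft, "standardized") <- TRUE
  ft
}

#' Check feature-table standardization (mean 0, sd 1 within tolerance)
#' @param ft a [feature_table()].
#' @param tol tolerance (default 1e-8).
#' @export
validate_feature_table <- function(ft, tol = 1e-8) {
  chk <- function(x, lab) {
    if (abs(mean(x)) > tol || abs(sd(x) - 1) > tol)
      stop("feature column not standardized: ", lab)
  }
  for (j in seq_len(ncol(ft$epigenetic)))
    chk(ft$epigenetic[, j], colnames(ft$epigenetic)[j])
  for (cl in setdiff(names(ft$interaction), c("snp_id", "gene_id")))
    chk(ft$interaction[[cl]], cl)
  invisible(ft)
}

#' Read or write a feature table as a pair of TSVs
#'
#' Writes `<prefix>_epigenetic.tsv` (snp_id + feature columns) and
#' `<prefix>_interaction.tsv` (snp_id, gene_id + feature columns).
#' @param prefix path prefix.
#' @export
read_feature_table <- function(prefix) {
  ep <- data.table::fread(paste0(prefix, "_epigenetic.tsv"), sep = "\t")
  em <- as.matrix(ep[, -1])
  rownames(em) <- ep$snp_id
  inter <- as.data.frame(
    data.table::fread(paste0(prefix, "_interaction.tsv"), sep = "\t"))
  feature_table(em, inter)
}

#' @rdname read_feature_table
#' @param ft a [feature_table()].
#' @export
write_feature_table <- function(ft, prefix) {
  data.table::fwrite(
    data.table::data.table(snp_id = rownames(ft$epigenetic), ft$epigenetic),
    paste0(prefix, "_epigenetic.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(ft$interaction),
                     paste0(prefix, "_interaction.tsv"), sep = "\t")
  invisible(prefix)
}
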