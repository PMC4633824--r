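#' Construct a genotype matrix
#'
#' Container for allele dosages across samples with per-SNP metadata. Dosages
#' are counts of the alternate (minor-coded) allele in \{0, 1, 2\}; missing
#' values are allowed before QC. The minor-allele frequency is always derived
#' from the dosages themselves, and every SNP carries exactly one LD-block
#' id (SNPs default to singleton blocks until [set_blocks()] is called).
#'
#' @param dosages numeric matrix, samples x SNPs; column names are SNP ids
#'   unless `snp_id` is given.
#' @param chrom,pos chromosome label and 1-based position per SNP.
#' @param snp_id SNP identifiers; defaults to `colnames(dosages)`.
#' @param block integer LD-block index per SNP; defaults to singleton blocks.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` (samples x SNPs) and `snp_info` (data.frame with `snp_id`,
#'   `chrom`, `pos`, `maf`, `block`).
#' @export
genotype_matrix <- function(dosages, chrom, pos, snp_id = colnames(dosages),
                            block = NULL) {
  dosages <- as.matrix(dosages)
  p <- ncol(dosages)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(p))
  if (length(chrom) == 1L) chrom <- rep(chrom, p)
  stopifnot(length(snp_id) == p, length(chrom) == p, length(pos) == p)
  if (is.null(block)) block <- seq_len(p)
  if (anyNA(block) || length(block) != p)
    stop("every SNP must belong to exactly one LD block")
  colnames(dosages) <- snp_id
  g <- structure(list(
    dosages = dosages,
    snp_info = data.frame(snp_id = as.character(snp_id),
                          chrom = as.character(chrom),
                          pos = as.integer(pos),
                          maf = maf_from_dosages(dosages),
                          block = as.integer(block),
                          stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
  g
}

maf_from_dosages <- function(dosages) {
  f <- colMeans(dosages, na.rm = TRUE) / 2
  unname(pmin(f, 1 - f))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs, %d LD blocks\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$snp_info$block))))
  if (anyNA(x$dosages)) cat("  contains missing dosages (pre-QC)\n")
  invisible(x)
}

#' Validate genotype-matrix invariants
#'
#' Checks that the stored MAF matches the MAF recomputed from dosages (to
#' 1e-12), that every SNP has a block id, and (if `post_qc`) that no dosage
#' is missing.
#' @param g a [genotype_matrix()].
#' @param post_qc logical; additionally require completeness.
#' @return `g`, invisibly; errors describe the violated invariant.
#' @export
validate_genotype_matrix <- function(g, post_qc = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  maf <- maf_from_dosages(g$dosages)
  if (max(abs(maf - g$snp_info$maf)) > 1e-12)
    stop("stored maf does not match maf recomputed from dosages")
  if (anyNA(g$snp_info$block))
    stop("every SNP must belong to exactly one LD block")
  if (post_qc && anyNA(g$dosages))
    stop("post-QC genotype matrix contains missing dosages")
  invisible(g)
}

#' Subset samples of a genotype matrix
#' @param g a [genotype_matrix()].
#' @param idx sample indices to keep.
#' @export
subset_samples <- function(g, idx) {
  out <- g
  out$dosages <- g$dosages[idx, , drop = FALSE]
  out$snp_info$maf <- maf_from_dosages(out$dosages)
  attr(out, "genes") <- attr(g, "genes")
  out
}

#' Read genotypes from VCF, PLINK-style dosage text, or the package TSV
#'
#' `format = "vcf"` reads diploid GT fields (via \pkg{vcfR}); multi-allelic
#' records and ploidy other than 2 are rejected. `format = "plink-text"`
#' reads a PLINK `.raw`-style additive dosage file (FID IID PAT MAT SEX
#' PHENOTYPE then one column per SNP). `format = "tsv"` reads the package's
#' own dialect written by [write_genotypes()].
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"vcf"`, `"plink-text"`.
#' @return a [genotype_matrix()]; dosage orientation is samples x SNPs.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "plink-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tsv = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path),
         `plink-text` = read_genotypes_raw(path))
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("snp_id", "chrom")))
  meta <- c("snp_id", "chrom", "pos", "block")
  if (!all(meta %in% names(dt)))
    stop("malformed genotype TSV: expected columns ", paste(meta, collapse = ", "))
  samples <- setdiff(names(dt), meta)
  dos <- t(as.matrix(dt[, samples, with = FALSE]))
  rownames(dos) <- samples
  genotype_matrix(dos, chrom = dt$chrom, pos = dt$pos, snp_id = dt$snp_id,
                  block = dt$block)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record not supported: ",
         fix[which(multi)[1], "ID"], " (variant line ", which(multi)[1], ")")
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(x, "[/|]")[[1]]
    if (length(al) != 2L)
      stop("unsupported ploidy (expected diploid GT): '", x, "'")
    if (any(al == ".")) return(NA_real_)
    sum(al == "1")
  })
  dos <- t(dos) # samples x SNPs
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(dos, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  snp_id = ids)
}

read_genotypes_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(dt)))
    stop("malformed PLINK .raw file: missing header columns")
  snp_cols <- setdiff(names(dt), meta)
  dos <- as.matrix(dt[, snp_cols, with = FALSE])
  rownames(dos) <- dt$IID
  ids <- sub("_[ACGT]$", "", snp_cols)
  genotype_matrix(dos, chrom = rep(NA_character_, length(ids)),
                  pos = seq_along(ids), snp_id = ids)
}

#' Write genotypes in the package TSV dialect
#'
#' One row per SNP: `snp_id`, `chrom`, `pos`, `block`, then one dosage
#' column per sample. Round-trips bit-exactly through [read_genotypes()].
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(g, path) {
  samp <- rownames(g$dosages)
  if (is.null(samp)) samp <- paste0("sample", seq_len(nrow(g$dosages)))
  dt <- data.table::as.data.table(
    c(g$snp_info[c("snp_id", "chrom", "pos", "block")],
      as.data.frame(t(g$dosages), col.names = samp)))
  data.table::setnames(dt, c("snp_id", "chrom", "pos", "block", samp))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Dosages must be complete and integer; 0/1/2 map to GT 0/0, 0/1, 1/1.
#' @inheritParams write_genotypes
#' @export
write_vcf <- function(g, path) {
  if (anyNA(g$dosages)) stop("write_vcf requires complete dosages")
  samp <- rownames(g$dosages)
  if (is.null(samp)) samp <- paste0("sample", seq_len(nrow(g$dosages)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samp), collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    gt <- gtmap[g$dosages[, j] + 1L]
    writeLines(paste(c(g$snp_info$chrom[j], g$snp_info$pos[j],
                       g$snp_info$snp_id[j], "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read or write LD blocks (PLINK `.blocks`-style text)
#'
#' Each line lists the SNP ids of one block, whitespace-separated; a leading
#' `*` token (as PLINK writes) is ignored.
#' @param path blocks file.
#' @return `read_blocks`: a list of character vectors of SNP ids.
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(trimws(lines), "\\s+"), function(x) setdiff(x, "*"))
}

#' @rdname read_blocks
#' @param blocks list of character vectors of SNP ids.
#' @export
write_blocks <- function(blocks, path) {
  writeLines(vapply(blocks, function(x) paste(c("*", x), collapse = " "),
                    character(1)), path)
  invisible(path)
}

#' Attach an LD-block partition to a genotype matrix
#'
#' SNPs not named in `blocks` keep singleton blocks (appended after the
#' listed ones).
#' @param g a [genotype_matrix()].
#' @param blocks list of character vectors of SNP ids (see [read_blocks()]).
#' @export
set_blocks <- function(g, blocks) {
  id <- g$snp_info$snp_id
  block <- rep(NA_integer_, length(id))
  for (b in seq_along(blocks)) {
    hit <- match(blocks[[b]], id)
    if (anyNA(hit))
      stop("block ", b, " names unknown SNP: ",
           blocks[[b]][which(is.na(hit))[1]])
    if (any(!is.na(block[hit])))
      stop("SNP assigned to more than one block")
    block[hit] <- b
  }
  nb <- length(blocks)
  singles <- which(is.na(block))
  block[singles] <- nb + seq_along(singles)
  g$snp_info$block <- as.integer(block)
  g
}
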