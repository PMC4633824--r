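#' Read position weight matrices (MEME-like or TRANSFAC-like text)
#'
#' MEME format: `MOTIF <id>` headers followed by a
#' `letter-probability matrix:` block of w rows (A C G T). TRANSFAC
#' format: `ID`/`NA` headers with numbered count rows and `//` separators.
#' Count matrices are converted to column probabilities.
#'
#' @param path PWM file.
#' @param format `"meme"` or `"transfac"`.
#' @return named list of 4 x w probability matrices (rows A, C, G, T).
#' @export
read_pwm <- function(path, format = c("meme", "transfac")) {
  format <- match.arg(format)
  lines <- readLines(path)
  out <- list()
  if (format == "meme") {
    i <- 1L
    while (i <= length(lines)) {
      if (grepl("^MOTIF\\s+", lines[i])) {
        id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
        j <- i + 1L
        while (j <= length(lines) &&
               !grepl("letter-probability matrix", lines[j])) j <- j + 1L
        if (j > length(lines)) stop("MEME motif ", id, " has no matrix block")
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
        rows <- lines[j + seq_len(w)]
        m <- t(vapply(rows, function(l)
          as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4)))
        out[[id]] <- t(m)
        rownames(out[[id]]) <- c("A", "C", "G", "T")
        i <- j + w + 1L
      } else i <- i + 1L
    }
  } else {
    cur <- NULL
    rows <- list()
    flush <- function() {
      if (!is.null(cur) && length(rows)) {
        m <- do.call(cbind, rows)
        rownames(m) <- c("A", "C", "G", "T")
        m <- sweep(m, 2, colSums(m), "/")
        out[[cur]] <<- m
      }
    }
    for (l in lines) {
      if (grepl("^(ID|NA)\\s+", l)) {
        flush(); rows <- list()
        cur <- strsplit(trimws(l), "\\s+")[[1]][2]
      } else if (grepl("^\\d+\\s", l)) {
        v <- strsplit(trimws(l), "\\s+")[[1]]
        rows[[length(rows) + 1L]] <- as.numeric(v[2:5])
      } else if (grepl("^//", l)) {
        flush(); rows <- list(); cur <- NULL
      }
    }
    flush()
  }
  if (!length(out)) stop("no motifs parsed from ", path)
  out
}

pwm_log_odds <- function(pwm, background = rep(0.25, 4),
                         pseudocount = 0.01) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (any(colSums(pwm) > 1.5)) # count matrix
    pwm <- sweep(pwm, 2, colSums(pwm), "/")
  q <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  log(q / background)
}

#' Exact PWM score distribution under the background model
#'
#' Dynamic program over the per-position score lattice: the full
#' distribution of the log-odds match score of a random background word.
#' Below `quantize_width` positions the lattice is kept exact (every
#' reachable score is a state, so the distribution equals brute-force
#' enumeration over all 4^w words); wider motifs are quantized to
#' `quantize` to bound the state count.
#'
#' @param pwm probability (or count) matrix, 4 x w.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount added per cell before log-odds (default 0.01).
#' @param quantize lattice resolution for wide motifs (default 1e-4).
#' @param quantize_width width above which quantization kicks in.
#' @return data.frame `score`, `prob` (sums to 1), sorted by score.
#' @export
pwm_score_distribution <- function(pwm, background = rep(0.25, 4),
                                   pseudocount = 0.01, quantize = 1e-4,
                                   quantize_width = 10) {
  lom <- pwm_log_odds(pwm, background, pseudocount)
  w <- ncol(lom)
  exact <- w <= quantize_width
  sc <- 0
  pr <- 1
  for (j in seq_len(w)) {
    ns <- as.vector(outer(sc, lom[, j], "+")) # partial-sum-first order
    np <- as.vector(outer(pr, background, "*"))
    key <- if (exact) ns else round(ns / quantize) * quantize
    agg <- rowsum(np, group = key)
    sc <- as.numeric(rownames(agg))
    pr <- as.vector(agg)
  }
  o <- order(sc)
  data.frame(score = sc[o], prob = pr[o])
}

#' Exact match P value of a PWM score
#'
#' `P(S >= s)` for a random background word, from the exact score
#' distribution ([pwm_score_distribution()]); scores within 1e-9 of `s`
#' count as matches.
#' @param score observed best log-odds score.
#' @param dist a [pwm_score_distribution()] (or a PWM, from which the
#'   distribution is computed).
#' @param ... passed to [pwm_score_distribution()] when `dist` is a PWM.
#' @export
pwm_match_pvalue <- function(score, dist, ...) {
  if (is.matrix(dist)) dist <- pwm_score_distribution(dist, ...)
  sum(dist$prob[dist$score >= score - 1e-9])
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

#' Allele-differential motif scan at a SNP
#'
#' Scans the SNP-centered sequence window with both alleles substituted at
#' the centre, over both strands and every motif offset that overlaps the
#' SNP. Each allele's best log-odds score is converted to an exact match P
#' value under the background model; the reported scores are -log10 P and
#' the differential is their difference (major minus minor). Offsets
#' containing ambiguous bases are skipped; a motif wider than the window is
#' an error.
#'
#' @param sequence SNP-centered window (odd length, e.g. 101 bp for 50-bp
#'   flanks), the variant base at the centre.
#' @param alleles character pair `(major, minor)`.
#' @param pwm probability or count matrix, 4 x w.
#' @param background base frequencies (default uniform).
#' @param pseudocount PWM pseudocount (default 0.01).
#' @param hit_p motif-hit significance threshold (default 2e-4); the pair
#'   passes when at least one allele's match P is below it.
#' @param motif_id,snp_id labels carried into the result.
#' @return one-row data.frame: `motif_id`, `snp_id`, `score_major`,
#'   `score_minor`, `differential`, `passes_hit_threshold`.
#' @export
scan_alleles <- function(sequence, alleles, pwm,
                         background = rep(0.25, 4), pseudocount = 0.01,
                         hit_p = 2e-4, motif_id = "motif", snp_id = "snp") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L %% 2 == 0) stop("sequence window must have odd length (SNP centered)")
  center <- (L + 1L) %/% 2L
  lom <- pwm_log_odds(pwm, background, pseudocount)
  w <- ncol(lom)
  if (w > L) stop("PWM wider than the sequence window")
  dist <- pwm_score_distribution(pwm, background, pseudocount)
  offs <- seq.int(max(1L, center - w + 1L), min(center, L - w + 1L))
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  score_one <- function(allele) {
    s2 <- sequence
    substr(s2, center, center) <- toupper(allele)
    best <- -Inf
    for (o in offs) {
      for (strand in 1:2) {
        sub <- substr(s2, o, o + w - 1L)
        if (strand == 2) sub <- revcomp(sub)
        idx <- base_idx[strsplit(sub, "")[[1]]]
        if (anyNA(idx)) next # ambiguous base: skip this offset
        sc <- 0
        for (j in seq_len(w)) sc <- sc + lom[idx[j], j]
        if (sc > best) best <- sc
      }
    }
    if (!is.finite(best)) return(0) # no scorable offset: P = 1
    -log10(pwm_match_pvalue(best, dist))
  }
  s_maj <- score_one(alleles[1])
  s_min <- score_one(alleles[2])
  data.frame(motif_id = motif_id, snp_id = snp_id, score_major = s_maj,
             score_minor = s_min, differential = s_maj - s_min,
             passes_hit_threshold = max(s_maj, s_min) >= -log10(hit_p),
             stringsAsFactors = FALSE)
}

#' Motif-disruption enrichment of case SNPs over controls
#'
#' Per motif: the ratio of mean absolute binding-score differentials
#' (case over control) and a two-sided Wilcoxon rank-sum P value. Motifs
#' passing both the fold and the P filter are returned, ordered by ratio.
#' Motifs with fewer than `min_case` scored case SNPs are excluded with a
#' warning.
#'
#' @param case,control data.frames with `motif_id` and `differential`
#'   (signed; absolute values are compared by default).
#' @param fold_min,p_max filters (defaults 1.5 and 0.05).
#' @param min_case minimum scored case SNPs per motif (default 5).
#' @param use_abs compare absolute differentials (default) or signed.
#' @return data.frame `motif_id`, `n_case`, `n_control`, `ratio`, `p`,
#'   ordered by decreasing ratio; the unfiltered table is attached as
#'   attribute `"all"`.
#' @export
motif_enrichment <- function(case, control, fold_min = 1.5, p_max = 0.05,
                             min_case = 5, use_abs = TRUE) {
  f <- if (use_abs) abs else identity
  motifs <- unique(case$motif_id)
  rows <- lapply(motifs, function(m) {
    cd <- f(case$differential[case$motif_id == m])
    xd <- f(control$differential[control$motif_id == m])
    if (length(cd) < min_case) {
      warning("motif ", m, ": fewer than ", min_case,
              " scored case SNPs; excluded")
      return(NULL)
    }
    if (!length(xd)) {
      warning("motif ", m, ": no control differentials; excluded")
      return(NULL)
    }
    p <- suppressWarnings(wilcox.test(cd, xd)$p.value)
    data.frame(motif_id = m, n_case = length(cd), n_control = length(xd),
               ratio = mean(cd) / mean(xd), p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(motif_id = character(0),
                                      n_case = integer(0),
                                      n_control = integer(0),
                                      ratio = numeric(0), p = numeric(0))
  pass <- tab[tab$ratio >= fold_min & tab$p < p_max, , drop = FALSE]
  pass <- pass[order(-pass$ratio), , drop = FALSE]
  attr(pass, "all") <- tab
  pass
}

#' Fraction of SNPs overlapping interval sets
#'
#' For each interval set (e.g. one DNase-footprint BED per cell type) and
#' for the pooled union: the fraction of SNPs whose +/- `flank` bp window
#' intersects at least one interval. BED files are converted from 0-based
#' half-open to 1-based inclusive on import; unsorted input is fine.
#'
#' @param snps a [genotype_matrix()] or data.frame with `chrom`, `pos`.
#' @param intervals named list of BED file paths or `GRanges` objects.
#' @param flank window half-width in bp (default 25).
#' @return named numeric vector of fractions, one per set plus `"pooled"`.
#' @export
footprint_fraction <- function(snps, intervals, flank = 25) {
  if (inherits(snps, "genotype_matrix")) snps <- snps$snp_info
  if (!nrow(snps)) stop("zero SNPs supplied")
  win <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(pmax(1L, snps$pos - flank),
                                 snps$pos + flank))
  if (inherits(intervals, "GRanges")) intervals <- list(set1 = intervals)
  grl <- lapply(intervals, function(iv) {
    if (is.character(iv)) rtracklayer::import(iv, format = "BED") else iv
  })
  frac <- vapply(grl, function(gr)
    mean(IRanges::overlapsAny(win, gr)), numeric(1))
  pooled <- mean(IRanges::overlapsAny(
    win, do.call(c, unname(lapply(grl, GenomicRanges::granges)))))
  c(frac, pooled = pooled)
}

#' Allelic imbalance at heterozygous SNPs
#'
#' From per-allele read counts: the read-count difference, the absolute
#' log-ratio with a +1 pseudo-count, and the max/min fold ratio.
#' Heterozygosity is called from the reads themselves: the minor allele
#' must carry at least `min_reads` reads and at least `min_frac` of the
#' total; other SNPs are retained but flagged `het = FALSE` (homozygous
#' evidence). SNPs with zero total reads are dropped.
#'
#' @param counts data.frame `snp_id`, `ref_count`, `alt_count`.
#' @param min_frac,min_reads heterozygosity call thresholds (defaults 0.02
#'   and 2).
#' @return data.frame with `het`, `difference` (ref - alt),
#'   `abs_log_ratio`, `fold`.
#' @export
allelic_imbalance <- function(counts, min_frac = 0.02, min_reads = 2) {
  tot <- counts$ref_count + counts$alt_count
  counts <- counts[tot > 0, , drop = FALSE]
  tot <- tot[tot > 0]
  lo <- pmin(counts$ref_count, counts$alt_count)
  hi <- pmax(counts$ref_count, counts$alt_count)
  data.frame(counts,
             het = lo >= min_reads & lo / tot >= min_frac,
             difference = counts$ref_count - counts$alt_count,
             abs_log_ratio = abs(log((counts$ref_count + 1) /
                                       (counts$alt_count + 1))),
             fold = ifelse(lo > 0, hi / lo, Inf))
}

#' Per-motif enrichment score of disruption differentials
#'
#' Ratio of mean absolute motif-disruption scores between a SNP set and a
#' presumed-background set, per motif — the `c` statistic entering
#' [causal_fraction()].
#' @inheritParams motif_enrichment
#' @export
disruption_enrichment <- function(case, control, use_abs = TRUE) {
  f <- if (use_abs) abs else identity
  motifs <- unique(case$motif_id)
  setNames(vapply(motifs, function(m) {
    mean(f(case$differential[case$motif_id == m])) /
      mean(f(control$differential[control$motif_id == m]))
  }, numeric(1)), motifs)
}

#' High-confidence causal reference SNPs by association gap
#'
#' Selects, per gene, the best-associated SNP when (i) its BH-adjusted P is
#' below `fdr` and (ii) the -log10 P gap to the second-best SNP exceeds
#' `gap` (conservatively 2.5).
#' @param assoc data.frame `gene_id`, `snp_id`, `p`.
#' @param fdr significance threshold on the best SNP (default 1e-6).
#' @param gap minimum -log10 P gap (default 2.5).
#' @return character vector of reference-causal SNP ids.
#' @export
select_causal_reference <- function(assoc, fdr = 1e-6, gap = 2.5) {
  assoc$p_adj <- p.adjust(assoc$p, method = "BH")
  unlist(lapply(split(assoc, assoc$gene_id), function(d) {
    if (nrow(d) < 2) return(character(0))
    d <- d[order(d$p), ]
    if (d$p_adj[1] <= fdr &&
        (-log10(d$p[1])) - (-log10(d$p[2])) > gap) d$snp_id[1]
    else character(0)
  }), use.names = FALSE)
}

#' Estimated fraction of called SNPs that are causal
#'
#' Excess-enrichment estimator: for each motif y preferentially disrupted
#' by reference-causal SNPs, `(c_case,y - 1) / (c_ref,y - 1)` clipped to
#' \[0, 1\], where `c` is the motif's disruption enrichment over background
#' ([disruption_enrichment()]); the mean over motifs is the headline
#' estimate. Motifs whose reference enrichment is <= 1 carry no signal and
#' are excluded.
#'
#' @param c_case named per-motif enrichment of the called (e.g. eeSNP) set.
#' @param c_ref named per-motif enrichment of the reference-causal set.
#' @return list `per_motif` (named fractions) and `mean`.
#' @export
causal_fraction <- function(c_case, c_ref) {
  stopifnot(all(c_case > 0), all(c_ref > 0))
  motifs <- intersect(names(c_case), names(c_ref))
  if (!length(motifs)) stop("no shared motifs between case and reference")
  drop <- motifs[c_ref[motifs] <= 1]
  if (length(drop)) {
    warning("excluding motif(s) with reference enrichment <= 1: ",
            paste(drop, collapse = ", "))
    motifs <- setdiff(motifs, drop)
  }
  if (!length(motifs)) stop("no motif with reference enrichment > 1")
  frac <- pmin(pmax((c_case[motifs] - 1) / (c_ref[motifs] - 1), 0), 1)
  list(per_motif = frac, mean = mean(frac))
}

#' Read FASTA sequence windows
#' @param path FASTA file of SNP-centered windows.
#' @return named character vector of sequences.
#' @export
read_fasta_windows <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}
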