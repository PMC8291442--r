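#' Per-gene methylation levels for a named gene set across samples
#'
#' Applies [element_ml()] per gene and sample over either the promoter
#' window or the genic region. The genic region is the gene body minus the
#' promoter window, so promoter signal cannot dilute gene-body contrasts.
#' Missing values (too few covered CpGs) propagate as NA.
#'
#' @param samples named list of `MethylomeTable`s (names become the
#'   `sample` column; unnamed lists fall back to each table's stage)
#' @param annotation an `AnnotationSet` with `gene_sets`
#' @param set_name which gene set to score
#' @param region `"promoter"` or `"genic"`
#' @param min_cpgs,min_cov see [element_ml()]
#' @return data.table of class `GeneSetMLTable`: set_name, cluster,
#'   gene_id, sample, region, n_cpgs, ml
#' @export
gene_set_ml <- function(samples, annotation, set_name,
                        region = c("promoter", "genic"),
                        min_cpgs = 3L, min_cov = 5L) {
  region <- match.arg(region)
  if (is.null(annotation$gene_sets) ||
      !set_name %in% annotation$gene_sets$set_name)
    stop("unknown gene set '", set_name, "'")
  keep <- annotation$gene_sets$set_name == set_name
  members <- annotation$gene_sets[which(keep)]
  iv <- gene_region_intervals(annotation, region)[gene_id %in% members$gene_id]
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, function(s)
      if (is.na(s$stage)) s$sample_id else s$stage, character(1))
  res <- lapply(names(samples), function(s) {
    em <- element_ml(samples[[s]], iv, min_cpgs = min_cpgs, min_cov = min_cov)
    em[, sample := s]
    em
  })
  out <- data.table::rbindlist(res)
  out <- merge(out, members[, .(gene_id, cluster)], by = "gene_id")
  out[, `:=`(set_name = set_name, region = region)]
  data.table::setcolorder(out, c("set_name", "cluster", "gene_id", "sample",
                                 "region", "n_cpgs"))
  data.table::setnames(out, "mean_ml", "ml")
  data.table::setattr(out, "class", c("GeneSetMLTable", class(out)))
  out[]
}

#' Promoter or promoter-excluded genic intervals for all genes
#'
#' @param annotation an `AnnotationSet`
#' @param region `"promoter"` or `"genic"` (gene body minus promoter
#'   window; empty remainders are dropped)
#' @return data.table(gene_id, chrom, start, end)
#' @export
gene_region_intervals <- function(annotation, region = c("promoter", "genic")) {
  region <- match.arg(region)
  if (region == "promoter")
    return(annotation$promoters[, .(gene_id, chrom, start, end)])
  g <- merge(annotation$genes[, .(gene_id, chrom, start, end)],
             annotation$promoters[, .(gene_id, pstart = start, pend = end)],
             by = "gene_id")
  # subtract the promoter window from the gene body; keep the larger
  # remaining piece (promoters sit at the gene edge, so at most one piece
  # is non-trivial)
  left <- g[, .(gene_id, chrom, start, end = pmin(end, pmax(start, pstart)))]
  right <- g[, .(gene_id, chrom, start = pmax(start, pmin(end, pend)), end)]
  both <- data.table::rbindlist(list(left, right))[end > start]
  both[, len := end - start]
  out <- both[order(-len), .SD[1], by = "gene_id"][, .(gene_id, chrom, start, end)]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Paired Wilcoxon signed-rank test on promoter MLs
#'
#' Two-sided paired test of per-gene MLs between two conditions (e.g.
#' embryo vs placenta). Zero differences are dropped (classic Wilcoxon
#' convention — visible with small gene sets); the exact null distribution
#' is used for n <= 25 non-zero differences without ties in |difference|,
#' otherwise the normal approximation with continuity correction.
#'
#' @param mls_a,mls_b equal-length paired numeric vectors (NA pairs
#'   dropped)
#' @return list with `statistic` (V, sum of positive ranks), `p`,
#'   `n_used` (non-zero differences), `method`
#' @export
paired_promoter_test <- function(mls_a, mls_b) {
  stopifnot(length(mls_a) == length(mls_b))
  keep <- !(is.na(mls_a) | is.na(mls_b))
  d <- mls_a[keep] - mls_b[keep]
  d <- d[d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p = 1, n_used = 0L, method = "degenerate"))
  }
  n <- length(d)
  r <- rank(abs(d))                  # midranks under ties
  v <- sum(r[d > 0])
  if (n <= 25L && !anyDuplicated(abs(d))) {
    wt <- stats::wilcox.test(d, exact = TRUE, alternative = "two.sided")
    p <- wt$p.value
    method <- "exact"
  } else if (n <= 15L) {
    # tied |differences|: signrank tables do not apply, but the sign-flip
    # null is small enough to enumerate directly with midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_null <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(v_null <= v), mean(v_null >= v)))
    method <- "exact"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE,
                         alternative = "two.sided"))
    p <- wt$p.value
    method <- "normal approximation"
  }
  list(statistic = v, p = p, n_used = n, method = method)
}

#' Methylation-expression association for a gene set
#'
#' Per sample: Spearman rank correlation between promoter ML and
#' log-scaled expression (`log2(FPKM + 1)`), plus a 2x2 contingency
#' summary of expressed (FPKM >= `fpkm_expressed`) versus methylated
#' (ML >= `ml_methylated`) genes. In systems where promoter methylation
#' silences the set (e.g. HOX genes in placenta), rho is negative and the
#' methylated/expressed cell is depleted.
#'
#' @param ml_table a `GeneSetMLTable` (or data.table with gene_id, sample,
#'   ml)
#' @param expression data.table/data.frame with gene_id, sample, fpkm
#' @param fpkm_expressed FPKM at or above which a gene counts as expressed
#' @param ml_methylated ML at or above which a promoter counts methylated
#' @param min_genes minimum shared genes per sample
#' @return data.table: sample, n_genes, spearman_rho,
#'   n_expressed_methylated, n_expressed_unmethylated,
#'   n_silent_methylated, n_silent_unmethylated
#' @export
methylation_expression_association <- function(ml_table, expression,
                                               fpkm_expressed = 1,
                                               ml_methylated = 0.5,
                                               min_genes = 3L) {
  ml <- data.table::as.data.table(ml_table)[, .(gene_id, sample, ml)]
  ex <- data.table::as.data.table(expression)[, .(gene_id, sample, fpkm)]
  if (any(ex$fpkm < 0)) stop("FPKM values must be non-negative")
  m <- merge(ml, ex, by = c("gene_id", "sample"))
  m <- m[!is.na(ml)]
  if (nrow(m) == 0L) stop("no overlapping (gene, sample) pairs")
  out <- m[, {
    if (.N < min_genes)
      stop("sample '", .BY$sample, "' has fewer than ", min_genes,
           " genes with both ML and expression")
    lx <- log2(fpkm + 1)
    rho <- if (stats::sd(lx) == 0 || stats::sd(ml) == 0) {
      warning("constant ML or expression in sample '", .BY$sample,
              "'; rho undefined")
      NaN
    } else suppressWarnings(stats::cor(ml, lx, method = "spearman"))
    expressed <- fpkm >= fpkm_expressed
    methylated <- ml >= ml_methylated
    list(n_genes = .N, spearman_rho = rho,
         n_expressed_methylated = sum(expressed & methylated),
         n_expressed_unmethylated = sum(expressed & !methylated),
         n_silent_methylated = sum(!expressed & methylated),
         n_silent_unmethylated = sum(!expressed & !methylated))
  }, by = "sample"]
  out[]
}
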