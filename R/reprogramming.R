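#' Sperm-oocyte methylome divergence
#'
#' Two complementary summaries of how far apart the parental methylomes
#' are: the difference of global MLs (`global_delta = sperm - oocyte`) and
#' the mean absolute difference of binned MLs over bins covered in both
#' samples (`mean_abs_bin_delta`, robust to compensating shifts). Across
#' animal evolution this divergence grows from near zero in cnidarians and
#' insects to large values in vertebrates.
#'
#' @param sperm,oocyte `MethylomeTable`s on the same genome
#' @param bin_bp bin width for the binned comparison
#' @param min_cov minimum site depth
#' @param context contexts to include
#' @return list with `global_delta`, `mean_abs_bin_delta`, `n_bins`
#' @export
sperm_oocyte_divergence <- function(sperm, oocyte, bin_bp = 1000L,
                                    min_cov = 5L, context = "CG") {
  binned <- function(x) {
    ml <- site_ml(x, min_cov = min_cov, context = context)
    ml[, bin := pos %/% as.integer(bin_bp)]
    ml[, .(mean_ml = mean(ml)), by = .(chrom, bin)]
  }
  m <- merge(binned(sperm), binned(oocyte), by = c("chrom", "bin"))
  if (nrow(m) == 0L) stop("no genomic bins covered in both samples")
  gs <- global_ml(sperm, context = context, min_cov = min_cov)$site_mean
  go <- global_ml(oocyte, context = context, min_cov = min_cov)$site_mean
  list(global_delta = gs - go,
       mean_abs_bin_delta = mean(abs(m$mean_ml.x - m$mean_ml.y)),
       n_bins = nrow(m))
}

#' Call differentially methylated promoters between two samples
#'
#' Per promoter, counts are pooled across its covered CpGs into a 2x2
#' table (methylated/unmethylated reads x sample) and tested with a
#' two-sided Fisher exact test; Benjamini-Hochberg correction is applied
#' over all tested promoters. A promoter is a DMP when `q <= alpha` and
#' the ML difference `delta = ml_a - ml_b` (count-weighted promoter MLs)
#' satisfies `|delta| >= delta_min`; direction is reported as
#' `hyper_in_a` / `hypo_in_a`. Promoters lacking `min_cpgs` covered CpGs
#' in either sample are not tested.
#'
#' @param a,b `MethylomeTable`s (e.g. sperm and oocyte)
#' @param promoters promoter intervals (an `AnnotationSet` or a table with
#'   gene_id, chrom, start, end)
#' @param min_cov minimum site depth
#' @param min_cpgs minimum covered CpGs per promoter in each sample
#' @param delta_min minimum absolute ML difference for a call
#' @param alpha BH-adjusted significance level
#' @param context contexts to include
#' @return data.table of class `DMPResult` rows: gene_id, ml_a, ml_b,
#'   delta, n_cpgs_used, p, q, status in {hyper_in_a, hypo_in_a, ns}
#' @export
call_dmps <- function(a, b, promoters, min_cov = 5L, min_cpgs = 3L,
                      delta_min = 0.2, alpha = 0.05, context = "CG") {
  prom <- if (inherits(promoters, "AnnotationSet")) promoters$promoters else
    data.table::as.data.table(promoters)
  ctx <- context
  pooled <- function(x) {
    rec <- x$records[context %in% ctx & n_total >= min_cov,
                     .(chrom, start = pos, end = pos + 1L, n_meth, n_total)]
    iv <- prom[, .(gene_id, chrom, start, end)]
    data.table::setkey(iv, chrom, start, end)
    ov <- data.table::foverlaps(rec, iv, type = "within", nomatch = NULL)
    ov[, .(n_cpgs = .N, meth = sum(n_meth), total = sum(n_total)),
       by = "gene_id"]
  }
  pa <- pooled(a); pb <- pooled(b)
  tab <- merge(pa, pb, by = "gene_id", suffixes = c("_a", "_b"))
  tab <- tab[n_cpgs_a >= min_cpgs & n_cpgs_b >= min_cpgs]
  if (nrow(tab) == 0L)
    stop("no promoter with >= ", min_cpgs, " covered CpGs in both samples")
  tab[, `:=`(ml_a = meth_a / total_a, ml_b = meth_b / total_b)]
  tab[, delta := ml_a - ml_b]
  tab[, p := vapply(seq_len(.N), function(i)
    stats::fisher.test(matrix(c(meth_a[i], total_a[i] - meth_a[i],
                                meth_b[i], total_b[i] - meth_b[i]),
                              nrow = 2L))$p.value, numeric(1))]
  tab[, q := stats::p.adjust(p, method = "BH")]
  tab[, status := data.table::fifelse(
    q <= alpha & delta >= delta_min, "hyper_in_a",
    data.table::fifelse(q <= alpha & delta <= -delta_min, "hypo_in_a", "ns"))]
  out <- tab[, .(gene_id, ml_a, ml_b, delta,
                 n_cpgs_used = pmin(n_cpgs_a, n_cpgs_b), p, q, status)]
  data.table::setattr(out, "class", c("DMPResult", class(out)))
  out[]
}

#' Classify stage-trajectory methylation dynamics
#'
#' The dynamics statistic is `D = max - min` of the per-stage global MLs
#' (the maximum pairwise absolute difference). Classes operationalize the
#' qualitative labels used for animal clades: `none` (D < 0.02), `minor`
#' (D < 0.05), `moderate` (D < 0.15), else `dramatic`. The genome-wide
#' demethylation flag is raised when any embryonic (non-gamete) stage ML
#' falls below half the gamete mean.
#'
#' @param stage_ml named numeric vector of per-stage global MLs, in
#'   developmental order; must include the gamete stages.
#' @param gametes names of the gamete stages within `stage_ml`
#' @param thresholds class cutoffs (upper bounds for none/minor/moderate)
#' @return object of class `ReprogrammingSummary`: list with `stages`,
#'   `stage_ml`, `max_delta`, `divergence` (first minus second gamete),
#'   `dynamics_class`, `demethylation_flag`.
#' @export
classify_dynamics <- function(stage_ml, gametes = c("sperm", "oocyte"),
                              thresholds = c(none = 0.02, minor = 0.05,
                                             moderate = 0.15)) {
  if (length(stage_ml) < 2L) {
    warning("need >= 2 stages; dynamics class undefined")
    return(structure(list(stages = names(stage_ml), stage_ml = stage_ml,
                          max_delta = NA_real_, divergence = NA_real_,
                          dynamics_class = NA_character_,
                          demethylation_flag = NA),
                     class = "ReprogrammingSummary"))
  }
  stopifnot(!is.null(names(stage_ml)), all(gametes %in% names(stage_ml)))
  D <- max(stage_ml) - min(stage_ml)
  cls <- if (D < thresholds[["none"]]) "none"
  else if (D < thresholds[["minor"]]) "minor"
  else if (D < thresholds[["moderate"]]) "moderate"
  else "dramatic"
  embryo <- stage_ml[setdiff(names(stage_ml), gametes)]
  gmean <- mean(stage_ml[gametes])
  flag <- length(embryo) > 0L && any(embryo < 0.5 * gmean)
  structure(list(stages = names(stage_ml), stage_ml = stage_ml,
                 max_delta = D,
                 divergence = unname(stage_ml[gametes[1]] - stage_ml[gametes[2]]),
                 dynamics_class = cls, demethylation_flag = flag),
            class = "ReprogrammingSummary")
}

#' @export
print.ReprogrammingSummary <- function(x, ...) {
  cat("ReprogrammingSummary:",
      paste(sprintf("%s=%.3f", x$stages, x$stage_ml), collapse = " "), "\n")
  cat(sprintf("  max |delta| = %.3f -> class '%s'; demethylation flag: %s\n",
              x$max_delta, x$dynamics_class, x$demethylation_flag))
  invisible(x)
}

#' Promoter-by-sample ML matrix for DMP heatmaps
#'
#' Rows are DMP promoters ordered by descending `delta`; columns are the
#' supplied samples; cells are count-weighted promoter MLs (NA where a
#' promoter lacks covered CpGs in a sample).
#'
#' @param samples named list of `MethylomeTable`s
#' @param dmps a `DMPResult` table (typically filtered to `status != "ns"`)
#' @param promoters promoter intervals (an `AnnotationSet` or table)
#' @param min_cov minimum site depth
#' @return numeric matrix promoters x samples, rownames = gene_id
#' @export
dmp_heatmap_matrix <- function(samples, dmps, promoters, min_cov = 5L) {
  stopifnot(nrow(dmps) > 0L)
  prom <- if (inherits(promoters, "AnnotationSet")) promoters$promoters else
    data.table::as.data.table(promoters)
  ord <- dmps[order(-delta)]
  prom <- prom[gene_id %in% ord$gene_id]
  if (is.null(names(samples)))
    names(samples) <- paste0("sample", seq_along(samples))
  mat <- matrix(NA_real_, nrow = nrow(ord), ncol = length(samples),
                dimnames = list(ord$gene_id, names(samples)))
  for (s in names(samples)) {
    rec <- samples[[s]]$records[n_total >= min_cov,
                                .(chrom, start = pos, end = pos + 1L,
                                  n_meth, n_total)]
    iv <- prom[, .(gene_id, chrom, start, end)]
    data.table::setkey(iv, chrom, start, end)
    ov <- data.table::foverlaps(rec, iv, type = "within", nomatch = NULL)
    ml <- ov[, .(ml = sum(n_meth) / sum(n_total)), by = "gene_id"]
    mat[ml$gene_id, s] <- ml$ml
  }
  mat
}
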