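#' Global methylation level of a sample
#'
#' The default (`site_mean`) is the arithmetic mean of per-site MLs
#' (`n_meth / n_total`) over sites passing the coverage filter; the
#' read-weighted alternative (`count_weighted`, pooled
#' `sum(n_meth) / sum(n_total)`) is computed alongside. Both agree exactly
#' when coverage is uniform.
#'
#' @param x a `MethylomeTable`
#' @param context contexts to include (default CpG only)
#' @param min_cov minimum site depth
#' @param weighting which estimate goes into `global_ml`
#' @return object of class `GlobalSummary`: list with `sample_id`,
#'   `context`, `n_sites_used`, `global_ml`, `weighting`, plus both
#'   `site_mean` and `count_weighted` values.
#' @export
global_ml <- function(x, context = "CG", min_cov = 5L,
                      weighting = c("site_mean", "count_weighted")) {
  weighting <- match.arg(weighting)
  ctx <- context
  rec <- x$records[context %in% ctx & n_total >= min_cov]
  if (nrow(rec) == 0L)
    stop("no sites retained after filtering (context in {",
         paste(ctx, collapse = ","), "}, min_cov = ", min_cov, ")")
  site_mean <- mean(rec$n_meth / rec$n_total)
  count_weighted <- sum(rec$n_meth) / sum(rec$n_total)
  structure(list(sample_id = x$sample_id, context = ctx,
                 n_sites_used = nrow(rec),
                 global_ml = if (weighting == "site_mean") site_mean else count_weighted,
                 weighting = weighting, site_mean = site_mean,
                 count_weighted = count_weighted),
            class = "GlobalSummary")
}

#' @export
print.GlobalSummary <- function(x, ...) {
  cat(sprintf("GlobalSummary '%s' [%s]: global ML = %.4f (%s; site_mean %.4f, count_weighted %.4f; %d sites)\n",
              x$sample_id, paste(x$context, collapse = ","), x$global_ml,
              x$weighting, x$site_mean, x$count_weighted, x$n_sites_used))
  invisible(x)
}

#' Bisulfite conversion rate from an unmethylated control
#'
#' Every site on the control (e.g. a lambda spike-in contig) is truly
#' unmethylated, so the conversion rate is the pooled fraction of reads
#' reporting unmethylated: `sum(n_total - n_meth) / sum(n_total)`. Its
#' complement is the non-conversion rate used to correct non-CpG levels.
#'
#' @param control a `MethylomeTable` of control sites
#' @return conversion rate in \[0, 1\]
#' @export
conversion_rate <- function(control) {
  tot <- sum(as.numeric(control$records$n_total))
  if (tot == 0) stop("control contig has zero total coverage")
  1 - sum(as.numeric(control$records$n_meth)) / tot
}

#' Non-CpG methylation level corrected for bisulfite non-conversion
#'
#' Raw non-CpG (CHG/CHH) levels are inflated by conversion failures; the
#' corrected level subtracts the non-conversion rate from the raw mean ML
#' and floors at zero: `max(0, raw - (1 - conv_rate))`.
#'
#' @param x a `MethylomeTable` (only CHG/CHH records are used)
#' @param conv_rate bisulfite conversion rate in \[0, 1\]
#' @param min_cov minimum site depth
#' @return corrected non-CpG ML, a non-negative fraction
#' @export
corrected_noncpg_ml <- function(x, conv_rate, min_cov = 5L) {
  stopifnot(conv_rate >= 0, conv_rate <= 1)
  raw <- global_ml(x, context = c("CHG", "CHH"), min_cov = min_cov)$site_mean
  max(0, raw - (1 - conv_rate))
}

#' Distribution of per-site methylation levels
#'
#' Normalized histogram over fixed bins of width 0.1 plus the bimodality
#' index: the fraction of sites that are essentially unmethylated
#' (ML <= 0.2) or essentially fully methylated (ML >= 0.8). Animal CpG
#' methylomes are bimodal, so this index is close to 1.
#'
#' @param x a `MethylomeTable`
#' @param min_cov minimum site depth
#' @param context contexts to include
#' @return object of class `DistributionSummary`: list with `breaks`,
#'   `density` (sums to 1), `frac_low`, `frac_high`, `bimodality`,
#'   `n_sites`.
#' @export
ml_distribution <- function(x, min_cov = 5L, context = "CG") {
  ml <- site_ml(x, min_cov = min_cov, context = context)$ml
  if (length(ml) == 0L) stop("no sites retained for ML distribution")
  breaks <- seq(0, 1, by = 0.1)
  h <- hist(ml, breaks = breaks, include.lowest = TRUE, right = TRUE,
            plot = FALSE)
  structure(list(breaks = breaks, density = h$counts / length(ml),
                 frac_low = mean(ml <= 0.2), frac_high = mean(ml >= 0.8),
                 bimodality = mean(ml <= 0.2) + mean(ml >= 0.8),
                 n_sites = length(ml)),
            class = "DistributionSummary")
}

#' CpG density vs methylation across genomic windows
#'
#' Tiles each chromosome into non-overlapping windows of `window_bp`,
#' scores windows with at least `min_sites` covered CpGs by their covered
#' CpG count (density) and mean ML, and reports the Pearson correlation
#' between the two. In CGI-bearing genomes this correlation is negative
#' (dense islands are unmethylated).
#'
#' @param x a `MethylomeTable`
#' @param window_bp window size (>= 100)
#' @param min_cov minimum site depth
#' @param min_sites minimum covered CpGs per scored window
#' @return list with `windows` (data.table chrom, window_start, n_sites,
#'   mean_ml) and `pearson_r`
#' @export
density_ml_relationship <- function(x, window_bp = 1000L, min_cov = 5L,
                                    min_sites = 3L) {
  stopifnot(window_bp >= 100)
  ml <- site_ml(x, min_cov = min_cov, context = "CG")
  ml[, window_start := (pos %/% as.integer(window_bp)) * as.integer(window_bp)]
  win <- ml[, .(n_sites = .N, mean_ml = mean(ml)), by = .(chrom, window_start)]
  win <- win[n_sites >= min_sites]
  if (nrow(win) < 2L)
    stop("fewer than 2 windows with >= ", min_sites, " covered CpGs")
  r <- if (stats::sd(win$n_sites) == 0 || stats::sd(win$mean_ml) == 0) {
    warning("density or ML constant across windows; correlation undefined")
    NaN
  } else stats::cor(win$n_sites, win$mean_ml)
  list(windows = win[], pearson_r = r)
}

#' Pearson correlation of binned MLs between two samples
#'
#' Mean per-site ML per `bin_bp` bin in each table, over bins covered in
#' both; used to quantify replicate agreement.
#'
#' @param a,b `MethylomeTable`s on the same genome
#' @param bin_bp bin width in bp
#' @param min_cov minimum site depth
#' @param context contexts to include
#' @return Pearson r
#' @export
replicate_correlation <- function(a, b, bin_bp = 1000L, min_cov = 5L,
                                  context = "CG") {
  binned <- function(x) {
    ml <- site_ml(x, min_cov = min_cov, context = context)
    ml[, bin := pos %/% as.integer(bin_bp)]
    ml[, .(mean_ml = mean(ml)), by = .(chrom, bin)]
  }
  m <- merge(binned(a), binned(b), by = c("chrom", "bin"))
  if (nrow(m) == 0L) stop("no genomic bins covered in both samples")
  stats::cor(m$mean_ml.x, m$mean_ml.y)
}
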