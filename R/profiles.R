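#' Strand-oriented methylation metaprofile around TSSs
#'
#' Maps every covered CpG within `flank_bp` of a TSS to a signed,
#' strand-oriented offset (`pos - tss` for + strand genes, `tss - pos` for
#' - strand genes), bins offsets into `bin_bp` windows (bin k covers
#' `[-flank + k*bin, -flank + (k+1)*bin)`), and averages MLs over all
#' (gene, site) pairs per bin. With the defaults this is the classic
#' 120-bin, 100-bp, +/- 6 kb TSS metaplot; vertebrate-style genomes show a
#' hypomethylation dip at the central bins (CGI promoters).
#'
#' @param x a `MethylomeTable`
#' @param annotation an `AnnotationSet` (or gene table with tss, strand)
#' @param flank_bp half-width of the window around the TSS
#' @param bin_bp bin width; must divide `flank_bp`
#' @param min_cov minimum site depth
#' @param context contexts to include
#' @return object of class `BinProfile`: data.table with `bin`,
#'   `offset_start`, `offset_end`, `mean_ml` (NA where no sites) and
#'   `n_sites`, one row per bin.
#' @export
tss_metaprofile <- function(x, annotation, flank_bp = 6000L, bin_bp = 100L,
                            min_cov = 5L, context = "CG") {
  stopifnot(flank_bp %% bin_bp == 0)
  genes <- if (inherits(annotation, "AnnotationSet")) annotation$genes else
    data.table::as.data.table(annotation)
  n_bins <- as.integer(2L * flank_bp / bin_bp)
  ml <- site_ml(x, min_cov = min_cov, context = context)
  ml[, `:=`(start = pos, end = pos + 1L)]
  win <- genes[, .(gene_id, chrom, start = pmax(0L, tss - as.integer(flank_bp) - 1L),
                   end = tss + as.integer(flank_bp) + 1L, tss, gstrand = strand)]
  data.table::setkey(win, chrom, start, end)
  ov <- data.table::foverlaps(ml, win, type = "within", nomatch = NULL)
  if (nrow(ov) > 0L) {
    ov[, offset := data.table::fifelse(gstrand == "+", pos - tss, tss - pos)]
    ov <- ov[offset >= -flank_bp & offset < flank_bp]
  }
  if (nrow(ov) == 0L)
    stop("no covered CpGs within ", flank_bp, " bp of any TSS")
  ov[, bin := (offset + as.integer(flank_bp)) %/% as.integer(bin_bp)]
  agg <- ov[, .(mean_ml = mean(ml), n_sites = .N), by = "bin"]
  prof <- data.table::data.table(bin = 0:(n_bins - 1L))
  prof[, `:=`(offset_start = -as.integer(flank_bp) + bin * as.integer(bin_bp),
              offset_end = -as.integer(flank_bp) + (bin + 1L) * as.integer(bin_bp))]
  prof <- merge(prof, agg, by = "bin", all.x = TRUE)
  prof[is.na(n_sites), n_sites := 0L]
  data.table::setattr(prof, "class", c("BinProfile", class(prof)))
  data.table::setattr(prof, "flank_bp", flank_bp)
  data.table::setattr(prof, "bin_bp", bin_bp)
  prof[]
}

#' Mean methylation level per interval
#'
#' Mean of per-site MLs over covered CpGs inside each interval; intervals
#' with fewer than `min_cpgs` covered CpGs get `NA` (flagged missing
#' rather than estimated from too little data).
#'
#' @param x a `MethylomeTable`
#' @param intervals data.table/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) and an id column (first non-coordinate column is
#'   used, typically `gene_id`).
#' @param min_cpgs minimum covered CpGs to score an interval
#' @param min_cov minimum site depth
#' @param context contexts to include
#' @return data.table: id column, `n_cpgs`, `mean_ml` (NA if below
#'   `min_cpgs`), one row per input interval, input order preserved.
#' @export
element_ml <- function(x, intervals, min_cpgs = 3L, min_cov = 5L,
                       context = "CG") {
  iv <- data.table::as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  idcol <- setdiff(names(iv), c("chrom", "start", "end", "strand"))[1]
  ids <- if (is.na(idcol)) seq_len(nrow(iv)) else iv[[idcol]]
  if (is.na(idcol)) idcol <- "interval_id"
  iv2 <- data.table::data.table(.id = ids, chrom = iv$chrom,
                                start = iv$start, end = iv$end)
  iv2[, `:=`(start = as.integer(start), end = as.integer(end))]
  ml <- site_ml(x, min_cov = min_cov, context = context)
  ml[, `:=`(start = pos, end = pos + 1L)]
  data.table::setkey(iv2, chrom, start, end)
  ov <- data.table::foverlaps(ml, iv2, type = "within", nomatch = NULL)
  agg <- ov[, .(n_cpgs = .N, mean_ml = mean(ml)), by = ".id"]
  out <- merge(data.table::data.table(.id = ids), agg, by = ".id",
               all.x = TRUE, sort = FALSE)
  out[is.na(n_cpgs), n_cpgs := 0L]
  out[n_cpgs < min_cpgs, mean_ml := NA_real_]
  data.table::setnames(out, ".id", idcol)
  out[]
}

#' Segment a methylome into methylated and unmethylated domains
#'
#' Deterministic segmentation of the mosaic architecture: per-site MLs are
#' smoothed with a centered running mean over `smooth_w` CpGs (partial
#' windows at chromosome edges), each site gets a binary state
#' (smoothed ML >= `state_threshold`), maximal runs of constant state
#' become candidate domains, and runs shorter than `min_cpgs_per_domain`
#' are absorbed into the longer flanking run (ties prefer the preceding
#' run). Domain coordinates span the first to last CpG of the run
#' (half-open); `mean_ml` is the mean of the raw (unsmoothed) site MLs, so
#' the CpG-weighted mean over domains equals the global site-mean ML.
#'
#' A chromosome with fewer covered CpGs than `smooth_w` is emitted as a
#' single domain with a warning.
#'
#' @param x a `MethylomeTable`
#' @param smooth_w running-mean window, in CpGs (odd recommended)
#' @param state_threshold smoothed ML at or above which a site is called
#'   methylated
#' @param min_cpgs_per_domain minimum CpGs for a domain to stand alone
#' @param min_cov minimum site depth
#' @param context contexts to include
#' @return data.table of domains: chrom, start, end, state
#'   ("methylated"/"unmethylated"), n_cpgs, mean_ml; non-overlapping and
#'   sorted. Attribute `site_states` carries the per-site state calls
#'   (data.table chrom, pos, state) for truth-recovery checks.
#' @export
segment_domains <- function(x, smooth_w = 5L, state_threshold = 0.5,
                            min_cpgs_per_domain = 5L, min_cov = 5L,
                            context = "CG") {
  ml <- site_ml(x, min_cov = min_cov, context = context)
  if (nrow(ml) == 0L) stop("no covered CpGs to segment")
  out <- list(); states <- list()
  for (chr in unique(ml$chrom)) {
    v <- ml[chrom == chr]
    res <- .segment_chrom(v$pos, v$ml, smooth_w, state_threshold,
                          min_cpgs_per_domain, chr)
    out[[chr]] <- res$domains
    states[[chr]] <- res$site_states
  }
  dom <- data.table::rbindlist(out)
  data.table::setorder(dom, chrom, start)
  data.table::setattr(dom, "site_states", data.table::rbindlist(states))
  dom[]
}

.segment_chrom <- function(pos, ml, smooth_w, state_threshold, min_len, chr) {
  n <- length(pos)
  if (n < smooth_w) {
    warning("chromosome ", chr, " has fewer CpGs (", n, ") than smooth_w (",
            smooth_w, "); emitted as a single domain")
    st <- mean(ml) >= state_threshold
    return(list(
      domains = data.table::data.table(
        chrom = chr, start = pos[1], end = pos[n] + 1L,
        state = if (st) "methylated" else "unmethylated",
        n_cpgs = n, mean_ml = mean(ml)),
      site_states = data.table::data.table(chrom = chr, pos = pos,
                                           state = rep(st, n))))
  }
  # centered running mean with shrinking windows at the edges
  h <- (smooth_w - 1L) %/% 2L
  cs <- c(0, cumsum(ml))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  state <- smoothed >= state_threshold

  r <- rle(state)
  # absorb runs shorter than min_len into the longer flanking run
  repeat {
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) break
    i <- short[1]
    if (i == 1L) {
      r$values[i] <- r$values[i + 1L]
    } else if (i == length(r$lengths)) {
      r$values[i] <- r$values[i - 1L]
    } else {
      # ties prefer the preceding run
      take_prev <- r$lengths[i - 1L] >= r$lengths[i + 1L]
      r$values[i] <- if (take_prev) r$values[i - 1L] else r$values[i + 1L]
    }
    merged <- rle(inverse.rle(r))
    r <- merged
  }
  state_final <- inverse.rle(r)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  dom <- data.table::data.table(
    chrom = chr,
    start = pos[starts], end = pos[ends] + 1L,
    state = ifelse(r$values, "methylated", "unmethylated"),
    n_cpgs = r$lengths,
    mean_ml = vapply(seq_along(starts), function(i)
      mean(ml[starts[i]:ends[i]]), numeric(1)))
  list(domains = dom,
       site_states = data.table::data.table(chrom = chr, pos = pos,
                                            state = state_final))
}

#' Classify promoters by CpG density
#'
#' Density = CpG count per promoter bp; promoters are split into low /
#' intermediate / high classes at the `low_q` and `high_q` quantiles of
#' the dataset's densities. Ties at the quantile cutoffs resolve downward
#' into the intermediate class (strict inequalities), so an all-equal
#' dataset is entirely intermediate.
#'
#' @param annotation an `AnnotationSet` (promoters used) or promoter table
#' @param cpg_positions data.table/data.frame with `chrom`, `pos` of all
#'   CpGs (coverage-independent; this is a sequence property)
#' @param low_q,high_q quantile cutoffs
#' @return data.table: gene_id, n_cpgs, width, density (CpG per bp),
#'   class in {low, intermediate, high}
#' @export
promoter_density_classes <- function(annotation, cpg_positions,
                                     low_q = 0.25, high_q = 0.75) {
  prom <- if (inherits(annotation, "AnnotationSet")) annotation$promoters else
    data.table::as.data.table(annotation)
  cp <- data.table::as.data.table(cpg_positions)
  cp <- cp[, .(chrom = as.character(chrom), start = as.integer(pos),
               end = as.integer(pos) + 1L)]
  iv <- prom[, .(gene_id, chrom, start, end)]
  data.table::setkey(iv, chrom, start, end)
  ov <- data.table::foverlaps(cp, iv, type = "within", nomatch = NULL)
  cnt <- ov[, .(n_cpgs = .N), by = "gene_id"]
  out <- merge(prom[, .(gene_id, width = end - start)], cnt, by = "gene_id",
               all.x = TRUE)
  out[is.na(n_cpgs), n_cpgs := 0L]
  out[, density := n_cpgs / width]
  qs <- stats::quantile(out$density, c(low_q, high_q), names = FALSE)
  out[, class := data.table::fifelse(density < qs[1], "low",
               data.table::fifelse(density > qs[2], "high", "intermediate"))]
  out[]
}
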