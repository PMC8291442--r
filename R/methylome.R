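#' Per-CpG methylome call table
#'
#' The central container: one WGBS sample (one species, one developmental
#' stage) as a table of per-cytosine counts. Coordinates are 0-based
#' throughout the package; positions on disk are converted at the I/O
#' boundary. The methylation level (ML) of a site is `n_meth / n_total`.
#'
#' @param records data.frame with columns `chrom` (character), `pos`
#'   (integer, 0-based), `strand` (`"+"`, `"-"` or `"*"`), `context`
#'   (`"CG"`, `"CHG"` or `"CHH"`), `n_meth`, `n_total` (non-negative
#'   integers, `n_meth <= n_total`).
#' @param sample_id,species,stage sample metadata strings; `stage` is a
#'   developmental stage label such as `"sperm"`, `"oocyte"`, `"blastula"`.
#' @param conversion_rate optional bisulfite conversion rate in \[0, 1\].
#' @param sort sort records by (chrom, pos)? Records must end up sorted.
#'
#' @return An object of class `MethylomeTable`: a list with `records`
#'   (a `data.table`) and the metadata fields.
#' @export
methylome_table <- function(records, sample_id = "sample", species = NA_character_,
                            stage = NA_character_, conversion_rate = NA_real_,
                            sort = TRUE) {
  rec <- data.table::as.data.table(records)
  required <- c("chrom", "pos", "strand", "context", "n_meth", "n_total")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0L)
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  rec <- rec[, required, with = FALSE]
  rec[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
             strand = as.character(strand), context = as.character(context),
             n_meth = as.integer(n_meth), n_total = as.integer(n_total))]
  if (sort) data.table::setorder(rec, chrom, pos)
  obj <- structure(
    list(records = rec, sample_id = sample_id, species = species,
         stage = stage, conversion_rate = conversion_rate),
    class = "MethylomeTable")
  validate_methylome_table(obj)
  obj
}

#' Validate MethylomeTable invariants
#'
#' Checks counts (`0 <= n_meth <= n_total`), context labels, uniqueness of
#' (chrom, pos, strand) and sort order. Called by the constructor; exported
#' so readers and simulators can re-check after manipulation.
#'
#' @param x a `MethylomeTable`
#' @return `x`, invisibly; stops on violation.
#' @export
validate_methylome_table <- function(x) {
  rec <- x$records
  if (nrow(rec) == 0L) return(invisible(x))
  if (anyNA(rec$n_meth) || anyNA(rec$n_total) || any(rec$n_meth < 0L) ||
      any(rec$n_total < 0L) || any(rec$n_meth > rec$n_total))
    stop("invalid counts: need 0 <= n_meth <= n_total at every site")
  if (!all(rec$context %in% c("CG", "CHG", "CHH")))
    stop("context must be one of CG, CHG, CHH")
  if (anyDuplicated(rec, by = c("chrom", "pos", "strand")))
    stop("duplicate (chrom, pos, strand) records")
  if (is.unsorted(order(rec$chrom, rec$pos)))
    stop("records must be sorted by (chrom, pos)")
  if (!is.na(x$conversion_rate) &&
      (x$conversion_rate < 0 || x$conversion_rate > 1))
    stop("conversion_rate must lie in [0, 1]")
  invisible(x)
}

#' @export
print.MethylomeTable <- function(x, ...) {
  cat(sprintf("MethylomeTable '%s' (%s, %s): %d sites on %d sequence(s)\n",
              x$sample_id, x$species, x$stage, nrow(x$records),
              data.table::uniqueN(x$records$chrom)))
  ctx <- x$records[, .N, by = "context"]
  cat("  contexts:", paste(sprintf("%s=%d", ctx$context, ctx$N), collapse = " "), "\n")
  invisible(x)
}

#' Number of sites in a methylome table
#' @param x a `MethylomeTable`
#' @return integer site count
#' @export
n_sites <- function(x) nrow(x$records)

#' Per-site methylation levels
#'
#' @param x a `MethylomeTable`
#' @param min_cov minimum read depth; sites below are dropped.
#' @param context contexts to keep.
#' @return data.table of chrom, pos, ml (= n_meth/n_total), n_total
#' @export
site_ml <- function(x, min_cov = 1L, context = c("CG", "CHG", "CHH")) {
  ctx <- context
  rec <- x$records[n_total >= min_cov & context %in% ctx]
  rec[, .(chrom, pos, ml = n_meth / n_total, n_total)]
}

#' Pool symmetric CpG dyads onto the plus strand
#'
#' A CpG on the + strand at position p and its complement on the - strand at
#' p + 1 interrogate the same dyad; pooling their counts doubles effective
#' coverage. Counts are summed into a single + strand record at p. Sites
#' without a partner are kept unchanged. Only CG-context records are paired;
#' other contexts pass through. Total `n_meth` and `n_total` are conserved.
#'
#' @param x a `MethylomeTable`
#' @return a `MethylomeTable` with dyads merged
#' @export
merge_cpg_dyads <- function(x) {
  rec <- data.table::copy(x$records)
  cg <- rec[context == "CG"]
  other <- rec[context != "CG"]
  plus <- cg[strand == "+"]
  minus <- cg[strand == "-"]
  unstranded <- cg[!strand %in% c("+", "-")]
  # pair - strand site at p+1 with + strand site at p
  minus[, anchor := pos - 1L]
  paired <- merge(plus[, .(chrom, pos, n_meth, n_total)],
                  minus[, .(chrom, anchor, m_meth = n_meth, m_total = n_total)],
                  by.x = c("chrom", "pos"), by.y = c("chrom", "anchor"),
                  all = TRUE)
  merged <- paired[, .(
    chrom, pos,
    strand = "+",
    context = "CG",
    n_meth = data.table::fifelse(is.na(n_meth), 0L, n_meth) +
      data.table::fifelse(is.na(m_meth), 0L, m_meth),
    n_total = data.table::fifelse(is.na(n_total), 0L, n_total) +
      data.table::fifelse(is.na(m_total), 0L, m_total))]
  # lone - strand sites (no + partner) keep their own position and strand
  lone_minus <- paired[is.na(n_total) & !is.na(m_total)]
  if (nrow(lone_minus) > 0L) {
    merged[paired[, is.na(n_total) & !is.na(m_total)],
           `:=`(pos = pos + 1L, strand = "-")]
  }
  out <- data.table::rbindlist(list(merged, unstranded, other), use.names = TRUE)
  methylome_table(out, sample_id = x$sample_id, species = x$species,
                  stage = x$stage, conversion_rate = x$conversion_rate)
}

#' Filter sites by read depth
#'
#' @param x a `MethylomeTable`
#' @param min_cov minimum `n_total` (>= 1) to retain a site.
#' @return a `MethylomeTable` with low-coverage sites removed; order kept.
#' @export
filter_by_coverage <- function(x, min_cov) {
  stopifnot(is.numeric(min_cov), min_cov >= 1)
  out <- x
  out$records <- x$records[n_total >= min_cov]
  out
}
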