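#' Read a Bismark-style cytosine report
#'
#' Tab-separated, 1-based positions, columns: chrom, position, strand,
#' count_methylated, count_unmethylated, context (an optional seventh
#' tri-nucleotide column is ignored). Positions are shifted to the package's
#' 0-based convention on the way in; zero-coverage sites are retained so
#' that coverage filtering stays an explicit, separate step.
#'
#' @param path file path
#' @param sample_id,species,stage,conversion_rate sample metadata; see
#'   [methylome_table()].
#' @return a `MethylomeTable`
#' @export
read_cytosine_report <- function(path, sample_id = basename(path),
                                 species = NA_character_, stage = NA_character_,
                                 conversion_rate = NA_real_) {
  if (file.size(path) == 0)
    return(methylome_table(empty_records(), sample_id, species, stage,
                           conversion_rate))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE,
                      colClasses = list(character = 1)),
    error = function(e) stop("failed to parse cytosine report '", path,
                             "': ", conditionMessage(e)))
  if (nrow(dt) == 0L)
    return(methylome_table(empty_records(), sample_id, species, stage,
                           conversion_rate))
  if (ncol(dt) < 6L)
    stop("cytosine report needs >= 6 columns, got ", ncol(dt))
  bad <- which(!grepl("^[0-9]+$", as.character(dt[[2]])) |
                 !grepl("^[0-9]+$", as.character(dt[[4]])) |
                 !grepl("^[0-9]+$", as.character(dt[[5]])))
  if (length(bad) > 0L)
    stop("malformed cytosine report line ", bad[1], " in '", path,
         "': non-numeric position or counts")
  n_meth <- as.integer(dt[[4]])
  n_unmeth <- as.integer(dt[[5]])
  if (any(n_meth < 0L) || any(n_unmeth < 0L))
    stop("negative counts in '", path, "'")
  rec <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    pos = as.integer(dt[[2]]) - 1L,      # 1-based on disk -> 0-based
    strand = as.character(dt[[3]]),
    context = as.character(dt[[6]]),
    n_meth = n_meth,
    n_total = n_meth + n_unmeth)
  methylome_table(rec, sample_id, species, stage, conversion_rate)
}

#' Write a Bismark-style cytosine report
#'
#' Inverse of [read_cytosine_report()]: positions go back to 1-based,
#' counts are split into methylated/unmethylated.
#'
#' @param x a `MethylomeTable`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cytosine_report <- function(x, path) {
  out <- x$records[, .(chrom, pos = pos + 1L, strand, n_meth,
                       n_unmeth = n_total - n_meth, context)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a count-bearing bedGraph methylation file
#'
#' The common 6-column dialect: chrom, 0-based start, end (= start + 1),
#' methylation percent, count_methylated, count_unmethylated. The percent
#' column is redundant with the counts and is ignored in their favour; if
#' it disagrees with the counts by more than 0.5 percentage points a
#' warning names the first offending line. Strand is not encoded in this
#' dialect and is recorded as `"*"`; context defaults to `"CG"`.
#'
#' @inheritParams read_cytosine_report
#' @param context context label to assign (the dialect does not carry one).
#' @return a `MethylomeTable`
#' @export
read_bedgraph_counts <- function(path, sample_id = basename(path),
                                 species = NA_character_, stage = NA_character_,
                                 conversion_rate = NA_real_, context = "CG") {
  if (file.size(path) == 0)
    return(methylome_table(empty_records(), sample_id, species, stage,
                           conversion_rate))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1)),
    error = function(e) stop("failed to parse bedGraph '", path, "': ",
                             conditionMessage(e)))
  if (nrow(dt) == 0L)
    return(methylome_table(empty_records(), sample_id, species, stage,
                           conversion_rate))
  if (ncol(dt) < 6L)
    stop("count bedGraph needs 6 columns, got ", ncol(dt))
  n_meth <- as.integer(dt[[5]])
  n_unmeth <- as.integer(dt[[6]])
  if (anyNA(n_meth) || anyNA(n_unmeth) || any(n_meth < 0L) || any(n_unmeth < 0L))
    stop("negative or non-numeric counts in '", path, "'")
  n_total <- n_meth + n_unmeth
  pct <- as.numeric(dt[[4]])
  pct_from_counts <- data.table::fifelse(n_total > 0L, 100 * n_meth / n_total, 0)
  off <- which(abs(pct - pct_from_counts) > 0.5)
  if (length(off) > 0L)
    warning("bedGraph '", path, "': percent column disagrees with counts on ",
            length(off), " line(s) (first at line ", off[1],
            "); counts take precedence")
  rec <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    pos = as.integer(dt[[2]]),           # already 0-based
    strand = "*",
    context = context,
    n_meth = n_meth,
    n_total = n_total)
  methylome_table(rec, sample_id, species, stage, conversion_rate)
}

#' Write the count-bearing bedGraph dialect
#'
#' @param x a `MethylomeTable`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph_counts <- function(x, path) {
  out <- x$records[, .(
    chrom, start = pos, end = pos + 1L,
    pct = data.table::fifelse(n_total > 0L, round(100 * n_meth / n_total, 6), 0),
    n_meth, n_unmeth = n_total - n_meth)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

empty_records <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         strand = character(), context = character(),
                         n_meth = integer(), n_total = integer())
}

#' Assemble an annotation set
#'
#' Bundles genes (with TSS), derived promoter intervals and named gene sets
#' into one object used by the profile, promoter and gene-cluster analyses.
#' All coordinates 0-based half-open.
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand; a `tss`
#'   column is derived if absent (start for + strand, end - 1 for - strand).
#' @param gene_sets optional data.frame (set_name, cluster, gene_id); every
#'   member must resolve to a gene_id in `genes`.
#' @param promoters optional precomputed promoter table; by default derived
#'   via [make_promoters()] with its defaults.
#' @param repeats optional repeat intervals (chrom, start, end).
#' @return an object of class `AnnotationSet`
#' @export
annotation_set <- function(genes, gene_sets = NULL, promoters = NULL,
                           repeats = NULL) {
  g <- data.table::as.data.table(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(g)))
  if (any(g$start < 0L) || any(g$start >= g$end))
    stop("gene intervals must satisfy 0 <= start < end")
  if (!all(g$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-'")
  if (!"tss" %in% names(g))
    g[, tss := data.table::fifelse(strand == "+", start, end - 1L)]
  g[, `:=`(start = as.integer(start), end = as.integer(end),
           tss = as.integer(tss))]
  data.table::setorder(g, chrom, start)
  if (!is.null(gene_sets)) {
    gs <- data.table::as.data.table(gene_sets)
    stopifnot(all(c("set_name", "gene_id") %in% names(gs)))
    if (!"cluster" %in% names(gs)) gs[, cluster := NA_character_]
    unresolved <- setdiff(gs$gene_id, g$gene_id)
    if (length(unresolved) > 0L)
      stop("gene set members not present in annotation: ",
           paste(utils::head(unresolved, 5), collapse = ", "))
  } else gs <- NULL
  obj <- structure(list(genes = g, promoters = NULL, gene_sets = gs,
                        repeats = if (is.null(repeats)) NULL else
                          data.table::as.data.table(repeats)),
                   class = "AnnotationSet")
  obj$promoters <- if (is.null(promoters)) make_promoters(obj)$promoters else
    data.table::as.data.table(promoters)
  obj
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d genes", nrow(x$genes)))
  if (!is.null(x$gene_sets))
    cat(sprintf(", %d gene-set entries (%s)", nrow(x$gene_sets),
                paste(unique(x$gene_sets$set_name), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Derive promoter intervals around each TSS
#'
#' Promoter = `[tss - upstream, tss + downstream)` for + strand genes,
#' mirrored (`[tss - downstream, tss + upstream)`) for - strand, clipped
#' at 0. Defaults give a 1.5 kb window biased upstream.
#'
#' @param annotation an `AnnotationSet` (or bare gene data.frame with tss,
#'   strand).
#' @param upstream,downstream extent in bp on the transcribed orientation.
#' @return the `AnnotationSet` with its `promoters` table replaced (or, for
#'   a bare gene table, the promoter `data.table` itself).
#' @export
make_promoters <- function(annotation, upstream = 1000L, downstream = 500L) {
  stopifnot(upstream >= 0, downstream >= 0)
  g <- if (inherits(annotation, "AnnotationSet")) annotation$genes else
    data.table::as.data.table(annotation)
  if (!all(g$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-' to place its promoter")
  prom <- g[, .(
    gene_id, chrom,
    start = pmax(0L, data.table::fifelse(strand == "+",
                                         tss - as.integer(upstream),
                                         tss - as.integer(downstream))),
    end = data.table::fifelse(strand == "+",
                              tss + as.integer(downstream),
                              tss + as.integer(upstream)),
    strand)]
  data.table::setorder(prom, chrom, start)
  if (inherits(annotation, "AnnotationSet")) {
    annotation$promoters <- prom
    annotation
  } else prom
}

#' Read gene annotation from BED6 or GFF3
#'
#' BED6 gives 0-based half-open intervals directly; GFF3 (gene features
#' only) is 1-based closed and converted at the boundary. Parsing is
#' delegated to `rtracklayer::import` when available.
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"bed6"` or `"gff3"`
#' @return gene `data.table` suitable for [annotation_set()]
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed6", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed6"
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = if (format == "bed6") "BED" else "GFF3")
    df <- as.data.frame(gr)
    if (format == "gff3") {
      if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
      id <- if ("ID" %in% names(df)) df$ID else df$Name
    } else id <- df$name
    g <- data.table::data.table(
      gene_id = as.character(id), chrom = as.character(df$seqnames),
      start = as.integer(df$start) - 1L,   # GRanges 1-based closed -> 0-based half-open
      end = as.integer(df$end), strand = as.character(df$strand))
  } else if (format == "bed6") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    g <- data.table::data.table(
      gene_id = as.character(dt[[4]]), chrom = as.character(dt[[1]]),
      start = as.integer(dt[[2]]), end = as.integer(dt[[3]]),
      strand = as.character(dt[[6]]))
  } else {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#")
    dt <- dt[dt[[3]] == "gene"]
    id <- sub(".*ID=([^;]+).*", "\\1", dt[[9]])
    g <- data.table::data.table(
      gene_id = id, chrom = as.character(dt[[1]]),
      start = as.integer(dt[[4]]) - 1L, end = as.integer(dt[[5]]),
      strand = as.character(dt[[7]]))
  }
  if (!all(g$strand %in% c("+", "-")))
    stop("annotation '", path, "' contains genes without strand")
  g
}

#' Read a gene-set TSV (set_name, cluster, gene_id)
#'
#' @param path TSV path; a header line is detected and skipped.
#' @return data.table(set_name, cluster, gene_id)
#' @export
read_gene_sets <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("gene-set file needs 3 columns (set_name, cluster, gene_id)")
  if (identical(tolower(as.character(dt[1, 1])), "set_name")) dt <- dt[-1]
  data.table::data.table(set_name = as.character(dt[[1]]),
                         cluster = as.character(dt[[2]]),
                         gene_id = as.character(dt[[3]]))
}

#' Write gene annotation as BED6
#' @param genes gene table (gene_id, chrom, start, end, strand)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_bed <- function(genes, path) {
  g <- data.table::as.data.table(genes)
  out <- g[, .(chrom, start, end, name = gene_id, score = 0L, strand)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
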