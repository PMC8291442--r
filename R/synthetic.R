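#' Specification for a synthetic multi-stage methylome
#'
#' Builds the parameter object driving the generator. Six presets emulate
#' the methylome architectures seen across animals:
#'
#' * `anemone_mosaic` — pre-bilaterian mosaic genome, ~11.5% of CpGs inside
#'   highly methylated domains, global ML ~0.11; stable across stages.
#' * `bee_sparse` — insect-style near-absent methylation, global ML ~0.01.
#' * `deutero_mosaic` — invertebrate deuterostome (sea urchin / sea squirt),
#'   ~29% of CpGs in domains, global ML ~0.27, minor gamete asymmetry.
#' * `chicken_intermediate` — intermediate vertebrate, ~45% in domains,
#'   global ML ~0.42, moderate gamete asymmetry.
#' * `fish_global` — globally methylated genome with unmethylated CpG
#'   islands (CGIs); oocyte differs from sperm and is remodeled to the
#'   paternal pattern by the mid-blastula transition ("mbt") stage.
#' * `mammal_global` — globally methylated; strong gamete asymmetry,
#'   genome-wide demethylation at the "icm" stage (truth drops to 0.3 x the
#'   gamete mean) followed by remethylation.
#'
#' Mosaic architectures place contiguous CpG runs (geometric length, mean
#' `domain_mean_cpgs`) either inside methylated domains (per-site true ML
#' `domain_ml`) or background (`background_ml`). Global architectures put
#' all CpGs at `domain_ml` except dense CGI clusters at `cgi_ml`.
#' `gamete_asymmetry` is the fraction of domain units whose state is
#' switched in the oocyte relative to sperm (for mosaic presets the switch
#' silences methylated domains, so sperm ML >= oocyte ML; for global
#' presets units flip in both directions, so CGIs can be oocyte-
#' hypermethylated). The read-count error model uses a per-read
#' non-conversion failure probability `nonconversion_rate` (an unmethylated
#' cytosine reads as methylated) and `overconversion_rate` (the reverse).
#'
#' @param preset one of the six architecture presets.
#' @param n_cpgs number of CpG dyads on the main contig.
#' @param genome_length optional main-contig length in bp; derived from the
#'   CpG spacing model when `NULL`. An explicit length too small to hold
#'   `n_cpgs` CpGs is rejected.
#' @param p_dom,domain_ml,background_ml,cgi_fraction,cgi_ml architecture
#'   parameters (see above); preset defaults used when `NULL`.
#' @param stages ordered stage names; preset default when `NULL`.
#' @param gamete_asymmetry fraction of domain units switched in the oocyte.
#' @param coverage_mean,coverage_dispersion negative-binomial read-depth
#'   model (mu / size parameterization).
#' @param nonconversion_rate,overconversion_rate per-read error rates f, g.
#' @param control_sites cytosines on the unmethylated control contig.
#' @param noncpg_sites CHH-context sites (true ML 0) added per stage.
#' @param domain_mean_cpgs mean CpGs per domain unit (geometric).
#' @param cgi_cluster_cpgs CpGs per CGI cluster (global presets).
#' @param mean_spacing,cgi_spacing mean inter-CpG spacing in bp outside /
#'   inside CGIs.
#' @param n_genes regular genes placed in the designed annotation (a
#'   10-gene HOX-like cluster and a 10-gene signaling set are always added).
#' @param seed RNG seed; identical spec + seed gives bit-identical output.
#' @return an object of class `SyntheticSpec`
#' @export
synthetic_spec <- function(preset = c("anemone_mosaic", "bee_sparse",
                                      "deutero_mosaic", "chicken_intermediate",
                                      "fish_global", "mammal_global"),
                           n_cpgs = 50000L, genome_length = NULL,
                           p_dom = NULL, domain_ml = NULL, background_ml = NULL,
                           cgi_fraction = NULL, cgi_ml = 0.03,
                           stages = NULL, gamete_asymmetry = NULL,
                           coverage_mean = 30, coverage_dispersion = 5,
                           nonconversion_rate = NULL, overconversion_rate = 0.001,
                           control_sites = 20000L, noncpg_sites = 5000L,
                           domain_mean_cpgs = 10, cgi_cluster_cpgs = 50L,
                           mean_spacing = 100, cgi_spacing = 10,
                           n_genes = 200L, seed = 1L) {
  preset <- match.arg(preset)
  def <- .preset_defaults[[preset]]
  take <- function(x, d) if (is.null(x)) d else x
  spec <- list(
    preset = preset,
    family = def$family,
    n_cpgs = as.integer(n_cpgs),
    genome_length = genome_length,
    p_dom = take(p_dom, def$p_dom),
    domain_ml = take(domain_ml, def$domain_ml),
    background_ml = take(background_ml, def$background_ml),
    cgi_fraction = take(cgi_fraction, def$cgi_fraction),
    cgi_ml = cgi_ml,
    stages = take(stages, def$stages),
    gamete_asymmetry = take(gamete_asymmetry, def$gamete_asymmetry),
    coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    nonconversion_rate = take(nonconversion_rate, def$nonconversion_rate),
    overconversion_rate = overconversion_rate,
    control_sites = as.integer(control_sites),
    noncpg_sites = as.integer(noncpg_sites),
    domain_mean_cpgs = domain_mean_cpgs,
    cgi_cluster_cpgs = as.integer(cgi_cluster_cpgs),
    mean_spacing = mean_spacing,
    cgi_spacing = cgi_spacing,
    n_genes = as.integer(n_genes),
    seed = as.integer(seed))
  class(spec) <- "SyntheticSpec"
  validate_synthetic_spec(spec)
  spec
}

.preset_defaults <- list(
  anemone_mosaic = list(family = "mosaic", p_dom = 0.115, domain_ml = 0.92,
                        background_ml = 0.005, cgi_fraction = 0,
                        gamete_asymmetry = 0.02, nonconversion_rate = 0.0074,
                        stages = c("sperm", "oocyte", "blastula", "gastrula")),
  bee_sparse = list(family = "mosaic", p_dom = 0.008, domain_ml = 0.85,
                    background_ml = 0.003, cgi_fraction = 0,
                    gamete_asymmetry = 0, nonconversion_rate = 0,
                    stages = c("sperm", "oocyte", "blastula", "gastrula")),
  deutero_mosaic = list(family = "mosaic", p_dom = 0.29, domain_ml = 0.92,
                        background_ml = 0.005, cgi_fraction = 0,
                        gamete_asymmetry = 0.10, nonconversion_rate = 0.0074,
                        stages = c("sperm", "oocyte", "blastula", "gastrula")),
  chicken_intermediate = list(family = "mosaic", p_dom = 0.45, domain_ml = 0.92,
                              background_ml = 0.01, cgi_fraction = 0,
                              gamete_asymmetry = 0.15, nonconversion_rate = 0,
                              stages = c("sperm", "oocyte", "blastula", "gastrula")),
  fish_global = list(family = "global", p_dom = NA_real_, domain_ml = 0.88,
                     background_ml = NA_real_, cgi_fraction = 0.10,
                     gamete_asymmetry = 0.12, nonconversion_rate = 0.0074,
                     stages = c("sperm", "oocyte", "mbt", "gastrula")),
  mammal_global = list(family = "global", p_dom = NA_real_, domain_ml = 0.88,
                       background_ml = NA_real_, cgi_fraction = 0.10,
                       gamete_asymmetry = 0.40, nonconversion_rate = 0.0074,
                       stages = c("sperm", "oocyte", "icm", "e75")))

validate_synthetic_spec <- function(spec) {
  frac_fields <- c("domain_ml", "cgi_fraction", "cgi_ml", "gamete_asymmetry",
                   "nonconversion_rate", "overconversion_rate")
  if (spec$family == "mosaic")
    frac_fields <- c(frac_fields, "p_dom", "background_ml")
  for (f in frac_fields) {
    v <- spec[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("spec field '", f, "' must be a fraction in [0, 1]")
  }
  if (spec$n_cpgs < 1L) stop("spec field 'n_cpgs' must be >= 1")
  if (spec$coverage_mean <= 0) stop("spec field 'coverage_mean' must be > 0")
  if (length(spec$stages) < 2L) stop("spec needs >= 2 stages")
  if (!all(c("sperm", "oocyte") %in% spec$stages))
    stop("stages must include 'sperm' and 'oocyte'")
  invisible(spec)
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf("SyntheticSpec preset '%s' (%s family): %d CpGs, stages %s\n",
              x$preset, x$family, x$n_cpgs, paste(x$stages, collapse = " -> ")))
  cat(sprintf("  expected truth-level global ML (sperm): %.4f\n",
              expected_global_ml(x, observed = FALSE)))
  invisible(x)
}

#' Closed-form expected global methylation level for a spec
#'
#' Mosaic: `p_dom * domain_ml + (1 - p_dom) * background_ml`; global:
#' `(1 - cgi_fraction) * domain_ml + cgi_fraction * cgi_ml`. With
#' `observed = TRUE` the bisulfite error model is folded in: the expected
#' observed per-read probability at a site of true ML m is
#' `m (1 - g) + (1 - m) f`.
#'
#' @param spec a `SyntheticSpec`
#' @param observed include non-/over-conversion error in the expectation?
#' @return expected mean per-site ML (sperm truth)
#' @export
expected_global_ml <- function(spec, observed = TRUE) {
  m <- if (spec$family == "mosaic") {
    spec$p_dom * spec$domain_ml + (1 - spec$p_dom) * spec$background_ml
  } else {
    (1 - spec$cgi_fraction) * spec$domain_ml + spec$cgi_fraction * spec$cgi_ml
  }
  if (observed)
    m * (1 - spec$overconversion_rate) + (1 - m) * spec$nonconversion_rate
  else m
}

#' Lay out CpG positions and CGI cluster labels
#'
#' Background CpGs get geometric inter-CpG spacing (mean `mean_spacing`);
#' CGI clusters are dense runs of `cgi_cluster_cpgs` CpGs at mean spacing
#' `cgi_spacing`, covering `cgi_fraction` of all CpGs and interleaved at
#' random points along the contig. Reproduces the empirical inverse
#' relationship between CpG density and methylation once truth is assigned
#' (CGIs dense and unmethylated).
#'
#' @param spec a `SyntheticSpec`
#' @return data.table(chrom, pos, cgi, cluster_id) sorted by position
#' @export
build_cpg_landscape <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_cpgs
  n_cgi <- round(spec$cgi_fraction * n)
  n_bg <- n - n_cgi
  n_clusters <- if (n_cgi > 0L) ceiling(n_cgi / spec$cgi_cluster_cpgs) else 0L
  # interleave: split background run into n_clusters + 1 random chunks
  cgi_flag <- logical(0)
  cluster_id <- integer(0)
  if (n_clusters > 0L) {
    cuts <- sort(sample.int(n_bg, n_clusters, replace = FALSE))
    chunk <- diff(c(0L, cuts, n_bg))
    sizes <- rep(spec$cgi_cluster_cpgs, n_clusters)
    sizes[n_clusters] <- n_cgi - spec$cgi_cluster_cpgs * (n_clusters - 1L)
    for (i in seq_len(n_clusters)) {
      cgi_flag <- c(cgi_flag, rep(FALSE, chunk[i]), rep(TRUE, sizes[i]))
      cluster_id <- c(cluster_id, rep(NA_integer_, chunk[i]), rep(i, sizes[i]))
    }
    cgi_flag <- c(cgi_flag, rep(FALSE, chunk[n_clusters + 1L]))
    cluster_id <- c(cluster_id, rep(NA_integer_, chunk[n_clusters + 1L]))
  } else {
    cgi_flag <- rep(FALSE, n)
    cluster_id <- rep(NA_integer_, n)
  }
  gaps <- integer(n)
  gaps[!cgi_flag] <- stats::rgeom(sum(!cgi_flag), 1 / spec$mean_spacing) + 1L
  if (any(cgi_flag))
    gaps[cgi_flag] <- stats::rgeom(sum(cgi_flag), 1 / spec$cgi_spacing) + 1L
  pos <- cumsum(as.numeric(gaps)) + 100
  if (!is.null(spec$genome_length)) {
    if (spec$genome_length < 2 * n)
      stop("infeasible CpG density: genome_length ", spec$genome_length,
           " cannot hold ", n, " CpG dyads")
    if (max(pos) + 1 > spec$genome_length)
      stop("infeasible CpG density: simulated positions exceed genome_length")
  }
  data.table::data.table(chrom = "chr1", pos = as.integer(pos),
                         cgi = cgi_flag, cluster_id = cluster_id)
}

#' Assign per-stage truth methylation, domains, annotation and DMP labels
#'
#' Builds the full truth set for a spec: CpG landscape, domain units and
#' their per-stage states, per-site true MLs per stage, a designed gene
#' annotation (regular genes, an unmethylated HOX-like 10-gene cluster, a
#' 10-gene unmethylated "signaling" set), and the list of designed
#' differentially methylated promoters (|truth delta| >= 0.5 between sperm
#' and oocyte).
#'
#' Stage trajectories: mosaic presets inherit the sperm truth in all
#' embryonic stages (stable architecture); `fish_global` remodels the
#' oocyte truth to the paternal pattern at "mbt"; `mammal_global` drops the
#' "icm" truth to 0.3 x the per-site gamete mean and restores the sperm
#' pattern afterwards. The HOX-like cluster is unmethylated at all stages
#' in mosaic presets, oocyte-hypermethylated (then remodeled) in
#' `fish_global`, and partially methylated in gametes, demethylated at
#' "icm" and kept unmethylated afterwards in `mammal_global`.
#'
#' @param spec a `SyntheticSpec`
#' @return an object of class `TruthSet`: list with `sites`, `units`,
#'   `truth` (matrix sites x stages of true MLs), `annotation`
#'   (an `AnnotationSet` with gene sets "HOX" and "signaling"),
#'   `designed_dmps`, `stages`, `spec`.
#' @export
assign_truth <- function(spec) {
  sites <- build_cpg_landscape(spec)
  set.seed((spec$seed + 1L) %% .Machine$integer.max)
  n <- spec$n_cpgs
  stages <- spec$stages

  ## --- domain units -------------------------------------------------------
  unit_id <- integer(n)
  if (spec$family == "mosaic") {
    lens <- integer(0)
    while (sum(lens) < n)
      lens <- c(lens, stats::rgeom(ceiling(n / spec$domain_mean_cpgs) + 50L,
                                   1 / spec$domain_mean_cpgs) + 1L)
    lens <- lens[cumsum(lens) - lens < n]
    unit_id <- rep(seq_along(lens), lens)[seq_len(n)]
    is_cgi_unit <- rep(FALSE, max(unit_id))
  } else {
    # CGI clusters are their own units; bulk CpGs get geometric blocks
    unit_id[sites$cgi] <- sites$cluster_id[sites$cgi]
    n_clusters <- max(c(0L, sites$cluster_id), na.rm = TRUE)
    bulk_idx <- which(!sites$cgi)
    lens <- integer(0)
    while (sum(lens) < length(bulk_idx))
      lens <- c(lens, stats::rgeom(ceiling(length(bulk_idx) /
                                             spec$domain_mean_cpgs) + 50L,
                                   1 / spec$domain_mean_cpgs) + 1L)
    lens <- lens[cumsum(lens) - lens < length(bulk_idx)]
    bulk_units <- rep(seq_along(lens), lens)[seq_along(bulk_idx)] + n_clusters
    unit_id[bulk_idx] <- bulk_units
    is_cgi_unit <- c(rep(TRUE, n_clusters),
                     rep(FALSE, max(bulk_units) - n_clusters))
  }
  n_units <- max(unit_id)
  unit_sizes <- tabulate(unit_id, n_units)

  ## --- designed annotation ------------------------------------------------
  ann <- .design_annotation(spec, sites)
  override_idx <- ann$override_idx      # site indices forced unmethylated/special

  ## --- sperm unit states --------------------------------------------------
  if (spec$family == "mosaic") {
    target <- round(spec$p_dom * n)
    free_per_unit <- tabulate(unit_id[setdiff(seq_len(n), ann$all_special_idx)],
                              n_units)
    ord <- sample.int(n_units)
    cum <- cumsum(free_per_unit[ord])
    k <- if (target <= 0) 0L else which(cum >= target)[1]
    if (is.na(k)) k <- n_units
    sperm_meth <- logical(n_units)
    if (k >= 1L) sperm_meth[ord[seq_len(k)]] <- TRUE
  } else {
    sperm_meth <- !is_cgi_unit
  }

  ## --- oocyte: switch a fraction of units --------------------------------
  oocyte_meth <- sperm_meth
  if (spec$gamete_asymmetry > 0) {
    if (spec$family == "mosaic") {
      cand <- setdiff(which(sperm_meth), unique(unit_id[ann$all_special_idx]))
      k <- round(spec$gamete_asymmetry * length(cand))
      if (k > 0L) oocyte_meth[sample(cand, k)] <- FALSE
    } else {
      cand <- setdiff(seq_len(n_units), unique(unit_id[ann$all_special_idx]))
      k <- round(spec$gamete_asymmetry * length(cand))
      if (k > 0L) {
        flip <- sample(cand, k)
        oocyte_meth[flip] <- !oocyte_meth[flip]
      }
    }
  }

  ## --- per-site truth per stage ------------------------------------------
  low_ml <- if (spec$family == "mosaic") spec$background_ml else spec$cgi_ml
  state_to_ml <- function(meth_units)
    data.table::fifelse(meth_units[unit_id], spec$domain_ml, low_ml)
  truth <- matrix(NA_real_, nrow = n, ncol = length(stages),
                  dimnames = list(NULL, stages))
  sperm_ml <- state_to_ml(sperm_meth)
  oocyte_ml <- state_to_ml(oocyte_meth)
  for (s in stages) {
    truth[, s] <- switch(s,
      sperm = sperm_ml,
      oocyte = oocyte_ml,
      icm = 0.3 * (sperm_ml + oocyte_ml) / 2,
      sperm_ml)   # stable inheritance / paternal remodeling for other stages
  }

  ## --- gene-set overrides -------------------------------------------------
  hox <- ann$hox_idx
  sig <- ann$signaling_idx
  if (length(sig) > 0L) truth[sig, ] <- low_ml
  if (length(hox) > 0L) {
    if (spec$family == "mosaic") {
      truth[hox, ] <- low_ml
    } else if (spec$preset == "fish_global") {
      truth[hox, ] <- low_ml
      truth[hox, "oocyte"] <- spec$domain_ml    # oocyte-hypermethylated HOX
    } else {                                    # mammal_global
      truth[hox, ] <- spec$cgi_ml
      truth[hox, c("sperm", "oocyte")] <- 0.45  # partially methylated gametes
      if ("icm" %in% stages) truth[hox, "icm"] <- 0.3 * 0.45
    }
  }

  dmps <- .designed_dmps(ann$annotation, sites, truth)

  structure(list(
    spec = spec, sites = sites, unit_id = unit_id,
    units = data.table::data.table(unit_id = seq_len(n_units),
                                   n_cpgs = unit_sizes,
                                   is_cgi = is_cgi_unit,
                                   sperm_methylated = sperm_meth,
                                   oocyte_methylated = oocyte_meth),
    truth = truth, stages = stages, annotation = ann$annotation,
    designed_dmps = dmps), class = "TruthSet")
}

# Place regular genes, the HOX-like cluster and the signaling set over the
# simulated CpG landscape. Returns site-index sets used for truth overrides.
.design_annotation <- function(spec, sites) {
  n <- spec$n_cpgs
  sites_per_gene <- 20L
  hox_span <- 25L
  hox_start <- max(1L, floor(0.45 * n))
  # shrink the cluster on small test genomes so every gene fits
  hox_genes <- max(1L, min(10L, (n - hox_start + 1L) %/% hox_span))
  hox_end <- min(n, hox_start + hox_genes * hox_span - 1L)
  # the override region extends upstream so the first HOX promoter window
  # (default 1 kb upstream) is covered by the forced truth state
  hox_idx <- max(1L, hox_start - 15L):hox_end
  pos <- sites$pos

  mk_gene <- function(id, i0, i1, strand = "+") {
    data.table::data.table(gene_id = id, chrom = "chr1",
                           start = max(0L, pos[i0] - 100L),
                           end = pos[i1] + 100L, strand = strand)
  }
  hox_list <- lapply(seq_len(hox_genes), function(i) {
    i0 <- hox_start + (i - 1L) * hox_span
    mk_gene(sprintf("hox%d", i), i0, min(i0 + hox_span - 1L, n))
  })

  # regular genes on an index grid outside the HOX region; global presets
  # anchor as many genes as possible at CGI clusters (vertebrate CGI
  # promoters), the rest fall back to the grid
  gene_list <- list()
  used <- rep(FALSE, n)
  used[hox_idx] <- TRUE
  g_count <- 0L
  if (spec$family == "global") {
    clusters <- which(!is.na(sites$cluster_id))
    first_of_cluster <- clusters[!duplicated(sites$cluster_id[clusters])]
    for (i0 in first_of_cluster) {
      if (g_count >= spec$n_genes) break
      i1 <- min(i0 + sites_per_gene - 1L, n)
      if (any(used[i0:i1])) next
      g_count <- g_count + 1L
      gene_list[[g_count]] <- mk_gene(sprintf("gene%d", g_count), i0, i1,
                                      strand = if (g_count %% 2L) "+" else "-")
      used[i0:i1] <- TRUE
    }
  }
  step <- max(sites_per_gene + 10L, floor(n / (spec$n_genes + 2L)))
  for (i0 in seq(10L, max(10L, n - sites_per_gene - 10L), by = step)) {
    if (g_count >= spec$n_genes) break
    i1 <- i0 + sites_per_gene - 1L
    if (any(used[i0:i1])) next
    g_count <- g_count + 1L
    gene_list[[g_count]] <- mk_gene(sprintf("gene%d", g_count), i0, i1,
                                    strand = if (g_count %% 2L) "+" else "-")
    used[i0:i1] <- TRUE
  }
  genes <- data.table::rbindlist(c(gene_list, hox_list))

  # signaling set: up to 10 regular genes, forced unmethylated at all stages
  sig_ids <- if (g_count >= 2L)
    sprintf("gene%d", utils::head(seq(2L, g_count, by = 2L), 10L))
  else character(0)
  gene_sets <- data.table::rbindlist(list(
    data.table::data.table(set_name = "HOX", cluster = "HOXA",
                           gene_id = sprintf("hox%d", seq_len(hox_genes))),
    if (length(sig_ids) > 0L)
      data.table::data.table(set_name = "signaling", cluster = NA_character_,
                             gene_id = sig_ids)))
  annotation <- annotation_set(genes, gene_sets = gene_sets)

  # site indices covered by signaling genes + their promoters
  sig_iv <- merge(annotation$genes[gene_id %in% sig_ids],
                  annotation$promoters[gene_id %in% sig_ids],
                  by = "gene_id", suffixes = c("", ".p"))
  sig_idx <- integer(0)
  for (r in seq_len(nrow(sig_iv))) {
    lo <- min(sig_iv$start[r], sig_iv$start.p[r])
    hi <- max(sig_iv$end[r], sig_iv$end.p[r])
    sig_idx <- c(sig_idx, which(pos >= lo & pos < hi))
  }
  sig_idx <- sort(unique(sig_idx))

  list(annotation = annotation, hox_idx = hox_idx, signaling_idx = sig_idx,
       override_idx = sort(unique(c(hox_idx, sig_idx))),
       all_special_idx = sort(unique(c(hox_idx, sig_idx))))
}

# Truth-level promoter MLs and the designed-DMP list (|delta| >= 0.5)
.designed_dmps <- function(annotation, sites, truth) {
  prom <- data.table::copy(annotation$promoters)
  site_dt <- data.table::data.table(chrom = sites$chrom, start = sites$pos,
                                    end = sites$pos + 1L,
                                    sperm = truth[, "sperm"],
                                    oocyte = truth[, "oocyte"])
  data.table::setkey(prom, chrom, start, end)
  ov <- data.table::foverlaps(site_dt, prom, type = "within", nomatch = NULL)
  by_gene <- ov[, .(truth_ml_sperm = mean(sperm), truth_ml_oocyte = mean(oocyte),
                    n_cpgs = .N), by = "gene_id"]
  by_gene[, truth_delta := truth_ml_sperm - truth_ml_oocyte]
  by_gene[, designed_dmp := abs(truth_delta) >= 0.5]
  by_gene[]
}

#' Simulate read counts from a truth set
#'
#' Per site and stage: read depth `n_total ~ NegBin(mu = coverage_mean,
#' size = coverage_dispersion)`; each read reports methylated with
#' probability `m (1 - g) + (1 - m) f` where m is the true ML, f the
#' non-conversion and g the over-conversion rate; `n_meth ~ Binomial`.
#' Adds `noncpg_sites` CHH sites with true ML 0 on contig "chrNC" per
#' stage, and one unmethylated control contig table ("lambda") shared by
#' the run. Fixed seed implies bit-identical output.
#'
#' @param truth a `TruthSet` from [assign_truth()]
#' @param spec the matching `SyntheticSpec` (defaults to `truth$spec`)
#' @param seed count-sampling seed; defaults to one derived from the spec
#'   seed. Re-drawing counts from the same `TruthSet` under a different
#'   `seed` produces technical replicates (same truth, independent reads).
#' @return list with `stages` (named list of `MethylomeTable`) and
#'   `control` (a `MethylomeTable` of the control contig)
#' @export
simulate_counts <- function(truth, spec = truth$spec, seed = NULL) {
  if (is.null(seed)) seed <- (spec$seed + 2L) %% .Machine$integer.max
  set.seed(seed)
  n <- spec$n_cpgs
  obs_prob <- function(m)
    m * (1 - spec$overconversion_rate) + (1 - m) * spec$nonconversion_rate
  nc_pos <- if (spec$noncpg_sites > 0L)
    as.integer(cumsum(stats::rgeom(spec$noncpg_sites, 1 / 50) + 1L) + 100L)
  else integer(0)
  tables <- list()
  for (s in spec$stages) {
    cov <- stats::rnbinom(n, size = spec$coverage_dispersion,
                          mu = spec$coverage_mean)
    nm <- stats::rbinom(n, cov, obs_prob(truth$truth[, s]))
    rec <- data.table::data.table(chrom = truth$sites$chrom,
                                  pos = truth$sites$pos, strand = "+",
                                  context = "CG", n_meth = nm, n_total = cov)
    if (length(nc_pos) > 0L) {
      ncov <- stats::rnbinom(length(nc_pos), size = spec$coverage_dispersion,
                             mu = spec$coverage_mean)
      nnm <- stats::rbinom(length(nc_pos), ncov, obs_prob(0))
      rec <- data.table::rbindlist(list(rec, data.table::data.table(
        chrom = "chrNC", pos = nc_pos, strand = "+", context = "CHH",
        n_meth = nnm, n_total = ncov)))
    }
    tables[[s]] <- methylome_table(rec,
                                   sample_id = paste(spec$preset, s, sep = "_"),
                                   species = spec$preset, stage = s)
  }
  ctrl_cov <- stats::rnbinom(spec$control_sites, size = spec$coverage_dispersion,
                             mu = spec$coverage_mean)
  ctrl_nm <- stats::rbinom(spec$control_sites, ctrl_cov, obs_prob(0))
  control <- methylome_table(
    data.table::data.table(chrom = "lambda",
                           pos = seq(0L, by = 50L,
                                     length.out = spec$control_sites),
                           strand = "+", context = "CG",
                           n_meth = ctrl_nm, n_total = ctrl_cov),
    sample_id = paste(spec$preset, "control", sep = "_"),
    species = spec$preset, stage = "control")
  list(stages = tables, control = control)
}

#' Generate a complete synthetic methylome set
#'
#' Convenience wrapper: [assign_truth()] then [simulate_counts()].
#'
#' @param spec a `SyntheticSpec`
#' @return list with `truth` (`TruthSet`), `stages` (named list of
#'   `MethylomeTable`), `control` (`MethylomeTable`), `annotation`.
#' @export
simulate_methylomes <- function(spec) {
  truth <- assign_truth(spec)
  counts <- simulate_counts(truth, spec)
  list(truth = truth, stages = counts$stages, control = counts$control,
       annotation = truth$annotation)
}

#' Simulate an unmethylated control contig on its own
#'
#' Used for conversion-rate estimation: every site has true ML 0, so any
#' methylated read is a bisulfite conversion failure.
#'
#' @param n_sites cytosines on the contig
#' @param nonconversion_rate per-read failure probability f
#' @param coverage_mean,coverage_dispersion negative-binomial depth model
#' @param seed RNG seed
#' @return a `MethylomeTable`
#' @export
simulate_control <- function(n_sites = 100000L, nonconversion_rate = 0.0074,
                             coverage_mean = 30, coverage_dispersion = 5,
                             seed = 1L) {
  set.seed(seed)
  cov <- stats::rnbinom(n_sites, size = coverage_dispersion, mu = coverage_mean)
  nm <- stats::rbinom(n_sites, cov, nonconversion_rate)
  methylome_table(
    data.table::data.table(chrom = "lambda",
                           pos = seq(0L, by = 50L, length.out = n_sites),
                           strand = "+", context = "CG",
                           n_meth = nm, n_total = cov),
    sample_id = "control", stage = "control")
}

#' Simulate a two-sample DMP benchmark with known positives
#'
#' `n_dmp` of `n_promoters` promoters carry a designed sperm-oocyte truth
#' difference of `delta` (sperm high); the rest are identical between
#' samples (half high, half low). Each promoter holds
#' `cpgs_per_promoter` CpGs inside its default promoter window.
#'
#' @param n_promoters,n_dmp promoter counts
#' @param delta designed truth difference (sperm - oocyte) at DMPs
#' @param cpgs_per_promoter CpGs per promoter
#' @param coverage_mean,coverage_dispersion depth model
#' @param nonconversion_rate,overconversion_rate error model
#' @param seed RNG seed
#' @return list with `sperm`, `oocyte` (`MethylomeTable`s), `annotation`
#'   (an `AnnotationSet`), `truth` (data.table with `is_dmp`).
#' @export
simulate_dmp_benchmark <- function(n_promoters = 1000L, n_dmp = 200L,
                                   delta = 0.85, cpgs_per_promoter = 10L,
                                   coverage_mean = 30, coverage_dispersion = 5,
                                   nonconversion_rate = 0.0074,
                                   overconversion_rate = 0.001, seed = 1L) {
  stopifnot(n_dmp <= n_promoters, delta > 0, delta <= 0.9)
  set.seed(seed)
  hi <- 0.05 + delta            # 0.90 at the default delta
  lo <- 0.05
  is_dmp <- c(rep(TRUE, n_dmp), rep(FALSE, n_promoters - n_dmp))
  base <- rep(c(hi, lo), length.out = n_promoters)   # null promoters alternate
  m_sperm <- ifelse(is_dmp, hi, base)
  m_oocyte <- ifelse(is_dmp, lo, base)
  tss <- seq(0L, by = 5000L, length.out = n_promoters) + 2000L
  genes <- data.table::data.table(gene_id = sprintf("p%04d", seq_len(n_promoters)),
                                  chrom = "chr1", start = tss,
                                  end = tss + 2000L, strand = "+")
  site_pos <- as.integer(rep(tss, each = cpgs_per_promoter) +
                           seq(0L, by = 45L, length.out = cpgs_per_promoter))
  obs <- function(m) m * (1 - overconversion_rate) +
    (1 - m) * nonconversion_rate
  one_sample <- function(m_per_prom, stage) {
    m <- rep(m_per_prom, each = cpgs_per_promoter)
    cov <- stats::rnbinom(length(site_pos), size = coverage_dispersion,
                          mu = coverage_mean)
    nm <- stats::rbinom(length(site_pos), cov, obs(m))
    methylome_table(data.table::data.table(chrom = "chr1", pos = site_pos,
                                           strand = "+", context = "CG",
                                           n_meth = nm, n_total = cov),
                    sample_id = paste0("bench_", stage), stage = stage)
  }
  list(sperm = one_sample(m_sperm, "sperm"),
       oocyte = one_sample(m_oocyte, "oocyte"),
       annotation = annotation_set(genes),
       truth = data.table::data.table(gene_id = genes$gene_id, is_dmp = is_dmp,
                                      truth_ml_sperm = m_sperm,
                                      truth_ml_oocyte = m_oocyte))
}

#' Write a synthetic dataset to disk
#'
#' Emits per-stage cytosine reports (and bedGraphs), the control contig,
#' the gene annotation (BED6), gene sets (TSV) and per-site truth MLs
#' (TSV), all in the package's on-disk dialects so the files round-trip
#' through the readers.
#'
#' @param spec a `SyntheticSpec`
#' @param dir output directory (created if needed)
#' @return the directory path, invisibly
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_methylomes(spec)
  for (s in names(sim$stages)) {
    write_cytosine_report(sim$stages[[s]],
                          file.path(dir, sprintf("%s_%s.CX_report.txt",
                                                 spec$preset, s)))
    write_bedgraph_counts(sim$stages[[s]],
                          file.path(dir, sprintf("%s_%s.bedGraph", spec$preset, s)))
  }
  write_cytosine_report(sim$control, file.path(dir, "control.CX_report.txt"))
  write_gene_bed(sim$annotation$genes, file.path(dir, "genes.bed"))
  data.table::fwrite(sim$annotation$gene_sets, file.path(dir, "gene_sets.tsv"),
                     sep = "\t")
  truth_dt <- data.table::data.table(chrom = sim$truth$sites$chrom,
                                     pos = sim$truth$sites$pos)
  for (s in sim$truth$stages) truth_dt[[paste0("ml_", s)]] <- sim$truth$truth[, s]
  data.table::fwrite(truth_dt, file.path(dir, "truth_ml.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$designed_dmps, file.path(dir, "designed_dmps.tsv"),
                     sep = "\t")
  invisible(dir)
}
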