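#' Run the full methylome-reprogramming analysis from a config
#'
#' Config-driven orchestration: load or simulate the per-stage methylomes,
#' then run global statistics, conversion-rate estimation, non-CpG
#' correction, domain segmentation, TSS metaprofiles, sperm-oocyte
#' divergence, DMP calling, stage-dynamics classification and gene-set
#' scoring, writing TSV/BED outputs and a machine-readable JSON summary.
#' Deterministic given config + seed.
#'
#' The config is a YAML file path or an equivalent named list:
#' \preformatted{
#' seed: 1
#' out_dir: results/run1
#' simulate:                 # either simulate ...
#'   preset: anemone_mosaic
#'   n_cpgs: 50000
#' samples:                  # ... or load call files
#'   - {path: sperm.CX_report.txt, format: cytosine_report, stage: sperm}
#'   - {path: oocyte.CX_report.txt, format: cytosine_report, stage: oocyte}
#' annotation: {genes: genes.bed, gene_sets: gene_sets.tsv}
#' params: {min_cov: 5, promoter_upstream: 1000, promoter_downstream: 500,
#'          dmp_delta_min: 0.2, dmp_alpha: 0.05, bin_bp: 1000,
#'          merge_dyads: true}
#' }
#'
#' @param config YAML path or named list
#' @return the summary list (also written as `summary.json`), invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  p <- cfg$params
  prm <- function(name, default) if (is.null(p[[name]])) default else p[[name]]
  min_cov <- prm("min_cov", 5L)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs ------------------------------------------------------------
  dat <- run_stage("input", {
    if (!is.null(cfg$simulate)) {
      spec <- do.call(synthetic_spec, c(cfg$simulate, list(seed = cfg$seed)))
      sim <- simulate_methylomes(spec)
      list(samples = sim$stages, annotation = sim$annotation,
           control = sim$control)
    } else {
      if (is.null(cfg$samples)) stop("config needs 'simulate' or 'samples'")
      samples <- list()
      for (s in cfg$samples) {
        if (!file.exists(s$path)) stop("sample file not found: ", s$path)
        reader <- switch(s$format %||% "cytosine_report",
                         cytosine_report = read_cytosine_report,
                         bedgraph_counts = read_bedgraph_counts,
                         stop("unknown sample format: ", s$format))
        samples[[s$stage]] <- reader(s$path, sample_id = s$stage,
                                     species = s$species %||% NA_character_,
                                     stage = s$stage)
      }
      ann <- NULL
      if (!is.null(cfg$annotation)) {
        if (!file.exists(cfg$annotation$genes))
          stop("annotation file not found: ", cfg$annotation$genes)
        genes <- read_gene_annotation(cfg$annotation$genes)
        gs <- if (!is.null(cfg$annotation$gene_sets))
          read_gene_sets(cfg$annotation$gene_sets) else NULL
        ann <- annotation_set(genes, gene_sets = gs)
      }
      ctrl <- if (!is.null(cfg$control) && file.exists(cfg$control))
        read_cytosine_report(cfg$control) else NULL
      list(samples = samples, annotation = ann, control = ctrl)
    }
  })
  samples <- dat$samples
  if (isTRUE(prm("merge_dyads", TRUE)))
    samples <- lapply(samples, merge_cpg_dyads)
  ann <- dat$annotation
  if (!is.null(ann))
    ann <- make_promoters(ann, prm("promoter_upstream", 1000L),
                          prm("promoter_downstream", 500L))

  summary <- list(seed = cfg$seed, stages = names(samples))

  ## ---- global statistics -------------------------------------------------
  glob <- run_stage("global", {
    g <- lapply(samples, global_ml, min_cov = min_cov)
    dt <- data.table::data.table(
      stage = names(g),
      n_sites = vapply(g, `[[`, integer(1), "n_sites_used"),
      site_mean = vapply(g, `[[`, numeric(1), "site_mean"),
      count_weighted = vapply(g, `[[`, numeric(1), "count_weighted"))
    write_tsv(dt, file.path(cfg$out_dir, "global_ml.tsv"))
    dt
  })
  stage_ml <- stats::setNames(glob$site_mean, glob$stage)
  summary$global_ml <- as.list(stage_ml)

  if (!is.null(dat$control)) {
    cr <- run_stage("conversion", conversion_rate(dat$control))
    summary$conversion_rate <- cr
    has_noncpg <- any(samples[[1]]$records$context %in% c("CHG", "CHH"))
    if (has_noncpg)
      summary$corrected_noncpg_ml <- run_stage("noncpg", lapply(
        samples, corrected_noncpg_ml, conv_rate = cr, min_cov = min_cov))
  }

  ## ---- domains and profiles ----------------------------------------------
  run_stage("segment", for (s in names(samples)) {
    dom <- segment_domains(samples[[s]], min_cov = min_cov)
    bed <- dom[, .(chrom, start, end, name = state)]
    write_tsv(bed, file.path(cfg$out_dir, paste0("domains_", s, ".bed")),
              col_names = FALSE)
  })
  if (!is.null(ann)) {
    run_stage("profile", for (s in names(samples)) {
      prof <- tss_metaprofile(samples[[s]], ann, min_cov = min_cov)
      write_tsv(prof, file.path(cfg$out_dir, paste0("tss_profile_", s, ".tsv")))
    })
  }

  ## ---- reprogramming -----------------------------------------------------
  gam <- intersect(c("sperm", "oocyte"), names(samples))
  if (length(gam) == 2L) {
    div <- run_stage("divergence", sperm_oocyte_divergence(
      samples$sperm, samples$oocyte, bin_bp = prm("bin_bp", 1000L),
      min_cov = min_cov))
    summary$divergence <- div[c("global_delta", "mean_abs_bin_delta")]
    if (!is.null(ann)) {
      dmps <- run_stage("dmp", call_dmps(
        samples$sperm, samples$oocyte, ann, min_cov = min_cov,
        delta_min = prm("dmp_delta_min", 0.2), alpha = prm("dmp_alpha", 0.05)))
      write_tsv(dmps, file.path(cfg$out_dir, "dmps_sperm_vs_oocyte.tsv"))
      summary$dmp <- list(n_tested = nrow(dmps),
                          n_hyper_in_sperm = sum(dmps$status == "hyper_in_a"),
                          n_hypo_in_sperm = sum(dmps$status == "hypo_in_a"))
      sig <- dmps[status != "ns"]
      if (nrow(sig) > 0L) {
        mat <- dmp_heatmap_matrix(samples, sig, ann, min_cov = min_cov)
        write_tsv(data.table::data.table(gene_id = rownames(mat), mat),
                  file.path(cfg$out_dir, "dmp_heatmap.tsv"))
      }
    }
  }
  dyn <- run_stage("dynamics", classify_dynamics(stage_ml, gametes = gam))
  summary$dynamics <- list(max_delta = dyn$max_delta,
                           dynamics_class = dyn$dynamics_class,
                           demethylation_flag = dyn$demethylation_flag)

  ## ---- gene sets ---------------------------------------------------------
  if (!is.null(ann) && !is.null(ann$gene_sets)) {
    run_stage("gene_sets", for (set in unique(ann$gene_sets$set_name)) {
      for (reg in c("promoter", "genic")) {
        tab <- gene_set_ml(samples, ann, set, region = reg, min_cov = min_cov)
        write_tsv(tab, file.path(cfg$out_dir,
                                 sprintf("gene_set_%s_%s.tsv", set, reg)))
        summary$gene_sets[[set]][[reg]] <-
          as.list(tapply(tab$ml, tab$sample, mean, na.rm = TRUE))
      }
    })
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TSV writer that stamps the coordinate convention into a header comment
write_tsv <- function(dt, path, col_names = TRUE) {
  con <- file(path, "w")
  writeLines("# coordinates: 0-based, half-open", con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", col.names = col_names,
                     append = TRUE)
  invisible(path)
}
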