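test_that("CpG landscapes are seed-deterministic with denser spacing inside CGIs", {
  spec <- synthetic_spec("fish_global", n_cpgs = 5000, seed = 11)
  l1 <- build_cpg_landscape(spec)
  l2 <- build_cpg_landscape(spec)
  expect_identical(l1, l2)
  expect_equal(sum(l1$cgi) / nrow(l1), spec$cgi_fraction, tolerance = 0.01)
  sp_in <- mean(diff(l1$pos)[utils::head(l1$cgi, -1) & utils::tail(l1$cgi, -1)])
  sp_out <- mean(diff(l1$pos)[!utils::head(l1$cgi, -1) & !utils::tail(l1$cgi, -1)])
  expect_lt(sp_in, sp_out)
  # mosaic presets have no CGI clusters
  lm <- build_cpg_landscape(synthetic_spec("anemone_mosaic", n_cpgs = 2000, seed = 1))
  expect_false(any(lm$cgi))
  expect_error(
    build_cpg_landscape(synthetic_spec("anemone_mosaic", n_cpgs = 1000,
                                       genome_length = 1500, seed = 1)),
    "infeasible")
})

test_that("spec validation rejects degenerate parameters", {
  expect_error(synthetic_spec("anemone_mosaic", n_cpgs = 0), "n_cpgs")
  expect_error(synthetic_spec("anemone_mosaic", p_dom = 1.5), "fraction")
  expect_error(synthetic_spec("anemone_mosaic", nonconversion_rate = -0.1),
               "fraction")
  expect_error(synthetic_spec("unknown_preset"))
})

test_that("truth assignment hits the closed-form global expectation and honors gamete symmetry", {
  spec <- synthetic_spec("anemone_mosaic", n_cpgs = 30000, seed = 3)
  tr <- assign_truth(spec)
  expect_equal(mean(tr$truth[, "sperm"]),
               0.115 * 0.92 + 0.885 * 0.005, tolerance = 0.005)
  expect_true(all(tr$truth >= 0 & tr$truth <= 1))
  # zero asymmetry makes the gamete truths identical
  tr0 <- assign_truth(synthetic_spec("deutero_mosaic", n_cpgs = 10000,
                                     gamete_asymmetry = 0, seed = 4))
  expect_identical(tr0$truth[, "sperm"], tr0$truth[, "oocyte"])
  # mammalian intermediate stage truth is 0.3 x the per-site gamete mean
  # (a small forced-unmethylated gene-set region is exempt)
  trm <- assign_truth(synthetic_spec("mammal_global", n_cpgs = 10000, seed = 5))
  icm_expect <- 0.3 * (trm$truth[, "sperm"] + trm$truth[, "oocyte"]) / 2
  expect_gte(mean(abs(trm$truth[, "icm"] - icm_expect) < 1e-12), 0.9)
  expect_equal(mean(trm$truth[, "icm"]), mean(icm_expect), tolerance = 0.02)
})

test_that("the read-count error model follows m(1-g) + (1-m)f", {
  spec <- synthetic_spec("anemone_mosaic", n_cpgs = 100, noncpg_sites = 0,
                         control_sites = 100, seed = 6)
  tr <- assign_truth(spec)
  # fully methylated truth with no conversion error: every read methylated
  tr1 <- tr; tr1$truth[] <- 1
  sp1 <- spec; sp1$nonconversion_rate <- 0; sp1$overconversion_rate <- 0
  cnt <- simulate_counts(tr1, sp1)
  expect_true(all(cnt$stages$sperm$records$n_meth ==
                    cnt$stages$sperm$records$n_total))
  # unmethylated truth: mean observed ML converges to f
  sp2 <- synthetic_spec("anemone_mosaic", n_cpgs = 50000, p_dom = 0,
                        background_ml = 0, noncpg_sites = 0,
                        overconversion_rate = 0, seed = 7)
  sim2 <- simulate_methylomes(sp2)
  g <- global_ml(sim2$stages$sperm, min_cov = 1)
  expect_lt(abs(g$count_weighted - 0.0074), 6e-4)
  # half-methylated truth with f=0.01, g=0.02: expected probability 0.495
  sp3 <- synthetic_spec("anemone_mosaic", n_cpgs = 50000, p_dom = 1,
                        domain_ml = 0.5, nonconversion_rate = 0.01,
                        overconversion_rate = 0.02, noncpg_sites = 0, seed = 8)
  expect_equal(expected_global_ml(sp3), 0.5 * 0.98 + 0.5 * 0.01)
  sim3 <- simulate_methylomes(sp3)
  # the designed unmethylated gene-set region (~1% of sites) pulls the
  # genome-wide mean slightly below the per-site expectation
  expect_lt(abs(global_ml(sim3$stages$sperm, min_cov = 1)$count_weighted -
                  0.495), 0.006)
})

test_that("identical spec and seed reproduce bit-identical tables", {
  spec <- synthetic_spec("bee_sparse", n_cpgs = 3000, seed = 9)
  s1 <- simulate_methylomes(spec)
  s2 <- simulate_methylomes(spec)
  expect_identical(s1$stages$sperm$records, s2$stages$sperm$records)
  expect_identical(s1$stages$gastrula$records, s2$stages$gastrula$records)
  expect_identical(s1$control$records, s2$control$records)
  # different seed, same schema, different draws
  s3 <- simulate_methylomes(synthetic_spec("bee_sparse", n_cpgs = 3000, seed = 10))
  expect_false(identical(s1$stages$sperm$records, s3$stages$sperm$records))
  expect_identical(names(s1$stages), names(s3$stages))
})

test_that("generated per-site MLs are bimodal for high-contrast presets", {
  for (p in c("anemone_mosaic", "deutero_mosaic", "fish_global")) {
    sim <- simulate_methylomes(synthetic_spec(p, n_cpgs = 20000, seed = 12))
    d <- ml_distribution(sim$stages$sperm, min_cov = 5)
    expect_gte(d$bimodality, 0.9)
  }
})

test_that("designed DMPs exist exactly where the gamete truths diverge at promoters", {
  tr <- assign_truth(synthetic_spec("deutero_mosaic", n_cpgs = 30000, seed = 13))
  dd <- tr$designed_dmps
  expect_true(all(abs(dd$truth_delta[dd$designed_dmp]) >= 0.5))
  expect_true(all(abs(dd$truth_delta[!dd$designed_dmp]) < 0.5))
  expect_gt(sum(dd$designed_dmp), 0)
  # HOX promoters are never designed DMPs in invertebrate presets
  expect_false(any(dd$designed_dmp[grepl("^hox", dd$gene_id)]))
})

test_that("a simulated dataset written to disk round-trips through the readers", {
  dir <- tempfile()
  spec <- synthetic_spec("anemone_mosaic", n_cpgs = 2000, control_sites = 500,
                         noncpg_sites = 200, seed = 14)
  simulate_dataset(spec, dir)
  sim <- simulate_methylomes(spec)
  back <- read_cytosine_report(file.path(dir, "anemone_mosaic_sperm.CX_report.txt"))
  expect_equal(back$records, sim$stages$sperm$records)
  genes <- read_gene_annotation(file.path(dir, "genes.bed"))
  expect_setequal(genes$gene_id, sim$annotation$genes$gene_id)
  gs <- read_gene_sets(file.path(dir, "gene_sets.tsv"))
  expect_setequal(unique(gs$set_name), c("HOX", "signaling"))
})
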