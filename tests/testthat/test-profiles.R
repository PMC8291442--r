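test_that("TSS metaprofile bins match a hand-mapped layout on both strands", {
  # two genes: plus-strand TSS at 10000, minus-strand TSS at 30000
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      start = c(10000L, 28000L), end = c(12000L, 30001L),
                      strand = c("+", "-"))
  ann <- annotation_set(genes)
  # sites: TSS+250 of gp -> offset +250 -> bin (250+6000)/100 = 62
  #        TSS-150 of gp -> offset -150 -> bin 58
  #        30000-250 = 29750 on gm -> offset tss-p = +250 -> bin 62
  #        30000+400 = 30400 on gm -> offset -400 -> bin 56
  mt <- make_ml_mt(c(9850L, 10250L, 29750L, 30400L),
                   c(0.2, 0.8, 0.6, 0.4), cov = 10L)
  prof <- tss_metaprofile(mt, ann, min_cov = 5)
  expect_equal(nrow(prof), 120L)
  expect_equal(prof[bin == 58]$mean_ml, 0.2)
  expect_equal(prof[bin == 62]$mean_ml, (0.8 + 0.6) / 2)
  expect_equal(prof[bin == 56]$mean_ml, 0.4)
  expect_equal(sum(prof$n_sites), 4L)
  # a uniform-ML genome profiles flat
  flat <- make_ml_mt(seq(4000L, 36000L, by = 400L), 0.5, cov = 10L)
  pf <- tss_metaprofile(flat, ann, min_cov = 5)
  expect_true(all(pf[n_sites > 0]$mean_ml == 0.5))
  expect_error(tss_metaprofile(make_mt(500000L, 1L, 10L), ann), "no covered CpGs")
})

test_that("flipping every gene strand mirrors the metaprofile", {
  set.seed(31)
  # even TSSs on both strands (end - 1 even) and odd site positions keep
  # every offset off the exact bin boundaries, where the half-open bins
  # of the original and mirrored profile would disagree
  genes <- data.frame(gene_id = sprintf("g%d", 1:6), chrom = "chr1",
                      start = seq(20000L, 120000L, by = 20000L),
                      end = seq(20000L, 120000L, by = 20000L) + 5001L,
                      strand = rep(c("+", "-"), 3))
  pos <- sort(unique(as.integer(sample(5000:130000, 3000) * 2L + 1L)))
  mt <- make_ml_mt(pos, runif(length(pos)), cov = 10L)
  flip <- genes
  flip$strand <- ifelse(genes$strand == "+", "-", "+")
  flip$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  p1 <- tss_metaprofile(mt, annotation_set(genes), min_cov = 5)
  p2 <- tss_metaprofile(mt, annotation_set(flip), min_cov = 5)
  expect_equal(p1$mean_ml, rev(p2$mean_ml))
  expect_equal(p1$n_sites, rev(p2$n_sites))
})

test_that("interval MLs average covered sites and flag data-poor intervals", {
  iv <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   start = c(0L, 1000L), end = c(1000L, 2000L))
  mt <- make_ml_mt(c(10L, 20L, 30L, 1500L, 1600L), c(1, 0, 0.5, 1, 1), cov = 10L)
  em <- element_ml(mt, iv, min_cpgs = 3)
  expect_equal(em[em$gene_id == "a", ]$mean_ml, 0.5)
  expect_true(is.na(em[em$gene_id == "b", ]$mean_ml))   # only 2 CpGs
  expect_equal(em[em$gene_id == "b", ]$n_cpgs, 2L)
  # truth-labeled synthetic domains score at their designed levels
  sim <- simulate_methylomes(synthetic_spec("deutero_mosaic", n_cpgs = 20000,
                                            seed = 32))
  truth_state <- sim$truth$truth[, "sperm"] >= 0.5
  r <- rle(truth_state)
  ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
  keep <- r$lengths >= 10
  truth_iv <- data.frame(id = seq_len(sum(keep)), chrom = "chr1",
                         start = sim$truth$sites$pos[starts[keep]],
                         end = sim$truth$sites$pos[ends[keep]] + 1L,
                         methylated = r$values[keep])
  em2 <- element_ml(sim$stages$sperm, truth_iv[, c("id", "chrom", "start", "end")],
                    min_cpgs = 3)
  scored <- merge(truth_iv, em2, by = "id")
  expect_true(all(scored$mean_ml[scored$methylated] >= 0.8, na.rm = TRUE))
  expect_true(all(scored$mean_ml[!scored$methylated] <= 0.1, na.rm = TRUE))
})

test_that("segmentation matches the run-length oracle on a designed toy", {
  # 30 CpGs: 10 high, 10 low, 10 high
  pos <- seq(100L, by = 100L, length.out = 30L)
  ml <- c(rep(0.9, 10), rep(0, 10), rep(0.9, 10))
  mt <- make_ml_mt(pos, ml, cov = 10L)
  dom <- segment_domains(mt, smooth_w = 5, state_threshold = 0.5,
                         min_cpgs_per_domain = 5)
  oracle <- segment_oracle(pos, ml, w = 5, thr = 0.5)
  expect_equal(nrow(dom), 3L)
  expect_equal(dom$state, oracle$state)
  expect_equal(dom$start, oracle$start)
  expect_equal(dom$end, oracle$end)
  # boundaries sit within (smooth_w-1)/2 sites of the designed changepoints
  expect_lte(abs(dom$start[2] - pos[11]), 200)
  expect_lte(abs(dom$start[3] - pos[21]), 200)
})

test_that("segmentation handles degenerate chromosomes and conserves the global mean", {
  # all-zero methylome: one unmethylated domain per chromosome
  mt0 <- methylome_table(data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
                                    pos = rep(seq(0L, 900L, by = 100L), 2),
                                    strand = "+", context = "CG",
                                    n_meth = 0L, n_total = 10L))
  d0 <- segment_domains(mt0)
  expect_equal(nrow(d0), 2L)
  expect_true(all(d0$state == "unmethylated"))
  # short chromosome emits a single domain with a warning
  mt1 <- make_mt(c(10L, 20L), c(10L, 10L), c(10L, 10L))
  expect_warning(d1 <- segment_domains(mt1), "fewer CpGs")
  expect_equal(d1$state, "methylated")
  # CpG-weighted mean of domain MLs equals the global site-mean ML
  sim <- simulate_methylomes(synthetic_spec("anemone_mosaic", n_cpgs = 10000,
                                            seed = 33))
  sp <- sim$stages$sperm
  dom <- segment_domains(sp, min_cov = 5)
  chr1 <- dom[chrom == "chr1"]
  expect_equal(sum(chr1$mean_ml * chr1$n_cpgs) / sum(chr1$n_cpgs),
               global_ml(sp, min_cov = 5)$site_mean)
})

test_that("segmentation recovers the generator's true domain states on mosaic presets", {
  for (p in c("anemone_mosaic", "deutero_mosaic")) {
    sim <- simulate_methylomes(synthetic_spec(p, n_cpgs = 30000, seed = 34))
    dom <- segment_domains(sim$stages$sperm, min_cov = 5)
    st <- attr(dom, "site_states")[chrom == "chr1"]
    truth <- data.table::data.table(pos = sim$truth$sites$pos,
                                    ts = sim$truth$truth[, "sperm"] >= 0.5)
    m <- merge(st, truth, by = "pos")
    expect_gte(mean(m$state == m$ts), 0.9)
  }
})

test_that("promoter density classes cut at the dataset quantiles with downward ties", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"), chrom = "chr1",
                  start = c(10000L, 20000L, 30000L, 40000L),
                  end = c(12000L, 22000L, 32000L, 42000L), strand = "+")
  ann <- annotation_set(g)   # promoters are 1.5 kb windows
  # densities 1,2,3,4 CpGs per promoter
  cpgs <- data.frame(chrom = "chr1",
                     pos = c(9200L,
                             19200L, 19300L,
                             29200L, 29300L, 29400L,
                             39200L, 39300L, 39400L, 39500L))
  cl <- promoter_density_classes(ann, cpgs)
  cl <- cl[match(c("a", "b", "c", "d"), cl$gene_id), ]
  expect_equal(cl$class, c("low", "intermediate", "intermediate", "high"))
  # equal densities everywhere: all intermediate
  cpge <- data.frame(chrom = "chr1", pos = c(9200L, 19200L, 29200L, 39200L))
  expect_true(all(promoter_density_classes(ann, cpge)$class == "intermediate"))
  # CGI-anchored promoters in a global genome are enriched in the high class
  sim <- simulate_methylomes(synthetic_spec("fish_global", n_cpgs = 20000,
                                            seed = 35))
  cls <- promoter_density_classes(sim$annotation,
                                  sim$truth$sites[, c("chrom", "pos")])
  cgi_genes <- sim$annotation$genes$gene_id[
    sim$annotation$genes$tss %in%
      sim$truth$sites$pos[sim$truth$sites$cgi]]
  frac_high_cgi <- mean(cls$class[cls$gene_id %in% cgi_genes] == "high")
  frac_high_rest <- mean(cls$class[!cls$gene_id %in% cgi_genes] == "high")
  expect_gt(frac_high_cgi, frac_high_rest)
})
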