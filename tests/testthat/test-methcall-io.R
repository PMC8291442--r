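test_that("cytosine reports parse with the 1-based to 0-based shift and keep zero-coverage sites", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("chr1\t10\t+\t3\t7\tCG",
               "chr1\t15\t+\t0\t0\tCG",
               "chr2\t5\t-\t2\t2\tCHH"), f)
  mt <- read_cytosine_report(f, sample_id = "s1")
  expect_equal(n_sites(mt), 3L)
  r <- mt$records[chrom == "chr1" & pos == 9L]
  expect_equal(r$n_meth, 3L)
  expect_equal(r$n_total, 10L)
  expect_equal(mt$records[chrom == "chr1" & pos == 14L]$n_total, 0L)
  expect_equal(mt$records[chrom == "chr2"]$context, "CHH")
})

test_that("malformed cytosine report lines are rejected with the line number", {
  f <- tempfile()
  writeLines(c("chr1\t10\t+\t3\t7\tCG", "chr1\tabc\t+\t1\t1\tCG"), f)
  expect_error(read_cytosine_report(f), "line 2")
})

test_that("both on-disk dialects round-trip through write and read", {
  mt <- make_mt(pos = c(9L, 14L, 100L), n_meth = c(3L, 0L, 10L),
                n_total = c(10L, 4L, 10L), sample_id = "rt")
  f1 <- tempfile(); f2 <- tempfile()
  write_cytosine_report(mt, f1)
  back1 <- read_cytosine_report(f1, sample_id = "rt")
  expect_equal(back1$records, mt$records)
  write_bedgraph_counts(mt, f2)
  back2 <- read_bedgraph_counts(f2, sample_id = "rt")
  expect_equal(back2$records[, .(chrom, pos, n_meth, n_total)],
               mt$records[, .(chrom, pos, n_meth, n_total)])
})

test_that("bedGraph counts win over an inconsistent percent column, with a warning", {
  f <- tempfile()
  writeLines("chr1\t9\t10\t100\t3\t7", f)
  expect_warning(mt <- read_bedgraph_counts(f), "counts take precedence")
  expect_equal(mt$records$n_meth / mt$records$n_total, 0.3)
  # consistent file parses silently; empty file gives an empty table
  writeLines("chr1\t9\t10\t30\t3\t7", f)
  expect_silent(read_bedgraph_counts(f))
  file.create(f2 <- tempfile())
  expect_equal(n_sites(read_bedgraph_counts(f2)), 0L)
})

test_that("table invariants are enforced", {
  expect_error(make_mt(1L, 5L, 3L), "n_meth <= n_total")
  expect_error(make_mt(1L, 0L, 3L, context = "CpG"), "context")
  expect_error(make_mt(c(1L, 1L), c(0L, 0L), c(3L, 3L)), "duplicate")
})

test_that("dyad merging pools counts onto the plus strand and conserves totals", {
  mt <- methylome_table(data.frame(
    chrom = "chr1", pos = c(9L, 10L, 50L, 60L),
    strand = c("+", "-", "+", "-"), context = "CG",
    n_meth = c(3L, 2L, 1L, 4L), n_total = c(10L, 10L, 5L, 8L)))
  m <- merge_cpg_dyads(mt)
  dyad <- m$records[pos == 9L]
  expect_equal(dyad$n_meth, 5L)
  expect_equal(dyad$n_total, 20L)
  expect_equal(dyad$strand, "+")
  # dyad ML equals the coverage-weighted mean of the strand MLs
  expect_equal(dyad$n_meth / dyad$n_total,
               (3 + 2) / (10 + 10))
  # lone sites unchanged (including a lone minus-strand site)
  expect_equal(m$records[pos == 50L, .(strand, n_meth, n_total)],
               data.table::data.table(strand = "+", n_meth = 1L, n_total = 5L))
  expect_equal(m$records[pos == 60L]$strand, "-")
  expect_equal(sum(m$records$n_meth), sum(mt$records$n_meth))
  expect_equal(sum(m$records$n_total), sum(mt$records$n_total))
})

test_that("dyad merging conserves genome-wide counts on simulated data with both strands", {
  set.seed(42)
  n <- 500
  pos <- sort(sample.int(50000, n))
  pos <- pos[diff(c(-10, pos)) > 1]            # avoid accidental adjacency
  both <- data.frame(
    chrom = "chr1",
    pos = c(pos, pos + 1L),
    strand = rep(c("+", "-"), each = length(pos)),
    context = "CG",
    n_meth = rbinom(2 * length(pos), 10, 0.3),
    n_total = 10L)
  mt <- methylome_table(both)
  m <- merge_cpg_dyads(mt)
  expect_equal(n_sites(m), length(pos))
  expect_equal(sum(m$records$n_meth), sum(both$n_meth))
  expect_equal(sum(m$records$n_total), sum(both$n_total))
})

test_that("coverage filtering applies the threshold and is idempotent", {
  mt <- make_mt(pos = 1:4 * 10L, n_meth = c(0L, 1L, 2L, 3L),
                n_total = c(0L, 4L, 5L, 30L))
  f5 <- filter_by_coverage(mt, 5L)
  expect_equal(n_sites(f5), 2L)
  expect_equal(n_sites(filter_by_coverage(mt, 1L)), 3L)
  expect_equal(filter_by_coverage(f5, 5L)$records, f5$records)
})

test_that("promoter windows follow the TSS, mirror on the minus strand and clip at zero", {
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                  start = c(5000L, 4000L, 300L), end = c(8000L, 5001L, 2000L),
                  strand = c("+", "-", "+"))
  ann <- annotation_set(g)
  prom <- make_promoters(ann, upstream = 1000, downstream = 500)$promoters
  expect_equal(unlist(prom[gene_id == "a", .(start, end)], use.names = FALSE),
               c(4000L, 5500L))
  expect_equal(unlist(prom[gene_id == "b", .(start, end)], use.names = FALSE),
               c(4500L, 6000L))
  expect_equal(unlist(prom[gene_id == "c", .(start, end)], use.names = FALSE),
               c(0L, 800L))
  g$strand[1] <- "*"
  expect_error(annotation_set(g), "strand")
})

test_that("gene annotation and gene sets read from disk and resolve against each other", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t2000\tgeneA\t0\t+",
               "chr1\t5000\t9000\tgeneB\t0\t-"), bed)
  g <- read_gene_annotation(bed)
  expect_equal(g$gene_id, c("geneA", "geneB"))
  expect_equal(g$start, c(100L, 5000L))
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t2000\t.\t+\t.\tID=geneA",
               "chr1\tsrc\tmRNA\t101\t2000\t.\t+\t.\tID=t1;Parent=geneA",
               "chr1\tsrc\tgene\t5001\t9000\t.\t-\t.\tID=geneB"), gff)
  g2 <- read_gene_annotation(gff)
  expect_equal(g2$start, c(100L, 5000L))   # 1-based closed -> 0-based half-open
  expect_equal(g2$end, c(2000L, 9000L))
  ann <- annotation_set(g)
  expect_equal(ann$genes[gene_id == "geneB"]$tss, 8999L)
  sets <- tempfile()
  writeLines(c("set_name\tcluster\tgene_id", "HOX\tHOXA\tgeneA"), sets)
  gs <- read_gene_sets(sets)
  expect_silent(annotation_set(g, gene_sets = gs))
  gs2 <- rbind(gs, data.frame(set_name = "HOX", cluster = "HOXA",
                              gene_id = "missing"))
  expect_error(annotation_set(g, gene_sets = gs2), "not present")
})
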