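test_that("the seven Venn regions enumerate membership patterns exactly", {
  vp <- venn_partition(candidate_sets(gcn = c("a", "b"), cc = c("b", "c"),
                                      wgcn = c("c", "d")))
  expect_equal(vp$regions$gcn_only, "a")
  expect_equal(vp$regions$cc_only, character(0))
  expect_equal(vp$regions$wgcn_only, "d")
  expect_equal(vp$regions$gcn_cc, "b")
  expect_equal(vp$regions$cc_wgcn, "c")
  expect_equal(vp$regions$gcn_wgcn, character(0))
  expect_equal(vp$regions$all_three, character(0))
  expect_equal(vp$union_size, 4L)

  same <- candidate_sets(letters[1:5], letters[1:5], letters[1:5])
  vp2 <- venn_partition(same)
  expect_equal(vp2$regions$all_three, letters[1:5])
  expect_equal(sum(lengths(vp2$regions)), 5L)
})

test_that("random partitions satisfy the inclusion-exclusion identities", {
  set.seed(30)
  pool <- sprintf("g%03d", 1:100)
  for (i in 1:20) {
    sets <- candidate_sets(gcn = sample(pool, sample(0:60, 1)),
                           cc = sample(pool, sample(0:60, 1)),
                           wgcn = sample(pool, sample(0:60, 1)))
    vp <- venn_partition(sets)
    r <- vp$regions
    all_genes <- unlist(r, use.names = FALSE)
    expect_equal(length(all_genes), length(unique(all_genes)))  # disjoint
    expect_equal(length(all_genes), vp$union_size)
    expect_equal(vp$union_size,
                 length(unique(c(sets$gcn, sets$cc, sets$wgcn))))
    # each original set is recovered from its four regions
    expect_setequal(c(r$gcn_only, r$gcn_cc, r$gcn_wgcn, r$all_three),
                    sets$gcn)
    expect_setequal(c(r$cc_only, r$gcn_cc, r$cc_wgcn, r$all_three),
                    sets$cc)
    expect_setequal(c(r$wgcn_only, r$gcn_wgcn, r$cc_wgcn, r$all_three),
                    sets$wgcn)
  }
})

snp_tab <- function(genes, region = "exon") {
  n <- length(genes)
  structure(data.frame(gene_id = genes, position = seq_len(n) %||% integer(),
                       ref = rep("A", n), alt = rep("G", n),
                       region_class = rep(region, length.out = n)),
            class = c("snp_table", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the SNP filter keeps exactly the evidence-bearing genes", {
  sets <- candidate_sets(gcn = c("a", "b"), cc = c("b", "c"),
                         wgcn = c("d"))
  none <- filter_by_snp(sets, snp_tab(character(0)))
  expect_equal(lengths(none[c("gcn", "cc", "wgcn", "combined")]),
               c(gcn = 0L, cc = 0L, wgcn = 0L, combined = 0L))
  all_ev <- filter_by_snp(sets, snp_tab(c("a", "b", "c", "d")))
  expect_equal(all_ev$gcn, sets$gcn)
  expect_equal(all_ev$combined, c("a", "b", "c", "d"))
  some <- filter_by_snp(sets, snp_tab(c("b", "d", "zz")))
  expect_equal(some$combined, c("b", "d"))
  # region-class restriction
  tab <- rbind(snp_tab("a", "promoter"), snp_tab("b", "intron"))
  class(tab) <- class(snp_tab("a"))
  promo <- filter_by_snp(sets, tab, region_classes = "promoter")
  expect_equal(promo$combined, "a")
})

test_that("SNP filtering on planted-only evidence is exact set algebra", {
  sim <- small_sim(seed = 2, snp_fraction_planted = 1,
                   snp_fraction_background = 0)
  fit <- saltnet(sim$combined)
  snps <- simulate_snp_table(sim$truth, rownames(sim$combined$values),
                             sim$config)
  filtered <- filter_by_snp(fit$candidates, snps)
  union <- unique(c(fit$candidates$gcn, fit$candidates$cc,
                    fit$candidates$wgcn))
  expect_setequal(filtered$combined,
                  intersect(union, sim$truth$planted_gene_ids))
})

test_that("interval filtering honors half-open BED overlap semantics", {
  ann <- structure(data.frame(
    gene_id = c("gIn", "gTouch", "gOut", "gChr2"),
    chromosome = c("chr1", "chr1", "chr1", "chr2"),
    start = c(150L, 200L, 500L, 150L),
    end = c(250L, 300L, 600L, 250L)),
    class = c("gene_annotation", "data.frame"))
  iv <- genomic_interval("chr1", 100, 200)
  kept <- filter_by_interval(c("gIn", "gTouch", "gOut", "gChr2"), ann, iv)
  expect_equal(kept, "gIn")   # 200 is excluded: half-open, no overlap
  within <- filter_by_interval("gIn", ann,
                               genomic_interval("chr1", 100, 300),
                               mode = "within")
  expect_equal(within, "gIn")
  expect_equal(filter_by_interval("gIn", ann,
                                  genomic_interval("chr1", 100, 200),
                                  mode = "within"), character(0))
  expect_warning(filter_by_interval(c("gIn", "nope"), ann, iv), "missing")
})

test_that("SNP and interval filters are contractive and commute", {
  set.seed(31)
  pool <- sprintf("g%03d", 1:60)
  ann <- structure(data.frame(
    gene_id = pool, chromosome = "chr1",
    start = seq(0, by = 1000, length.out = 60),
    end = seq(500, by = 1000, length.out = 60)),
    class = c("gene_annotation", "data.frame"))
  iv <- genomic_interval("chr1", 0, 20000)
  for (i in 1:10) {
    genes <- sample(pool, 30)
    snps <- snp_tab(sample(pool, 20))
    sets <- candidate_sets(gcn = genes, cc = genes, wgcn = genes)
    snp_then_iv <- filter_by_interval(filter_by_snp(sets, snps)$combined,
                                      ann, iv)
    iv_first <- filter_by_interval(genes, ann, iv)
    iv_then_snp <- filter_by_snp(
      candidate_sets(iv_first, iv_first, iv_first), snps)$combined
    expect_equal(snp_then_iv, iv_then_snp)
    expect_true(all(snp_then_iv %in% genes))   # contractive
  }
})

test_that("the config-driven pipeline runs end to end, deterministically", {
  dir <- withr::local_tempdir()
  sim <- small_sim(seed = 5, snp_fraction_planted = 1,
                   snp_fraction_background = 0.05)
  genes <- rownames(sim$combined$values)
  write_expression_matrix(sim$combined, file.path(dir, "counts.tsv"),
                          file.path(dir, "samples.tsv"))
  write_snp_table(simulate_snp_table(sim$truth, genes, sim$config),
                  file.path(dir, "snps.tsv"))
  iv <- genomic_interval("chr1", 10000, 40000, "QTL")
  write_gene_annotation(
    simulate_annotation(genes, iv, sim$truth, 1, seed = 5),
    file.path(dir, "genes.bed"))
  cfg <- list(counts = file.path(dir, "counts.tsv"),
              samples = file.path(dir, "samples.tsv"),
              snps = file.path(dir, "snps.tsv"),
              annotation = file.path(dir, "genes.bed"),
              interval = "chr1:10000-40000",
              out_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  fit <- run_pipeline(cfg_path)
  summary_path <- file.path(dir, "out", "run_summary.json")
  expect_true(file.exists(summary_path))
  js <- jsonlite::read_json(summary_path)
  expect_equal(sum(unlist(js$venn_regions)), js$counts$union)
  expect_true(all(unlist(js$final_genes) %in%
                    sim$truth$planted_gene_ids))
  # rerun is byte-identical
  first <- readLines(summary_path)
  run_pipeline(cfg_path)
  expect_identical(readLines(summary_path), first)
  # an empty SNP table empties the final list but the run completes
  write_snp_table(snp_tab(character(0)), file.path(dir, "snps.tsv"))
  fit2 <- run_pipeline(cfg_path)
  expect_equal(length(fit2$final_genes), 0L)
})
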