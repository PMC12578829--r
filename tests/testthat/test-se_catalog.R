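test_that("interval index honours half-open semantics", {
  idx <- build_interval_index(list(genomic_interval("chr1", 100, 200, "a")))
  expect_length(query_index(idx, "chr1", 150, 160), 1L)
  expect_length(query_index(idx, "chr1", 200, 300), 0L)  # abutting
  expect_length(query_index(idx, "chr1", 0, 100), 0L)
  expect_length(query_index(idx, "chr2", 150, 160), 0L)
  # "chr" prefix stripped on both sides
  expect_length(query_index(idx, "1", 150, 160), 1L)
  empty <- build_interval_index(list())
  expect_length(query_index(empty, "chr1", 0, 10), 0L)
})

test_that("index equals the brute-force scan on random instances", {
  set.seed(42)
  ivs <- rand_intervals(1000, chroms = c("chr1", "chr2", "chr3"))
  idx <- build_interval_index(ivs)
  for (q in 1:100) {
    chrom <- sample(c("chr1", "chr2", "chr3"), 1)
    s <- sample.int(9900, 1) - 1L
    e <- s + sample.int(300, 1)
    expect_identical(query_index(idx, chrom, s, e),
                     sort(bf_query(ivs, chrom, s, e)))
  }
})

test_that("gene_overlap matching follows the >= 1 bp half-open rule", {
  se <- list(genomic_interval("chr1", 100, 200, "SE1"))
  g_in <- list(gene_model("gA", "chr1", "+", 150, 250))
  g_out <- list(gene_model("gB", "chr1", "+", 200, 300))
  cat1 <- identify_se_lncrnas(se, g_in)
  expect_equal(cat1$entries$overlap_bp, 50L)
  expect_equal(cat1$se_lncrna_ids, "gA")
  cat2 <- identify_se_lncrnas(se, g_out)
  expect_length(cat2$se_lncrna_ids, 0L)
})

test_that("tss_window mode respects strand and window monotonicity", {
  se <- list(genomic_interval("chr1", 1000, 2000, "SE1"))
  # + strand gene: TSS at span start
  g_plus <- gene_model("gp", "chr1", "+", 2500, 3000)
  # - strand gene: TSS at span end - 1
  g_minus <- gene_model("gm", "chr1", "-", 0, 501)
  for (g in list(g_plus, g_minus)) {
    hit <- identify_se_lncrnas(se, list(g), mode = "tss_window",
                               window_bp = 600)
    mis <- identify_se_lncrnas(se, list(g), mode = "tss_window",
                               window_bp = 100)
    expect_equal(hit$se_lncrna_ids, g$gene_id)
    expect_length(mis$se_lncrna_ids, 0L)
  }
  # enlarging the window never removes an SE-lncRNA
  set.seed(7)
  se_r <- rand_intervals(30, prefix = "se")
  genes_r <- rand_genes(60)
  prev <- character(0)
  for (w in c(0, 50, 200, 1000, 5000)) {
    cur <- identify_se_lncrnas(se_r, genes_r, mode = "tss_window",
                               window_bp = w)$se_lncrna_ids
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("catalogue equals the brute-force double loop on random inputs", {
  set.seed(99)
  se <- rand_intervals(50, prefix = "se")
  genes <- rand_genes(100)
  got <- identify_se_lncrnas(se, genes)$entries
  got <- got[order(got$gene_id, got$se_name),
             c("gene_id", "se_name", "overlap_bp")]
  rownames(got) <- NULL
  want <- bf_catalog(se, genes)
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("disjoint chromosome sets give a warned empty catalogue", {
  se <- list(genomic_interval("chrX", 0, 100, "SE1"))
  g <- list(gene_model("g1", "chr1", "+", 0, 100))
  expect_warning(ct <- identify_se_lncrnas(se, g), "disjoint")
  expect_length(ct$se_lncrna_ids, 0L)
})

test_that("chromosome_density counts per chromosome in natural order", {
  se <- list(genomic_interval("chr1", 0, 100, "SE1"),
             genomic_interval("chr2", 0, 100, "SE2"),
             genomic_interval("chr10", 0, 100, "SE3"),
             genomic_interval("chrX", 0, 100, "SE4"))
  genes <- list(gene_model("a", "chr1", "+", 50, 150),
                gene_model("b", "chr1", "+", 10, 60),
                gene_model("c", "chr2", "+", 0, 30),
                gene_model("d", "chr10", "+", 500, 600))
  ct <- identify_se_lncrnas(se, genes)
  dens <- chromosome_density(ct, genes, se)
  expect_equal(dens$chrom, c("1", "2", "10", "X"))
  expect_equal(dens$n_se_lncrna, c(2L, 1L, 0L, 0L))
  expect_equal(dens$n_se, c(1L, 1L, 0L, 0L))
  # empty catalogue: all zeros
  ct0 <- identify_se_lncrnas(list(genomic_interval("chr2", 5000, 5100, "Z")),
                             list(gene_model("a", "chr2", "+", 0, 10)))
  d0 <- chromosome_density(ct0, genes, se)
  expect_true(all(d0$n_se_lncrna == 0L))
})

test_that("planted-overlap recovery is exact across overlap fractions", {
  for (f in c(0, 0.3, 1)) {
    cfg <- sim_config(seed = 11, overlap_fraction = f, n_genes = 60,
                      n_transcripts = 60)
    ann <- simulate_annotation(cfg)
    ct <- identify_se_lncrnas(ann$se, ann$genes)
    expect_setequal(ct$se_lncrna_ids, ann$truth$se_lncrna_ids)
    expect_length(ct$se_lncrna_ids, round(f * 60))
  }
})
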