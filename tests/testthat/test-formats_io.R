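test_that("read_bed maps fields, skips non-data lines and validates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment",
               "track name=se",
               "chr1\t100\t200\tSE1",
               "chr2\t40\t90"), f)
  ivs <- read_bed(f)
  expect_length(ivs, 2L)
  expect_equal(ivs[[1]]$chrom, "chr1")
  expect_equal(ivs[[1]]$start, 100L)
  expect_equal(ivs[[1]]$end, 200L)
  expect_equal(ivs[[1]]$name, "SE1")
  expect_match(ivs[[2]]$name, "^bed_")

  writeLines("chr2\t5\t5", f)
  expect_error(read_bed(f), "start >= end at line 1")
  writeLines("chr2\tfive\t10", f)
  expect_error(read_bed(f), "non-integer")
  writeLines(character(0), f)
  expect_error(read_bed(f), "empty")
  writeLines(c("chr1\t1\t2\tA", "chr1\t5\t9\tA"), f)
  expect_error(read_bed(f), "duplicate")
})

test_that("read_gtf converts 1-based closed to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\tgene\t101\t200\t.\t+\t.\tgene_id "g1"; gene_biotype "lncRNA";',
    'chr1\tx\texon\t101\t150\t.\t+\t.\tgene_id "g1"; gene_biotype "lncRNA";',
    'chr1\tx\tgene\t300\t400\t.\t-\t.\tgene_id "g2"; gene_biotype "protein_coding";'),
    f)
  g <- read_gtf(f, biotype_filter = "any")
  expect_length(g, 2L)
  g1 <- g[[which(vapply(g, `[[`, "", "gene_id") == "g1")]]
  expect_equal(g1$span$start, 100L)
  expect_equal(g1$span$end, 200L)
  expect_equal(g1$exons[[1]]$start, 100L)
  expect_equal(g1$exons[[1]]$end, 150L)
  expect_length(read_gtf(f, biotype_filter = "lncRNA"), 1L)
  # gene without exon lines gets a single span exon
  g2 <- g[[which(vapply(g, `[[`, "", "gene_id") == "g2")]]
  expect_length(g2$exons, 1L)
  expect_equal(g2$exons[[1]]$start, g2$span$start)

  writeLines('chr1\tx\tgene\t101\t200\t.\t+\t.\tfoo "bar";', f)
  expect_error(read_gtf(f), "gene_id")
  writeLines(c(
    'chr1\tx\tgene\t101\t200\t.\t+\t.\tgene_id "g1";',
    'chr1\tx\texon\t50\t60\t.\t+\t.\tgene_id "g1";'), f)
  expect_error(read_gtf(f), "exon outside gene span")
})

test_that("a BED line and a GTF gene describing one locus agree internally", {
  fb <- withr::local_tempfile(fileext = ".bed")
  fg <- withr::local_tempfile(fileext = ".gtf")
  writeLines("chr3\t500\t800\tL1", fb)
  writeLines('chr3\tx\tgene\t501\t800\t.\t+\t.\tgene_id "L1";', fg)
  iv <- read_bed(fb)[[1]]
  gm <- read_gtf(fg)[[1]]
  expect_equal(c(iv$start, iv$end), c(gm$span$start, gm$span$end))
})

test_that("read_fasta normalises case and U, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x desc", "acgu"), f)
  expect_equal(unname(read_fasta(f)["x"]), "ACGT")
  writeLines(c(">x", "ACGT", ">x", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">x", "ACXT"), f)
  expect_error(read_fasta(f), "invalid characters")
})

test_that("matrix and clinical readers validate their invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t4\t5\t6"), f)
  em <- read_matrix(f)
  expect_equal(dim(em$values), c(2L, 3L))
  writeLines(c("feature\ts1", "g1\t-2"), f)
  expect_error(read_matrix(f, scale = "raw"), "negative")
  writeLines(c("sample\ttime\tevent", "s1\t0\t1"), f)
  expect_error(read_clinical(f), "time")
  writeLines(c("sample\ttime\tevent", "s1\t5\t2"), f)
  expect_error(read_clinical(f), "event")
})

test_that("write-then-read round-trips every format on random fixtures", {
  set.seed(401)
  td <- withr::local_tempdir()
  for (rep in 1:3) {
    ivs <- rand_intervals(20, prefix = sprintf("se%d_", rep))
    f <- file.path(td, "rt.bed")
    write_bed(ivs, f)
    expect_equal(read_bed(f), ivs)

    genes <- rand_genes(10)
    fg <- file.path(td, "rt.gtf")
    write_gtf(genes, fg)
    back <- read_gtf(fg, biotype_filter = "lncRNA")
    ids <- vapply(back, `[[`, "", "gene_id")
    expect_setequal(ids, vapply(genes, `[[`, "", "gene_id"))
    for (g in genes) {
      b <- back[[which(ids == g$gene_id)]]
      expect_equal(b$span, g$span)
      expect_equal(length(b$exons), length(g$exons))
    }

    seqs <- setNames(vapply(1:5, function(i) rand_seq(sample(50:200, 1)),
                            character(1)), paste0("t", 1:5))
    ff <- file.path(td, "rt.fa")
    write_fasta(seqs, ff)
    expect_equal(read_fasta(ff), seqs)

    M <- matrix(round(abs(rnorm(12)), 6), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    em <- expression_matrix(M, scale = "raw")
    fm <- file.path(td, "rt.tsv")
    write_matrix(em, fm)
    expect_equal(read_matrix(fm, scale = "raw")$values, em$values)

    clin <- data.frame(sample = paste0("s", 1:6),
                       time = round(runif(6, 1, 10), 4),
                       event = rbinom(6, 1, 0.5),
                       subtype = sample(c("Basal", "LumA"), 6, TRUE),
                       stringsAsFactors = FALSE)
    class(clin) <- c("selnc_clinical", "data.frame")
    fc <- file.path(td, "rt_clin.tsv")
    write_clinical(clin, fc)
    expect_equal(as.data.frame(read_clinical(fc)), as.data.frame(clin))
  }
})

test_that("interval and gene constructors enforce invariants", {
  expect_error(genomic_interval("chr1", 10, 10, "a"), "invalid interval")
  expect_error(genomic_interval("", 0, 5, "a"), "non-empty")
  expect_error(gene_model("g", "chr1", "+", 100, 200,
                          exons = list(genomic_interval("chr1", 50, 60))),
               "exon outside")
  expect_error(gene_model("g", "chr1", "+", 0, 100, exons = list(
    genomic_interval("chr1", 0, 50), genomic_interval("chr1", 40, 80))),
    "overlapping exons")
  expect_error(gene_model("g", "chr1", ".", 0, 100), "strand")
})
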