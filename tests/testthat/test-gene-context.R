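test_that("gene models derive introns and UTRs from GFF3", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(gff)
  models <- build_gene_models(gff)
  expect_length(models, 2L)
  a <- models[["geneA"]]
  expect_identical(a$strand, "+")
  expect_identical(BiocGenerics::start(a$introns), 1501L)
  expect_identical(BiocGenerics::end(a$introns), 2000L)
  expect_identical(BiocGenerics::start(a$utr5), 1001L)
  expect_identical(BiocGenerics::end(a$utr5), 1200L)
  expect_identical(BiocGenerics::start(a$utr3), 2801L)
  expect_identical(BiocGenerics::end(a$utr3), 3000L)
  # single exon == CDS: no introns, no UTRs
  b <- models[["geneB"]]
  expect_length(b$introns, 0L)
  expect_length(b$utr5, 0L)
  expect_length(b$utr3, 0L)
})

test_that("UTR ends swap on the minus strand", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t3000\t.\t-\t.\tID=geneC",
    "chr1\ttest\tmRNA\t1001\t3000\t.\t-\t.\tID=geneC.1;Parent=geneC",
    "chr1\ttest\texon\t1001\t1500\t.\t-\t.\tID=e1;Parent=geneC.1",
    "chr1\ttest\texon\t2001\t3000\t.\t-\t.\tID=e2;Parent=geneC.1",
    "chr1\ttest\tCDS\t1201\t1500\t.\t-\t0\tID=c;Parent=geneC.1",
    "chr1\ttest\tCDS\t2001\t2800\t.\t-\t0\tID=c;Parent=geneC.1")
  writeLines(lines, gff)
  m <- build_gene_models(gff)[["geneC"]]
  expect_identical(BiocGenerics::start(m$utr3), 1001L)  # 3' end now left
  expect_identical(BiocGenerics::start(m$utr5), 2801L)
})

test_that("a gene without an mRNA child is skipped with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t100\t900\t.\t+\t.\tID=orphan",
               "chr1\ttest\tgene\t2000\t2900\t.\t+\t.\tID=ok",
               "chr1\ttest\tmRNA\t2000\t2900\t.\t+\t.\tID=ok.1;Parent=ok",
               "chr1\ttest\texon\t2000\t2900\t.\t+\t.\tID=ok.e;Parent=ok.1",
               "chr1\ttest\tCDS\t2000\t2900\t.\t+\t0\tID=ok.c;Parent=ok.1"),
             gff)
  expect_warning(models <- build_gene_models(gff),
                 class = "orthotale_warning_gff")
  expect_identical(names(models), "ok")
})

test_that("sites are classified by feature precedence and flank side", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(gff)
  genes <- build_gene_models(gff)

  # inside geneA's CDS (1-based 1250 => 0-based 1249)
  ann <- classify_site(site_row("chr1", 1249), genes)
  expect_identical(ann$category[ann$gene_id == "geneA"], "CDS")
  expect_identical(ann$distance_bp[ann$gene_id == "geneA"], 0L)
  # in the intron
  ann2 <- classify_site(site_row("chr1", 1600), genes)
  expect_identical(ann2$category[ann2$gene_id == "geneA"], "intron")
  # in the 5' UTR
  ann3 <- classify_site(site_row("chr1", 1050), genes)
  expect_identical(ann3$category[ann3$gene_id == "geneA"], "5'UTR")
  # 1.7 kbp upstream of the sense-strand gene start (shifted copy so the
  # flank fits on the contig): gene start 3001, site midpoint 1301
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(gff2, offset = 2000L)
  genes2 <- build_gene_models(gff2)
  ann4 <- classify_site(site_row("chr1", 1291), genes2)
  expect_identical(ann4$category[ann4$gene_id == "geneA"], "upstream")
  expect_identical(ann4$distance_bp[ann4$gene_id == "geneA"], 1700L)
  # ~2 kbp 3' of geneA's end: downstream of the nearest gene
  dn <- site_row("chr1", 5000)
  ann5 <- classify_site(dn, genes)
  expect_identical(ann5$category[ann5$gene_id == "geneA"], "downstream")
  # 8 kbp from everything -> unassociated
  far <- site_row("chr1", 11000)
  ann6 <- classify_site(far, genes)
  expect_identical(ann6$category, "unassociated")
  expect_true(is.na(ann6$gene_id))
})

test_that("only the nearest gene claims the flank; farther genes read intergenic", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  # two plus-strand genes 6 kb apart; a site between them is downstream of
  # the left gene (nearest) and intergenic w.r.t. the right one
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1000\t2000\t.\t+\t.\tID=left",
    "chr1\ttest\tmRNA\t1000\t2000\t.\t+\t.\tID=left.1;Parent=left",
    "chr1\ttest\texon\t1000\t2000\t.\t+\t.\tID=le;Parent=left.1",
    "chr1\ttest\tCDS\t1000\t2000\t.\t+\t0\tID=lc;Parent=left.1",
    "chr1\ttest\tgene\t8000\t9000\t.\t+\t.\tID=right",
    "chr1\ttest\tmRNA\t8000\t9000\t.\t+\t.\tID=right.1;Parent=right",
    "chr1\ttest\texon\t8000\t9000\t.\t+\t.\tID=re;Parent=right.1",
    "chr1\ttest\tCDS\t8000\t9000\t.\t+\t0\tID=rc;Parent=right.1"), gff)
  genes <- build_gene_models(gff)
  ann <- classify_site(site_row("chr1", 3500), genes)  # midpoint ~3510
  expect_identical(ann$category[ann$gene_id == "left"], "downstream")
  expect_identical(ann$category[ann$gene_id == "right"], "intergenic")
})

test_that("classification is invariant under a coordinate shift", {
  for (offset in c(0L, 5000L)) {
    gff <- withr::local_tempfile(fileext = ".gff3")
    write_toy_gff3(gff, offset = offset)
    genes <- build_gene_models(gff)
    ann <- classify_site(site_row("chr1", 1249 + offset), genes)
    expect_identical(ann$category[ann$gene_id == "geneA"], "CDS")
    ann2 <- classify_site(site_row("chr1", 100 + offset), genes)
    expect_identical(ann2$category[ann2$gene_id == "geneA"], "upstream")
  }
})

test_that("category summaries count genes once under their top category", {
  ann <- data.frame(
    site_id = c("s1", "s2", "s3", "s4"),
    chrom = "chr1", start = 0L, end = 19L,
    gene_id = c("g1", "g1", "g2", NA),
    category = c("CDS", "upstream", "upstream", "unassociated"),
    distance_bp = c(0L, 500L, 700L, NA))
  tab <- summarize_categories(ann)
  expect_identical(tab$n_genes[tab$category == "CDS"], 1L)
  expect_identical(tab$n_genes[tab$category == "upstream"], 1L)  # g2 only
  tab_all <- summarize_categories(ann, mode = "all")
  expect_identical(tab_all$n_genes[tab_all$category == "upstream"], 2L)
  # expressed-set intersection
  tab_e <- summarize_categories(ann, expressed = "g2", up = character(0))
  expect_identical(tab_e$n_expressed[tab_e$category == "CDS"], 0L)
  expect_identical(tab_e$n_expressed[tab_e$category == "upstream"], 1L)
  expect_identical(tab_e$n_up, c(0L, 0L))
  # empty annotations give an empty table
  expect_identical(nrow(summarize_categories(ann[0, ])), 0L)
})

test_that("category tables round-trip through the TSV writer", {
  tab <- data.frame(category = c("CDS", "upstream"), n_genes = c(3L, 5L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_category_table(tab, f)
  expect_identical(read_category_table(f), tab)
})
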