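test_that("promoter windows are strand-aware, inclusive and clipped at the chromosome start", {
  g_plus <- make_genes("gA", "chr1", 10001, 12000, "+")
  expect_equal(promoter_interval(g_plus, 5000)[, c("start", "end")],
               data.frame(start = 5001L, end = 10000L))
  g_minus <- make_genes("gB", "chr1", 10001, 12000, "-")
  expect_equal(promoter_interval(g_minus, 5000)[, c("start", "end")],
               data.frame(start = 12001L, end = 17000L))
  g_edge <- make_genes("gC", "chr1", 3000, 4000, "+")
  expect_equal(promoter_interval(g_edge, 5000)[, c("start", "end")],
               data.frame(start = 1L, end = 2999L))
  g_first <- make_genes("gD", "chr1", 1, 500, "+")
  pw <- promoter_interval(g_first, 5000)
  expect_true(pw$start > pw$end)  # empty window
})

test_that("hand-built fixtures assign genic and promoter hits as expected", {
  genes <- make_genes(c("gA", "gB"), "chr1", c(10001, 1000), c(12000, 2000),
                      c("+", "-"))
  hits <- make_hits("chr1", c(10500, 9000, 10700, 2500),
                    c("TBN", "TBN", "TBN", "Starch"))
  tm <- assign_snps_to_genes(genes, hits, include_promoters = TRUE)
  df <- as.data.frame(tm)
  # genic containment
  expect_true(any(df$gene == "gA" & df$region_class == "genic"))
  # promoter hit at 9000 in [5001, 10000]
  expect_true(any(df$gene == "gA" & df$region_class == "promoter"))
  # duplicate-trait hits collapse to one nonredundant trait
  expect_equal(sum(df$gene == "gA" & df$trait == "TBN" & df$region_class == "genic"), 1)
  expect_equal(unique(df$trait[df$gene == "gA"]), "TBN")
  # minus-strand promoter of gB is [2001, 7000]
  expect_true(any(df$gene == "gB" & df$trait == "Starch" & df$region_class == "promoter"))

  tm_genic <- assign_snps_to_genes(genes, hits, include_promoters = FALSE)
  dfg <- as.data.frame(tm_genic)
  expect_false("gB" %in% dfg$gene)
  expect_false(any(dfg$region_class == "promoter"))
})

test_that("a hit inside one gene body and another gene's promoter assigns to both", {
  genes <- make_genes(c("gA", "gB"), "chr1", c(100, 1200), c(1000, 2000),
                      c("+", "+"))
  # 900 is inside gA's body and inside gB's promoter [1, 1199]
  tm <- assign_snps_to_genes(genes, make_hits("chr1", 900, "TBN"))
  df <- as.data.frame(tm)
  expect_setequal(df$gene, c("gA", "gB"))
  expect_equal(df$region_class[df$gene == "gA"], "genic")
  expect_equal(df$region_class[df$gene == "gB"], "promoter")
})

test_that("interval assignment equals the brute-force containment oracle", {
  set.seed(99)
  n <- 300
  genes <- make_genes(sprintf("g%03d", 1:n),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      start = s <- sample(1:500000, n),
                      end = s + sample(200:5000, n, replace = TRUE),
                      strand = sample(c("+", "-"), n, replace = TRUE))
  genes <- genes[!duplicated(genes$pan_gene_id), ]
  hits <- make_hits(sample(c("chr1", "chr2", "chrX"), 300, replace = TRUE),
                    sample(1:520000, 300, replace = TRUE),
                    sample(c("t1", "t2", "t3"), 300, replace = TRUE))
  for (ip in c(TRUE, FALSE)) {
    got <- as.data.frame(assign_snps_to_genes(genes, hits, include_promoters = ip))
    want <- brute_force_assign(genes, hits, include_promoters = ip)
    expect_identical(got[, c("gene", "trait", "region_class")], want)
  }
  got <- assign_snps_to_genes(genes, hits)
  expect_equal(attr(got, "n_unmapped_chrom"), sum(hits$chrom == "chrX"))
})

test_that("the promoter-inclusive map is a superset of the genic-only map", {
  set.seed(7)
  n <- 150
  genes <- make_genes(sprintf("g%03d", 1:n), "chr1",
                      s <- sample(1:200000, n),
                      s + sample(100:3000, n, replace = TRUE),
                      sample(c("+", "-"), n, replace = TRUE))
  hits <- make_hits("chr1", sample(1:210000, 200, replace = TRUE),
                    sample(c("t1", "t2"), 200, replace = TRUE))
  with_p <- as.data.frame(assign_snps_to_genes(genes, hits, include_promoters = TRUE))
  without_p <- as.data.frame(assign_snps_to_genes(genes, hits, include_promoters = FALSE))
  key <- function(d) paste(d$gene, d$trait)
  expect_true(all(key(without_p) %in% key(with_p)))
  expect_true(all(unique(without_p$gene) %in% unique(with_p$gene)))
})

test_that("trait maps merge across genomes by pan-gene union", {
  m1 <- assign_snps_to_genes(make_genes("gA", "chr1", 100, 200, "+", "g1"),
                             make_hits("chr1", 150, "TBN"))
  m2 <- assign_snps_to_genes(make_genes(c("gA", "gB"), "chr1", c(100, 6000),
                                        c(200, 6100), c("+", "+"), "g2"),
                             make_hits("chr1", c(150, 6050), c("Starch", "TBN")))
  merged <- merge_trait_maps(list(m1, m2))
  sets <- trait_sets(merged)
  expect_equal(sets$gA, c("Starch", "TBN"))
  expect_equal(sets$gB, "TBN")
})
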