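test_that("union of per-genome networks records genome sets and occurrences", {
  e_g1 <- make_edges(c("A", "C"), c("B", "D"))
  e_g2 <- make_edges(c("B", "E"), c("A", "F"))   # (B,A) == (A,B)
  e_g3 <- make_edges("A", "B")
  pan <- union_networks(list(g1 = e_g1, g2 = e_g2, g3 = e_g3))
  ab <- pan$edges[pan$edges$gene_a == "A" & pan$edges$gene_b == "B", ]
  expect_equal(ab$occurrence, 3L)
  expect_equal(ab$genomes, "g1,g2,g3")
  expect_equal(pan$edges$occurrence[pan$edges$gene_a == "C"], 1L)

  # disjoint edge sets: pan size is the sum of sizes
  d1 <- make_edges(c("A", "C"), c("B", "D"))
  d2 <- make_edges(c("E", "G"), c("F", "H"))
  expect_equal(nrow(union_networks(list(g1 = d1, g2 = d2))$edges), 4)

  # identical edge sets across G genomes: every occurrence = G
  same <- make_edges(c("A", "C"), c("B", "D"))
  pan_same <- union_networks(list(g1 = same, g2 = same, g3 = same, g4 = same))
  expect_true(all(pan_same$edges$occurrence == 4L))

  expect_error(union_networks(list()), "at least one genome")
  expect_error(union_networks(list(make_edges("A", "B"))), "named")
})

test_that("classification reproduces the hand-computed 100-edge example", {
  # occurrences: 1 edge in 26 genomes, 4 in 20, 45 in 5, 50 in 1
  occ <- c(26L, rep(20L, 4), rep(5L, 45), rep(1L, 50))
  genes <- sprintf("g%03d", seq_len(200))
  edges <- data.frame(
    gene_a = genes[seq_along(occ) * 2 - 1],
    gene_b = genes[seq_along(occ) * 2],
    occurrence = occ,
    genomes = vapply(occ, function(o)
      paste(sprintf("G%02d", seq_len(o)), collapse = ","), character(1)),
    category = NA_character_, stringsAsFactors = FALSE)
  pan <- structure(list(edges = edges, genomes = sprintf("G%02d", 1:26)),
                   class = "pan_network")
  pan <- classify_edges(pan, core_frac = 0.01, nearcore_frac = 0.05)
  tab <- table(pan$edges$category)
  expect_equal(as.integer(tab[c("core", "near-core", "dispensable", "private")]),
               c(1L, 4L, 45L, 50L))
  expect_equal(unique(pan$edges$occurrence[pan$edges$category == "core"]), 26L)
  expect_equal(unique(pan$edges$occurrence[pan$edges$category == "near-core"]), 20L)
})

test_that("occurrence-1 edges are always private; all-private networks degenerate cleanly", {
  pan <- random_pan(50, n_genomes = 1, seed = 3)
  pan <- classify_edges(pan)
  expect_true(all(pan$edges$category == "private"))

  expect_error(classify_edges(random_pan(10, 3, 1), core_frac = 0.05,
                              nearcore_frac = 0.05), "core_frac")
})

test_that("partition and level-monotonicity hold on random occurrence histograms", {
  for (seed in 1:60) {
    pan <- classify_edges(random_pan(n_edges = 40 + (seed %% 7) * 30,
                                     n_genomes = 2 + (seed %% 9), seed = seed))
    e <- pan$edges
    # partition: every edge exactly one category, counts sum to total
    expect_false(anyNA(e$category))
    expect_equal(sum(table(e$category)), nrow(e))
    # private iff occurrence 1
    expect_true(all((e$category == "private") == (e$occurrence == 1L)))
    # threshold discipline on the realized core fraction
    expect_lte(sum(e$category == "core") / nrow(e), 0.01)
    # level monotonicity: core >= near-core >= dispensable occurrences
    occ_core <- e$occurrence[e$category == "core"]
    occ_nc <- e$occurrence[e$category == "near-core"]
    occ_disp <- e$occurrence[e$category == "dispensable"]
    if (length(occ_core) && length(occ_nc)) expect_gte(min(occ_core), max(occ_nc))
    if (length(occ_nc) && length(occ_disp)) expect_gte(min(occ_nc), max(occ_disp))
    # near-core includes the crossing level: core+near-core reaches 5%
    # whenever enough multi-genome edges exist below it
    frac_cnc <- sum(e$category %in% c("core", "near-core")) / nrow(e)
    frac_multi <- sum(e$occurrence > 1) / nrow(e)
    expect_gte(frac_cnc, min(0.05, frac_multi) - 1e-12)
  }
})

test_that("strict core keeps only all-genome edges", {
  pan <- random_pan(200, n_genomes = 4, seed = 10)
  strict <- classify_edges(pan, strict_core = TRUE)
  e <- strict$edges
  expect_true(all(e$occurrence[e$category == "core"] == 4L))
  expect_true(all(e$category[e$occurrence == 4L] == "core"))
})

test_that("category summary counts genes per category with shared genes counted in each", {
  edges <- data.frame(
    gene_a = c("A", "A"), gene_b = c("B", "C"),
    occurrence = c(3L, 1L), genomes = c("g1,g2,g3", "g1"),
    category = c("core", "private"), stringsAsFactors = FALSE)
  pan <- structure(list(edges = edges, genomes = c("g1", "g2", "g3")),
                   class = "pan_network")
  cs <- category_summary(pan)
  tab <- cs$table
  expect_equal(tab$n_genes[tab$category == "core"], 2)
  expect_equal(tab$n_genes[tab$category == "private"], 2)
  expect_equal(tab$n_genes[tab$category == "pan"], 3)   # A shared
  expect_equal(sum(tab$n_edges[tab$category != "pan"]),
               tab$n_edges[tab$category == "pan"])
  expect_equal(cs$private_per_genome[["g1"]], 1L)
  expect_equal(cs$occurrence_histogram$n_edges[cs$occurrence_histogram$occurrence == 3], 1L)

  bad <- pan
  bad$edges$category[1] <- NA
  expect_error(category_summary(bad), "unclassified")
})

test_that("growth curve is monotone in expectation and hits exact endpoints", {
  pan <- classify_edges(random_pan(300, n_genomes = 6, seed = 42))
  gc <- growth_curve(pan, n_reps = 30, seed = 9)
  expect_equal(nrow(gc), 6)
  expect_true(all(diff(gc$pan_mean) >= 0))
  expect_equal(gc$pan_mean[6], nrow(pan$edges))  # full panel = whole pan
  expect_equal(gc$pan_sd[6], 0)
  # determinism under the seed
  gc2 <- growth_curve(pan, n_reps = 30, seed = 9)
  expect_identical(gc, gc2)
})

test_that("print and summary methods report the classified pan-network", {
  pan <- classify_edges(random_pan(80, n_genomes = 5, seed = 2))
  expect_output(print(pan), "genomes: 5")
  expect_output(print(pan), "core")
  s <- summary(pan)
  expect_named(s, c("table", "occurrence_histogram", "private_per_genome"))
})
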