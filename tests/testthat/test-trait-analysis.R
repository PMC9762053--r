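# A small classified pan-network plus trait map used across the blocks.
toy_pan <- function() {
  edges <- data.frame(
    gene_a = c("A", "A", "B", "D", "F"),
    gene_b = c("B", "C", "C", "E", "G"),
    occurrence = c(5L, 5L, 2L, 1L, 1L),
    genomes = c("g1,g2,g3,g4,g5", "g1,g2,g3,g4,g5", "g1,g2", "g3", "g4"),
    category = c("core", "core", "dispensable", "private", "private"),
    stringsAsFactors = FALSE)
  structure(list(edges = edges, genomes = sprintf("g%d", 1:5)),
            class = "pan_network")
}

toy_map <- function() {
  structure(data.frame(
    gene = c("A", "B", "B", "C", "D", "E", "F", "G"),
    trait = c("TBN", "TBN", "Starch", "TBN", "Starch", "Starch", "Starch", "TBN"),
    region_class = "genic", stringsAsFactors = FALSE),
    class = c("trait_gene_map", "data.frame"))
}

test_that("trait subnetworks apply the both-endpoint rule", {
  sub <- trait_subnetwork(toy_pan(), toy_map(), "TBN")
  # A-B, A-C, B-C qualify (all endpoints TBN); D-E, F-G do not (F lacks TBN)
  expect_equal(nrow(sub$edges), 3)
  expect_setequal(sub$nodes, c("A", "B", "C"))
  # B carries Starch too, but its partners for Starch are not Starch genes
  sub_starch <- trait_subnetwork(toy_pan(), toy_map(), "Starch")
  expect_equal(nrow(sub_starch$edges), 1)   # only D-E
  expect_setequal(sub_starch$nodes, c("D", "E"))
  expect_error(trait_subnetwork(toy_pan(), toy_map(), "Oil"), "known traits")
})

test_that("category restriction filters subnetwork edges monotonically", {
  all_tbn <- trait_subnetwork(toy_pan(), toy_map(), "TBN")
  core_tbn <- trait_subnetwork(toy_pan(), toy_map(), "TBN", category = "core")
  key <- function(e) paste(e$gene_a, e$gene_b)
  expect_true(all(key(core_tbn$edges) %in% key(all_tbn$edges)))
  expect_equal(nrow(core_tbn$edges), 2)
  empty <- trait_subnetwork(toy_pan(), toy_map(), "Starch", category = "core")
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$nodes), 0)
})

test_that("degrees, hubs and the handshake identity behave on canonical topologies", {
  triangle <- list(edges = make_edges(c("A", "A", "B"), c("B", "C", "C")))
  dr <- node_degrees(triangle)
  expect_true(all(dr$degrees$degree == 2))
  expect_setequal(dr$hubs, c("A", "B", "C"))

  star <- list(edges = make_edges(rep("H", 8), sprintf("L%d", 1:8)))
  ds <- node_degrees(star)
  expect_equal(ds$degrees$degree[ds$degrees$gene == "H"], 8)
  expect_equal(hub_genes(star), "H")

  expect_equal(nrow(node_degrees(list(edges = make_edges(character(0), character(0))))$degrees), 0)

  # handshake: sum of degrees = 2 x edges, on random subnetworks
  for (seed in 1:10) {
    pan <- classify_edges(random_pan(60, 4, seed))
    dr <- node_degrees(list(edges = pan$edges))
    expect_equal(sum(dr$degrees$degree), 2 * nrow(pan$edges))
  }
})

test_that("per-trait category tables are consistent with the pan partition", {
  tab <- trait_category_table(toy_pan(), toy_map())
  tbn <- tab[tab$trait == "TBN", ]
  expect_equal(tbn$core_e + tbn$near_core_e + tbn$dispensable_e + tbn$private_e,
               tbn$pan_e)
  expect_equal(tbn$pan_n, 3)
  starch <- tab[tab$trait == "Starch", ]
  expect_equal(starch$pan_e, 1)
  expect_equal(starch$private_e, 1)
})

test_that("trait representation finds planted category preferences", {
  rep_out <- trait_representation(toy_pan(), toy_map())
  pr <- rep_out$proportions
  # TBN covers all 3 core genes; Starch none of them
  expect_equal(pr$proportion[pr$trait == "TBN" & pr$category == "core"], 1)
  expect_equal(pr$proportion[pr$trait == "Starch" & pr$category == "core"], 0)
  # Starch dominates private (D,E of D,E,F,G)
  expect_equal(pr$proportion[pr$trait == "Starch" & pr$category == "private"], 0.5)
  expect_equal(pr$proportion[pr$trait == "TBN" & pr$category == "private"], 0)
  expect_equal(rep_out$top_traits$core, "TBN")
  expect_equal(rep_out$top_traits$private, "Starch")
  # shares within a category sum to one where any trait is represented
  s <- tapply(pr$share_within_category, pr$category, sum)
  expect_true(all(abs(s[s > 0] - 1) < 1e-12))

  # single trait covering all genes: proportion 1 in every nonempty category
  map_all <- structure(data.frame(
    gene = c("A", "B", "C", "D", "E", "F", "G"), trait = "only",
    region_class = "genic", stringsAsFactors = FALSE),
    class = c("trait_gene_map", "data.frame"))
  pr_all <- trait_representation(toy_pan(), map_all)$proportions
  expect_true(all(pr_all$proportion[pr_all$category_genes > 0] == 1))
})

test_that("pleiotropic genes and focal co-occurrence match hand enumeration", {
  tm <- structure(data.frame(
    gene = c("g1", "g1", "g1", "g2", "g2", "g3"),
    trait = c("Starch", "PH", "EH", "Starch", "PH", "Starch"),
    region_class = "genic", stringsAsFactors = FALSE),
    class = c("trait_gene_map", "data.frame"))
  out <- pleiotropic_genes(tm, min_traits = 2, focal_trait = "Starch")
  expect_setequal(out$genes$gene, c("g1", "g2"))
  expect_equal(out$genes$n_traits[out$genes$gene == "g1"], 3)
  expect_equal(out$n_focal_pleiotropic, 2)
  # PH co-occurs with Starch in g1 and g2; EH only in g1
  expect_equal(out$focal_table$n_genes[out$focal_table$trait == "PH"], 2)
  expect_equal(out$focal_table$n_genes[out$focal_table$trait == "EH"], 1)
  # single-trait genes excluded
  expect_false("g3" %in% out$genes$gene)
})
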