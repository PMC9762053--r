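# Shared fixture builders and independent oracles.

make_genes <- function(pan_gene_id, chrom, start, end, strand,
                       genome_id = "g1") {
  data.frame(pan_gene_id = pan_gene_id, genome_id = genome_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

make_hits <- function(chrom, pos, trait) {
  data.frame(chrom = chrom, pos = as.integer(pos), trait = trait,
             stringsAsFactors = FALSE)
}

make_edges <- function(a, b, ...) {
  data.frame(gene_a = a, gene_b = b, ..., stringsAsFactors = FALSE)
}

# Brute-force per-pair correlation screen: the oracle for build_network.
brute_force_network <- function(mat, r_min = 0.9, p_max = 0.01,
                                absolute_r = FALSE) {
  genes <- rownames(mat)
  sds <- apply(mat, 1, sd)
  genes <- genes[sds > 0]
  rows <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      ct <- suppressWarnings(cor.test(mat[genes[i], ], mat[genes[j], ]))
      r <- unname(ct$estimate)
      ok_r <- if (absolute_r) abs(r) > r_min else r > r_min
      if (ok_r && ct$p.value < p_max) {
        a <- min(genes[i], genes[j]); b <- max(genes[i], genes[j])
        rows[[length(rows) + 1L]] <- data.frame(gene_a = a, gene_b = b, r = r,
                                                p = ct$p.value,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(gene_a = character(),
                                                gene_b = character(),
                                                r = numeric(), p = numeric(),
                                                stringsAsFactors = FALSE))))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force SNP-to-gene assignment by all-pairs interval containment.
brute_force_assign <- function(genes, hits, include_promoters = TRUE,
                               window = 5000) {
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    for (g in seq_len(nrow(genes))) {
      if (hits$chrom[h] != genes$chrom[g]) next
      pos <- hits$pos[h]
      if (pos >= genes$start[g] && pos <= genes$end[g]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes$pan_gene_id[g], trait = hits$trait[h],
          region_class = "genic", stringsAsFactors = FALSE)
      }
      if (include_promoters) {
        if (genes$strand[g] == "+") {
          ps <- max(1, genes$start[g] - window); pe <- genes$start[g] - 1
        } else {
          ps <- genes$end[g] + 1; pe <- genes$end[g] + window
        }
        if (pe >= ps && pos >= ps && pos <= pe) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = genes$pan_gene_id[g], trait = hits$trait[h],
            region_class = "promoter", stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- unique(do.call(rbind, c(rows, list(data.frame(
    gene = character(), trait = character(), region_class = character(),
    stringsAsFactors = FALSE)))))
  out <- out[order(out$gene, out$trait, out$region_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive hypergeometric upper tail by direct summation of the pmf.
enum_hypergeom_upper <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random occurrence histogram -> pan_network object with given genome count.
random_pan <- function(n_edges, n_genomes, seed) {
  set.seed(seed)
  occ <- sample(seq_len(n_genomes), n_edges, replace = TRUE,
                prob = 0.6^seq_len(n_genomes))
  genes <- sprintf("g%05d", seq_len(2 * n_edges))
  edges <- data.frame(
    gene_a = genes[seq_len(n_edges) * 2 - 1],
    gene_b = genes[seq_len(n_edges) * 2],
    occurrence = as.integer(occ),
    genomes = vapply(occ, function(o)
      paste(sprintf("genome_%02d", seq_len(o)), collapse = ","), character(1)),
    category = NA_character_, stringsAsFactors = FALSE)
  structure(list(edges = edges,
                 genomes = sprintf("genome_%02d", seq_len(n_genomes))),
            class = "pan_network")
}

# Small synthetic dataset shared by several tests (cheap to regenerate).
small_config <- function(seed = 11) {
  simulation_config(n_genomes = 3, n_genes = 60, n_samples = 20,
                    modules = list(list(size = 4, genomes = NULL,
                                        loading = 1, noise_sd = 0.1)),
                    n_private_pairs = 2, frac_low_expression = 0.1,
                    snps_per_trait = 6, seed = seed)
}

write_small_dataset <- function(dir, seed = 11) {
  ds <- generate_dataset(small_config(seed))
  write_dataset(ds, dir)
  ds
}

pipeline_config_for <- function(dir, genomes, ...) {
  pipeline_config(
    annotation_paths = setNames(file.path(dir, paste0(genomes, ".gff3")), genomes),
    expression_paths = setNames(file.path(dir, paste0(genomes, "_tpm.tsv")), genomes),
    gwas_path = file.path(dir, "gwas_hits.tsv"), ...)
}
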