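#' Expected correlation of two genes sharing one latent factor
#'
#' Under the generator's log-scale model two module genes are
#' \eqn{x = b z + \epsilon_1}, \eqn{y = b z + \epsilon_2} with a shared
#' standard-normal factor z and independent noise of standard deviation
#' \eqn{\sigma}; their population Pearson correlation is
#' \eqn{b^2 / (b^2 + \sigma^2)}. This is the design target used to pick
#' loadings for a desired correlation regime (e.g. \eqn{\sigma^2 = b^2 (1 -
#' r) / r} solves for a target r).
#'
#' @param loading Factor loading b (>= 0).
#' @param noise_sd Noise standard deviation \eqn{\sigma} (>= 0).
#' @return Population correlation in [0, 1].
#' @export
expected_module_correlation <- function(loading, noise_sd) {
  if (loading < 0 || noise_sd < 0) stop("loading and noise_sd must be >= 0")
  if (loading == 0 && noise_sd == 0) {
    stop("degenerate model: loading and noise_sd cannot both be zero")
  }
  loading^2 / (loading^2 + noise_sd^2)
}

#' Configuration of the synthetic multi-genome dataset
#'
#' Collects and validates the parameters of the simulator. Defaults
#' describe the package's reference study conditions: 10 genomes sharing a
#' pan-gene namespace of 300 genes, 20 expression samples per genome, one
#' 10-gene co-expression module shared by every genome at a population
#' latent correlation of about 0.99 (loading 1, noise sd 0.1), 5 planted
#' genome-private correlated pairs per genome, 10% low-expression genes
#' (median TPM < 5), and three traits whose GWAS hits target module genes,
#' private-pair genes and arbitrary genes respectively, half of the hits in
#' promoter windows.
#'
#' @param n_genomes Number of genomes.
#' @param n_genes Pan-gene namespace size.
#' @param n_samples Expression samples per genome (default 20).
#' @param modules List of module specs: \code{list(size =, genomes =,
#'   loading =, noise_sd =)}; \code{genomes = NULL} means all genomes.
#' @param n_private_pairs Planted private correlated pairs per genome.
#' @param private_loading,private_noise_sd Latent-factor parameters of the
#'   private pairs.
#' @param background_sd Log-scale standard deviation of independent
#'   background genes.
#' @param frac_low_expression Fraction of genes forced to median TPM < 5.
#' @param traits Character vector of trait names.
#' @param trait_targets Named list mapping trait to a target pool:
#'   \code{"module"}, \code{"module:<k>"}, \code{"private"},
#'   \code{"background"}, \code{"any"}, or an explicit gene-ID vector.
#'   Unlisted traits default to \code{"any"}.
#' @param snps_per_trait GWAS hits per trait.
#' @param promoter_hit_fraction Fraction of each trait's hits placed in
#'   promoter windows (the rest are genic).
#' @param promoter_window Promoter width in bases (default 5000).
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @return A validated \code{simulation_config} list.
#' @export
simulation_config <- function(n_genomes = 10, n_genes = 300, n_samples = 20,
                              modules = list(list(size = 10, genomes = NULL,
                                                  loading = 1, noise_sd = 0.1)),
                              n_private_pairs = 5, private_loading = 1,
                              private_noise_sd = 0.1, background_sd = 0.5,
                              frac_low_expression = 0.1,
                              traits = c("trait_core", "trait_private",
                                         "trait_mixed"),
                              trait_targets = list(trait_core = "module:1",
                                                   trait_private = "private",
                                                   trait_mixed = "any"),
                              snps_per_trait = 10,
                              promoter_hit_fraction = 0.5,
                              promoter_window = 5000, seed = 1L) {
  stopifnot(n_genomes >= 1, n_genes >= 1, n_samples >= 1,
            n_private_pairs >= 0, private_loading >= 0, private_noise_sd >= 0,
            background_sd > 0, frac_low_expression >= 0,
            frac_low_expression < 1, snps_per_trait >= 0,
            promoter_hit_fraction >= 0, promoter_hit_fraction <= 1,
            promoter_window >= 1)
  modules <- lapply(modules, function(m) {
    m$size <- as.integer(m$size)
    if (m$size < 2) stop("module size must be >= 2")
    if (is.null(m$genomes)) m$genomes <- seq_len(n_genomes)
    m$genomes <- as.integer(m$genomes)
    if (length(m$genomes) == 0 || !all(m$genomes %in% seq_len(n_genomes))) {
      stop("module genome subset must be a nonempty subset of 1..n_genomes")
    }
    m$loading <- m$loading %||% 1
    m$noise_sd <- m$noise_sd %||% 0.1
    if (m$loading < 0 || m$noise_sd < 0) stop("loading and noise_sd must be >= 0")
    if (m$loading == 0 && m$noise_sd == 0) stop("degenerate module: loading and noise_sd both zero")
    m
  })
  planted <- sum(vapply(modules, `[[`, integer(1), "size")) +
    2L * n_private_pairs * n_genomes
  if (planted > n_genes) {
    stop("capacity error: ", planted, " planted genes exceed n_genes = ", n_genes)
  }
  structure(list(
    n_genomes = as.integer(n_genomes), n_genes = as.integer(n_genes),
    n_samples = as.integer(n_samples), modules = modules,
    n_private_pairs = as.integer(n_private_pairs),
    private_loading = private_loading, private_noise_sd = private_noise_sd,
    background_sd = background_sd, frac_low_expression = frac_low_expression,
    traits = traits, trait_targets = trait_targets,
    snps_per_trait = as.integer(snps_per_trait),
    promoter_hit_fraction = promoter_hit_fraction,
    promoter_window = as.integer(promoter_window), seed = as.integer(seed)),
    class = "simulation_config")
}

#' Generate a synthetic multi-genome dataset with known planted structure
#'
#' Produces, per genome, a gene annotation table and a TPM expression
#' matrix, plus one GWAS hit table and the ground truth of everything that
#' was planted. Module genes in the genomes of their module subset follow a
#' log-scale one-factor model \eqn{x = b z_s + \epsilon} (z standard normal
#' per sample, shared within the module; \eqn{\epsilon} independent
#' normal), then exponentiated and per-gene rescaled so that non-low
#' genes have median TPM >= 5. Private pairs share a factor in exactly one
#' genome. Low-expression genes get a constant small value plus jitter
#' (median TPM < 5). Genes are laid out on chromosomes with wide spacing on
#' alternating strands so genic and promoter windows never overlap; GWAS
#' hits are placed inside the genic or promoter window of their target
#' gene.
#'
#' @param config A [simulation_config()].
#' @return List with \code{config}, \code{annotations} (named list of gene
#'   annotation \code{data.frame}s per genome), \code{hits} (GWAS
#'   \code{data.frame}), \code{expression} (named list of TPM matrices) and
#'   \code{truth} (list: \code{planted_edges}, \code{trait_assignments},
#'   \code{low_expression_genes}).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  G <- config$n_genomes
  n_genes <- config$n_genes
  n_samples <- config$n_samples
  genome_ids <- sprintf("genome_%02d", seq_len(G))
  gene_ids <- sprintf("pan_gene_%05d", seq_len(n_genes))

  # --- assign planted roles to gene indices (sequential blocks) ------------
  cursor <- 0L
  take <- function(n) {
    idx <- cursor + seq_len(n)
    cursor <<- cursor + n
    idx
  }
  module_idx <- lapply(config$modules, function(m) take(m$size))
  private_idx <- lapply(seq_len(G), function(g) {
    if (config$n_private_pairs == 0) return(integer(0))
    matrix(take(2L * config$n_private_pairs), ncol = 2L, byrow = TRUE)
  })
  background <- setdiff(seq_len(n_genes), unlist(c(module_idx, private_idx)))

  n_low <- floor(config$frac_low_expression * n_genes)
  if (n_low > length(background)) {
    stop("capacity error: not enough background genes (", length(background),
         ") to host ", n_low, " low-expression genes")
  }
  low_idx <- if (n_low > 0) sort(sample(background, n_low)) else integer(0)

  # --- gene layout: wide spacing, alternating strands ----------------------
  genes_per_chrom <- 100L
  slot <- (seq_len(n_genes) - 1L) %% genes_per_chrom
  chrom <- sprintf("chr%d", (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L)
  start <- 10000L + slot * 20000L
  end <- start + 1999L
  strand <- ifelse(seq_len(n_genes) %% 2L == 1L, "+", "-")
  layout <- data.frame(pan_gene_id = gene_ids, chrom = chrom, start = start,
                       end = end, strand = strand, stringsAsFactors = FALSE)
  annotations <- setNames(lapply(genome_ids, function(g) {
    validate_gene_annotations(cbind(layout[1], genome_id = g, layout[-1]))
  }), genome_ids)

  # --- GWAS hits -----------------------------------------------------------
  pool_for <- function(target) {
    if (length(target) > 1 || grepl("^pan_gene_", target[1])) {
      return(match(target, gene_ids))
    }
    if (target == "any") return(seq_len(n_genes))
    if (target == "module") return(unlist(module_idx))
    if (target == "private") return(sort(unlist(private_idx)))
    if (target == "background") return(setdiff(background, low_idx))
    if (grepl("^module:[0-9]+$", target)) {
      k <- as.integer(sub("^module:", "", target))
      if (k > length(module_idx)) stop("trait target refers to missing module ", k)
      return(module_idx[[k]])
    }
    stop("unknown trait target: ", target)
  }
  hit_rows <- list()
  truth_traits <- list()
  for (tr in config$traits) {
    target_spec <- config$trait_targets[[tr]] %||% "any"
    n_snps <- config$snps_per_trait
    if (n_snps == 0) next
    if (identical(target_spec, "private") && config$n_private_pairs > 0) {
      # hit whole pairs so both endpoints of a planted private edge carry
      # the trait (the subnetwork rule requires both)
      pairs <- do.call(rbind, private_idx)
      n_pairs <- min(nrow(pairs), ceiling(n_snps / 2))
      chosen <- pairs[sample.int(nrow(pairs), n_pairs), , drop = FALSE]
      base <- as.integer(t(chosen))
      targets <- base[(seq_len(n_snps) - 1L) %% length(base) + 1L]
    } else {
      pool <- pool_for(target_spec)
      if (length(pool) == 0) next  # nothing to target for this trait
      targets <- pool[sample.int(length(pool), n_snps,
                                 replace = length(pool) < n_snps)]
    }
    n_prom <- round(config$promoter_hit_fraction * n_snps)
    in_prom <- seq_len(n_snps) <= n_prom
    pos <- integer(n_snps)
    for (i in seq_len(n_snps)) {
      gi <- targets[i]
      if (in_prom[i]) {
        pw <- promoter_interval(layout[gi, ], config$promoter_window)
        pos[i] <- sample(pw$start:pw$end, 1L)
      } else {
        pos[i] <- sample(layout$start[gi]:layout$end[gi], 1L)
      }
    }
    hit_rows[[tr]] <- data.frame(chrom = layout$chrom[targets], pos = pos,
                                 trait = tr, stringsAsFactors = FALSE)
    truth_traits[[tr]] <- data.frame(
      gene = gene_ids[targets], trait = tr,
      region_class = ifelse(in_prom, "promoter", "genic"),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, c(hit_rows, list(data.frame(chrom = character(),
                                                     pos = integer(),
                                                     trait = character(),
                                                     stringsAsFactors = FALSE))))
  rownames(hits) <- NULL
  trait_assignments <- unique(do.call(rbind, truth_traits))
  if (!is.null(trait_assignments)) {
    trait_assignments <- trait_assignments[
      order(trait_assignments$gene, trait_assignments$trait,
            trait_assignments$region_class), , drop = FALSE]
    rownames(trait_assignments) <- NULL
  } else {
    trait_assignments <- data.frame(gene = character(), trait = character(),
                                    region_class = character(),
                                    stringsAsFactors = FALSE)
  }

  # --- expression ----------------------------------------------------------
  sample_ids <- sprintf("sample_%02d", seq_len(n_samples))
  expression <- setNames(vector("list", G), genome_ids)
  for (g in seq_len(G)) {
    logx <- matrix(rnorm(n_genes * n_samples, sd = config$background_sd),
                   nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    for (mi in seq_along(config$modules)) {
      m <- config$modules[[mi]]
      if (!g %in% m$genomes) next
      z <- rnorm(n_samples)
      for (gi in module_idx[[mi]]) {
        logx[gi, ] <- m$loading * z + rnorm(n_samples, sd = m$noise_sd)
      }
    }
    if (config$n_private_pairs > 0) {
      pp <- private_idx[[g]]
      for (pr in seq_len(nrow(pp))) {
        z <- rnorm(n_samples)
        for (gi in pp[pr, ]) {
          logx[gi, ] <- config$private_loading * z +
            rnorm(n_samples, sd = config$private_noise_sd)
        }
      }
    }
    tpm <- exp(logx)
    target_median <- runif(n_genes, 8, 100)
    tpm <- tpm * (target_median / apply(tpm, 1L, median))
    if (length(low_idx) > 0) {
      base <- runif(length(low_idx), 0.5, 4)
      tpm[low_idx, ] <- base + matrix(runif(length(low_idx) * n_samples, 0, 0.5),
                                      nrow = length(low_idx))
    }
    expression[[g]] <- structure(tpm, genome_id = genome_ids[g])
  }

  # --- ground truth of planted pairs ---------------------------------------
  edge_rows <- list()
  for (mi in seq_along(config$modules)) {
    idx <- sort(module_idx[[mi]])
    prs <- t(combn(idx, 2L))
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      gene_a = gene_ids[prs[, 1]], gene_b = gene_ids[prs[, 2]],
      type = "module", module = mi,
      genomes = paste(genome_ids[config$modules[[mi]]$genomes], collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (g in seq_len(G)) {
    pp <- private_idx[[g]]
    if (length(pp) == 0) next
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      gene_a = gene_ids[pmin(pp[, 1], pp[, 2])],
      gene_b = gene_ids[pmax(pp[, 1], pp[, 2])],
      type = "private", module = NA_integer_, genomes = genome_ids[g],
      stringsAsFactors = FALSE)
  }
  planted_edges <- do.call(rbind, edge_rows)
  if (is.null(planted_edges)) {
    planted_edges <- data.frame(gene_a = character(), gene_b = character(),
                                type = character(), module = integer(),
                                genomes = character(), stringsAsFactors = FALSE)
  }
  rownames(planted_edges) <- NULL

  list(config = config, annotations = annotations, hits = hits,
       expression = expression,
       truth = list(planted_edges = planted_edges,
                    trait_assignments = trait_assignments,
                    low_expression_genes = gene_ids[low_idx]))
}

#' Simulate a gene-to-GO annotation map
#'
#' Randomly assigns GO-style term identifiers to a subset of genes, for
#' exercising the enrichment stage on synthetic data. A fraction of genes
#' stays unannotated, as with real InterPro-derived maps. Term identifiers
#' are synthetic (GO:0000001 upward) and carry no ontology semantics.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_terms Number of distinct terms (default 20).
#' @param mean_terms_per_gene Average terms per annotated gene (default 2).
#' @param frac_annotated Fraction of genes with at least one term
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A gene-to-GO map as from [build_go_map()].
#' @export
simulate_go_annotations <- function(gene_ids, n_terms = 20,
                                    mean_terms_per_gene = 2,
                                    frac_annotated = 0.8, seed = 1L) {
  stopifnot(n_terms >= 1, mean_terms_per_gene > 0,
            frac_annotated > 0, frac_annotated <= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  annotated <- sort(sample(gene_ids, round(frac_annotated * length(gene_ids))))
  counts <- pmin(n_terms, 1L + stats::rpois(length(annotated),
                                            mean_terms_per_gene - 1))
  gene_col <- rep(annotated, counts)
  go_col <- unlist(lapply(counts, function(k) sample(terms, k)), use.names = FALSE)
  build_go_map(gene_col, go_col,
               term_names = setNames(paste("synthetic term", seq_len(n_terms)),
                                     terms))
}

#' Write a synthetic dataset to disk
#'
#' Serializes a [generate_dataset()] result: one GFF3 annotation and one
#' TPM TSV per genome, a GWAS hits TSV, and the ground truth as JSON.
#' Output bytes are a pure function of the dataset.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named list of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (g in names(dataset$annotations)) {
    p <- file.path(dir, paste0(g, ".gff3"))
    write_gff3_genes(dataset$annotations[[g]], p)
    paths[[paste0("gff3_", g)]] <- p
    p <- file.path(dir, paste0(g, "_tpm.tsv"))
    write_expression_matrix(dataset$expression[[g]], p)
    paths[[paste0("tpm_", g)]] <- p
  }
  paths$hits <- file.path(dir, "gwas_hits.tsv")
  write_gwas_hits(dataset$hits, paths$hits)
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(dataset$truth, paths$truth, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(paths)
}
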