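#' Pipeline configuration
#'
#' Collects the input paths, thresholds and flags of a full run. All printed
#' method parameters are here with their defaults: median TPM filter 5,
#' correlation cutoff r > 0.9 with p < 0.01, promoter window 5000 bases,
#' core fraction 0.01, near-core fraction 0.05, enrichment alpha 0.05.
#'
#' @param annotation_paths Named character vector (genome ID -> GFF3 path).
#' @param expression_paths Named character vector (genome ID -> TPM TSV
#'   path); names must match \code{annotation_paths}.
#' @param gwas_path Path to the GWAS hit table.
#' @param go_path Optional path to a gene-to-GO map TSV (\code{NULL} skips
#'   enrichment).
#' @param median_tpm,r_min,p_max,promoter_window,core_frac,nearcore_frac,alpha
#'   Thresholds (see above).
#' @param include_promoters,absolute_r,strict_core Flags (see
#'   [assign_snps_to_genes()], [build_network()], [classify_edges()]).
#' @param enrichment_background \code{"filtered"} (all median-filtered
#'   annotated genes, the default high-coverage background) or
#'   \code{"pan"} (pan-network genes).
#' @param growth_curve_reps Replicates per subset size for the growth curve
#'   (default 100).
#' @param seed Seed driving all randomness (growth-curve subsampling).
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(annotation_paths, expression_paths, gwas_path,
                            go_path = NULL, median_tpm = 5, r_min = 0.9,
                            p_max = 0.01, promoter_window = 5000,
                            core_frac = 0.01, nearcore_frac = 0.05,
                            alpha = 0.05, include_promoters = TRUE,
                            absolute_r = FALSE, strict_core = FALSE,
                            enrichment_background = c("filtered", "pan"),
                            growth_curve_reps = 100, seed = 1L) {
  if (is.null(names(annotation_paths)) || is.null(names(expression_paths)) ||
      !identical(sort(names(annotation_paths)), sort(names(expression_paths)))) {
    stop("annotation_paths and expression_paths must be named by the same genome IDs")
  }
  if (!(core_frac > 0 && core_frac < nearcore_frac && nearcore_frac < 1)) {
    stop("need 0 < core_frac < nearcore_frac < 1")
  }
  stopifnot(median_tpm > 0, r_min > 0, p_max > 0, promoter_window > 0,
            alpha > 0, growth_curve_reps >= 1)
  structure(list(
    annotation_paths = annotation_paths, expression_paths = expression_paths,
    gwas_path = gwas_path, go_path = go_path, median_tpm = median_tpm,
    r_min = r_min, p_max = p_max, promoter_window = promoter_window,
    core_frac = core_frac, nearcore_frac = nearcore_frac, alpha = alpha,
    include_promoters = include_promoters, absolute_r = absolute_r,
    strict_core = strict_core,
    enrichment_background = match.arg(enrichment_background),
    growth_curve_reps = growth_curve_reps, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Semantic hash of a pipeline configuration
#'
#' MD5 of a canonical serialization of every semantic parameter (paths
#' excluded from semantics only in name, included here so a changed input
#' file location is visible); changes iff a parameter changes.
#'
#' @param config A \code{pipeline_config}.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  canon <- paste(names(flat), vapply(flat, format_num_or_char, character(1)),
                 sep = "=", collapse = ";")
  string_md5(canon)
}

format_num_or_char <- function(x) {
  if (is.numeric(x)) format_num(as.numeric(x)) else as.character(x)
}

#' Run the full pan-network pipeline
#'
#' Executes map-snps, median filtering, per-genome network construction,
#' pan-network union and classification, trait analyses and (when a GO map
#' is configured) enrichment, writing every artifact into \code{out_dir}.
#' Reruns with the same configuration and inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (\code{trait_maps},
#'   \code{networks}, \code{pan}, \code{summary}, \code{trait_table},
#'   \code{representation}, \code{enrichment}, \code{paths}).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- names(config$annotation_paths)
  log_lines <- c(sprintf("config_hash\t%s", config_hash(config)),
                 sprintf("pancoex_version\t%s",
                         as.character(utils::packageVersion("pancoex"))))
  paths <- list()

  # stage: map-snps
  hits <- read_gwas_hits(config$gwas_path)
  trait_maps <- list()
  for (g in genomes) {
    ann <- read_gff3_genes(config$annotation_paths[[g]], g)
    tm <- assign_snps_to_genes(ann, hits,
                               include_promoters = config$include_promoters,
                               promoter_window = config$promoter_window)
    trait_maps[[g]] <- tm
    p <- file.path(out_dir, paste0("trait_map_", g, ".tsv"))
    write_trait_map(tm, p)
    paths[[paste0("trait_map_", g)]] <- p
    log_lines <- c(log_lines, sprintf(
      "map-snps\t%s\tgenes_with_traits=%d\tunmapped_chrom_hits=%d",
      g, length(unique(tm$gene)), attr(tm, "n_unmapped_chrom")))
  }
  merged_map <- merge_trait_maps(trait_maps)
  paths$trait_map_merged <- file.path(out_dir, "trait_map_merged.tsv")
  write_trait_map(merged_map, paths$trait_map_merged)

  # stage: filter + build-networks
  networks <- list()
  filtered_genes <- character(0)
  for (g in genomes) {
    mat <- read_expression_matrix(config$expression_paths[[g]], g)
    mat <- filter_by_median_tpm(mat, config$median_tpm)
    filtered_genes <- union(filtered_genes, rownames(mat))
    goi <- unique(trait_maps[[g]]$gene)
    net <- build_network(mat, genes_of_interest = goi, r_min = config$r_min,
                         p_max = config$p_max, absolute_r = config$absolute_r)
    networks[[g]] <- net
    p <- file.path(out_dir, paste0("network_", g, ".tsv"))
    write_edge_list(net, p)
    paths[[paste0("network_", g)]] <- p
    log_lines <- c(log_lines, sprintf(
      "build-networks\t%s\tfiltered_genes=%d\tnetwork_genes=%d\tconstant_genes=%d\tedges=%d",
      g, nrow(mat), attr(net, "n_genes"), attr(net, "n_constant"), nrow(net)))
  }

  # stage: pan + classify
  pan <- union_networks(networks)
  if (nrow(pan$edges) > 0) {
    pan <- classify_edges(pan, core_frac = config$core_frac,
                          nearcore_frac = config$nearcore_frac,
                          strict_core = config$strict_core)
  }
  paths$pan_edges <- file.path(out_dir, "pan_network.tsv")
  write_pan_network(pan, paths$pan_edges)
  paths$pan_sif <- file.path(out_dir, "pan_network.sif")
  write_sif(pan$edges, paths$pan_sif)
  summ <- if (nrow(pan$edges) > 0) category_summary(pan) else NULL
  if (!is.null(summ)) {
    paths$summary <- file.path(out_dir, "category_summary.json")
    jsonlite::write_json(list(table = summ$table,
                              occurrence_histogram = summ$occurrence_histogram,
                              private_per_genome = as.list(summ$private_per_genome)),
                         paths$summary, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    gc_df <- growth_curve(pan, n_reps = config$growth_curve_reps,
                          core_frac = config$core_frac,
                          nearcore_frac = config$nearcore_frac,
                          seed = config$seed)
    paths$growth_curve <- file.path(out_dir, "growth_curve.tsv")
    write_tsv(gc_df, paths$growth_curve)
    log_lines <- c(log_lines, sprintf("pan\tedges=%d\tgenes=%d",
                                      nrow(pan$edges),
                                      summ$table$n_genes[summ$table$category == "pan"]))
    log_lines <- c(log_lines, sprintf(
      "classify\t%s=%d", summ$table$category, summ$table$n_edges))
  }

  # stage: traits
  trait_table <- representation <- NULL
  if (nrow(pan$edges) > 0 && nrow(merged_map) > 0) {
    trait_table <- trait_category_table(pan, merged_map)
    paths$trait_table <- file.path(out_dir, "trait_category_table.tsv")
    write_tsv(trait_table, paths$trait_table)
    representation <- trait_representation(pan, merged_map)
    paths$trait_representation <- file.path(out_dir, "trait_representation.tsv")
    write_tsv(representation$proportions, paths$trait_representation)
    pleio <- pleiotropic_genes(merged_map)
    paths$pleiotropic <- file.path(out_dir, "pleiotropic_genes.tsv")
    write_tsv(pleio$genes, paths$pleiotropic)
    for (tr in sort(unique(merged_map$trait))) {
      s <- trait_subnetwork(pan, merged_map, tr)
      p <- file.path(out_dir, paste0("trait_edges_", gsub("[^A-Za-z0-9_.-]", "_", tr), ".tsv"))
      write_edge_list(s$edges, p)
      paths[[paste0("trait_edges_", tr)]] <- p
    }
  }

  # stage: enrich
  enrichment <- NULL
  if (!is.null(config$go_path) && nrow(pan$edges) > 0) {
    go_map <- read_go_map(config$go_path)
    pan_genes <- unique(c(pan$edges$gene_a, pan$edges$gene_b))
    background <- if (config$enrichment_background == "filtered")
      filtered_genes else pan_genes
    enrichment <- go_enrichment(pan_genes, background, go_map,
                                alpha = config$alpha)
    paths$enrichment <- file.path(out_dir, "enrichment_pan.tsv")
    write_enrichment(enrichment, paths$enrichment)
    log_lines <- c(log_lines, sprintf(
      "enrich\tterms_tested=%d\tsignificant=%d", nrow(enrichment),
      sum(enrichment$significant)))
  }

  paths$log <- file.path(out_dir, "run_log.tsv")
  con <- file(paths$log, open = "wb")
  writeLines(log_lines, con)
  close(con)

  invisible(list(config = config, trait_maps = trait_maps,
                 merged_map = merged_map, networks = networks, pan = pan,
                 summary = summ, trait_table = trait_table,
                 representation = representation, enrichment = enrichment,
                 paths = paths))
}

#' Compare genic-only and genic+promoter pipelines
#'
#' Runs the pipeline twice on the same inputs — once with promoter windows
#' (genic/promoter network) and once restricted to genic hits — and reports
#' the fraction of genes and of gene-associations (edges) of the
#' genic+promoter pan-network that are retained in the genic-only
#' pan-network.
#'
#' @param config A [pipeline_config()] (its \code{include_promoters} flag is
#'   overridden for each arm).
#' @param out_dir Output directory; arms go to \code{genic_promoter/} and
#'   \code{genic_only/}, the diff to \code{genic_diff.json}.
#' @return List with both run results and \code{diff} (gene_retention,
#'   edge_retention, counts).
#' @export
compare_genic_promoter <- function(config, out_dir) {
  cfg_gp <- config; cfg_gp$include_promoters <- TRUE
  cfg_g <- config; cfg_g$include_promoters <- FALSE
  run_gp <- run_pipeline(cfg_gp, file.path(out_dir, "genic_promoter"))
  run_g <- run_pipeline(cfg_g, file.path(out_dir, "genic_only"))
  genes_gp <- unique(c(run_gp$pan$edges$gene_a, run_gp$pan$edges$gene_b))
  genes_g <- unique(c(run_g$pan$edges$gene_a, run_g$pan$edges$gene_b))
  diff <- list(
    genic_promoter_genes = length(genes_gp),
    genic_genes = length(genes_g),
    gene_retention = if (length(genes_gp)) length(genes_g) / length(genes_gp) else NA,
    genic_promoter_edges = nrow(run_gp$pan$edges),
    genic_edges = nrow(run_g$pan$edges),
    edge_retention = if (nrow(run_gp$pan$edges))
      nrow(run_g$pan$edges) / nrow(run_gp$pan$edges) else NA)
  jsonlite::write_json(diff, file.path(out_dir, "genic_diff.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(genic_promoter = run_gp, genic_only = run_g, diff = diff)
}
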