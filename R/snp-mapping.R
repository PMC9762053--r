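#' Promoter interval of a gene
#'
#' The promoter is the window of \code{window} bases immediately upstream
#' (5', strand-aware) of the annotated gene start: for a + strand gene
#' \code{[max(1, start - window), start - 1]}, for a - strand gene
#' \code{[end + 1, end + window]}. Intervals are 1-based and closed on both
#' ends, matching GFF3. A + strand gene starting at position 1 has no
#' promoter.
#'
#' @param gene One-row gene annotation (see [read_gff3_genes()]), or a
#'   multi-row annotation \code{data.frame} (vectorized).
#' @param window Window width in bases (default 5000, i.e. < 5 kb upstream).
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}; rows with \code{start > end} denote an empty promoter.
#' @export
promoter_interval <- function(gene, window = 5000) {
  stopifnot(window >= 1)
  plus <- gene$strand == "+"
  start <- ifelse(plus, pmax(1L, gene$start - as.integer(window)), gene$end + 1L)
  end <- ifelse(plus, gene$start - 1L, gene$end + as.integer(window))
  data.frame(chrom = gene$chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Assign GWAS hits to genes through genic and promoter windows
#'
#' Intersects SNP positions with gene bodies (\code{[start, end]}) and,
#' optionally, with strand-aware promoter windows (see
#' [promoter_interval()]). A gene receives a trait when any hit for that
#' trait falls in one of its windows; trait annotations are nonredundant (a
#' gene hit by several SNPs of the same trait carries the trait once), and a
#' hit inside one gene's body and another gene's promoter is assigned to
#' both genes. Hits on chromosomes absent from the annotation are counted
#' and reported via the \code{n_unmapped_chrom} attribute, not an error.
#'
#' @param genes Gene annotation \code{data.frame} for one genome.
#' @param hits GWAS hit \code{data.frame} (\code{chrom}, \code{pos},
#'   \code{trait}).
#' @param include_promoters Include promoter windows (default \code{TRUE});
#'   \code{FALSE} restricts to genic hits only.
#' @param promoter_window Promoter width in bases (default 5000).
#' @return A trait-gene map: \code{data.frame} with columns \code{gene},
#'   \code{trait}, \code{region_class} (\code{"genic"} or
#'   \code{"promoter"}), unique rows, sorted; attributes \code{genome_id}
#'   and \code{n_unmapped_chrom}.
#' @export
assign_snps_to_genes <- function(genes, hits, include_promoters = TRUE,
                                 promoter_window = 5000) {
  genes <- validate_gene_annotations(genes)
  genome_id <- genes$genome_id[1] %||% NA_character_
  empty <- data.frame(gene = character(), trait = character(),
                      region_class = character(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0 || nrow(genes) == 0) {
    return(structure(empty, genome_id = genome_id, n_unmapped_chrom = 0L,
                     class = c("trait_gene_map", "data.frame")))
  }
  unmapped <- sum(!hits$chrom %in% genes$chrom)

  hit_gr <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$pos, width = 1L))
  genic_gr <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(hit_gr, genic_gr)
  res <- data.frame(
    gene = genes$pan_gene_id[S4Vectors::subjectHits(ov)],
    trait = hits$trait[S4Vectors::queryHits(ov)],
    region_class = rep("genic", length(ov)),
    stringsAsFactors = FALSE
  )
  if (include_promoters) {
    prom <- promoter_interval(genes, promoter_window)
    ok <- prom$start <= prom$end
    if (any(ok)) {
      prom_gr <- GenomicRanges::GRanges(prom$chrom[ok],
                                        IRanges::IRanges(prom$start[ok], prom$end[ok]))
      ovp <- GenomicRanges::findOverlaps(hit_gr, prom_gr)
      res <- rbind(res, data.frame(
        gene = genes$pan_gene_id[which(ok)][S4Vectors::subjectHits(ovp)],
        trait = hits$trait[S4Vectors::queryHits(ovp)],
        region_class = rep("promoter", length(ovp)),
        stringsAsFactors = FALSE
      ))
    }
  }
  res <- unique(res)
  res <- res[order(res$gene, res$trait, res$region_class), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, genome_id = genome_id, n_unmapped_chrom = as.integer(unmapped),
            class = c("trait_gene_map", "data.frame"))
}

#' Merge trait-gene maps across genomes
#'
#' Pan-network edges are keyed by pan-gene IDs, so trait maps from the
#' individual genomes are merged by pan-gene union before subnetwork
#' extraction: a gene carries a trait if it carries it in any genome.
#'
#' @param maps List of trait-gene maps from [assign_snps_to_genes()].
#' @return A merged trait-gene map (no \code{genome_id}).
#' @export
merge_trait_maps <- function(maps) {
  res <- unique(do.call(rbind, lapply(maps, function(m) {
    as.data.frame(m)[, c("gene", "trait", "region_class"), drop = FALSE]
  })))
  res <- res[order(res$gene, res$trait, res$region_class), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("trait_gene_map", "data.frame"))
}

#' Traits associated with each gene
#' @param trait_map A trait-gene map.
#' @return Named list gene -> sorted character vector of distinct traits.
#' @export
trait_sets <- function(trait_map) {
  df <- as.data.frame(trait_map)
  lapply(split(df$trait, df$gene), function(x) sort(unique(x)))
}

#' Write a trait-gene map as TSV
#' @param trait_map A trait-gene map.
#' @param path Output path.
#' @export
write_trait_map <- function(trait_map, path) {
  write_tsv(as.data.frame(trait_map)[, c("gene", "trait", "region_class")], path)
}
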