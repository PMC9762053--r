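#' Read gene annotations from a GFF3 file
#'
#' Parses a GFF3 annotation file and returns one record per feature of type
#' \code{gene}, keyed by the pan-gene identifier carried in the \code{ID}
#' attribute. Child features (mRNA, exon, ...) and other feature types are
#' ignored. Coordinates are taken verbatim: GFF3 is 1-based with inclusive
#' start and end, and that convention is kept throughout the package.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Identifier of the genome the annotation belongs to.
#' @return A \code{data.frame} with columns \code{pan_gene_id},
#'   \code{genome_id}, \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @export
read_gff3_genes <- function(path, genome_id) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  ids <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else as.character(gr$ID)
  if (length(gr) > 0 && any(is.na(ids) | ids == "")) {
    # recover line numbers of the offending records for the error message
    raw <- readLines(path)
    feat <- grepl("\t", raw) & !startsWith(raw, "#")
    fields <- strsplit(raw[feat], "\t", fixed = TRUE)
    is_gene <- vapply(fields, function(f) length(f) >= 8 && f[3] == "gene", logical(1))
    has_id <- vapply(fields, function(f) length(f) >= 9 && grepl("(^|;)ID=", f[9]), logical(1))
    bad <- which(feat)[is_gene & !has_id]
    stop("gene feature(s) without an ID attribute at line(s): ",
         paste(bad, collapse = ", "))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("gene feature(s) with unstranded or invalid strand ('.'/'*'): ",
         paste(ids[!strand %in% c("+", "-")], collapse = ", "))
  }
  ann <- data.frame(
    pan_gene_id = ids,
    genome_id = genome_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  validate_gene_annotations(ann)
}

validate_gene_annotations <- function(ann) {
  stopifnot(all(c("pan_gene_id", "genome_id", "chrom", "start", "end", "strand")
                %in% names(ann)))
  if (any(ann$start < 1 | ann$start > ann$end)) {
    stop("invalid gene coordinates: need 1 <= start <= end")
  }
  if (anyDuplicated(paste(ann$pan_gene_id, ann$genome_id))) {
    stop("duplicate (pan_gene_id, genome_id) in annotation")
  }
  rownames(ann) <- NULL
  ann
}

#' Write gene annotations to GFF3
#'
#' Inverse of [read_gff3_genes()]: emits a version-3 pragma and one
#' \code{gene} line per record with the pan-gene ID in the \code{ID}
#' attribute. Output is byte-deterministic for a given input.
#'
#' @param ann Gene annotation \code{data.frame} (see [read_gff3_genes()]).
#' @param path Output path.
#' @export
write_gff3_genes <- function(ann, path) {
  ann <- validate_gene_annotations(ann)
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tpancoex\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            ann$chrom, ann$start, ann$end, ann$strand, ann$pan_gene_id)
  )
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
  invisible(path)
}

#' Read a GWAS hit table
#'
#' Two dialects are accepted. The long dialect is a TSV with columns
#' \code{chrom}, \code{pos}, \code{trait} (one row per SNP-trait
#' association). The wide dialect is a presence/absence trait matrix:
#' \code{chrom}, \code{pos}, then one 0/1 column per trait; a row flagged for
#' k traits flattens to k hits. A SNP associated with several traits always
#' yields one hit per trait.
#'
#' @param path Path to the TSV file (header row required).
#' @return A \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{trait}.
#' @export
read_gwas_hits <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 3) stop("GWAS table needs at least chrom, pos and one trait column")
  names(df)[1:2] <- c("chrom", "pos")
  if (nrow(df) > 0 && any(is.na(suppressWarnings(as.integer(df$pos))))) {
    stop("non-integer GWAS position(s) in column 2")
  }
  df$pos <- as.integer(df$pos)
  long <- tolower(names(df)[3]) == "trait" ||
    (ncol(df) == 3 && !all(unlist(df[[3]]) %in% c(0, 1, "0", "1")))
  if (long) {
    names(df)[3] <- "trait"
    hits <- df[, c("chrom", "pos", "trait")]
  } else {
    trait_cols <- names(df)[-(1:2)]
    pieces <- lapply(trait_cols, function(tr) {
      flag <- df[[tr]]
      keep <- !is.na(flag) & (flag == 1 | flag == "1")
      if (!any(keep)) return(NULL)
      data.frame(chrom = df$chrom[keep], pos = df$pos[keep], trait = tr,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, c(pieces, list(data.frame(chrom = character(),
                                                     pos = integer(),
                                                     trait = character(),
                                                     stringsAsFactors = FALSE))))
    ord <- order(match(hits$chrom, unique(df$chrom)), hits$pos, hits$trait)
    hits <- hits[ord, , drop = FALSE]
  }
  if (nrow(hits) > 0 && any(hits$pos < 1)) stop("GWAS positions must be >= 1")
  if (nrow(hits) > 0 && any(is.na(hits$trait) | hits$trait == "")) {
    stop("empty trait name in GWAS table")
  }
  rownames(hits) <- NULL
  hits
}

#' Write a GWAS hit table (long dialect)
#' @param hits \code{data.frame} with \code{chrom}, \code{pos}, \code{trait}.
#' @param path Output path.
#' @export
write_gwas_hits <- function(hits, path) {
  write_tsv(hits[, c("chrom", "pos", "trait")], path)
}

#' Read a TPM expression matrix
#'
#' Reads a genes-by-samples TSV: first column gene identifiers, remaining
#' columns numeric TPM values. Values must be finite and non-negative and
#' gene identifiers unique. The reader accepts a single-sample matrix; the
#' correlation stage separately requires at least three samples.
#'
#' @param path Path to the TSV file.
#' @param genome_id Genome identifier attached to the matrix.
#' @return A numeric matrix (genes in rows, samples in columns) with a
#'   \code{genome_id} attribute.
#' @export
read_expression_matrix <- function(path, genome_id) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 2) stop("expression matrix needs a gene column and >= 1 sample column")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ID(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric TPM value at gene ", genes[bad[1, 1]],
         ", sample ", colnames(df)[-1][bad[1, 2]])
  }
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-finite TPM value at gene ", genes[bad[1, 1]],
         ", sample ", colnames(vals)[bad[1, 2]])
  }
  rownames(vals) <- genes
  structure(vals, genome_id = genome_id)
}

#' Write a TPM expression matrix
#' @param mat Numeric matrix, genes in rows (rownames), samples in columns.
#' @param path Output path.
#' @param gene_column Name of the first (gene identifier) column.
#' @export
write_expression_matrix <- function(mat, path, gene_column = "gene_id") {
  df <- data.frame(rownames(mat), as.data.frame(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(gene_column, colnames(mat))
  write_tsv(df, path)
}

#' Read a gene-to-GO annotation map
#'
#' Long TSV with columns \code{gene}, \code{go_id} and optionally
#' \code{term_name}. GO identifiers must match \code{GO:} followed by seven
#' digits.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping gene to a character vector of GO ids, with a
#'   \code{term_names} attribute (named character vector, possibly empty).
#' @export
read_go_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "go_id")
  build_go_map(df$gene, df$go_id,
               term_names = if (ncol(df) >= 3) setNames(df[[3]], df$go_id))
}

#' Build a gene-to-GO map from vectors
#' @param gene,go_id Parallel character vectors (one annotation per element).
#' @param term_names Optional named character vector of GO term labels.
#' @return Same structure as [read_go_map()].
#' @export
build_go_map <- function(gene, go_id, term_names = NULL) {
  if (length(go_id) > 0 && any(!grepl("^GO:[0-9]{7}$", go_id))) {
    stop("malformed GO id(s): ",
         paste(head(unique(go_id[!grepl("^GO:[0-9]{7}$", go_id)]), 5), collapse = ", "))
  }
  map <- lapply(split(go_id, gene), function(x) sort(unique(x)))
  if (!is.null(term_names)) term_names <- term_names[!duplicated(names(term_names))]
  structure(map, term_names = term_names)
}

#' Write a gene-to-GO map
#' @param go_map Map as returned by [read_go_map()] / [build_go_map()].
#' @param path Output path.
#' @export
write_go_map <- function(go_map, path) {
  genes <- rep(names(go_map), lengths(go_map))
  ids <- unlist(go_map, use.names = FALSE)
  df <- data.frame(gene = genes, go_id = ids, stringsAsFactors = FALSE)
  tn <- attr(go_map, "term_names")
  if (!is.null(tn)) df$term_name <- unname(tn[df$go_id])
  write_tsv(df, path)
}

#' Write a network edge list as TSV
#'
#' Pairs are written in canonical order (\code{gene_a < gene_b}); any extra
#' columns (r, p, occurrence, category, ...) are carried through.
#'
#' @param edges \code{data.frame} with at least \code{gene_a}, \code{gene_b}.
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    cp <- canonical_pairs(edges$gene_a, edges$gene_b)
    edges$gene_a <- cp$gene_a
    edges$gene_b <- cp$gene_b
  }
  write_tsv(edges, path)
}

#' Write a network in SIF (simple interaction format)
#'
#' One line per edge, \code{"geneA pp geneB"}, pairs in canonical order.
#'
#' @inheritParams write_edge_list
#' @export
write_sif <- function(edges, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  if (nrow(edges) == 0) {
    writeLines(character(0), con)
    return(invisible(path))
  }
  cp <- canonical_pairs(edges$gene_a, edges$gene_b)
  writeLines(sprintf("%s pp %s", cp$gene_a, cp$gene_b), con)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#' @param path Path to the TSV file.
#' @return \code{data.frame} of edges.
#' @export
read_edge_list <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
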