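#' Exclude low-expression genes by median TPM
#'
#' Genes with median TPM below the threshold across the samples are removed
#' for noise attenuation; genes whose median equals the threshold are
#' retained. For an even number of samples the median is the mean of the two
#' middle order statistics.
#'
#' @param mat Expression matrix (genes in rows, samples in columns).
#' @param threshold Minimum median TPM to retain a gene (default 5).
#' @return The matrix restricted to retained genes (possibly 0 rows);
#'   attributes are preserved.
#' @export
filter_by_median_tpm <- function(mat, threshold = 5) {
  if (ncol(mat) < 1) stop("expression matrix has no samples")
  if (nrow(mat) == 0) return(mat)
  med <- apply(mat, 1L, median)
  out <- mat[med >= threshold, , drop = FALSE]
  attr(out, "genome_id") <- attr(mat, "genome_id")
  out
}

#' Pearson product-moment correlation of two vectors
#'
#' @param x,y Numeric vectors of equal length n >= 3; both non-constant.
#' @return The sample correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of the t statistic
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with \eqn{n-2} degrees of freedom:
#' \eqn{p = 2\,P(T_{n-2} \ge |t|)}. \eqn{|r| = 1} maps to \eqn{p = 0}.
#'
#' @param r Correlation coefficient(s) in [-1, 1].
#' @param n Sample size (n >= 3).
#' @return Two-sided p-value(s).
#' @export
pearson_p <- function(r, n) {
  if (n < 3) stop("insufficient samples: need n >= 3")
  if (any(abs(r) > 1 + 1e-12)) stop("correlation outside [-1, 1]")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) == 1, 0, {
    t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
    2 * pt(t, df = n - 2, lower.tail = FALSE)
  })
  pmin(p, 1)
}

#' Build a per-genome co-expression network
#'
#' Computes all pairwise Pearson correlations among the genes of interest
#' present in the (already median-filtered) expression matrix and keeps the
#' significant co-expressed pairs: \code{r > r_min} and \code{p < p_max}
#' (or \code{|r| > r_min} with \code{absolute_r = TRUE}). The network is
#' unsigned in the sense that edges carry no activation/repression label;
#' the stated cutoff \code{r > 0.9} is applied to the signed correlation by
#' default. Genes with zero variance across samples cannot be correlated and
#' are excluded (their count is reported in the \code{n_constant} attribute).
#'
#' @param mat Expression matrix (genes x samples), already median-filtered.
#' @param genes_of_interest Character vector of gene IDs to restrict the
#'   network to (e.g. trait-associated genes); \code{NULL} uses all genes.
#' @param r_min Correlation cutoff (default 0.9, strict inequality).
#' @param p_max Significance cutoff (default 0.01, strict inequality).
#' @param absolute_r Threshold |r| instead of signed r (default \code{FALSE}).
#' @return \code{data.frame} of edges (\code{gene_a}, \code{gene_b},
#'   \code{r}, \code{p}) in canonical pair order, sorted; attributes
#'   \code{genome_id}, \code{n_samples}, \code{n_genes}, \code{n_constant}.
#' @export
build_network <- function(mat, genes_of_interest = NULL, r_min = 0.9,
                          p_max = 0.01, absolute_r = FALSE) {
  if (ncol(mat) < 3) stop("need at least 3 samples to estimate correlations")
  genes <- rownames(mat)
  if (!is.null(genes_of_interest)) genes <- intersect(genes, genes_of_interest)
  sub <- mat[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  n_constant <- sum(sds == 0)
  sub <- sub[sds > 0, , drop = FALSE]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (nrow(sub) < 2) {
    return(structure(empty, genome_id = attr(mat, "genome_id"),
                     n_samples = ncol(mat), n_genes = nrow(sub),
                     n_constant = n_constant))
  }
  cmat <- cor(t(sub))
  keep <- if (absolute_r) abs(cmat) > r_min else cmat > r_min
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  r <- cmat[idx]
  p <- pearson_p(r, ncol(sub))
  sel <- p < p_max
  cp <- canonical_pairs(rownames(sub)[idx[sel, 1]], rownames(sub)[idx[sel, 2]])
  edges <- data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                      r = r[sel], p = p[sel], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, genome_id = attr(mat, "genome_id"), n_samples = ncol(mat),
            n_genes = nrow(sub), n_constant = n_constant)
}
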