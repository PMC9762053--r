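#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the chance of
#' drawing at least k annotated genes in a study set of size n from a
#' background of N genes of which K carry the annotation. Computed through
#' the stable tail routine of \code{stats::phyper}.
#'
#' @param k Observed count of study genes with the term.
#' @param K Background genes with the term.
#' @param n Study set size.
#' @param N Background size.
#' @return Upper-tail p-value; \code{k = 0} gives exactly 1.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(K < 0 | K > N)) stop("need 0 <= K <= N")
  if (any(n < 0 | n > N)) stop("need 0 <= n <= N")
  if (any(k < 0 | k > pmin(n, K))) stop("need 0 <= k <= min(n, K)")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted value for the i-th smallest p is
#' \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j}, capped at 1; values are
#' returned in the input order (delegates to \code{stats::p.adjust}).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' GO term over-representation test
#'
#' One-sided hypergeometric test per GO term present in the study set,
#' against a configurable background, with Benjamini-Hochberg FDR control.
#' Genes without any GO annotation are excluded from both the study count n
#' and the background count N, so adding unannotated genes never changes
#' the result.
#'
#' @param study_genes Character vector of study gene IDs (e.g. the genes of
#'   a network category).
#' @param background_genes Character vector of background gene IDs; the
#'   annotated study set must be a subset of the annotated background.
#' @param annotations Gene-to-GO map (see [build_go_map()]).
#' @param alpha Significance level on the adjusted value (default 0.05).
#' @return \code{data.frame} sorted by q then p then GO id: \code{go_id},
#'   \code{term_name}, \code{k}, \code{n}, \code{K}, \code{N}, \code{p},
#'   \code{q}, \code{significant}.
#' @export
go_enrichment <- function(study_genes, background_genes, annotations,
                          alpha = 0.05) {
  annotated <- names(annotations)
  bg <- intersect(unique(background_genes), annotated)
  study <- intersect(unique(study_genes), annotated)
  if (!all(study %in% bg)) {
    stop("annotated study genes must be a subset of the annotated background")
  }
  empty <- data.frame(go_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (length(study) == 0) {
    warning("no annotated study genes; empty enrichment result")
    return(empty)
  }
  study_terms <- sort(unique(unlist(annotations[study], use.names = FALSE)))
  bg_term_counts <- table(unlist(annotations[bg], use.names = FALSE))
  st_term_counts <- table(unlist(annotations[study], use.names = FALSE))
  k <- as.integer(st_term_counts[study_terms])
  K <- as.integer(bg_term_counts[study_terms])
  n <- length(study)
  N <- length(bg)
  p <- hypergeom_upper_tail(k, K, n, N)
  q <- bh_fdr(p)
  tn <- attr(annotations, "term_names")
  res <- data.frame(
    go_id = study_terms,
    term_name = if (is.null(tn)) NA_character_ else unname(tn[study_terms]),
    k = k, n = n, K = K, N = N, p = p, q = q,
    significant = q < alpha,
    stringsAsFactors = FALSE)
  res <- res[order(res$q, res$p, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an enrichment result table as TSV
#' @param result \code{data.frame} from [go_enrichment()].
#' @param path Output path.
#' @export
write_enrichment <- function(result, path) write_tsv(result, path)
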