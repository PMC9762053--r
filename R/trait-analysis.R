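#' Extract a trait-specific subnetwork of the pan-network
#'
#' Keeps the pan-network edges whose \emph{both} endpoints are associated
#' with the trait (in any genome, after merging trait maps), optionally
#' restricted to one pan-network category. The both-endpoint rule reflects
#' co-expression among genes associated with the same trait; a one-endpoint
#' rule would pull in trait-unrelated partner genes.
#'
#' @param pan A \code{pan_network} (classified if \code{category} is used).
#' @param trait_map Merged trait-gene map (see [merge_trait_maps()]).
#' @param trait Trait name.
#' @param category Optional category filter (\code{"core"},
#'   \code{"near-core"}, \code{"dispensable"}, \code{"private"}).
#' @return A \code{trait_subnetwork}: list with \code{trait},
#'   \code{category}, \code{edges} (pan-edge \code{data.frame} subset) and
#'   \code{nodes} (endpoints of those edges).
#' @export
trait_subnetwork <- function(pan, trait_map, trait, category = NULL) {
  stopifnot(inherits(pan, "pan_network"))
  tm <- as.data.frame(trait_map)
  known <- sort(unique(tm$trait))
  if (!trait %in% known) {
    stop("unknown trait '", trait, "'; known traits: ",
         paste(known, collapse = ", "))
  }
  trait_genes <- unique(tm$gene[tm$trait == trait])
  edges <- pan$edges
  if (!is.null(category)) {
    if (anyNA(edges$category)) stop("pan-network is unclassified; run classify_edges()")
    edges <- edges[edges$category == category, , drop = FALSE]
  }
  keep <- edges$gene_a %in% trait_genes & edges$gene_b %in% trait_genes
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(trait = trait, category = category, edges = edges,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b)))),
            class = "trait_subnetwork")
}

#' @export
print.trait_subnetwork <- function(x, ...) {
  cat(sprintf("Trait subnetwork '%s'%s: %d genes, %d edges\n", x$trait,
              if (is.null(x$category)) "" else paste0(" [", x$category, "]"),
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees and hub genes of a subnetwork
#'
#' Degree is the number of incident edges; the genes of maximal degree are
#' the hub genes (all ties reported).
#'
#' @param sub A \code{trait_subnetwork} (or any list with an \code{edges}
#'   data.frame carrying \code{gene_a}, \code{gene_b}).
#' @return List with \code{degrees} (\code{data.frame}: gene, degree, sorted
#'   by decreasing degree then gene) and \code{hubs} (character vector).
#' @export
node_degrees <- function(sub) {
  edges <- if (is.data.frame(sub)) sub else sub$edges
  if (nrow(edges) == 0) {
    return(list(degrees = data.frame(gene = character(), degree = integer(),
                                     stringsAsFactors = FALSE),
                hubs = character()))
  }
  tab <- table(c(edges$gene_a, edges$gene_b))
  df <- data.frame(gene = names(tab), degree = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  list(degrees = df, hubs = df$gene[df$degree == max(df$degree)])
}

#' Hub genes of a subnetwork
#' @inheritParams node_degrees
#' @return Character vector of the maximal-degree genes (ties included).
#' @export
hub_genes <- function(sub) node_degrees(sub)$hubs

#' Per-trait node and edge counts across pan-network categories
#'
#' Reproduces trait-level network statistics: for every trait, the node and
#' edge counts of its subnetwork within each category and in the whole
#' pan-network.
#'
#' @param pan A classified \code{pan_network}.
#' @param trait_map Merged trait-gene map.
#' @param traits Traits to tabulate (default: all traits in the map).
#' @return \code{data.frame}: trait, then \code{<category>_n},
#'   \code{<category>_e} columns for core, near-core, dispensable, private
#'   and pan.
#' @export
trait_category_table <- function(pan, trait_map, traits = NULL) {
  tm <- as.data.frame(trait_map)
  if (is.null(traits)) traits <- sort(unique(tm$trait))
  cats <- c("core", "near-core", "dispensable", "private")
  rows <- lapply(traits, function(tr) {
    row <- list(trait = tr)
    for (cl in cats) {
      s <- trait_subnetwork(pan, trait_map, tr, category = cl)
      row[[paste0(gsub("-", "_", cl), "_n")]] <- length(s$nodes)
      row[[paste0(gsub("-", "_", cl), "_e")]] <- nrow(s$edges)
    }
    s <- trait_subnetwork(pan, trait_map, tr)
    row$pan_n <- length(s$nodes)
    row$pan_e <- nrow(s$edges)
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trait representation across pan-network categories
#'
#' For each trait and category, the proportion of that category's genes
#' that belong to the trait's subnetwork:
#' \code{|nodes(trait, category)| / |genes(category)|}. Because the exact
#' normalization is a modelling choice, a second column rescales the
#' proportions to sum to one across traits within each category
#' (\code{share_within_category}); both are returned, labeled.
#'
#' @param pan A classified \code{pan_network}.
#' @param trait_map Merged trait-gene map.
#' @param categories Categories to include (default all four plus
#'   \code{"pan"}).
#' @param top_k How many top traits per category to flag (default 10).
#' @return List with \code{proportions} (\code{data.frame}: trait, category,
#'   n_genes, category_genes, proportion, share_within_category) and
#'   \code{top_traits} (named list category -> character vector of the
#'   \code{top_k} most represented traits).
#' @export
trait_representation <- function(pan, trait_map, categories = NULL, top_k = 10) {
  stopifnot(inherits(pan, "pan_network"))
  if (anyNA(pan$edges$category)) stop("pan-network is unclassified")
  tm <- as.data.frame(trait_map)
  traits <- sort(unique(tm$trait))
  if (is.null(categories)) {
    categories <- c("core", "near-core", "dispensable", "private", "pan")
  }
  rows <- list()
  for (cl in categories) {
    cat_edges <- if (cl == "pan") pan$edges else
      pan$edges[pan$edges$category == cl, , drop = FALSE]
    cat_genes <- unique(c(cat_edges$gene_a, cat_edges$gene_b))
    for (tr in traits) {
      s <- trait_subnetwork(pan, trait_map, tr,
                            category = if (cl == "pan") NULL else cl)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, category = cl, n_genes = length(s$nodes),
        category_genes = length(cat_genes),
        proportion = if (length(cat_genes)) length(s$nodes) / length(cat_genes) else 0,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$share_within_category <- stats::ave(df$proportion, df$category, FUN = function(x) {
    if (sum(x) > 0) x / sum(x) else x
  })
  top <- lapply(split(df, df$category), function(d) {
    d <- d[order(-d$proportion, d$trait), , drop = FALSE]
    head(d$trait[d$proportion > 0], top_k)
  })
  rownames(df) <- NULL
  list(proportions = df, top_traits = top[unique(df$category)])
}

#' Pleiotropic genes and trait co-occurrence with a focal trait
#'
#' A pleiotropic gene is associated with at least \code{min_traits} distinct
#' (nonredundant) traits. When a focal trait is given, also counts, for each
#' other trait, the pleiotropic focal-trait genes shared with it.
#'
#' @param trait_map Merged trait-gene map.
#' @param min_traits Minimum number of distinct traits (default 2).
#' @param focal_trait Optional focal trait for the co-occurrence table.
#' @param focal_genes Optional gene universe to restrict the focal table to
#'   (e.g. the genes of a trait's pan-subnetwork).
#' @return List with \code{genes} (\code{data.frame}: gene, n_traits, traits
#'   (comma-separated)) and, when \code{focal_trait} is given,
#'   \code{focal_table} (\code{data.frame}: trait, n_genes, sorted
#'   decreasing).
#' @export
pleiotropic_genes <- function(trait_map, min_traits = 2, focal_trait = NULL,
                              focal_genes = NULL) {
  sets <- trait_sets(trait_map)
  n_traits <- lengths(sets)
  keep <- n_traits >= min_traits
  genes <- data.frame(
    gene = names(sets)[keep],
    n_traits = unname(n_traits[keep]),
    traits = vapply(sets[keep], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  genes <- genes[order(-genes$n_traits, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  out <- list(genes = genes)
  if (!is.null(focal_trait)) {
    focal <- sets[vapply(sets, function(s) focal_trait %in% s, logical(1))]
    focal <- focal[names(focal) %in% genes$gene]
    if (!is.null(focal_genes)) focal <- focal[names(focal) %in% focal_genes]
    other <- sort(setdiff(unique(unlist(focal)), focal_trait))
    counts <- vapply(other, function(tr) {
      sum(vapply(focal, function(s) tr %in% s, logical(1)))
    }, integer(1))
    ft <- data.frame(trait = other, n_genes = unname(counts),
                     stringsAsFactors = FALSE)
    ft <- ft[order(-ft$n_genes, ft$trait), , drop = FALSE]
    rownames(ft) <- NULL
    out$focal_table <- ft
    out$n_focal_pleiotropic <- length(focal)
  }
  out
}
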