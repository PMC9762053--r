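#' Union per-genome co-expression networks into a pan-network
#'
#' The pan-network is the union of the co-expression pairs over all genomes:
#' one edge per distinct unordered gene pair, annotated with the set of
#' genomes in which the pair is significant and its occurrence (the size of
#' that set). Categories are assigned separately by [classify_edges()].
#'
#' @param per_genome_edges Named list mapping genome ID to an edge
#'   \code{data.frame} (\code{gene_a}, \code{gene_b}, ...), as produced by
#'   [build_network()].
#' @return A \code{pan_network} object: list with \code{edges} (a
#'   \code{data.frame} with \code{gene_a}, \code{gene_b}, \code{occurrence},
#'   \code{genomes} (comma-separated), \code{category} (NA until
#'   classified)) and \code{genomes} (the input genome IDs, in order).
#' @export
union_networks <- function(per_genome_edges) {
  if (length(per_genome_edges) < 1) stop("need at least one genome")
  if (is.null(names(per_genome_edges)) || any(names(per_genome_edges) == "")) {
    stop("per_genome_edges must be a named list (genome IDs)")
  }
  genomes <- names(per_genome_edges)
  pieces <- lapply(genomes, function(g) {
    e <- per_genome_edges[[g]]
    if (nrow(e) == 0) return(NULL)
    cp <- canonical_pairs(e$gene_a, e$gene_b)
    data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b, genome = g,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  if (is.null(all)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        occurrence = integer(), genomes = character(),
                        category = character(), stringsAsFactors = FALSE)
  } else {
    key <- pair_key(all$gene_a, all$gene_b)
    by_key <- split(all$genome, key)
    keys <- sort(names(by_key))
    gsets <- lapply(by_key[keys], function(g) genomes[sort(match(unique(g), genomes))])
    parts <- strsplit(keys, "\t", fixed = TRUE)
    edges <- data.frame(
      gene_a = vapply(parts, `[`, character(1), 1L),
      gene_b = vapply(parts, `[`, character(1), 2L),
      occurrence = lengths(gsets),
      genomes = vapply(gsets, paste, character(1), collapse = ","),
      category = NA_character_,
      stringsAsFactors = FALSE
    )
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, genomes = genomes), class = "pan_network")
}

#' Classify pan-network edges into core, near-core, dispensable and private
#'
#' Edges are ranked by occurrence (number of genomes supporting them),
#' descending, and whole occurrence levels are assigned greedily:
#' \itemize{
#'   \item \strong{core}: the maximal prefix of occurrence levels whose
#'     cumulative edge fraction stays at or below \code{core_frac};
#'   \item \strong{near-core}: the subsequent levels up to and including the
#'     level at which the cumulative fraction first reaches
#'     \code{nearcore_frac};
#'   \item \strong{private}: every edge observed in exactly one genome,
#'     unconditionally (occurrence-1 levels never enter core or near-core);
#'   \item \strong{dispensable}: the remainder.
#' }
#' All edges at the same occurrence level share a category, so the realized
#' core fraction under-shoots \code{core_frac} while core plus near-core
#' crosses \code{nearcore_frac}. With \code{strict_core = TRUE} the core is
#' instead the edges present in every genome (the classical pan-genome
#' "core" definition), near-core still fills to \code{nearcore_frac}.
#'
#' @param pan A \code{pan_network} from [union_networks()].
#' @param core_frac Target cumulative edge fraction for the core (default
#'   0.01, i.e. the highest represented ~1% of pairs).
#' @param nearcore_frac Cumulative fraction at which near-core stops
#'   (default 0.05).
#' @param strict_core Use the all-genomes core definition instead of the
#'   top-fraction rule (default \code{FALSE}).
#' @return The \code{pan_network} with \code{edges$category} filled in; the
#'   four categories partition the edge set.
#' @export
classify_edges <- function(pan, core_frac = 0.01, nearcore_frac = 0.05,
                           strict_core = FALSE) {
  stopifnot(inherits(pan, "pan_network"))
  if (core_frac >= nearcore_frac) stop("core_frac must be < nearcore_frac")
  if (core_frac <= 0 || nearcore_frac >= 1) stop("need 0 < core_frac < nearcore_frac < 1")
  edges <- pan$edges
  if (nrow(edges) == 0) stop("pan-network has no edges")
  occ <- edges$occurrence
  total <- length(occ)
  levels_desc <- sort(unique(occ), decreasing = TRUE)
  counts <- vapply(levels_desc, function(l) sum(occ == l), integer(1))
  category_of_level <- setNames(rep("dispensable", length(levels_desc)),
                                levels_desc)
  cum <- cumsum(counts) / total
  eligible <- levels_desc > 1
  if (strict_core) {
    n_genomes <- length(pan$genomes)
    core_lv <- eligible & levels_desc == n_genomes
  } else {
    core_lv <- eligible & cum <= core_frac
    # maximal prefix only: stop at the first level that overflows
    if (any(!core_lv)) core_lv[seq_along(core_lv) >= which(!core_lv)[1]] <- FALSE
  }
  after_core <- if (any(core_lv)) max(which(core_lv)) else 0L
  crossing <- which(cum >= nearcore_frac & eligible)
  nearcore_end <- if (length(crossing)) crossing[1] else max(which(eligible), 0L)
  nc_lv <- rep(FALSE, length(levels_desc))
  if (nearcore_end > after_core) {
    nc_lv[(after_core + 1L):nearcore_end] <- eligible[(after_core + 1L):nearcore_end]
  }
  category_of_level[core_lv] <- "core"
  category_of_level[nc_lv] <- "near-core"
  category_of_level[levels_desc == 1] <- "private"
  edges$category <- unname(category_of_level[as.character(occ)])
  pan$edges <- edges
  pan$core_frac <- core_frac
  pan$nearcore_frac <- nearcore_frac
  pan
}

#' Per-category gene and edge counts
#'
#' For each category and for the whole pan-network: the number of edges and
#' the number of distinct genes incident to at least one edge of the
#' category. A gene incident to edges of several categories is counted in
#' each, so category gene counts may sum to more than the pan total. Also
#' returns the occurrence histogram (edges per number of supporting
#' genomes) and per-genome private edge counts.
#'
#' @param pan A classified \code{pan_network}.
#' @return List with \code{table} (\code{data.frame}: category, n_genes,
#'   n_edges; last row \code{pan}), \code{occurrence_histogram}
#'   (\code{data.frame}: occurrence, n_edges) and \code{private_per_genome}
#'   (named integer vector).
#' @export
category_summary <- function(pan) {
  stopifnot(inherits(pan, "pan_network"))
  edges <- pan$edges
  if (nrow(edges) > 0 && anyNA(edges$category)) {
    stop("unclassified edges present; run classify_edges() first")
  }
  cats <- c("core", "near-core", "dispensable", "private")
  rows <- lapply(cats, function(cl) {
    e <- edges[edges$category == cl, , drop = FALSE]
    data.frame(category = cl,
               n_genes = length(unique(c(e$gene_a, e$gene_b))),
               n_edges = nrow(e), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(
    category = "pan",
    n_genes = length(unique(c(edges$gene_a, edges$gene_b))),
    n_edges = nrow(edges), stringsAsFactors = FALSE))
  occ_tab <- table(factor(edges$occurrence,
                          levels = seq_len(max(edges$occurrence, 1L))))
  occ_hist <- data.frame(occurrence = as.integer(names(occ_tab)),
                         n_edges = as.integer(occ_tab))
  priv <- edges[edges$occurrence == 1L, , drop = FALSE]
  private_per_genome <- vapply(pan$genomes,
                               function(g) sum(priv$genomes == g), integer(1))
  list(table = tab, occurrence_histogram = occ_hist,
       private_per_genome = private_per_genome)
}

#' Pan- and core-network growth curves under genome subsampling
#'
#' For k = 1..G genomes, draws random genome subsets of size k and records
#' the pan-network size (edges present in at least one subset genome) and
#' the core-network size after re-classifying occurrences within the
#' subset. Averages and standard deviations over the replicates trace how
#' the pan-network grows and the core shrinks as genomes are added.
#'
#' @param pan A \code{pan_network} (classification not required).
#' @param n_reps Replicates per subset size (default 100).
#' @param core_frac,nearcore_frac Classification fractions used within each
#'   subset (defaults 0.01 / 0.05).
#' @param seed Integer seed for the subsampling.
#' @return \code{data.frame}: \code{k}, \code{pan_mean}, \code{pan_sd},
#'   \code{core_mean}, \code{core_sd}.
#' @export
growth_curve <- function(pan, n_reps = 100, core_frac = 0.01,
                         nearcore_frac = 0.05, seed = 1L) {
  stopifnot(inherits(pan, "pan_network"))
  genomes <- pan$genomes
  G <- length(genomes)
  gsets <- strsplit(pan$edges$genomes, ",", fixed = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(G), function(k) {
    pan_sizes <- core_sizes <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      sub <- if (k == G) genomes else sample(genomes, k)
      occ_sub <- vapply(gsets, function(gs) sum(gs %in% sub), integer(1))
      present <- occ_sub > 0L
      pan_sizes[i] <- sum(present)
      core_sizes[i] <- core_size_from_occ(occ_sub[present], core_frac)
    }
    data.frame(k = k, pan_mean = mean(pan_sizes), pan_sd = stats::sd(pan_sizes),
               core_mean = mean(core_sizes), core_sd = stats::sd(core_sizes))
  })
  do.call(rbind, rows)
}

# core edge count under the level-granular top-fraction rule for a vector of
# subset occurrences (occurrence-1 edges never core)
core_size_from_occ <- function(occ, core_frac) {
  if (length(occ) == 0) return(0)
  lv <- sort(unique(occ), decreasing = TRUE)
  counts <- vapply(lv, function(l) sum(occ == l), integer(1))
  cum <- cumsum(counts) / length(occ)
  ok <- cum <= core_frac & lv > 1
  if (any(!ok)) ok[seq_along(ok) >= which(!ok)[1]] <- FALSE
  sum(counts[ok])
}

#' @export
print.pan_network <- function(x, ...) {
  cat("Pan-genome co-expression network\n")
  cat(sprintf("  genomes: %d\n", length(x$genomes)))
  cat(sprintf("  edges:   %d  (genes: %d)\n", nrow(x$edges),
              length(unique(c(x$edges$gene_a, x$edges$gene_b)))))
  if (nrow(x$edges) > 0 && !anyNA(x$edges$category)) {
    tb <- table(factor(x$edges$category,
                       levels = c("core", "near-core", "dispensable", "private")))
    cat("  categories:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "), "\n")
  } else {
    cat("  categories: <unclassified>\n")
  }
  invisible(x)
}

#' @export
summary.pan_network <- function(object, ...) {
  if (anyNA(object$edges$category)) {
    stop("classify_edges() must be run before summary()")
  }
  category_summary(object)
}

#' Plot a pan-network overview
#'
#' Two base-graphics panels: the occurrence histogram of edges (how many
#' genomes support each pair) and the growth curve of pan and core edge
#' counts under genome subsampling.
#'
#' @param x A \code{pan_network}.
#' @param n_reps Growth-curve replicates (default 20).
#' @param seed Seed for the growth-curve subsampling.
#' @param ... Passed to \code{barplot}/\code{plot}.
#' @export
plot.pan_network <- function(x, n_reps = 20, seed = 1L, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  cs <- category_summary(if (anyNA(x$edges$category)) {
    classify_edges(x)
  } else x)
  graphics::barplot(cs$occurrence_histogram$n_edges,
                    names.arg = cs$occurrence_histogram$occurrence,
                    xlab = "genomes supporting edge", ylab = "edges",
                    main = "Occurrence histogram", ...)
  gc <- growth_curve(x, n_reps = n_reps, seed = seed)
  graphics::plot(gc$k, gc$pan_mean, type = "b", pch = 16,
                 xlab = "genomes sampled", ylab = "edges",
                 main = "Pan / core growth", ...)
  graphics::lines(gc$k, gc$core_mean, type = "b", pch = 1, lty = 2)
  graphics::legend("topleft", legend = c("pan", "core"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Write pan-network edges as TSV
#'
#' Emits pair, occurrence, supporting genome list and category, one row per
#' pan-edge.
#'
#' @param pan A \code{pan_network}.
#' @param path Output path.
#' @export
write_pan_network <- function(pan, path) {
  write_tsv(pan$edges, path)
}
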