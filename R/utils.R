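#' @importFrom stats cor median pt phyper p.adjust runif rnorm setNames
#' @importFrom utils read.delim write.table head combn
NULL

# Canonicalize an unordered gene pair: gene_a < gene_b under the natural
# character ordering (C collation, locale-independent).
canonical_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  swap <- cmp_gt(a, b)
  ga <- ifelse(swap, b, a)
  gb <- ifelse(swap, a, b)
  if (any(ga == gb)) stop("self-pairs are not allowed (gene_a == gene_b)")
  list(gene_a = ga, gene_b = gb)
}

# locale-independent string comparison
cmp_gt <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  a > b
}

pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\t")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic md5 of a canonical string (base tools only).
string_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(x, tf, sep = "")
  unname(tools::md5sum(tf))
}

# Numbers are written with full precision but a fixed format so that reruns
# are byte-identical across platforms.
format_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  cols <- vapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) format_num(col) else as.character(col)
  }, FUN.VALUE = character(nrow(df) %||% 0L))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L, dimnames = list(NULL, names(df)))
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df) > 0L) apply(cols, 1L, paste, collapse = "\t")
  )
  writeLines(lines, con)
  invisible(path)
}
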