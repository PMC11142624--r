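#' Load gene sets from a gmt file
#'
#' Standard tab-separated gmt: set name, description, then member genes.
#' Duplicate genes within a set are collapsed; a line with fewer than three
#' fields is a parse error reporting the line number; duplicate set names
#' are a collection error.
#'
#' @param path gmt file path
#' @return named list of character vectors (class `gene_set_collection`);
#'   each element carries its description in attribute `"description"`
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("gmt not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("load_gmt: line %d has %d field(s); need name, description, >=1 gene",
                   i, length(fields)), call. = FALSE)
    name <- fields[1L]
    if (name %in% names(sets))
      stop(sprintf("load_gmt: duplicate set name '%s' at line %d", name, i),
           call. = FALSE)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("load_gmt: set '%s' (line %d) has no genes", name, i),
           call. = FALSE)
    sets[[name]] <- structure(genes, description = fields[2L])
  }
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets to a gmt file
#'
#' @param sets named list of character vectors
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each set, genes are first intersected with the universe; sets whose
#' effective size falls below `min_size` are excluded (knowledge-based
#' collections are only considered reliable from 20 genes up, the
#' default). The p-value is the upper hypergeometric tail
#' `P(X >= k)` for `k` query genes falling in a set of size `K`, drawing
#' `n` from a universe of `N`; Benjamini-Hochberg adjustment is applied
#' across the tested sets.
#'
#' @param query character vector of (DAS) gene identifiers; genes outside
#'   the universe are dropped with a warning
#' @param sets a [load_gmt()] collection or named list of gene vectors
#' @param universe character vector of all eligible genes
#' @param min_size minimum effective set size (default 20)
#' @return data.frame sorted by `p_adj` then set name, with columns
#'   `set`, `k`, `K`, `n`, `N`, `p`, `p_adj`
#' @export
ora_test <- function(query, sets, universe, min_size = 20L) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (length(universe) == 0L) stop("ora_test: empty universe", call. = FALSE)
  if (length(query) == 0L) stop("ora_test: empty query", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(sprintf("ora_test: dropping %d query gene(s) outside the universe",
                    length(outside)), call. = FALSE)
    query <- intersect(query, universe)
    if (length(query) == 0L) stop("ora_test: empty query after universe restriction",
                                  call. = FALSE)
  }
  N <- length(universe); n <- length(query)
  eff <- lapply(sets, function(g) intersect(unique(as.character(g)), universe))
  keep <- vapply(eff, length, integer(1)) >= min_size
  eff <- eff[keep]
  if (length(eff) == 0L)
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  K <- vapply(eff, length, integer(1))
  k <- vapply(eff, function(g) length(intersect(g, query)), integer(1))
  # upper tail P(X >= k); k = 0 gives p = 1 exactly
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(set = names(eff), k = k, K = K, n = n, N = N, p = p,
                    p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  res <- res[order(res$p_adj, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, capped at 1
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Test pairwise dependency between two feature classes
#'
#' Builds the 2x2 presence/absence table of the two classes over the
#' annotated events and applies the two-sided Fisher exact test. The
#' reported odds ratio is the sample odds ratio `(a*d)/(b*c)`, with 0.5
#' added to every cell iff any cell is zero (Haldane correction).
#'
#' @param table an annotation table from [annotate_events()]
#' @param class_a,class_b two of the twelve feature class codes
#' @return list of class `dependency_result`: `classes`, `table` (2x2
#'   matrix: rows = class_a present/absent, cols = class_b), `odds_ratio`,
#'   `p`
#' @export
feature_dependency_test <- function(table, class_a, class_b) {
  for (cls in c(class_a, class_b))
    if (!cls %in% names(CLASS_COLUMN_MAP))
      stop(sprintf("feature_dependency_test: unknown class '%s'", cls),
           call. = FALSE)
  if (nrow(table) == 0L)
    stop("feature_dependency_test: no annotated events", call. = FALSE)
  pres <- class_presence(table)
  pa <- pres[, class_a]; pb <- pres[, class_b]
  a <- sum(pa & pb); b <- sum(pa & !pb); c_ <- sum(!pa & pb); d <- sum(!pa & !pb)
  m <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE,
              dimnames = list(c("A_present", "A_absent"),
                              c("B_present", "B_absent")))
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    stop(sprintf("feature_dependency_test: degenerate table (%s or %s present in all or no events)",
                 class_a, class_b), call. = FALSE)
  cells <- c(a, b, c_, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  p <- stats::fisher.test(m, alternative = "two.sided")$p.value
  structure(list(classes = c(class_a, class_b), table = m,
                 odds_ratio = or, p = p),
            class = "dependency_result")
}

#' @exportS3Method print dependency_result
print.dependency_result <- function(x, ...) {
  cat(sprintf("<dependency_result> %s vs %s: OR = %.3g, two-sided Fisher p = %.3g\n",
              x$classes[1L], x$classes[2L], x$odds_ratio, x$p))
  print(x$table)
  invisible(x)
}
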