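# Module functional enrichment: one-sided Fisher's exact
# (hypergeometric) over-representation test per (module, category, term)
# with Bonferroni correction within each (module, category) family.

#' One-sided Fisher over-representation P value
#'
#' Tests whether a term's genes are over-represented in a module relative
#' to a background universe: the upper hypergeometric tail of the observed
#' module/term overlap given the margins, identical to a one-sided Fisher
#' exact test on the 2x2 table.
#'
#' Term genes outside the background are ignored (with a message).
#'
#' @param module_genes Character vector of module gene ids (must be a
#'   subset of `background`).
#' @param term_genes Character vector of term gene ids.
#' @param background Character vector, the gene universe.
#' @return The one-sided over-representation P value.
#' @export
fisher_overrep <- function(module_genes, term_genes, background) {
  background <- unique(background)
  if (length(background) == 0)
    stop("background universe must be non-empty", call. = FALSE)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% background))
    stop("module genes must be a subset of the background", call. = FALSE)
  term_genes <- unique(term_genes)
  outside <- sum(!(term_genes %in% background))
  if (outside > 0) {
    message(sprintf("%d term gene(s) outside the background ignored",
                    outside))
    term_genes <- term_genes[term_genes %in% background]
  }
  n_bg <- length(background)
  n_term <- length(term_genes)
  n_mod <- length(module_genes)
  x <- length(intersect(module_genes, term_genes))
  # upper tail P(X >= x) for X ~ Hypergeometric(n_term, n_bg - n_term, n_mod)
  stats::phyper(x - 1, n_term, n_bg - n_term, n_mod, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * m)` with `m` the family size (defaults to the
#' number of P values supplied).
#'
#' @param p_values Numeric vector of P values in \[0, 1\].
#' @param m Family size, >= length(p_values) tests assumed (default
#'   `length(p_values)`).
#' @return Adjusted P values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("P values must lie in [0, 1]", call. = FALSE)
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' A gene-set collection
#'
#' @param category Collection name (e.g. `"KEGG_PATHWAY"`).
#' @param sets Named list of character vectors, term -> member gene ids;
#'   no empty sets.
#' @param descriptions Optional named character vector of term
#'   descriptions.
#' @return Object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(category, sets, descriptions = NULL) {
  if (!is.character(category) || length(category) != 1L)
    stop("category must be a single string", call. = FALSE)
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list of gene id vectors", call. = FALSE)
  if (any(lengths(sets) == 0))
    stop("gene-set collections may not contain empty terms", call. = FALSE)
  structure(list(category = category,
                 sets = lapply(sets, function(s) unique(as.character(s))),
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d term(s), %d distinct gene(s)\n",
              x$category, length(x$sets),
              length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Enrichment of annotation terms in each module
#'
#' For every non-grey module and every term of every collection: the
#' module/term overlap count, the percentage of the module covered, the
#' one-sided Fisher over-representation P value against the background,
#' and the Bonferroni-adjusted P value within the (module, category)
#' family.  Grey (unassigned) genes never form a module but remain part of
#' the background when present there.
#'
#' Terms with fewer than 2 background members are untestable and skipped
#' (counted in attribute `"skipped_terms"`).
#'
#' @param assignment `"module_assignment"` from [cut_modules()] (or any
#'   named colour vector with `"grey"` = unassigned).
#' @param collections A `"gene_set_collection"` or list of them.
#' @param background Character vector of gene ids; defaults to the genes
#'   of `assignment`.
#' @return Data frame `module`, `category`, `term`, `count`, `percent`,
#'   `p_value`, `p_bonferroni`, sorted by (module, category, p_value).
#' @export
enrich_modules <- function(assignment, collections,
                           background = names(assignment)) {
  if (inherits(collections, "gene_set_collection"))
    collections <- list(collections)
  if (!all(vapply(collections, inherits, logical(1), "gene_set_collection")))
    stop("collections must be gene_set_collection objects", call. = FALSE)
  background <- unique(as.character(background))
  labels <- unclass(assignment)
  modules <- setdiff(unique(labels), "grey")
  if (length(modules) == 0)
    stop("no non-grey modules to test", call. = FALSE)
  # preserve palette (size-rank) order where known
  modules <- modules[order(match(modules, module_palette()))]

  rows <- list()
  skipped <- 0L
  for (mod in modules) {
    mod_genes <- intersect(names(labels)[labels == mod], background)
    for (coll in collections) {
      res <- lapply(names(coll$sets), function(term) {
        tg <- intersect(coll$sets[[term]], background)
        if (length(tg) < 2) return(NULL)
        cnt <- length(intersect(mod_genes, tg))
        data.frame(module = mod, category = coll$category, term = term,
                   count = cnt,
                   percent = 100 * cnt / length(mod_genes),
                   p_value = fisher_overrep(mod_genes, tg, background),
                   stringsAsFactors = FALSE)
      })
      skipped <- skipped + sum(vapply(res, is.null, logical(1)))
      res <- do.call(rbind, res)
      if (!is.null(res) && nrow(res) > 0) {
        res$p_bonferroni <- bonferroni(res$p_value)
        res <- res[order(res$p_value, res$term), , drop = FALSE]
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), category = character(0),
               term = character(0), count = integer(0),
               percent = numeric(0), p_value = numeric(0),
               p_bonferroni = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_terms") <- skipped
  out
}
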