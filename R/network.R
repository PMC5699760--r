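# Weighted gene co-expression network construction: soft-threshold
# adjacency a_ij = |cor(x_i, x_j)|^beta, scale-free topology fit for beta
# selection, topological overlap, average-linkage module detection with
# colour labels, and recovery scoring against planted truth.

#' Pairwise Pearson correlation between genes
#'
#' @param expression Numeric matrix, genes x samples, >= 3 samples; every
#'   gene must have nonzero variance (filter constant genes first).
#' @return Symmetric correlation matrix with unit diagonal and the gene ids
#'   as dimnames.
#' @export
pearson_correlation <- function(expression) {
  expression <- validate_expression(expression)
  if (ncol(expression) < 3)
    stop("at least 3 samples are required for correlation", call. = FALSE)
  v <- apply(expression, 1, stats::var)
  if (any(v == 0))
    stop(sprintf("zero-variance gene(s): %s",
                 paste(utils::head(rownames(expression)[v == 0], 5),
                       collapse = ", ")), call. = FALSE)
  r <- stats::cor(t(expression))
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Raises the absolute correlation to the power `beta`,
#' `a_ij = |cor(x_i, x_j)|^beta`, turning a hard correlation cutoff into a
#' continuous connection strength.  The diagonal is set to 0 so that
#' self-similarity never contributes to connectivity or topological
#' overlap.
#'
#' @param cor_mat Symmetric correlation matrix (unit diagonal).
#' @param beta Positive soft-threshold power.
#' @return Adjacency matrix in \[0, 1\] with zero diagonal and attribute
#'   `"beta"`.
#' @export
soft_adjacency <- function(cor_mat, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0)
    stop("beta must be a single positive number", call. = FALSE)
  adj <- abs(cor_mat)^beta
  diag(adj) <- 0
  attr(adj, "beta") <- beta
  adj
}

#' Whole-network connectivity
#'
#' `k_i = sum_{j != i} a_ij`, each gene's summed connection strength.
#'
#' @param adj Adjacency matrix (zero diagonal).
#' @return Named numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  check_adjacency(adj)
  rowSums(adj)
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (any(adj < 0) || any(adj > 1))
    stop("adjacency values must lie in [0, 1]", call. = FALSE)
  if (any(diag(adj) != 0))
    stop("adjacency diagonal must be zero", call. = FALSE)
  invisible(adj)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `n_bins` equal-width bins, estimates the
#' degree density p(k) as the fraction of genes per bin, and fits the
#' ordinary least-squares regression of log10 p(k) on log10 (mean k per
#' bin) over the non-empty bins.  An approximately scale-free network gives
#' a straight, negatively sloped line; the signed fit index
#' `-sign(slope) * R^2` is therefore close to 1 for scale-free topology and
#' cannot be inflated by an increasing density.
#'
#' @param k Numeric vector of connectivities (>= 2 genes with k > 0).
#' @param n_bins Number of equal-width bins (default 10).
#' @return Object of class `"scale_free_fit"`: list with `r_squared`,
#'   `slope`, `signed_index`, `bins_used`, and the `bins` table
#'   (`k_mean`, `p`).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- as.numeric(k)
  if (sum(k > 0) < 2)
    stop("need at least 2 genes with positive connectivity", call. = FALSE)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  if (breaks[1] == breaks[length(breaks)])
    stop("connectivities are all identical; cannot bin", call. = FALSE)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  k_mean <- vapply(seq_len(n_bins),
                   function(b) if (counts[b] > 0) mean(k[bin == b]) else NA_real_,
                   numeric(1))
  keep <- counts > 0 & !is.na(k_mean) & k_mean > 0
  if (sum(keep) < 2)
    stop("fewer than 2 usable bins; cannot fit scale-free model",
         call. = FALSE)
  p <- counts[keep] / length(k)
  km <- k_mean[keep]
  lp <- log10(p)
  lk <- log10(km)
  if (stats::var(lp) == 0) {
    # flat density: slope 0 by definition, no variance to explain
    slope <- 0
    r2 <- 0
  } else {
    # simple OLS of log10 p(k) on log10 k
    slope <- stats::cov(lk, lp) / stats::var(lk)
    r2 <- stats::cor(lk, lp)^2
  }
  structure(
    list(r_squared = r2,
         slope = slope,
         signed_index = -sign(slope) * r2,
         bins_used = sum(keep),
         bins = data.frame(k_mean = km, p = p)),
    class = "scale_free_fit")
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat(sprintf(
    "scale-free fit: R^2 = %.3f, slope = %.3f, signed index = %.3f (%d bins)\n",
    x$r_squared, x$slope, x$signed_index, x$bins_used))
  invisible(x)
}

#' Select the soft-threshold power by the scale-free criterion
#'
#' Sweeps candidate powers, computes the signed scale-free fit index of the
#' resulting connectivity distribution at each, and returns the smallest
#' candidate whose signed index reaches `target`.  If no candidate
#' qualifies, the candidate with the largest signed index is returned with
#' a warning and `reached_target = FALSE`.
#'
#' @param cor_mat Correlation matrix from [pearson_correlation()].
#' @param candidates Candidate powers (default `1:20`).
#' @param target Required signed fit index (default 0.8).
#' @param n_bins Bins passed to [scale_free_fit()].
#' @return List with `beta` (selected power), `fit` (its
#'   [scale_free_fit()]), `reached_target`, and `sweep`, a data frame of
#'   `beta`, `r_squared`, `slope`, `signed_index`, `bins_used` for every
#'   candidate (NA rows where the fit failed).
#' @export
select_beta <- function(cor_mat, candidates = 1:20, target = 0.8,
                        n_bins = 10) {
  if (length(candidates) < 1)
    stop("candidate list must be non-empty", call. = FALSE)
  fits <- vector("list", length(candidates))
  sweep <- data.frame(beta = as.numeric(candidates),
                      r_squared = NA_real_, slope = NA_real_,
                      signed_index = NA_real_, bins_used = NA_integer_)
  for (i in seq_along(candidates)) {
    f <- tryCatch(
      scale_free_fit(connectivity(soft_adjacency(cor_mat, candidates[i])),
                     n_bins = n_bins),
      error = function(e) e)
    if (inherits(f, "scale_free_fit")) {
      fits[[i]] <- f
      sweep$r_squared[i] <- f$r_squared
      sweep$slope[i] <- f$slope
      sweep$signed_index[i] <- f$signed_index
      sweep$bins_used[i] <- f$bins_used
    }
  }
  ok <- which(!is.na(sweep$signed_index))
  if (length(ok) == 0)
    stop("scale-free fit failed for every candidate beta", call. = FALSE)
  hit <- ok[sweep$signed_index[ok] >= target]
  if (length(hit) > 0) {
    sel <- hit[which.min(candidates[hit])]
    reached <- TRUE
  } else {
    sel <- ok[which.max(sweep$signed_index[ok])]
    reached <- FALSE
    warning(sprintf(
      "no candidate beta reached signed fit index %.2f; returning beta = %g (index %.3f)",
      target, candidates[sel], sweep$signed_index[sel]), call. = FALSE)
  }
  list(beta = candidates[sel], fit = fits[[sel]],
       reached_target = reached, sweep = sweep)
}

#' Topological overlap matrix
#'
#' Transforms an adjacency matrix into the topological overlap similarity
#' `w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_{u != i,j} a_iu a_uj`, the standard weighted-network
#' generalisation: two genes overlap when they are directly connected and
#' when they share neighbours.  With adjacency in \[0, 1\] the overlap is
#' guaranteed to lie in \[0, 1\]; the diagonal is 1 by convention.
#'
#' @param adj Adjacency matrix in \[0, 1\] with zero diagonal.
#' @return Symmetric TOM matrix with unit diagonal; `1 - tom()` is the
#'   clustering dissimilarity.
#' @export
tom_similarity <- function(adj) {
  check_adjacency(adj)
  k <- rowSums(adj)
  l <- adj %*% adj          # a_ii = 0, so (A^2)_ij = sum_{u != i,j} a_iu a_uj
  denom <- outer(k, k, pmin) + 1 - adj
  w <- (l + adj) / denom
  diag(w) <- 1
  w <- (w + t(w)) / 2       # symmetrise away rounding asymmetry
  attr(w, "beta") <- NULL
  dimnames(w) <- dimnames(adj)
  w
}

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' @param dissim Symmetric non-negative dissimilarity matrix with zero
#'   diagonal, typically `1 - tom_similarity(adj)`.
#' @return An [stats::hclust] tree (method `"average"`); merge heights are
#'   non-decreasing.
#' @export
average_linkage <- function(dissim) {
  if (!is.matrix(dissim) || nrow(dissim) != ncol(dissim))
    stop("dissimilarity must be a square matrix", call. = FALSE)
  if (max(abs(dissim - t(dissim))) > 1e-8)
    stop("dissimilarity must be symmetric", call. = FALSE)
  if (any(diag(dissim) != 0))
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  if (any(dissim < 0))
    stop("dissimilarity must be non-negative", call. = FALSE)
  stats::hclust(stats::as.dist(dissim), method = "average")
}

# Fixed module colour palette, assigned in decreasing module-size order.
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue")
}

#' Cut a dendrogram into colour-labelled modules
#'
#' Cuts the tree at a static height; every resulting cluster with at least
#' `min_size` genes becomes a module, labelled from a fixed colour palette
#' (turquoise, blue, brown, yellow, green, ...) in decreasing size order
#' (size ties broken by the smallest leaf index).  Genes in smaller
#' clusters are unassigned and labelled `"grey"`.
#'
#' The default cut height is `0.99 * max(tree$height)`: a static cut just
#' below the top of the dendrogram, beneath which tight modules (including
#' their peripheral members) have already agglomerated while unclustered
#' genes, whose topological-overlap dissimilarities sit on a plateau near
#' the maximum, have not.  The 0.99 fraction is the conventional static
#' cut used with topological-overlap dendrograms.
#'
#' @param tree An [stats::hclust] tree from [average_linkage()].
#' @param height Cut height (> 0); default `0.99 * max(tree$height)`.
#' @param min_size Minimum module size (default 30).
#' @return Named character vector of class `"module_assignment"` mapping
#'   gene id to colour, `"grey"` = unassigned.
#' @export
cut_modules <- function(tree, height = NULL, min_size = 30) {
  if (!inherits(tree, "hclust"))
    stop("tree must be an hclust object", call. = FALSE)
  if (is.null(height)) height <- 0.99 * max(tree$height)
  if (!is.finite(height) || height <= 0)
    stop("height must be a positive number", call. = FALSE)
  if (min_size < 1)
    stop("min_size must be >= 1", call. = FALSE)
  # exact merge-height ties can wiggle by float noise; cutree requires
  # strictly sorted heights
  tree$height <- cummax(tree$height)
  cl <- stats::cutree(tree, h = height)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  # order surviving clusters by decreasing size, ties by smallest leaf index
  first_leaf <- vapply(keep, function(id) min(which(cl == id)), integer(1))
  keep <- keep[order(-as.integer(sizes[as.character(keep)]), first_leaf)]
  palette <- module_palette()
  if (length(keep) > length(palette))
    palette <- c(palette,
                 sprintf("module%d", seq_len(length(keep) - length(palette))))
  colours <- rep("grey", length(cl))
  for (i in seq_along(keep)) colours[cl == keep[i]] <- palette[i]
  names(colours) <- names(cl)
  structure(colours, class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  tab <- sort(table(unclass(x)), decreasing = TRUE)
  cat(sprintf("module assignment: %d genes, %d module(s) + grey\n",
              length(x), sum(names(tab) != "grey")))
  print(tab)
  invisible(x)
}

#' Adjusted Rand index between two labelled partitions
#'
#' Chance-corrected agreement between two partitions of the same elements:
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param labels_a,labels_b Vectors of cluster labels over the same
#'   elements (compared positionally).
#' @return The adjusted Rand index, a single number <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must cover the same elements", call. = FALSE)
  n <- length(labels_a)
  if (n < 2) return(1)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Score module recovery against planted truth
#'
#' Computes the adjusted Rand index between a module assignment and the
#' planted module labels, treating unassigned (`"grey"`) and background
#' genes as one class each.
#'
#' @param assignment `"module_assignment"` (named colour vector) from
#'   [cut_modules()].
#' @param truth Named vector of planted module labels (e.g. `"M1"`,
#'   `"background"`) covering the same genes.
#' @return Adjusted Rand index.
#' @export
module_recovery <- function(assignment, truth) {
  genes <- names(assignment)
  if (is.null(genes) || is.null(names(truth)))
    stop("assignment and truth must be named by gene id", call. = FALSE)
  if (!setequal(genes, names(truth)))
    stop("assignment and truth must cover the same genes", call. = FALSE)
  adjusted_rand_index(unclass(assignment)[genes], truth[genes])
}

#' Export network edges above a weight threshold
#'
#' @param mat Symmetric similarity matrix (TOM or adjacency) with gene id
#'   dimnames.
#' @param threshold Keep edges with weight >= threshold.
#' @return Data frame `gene_a`, `gene_b`, `weight`; each unordered pair
#'   appears once with `gene_a < gene_b` lexicographically, rows sorted by
#'   (`gene_a`, `gene_b`).
#' @export
export_edges <- function(mat, threshold) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) || is.null(rownames(mat)))
    stop("mat must be a square matrix with gene id dimnames", call. = FALSE)
  if (!is.finite(threshold))
    stop("threshold must be finite", call. = FALSE)
  idx <- which(upper.tri(mat) & mat >= threshold, arr.ind = TRUE)
  ids <- rownames(mat)
  a <- ids[idx[, 1]]; b <- ids[idx[, 2]]
  ga <- pmin(a, b); gb <- pmax(a, b)
  out <- data.frame(gene_a = ga, gene_b = gb, weight = mat[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
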