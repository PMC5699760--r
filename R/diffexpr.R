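# Two-group differential expression on log10-ratio expression data:
# pooled-variance Student t-test per gene plus a geometric fold change
# FC = 10^|mean_F - mean_M|, reported >= 1 with a separate bias direction.

#' Fold change and bias direction from group means
#'
#' Expression values are log10(sample/reference) ratios, so a difference of
#' group means is a log10 ratio of geometric means and the linear-scale fold
#' change is `10^|mean_f - mean_m|`.  The fold change is always >= 1; the
#' sign of the difference is reported separately as the biased sex.
#'
#' @param mean_f,mean_m Mean log10 ratio in females / males (vectorised).
#' @return A data frame with columns `fold_change` (>= 1) and `bias`
#'   (`"F"`, `"M"` or `"none"` when the means are identical).
#' @examples
#' compute_fold_change(1, 0)     # 10-fold, female-biased
#' compute_fold_change(0.5, 0.5) # no difference
#' @export
compute_fold_change <- function(mean_f, mean_m) {
  if (length(mean_f) != length(mean_m))
    stop("mean_f and mean_m must have the same length", call. = FALSE)
  if (any(!is.finite(mean_f)) || any(!is.finite(mean_m)))
    stop("group means must be finite to compute a fold change",
         call. = FALSE)
  d <- mean_f - mean_m
  data.frame(fold_change = 10^abs(d),
             bias = ifelse(d > 0, "F", ifelse(d < 0, "M", "none")),
             stringsAsFactors = FALSE)
}

# Vectorised pooled-variance two-sample t over the rows of two matrices.
# Returns df with t, p (two-sided), mean_1, mean_2.  Degenerate rows:
# zero pooled variance with equal means -> t = 0, p = 1; zero pooled
# variance with unequal means -> t = +/-Inf, p = 0.
row_pooled_t <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples for a t-test", call. = FALSE)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  d <- m1 - m2
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              0)
  data.frame(t_stat = t, p_value = p, mean_1 = m1, mean_2 = m2)
}

#' Pooled-variance Student t-test for two groups
#'
#' The classical equal-variance two-sample t statistic with
#' `n_f + n_m - 2` degrees of freedom and a two-sided P value.  When all
#' values are identical the test is defined as `t = 0, p = 1`; a zero
#' pooled variance with unequal means is degenerate and reported as
#' `p = 0` with an infinite statistic.
#'
#' @param values_f,values_m Numeric vectors of log10 ratios (>= 2 values
#'   each).
#' @return A list with elements `t_stat`, `p_value`, `df`, and `degenerate`
#'   (`TRUE` when the pooled variance is zero with unequal means).
#' @export
student_t <- function(values_f, values_m) {
  values_f <- as.numeric(values_f); values_m <- as.numeric(values_m)
  if (any(!is.finite(values_f)) || any(!is.finite(values_m)))
    stop("t-test input must be finite", call. = FALSE)
  r <- row_pooled_t(matrix(values_f, nrow = 1), matrix(values_m, nrow = 1))
  list(t_stat = r$t_stat, p_value = r$p_value,
       df = length(values_f) + length(values_m) - 2L,
       degenerate = !is.finite(r$t_stat))
}

#' Filter and rank differential-expression results
#'
#' Retains genes with `p_value < p_max` and `fold_change > fc_min` (both
#' strict), ranks them by decreasing fold change, breaking ties by
#' increasing P value and then by gene id, and prepends a `rank` column.
#'
#' @param results Data frame with at least `gene_id`, `p_value`,
#'   `fold_change` columns (as produced by [run_screen()]).
#' @param p_max Retain genes with P strictly below this value, in (0, 1].
#' @param fc_min Retain genes with fold change strictly above this value,
#'   >= 1.
#' @return The filtered, ranked data frame (possibly zero rows).
#' @export
screen_results <- function(results, p_max = 0.05, fc_min = 1.1) {
  if (!all(c("gene_id", "p_value", "fold_change") %in% names(results)))
    stop("results must have gene_id, p_value and fold_change columns",
         call. = FALSE)
  if (!is.finite(p_max) || p_max <= 0 || p_max > 1)
    stop("p_max must lie in (0, 1]", call. = FALSE)
  if (is.na(fc_min) || fc_min < 1)
    stop("fc_min must be >= 1", call. = FALSE)
  keep <- results$p_value < p_max & results$fold_change > fc_min
  out <- results[keep, , drop = FALSE]
  ord <- order(-out$fold_change, out$p_value, out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Screen an expression matrix for sex-differential genes
#'
#' For every gene: female and male mean log10 ratios, geometric fold change
#' with bias direction, pooled-variance Student t-test, then strict
#' thresholding and fold-change ranking via [screen_results()].
#'
#' Genes whose values are constant within both sexes carry no testable
#' signal and are excluded with a warning.
#'
#' @param expression Numeric matrix, genes x samples, with dimnames.
#' @param samples Data frame with columns `sample_id` and `sex`
#'   (`"M"`/`"F"`); every matrix column must be annotated and both sexes
#'   need >= 2 samples.
#' @param p_max,fc_min Screening thresholds, see [screen_results()].
#' @return Ranked data frame with columns `rank`, `gene_id`, `mean_f`,
#'   `mean_m`, `fold_change`, `bias`, `t_stat`, `p_value`, `degenerate`.
#'   The full unscreened table is attached as attribute `"all_results"`.
#' @examples
#' ds <- generate_dataset(simulation_config(
#'   n_genes = 30, n_male = 15, n_female = 15,
#'   sex_effects = data.frame(gene = 1, log10_fc = 0.3, bias = "F"),
#'   seed = 1))
#' run_screen(ds$expression, ds$samples)
#' @export
run_screen <- function(expression, samples, p_max = 0.05, fc_min = 1.1) {
  expression <- validate_expression(expression)
  samples <- validate_samples(samples, colnames(expression))
  sex <- samples$sex[match(colnames(expression), samples$sample_id)]
  xf <- expression[, sex == "F", drop = FALSE]
  xm <- expression[, sex == "M", drop = FALSE]

  r <- row_pooled_t(xf, xm)
  fc <- compute_fold_change(r$mean_1, r$mean_2)
  res <- data.frame(gene_id = rownames(expression),
                    mean_f = r$mean_1,
                    mean_m = r$mean_2,
                    fold_change = fc$fold_change,
                    bias = fc$bias,
                    t_stat = r$t_stat,
                    p_value = r$p_value,
                    degenerate = !is.finite(r$t_stat),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL

  novar <- apply(xf, 1, stats::var) == 0 & apply(xm, 1, stats::var) == 0
  if (any(novar)) {
    warning(sprintf("%d gene(s) with zero variance in both groups excluded",
                    sum(novar)), call. = FALSE)
    res <- res[!novar, , drop = FALSE]
  }
  out <- screen_results(res, p_max = p_max, fc_min = fc_min)
  attr(out, "all_results") <- res
  out
}

#' Chromosome breakdown of a gene list
#'
#' Counts how many genes of a list map to the X chromosome, the Y
#' chromosome, autosomes (1--22), or lack an annotation.
#'
#' @param gene_ids Character vector of gene ids.
#' @param genes Gene annotation data frame with `gene_id` and `chromosome`
#'   columns (`"1"`..`"22"`, `"X"`, `"Y"`, anything else counts as
#'   unknown).
#' @return Named integer vector with elements `X`, `Y`, `autosome`,
#'   `unknown`, summing to `length(gene_ids)`.
#' @export
chromosome_breakdown <- function(gene_ids, genes) {
  chrom <- genes$chromosome[match(gene_ids, genes$gene_id)]
  if (anyNA(chrom) && length(gene_ids) > 0)
    warning(sprintf("%d gene id(s) missing from the annotation counted as unknown",
                    sum(is.na(chrom))), call. = FALSE)
  cls <- ifelse(is.na(chrom), "unknown",
                ifelse(chrom == "X", "X",
                       ifelse(chrom == "Y", "Y",
                              ifelse(chrom %in% as.character(1:22),
                                     "autosome", "unknown"))))
  c(X = sum(cls == "X"), Y = sum(cls == "Y"),
    autosome = sum(cls == "autosome"), unknown = sum(cls == "unknown"))
}

#' Collapse probe-level rows to one row per gene
#'
#' Keeps, for each gene, the probe with the largest variance across samples
#' (ties broken by the lexicographically smallest probe id).  Probes absent
#' from the mapping are dropped with a warning.
#'
#' @param expression Probe x sample numeric matrix with probe row names.
#' @param probe_to_gene Named character vector mapping probe id to gene id.
#' @return Gene x sample matrix with gene row names.
#' @export
collapse_probes <- function(expression, probe_to_gene) {
  expression <- validate_expression(expression)
  probes <- rownames(expression)
  mapped <- probes %in% names(probe_to_gene)
  if (any(!mapped)) {
    warning(sprintf("%d unmapped probe(s) dropped", sum(!mapped)),
            call. = FALSE)
    expression <- expression[mapped, , drop = FALSE]
    probes <- probes[mapped]
  }
  gene <- unname(probe_to_gene[probes])
  v <- apply(expression, 1, stats::var)
  ord <- order(gene, -v, probes)
  keep <- ord[!duplicated(gene[ord])]
  keep <- keep[order(match(gene[keep], unique(gene)))]
  out <- expression[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out
}

validate_expression <- function(expression) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("expression must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(expression)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(expression)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  expression
}

validate_samples <- function(samples, sample_ids) {
  if (!is.data.frame(samples) ||
      !all(c("sample_id", "sex") %in% names(samples)))
    stop("samples must be a data frame with sample_id and sex columns",
         call. = FALSE)
  if (!all(samples$sex %in% c("M", "F")))
    stop("sample sex must be 'M' or 'F'", call. = FALSE)
  missing <- setdiff(sample_ids, samples$sample_id)
  if (length(missing))
    stop(sprintf("samples missing from the sample sheet: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  sex <- samples$sex[match(sample_ids, samples$sample_id)]
  if (sum(sex == "M") < 2 || sum(sex == "F") < 2)
    stop("both sexes must be present with at least 2 samples each",
         call. = FALSE)
  samples
}
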