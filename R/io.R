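# Readers and writers for the on-disk formats: tab-delimited expression
# matrices, sample sheets, gene tables, GMT gene sets, SIF/TSV edge lists,
# and the bundled table of 77 DMET genes with published sex-biased hepatic
# expression.

#' Read / write a gene-by-sample expression matrix (TSV)
#'
#' The canonical layout is tab-delimited with a header row of sample ids
#' and the gene id in the first column (named `gene_id`).  Values are
#' log10(sample/reference) ratios.
#'
#' @param path File path.
#' @return `read_expression_tsv()`: a numeric matrix with gene row names
#'   and sample column names.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop(sprintf("%s: expected gene id column plus sample columns", path),
         call. = FALSE)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop(sprintf("%s:%d: duplicate gene id '%s'", path, dup[1] + 1L,
                 ids[dup[1]]), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("%s: non-numeric expression values", path), call. = FALSE)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop(sprintf("%s: duplicate sample ids in header", path), call. = FALSE)
  m
}

#' @rdname read_expression_tsv
#' @param expression Numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(expression, path) {
  expression <- validate_expression(expression)
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet (TSV: sample_id, sex)
#'
#' @param path File path.
#' @return A data frame with columns `sample_id` and `sex` (`"M"`/`"F"`).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "sex") %in% names(df)))
    stop(sprintf("%s: sample sheet needs sample_id and sex columns", path),
         call. = FALSE)
  bad <- which(!(df$sex %in% c("M", "F")))
  if (length(bad))
    stop(sprintf("%s:%d: sex must be 'M' or 'F', got '%s'", path,
                 bad[1] + 1L, df$sex[bad[1]]), call. = FALSE)
  dup <- which(duplicated(df$sample_id))
  if (length(dup))
    stop(sprintf("%s:%d: duplicate sample id '%s'", path, dup[1] + 1L,
                 df$sample_id[dup[1]]), call. = FALSE)
  df
}

#' @rdname read_sample_sheet
#' @param samples Data frame with `sample_id` and `sex`.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write the gene annotation table (TSV)
#'
#' Expected columns: `gene_id`, `symbol`, `chromosome`, `is_dmet`; the
#' simulator additionally writes `truth_module`, `truth_fc`, `truth_bias`.
#'
#' @param path File path.
#' @return Data frame with one row per gene.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop(sprintf("%s: gene table needs a gene_id column", path),
         call. = FALSE)
  dup <- which(duplicated(df$gene_id))
  if (length(dup))
    stop(sprintf("%s:%d: duplicate gene id '%s'", path, dup[1] + 1L,
                 df$gene_id[dup[1]]), call. = FALSE)
  if ("is_dmet" %in% names(df)) df$is_dmet <- as.logical(df$is_dmet)
  df
}

#' @rdname read_gene_table
#' @param genes Gene annotation data frame.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-delimited as
#' `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path File path.
#' @param category Collection name; defaults to the file name without
#'   extension.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (is.null(category))
    category <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("%s:%d: GMT line needs term, description and >= 1 gene",
                   path, i), call. = FALSE)
    term <- parts[1]
    if (term %in% names(sets))
      stop(sprintf("%s:%d: duplicate term '%s'", path, i, term),
           call. = FALSE)
    sets[[term]] <- unique(parts[-(1:2)])
    desc[term] <- parts[2]
  }
  gene_set_collection(category, sets, desc)
}

#' Write network edges as SIF and weighted TSV
#'
#' SIF lines are `geneA pp geneB`; the TSV variant adds the edge weight.
#'
#' @param edges Edge data frame from [export_edges()].
#' @param path Output path (`write_edges_sif()` expects `.sif`).
#' @export
write_edges_sif <- function(edges, path) {
  writeLines(sprintf("%s\tpp\t%s", edges$gene_a, edges$gene_b), path)
  invisible(path)
}

#' @rdname write_edges_sif
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled table of 77 sex-dimorphic hepatic DMET genes
#'
#' Loads the packaged transcription of the published table of 77
#' drug-metabolizing-enzyme/transporter genes with sex-differential
#' expression in human liver (P value, linear fold change >= 1, and biased
#' sex per gene).  The loader verifies the table's integrity: exactly 77
#' rows, all P values below 0.05, all fold changes above 1.1.
#'
#' @return Data frame with columns `number`, `gene_id`, `symbol`,
#'   `gene_title`, `p_value`, `fold_change`, `bias`.
#' @examples
#' t1 <- load_table1_fixture()
#' head(screen_results(t1, p_max = 0.05, fc_min = 1.5))
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "dmet_sex_dimorphic_genes.tsv",
                      package = "hepatodimorph")
  if (path == "")
    stop("bundled DMET table not found; reinstall the package",
         call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          quote = "", stringsAsFactors = FALSE)
  ok <- nrow(df) == 77 &&
    all(c("number", "symbol", "gene_title", "p_value", "fold_change",
          "bias") %in% names(df)) &&
    all(df$p_value > 0 & df$p_value < 0.05) &&
    all(df$fold_change > 1.1) &&
    all(df$bias %in% c("F", "M")) &&
    !anyDuplicated(df$symbol)
  if (!ok)
    stop("bundled DMET table failed its integrity check", call. = FALSE)
  df$gene_id <- df$symbol
  df[, c("number", "gene_id", "symbol", "gene_title", "p_value",
         "fold_change", "bias")]
}
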