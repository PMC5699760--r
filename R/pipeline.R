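# End-to-end pipeline: (optional) simulate -> screen -> network on the
# screened genes -> enrichment, with every stage's outputs and a JSON run
# manifest written to an output directory.

#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_all()].
#' Either `simulate` (a [simulation_config()]) or the three input paths
#' (`expression`, `samples`, `genes`) must be provided.
#'
#' @param out_dir Output directory (created if missing).
#' @param simulate Optional [simulation_config()]; when given, the
#'   dataset is generated and written as the pipeline input.
#' @param expression,samples,genes Paths of the input TSVs when not
#'   simulating.
#' @param gene_sets Character vector of GMT paths for the enrichment stage
#'   (may be empty; the stage is then skipped).
#' @param p_max,fc_min Screening thresholds.
#' @param beta Fixed soft-threshold power, or `NULL` to select it by the
#'   scale-free criterion.
#' @param target_fit Signed fit index required by [select_beta()].
#' @param n_bins Degree-density bins for the scale-free fit.
#' @param cut_height Static cut height, or `NULL` for the default
#'   (0.99 of the dendrogram top, see [cut_modules()]).
#' @param min_module_size Minimum module size.
#' @param edge_threshold TOM weight threshold for the exported edge list.
#' @param network_genes `"screened"` (default: the network is built on the
#'   genes retained by the screen) or `"all"`.
#' @param seed Seed recorded in the manifest and used for simulation.
#' @param verbose Emit progress messages.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = NULL,
                            expression = NULL,
                            samples = NULL,
                            genes = NULL,
                            gene_sets = character(0),
                            p_max = 0.05,
                            fc_min = 1.1,
                            beta = NULL,
                            target_fit = 0.8,
                            n_bins = 10,
                            cut_height = NULL,
                            min_module_size = 30,
                            edge_threshold = 0.1,
                            network_genes = c("screened", "all"),
                            seed = 1L,
                            verbose = FALSE) {
  network_genes <- match.arg(network_genes)
  if (is.null(simulate) &&
      (is.null(expression) || is.null(samples)))
    stop("provide either a simulation config or expression + samples paths",
         call. = FALSE)
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop("simulate must be a simulation_config()", call. = FALSE)
  if (!is.finite(p_max) || p_max <= 0 || p_max > 1)
    stop("p_max must lie in (0, 1]", call. = FALSE)
  if (fc_min < 1) stop("fc_min must be >= 1", call. = FALSE)
  if (!is.null(beta) && (!is.finite(beta) || beta <= 0))
    stop("beta must be positive when given", call. = FALSE)
  structure(list(out_dir = out_dir, simulate = simulate,
                 expression = expression, samples = samples, genes = genes,
                 gene_sets = gene_sets, p_max = p_max, fc_min = fc_min,
                 beta = beta, target_fit = target_fit, n_bins = n_bins,
                 cut_height = cut_height,
                 min_module_size = min_module_size,
                 edge_threshold = edge_threshold,
                 network_genes = network_genes,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulation (when configured), the
#' sex-differential-expression screen, network construction on the
#' screened genes (correlation, soft-threshold adjacency with fixed or
#' selected beta, TOM, average-linkage module detection, edge export), and
#' module enrichment against the supplied GMT collections.  All outputs
#' are tab-delimited files under `config$out_dir`, plus a JSON run
#' manifest recording parameters, seed, package version, input checksums
#' and completed stages.  Identical configurations produce byte-identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`dataset`/`inputs`, `screen`, `network`, `enrichment`, `manifest`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  stages <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  # --- stage 1: inputs ----------------------------------------------------
  input_files <- character(0)
  if (!is.null(config$simulate)) {
    say("simulating dataset (seed %d)", config$simulate$seed)
    ds <- generate_dataset(config$simulate)
    expression <- ds$expression
    samples <- ds$samples
    genes <- ds$genes
    write_expression_tsv(expression, out("expression.tsv"))
    write_sample_sheet(samples, out("samples.tsv"))
    write_gene_table(genes, out("genes.tsv"))
    stages <- c(stages, "simulate")
  } else {
    ds <- NULL
    expression <- read_expression_tsv(config$expression)
    samples <- read_sample_sheet(config$samples)
    genes <- if (!is.null(config$genes)) read_gene_table(config$genes)
             else NULL
    input_files <- c(config$expression, config$samples, config$genes)
  }

  # --- stage 2: differential-expression screen ----------------------------
  say("screening %d genes (p < %g, FC > %g)", nrow(expression),
      config$p_max, config$fc_min)
  scr <- run_screen(expression, samples,
                    p_max = config$p_max, fc_min = config$fc_min)
  utils::write.table(scr, out("screen.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stages <- c(stages, "screen")

  # --- stage 3: co-expression network -------------------------------------
  net_ids <- if (config$network_genes == "screened") scr$gene_id
             else rownames(expression)
  net <- NULL
  if (length(net_ids) >= 3) {
    say("building network on %d genes", length(net_ids))
    cor_mat <- pearson_correlation(expression[net_ids, , drop = FALSE])
    if (is.null(config$beta)) {
      sel <- select_beta(cor_mat, target = config$target_fit,
                         n_bins = config$n_bins)
      beta <- sel$beta
      utils::write.table(sel$sweep, out("beta_sweep.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      sel <- NULL
      beta <- config$beta
    }
    adj <- soft_adjacency(cor_mat, beta)
    fit <- scale_free_fit(connectivity(adj), n_bins = config$n_bins)
    tom <- tom_similarity(adj)
    tree <- average_linkage(1 - tom)
    modules <- cut_modules(tree, height = config$cut_height,
                           min_size = config$min_module_size)
    utils::write.table(
      data.frame(gene_id = names(modules), module = unclass(modules),
                 stringsAsFactors = FALSE),
      out("modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(beta = beta, r_squared = fit$r_squared,
                 slope = fit$slope, signed_index = fit$signed_index),
      out("scale_free_fit.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    edges <- export_edges(tom, config$edge_threshold)
    write_edges_sif(edges, out("edges.sif"))
    write_edges_tsv(edges, out("edges.tsv"))
    utils::write.table(
      data.frame(merge_a = tree$merge[, 1], merge_b = tree$merge[, 2],
                 height = tree$height),
      out("dendrogram.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    net <- list(beta = beta, selection = sel, fit = fit, tom = tom,
                tree = tree, modules = modules, edges = edges)
    stages <- c(stages, "network")
  } else {
    say("fewer than 3 screened genes; network stage skipped")
  }

  # --- stage 4: enrichment -------------------------------------------------
  enr <- NULL
  if (!is.null(net) && length(config$gene_sets) > 0 &&
      any(unclass(net$modules) != "grey")) {
    say("enrichment against %d collection(s)", length(config$gene_sets))
    collections <- lapply(config$gene_sets, read_gmt)
    enr <- enrich_modules(net$modules, collections,
                          background = rownames(expression))
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stages <- c(stages, "enrich")
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "hepatodimorph",
    version = as.character(utils::packageVersion("hepatodimorph")),
    seed = config$seed,
    parameters = list(
      p_max = config$p_max, fc_min = config$fc_min,
      beta = if (is.null(net)) NULL else net$beta,
      beta_selected = is.null(config$beta),
      target_fit = config$target_fit, n_bins = config$n_bins,
      cut_height = config$cut_height,
      min_module_size = config$min_module_size,
      edge_threshold = config$edge_threshold,
      network_genes = config$network_genes),
    input_checksums = if (length(input_files))
      as.list(tools::md5sum(input_files)) else NULL,
    n_genes = nrow(expression),
    n_samples = ncol(expression),
    n_screened = nrow(scr),
    stages_completed = stages)
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(dataset = ds, expression = expression, samples = samples,
                 genes = genes, screen = scr, network = net,
                 enrichment = enr, manifest = manifest))
}
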