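#' Full analysis configuration
#'
#' Bundles every tunable of the pipeline. All fields have defaults; the
#' object serializes to and from plain JSON so a run manifest alone can
#' reproduce a run.
#'
#' @param network A [net_config()].
#' @param adjustment An [adjust_config()].
#' @param covariates Covariate subset for the regression, or `"all"`.
#' @param group_a_level,group_b_level Optional explicit condition levels
#'   (default: lexicographic order; Group A = smaller level).
#' @param seed Integer seed for the stochastic components (the robust
#'   fits' initial subsampling); the network/pseudo-value stages are
#'   deterministic.
#' @param jobs Worker count for leave-one-out fits and per-gene
#'   regressions.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(network = net_config(), adjustment = adjust_config(),
                       covariates = "all", group_a_level = NULL,
                       group_b_level = NULL, seed = 1L, jobs = 1L) {
  structure(list(network = network, adjustment = adjustment,
                 covariates = covariates,
                 group_a_level = group_a_level, group_b_level = group_b_level,
                 seed = as.integer(seed), jobs = as.integer(jobs)),
            class = "run_config")
}

config_to_list <- function(config) {
  list(network = unclass(config$network),
       adjustment = unclass(config$adjustment),
       covariates = config$covariates,
       group_a_level = config$group_a_level,
       group_b_level = config$group_b_level,
       seed = config$seed, jobs = config$jobs)
}

#' Rebuild a run configuration from a manifest list
#'
#' @param x A list as produced by parsing a run manifest's `config` entry.
#' @return A `run_config`.
#' @export
config_from_list <- function(x) {
  run_config(network = do.call(net_config, x$network),
             adjustment = do.call(adjust_config, x$adjustment),
             covariates = x$covariates,
             group_a_level = x$group_a_level, group_b_level = x$group_b_level,
             seed = x$seed, jobs = x$jobs)
}

#' Run the covariate-adjusted differential network analysis end to end
#'
#' Executes the whole pipeline: align and split the samples by condition;
#' estimate each group's ARACNE association network and degree centralities;
#' re-estimate leaving each sample out to form jackknife pseudo-values;
#' pool the pseudo-values and fit one robust regression per gene on the
#' group indicator plus covariates; adjust each predictor's p-value family.
#'
#' @param expr Samples x genes expression matrix.
#' @param pheno Phenotype `data.frame` with a `group_variable` attribute
#'   (see [as_phenotype_table()] / [read_phenotype()]).
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, writes
#'   `coefficients.tsv`, `pvalues.tsv`, `adj_pvalues.tsv`, `dc_genes.tsv`
#'   and `manifest.json` (config, input checksums, package version).
#' @param verbose Emit stage-level progress messages with wall time.
#' @return A `dn_result` with coefficients, p-values, adjusted p-values,
#'   per-gene fit flags, and the `aligned` data attached as an attribute.
#' @export
run_analysis <- function(expr, pheno, config = run_config(),
                         output_dir = NULL, verbose = FALSE) {
  stage <- function(msg, value) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(value)
    if (verbose) message(sprintf("[%s] %.1fs", msg, proc.time()[["elapsed"]] - t0))
    out
  }
  aligned <- stage("align", align_and_split(expr, pheno,
                                            config$group_a_level,
                                            config$group_b_level))
  ex <- aligned$expr
  asg <- aligned$assignment

  block_a <- stage("pseudo-values group A", jackknife_pseudovalues(
    ex[asg$group_a, , drop = FALSE], config$network, jobs = config$jobs))
  block_b <- stage("pseudo-values group B", jackknife_pseudovalues(
    ex[asg$group_b, , drop = FALSE], config$network, jobs = config$jobs))
  psv <- assemble_pseudovalues(block_a, block_b, asg)

  X <- build_design(aligned$pheno, asg, config$covariates)
  res <- stage("robust regressions", fit_all_genes(psv, X, seed = config$seed,
                                                   jobs = config$jobs))
  res <- adjust_results(res, config$adjustment)
  res$pseudovalues <- psv
  attr(res, "assignment") <- asg

  if (!is.null(output_dir)) {
    write_results(res, output_dir, expr = expr, pheno = pheno, config = config)
  }
  res
}

full_precision_table <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Serialize a result set to a results directory
#'
#' Writes the three gene x predictor tables, the significant-gene table at
#' the configured alpha, and a JSON manifest (configuration, input
#' checksums, package version) sufficient to re-execute the run.
#'
#' @param results A `dn_result`.
#' @param output_dir Directory (created if needed).
#' @param expr,pheno The original inputs (checksummed into the manifest).
#' @param config The `run_config` used.
#' @export
write_results <- function(results, output_dir, expr = NULL, pheno = NULL,
                          config = run_config()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  full_precision_table(results$coefficients, file.path(output_dir, "coefficients.tsv"))
  full_precision_table(results$pvalues, file.path(output_dir, "pvalues.tsv"))
  full_precision_table(results$adj_pvalues, file.path(output_dir, "adj_pvalues.tsv"))
  dc <- sig_dc_genes(results, alpha = config$adjustment$alpha)
  utils::write.table(
    data.frame(gene_id = dc$gene_id,
               adj_pvalue = format(dc$adj_pvalue, digits = 17, trim = TRUE,
                                   scientific = TRUE),
               stringsAsFactors = FALSE),
    file.path(output_dir, "dc_genes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  checksum <- function(obj) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(obj, f)
    unname(tools::md5sum(f))
  }
  manifest <- list(
    package = "psvnet",
    version = as.character(utils::packageVersion("psvnet")),
    config = config_to_list(config),
    inputs = list(
      n_samples = if (is.null(expr)) NA else nrow(expr),
      n_genes = if (is.null(expr)) NA else ncol(expr),
      expr_md5 = if (is.null(expr)) NA else checksum(expr),
      pheno_md5 = if (is.null(pheno)) NA else checksum(pheno)),
    flags = as.list(results$flags[results$flags != "ok"]))
  # digits = I(17): doubles must survive the JSON round trip bit-exactly so
  # a manifest-reconstructed config reproduces the run identically
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17), null = "null")
  invisible(output_dir)
}
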