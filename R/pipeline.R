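#' Run the full module-detection pipeline
#'
#' Executes read (or accepts in-memory inputs), preprocessing, mesh and
#' penalty construction, penalized fitting with unified-lambda selection,
#' iterative hierarchical clustering, and (when truth labels are given)
#' evaluation. Writes labels, coefficients, and diagnostics when
#' `out_dir` is set, plus a JSON report echoing the configuration; the
#' whole run is deterministic for a fixed config.
#'
#' @param config list (or path to a JSON file) with entries:
#'   `expression` (path, or an `expression_matrix`), `coordinates` (path,
#'   or a `spot_set`), optional `truth` (path to TSV with columns
#'   `gene_id`, `module`, or a vector), `family` (`"normal"`),
#'   `transform` (`"log1p"`, `"anscombe"`, `"none"`; default `"log1p"`),
#'   `cpm` (FALSE), `min_genes_per_spot` / `min_reads_per_gene`
#'   (0 = no filtering), `grid_size` (U, 20), `center` (`"mean"`),
#'   `lambda_grid` (NULL), `out_dir` (NULL).
#' @return list with `result` (`stihc_result`), `coefficients`
#'   (`coef_matrix`), `basis`, `expression`, `spots`, `evaluation`
#'   (NULL without truth), `report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(family = "normal", transform = "log1p",
                                cpm = FALSE, min_genes_per_spot = 0L,
                                min_reads_per_gene = 0L, grid_size = 20L,
                                center = "mean", lambda_grid = NULL,
                                out_dir = NULL),
                           config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  em <- stage("read_expression", {
    if (inherits(cfg$expression, "expression_matrix")) cfg$expression
    else read_expression(cfg$expression)
  })
  spots <- stage("read_coordinates", {
    if (inherits(cfg$coordinates, "spot_set")) cfg$coordinates
    else read_coordinates(cfg$coordinates, spot_ids = em$spot_ids)
  })
  em <- stage("filter", {
    if (cfg$min_genes_per_spot > 0 || cfg$min_reads_per_gene > 0)
      filter_spots_genes(em, cfg$min_genes_per_spot, cfg$min_reads_per_gene)
    else em
  })
  if (!identical(spots$spot_ids, em$spot_ids)) {
    idx <- match(em$spot_ids, spots$spot_ids)
    if (anyNA(idx)) stop("pipeline stage 'align': spots missing coordinates")
    spots <- spot_set(spots$coords[idx, , drop = FALSE], em$spot_ids)
  }
  em <- stage("transform", {
    x <- if (isTRUE(cfg$cpm)) cpm_normalize(em) else em
    switch(cfg$transform,
           log1p = log1p_transform(x),
           anscombe = anscombe_transform(x),
           none = x,
           stop("unknown transform: ", cfg$transform))
  })
  basis <- stage("mesh", basis_system(spots))
  fitc <- fit_config(family = cfg$family, lambda_grid = cfg$lambda_grid)
  coefs <- stage("fit", fit_all(em$values, basis, fitc))
  res <- stage("cluster", run_stihc(coefs, U = cfg$grid_size,
                                    center_method = cfg$center))
  evaluation <- NULL
  if (!is.null(cfg$truth)) {
    truth <- stage("truth", {
      if (is.character(cfg$truth) && length(cfg$truth) == 1L &&
          file.exists(cfg$truth)) {
        tdf <- utils::read.table(cfg$truth, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        tdf$module[match(em$gene_ids, tdf$gene_id)]
      } else cfg$truth
    })
    evaluation <- stage("evaluate", list(
      ari = adjusted_rand_index(res$labels, truth),
      dbi = if (length(unique(res$labels)) >= 2L)
        davies_bouldin(coefs$C, res$labels) else NA_real_,
      cluster_sizes = as.integer(table(res$labels))))
  }
  report <- list(package_version = as.character(utils::packageVersion("stmodules")),
                 config = cfg[setdiff(names(cfg),
                                      c("expression", "coordinates", "truth"))],
                 n_genes = length(em$gene_ids), n_spots = length(em$spot_ids),
                 lambda_opt = coefs$lambda_opt, alpha_opt = res$alpha_opt,
                 n_clusters = length(unique(res$labels)),
                 cluster_sizes = as.integer(table(res$labels)),
                 mean_silhouette = max(res$per_alpha$mean_silhouette),
                 evaluation = evaluation)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(data.frame(gene_id = names(res$labels),
                                  cluster = as.integer(res$labels)),
                       file.path(cfg$out_dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cdf <- data.frame(gene_id = rownames(coefs$C), coefs$C,
                      check.names = FALSE)
    utils::write.table(cdf, file.path(cfg$out_dir, "coefficients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$per_alpha,
                       file.path(cfg$out_dir, "alpha_diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  list(result = res, coefficients = coefs, basis = basis, expression = em,
       spots = spots, evaluation = evaluation, report = report)
}
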