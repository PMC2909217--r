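# End-to-end orchestration: read inputs, impute and cluster expression,
# assemble the weighted functional gene network, extract pair features,
# run the classifier comparison and the per-feature KS report, and persist
# every artifact in the formats_io dialects.

#' Pipeline configuration
#'
#' @param expression,ppi,complexes,labels Input file paths (formats of
#'   [read_expression()], [read_edge_list()], [read_complexes()],
#'   [read_pair_labels()]).
#' @param outdir Output directory.
#' @param weight A [weight_config()].
#' @param ssl An [ssl_config()].
#' @param svm An [svm_grid()].
#' @param n_pos,n_neg Optional balanced-sample sizes drawn from the labelled
#'   pairs before cross-validation (`NULL` = use all pairs as-is).
#' @param train_fractions Training fractions for [run_comparison()].
#' @param seeds Master seeds (one repetition each).
#' @param methods Classifiers to run (`"ssl"`, `"svm"`).
#' @param seed Master seed for the balanced sampling stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, ppi, complexes, labels, outdir,
                            weight = weight_config(), ssl = ssl_config(),
                            svm = svm_grid(), n_pos = NULL, n_neg = NULL,
                            train_fractions = c(0.8, 0.5, 0.2), seeds = 1:5,
                            methods = c("ssl", "svm"), seed = 1L) {
  structure(list(expression = expression, ppi = ppi, complexes = complexes,
                 labels = labels, outdir = outdir, weight = weight, ssl = ssl,
                 svm = svm, n_pos = n_pos, n_neg = n_neg,
                 train_fractions = train_fractions, seeds = seeds,
                 methods = methods, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; nested blocks
#' `weight`, `ssl` and `svm` are passed to [weight_config()], [ssl_config()]
#' and [svm_grid()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("expression", "ppi", "complexes", "labels",
                                  "outdir", "n_pos", "n_neg",
                                  "train_fractions", "seeds", "methods", "seed"))]
  if (!is.null(y$weight)) args$weight <- do.call(weight_config, y$weight)
  if (!is.null(y$ssl)) args$ssl <- do.call(ssl_config, y$ssl)
  if (!is.null(y$svm)) args$svm <- do.call(svm_grid, y$svm)
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full prediction pipeline
#'
#' Stages: input validation and reading; imputation; divisive clustering;
#' network assembly and weighting; pair feature extraction; classifier
#' comparison under cross-validation; per-feature KS report. All artifacts
#' (weighted network, cluster assignment, feature table, comparison summary,
#' averaged ROC points, KS report) are written as TSV to `outdir`, together
#' with a YAML manifest recording the configuration. Errors carry the name
#' of the failing stage. Reruns with the same configuration reproduce
#' identical tables.
#'
#' @param cfg A [pipeline_config()] or path to a YAML config.
#' @return List of class `pipeline_report` with the in-memory artifacts and
#'   the output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  .stage("inputs", {
    for (f in c("expression", "ppi", "complexes", "labels"))
      if (!file.exists(cfg[[f]]))
        stop("missing ", f, " file: ", cfg[[f]])
  })
  expr <- .stage("inputs", read_expression(cfg$expression))
  ppi <- .stage("inputs", read_edge_list(cfg$ppi))
  complexes <- .stage("inputs", read_complexes(cfg$complexes))
  labels <- .stage("inputs", read_pair_labels(cfg$labels))

  imputed <- .stage("impute", impute_missing(expr))
  partition <- .stage("cluster", divisive_cluster(imputed))
  fgn <- .stage("network", {
    skeleton <- merge_topology(ppi, expand_complexes(complexes))
    build_fgn(skeleton, imputed, partition, cfg$weight)
  })
  if (!is.null(cfg$n_pos))
    labels <- .stage("sample", sample_balanced(labels, cfg$n_pos, cfg$n_neg, cfg$seed))
  features <- .stage("features", pair_features(fgn, labels))
  comparison <- .stage("evaluate",
                       run_comparison(features,
                                      train_fractions = cfg$train_fractions,
                                      seeds = cfg$seeds, ssl = cfg$ssl,
                                      grid = cfg$svm, methods = cfg$methods))
  ks <- .stage("evaluate", feature_distribution_report(features))

  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- list(
    network = file.path(outdir, "fgn.tsv"),
    clusters = file.path(outdir, "clusters.tsv"),
    features = file.path(outdir, "features.tsv"),
    summary = file.path(outdir, "comparison_summary.tsv"),
    roc = file.path(outdir, "roc_points.tsv"),
    ks = file.path(outdir, "ks_report.tsv"),
    manifest = file.path(outdir, "manifest.yaml"))
  write_table(fgn$edges, paths$network)
  write_table(data.frame(gene = names(partition$assignment),
                         cluster = as.integer(partition$assignment)),
              paths$clusters)
  write_table(features, paths$features)
  write_table(comparison$summary, paths$summary)
  write_table(comparison$mean_roc, paths$roc)
  write_table(ks, paths$ks)
  yaml::write_yaml(list(package = "sgipred",
                        version = as.character(utils::packageVersion("sgipred")),
                        config = .manifest_config(cfg)),
                   paths$manifest)
  structure(list(network = fgn, partition = partition, features = features,
                 comparison = comparison, ks = ks, paths = paths),
            class = "pipeline_report")
}

.manifest_config <- function(cfg) {
  lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  print(x$network)
  print(x$partition)
  print(x$comparison)
  invisible(x)
}
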