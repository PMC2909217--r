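# Seeded synthetic datasets with the statistical structure the pipeline
# assumes: modular co-expression (archetype + i.i.d. Gaussian noise), a
# sparse modular interaction graph, complexes as dense within-module
# subsets, and interaction labels correlated with pair topology through a
# logistic model on node strength and closeness.

#' Specification of a synthetic dataset
#'
#' Defaults describe the benchmark conditions used throughout the package:
#' six co-expression modules of 30 genes over 64 conditions, a sparse
#' modular interaction graph, and 600 labelled pairs whose labels follow a
#' logistic model with coefficient `sgi_signal_strength` on the planted
#' topology score, at an expected positive fraction of 0.5 (set
#' `sgi_positive_fraction` low, e.g. 0.0065, for a screen-like imbalance).
#'
#' @param n_modules Number of co-expression modules.
#' @param genes_per_module Genes per module.
#' @param n_conditions Expression conditions (columns).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian expression
#'   noise around each module archetype (log-ratio units).
#' @param archetypes `"random"` (independent standard-normal archetypes) or
#'   `"anti_correlated"` (archetypes planted on a circle in a 2-D profile
#'   subspace so that inter-module correlations are negative; used to test
#'   module recovery by divisive clustering).
#' @param p_edge_within,p_edge_between Bernoulli edge probabilities for
#'   within-module and between-module gene pairs.
#' @param n_complexes,complex_size Number and size of protein complexes,
#'   drawn as random within-module subsets.
#' @param n_pairs Number of labelled gene pairs to draw.
#' @param sgi_signal_strength Logistic coefficient on the standardized
#'   planted topology score (0 = labels independent of topology).
#' @param sgi_positive_fraction Expected fraction of positive labels.
#' @param missing_fraction Fraction of expression entries blanked at random.
#' @param seed Master seed; all generator randomness derives from it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modules = 6L, genes_per_module = 30L,
                           n_conditions = 64L, noise_sd = 0.3,
                           archetypes = c("random", "anti_correlated"),
                           p_edge_within = 0.3, p_edge_between = 0.02,
                           n_complexes = 12L, complex_size = 5L,
                           n_pairs = 600L, sgi_signal_strength = 4,
                           sgi_positive_fraction = 0.5,
                           missing_fraction = 0.05, seed = 1L) {
  stopifnot(n_modules >= 1, genes_per_module >= 1, n_conditions >= 2,
            noise_sd >= 0, p_edge_within >= 0, p_edge_within <= 1,
            p_edge_between >= 0, p_edge_between <= 1,
            sgi_signal_strength >= 0,
            sgi_positive_fraction > 0, sgi_positive_fraction < 1,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 n_conditions = as.integer(n_conditions),
                 noise_sd = noise_sd, archetypes = match.arg(archetypes),
                 p_edge_within = p_edge_within, p_edge_between = p_edge_between,
                 n_complexes = as.integer(n_complexes),
                 complex_size = as.integer(complex_size),
                 n_pairs = as.integer(n_pairs),
                 sgi_signal_strength = sgi_signal_strength,
                 sgi_positive_fraction = sgi_positive_fraction,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.spec_genes <- function(spec) {
  sprintf("g%03d", seq_len(spec$n_modules * spec$genes_per_module))
}

.spec_modules <- function(spec) {
  rep(seq_len(spec$n_modules), each = spec$genes_per_module)
}

# sub-seed streams so stages can be regenerated independently
.sub_seed <- function(seed, offset) (seed * 1009L + offset) %% 2147483647L

.make_archetypes <- function(spec) {
  k <- spec$n_modules; N <- spec$n_conditions
  if (spec$archetypes == "random") {
    matrix(stats::rnorm(k * N), nrow = k)
  } else {
    # place archetypes on a circle in a 2-D subspace; the stagger keeps the
    # angular gaps unequal so recursive splitting resolves every module
    u <- stats::rnorm(N); u <- u - mean(u); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(N); v <- v - mean(v)
    v <- v - sum(u * v) * u; v <- v / sqrt(sum(v^2))
    theta <- 2 * pi * (seq_len(k) - 1) / k + 0.15 * (seq_len(k) - 1)
    t(vapply(theta, function(a) sqrt(N) * (cos(a) * u + sin(a) * v), numeric(N)))
  }
}

#' Generate a synthetic expression matrix
#'
#' Each module has an archetype profile; member profiles are the archetype
#' plus independent Gaussian noise, with a fraction of entries blanked.
#'
#' @param spec A [synthetic_spec()].
#' @return Numeric genes x conditions matrix (with `NA`s if
#'   `missing_fraction > 0`).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- .spec_genes(spec); mod <- .spec_modules(spec)
  .with_seed(.sub_seed(spec$seed, 1L), {
    arch <- .make_archetypes(spec)
    m <- arch[mod, , drop = FALSE] +
      matrix(stats::rnorm(length(genes) * spec$n_conditions, sd = spec$noise_sd),
             nrow = length(genes))
    dimnames(m) <- list(genes, sprintf("c%02d", seq_len(spec$n_conditions)))
    if (spec$missing_fraction > 0) {
      holes <- which(stats::runif(length(m)) < spec$missing_fraction)
      m[holes] <- NA
      # keep every condition observed at least once
      for (j in which(colSums(!is.na(m)) == 0L)) m[1L, j] <- arch[mod[1L], j]
    }
    m
  })
}

#' Generate a synthetic interaction graph and complexes
#'
#' Within-module pairs become edges with probability `p_edge_within`,
#' between-module pairs with `p_edge_between`; complexes are random
#' within-module subsets of size `complex_size`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `ppi` (two-column pair matrix) and `complexes`
#'   (list of member vectors).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- .spec_genes(spec); mod <- .spec_modules(spec)
  M <- length(genes)
  .with_seed(.sub_seed(spec$seed, 2L), {
    idx <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
    same <- mod[idx[, 1L]] == mod[idx[, 2L]]
    p <- ifelse(same, spec$p_edge_within, spec$p_edge_between)
    keep <- stats::runif(nrow(idx)) < p
    ppi <- cbind(from = genes[idx[keep, 1L]], to = genes[idx[keep, 2L]])
    complexes <- lapply(seq_len(spec$n_complexes), function(i) {
      m <- sample.int(spec$n_modules, 1L)
      members <- genes[mod == m]
      sort(sample(members, min(spec$complex_size, length(members))))
    })
    list(ppi = .canonical_pairs(ppi[, 1L], ppi[, 2L]), complexes = complexes)
  })
}

#' Generate topology-correlated interaction labels
#'
#' Draws `n_pairs` distinct candidate gene pairs and labels each one
#' Bernoulli with probability `plogis(b + s * z)`, where z is the
#' standardized planted topology score (sum of the standardized pair-mean
#' strength and pair-mean closeness), s is `sgi_signal_strength`, and the
#' intercept b is solved so the expected positive fraction equals
#' `sgi_positive_fraction`.
#'
#' @param spec A [synthetic_spec()].
#' @param features Pair feature table for the candidate pairs (must contain
#'   `strength_mean` and `closeness_mean`).
#' @return Labelled pair data.frame (columns `from`, `to`, `label`).
#' @export
generate_labels <- function(spec, features) {
  stopifnot(inherits(spec, "synthetic_spec"),
            all(c("from", "to", "strength_mean", "closeness_mean") %in% names(features)))
  zs <- function(x) if (stats::sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / stats::sd(x)
  z <- zs(zs(features$strength_mean) + zs(features$closeness_mean))
  s <- spec$sgi_signal_strength
  b <- stats::uniroot(function(b0) mean(stats::plogis(b0 + s * z)) - spec$sgi_positive_fraction,
                      interval = c(-50, 50))$root
  .with_seed(.sub_seed(spec$seed, 3L), {
    lab <- stats::rbinom(length(z), 1L, stats::plogis(b + s * z))
    pair_labels(features$from, features$to, as.integer(lab))
  })
}

# distinct candidate pairs among the generated genes, uniform without
# replacement
.sample_candidate_pairs <- function(spec, nodes) {
  M <- length(nodes)
  n_all <- M * (M - 1) / 2
  n <- min(spec$n_pairs, n_all)
  .with_seed(.sub_seed(spec$seed, 4L), {
    sel <- sort(sample.int(n_all, n))
    idx <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
    cbind(from = nodes[idx[sel, 1L]], to = nodes[idx[sel, 2L]])
  })
}

#' Generate a complete synthetic dataset bundle
#'
#' Runs the full generator (expression, graph, complexes, candidate pairs,
#' labels), optionally writing the four input files plus a manifest to a
#' directory. Re-running with the same spec reproduces identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (created if needed).
#' @return List with `expression`, `ppi`, `complexes`, `labels`, the
#'   intermediate `network`, `partition` and `features`, and `paths` when
#'   `dir` was given.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  expr <- generate_expression(spec)
  netdata <- generate_network(spec)
  imputed <- impute_missing(expr)
  partition <- divisive_cluster(imputed)
  skeleton <- merge_topology(netdata$ppi, expand_complexes(netdata$complexes))
  fgn <- suppressMessages(build_fgn(skeleton, imputed, partition))
  cand <- .sample_candidate_pairs(spec, fgn$nodes)
  features <- suppressMessages(pair_features(fgn, cand))
  labels <- generate_labels(spec, features)
  features$label <- labels$label[match(paste(features$from, features$to),
                                       paste(labels$from, labels$to))]
  out <- list(expression = expr, ppi = netdata$ppi,
              complexes = netdata$complexes, labels = labels,
              network = fgn, partition = partition, features = features)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
    paths <- list(expression = file.path(dir, "expression.tsv"),
                  ppi = file.path(dir, "ppi.tsv"),
                  complexes = file.path(dir, "complexes.tsv"),
                  labels = file.path(dir, "labels.tsv"),
                  manifest = file.path(dir, "manifest.yaml"))
    write_expression(expr, paths$expression)
    utils::write.table(netdata$ppi, paths$ppi, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines(vapply(netdata$complexes, paste, character(1), collapse = "\t"),
               paths$complexes)
    utils::write.table(labels, paths$labels, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    yaml::write_yaml(list(generator = "sgipred synthetic_data",
                          spec = unclass(spec)), paths$manifest)
    out$paths <- paths
  }
  out
}
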