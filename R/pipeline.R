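# End-to-end orchestration: preprocessing -> feature screen -> signatures
# -> distances -> map -> communities -> cluster labels -> neighbour
# majority diagnosis -> evaluation, with every intermediate result kept on
# the fitted object.

#' Fit a rank-based signature map
#'
#' Runs the full diagnostic-map pipeline on an expression matrix and a
#' label table: drops probes with missing values, divides by the virtual
#' control, screens features with a Mann-Whitney test at `alpha`, extracts
#' each sample's top-`n1`/bottom-`n2` rank signature, computes the
#' bidirectional enrichment-score distance between every pair, keeps the
#' `n_pct`% smallest distances as edges, partitions the map into
#' communities, labels each community by its anchor majority, and
#' diagnoses every node from its neighbours' labels (leave-one-out: a
#' node's own label never votes).
#'
#' @param expression Expression tibble ([read_expression()]) of positive
#'   linear-scale intensities.
#' @param labels Label tibble; `control`/`affected` samples anchor the
#'   feature screen, cluster labelling and the vote.
#' @param n1,n2 Signature sizes.
#' @param alpha Feature-screen significance level.
#' @param n_pct Percentage of smallest distances kept as map edges.
#' @param weighted Use inverse-distance vote weighting.
#' @param inclusive,exact Feature-screen threshold semantics, see
#'   [select_features()].
#' @param mode,cutoff Edge filtering mode, see [threshold_edges()].
#' @param verbose Log each stage with counts.
#' @return A `signature_map` object holding every stage's output;
#'   `tidy()` gives the per-sample table, `glance()` the metrics,
#'   `autoplot()` the map.
#' @export
#' @examples
#' cohort <- synthetic_cohort(n_probes = 120, n_control = 8, n_affected = 8,
#'                            frac_diff = 0.2, fold = 4, sigma = 0.2, seed = 7)
#' fit <- fit_signature_map(cohort$expression, cohort$labels,
#'                          n1 = 10, n2 = 10, n_pct = 20)
#' glance(fit)
fit_signature_map <- function(expression, labels, n1 = 25, n2 = 25,
                              alpha = 0.1, n_pct = 10, weighted = FALSE,
                              inclusive = TRUE,
                              exact = c("auto", "exact", "approx"),
                              mode = c("percentile", "absolute"),
                              cutoff = NULL, verbose = FALSE) {
  exact <- match.arg(exact)
  mode <- match.arg(mode)
  labels <- check_labels(labels)
  say <- function(...) if (verbose) message(...)

  complete <- drop_incomplete_probes(expression)
  say("complete probes: ", nrow(complete), " of ", nrow(expression))
  control <- virtual_control(complete)
  differential <- differential_transform(complete, control)
  features <- select_features(differential, labels, alpha = alpha,
                              inclusive = inclusive, exact = exact)
  selected <- features$probe_id[features$selected]
  say("selected features: ", length(selected), " at alpha = ", alpha)
  if (length(selected) < n1 + n2) {
    abort(paste0("feature screen retained ", length(selected),
                 " probes but the signature needs n1 + n2 = ", n1 + n2))
  }
  signatures <- extract_signatures(differential, n1 = n1, n2 = n2,
                                   probes = selected)
  dist <- signature_distances(differential, probes = selected,
                              n1 = n1, n2 = n2)
  map <- build_map(dist, n_pct = n_pct, mode = mode, cutoff = cutoff)
  say("map: ", length(map$sample_ids), " nodes, ", nrow(map$edges), " edges")
  communities <- detect_communities(map)
  cluster_labels <- label_clusters(communities, labels)
  say("communities: ", nrow(cluster_labels))
  diagnosis <- classify_majority(map, labels, weighted = weighted)
  metrics <- evaluate_diagnosis(diagnosis, labels)
  say("accuracy: ", sprintf("%.3f", metrics$accuracy))

  structure(list(expression = complete, control = control,
                 differential = differential, features = features,
                 selected = selected, signatures = signatures, dist = dist,
                 map = map, communities = communities,
                 cluster_labels = cluster_labels, diagnosis = diagnosis,
                 metrics = metrics, labels = labels,
                 params = list(n1 = n1, n2 = n2, alpha = alpha,
                               n_pct = n_pct, weighted = weighted,
                               inclusive = inclusive, exact = exact,
                               mode = mode, cutoff = cutoff)),
            class = "signature_map")
}

#' @export
print.signature_map <- function(x, ...) {
  cat("Rank-based signature map\n")
  cat("  samples:", length(x$map$sample_ids),
      " probes:", nrow(x$expression),
      " selected:", length(x$selected), "\n")
  cat("  n1 =", x$params$n1, " n2 =", x$params$n2,
      " alpha =", x$params$alpha, " N% =", x$params$n_pct, "\n")
  cat("  communities:", nrow(x$cluster_labels),
      " edges:", nrow(x$map$edges), "\n")
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f (%d abstained)\n",
              x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity, x$metrics$n_abstain))
  invisible(x)
}

#' Per-sample summary of a fitted signature map
#'
#' @param x A `signature_map` from [fit_signature_map()].
#' @param ... Unused.
#' @return Tibble: `sample_id`, `phenotype` (truth), `community`,
#'   `community_label`, `predicted`, `correct` (`NA` where the truth is
#'   unknown).
#' @method tidy signature_map
#' @export
tidy.signature_map <- function(x, ...) {
  out <- x$communities |>
    dplyr::left_join(x$cluster_labels[c("community", "phenotype")],
                     by = "community") |>
    dplyr::rename(community_label = "phenotype") |>
    dplyr::left_join(x$diagnosis[c("sample_id", "predicted")],
                     by = "sample_id") |>
    dplyr::mutate(phenotype = phenotype_of(.data$sample_id, x$labels),
                  .after = "sample_id")
  out$correct <- ifelse(out$phenotype %in% c("control", "affected"),
                        out$predicted == out$phenotype, NA)
  out
}

#' One-row summary of a fitted signature map
#'
#' @param x A `signature_map`.
#' @param ... Unused.
#' @return Tibble: `n_samples`, `n_probes`, `n_selected`, `n_edges`,
#'   `n_communities`, `modularity`, `accuracy`, `sensitivity`,
#'   `specificity`, `n_abstain`.
#' @method glance signature_map
#' @export
glance.signature_map <- function(x, ...) {
  tibble(n_samples = length(x$map$sample_ids),
         n_probes = nrow(x$expression),
         n_selected = length(x$selected),
         n_edges = nrow(x$map$edges),
         n_communities = length(unique(x$communities$community)),
         modularity = map_modularity(x$map, x$communities),
         accuracy = x$metrics$accuracy,
         sensitivity = x$metrics$sensitivity,
         specificity = x$metrics$specificity,
         n_abstain = x$metrics$n_abstain)
}

#' Plot a fitted signature map
#'
#' @param object A `signature_map`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_map
#' @export
autoplot.signature_map <- function(object, seed = 1L, ...) {
  autoplot.sample_map(object$map, labels = object$labels, seed = seed)
}

#' Write every pipeline artifact to a directory
#'
#' Feature report, per-sample signatures, edge list, full distance matrix,
#' GraphML, diagnosis report and metrics JSON.
#'
#' @param fit A `signature_map`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_map_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "signature_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_report(fit$features, file.path(dir, "features.tsv"))
  readr::write_tsv(fit$signatures, file.path(dir, "signatures.tsv"),
                   progress = FALSE)
  write_distance_matrix(fit$dist, file.path(dir, "distances.tsv"))
  write_edge_list(fit$map$edges, file.path(dir, "edges.tsv"))
  export_graphml(fit$map, file.path(dir, "map.graphml"),
                 labels = fit$labels, communities = fit$communities,
                 diagnosis = fit$diagnosis)
  truth <- phenotype_of(fit$diagnosis$sample_id, fit$labels)
  report <- dplyr::mutate(fit$diagnosis, true = truth, .after = "predicted")
  readr::write_tsv(report, file.path(dir, "diagnosis.tsv"), progress = FALSE)
  jsonlite::write_json(as.list(glance.signature_map(fit)),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Scan signature and map parameters for cluster separation
#'
#' Re-runs the signature/distance/map stages over a grid of (`n1`, `n2`,
#' `n_pct`) and scores each setting by the weighted modularity of its
#' community partition — the map-sharpening loop, exposed as a grid scan
#' rather than an automatic optimiser.
#'
#' @param expression,labels As [fit_signature_map()].
#' @param n1,n2,n_pct Numeric vectors defining the grid.
#' @param ... Further arguments passed to [fit_signature_map()].
#' @return Tibble: one row per grid point with `n1`, `n2`, `n_pct`,
#'   `modularity`, `n_communities`, `accuracy`, sorted by decreasing
#'   modularity.
#' @export
scan_parameters <- function(expression, labels, n1 = c(15, 25, 50),
                            n2 = n1, n_pct = c(10, 20), ...) {
  grid <- tidyr::expand_grid(n1 = unique(n1), n2 = unique(n2),
                             n_pct = unique(n_pct))
  rows <- purrr::pmap(grid, function(n1, n2, n_pct) {
    fit <- fit_signature_map(expression, labels, n1 = n1, n2 = n2,
                             n_pct = n_pct, ...)
    g <- glance.signature_map(fit)
    tibble(n1 = n1, n2 = n2, n_pct = n_pct, modularity = g$modularity,
           n_communities = g$n_communities, accuracy = g$accuracy)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$modularity))
}

map_modularity <- function(map, communities) {
  g <- map$graph
  if (igraph::ecount(g) == 0L) return(NA_real_)
  member <- communities$community[match(igraph::V(g)$name,
                                        communities$sample_id)]
  igraph::modularity(g, member, weights = igraph::E(g)$weight)
}
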