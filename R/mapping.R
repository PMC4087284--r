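# Map construction and analysis: keep the N% smallest pairwise distances
# as edges, partition the resulting graph into communities, label clusters
# by anchor majority, diagnose nodes by neighbour majority vote, and score
# the diagnoses.

#' Keep the N% smallest pairwise distances
#'
#' From the P = n(n-1)/2 unordered pairs, keeps the K = ceiling(N/100 x P)
#' smallest distances. Exact ties straddling the cutoff are resolved by
#' lexicographic pair ID so exactly K pairs are kept. An absolute-cutoff
#' mode (`mode = "absolute"`) keeps every pair with distance <= `cutoff`
#' instead.
#'
#' @param d A `signature_dist` object, or a symmetric numeric distance
#'   matrix with sample IDs as dimnames.
#' @param n_pct Percentage in (0, 100] of smallest distances to keep
#'   (the map-sparsity parameter; 10 is usually enough for a clear map).
#' @param mode `"percentile"` (default) or `"absolute"`.
#' @param cutoff Distance cutoff, required for `mode = "absolute"`.
#' @return Edge tibble: `sample_a`, `sample_b`, `distance`, `similarity`.
#' @export
threshold_edges <- function(d, n_pct = 10, mode = c("percentile", "absolute"),
                            cutoff = NULL) {
  mode <- match.arg(mode)
  pairs <- dist_pairs(d)
  if (mode == "absolute") {
    if (is.null(cutoff)) {
      abort("mode = \"absolute\" needs a distance cutoff")
    }
    return(pairs[pairs$distance <= cutoff, ])
  }
  if (!(n_pct > 0 && n_pct <= 100)) {
    abort("n_pct must lie in (0, 100]")
  }
  k <- ceiling(n_pct / 100 * nrow(pairs))
  pairs[seq_len(k), ]
}

#' Build a sample similarity map
#'
#' Every sample becomes a node (isolated ones included); the kept pairs
#' become undirected edges carrying `distance` and `weight` = 1 - distance.
#'
#' @param d A `signature_dist` object or symmetric distance matrix.
#' @param n_pct,mode,cutoff Passed to [threshold_edges()]; alternatively
#'   supply a ready-made edge tibble via `edges`.
#' @param edges Optional edge tibble overriding the thresholding.
#' @return A `sample_map` object wrapping an igraph graph; `tidy()` returns
#'   the edges, `autoplot()` draws the map.
#' @export
build_map <- function(d, n_pct = 10, mode = c("percentile", "absolute"),
                      cutoff = NULL, edges = NULL) {
  mode <- match.arg(mode)
  ids <- if (inherits(d, "signature_dist")) d$sample_ids else rownames(d)
  if (is.null(edges)) {
    edges <- threshold_edges(d, n_pct = n_pct, mode = mode, cutoff = cutoff)
  } else {
    edges <- canonical_edges(edges)
  }
  g <- igraph::graph_from_data_frame(
    edges[c("sample_a", "sample_b", "distance", "similarity")],
    directed = FALSE,
    vertices = data.frame(name = ids))
  igraph::E(g)$weight <- 1 - igraph::E(g)$distance
  structure(list(graph = g, edges = edges, sample_ids = ids,
                 n_pct = if (mode == "percentile") n_pct else NA_real_),
            class = "sample_map")
}

#' @export
print.sample_map <- function(x, ...) {
  cat("Sample similarity map:", length(x$sample_ids), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' @method tidy sample_map
#' @export
tidy.sample_map <- function(x, ...) x$edges

#' Plot a sample map
#'
#' Draws the graph with a force-directed (Fruchterman-Reingold) layout on
#' edge weights, colouring nodes by phenotype.
#'
#' @param object A `sample_map`.
#' @param labels Optional label tibble used to colour the nodes.
#' @param seed Layout seed (layout only; no analysis randomness).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sample_map
#' @export
autoplot.sample_map <- function(object, labels = NULL, seed = 1L, ...) {
  g <- object$graph
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(sample_id = igraph::V(g)$name,
                  x = xy[, 1], y = xy[, 2],
                  phenotype = phenotype_of(igraph::V(g)$name, labels))
  el <- igraph::as_edgelist(g)
  segs <- tibble(x = nodes$x[match(el[, 1], nodes$sample_id)],
                 y = nodes$y[match(el[, 1], nodes$sample_id)],
                 xend = nodes$x[match(el[, 2], nodes$sample_id)],
                 yend = nodes$y[match(el[, 2], nodes$sample_id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$phenotype), size = 3) +
    ggplot2::scale_colour_manual(values = c(control = "#2E8B57",
                                            affected = "#CC3311",
                                            unknown = "grey50")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "phenotype")
}

#' Partition a sample map into communities
#'
#' Greedy agglomerative modularity maximisation (Clauset-Newman-Moore) on
#' the edge weights; deterministic for a fixed graph. Isolated nodes come
#' out as singleton communities.
#'
#' @param map A `sample_map`.
#' @return Tibble with columns `sample_id`, `community` (integer IDs).
#' @export
detect_communities <- function(map) {
  stopifnot(inherits(map, "sample_map"))
  g <- map$graph
  if (igraph::vcount(g) == 0L) {
    abort("map has no nodes")
  }
  if (igraph::ecount(g) == 0L) {
    member <- seq_len(igraph::vcount(g))
  } else {
    cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
    # pick the cut of the merge tree with maximal modularity ourselves:
    # exact ties (e.g. a single clique, where Q = 0 both whole and split)
    # must resolve to the coarsest partition, not to floating-point noise
    ks <- seq.int(igraph::components(g)$no, igraph::vcount(g))
    qs <- vapply(ks, function(k) {
      igraph::modularity(g, igraph::cut_at(cl, no = k),
                         weights = igraph::E(g)$weight)
    }, numeric(1))
    member <- igraph::cut_at(cl, no = ks[which(qs >= max(qs) - 1e-10)[1]])
  }
  tibble(sample_id = igraph::V(g)$name, community = as.integer(member))
}

#' Label communities by their anchor members
#'
#' Each community takes the majority phenotype of its members with a known
#' (anchor) label; a tie between anchors, or a community with no anchors,
#' yields `unknown`.
#'
#' @param communities Tibble from [detect_communities()].
#' @param anchors Label tibble of known samples.
#' @return Tibble with columns `community`, `phenotype`, `n_control`,
#'   `n_affected`.
#' @export
label_clusters <- function(communities, anchors) {
  ph <- phenotype_of(communities$sample_id, anchors)
  if (!any(ph %in% c("control", "affected"))) {
    abort("no anchor-labelled samples available for cluster labelling")
  }
  communities |>
    dplyr::mutate(phenotype = ph) |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(
      n_control = sum(.data$phenotype == "control"),
      n_affected = sum(.data$phenotype == "affected")) |>
    dplyr::mutate(phenotype = dplyr::case_when(
      .data$n_control > .data$n_affected ~ "control",
      .data$n_affected > .data$n_control ~ "affected",
      TRUE ~ "unknown")) |>
    dplyr::select("community", "phenotype", "n_control", "n_affected")
}

#' Diagnose samples by neighbour majority vote
#'
#' For each target node, its immediate neighbours with a known label vote
#' for their own phenotype; a strict majority wins. With `weighted = TRUE`
#' each vote counts 1 / max(distance, eps) instead of 1. An exact tie, or a
#' node with no labelled neighbour, yields `abstain` (scored as an error by
#' [evaluate_diagnosis()]). A node's own label never votes, so running this
#' with the full truth table is the leave-one-out protocol.
#'
#' @param map A `sample_map`.
#' @param known Label tibble of the voting labels.
#' @param weighted Inverse-distance weighting flag (default unweighted).
#' @param targets Sample IDs to diagnose; default all nodes.
#' @param eps Floor applied to distances inside inverse weights.
#' @return Tibble: `sample_id`, `predicted` (`control`/`affected`/
#'   `abstain`), `vote_control`, `vote_affected`, `n_neighbors`.
#' @export
classify_majority <- function(map, known, weighted = FALSE, targets = NULL,
                              eps = 1e-12) {
  stopifnot(inherits(map, "sample_map"))
  g <- map$graph
  ids <- igraph::V(g)$name
  targets <- targets %||% ids
  ph <- setNames(phenotype_of(ids, known), ids)
  adj <- igraph::adjacent_vertices(g, targets)
  rows <- purrr::map2(targets, adj, function(id, nb) {
    nb_ids <- nb$name
    nb_ph <- ph[nb_ids]
    keep <- nb_ph %in% c("control", "affected")
    nb_ids <- nb_ids[keep]
    nb_ph <- nb_ph[keep]
    if (weighted && length(nb_ids) > 0L) {
      eid <- igraph::get_edge_ids(g, rbind(rep(id, length(nb_ids)), nb_ids))
      w <- 1 / pmax(igraph::E(g)$distance[eid], eps)
    } else {
      w <- rep(1, length(nb_ids))
    }
    vc <- sum(w[nb_ph == "control"])
    va <- sum(w[nb_ph == "affected"])
    pred <- if (length(nb_ids) == 0L || vc == va) "abstain"
            else if (vc > va) "control" else "affected"
    tibble(sample_id = id, predicted = pred,
           vote_control = vc, vote_affected = va,
           n_neighbors = length(nb_ids))
  })
  dplyr::bind_rows(rows)
}

#' Score diagnoses against the truth
#'
#' Accuracy, sensitivity and specificity of a diagnosis over the samples
#' with known truth. An abstention counts as an error. Sensitivity is the
#' fraction of affected samples called affected; specificity the fraction
#' of controls called control.
#'
#' @param diagnosis Tibble from [classify_majority()].
#' @param truth Label tibble with the true phenotypes.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `n_evaluated`, `n_abstain`.
#' @export
evaluate_diagnosis <- function(diagnosis, truth) {
  ph <- phenotype_of(diagnosis$sample_id, truth)
  keep <- ph %in% c("control", "affected")
  if (!any(keep)) {
    abort("no samples with known truth to evaluate")
  }
  pred <- diagnosis$predicted[keep]
  ph <- ph[keep]
  correct <- pred == ph
  sens <- if (any(ph == "affected")) {
    mean(correct[ph == "affected"])
  } else NA_real_
  spec <- if (any(ph == "control")) {
    mean(correct[ph == "control"])
  } else NA_real_
  tibble(accuracy = mean(correct), sensitivity = sens, specificity = spec,
         n_evaluated = sum(keep), n_abstain = sum(pred == "abstain"))
}

# unordered pairs of a distance input, sorted by (distance, pair ID)
dist_pairs <- function(d) {
  if (inherits(d, "signature_dist")) {
    pairs <- tidy.signature_dist(d)
  } else {
    d <- as.matrix(d)
    if (is.null(rownames(d))) {
      abort("distance matrix needs sample IDs as dimnames")
    }
    ids <- rownames(d)
    ut <- which(upper.tri(d), arr.ind = TRUE)
    pairs <- canonical_edges(tibble(sample_a = ids[ut[, 1]],
                                    sample_b = ids[ut[, 2]],
                                    distance = d[ut]))
  }
  if (nrow(pairs) == 0L) {
    abort("need at least 2 samples to threshold distances")
  }
  dplyr::arrange(pairs, .data$distance, .data$sample_a, .data$sample_b)
}
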