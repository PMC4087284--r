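# helper: symmetric distance matrix from a vector of upper-tri values
sym_dist <- function(values, ids) {
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- values
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

test_that("edge thresholding keeps exactly ceil(N% of pairs), smallest first", {
  ids <- paste0("s", 1:5)
  d <- sym_dist(seq(0.1, 1, length.out = 10), ids)
  kept <- threshold_edges(d, n_pct = 20)        # ceil(0.2 * 10) = 2
  expect_equal(nrow(kept), 2L)
  expect_true(max(kept$distance) <= min(setdiff(d[upper.tri(d)], kept$distance)))

  expect_equal(nrow(threshold_edges(d, n_pct = 100)), 10L)

  tied <- sym_dist(rep(0.5, 10), ids)
  kept_tied <- threshold_edges(tied, n_pct = 10)  # ceil(1) = 1, tie by pair ID
  expect_equal(nrow(kept_tied), 1L)
  expect_equal(kept_tied$sample_a, "s1")
  expect_equal(kept_tied$sample_b, "s2")

  one <- matrix(0, 1, 1, dimnames = list("s1", "s1"))
  expect_error(threshold_edges(one, n_pct = 10), "at least 2")
  expect_error(threshold_edges(d, n_pct = 0), "n_pct")
})

test_that("absolute-cutoff mode keeps every pair at or below the cutoff", {
  ids <- paste0("s", 1:4)
  d <- sym_dist(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), ids)
  kept <- threshold_edges(d, mode = "absolute", cutoff = 0.3)
  expect_equal(sort(kept$distance), c(0.1, 0.2, 0.3))
  expect_error(threshold_edges(d, mode = "absolute"), "cutoff")
})

test_that("maps keep isolated nodes and the weight contract", {
  ids <- paste0("s", 1:3)
  d <- sym_dist(c(0.3, 0.8, 0.9), ids)
  map <- build_map(d, n_pct = 34)  # ceil(0.34 * 3) = 2... check below
  expect_s3_class(map, "sample_map")
  expect_equal(length(map$sample_ids), 3L)

  map1 <- build_map(d, edges = tibble::tibble(
    sample_a = "s1", sample_b = "s2", distance = 0.3, similarity = 0.4))
  expect_equal(igraph::vcount(map1$graph), 3)
  expect_equal(igraph::ecount(map1$graph), 1)
  expect_equal(igraph::degree(map1$graph)[["s3"]], 0)
  expect_equal(igraph::E(map1$graph)$weight, 0.7)
  expect_equal(tidy(map1)$distance, 0.3)
})

test_that("community detection recovers planted cliques and handles edge cases", {
  # two 4-cliques joined by one weak bridge
  ids <- paste0("s", 1:8)
  edges <- dplyr::bind_rows(
    tidyr::expand_grid(sample_a = ids[1:4], sample_b = ids[1:4]),
    tidyr::expand_grid(sample_a = ids[5:8], sample_b = ids[5:8])) |>
    dplyr::filter(sample_a < sample_b) |>
    dplyr::mutate(distance = 0.1, similarity = 0.8)
  bridge <- tibble::tibble(sample_a = "s4", sample_b = "s5",
                           distance = 0.9, similarity = -0.8)
  map <- build_map(sym_dist(rep(1, 28), ids),
                   edges = dplyr::bind_rows(edges, bridge))
  comm <- detect_communities(map)
  expect_equal(length(unique(comm$community)), 2L)
  expect_equal(length(unique(comm$community[1:4])), 1L)
  expect_equal(length(unique(comm$community[5:8])), 1L)

  # exhaustive modularity over all 2-partitions agrees with the cliques
  oracle <- best_two_partition(map$graph)
  expect_equal(oracle$membership, rep(1:2, each = 4))
  member <- comm$community[match(igraph::V(map$graph)$name, comm$sample_id)]
  expect_equal(igraph::modularity(map$graph, member,
                                  weights = igraph::E(map$graph)$weight),
               oracle$modularity)

  # edgeless graph: every node its own community; one clique: one community
  lone <- build_map(sym_dist(c(0.5, 0.5, 0.5), paste0("s", 1:3)),
                    edges = edges[0, ])
  expect_equal(detect_communities(lone)$community, 1:3)
  clique <- build_map(sym_dist(rep(0.1, 6), paste0("s", 1:4)), n_pct = 100)
  expect_equal(length(unique(detect_communities(clique)$community)), 1L)
})

test_that("clusters take the majority phenotype of their anchors", {
  comm <- tibble::tibble(sample_id = paste0("s", 1:6),
                         community = c(1, 1, 1, 2, 2, 3))
  anchors <- tibble::tibble(
    sample_id = c("s1", "s2", "s4", "s5"),
    phenotype = c("control", "control", "affected", "control"))
  lab <- label_clusters(comm, anchors)
  expect_equal(lab$phenotype[lab$community == 1], "control")
  expect_equal(lab$phenotype[lab$community == 2], "unknown")  # anchor tie
  expect_equal(lab$phenotype[lab$community == 3], "unknown")  # no anchors

  expect_error(label_clusters(comm, comm[0, ] |>
                                dplyr::mutate(phenotype = character(0))),
               "anchor")
})

test_that("majority vote follows the tally, abstains on ties, weights optionally", {
  ids <- c("t", "a1", "a2", "c1")
  edges <- tibble::tibble(sample_a = "t", sample_b = c("a1", "a2", "c1"),
                          distance = c(0.1, 0.2, 0.4))
  map <- build_map(sym_dist(rep(1, 6), ids), edges = edges)
  labs <- tibble::tibble(sample_id = c("a1", "a2", "c1"),
                         phenotype = c("affected", "affected", "control"))
  diag_u <- classify_majority(map, labs)
  expect_equal(diag_u$predicted[diag_u$sample_id == "t"], "affected")
  expect_equal(diag_u$vote_affected[diag_u$sample_id == "t"], 2)

  # two-neighbour tie abstains
  edges2 <- edges[c(1, 3), ]
  map2 <- build_map(sym_dist(rep(1, 6), ids), edges = edges2)
  diag2 <- classify_majority(map2, labs)
  expect_equal(diag2$predicted[diag2$sample_id == "t"], "abstain")

  # inverse-distance weighting: affected at 0.1 (10) beats control at 0.4 (2.5)
  diag_w <- classify_majority(map2, labs, weighted = TRUE)
  t_row <- diag_w[diag_w$sample_id == "t", ]
  expect_equal(t_row$predicted, "affected")
  expect_equal(t_row$vote_affected, 10)
  expect_equal(t_row$vote_control, 2.5)

  # isolated node (a2 has no edges here) abstains
  expect_equal(diag2$predicted[diag2$sample_id == "a2"], "abstain")
})

test_that("unweighted voting is invariant under monotone distance rescaling; weighted is not", {
  ids <- c("t", "a1", "c1", "c2")
  edges <- tibble::tibble(sample_a = "t", sample_b = c("a1", "c1", "c2"),
                          distance = c(0.1, 0.4, 0.4))
  labs <- tibble::tibble(sample_id = c("a1", "c1", "c2"),
                         phenotype = c("affected", "control", "control"))
  rescaled <- dplyr::mutate(edges, distance = distance + 1)
  map_a <- build_map(sym_dist(rep(1, 6), ids), edges = edges)
  map_b <- build_map(sym_dist(rep(1, 6), ids), edges = rescaled)

  u_a <- classify_majority(map_a, labs)$predicted
  u_b <- classify_majority(map_b, labs)$predicted
  expect_equal(u_a, u_b)

  w_a <- classify_majority(map_a, labs, weighted = TRUE)
  w_b <- classify_majority(map_b, labs, weighted = TRUE)
  expect_equal(w_a$predicted[w_a$sample_id == "t"], "affected")  # 10 vs 5
  expect_equal(w_b$predicted[w_b$sample_id == "t"], "control")   # 0.91 vs 1.43
})

test_that("evaluation scores abstentions as errors and splits by phenotype", {
  truth <- tibble::tibble(sample_id = paste0("s", 1:10),
                          phenotype = rep(c("affected", "control"), each = 5))
  pred <- tibble::tibble(
    sample_id = paste0("s", 1:10),
    predicted = c("affected", "affected", "affected", "affected", "control",
                  "control", "control", "control", "control", "abstain"))
  m <- evaluate_diagnosis(pred, truth)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$n_abstain, 1L)

  all_good <- dplyr::mutate(pred, predicted = truth$phenotype)
  expect_equal(evaluate_diagnosis(all_good, truth)$sensitivity, 1)

  flipped <- dplyr::mutate(pred,
    predicted = ifelse(truth$phenotype == "affected", "control", "control"))
  m2 <- evaluate_diagnosis(flipped, truth)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)

  expect_error(
    evaluate_diagnosis(pred, dplyr::mutate(truth, phenotype = "unknown")),
    "known truth")
})

test_that("perfectly separated communities give perfect leave-one-out accuracy", {
  ids <- c(paste0("c", 1:5), paste0("a", 1:5))
  edges <- dplyr::bind_rows(
    tidyr::expand_grid(sample_a = ids[1:5], sample_b = ids[1:5]),
    tidyr::expand_grid(sample_a = ids[6:10], sample_b = ids[6:10])) |>
    dplyr::filter(sample_a < sample_b) |>
    dplyr::mutate(distance = 0.2, similarity = 0.6)
  map <- build_map(sym_dist(rep(1, 45), ids), edges = edges)
  truth <- tibble::tibble(sample_id = ids,
                          phenotype = rep(c("control", "affected"), each = 5))
  m <- evaluate_diagnosis(classify_majority(map, truth), truth)
  expect_equal(m$accuracy, 1)
})
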