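# Enrichment-score similarity between rank signatures. The score of one
# sample's signature against another sample's full ranking is the classic
# unweighted running-sum statistic (Kolmogorov-Smirnov style, weighting
# exponent zero): walking the ranking, a member of the set adds 1/m and a
# non-member subtracts 1/(G-m); the score is the running-sum deviation of
# largest absolute magnitude, signed. A value-weighted variant would break
# the rank-only robustness the method is built on, so it is not offered.

#' Unweighted enrichment score of a gene set against a ranking
#'
#' @param ranking Character vector of probe IDs, highest first.
#' @param gene_set Character vector of probe IDs; must be a non-empty
#'   proper subset of `ranking`.
#' @return Score in \[-1, 1\]; +1 when the set occupies the very top of the
#'   ranking, -1 the very bottom. When the maximal positive and negative
#'   excursions tie in magnitude the positive one is returned.
#' @export
#' @examples
#' enrichment_score(paste0("g", 1:6), c("g1", "g2"))  #  1
#' enrichment_score(paste0("g", 1:6), c("g3", "g5"))  # -0.5
enrichment_score <- function(ranking, gene_set) {
  es_from_hits(ranking %in% gene_set)
}

# core running-sum extremum over a logical hit vector
es_from_hits <- function(hits) {
  g <- length(hits)
  p <- which(hits)
  m <- length(p)
  if (m == 0L || m == g) {
    abort("gene set must be a non-empty proper subset of the ranking")
  }
  j <- seq_len(m)
  # running sum just after the j-th hit, and just before it (the local
  # minimum of the preceding down-slope); extremes occur only there.
  # Integer numerators over the common denominator m(G-m) — a hit steps
  # +(G-m), a miss -m — so exact magnitude ties resolve exactly.
  after <- j * (g - m) - (p - j) * m
  before <- (j - 1) * (g - m) - (p - j) * m
  max_pos <- max(after)
  min_neg <- min(before)
  (if (max_pos >= -min_neg) max_pos else min_neg) / (m * (g - m))
}

#' Directional enrichment score of a signature against a ranking
#'
#' The score of a composite signature is the average of its two parts: the
#' top part scored against the other sample's descending ranking and the
#' bottom part against the reversed (ascending) ranking, so that concordant
#' under-expression also contributes positively.
#'
#' @param signature List with `top` and `bottom` probe ID vectors
#'   ([extract_signature()]).
#' @param ranking Character vector of probe IDs, highest first.
#' @return Score in \[-1, 1\].
#' @export
directional_es <- function(signature, ranking) {
  (enrichment_score(ranking, signature$top) +
     enrichment_score(rev(ranking), signature$bottom)) / 2
}

#' Bidirectional signature similarity between two samples
#'
#' Averages the directional score of A's signature against B's ranking with
#' the score of B's signature against A's ranking, making the measure
#' symmetric by construction.
#'
#' @param sig_a,sig_b Signatures (lists with `top`, `bottom`).
#' @param rank_a,rank_b Full descending rankings of the two samples.
#' @return Similarity in \[-1, 1\]; 1 for identical rankings.
#' @export
pairwise_similarity <- function(sig_a, rank_a, sig_b, rank_b) {
  (directional_es(sig_a, rank_b) + directional_es(sig_b, rank_a)) / 2
}

#' All-to-all signature distance matrix
#'
#' Extracts each sample's ranking and composite signature over the given
#' probe set and computes every pairwise similarity s, mapped to a distance
#' d = (1 - s) / 2 so that s = 1 gives d = 0 and s = -1 gives d = 1.
#'
#' @param x Differential tibble.
#' @param probes Probe subset to use (typically the selected features);
#'   `NULL` for all.
#' @param n1,n2 Signature sizes.
#' @return A `signature_dist` object: symmetric distance and similarity
#'   matrices plus the parameters used. `as.matrix()` returns the distance
#'   matrix, `tidy()` the unordered pairs as a tibble, `autoplot()` a
#'   heatmap.
#' @export
signature_distances <- function(x, probes = NULL, n1 = 25, n2 = 25) {
  rk <- ranked_matrix(x, probes)
  n <- ncol(rk)
  g <- nrow(rk)
  ids <- colnames(rk)
  if (n1 < 1L || n2 < 1L || n1 + n2 > g) {
    abort(paste0("signature sizes n1 = ", n1, ", n2 = ", n2,
                 " must be >= 1 with n1 + n2 <= ", g, " ranked probes"))
  }
  hit_top <- matrix(FALSE, g, n)
  hit_bot <- matrix(FALSE, g, n)
  rev_idx <- seq.int(g, 1L)
  for (j in seq_len(n)) {
    sig <- extract_signature(rk[, j], n1, n2)
    for (k in seq_len(n)) {
      hit_top[, k] <- rk[, k] %in% sig$top
      hit_bot[, k] <- rk[rev_idx, k] %in% sig$bottom
    }
    if (j == 1L) {
      des <- matrix(0, n, n, dimnames = list(ids, ids))
    }
    # directional score of sample j's signature against every ranking
    des[j, ] <- (apply(hit_top, 2, es_from_hits) +
                   apply(hit_bot, 2, es_from_hits)) / 2
  }
  s <- (des + t(des)) / 2
  diag(s) <- 1
  d <- (1 - s) / 2
  structure(list(distance = d, similarity = s, sample_ids = ids,
                 n1 = n1, n2 = n2, n_probes = g),
            class = "signature_dist")
}

#' @export
as.matrix.signature_dist <- function(x, ...) x$distance

#' @export
print.signature_dist <- function(x, ...) {
  cat("Signature distance matrix:", length(x$sample_ids), "samples over",
      x$n_probes, "probes (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  cat("distance range:",
      sprintf("%.3f - %.3f", min(x$distance[upper.tri(x$distance)]),
              max(x$distance)), "\n")
  invisible(x)
}

#' Tidy a signature distance matrix into sample pairs
#'
#' @param x A `signature_dist` object.
#' @param ... Unused.
#' @return Tibble of unordered pairs: `sample_a`, `sample_b`, `distance`,
#'   `similarity`, with `sample_a < sample_b`.
#' @method tidy signature_dist
#' @export
tidy.signature_dist <- function(x, ...) {
  ids <- x$sample_ids
  ut <- which(upper.tri(x$distance), arr.ind = TRUE)
  canonical_edges(tibble(sample_a = ids[ut[, 1]], sample_b = ids[ut[, 2]],
                         distance = x$distance[ut],
                         similarity = x$similarity[ut]))
}

#' Heatmap of a signature distance matrix
#'
#' @param object A `signature_dist` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_dist
#' @export
autoplot.signature_dist <- function(object, ...) {
  ids <- object$sample_ids
  df <- tidyr::expand_grid(sample_a = ids, sample_b = ids)
  df$distance <- as.vector(t(object$distance))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write a full distance matrix as square TSV
#'
#' @param d A `signature_dist` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(inherits(d, "signature_dist"))
  out <- as_tibble(as.data.frame(d$distance))
  out <- dplyr::bind_cols(tibble(sample_id = d$sample_ids), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
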