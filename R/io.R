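# Readers/writers for the package's tab-separated dialect: expression
# matrices (header row = sample IDs, first column = probe IDs), label
# tables, edge lists, and GraphML export for external graph viewers.

#' Read an expression matrix from TSV
#'
#' Parses a tab-separated file whose first row holds sample identifiers and
#' whose first column holds probe identifiers. Cells must be numeric or one
#' of the missing tokens `"NA"` / empty string; missing cells are kept as
#' `NA` (use [drop_incomplete_probes()] to remove them). Intensities are
#' expected on a linear scale — the virtual-control transform divides by a
#' per-probe mean, which is meaningless for log-scale data; no log detection
#' is attempted.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a character `probe_id` column followed by one
#'   numeric column per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\ts1\ts2", "g1\t1.5\t2", "g2\tNA\t4"), tf)
#' read_expression(tf)
read_expression <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("expression matrix file not found: ", path))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    abort("expression matrix needs a probe column plus at least one sample column")
  }
  sample_ids <- header[-1L]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated sample ID(s): ", paste(dup, collapse = ", ")))
  }
  raw <- readr::read_tsv(path, skip = 1L, col_names = c("probe_id", sample_ids),
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  dup <- unique(raw$probe_id[duplicated(raw$probe_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated probe ID(s): ", paste(dup, collapse = ", ")))
  }
  parse_col <- function(chr, sample_id) {
    missing_tok <- is.na(chr) | chr == "" | chr == "NA"
    val <- suppressWarnings(as.numeric(chr))
    bad <- which(!missing_tok & is.na(val))
    if (length(bad) > 0L) {
      abort(paste0("non-numeric cell \"", chr[bad[1]], "\" at probe ",
                   raw$probe_id[bad[1]], ", sample ", sample_id))
    }
    val
  }
  parsed <- purrr::imap(raw[-1L], parse_col)
  tibble(probe_id = raw$probe_id, !!!parsed)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: round-trips probe IDs, sample IDs,
#' values and missing cells losslessly (missing written as `NA`).
#'
#' @param x Expression tibble (`probe_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- check_expression(x)
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a phenotype label table
#'
#' Two-column TSV mapping `sample_id` to a phenotype in `control`,
#' `affected`, `unknown`. A header row `sample_id<TAB>phenotype` is
#' accepted and skipped. Samples absent from the table are treated as
#' `unknown` wherever labels are joined to a matrix.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `phenotype`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("label file not found: ", path))
  }
  tab <- readr::read_tsv(path, col_names = c("sample_id", "phenotype"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tab) > 0L && identical(unlist(tab[1L, ], use.names = FALSE),
                                  c("sample_id", "phenotype"))) {
    tab <- tab[-1L, ]
  }
  check_labels(tab)
}

#' Write a phenotype label table
#'
#' @param labels Tibble with columns `sample_id`, `phenotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- check_labels(labels)
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}

#' Write a filtered distance edge list to TSV
#'
#' Columns `sample_a`, `sample_b`, `distance`, `similarity`; each unordered
#' pair appears once with `sample_a < sample_b` lexicographically, never as
#' a self-pair.
#'
#' @param edges Edge tibble as returned by [threshold_edges()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  edges <- canonical_edges(edges)
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path Path to a TSV edge list.
#' @return Tibble with columns `sample_a`, `sample_b`, `distance`,
#'   `similarity`.
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = "ccdd", progress = FALSE)
}

#' Export a sample map as GraphML
#'
#' Writes the similarity map for external viewers (e.g. Cytoscape, which
#' the force-directed rendering is delegated to). Nodes carry `sample_id`,
#' `phenotype` and, when available, `predicted` and `community` attributes;
#' edges carry `distance` and `weight` = 1 - distance.
#'
#' @param map A `sample_map` from [build_map()].
#' @param path Output path.
#' @param labels Optional label tibble; defaults to the labels already
#'   attached to the map (if any), missing samples become `unknown`.
#' @param communities Optional tibble (`sample_id`, `community`).
#' @param diagnosis Optional tibble (`sample_id`, `predicted`).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(map, path, labels = NULL, communities = NULL,
                           diagnosis = NULL) {
  stopifnot(inherits(map, "sample_map"))
  g <- map$graph
  ids <- igraph::V(g)$name
  igraph::V(g)$sample_id <- ids
  igraph::V(g)$phenotype <- phenotype_of(ids, labels)
  if (!is.null(communities)) {
    igraph::V(g)$community <-
      communities$community[match(ids, communities$sample_id)]
  }
  if (!is.null(diagnosis)) {
    igraph::V(g)$predicted <-
      diagnosis$predicted[match(ids, diagnosis$sample_id)]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# ---- internal validation helpers -------------------------------------------

check_expression <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 2L || names(x)[1] != "probe_id") {
    abort("expected an expression tibble: a `probe_id` column followed by sample columns")
  }
  dup <- unique(x$probe_id[duplicated(x$probe_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated probe ID(s): ", paste(dup, collapse = ", ")))
  }
  samples <- names(x)[-1L]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated sample ID(s): ", paste(dup, collapse = ", ")))
  }
  as_tibble(x)
}

check_labels <- function(labels) {
  if (!is.data.frame(labels) ||
      !all(c("sample_id", "phenotype") %in% names(labels))) {
    abort("expected a label tibble with columns sample_id, phenotype")
  }
  dup <- unique(labels$sample_id[duplicated(labels$sample_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicated sample ID(s) in labels: ",
                 paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(labels$phenotype), .phenotypes)
  if (length(bad) > 0L) {
    abort(paste0("unrecognised phenotype(s): ", paste(bad, collapse = ", "),
                 "; accepted values are: ", paste(.phenotypes, collapse = ", ")))
  }
  as_tibble(labels[c("sample_id", "phenotype")])
}

# probes x samples numeric matrix view of an expression tibble
expr_values <- function(x) {
  x <- check_expression(x)
  m <- as.matrix(x[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- x$probe_id
  m
}

# phenotype lookup with the unknown default for unlisted samples
phenotype_of <- function(sample_ids, labels) {
  if (is.null(labels)) {
    return(rep("unknown", length(sample_ids)))
  }
  labels <- check_labels(labels)
  ph <- labels$phenotype[match(sample_ids, labels$sample_id)]
  ph[is.na(ph)] <- "unknown"
  ph
}

# enforce sample_a < sample_b and drop self-pairs is an error, not silent
canonical_edges <- function(edges) {
  if (!all(c("sample_a", "sample_b", "distance") %in% names(edges))) {
    abort("edge tibble needs columns sample_a, sample_b, distance")
  }
  if (any(edges$sample_a == edges$sample_b)) {
    abort("self-pairs are not allowed in an edge list")
  }
  if (!"similarity" %in% names(edges)) {
    edges$similarity <- 1 - 2 * edges$distance
  }
  swap <- edges$sample_a > edges$sample_b
  a <- ifelse(swap, edges$sample_b, edges$sample_a)
  b <- ifelse(swap, edges$sample_a, edges$sample_b)
  out <- tibble(sample_a = a, sample_b = b,
                distance = edges$distance, similarity = edges$similarity)
  dplyr::arrange(out, .data$sample_a, .data$sample_b)
}
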