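# Per-sample rank signatures: order each (differential) profile from the
# highest to the lowest value and keep the identities of the n1 most and
# n2 least expressed probes. Only the ordering matters, which is what makes
# the signature robust to calibration differences and batch effects.

#' Rank one profile from highest to lowest
#'
#' @param values Named numeric vector (names are probe IDs).
#' @return Character vector of probe IDs in descending value order; ties
#'   are broken by probe ID, ascending, so the ordering is deterministic.
#' @export
rank_profile <- function(values) {
  if (length(values) == 0L) {
    abort("cannot rank an empty profile")
  }
  if (is.null(names(values)) || anyNA(values) || any(!is.finite(values))) {
    abort("profile values must be finite and named by probe ID")
  }
  names(values)[order(-values, names(values), method = "radix")]
}

#' Extract the top/bottom composite signature from a ranking
#'
#' @param ranked Character vector of probe IDs, highest first.
#' @param n1 Number of most-expressed probe IDs to keep.
#' @param n2 Number of least-expressed probe IDs to keep.
#' @return List with character vectors `top` (the first `n1`) and `bottom`
#'   (the last `n2`, in ranking order).
#' @export
extract_signature <- function(ranked, n1, n2) {
  g <- length(ranked)
  if (n1 < 1L || n2 < 1L || n1 + n2 > g) {
    abort(paste0("signature sizes n1 = ", n1, ", n2 = ", n2,
                 " must be >= 1 with n1 + n2 <= ", g, " ranked probes"))
  }
  list(top = ranked[seq_len(n1)], bottom = ranked[seq.int(g - n2 + 1L, g)])
}

#' Rank every sample's profile over a probe subset
#'
#' @param x Differential (or expression) tibble.
#' @param probes Probe IDs to rank over (typically the selected feature
#'   set); `NULL` uses all probes.
#' @return Tidy tibble with columns `sample_id`, `rank`, `probe_id`.
#' @export
rank_profiles <- function(x, probes = NULL) {
  m <- ranked_matrix(x, probes)
  tibble(sample_id = rep(colnames(m), each = nrow(m)),
         rank = rep(seq_len(nrow(m)), times = ncol(m)),
         probe_id = as.vector(m))
}

#' Extract every sample's composite signature
#'
#' @inheritParams rank_profiles
#' @param n1,n2 Signature sizes (defaults 25/25, the serum-panel setting).
#' @return Tidy tibble with columns `sample_id`, `part` (`"top"` or
#'   `"bottom"`), `rank` (position within the full ranking), `probe_id`.
#' @export
extract_signatures <- function(x, n1 = 25, n2 = 25, probes = NULL) {
  m <- ranked_matrix(x, probes)
  g <- nrow(m)
  if (n1 < 1L || n2 < 1L || n1 + n2 > g) {
    abort(paste0("signature sizes n1 = ", n1, ", n2 = ", n2,
                 " must be >= 1 with n1 + n2 <= ", g, " ranked probes"))
  }
  rows <- c(seq_len(n1), seq.int(g - n2 + 1L, g))
  part <- rep(c("top", "bottom"), c(n1, n2))
  tibble(sample_id = rep(colnames(m), each = length(rows)),
         part = rep(part, times = ncol(m)),
         rank = rep(rows, times = ncol(m)),
         probe_id = as.vector(m[rows, , drop = FALSE]))
}

# probe-ID matrix of per-sample rankings (rows = rank position)
ranked_matrix <- function(x, probes = NULL) {
  m <- expr_values(x)
  if (!is.null(probes)) {
    missing_p <- setdiff(probes, rownames(m))
    if (length(missing_p) > 0L) {
      abort(paste0("probes not present in the matrix: ",
                   paste(head(missing_p, 5), collapse = ", ")))
    }
    m <- m[rownames(m) %in% probes, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    abort("no probes to rank")
  }
  vapply(colnames(m), function(s) rank_profile(m[, s]),
         character(nrow(m)))
}
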