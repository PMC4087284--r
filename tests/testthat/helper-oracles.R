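# Independent oracles used to check the implementation. These deliberately
# use the slowest, most literal formulation of each quantity and share no
# code with the package internals.

# Explicit position-by-position running-sum walk: +1/m on a hit,
# -1/(G-m) on a miss; return the deviation of largest absolute magnitude,
# preferring the positive one on an exact magnitude tie.
# The walk is carried in integer units of 1/(m*(G-m)) — a hit steps
# +(G-m), a miss -m — so magnitude ties are compared exactly rather than
# through accumulated floating-point error.
es_walk_oracle <- function(ranking, gene_set) {
  hits <- ranking %in% gene_set
  g <- length(hits)
  m <- sum(hits)
  stopifnot(m > 0, m < g)
  run <- 0
  best <- 0
  for (i in seq_len(g)) {
    run <- run + if (hits[i]) (g - m) else -m
    if (abs(run) > abs(best) || (abs(run) == abs(best) && run > best)) {
      best <- run
    }
  }
  best / (m * (g - m))
}

# Directional score oracle: average of the walk on the top part (descending
# ranking) and the bottom part (ascending ranking).
directional_es_oracle <- function(sig, ranking) {
  (es_walk_oracle(ranking, sig$top) +
     es_walk_oracle(rev(ranking), sig$bottom)) / 2
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of ranks
# to group A (no ties assumed). U is counted for group A.
mw_enumeration_oracle <- function(a, b) {
  na <- length(a)
  n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) sum(idx) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(u = u_obs, p = min(1, p))
}

# All permutations of 1..n as a matrix with one permutation per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    shifted <- sub + (sub >= i)
    cbind(i, shifted, deparse.level = 0)
  }))
}

# Best 2-partition of a weighted graph by exhaustive modularity search.
best_two_partition <- function(graph) {
  n <- igraph::vcount(graph)
  w <- igraph::E(graph)$weight
  best_q <- -Inf
  best_member <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    member <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    q <- igraph::modularity(graph, member, weights = w)
    if (q > best_q) {
      best_q <- q
      best_member <- member
    }
  }
  list(membership = best_member, modularity = best_q)
}

# Small random positive expression cohort for property tests.
random_cohort <- function(n_probes, n_samples, seed) {
  withr::with_seed(seed, {
    vals <- matrix(exp(rnorm(n_probes * n_samples)), n_probes, n_samples)
  })
  ids <- paste0("s", seq_len(n_samples))
  colnames(vals) <- ids
  tibble::tibble(probe_id = paste0("g", seq_len(n_probes)),
                 !!!as.data.frame(vals))
}
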