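# Independent oracles used across tests. These deliberately use naive,
# obviously-correct formulations (direct means, explicit enumeration,
# closed forms) so they share no code path with the implementation.

# exhaustive two-segment split search with direct mean/RSS computation
brute_breakpoint <- function(x, min_seg_frac) {
  n <- length(x)
  m <- max(1L, as.integer(ceiling(min_seg_frac * n)))
  best_k <- NA_integer_
  best_rss <- Inf
  for (k in m:(n - m)) {
    a <- x[1:k]
    b <- x[(k + 1):n]
    rss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_k <- k
    }
  }
  list(index = best_k, rss = best_rss)
}

# exact expected absorption time of the synchronous language dynamics on
# a star whose hub starts L2 with k of L leaves L1: leaves copy the hub's
# (old) state each tick, the hub copies a uniform leaf. While the hub is
# L2 the L1 leaf count stays k, the hub flips with probability k/L; one
# further tick saturates the rest. E[T] = L/k + 1.
star_absorption_mean <- function(n_leaves, l1_leaves) {
  n_leaves / l1_leaves + 1
}

# closed-form logistic growth, the d = 0 solution of the refuge
# compartment
logistic_solution <- function(t, A0, r, K) {
  K * A0 * exp(r * t) / (K + A0 * (exp(r * t) - 1))
}

# build an lc_network by hand from an explicit edge list
manual_lc_network <- function(n, edges, is_l1) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]
    b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  structure(list(n_nodes = n, edges = edges, adj = adj, is_l1 = is_l1),
            class = "lc_network")
}

# noiseless records on an exact power law, for fit round trips
power_law_records <- function(n = 6, slope = 0.5, intercept = 0) {
  la <- seq(0, 5, length.out = n)
  tibble::tibble(
    name = paste0("sys", seq_len(n)),
    environment = rep("marine", n),
    area_km2 = 10^la,
    duration_yr = 10^(intercept + slope * la))
}
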