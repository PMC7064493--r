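#' Build a random connected network for the language-adoption model
#'
#' Nodes are wired as a random recursive spanning tree (each new node
#' attaches to a uniformly chosen earlier node, guaranteeing
#' connectivity), after which any remaining links are added uniformly at
#' random among the absent pairs. The effective link count is
#' `max(n_links, n_nodes - 1)`: a requested count below the spanning-tree
#' minimum defaults to `n_nodes - 1` so all nodes stay connected.
#' `round(init_l1_fraction * n_nodes)` randomly chosen nodes start out
#' speaking the dominant language L1; the rest speak L2.
#'
#' @param n_nodes Number of nodes (>= 3).
#' @param n_links Requested number of undirected links.
#' @param init_l1_fraction Fraction of nodes initially speaking L1.
#' @param seed Optional integer seed.
#' @return An `lc_network`: list with `n_nodes`, `edges` (2-column
#'   matrix), `adj` (adjacency list) and `is_l1` (logical state vector).
#' @export
lc_build <- function(n_nodes, n_links = n_nodes - 1,
                     init_l1_fraction = 0.10, seed = NULL) {
  check_scalar(n_nodes, "n_nodes", lo = 3, integer = TRUE)
  check_scalar(n_links, "n_links", lo = 0, integer = TRUE)
  check_scalar(init_l1_fraction, "init_l1_fraction", lo = 0, hi = 1)
  n <- as.integer(n_nodes)
  max_links <- n * (n - 1) / 2
  if (n_links > max_links)
    stop(sprintf("n_links = %d exceeds the %d possible pairs of %d nodes",
                 n_links, max_links, n), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eff <- max(as.integer(n_links), n - 1L)
  # random recursive spanning tree
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  edges <- cbind(parent, 2:n)
  extra <- eff - (n - 1L)
  if (extra > 0) {
    pair_id <- function(a, b) {  # a < b, 0-based id over all pairs
      (b - 2) * (b - 1) / 2 + a
    }
    have <- pair_id(pmin(edges[, 1], edges[, 2]),
                    pmax(edges[, 1], edges[, 2]))
    if (max_links <= 2e5) {
      all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      ids <- pair_id(all_pairs[, 1], all_pairs[, 2])
      absent <- which(!ids %in% have)
      pick <- absent[sample.int(length(absent), extra)]
      edges <- rbind(edges, cbind(all_pairs[pick, 1], all_pairs[pick, 2]))
    } else {
      taken <- new.env(hash = TRUE)
      for (id in have) assign(as.character(id), TRUE, envir = taken)
      added <- 0L
      while (added < extra) {
        ab <- sort(sample.int(n, 2L))
        key <- as.character(pair_id(ab[1], ab[2]))
        if (!exists(key, envir = taken, inherits = FALSE)) {
          assign(key, TRUE, envir = taken)
          edges <- rbind(edges, ab)
          added <- added + 1L
        }
      }
    }
  }
  dimnames(edges) <- NULL
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  is_l1 <- rep(FALSE, n)
  n_l1 <- round(init_l1_fraction * n)
  if (n_l1 > 0) is_l1[sample.int(n, n_l1)] <- TRUE
  structure(list(n_nodes = n, edges = edges, adj = adj, is_l1 = is_l1),
            class = "lc_network")
}

#' One synchronous step of the language-adoption dynamics
#'
#' Every node still speaking L2 samples one of its neighbours uniformly
#' and adopts that neighbour's language; L1 is dominant and can never be
#' lost once adopted, so the L1 count is non-decreasing.
#'
#' @param net An `lc_network`.
#' @return The network after one tick.
#' @export
lc_step <- function(net) {
  stopifnot(inherits(net, "lc_network"))
  l2 <- which(!net$is_l1)
  if (length(l2) == 0) return(net)
  nb_of <- net$adj[l2]
  lens <- lengths(nb_of)
  flat <- unlist(nb_of, use.names = FALSE)
  offset <- cumsum(c(0L, lens[-length(lens)]))
  pick <- offset + floor(stats::runif(length(l2)) * lens) + 1L
  chosen <- flat[pick]
  net$is_l1[l2] <- net$is_l1[chosen]
  net
}

#' Run the language-adoption model to saturation
#'
#' The network starts in a mixed, unstable state; the single regime shift
#' ends at the first tick every node speaks the dominant language L1. A
#' network with no initial L1 speakers is absorbed in all-L2 and reports
#' `no_shift`, as does a run that reaches `max_ticks` still mixed.
#'
#' @param net An `lc_network` from [lc_build()].
#' @param max_ticks Horizon (default 5000).
#' @param seed Optional integer seed.
#' @return List with `trace` (a `sim_trace` with columns `tick`,
#'   `l1_count`), `event` (one-row shift-event tibble) and `network` (the
#'   final state).
#' @examples
#' net <- lc_build(20, seed = 1)
#' lc_run(net, seed = 2)$event
#' @export
lc_run <- function(net, max_ticks = 5000, seed = NULL) {
  stopifnot(inherits(net, "lc_network"))
  if (!is.null(seed)) set.seed(seed)
  n <- net$n_nodes
  counts <- sum(net$is_l1)
  tick <- 0L
  while (tick < max_ticks) {
    cur <- counts[length(counts)]
    if (cur == n || cur == 0L) break
    net <- lc_step(net)
    counts <- c(counts, sum(net$is_l1))
    tick <- tick + 1L
  }
  params <- list(n_nodes = n, n_links = nrow(net$edges),
                 max_ticks = max_ticks)
  trace <- new_sim_trace(
    tibble::tibble(tick = seq_along(counts) - 1L, l1_count = counts),
    model = "lc", params = params, seed = seed)
  list(trace = trace,
       event = duration_unstable_start(trace, "all_same_language",
                                       n_nodes = n),
       network = net)
}

#' Write a language-adoption network to CSV
#'
#' Writes the edge list (`node_a,node_b`) to `path` and the per-node
#' language state (`node,language`) to `<path base>_state.csv`.
#'
#' @param net An `lc_network`.
#' @param path Edge-list CSV path.
#' @return `path`, invisibly.
#' @export
lc_write_network <- function(net, path) {
  stopifnot(inherits(net, "lc_network"))
  readr::write_csv(tibble::tibble(node_a = net$edges[, 1],
                                  node_b = net$edges[, 2]), path)
  state_path <- sub("(\\.csv)?$", "_state.csv", path)[1]
  readr::write_csv(tibble::tibble(node = seq_len(net$n_nodes),
                                  language = ifelse(net$is_l1, "L1", "L2")),
                   state_path)
  invisible(path)
}

#' Degree heterogeneity of a network
#'
#' Population standard deviation of the node degrees, used as the measure
#' of how heterogeneously a network is wired (0 for regular graphs; large
#' when a few keystone nodes hold most connections).
#'
#' @param net An `lc_network`.
#' @return Non-negative numeric scalar.
#' @export
lc_degree_sd <- function(net) {
  stopifnot(inherits(net, "lc_network"))
  deg <- lengths(net$adj)
  sqrt(mean((deg - mean(deg))^2))
}
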