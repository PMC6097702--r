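# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

# a thresholded_network built directly from an edge list (region names,
# weights = |r|); signed_r defaults to the weights
make_net <- function(regions, edges, weights, signed_r = weights, n = 10,
                     r_full = NULL) {
  R <- length(regions)
  g <- igraph::make_empty_graph(n = R, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = regions)
  if (length(weights) > 0) {
    idx <- cbind(match(edges[, 1], regions), match(edges[, 2], regions))
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "signed_r", value = signed_r)
    g <- igraph::set_edge_attr(g, "weight", value = weights)
    g <- igraph::set_edge_attr(g, "distance", value = 1 - weights)
  }
  if (is.null(r_full)) {
    r_full <- diag(R)
    dimnames(r_full) <- list(regions, regions)
    if (length(weights) > 0) {
      idx <- cbind(match(edges[, 1], regions), match(edges[, 2], regions))
      r_full[idx] <- signed_r
      r_full[idx[, c(2, 1), drop = FALSE]] <- signed_r
    }
  }
  structure(list(graph = g, level = 0.05, n = n, r_full = r_full,
                 regions = regions),
            class = "thresholded_network")
}

# a random connected-ish weighted igraph for oracle comparisons
random_weighted_graph <- function(n_nodes, p_edge = 0.45, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n_nodes, n_nodes)
    ut <- which(upper.tri(A))
    on <- ut[stats::runif(length(ut)) < p_edge]
    if (length(on) >= 2) break
  }
  w <- stats::runif(length(on), 0.2, 0.95)
  A[on] <- w
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  igraph::set_edge_attr(g, "distance", value = 1 - igraph::E(g)$weight)
}

# a small expression matrix with iid noise
random_expr <- function(n_subj, regions, group = "G", seed = 1,
                        mean = 1000, sd = 150) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_subj * length(regions), mean, sd),
              n_subj, length(regions),
              dimnames = list(paste0(group, seq_len(n_subj)), regions))
  expression_matrix(abs(v), rep(group, n_subj))
}

# 12-region two-community scenario used by several suites
twelve_region_scenario <- function(n_a = 10, n_b = 10,
                                   mods_b = list(), seed = 1) {
  regs <- paste0("R", 1:12)
  comm <- stats::setNames(rep(c("a", "b"), each = 6), regs)
  sim_scenario(regs, comm, base_corr_within = 0.7, base_corr_between = 0.3,
               group_specs = list(
                 A = list(n_subjects = n_a),
                 B = list(n_subjects = n_b, edge_modifications = mods_b)),
               rng_seed = seed)
}
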