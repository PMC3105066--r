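# Network generation and topology statistics.
#
# Interaction networks are plain undirected, simple igraph objects; agents
# are vertices 1..n. Generators follow fixed construction dialects so that
# a (parameters, seed) pair is bit-reproducible.

validate_network <- function(net) {
  if (!igraph::is_igraph(net)) {
    stop("`net` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop("interaction networks must be undirected", call. = FALSE)
  }
  if (igraph::any_loop(net) || igraph::any_multiple(net)) {
    stop("interaction networks must be simple (no self-loops, no duplicate edges)",
         call. = FALSE)
  }
  invisible(net)
}

new_network <- function(n, edges, model, params) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g <- igraph::set_graph_attr(g, "model", model)
  for (p in names(params)) g <- igraph::set_graph_attr(g, p, params[[p]])
  validate_network(g)
}

#' Generate a Barabasi-Albert preferential-attachment network
#'
#' Grows a connected scale-free network: starting from a complete graph on
#' `m` seed vertices, each new vertex attaches `m` edges to distinct
#' existing vertices chosen with probability proportional to their current
#' degree (uniformly while all degrees are zero). With `m = 1` the result
#' is a tree and therefore triangle-free.
#'
#' @param n Number of agents; must satisfy `n >= m + 1`.
#' @param m Edges added per new vertex (`m >= 1`).
#' @param seed Optional integer seed; when given, `set.seed()` is called so
#'   the edge set is reproducible.
#' @return An undirected simple igraph object with `n` vertices and
#'   `choose(m, 2) + (n - m) * m` edges.
#' @examples
#' g <- generate_ba(50, 2, seed = 1)
#' igraph::ecount(g)
#' @export
generate_ba <- function(n, m, seed = NULL) {
  if (!is.numeric(n) || !is.numeric(m) || length(n) != 1 || length(m) != 1 ||
      n != round(n) || m != round(m) || m < 1 || n < m + 1) {
    stop("invalid Barabasi-Albert parameters: need integer m >= 1 and n >= m + 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  m <- as.integer(m)
  deg <- integer(n)
  edges <- integer(0)
  if (m >= 2) {
    seed_pairs <- utils::combn(seq_len(m), 2)
    edges <- as.integer(seed_pairs)
    deg[seq_len(m)] <- m - 1L
  }
  for (v in seq.int(m + 1L, n)) {
    w <- deg[seq_len(v - 1L)]
    if (sum(w) == 0) w <- rep(1, v - 1L)
    targets <- sample.int(v - 1L, m, prob = w)
    edges <- c(edges, rbind(rep(v, m), targets))
    deg[targets] <- deg[targets] + 1L
    deg[v] <- m
  }
  new_network(n, edges, "ba", list(m = m))
}

#' Generate a Watts ring-rewiring (small-world) network
#'
#' Builds a ring lattice in which every vertex is linked to its `k/2`
#' nearest neighbours on each side, then visits each lattice edge once and,
#' with probability `beta`, rewires its far endpoint to a uniformly chosen
#' vertex that is neither the home vertex nor already a neighbour of it
#' (the rewire is skipped if no such vertex exists). `beta = 0` keeps the
#' regular lattice; `beta = 1` yields an essentially random graph with the
#' same number of edges, `n * k / 2`.
#'
#' @param n Number of agents (`n > k`).
#' @param k Even ring degree.
#' @param beta Rewiring probability in `[0, 1]`.
#' @inheritParams generate_ba
#' @return An undirected simple igraph object.
#' @examples
#' g <- generate_watts(50, 4, beta = 0.2, seed = 1)
#' @export
generate_watts <- function(n, k, beta, seed = NULL) {
  if (!is.numeric(n) || !is.numeric(k) || length(n) != 1 || length(k) != 1 ||
      n != round(n) || k != round(k) || k < 2 || k %% 2 != 0 || n <= k) {
    stop("invalid Watts parameters: need even k >= 2 and n > k", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta > 1) {
    stop("`beta` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  k <- as.integer(k)
  home <- rep(seq_len(n), each = k %/% 2L)
  shift <- rep(seq_len(k %/% 2L), times = n)
  away <- ((home - 1L + shift) %% n) + 1L
  nbr <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_along(home)) {
    nbr[[home[e]]] <- c(nbr[[home[e]]], away[e])
    nbr[[away[e]]] <- c(nbr[[away[e]]], home[e])
  }
  rewire <- stats::runif(length(home)) < beta
  for (e in seq_along(home)) {
    if (!rewire[e]) next
    i <- home[e]
    j <- away[e]
    candidates <- setdiff(seq_len(n), c(i, nbr[[i]]))
    if (!length(candidates)) next
    jn <- candidates[sample.int(length(candidates), 1L)]
    nbr[[i]] <- c(setdiff(nbr[[i]], j), jn)
    nbr[[j]] <- setdiff(nbr[[j]], i)
    nbr[[jn]] <- c(nbr[[jn]], i)
    away[e] <- jn
  }
  new_network(n, as.integer(rbind(home, away)), "watts",
              list(k = k, beta = beta))
}

#' Generate an Erdos-Renyi random network
#'
#' Each of the `choose(n, 2)` possible edges is present independently with
#' probability `p`.
#'
#' @param n Number of agents.
#' @param p Edge probability in `[0, 1]`.
#' @inheritParams generate_ba
#' @return An undirected simple igraph object.
#' @export
generate_er <- function(n, p, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  edges <- integer(0)
  if (n >= 2 && p > 0) {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    edges <- as.integer(pairs[, keep, drop = FALSE])
  }
  new_network(n, edges, "er", list(p = p))
}

#' Expand a network to interaction radius two
#'
#' Returns the graph in which two agents are linked whenever their
#' shortest-path distance in `net` is one or two, modelling agents that can
#' observe (and sanction) not only direct neighbours but also neighbours of
#' neighbours. Applying the closure to a graph of diameter at most two
#' returns the same edge set.
#'
#' @param net An undirected simple igraph object.
#' @return An undirected simple igraph object on the same vertices.
#' @examples
#' igraph::ecount(radius2_closure(generate_watts(10, 2, 0)))  # C10 -> ring k=4
#' @export
radius2_closure <- function(net) {
  validate_network(net)
  out <- igraph::simplify(igraph::connect(net, 2))
  out <- igraph::set_graph_attr(out, "radius", 2)
  out
}

#' Triplets through an agent
#'
#' Counts, for each requested agent, the number of unordered pairs of its
#' neighbours that are themselves linked — that is, the number of triangles
#' passing through the agent. The population mean of this quantity is the
#' network's interconnectedness.
#'
#' @param net An undirected simple igraph object.
#' @param i Agent index (1-based) or vector of indices; `NULL` for all.
#' @return Integer vector of triplet counts.
#' @export
node_triplets <- function(net, i = NULL) {
  validate_network(net)
  n <- igraph::vcount(net)
  if (is.null(i)) i <- seq_len(n)
  if (any(i < 1 | i > n | i != round(i))) {
    stop("agent index out of range", call. = FALSE)
  }
  as.integer(igraph::count_triangles(net, vids = i))
}

#' Local clustering of an agent
#'
#' Fraction of an agent's neighbour pairs that are linked:
#' `node_triplets(net, i) / choose(k_i, 2)`. Defined only for agents with
#' at least two neighbours; calling it on a lower-degree agent is an error
#' (aggregate statistics treat such agents as contributing clustering 0).
#'
#' @inheritParams node_triplets
#' @return Numeric vector of clustering coefficients in `[0, 1]`.
#' @export
node_clustering <- function(net, i = NULL) {
  validate_network(net)
  n <- igraph::vcount(net)
  if (is.null(i)) i <- seq_len(n)
  k <- igraph::degree(net, v = i)
  if (any(k < 2)) {
    stop("clustering is undefined for agents with fewer than two neighbours",
         call. = FALSE)
  }
  node_triplets(net, i) / choose(k, 2)
}

#' Topology statistics driving the metanorms dynamics
#'
#' Computes the statistics that parameterize the analytic model: the degree
#' distribution, the mean clustering of each degree class (agents with
#' fewer than two neighbours count as clustering 0), the average degree
#' and the interconnectedness — the mean number of triplets (triangles)
#' per agent, equal to three times the triangle count divided by `n`.
#'
#' @param net An undirected simple igraph object.
#' @return An object of class `"network_stats"`: a list with elements
#'   `n`, `avg_degree`, `interconnectedness`, `mean_clustering`,
#'   `degree_dist` (named fractions) and `clustering_by_degree`.
#' @examples
#' network_stats(generate_watts(50, 4, 0))
#' @export
network_stats <- function(net) {
  validate_network(net)
  n <- igraph::vcount(net)
  k <- igraph::degree(net)
  tri <- as.integer(igraph::count_triangles(net))
  cl <- ifelse(k >= 2, tri / choose(k, 2), 0)
  dd <- table(factor(k, levels = sort(unique(k)))) / n
  structure(
    list(
      n = n,
      avg_degree = mean(k),
      interconnectedness = mean(tri),
      mean_clustering = mean(cl),
      degree_dist = stats::setNames(as.numeric(dd), names(dd)),
      clustering_by_degree = vapply(split(cl, k), mean, numeric(1))
    ),
    class = "network_stats"
  )
}

#' Construct homogeneous network statistics directly
#'
#' Builds a `"network_stats"` object from a prescribed average degree and
#' interconnectedness without an underlying graph. Used by the analytic
#' model to study hypothetical topologies, e.g. when tracing the minimal
#' interconnectedness required for a cooperative ESS.
#'
#' @param n Agent count.
#' @param avg_degree Mean degree (non-negative).
#' @param interconnectedness Mean triplets per agent (non-negative).
#' @return A `"network_stats"` object.
#' @export
homogeneous_stats <- function(n, avg_degree, interconnectedness) {
  stopifnot(n >= 1, avg_degree >= 0, interconnectedness >= 0)
  structure(
    list(
      n = n,
      avg_degree = avg_degree,
      interconnectedness = interconnectedness,
      mean_clustering = if (avg_degree >= 2) {
        min(1, interconnectedness / choose(avg_degree, 2))
      } else 0,
      degree_dist = stats::setNames(1, as.character(avg_degree)),
      clustering_by_degree = NULL
    ),
    class = "network_stats"
  )
}

#' @export
print.network_stats <- function(x, ...) {
  cat("Interaction network statistics\n")
  cat(sprintf("  agents:              %d\n", x$n))
  cat(sprintf("  average degree:      %.4f\n", x$avg_degree))
  cat(sprintf("  interconnectedness:  %.4f (triplets per agent)\n",
              x$interconnectedness))
  cat(sprintf("  mean clustering:     %.4f\n", x$mean_clustering))
  invisible(x)
}

# 0-based adjacency list for the compiled engine
as_adjacency0 <- function(net) {
  validate_network(net)
  lapply(igraph::adjacent_vertices(net, seq_len(igraph::vcount(net))),
         function(v) as.integer(v) - 1L)
}
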