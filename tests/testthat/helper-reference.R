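# Shared fixtures and a deliberately slow pure-R reference implementation
# of one game round, kept independent of the compiled engine so the two
# can be cross-checked statistically.

graph_from_pairs <- function(n, pairs) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(pairs)) g <- igraph::add_edges(g, pairs)
  g
}

edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# Reference round player: same stage semantics as the engine, written
# independently with plain loops over igraph neighbourhoods. b, v are
# numeric trait values; returns the per-agent round payoff.
ref_play_round <- function(net, b, v, cfg = game_config()) {
  n <- igraph::vcount(net)
  nb <- lapply(seq_len(n), function(i) as.integer(igraph::neighbors(net, i)))
  pay <- numeric(n)
  s <- runif(n)
  defect <- b > s
  nd <- sum(defect)
  pay <- pay + cfg$hurt * (nd - defect)
  pay[defect] <- pay[defect] + cfg$temptation
  for (i in which(defect)) {
    for (j in nb[[i]]) {
      if (runif(1) >= s[i]) next
      if (runif(1) < v[j]) {
        pay[j] <- pay[j] + cfg$enforcement
        pay[i] <- pay[i] + cfg$punishment
      } else {
        for (l in intersect(nb[[i]], nb[[j]])) {
          if (runif(1) >= s[i]) next
          if (runif(1) < v[l]) {
            pay[l] <- pay[l] + cfg$meta_enforcement
            pay[j] <- pay[j] + cfg$meta_punishment
          }
        }
      }
    }
  }
  pay
}

# exhaustive O(n^3) triangle-through-node count
ref_node_triplets <- function(net, i) {
  nb <- as.integer(igraph::neighbors(net, i))
  cnt <- 0L
  if (length(nb) >= 2) {
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && igraph::are_adjacent(net, nb[a], nb[b])) cnt <- cnt + 1L
      }
    }
  }
  cnt
}
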