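# Experiment layer: zone classification, long-run occupancy, ensemble
# sweeps and empirical drift maps.

#' Zone specification for norm collapse and establishment
#'
#' The norm-collapse zone holds population states with mean boldness at
#' least `collapse_min_b` and mean vengefulness at most `collapse_max_v`;
#' the norm-establishment zone holds states with mean boldness at most
#' `establish_max_b` and mean vengefulness at least `establish_min_v`.
#' All comparisons are inclusive. The default bounds (6/7 and 1/7) make
#' the zones disjoint corners of the unit square.
#'
#' @param collapse_min_b,collapse_max_v,establish_max_b,establish_min_v
#'   Zone bounds in `[0, 1]`.
#' @return An object of class `"zone_spec"`.
#' @export
zone_spec <- function(collapse_min_b = 6 / 7, collapse_max_v = 1 / 7,
                      establish_max_b = 1 / 7, establish_min_v = 6 / 7) {
  z <- list(collapse_min_b = collapse_min_b, collapse_max_v = collapse_max_v,
            establish_max_b = establish_max_b,
            establish_min_v = establish_min_v)
  if (collapse_min_b <= establish_max_b && establish_min_v <= collapse_max_v) {
    stop("zones must be disjoint", call. = FALSE)
  }
  structure(z, class = "zone_spec")
}

#' Classify population states into norm zones
#'
#' Pure threshold classification (no randomness): a state is `collapse`,
#' `establishment` or `neither` according to [zone_spec()], with boundary
#' values included in the zones.
#'
#' @param mean_b,mean_v Numeric vectors of population means in `[0, 1]`.
#' @param zones A [zone_spec()].
#' @return Factor with levels `collapse`, `establishment`, `neither`.
#' @examples
#' classify_state(c(1, 0, 0.5), c(0, 1, 0.5))
#' @export
classify_state <- function(mean_b, mean_v, zones = zone_spec()) {
  stopifnot(length(mean_b) == length(mean_v),
            all(mean_b >= 0 & mean_b <= 1), all(mean_v >= 0 & mean_v <= 1))
  out <- rep("neither", length(mean_b))
  out[mean_b >= zones$collapse_min_b & mean_v <= zones$collapse_max_v] <-
    "collapse"
  out[mean_b <= zones$establish_max_b & mean_v >= zones$establish_min_v] <-
    "establishment"
  factor(out, levels = c("collapse", "establishment", "neither"))
}

#' Long-run zone occupancy of a trajectory
#'
#' Fraction of recorded generations a simulation spent in the
#' norm-collapse zone, the norm-establishment zone and elsewhere. For an
#' ergodic run these frequencies approximate the occupancy (limiting)
#' distribution of the underlying Markov chain over the zones.
#'
#' @param trajectory A `"metanorm_trajectory"` (see [run_simulation()]) or
#'   any data frame with `mean_boldness` and `mean_vengefulness` columns.
#' @param zones A [zone_spec()].
#' @param burn_in Number of initial generations to discard (default 0).
#' @return An object of class `"occupancy_result"`: list with fractions
#'   `collapse`, `establishment`, `neither` (summing to 1) and the number
#'   of `generations` counted.
#' @export
occupancy <- function(trajectory, zones = zone_spec(), burn_in = 0) {
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0) {
    stop("`trajectory` must be a nonempty data frame", call. = FALSE)
  }
  keep <- trajectory$generation >= burn_in
  if (!any(keep)) stop("burn-in removes the whole trajectory", call. = FALSE)
  cls <- classify_state(trajectory$mean_boldness[keep],
                        trajectory$mean_vengefulness[keep], zones)
  frac <- as.numeric(table(cls)) / length(cls)
  structure(
    list(collapse = frac[1], establishment = frac[2], neither = frac[3],
         generations = length(cls), burn_in = burn_in,
         network_stats = attr(trajectory, "network_stats"),
         config = attr(trajectory, "config")),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf(
    "Zone occupancy over %d generations:\n  collapse %.3f  establishment %.3f  neither %.3f\n",
    x$generations, x$collapse, x$establishment, x$neither))
  invisible(x)
}

#' Sample an ensemble of interaction networks
#'
#' Draws networks from the three generators with parameters sampled from
#' configurable grids, optionally expanding a random subset to interaction
#' radius two — the sampling scheme behind the topology sweeps, covering a
#' wide range of (average degree, interconnectedness) combinations at
#' fixed population size.
#'
#' @param n_networks Number of networks to sample.
#' @param n Agents per network.
#' @param seed Master seed for the ensemble.
#' @param models Generator names to sample from.
#' @param ba_m,watts_k,watts_beta,er_p Parameter grids for the generators.
#' @param radius2_fraction Probability that a sampled network is expanded
#'   to radius two.
#' @return List of igraph objects; each carries `model` and parameter
#'   graph attributes.
#' @export
sample_network_ensemble <- function(n_networks, n = 50, seed = NULL,
                                    models = c("ba", "watts", "er"),
                                    ba_m = 1:5,
                                    watts_k = c(2, 4, 6, 8, 10, 12),
                                    watts_beta = c(0, 0.05, 0.2, 1),
                                    er_p = c(0.05, 0.1, 0.2, 0.35, 0.5),
                                    radius2_fraction = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_networks), function(ix) {
    model <- sample(models, 1)
    g <- switch(model,
      ba = generate_ba(n, sample(ba_m, 1)),
      watts = generate_watts(n, sample(watts_k, 1),
                             sample(watts_beta, 1)),
      er = generate_er(n, sample(er_p, 1)))
    if (stats::runif(1) < radius2_fraction) g <- radius2_closure(g)
    g
  })
}

#' Occupancy sweep over a network ensemble
#'
#' Runs the full simulation on every (network, seed) combination and
#' tabulates zone occupancies together with the topology statistics of
#' each network. Child seeds are spawned deterministically from
#' `config$seed` before any run starts, so results are independent of
#' execution order and bit-reproducible.
#'
#' @param networks List of igraph objects (e.g. from
#'   [sample_network_ensemble()]).
#' @param config A [game_config()]; its `generations` field sets the run
#'   length and its `seed` field is the sweep master seed.
#' @param seeds_per_net Replicate runs per network.
#' @param zones A [zone_spec()].
#' @param burn_in Generations discarded before computing occupancy.
#' @return Data frame with one row per run: `net_id`, `seed`, `n`,
#'   `avg_degree`, `interconnectedness`, `sqrt_interconnectedness`,
#'   `mean_clustering`, `collapse`, `establishment`, `neither`.
#' @export
sweep_occupancy <- function(networks, config = game_config(),
                            seeds_per_net = 3, zones = zone_spec(),
                            burn_in = 0) {
  if (!length(networks)) stop("empty network ensemble", call. = FALSE)
  n_runs <- length(networks) * seeds_per_net
  if (!is.null(config$seed)) set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  rows <- vector("list", n_runs)
  run <- 0L
  for (g_ix in seq_along(networks)) {
    net <- networks[[g_ix]]
    ns <- network_stats(net)
    for (s_ix in seq_len(seeds_per_net)) {
      run <- run + 1L
      cfg <- config
      cfg$seed <- child_seeds[run]
      occ <- occupancy(run_simulation(net, cfg), zones, burn_in)
      rows[[run]] <- data.frame(
        net_id = g_ix, seed = cfg$seed, n = ns$n,
        avg_degree = ns$avg_degree,
        interconnectedness = ns$interconnectedness,
        sqrt_interconnectedness = sqrt(ns$interconnectedness),
        mean_clustering = ns$mean_clustering,
        collapse = occ$collapse, establishment = occ$establishment,
        neither = occ$neither)
    }
  }
  do.call(rbind, rows)
}

#' Bin sweep results over two topology statistics
#'
#' 2-D histogram aggregation of a [sweep_occupancy()] table: occupancy
#' fractions are averaged within bins of two chosen statistics (weighted
#' by run counts), the projection used to visualize how topology shapes
#' long-run behaviour.
#'
#' @param sweep_df Output of [sweep_occupancy()].
#' @param x,y Column names of the binning statistics.
#' @param bins Number of bins per axis, or a list of two breakpoint
#'   vectors.
#' @return Data frame with bin midpoints, run counts and mean occupancies.
#' @export
bin_occupancy <- function(sweep_df, x = "avg_degree",
                          y = "sqrt_interconnectedness", bins = 6) {
  stopifnot(all(c(x, y, "collapse", "establishment") %in% names(sweep_df)))
  brk <- function(vals, b) {
    if (is.numeric(b) && length(b) == 1) {
      seq(min(vals), max(vals), length.out = b + 1)
    } else b
  }
  if (is.list(bins)) {
    bx <- bins[[1]]
    by <- bins[[2]]
  } else {
    bx <- brk(sweep_df[[x]], bins)
    by <- brk(sweep_df[[y]], bins)
  }
  ix <- cut(sweep_df[[x]], bx, include.lowest = TRUE)
  iy <- cut(sweep_df[[y]], by, include.lowest = TRUE)
  agg <- stats::aggregate(
    sweep_df[, c("collapse", "establishment", "neither")],
    by = list(x_bin = ix, y_bin = iy), FUN = mean)
  counts <- stats::aggregate(list(n_runs = rep(1, nrow(sweep_df))),
                             by = list(x_bin = ix, y_bin = iy), FUN = sum)
  merge(agg, counts, by = c("x_bin", "y_bin"))
}

#' Within-bin rank trend of occupancy against a topology statistic
#'
#' Measures how a zone-occupancy fraction depends on one topology
#' statistic while holding another fixed. By default (`n_bins = NULL`)
#' this is the partial Spearman rank correlation between occupancy and
#' the statistic of interest, controlling for the conditioning statistic
#' (computed on rank residuals). Alternatively, with `n_bins` set, runs
#' are split into quantile bins of the conditioning statistic and the
#' within-bin Spearman correlations are combined by a run-count-weighted
#' mean. Used to test, e.g., that norm-establishment time increases with
#' interconnectedness at fixed average degree.
#'
#' @param sweep_df Output of [sweep_occupancy()].
#' @param response Occupancy column (`"establishment"`, `"collapse"` or
#'   `"neither"`).
#' @param vs Statistic whose effect is measured.
#' @param within Conditioning statistic held fixed.
#' @param n_bins `NULL` for the partial rank correlation (default), or a
#'   number of quantile bins for the binned estimate.
#' @return Correlation estimate in `[-1, 1]` (scalar); for the binned
#'   variant the per-bin correlations and counts are attached as an
#'   attribute.
#' @export
occupancy_trend <- function(sweep_df, response = "establishment",
                            vs = "interconnectedness",
                            within = "avg_degree", n_bins = NULL) {
  stopifnot(all(c(response, vs, within) %in% names(sweep_df)))
  if (is.null(n_bins)) {
    ry <- rank(sweep_df[[response]])
    rx <- rank(sweep_df[[vs]])
    rz <- rank(sweep_df[[within]])
    return(stats::cor(stats::resid(stats::lm(ry ~ rz)),
                      stats::resid(stats::lm(rx ~ rz))))
  }
  qs <- unique(stats::quantile(sweep_df[[within]],
                               probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(sweep_df[[within]], qs, include.lowest = TRUE)
  per_bin <- lapply(split(sweep_df, bins), function(d) {
    if (nrow(d) < 4 || stats::sd(d[[vs]]) == 0 ||
        stats::sd(d[[response]]) == 0) {
      return(c(cor = NA_real_, n = nrow(d)))
    }
    c(cor = stats::cor(d[[vs]], d[[response]], method = "spearman"),
      n = nrow(d))
  })
  tab <- do.call(rbind, per_bin)
  ok <- !is.na(tab[, "cor"])
  est <- sum(tab[ok, "cor"] * tab[ok, "n"]) / sum(tab[ok, "n"])
  attr(est, "per_bin") <- tab
  est
}

#' Empirical drift map of population movement
#'
#' Simulation counterpart of [gradient_map()]: for every cell of a grid
#' over the strategy square, the population is initialized homogeneously
#' at the nearest 8-level strategy, run for `horizon` generations `reps`
#' times, and the mean per-generation displacement of (mean boldness,
#' mean vengefulness) is recorded.
#'
#' @param net An undirected simple igraph object.
#' @param config A [game_config()]; `config$seed` seeds the whole map.
#' @param resolution Grid points per axis over `[0, 1]^2`.
#' @param reps Replicate runs per cell.
#' @param horizon Generations per replicate.
#' @return A `"gradient_field"` data frame with columns `b`, `v`, `db`,
#'   `dv`, `speed` (displacements per generation).
#' @export
empirical_drift_map <- function(net, config = game_config(),
                                resolution = 8, reps = 200, horizon = 1) {
  stopifnot(resolution >= 2, reps >= 1, horizon >= 1)
  adj <- as_adjacency0(net)
  n <- length(adj)
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$generations <- as.integer(horizon)
  cfg$seed <- NULL # one RNG stream for the whole map
  grid <- expand.grid(b = seq(0, 1, length.out = resolution),
                      v = seq(0, 1, length.out = resolution),
                      KEEP.OUT.ATTRS = FALSE)
  res <- t(mapply(function(b, v) {
    init <- make_strategies(rep(round(b * 7) / 7, n),
                            rep(round(v * 7) / 7, n))
    disp <- vapply(seq_len(reps), function(r) {
      traj <- run_simulation(net, cfg, init = init)
      last <- nrow(traj)
      c(traj$mean_boldness[last] - traj$mean_boldness[1],
        traj$mean_vengefulness[last] - traj$mean_vengefulness[1]) / horizon
    }, numeric(2))
    rowMeans(disp)
  }, grid$b, grid$v))
  out <- data.frame(b = grid$b, v = grid$v, db = res[, 1], dv = res[, 2],
                    speed = sqrt(res[, 1]^2 + res[, 2]^2))
  attr(out, "network_stats") <- network_stats(net)
  attr(out, "payoffs") <- payoff_vector(config)
  class(out) <- c("gradient_field", "data.frame")
  out
}
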