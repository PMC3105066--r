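# Three-stage metanorms game and evolutionary update.
#
# Strategies are pairs of 3-bit traits: boldness (propensity to defect)
# and vengefulness (propensity to punish / meta-punish), each taking the
# eight values 0/7 .. 7/7. Strategy sets are integer matrices with columns
# b_level and v_level in 0..7, one row per agent.

#' The eight strategy levels of a 3-bit trait
#'
#' @return Numeric vector `c(0, 1/7, ..., 1)`.
#' @export
strategy_levels <- function() 0:7 / 7

#' The joint strategy space
#'
#' All joint (boldness, vengefulness) strategies an agent can hold: both
#' traits are 3-bit strings, so there are 8 levels per trait and 64 joint
#' strategies.
#'
#' @return Data frame with columns `boldness` and `vengefulness`, one row
#'   per joint strategy.
#' @export
strategy_space <- function() {
  expand.grid(boldness = strategy_levels(), vengefulness = strategy_levels(),
              KEEP.OUT.ATTRS = FALSE)
}

#' Build a strategy matrix from trait values
#'
#' @param b,v Numeric vectors of boldness / vengefulness values on the
#'   `k/7` grid (recycled to a common length).
#' @return Integer matrix with columns `b_level`, `v_level` in `0..7`.
#' @export
make_strategies <- function(b, v) {
  nn <- max(length(b), length(v))
  b <- rep_len(b, nn)
  v <- rep_len(v, nn)
  bl <- round(b * 7)
  vl <- round(v * 7)
  if (any(abs(bl - b * 7) > 1e-8) || any(abs(vl - v * 7) > 1e-8) ||
      any(bl < 0 | bl > 7 | vl < 0 | vl > 7)) {
    stop("strategy values must lie on the 8-level grid 0/7 .. 7/7",
         call. = FALSE)
  }
  cbind(b_level = as.integer(bl), v_level = as.integer(vl))
}

#' Draw uniformly random strategies
#'
#' Each agent receives a boldness and a vengefulness level drawn uniformly
#' from the 64 joint strategies (uses the current RNG state).
#'
#' @param n Number of agents.
#' @return Integer strategy matrix.
#' @export
random_strategies <- function(n) {
  cbind(b_level = sample.int(8, n, replace = TRUE) - 1L,
        v_level = sample.int(8, n, replace = TRUE) - 1L)
}

check_strategies <- function(strategies, n) {
  if (!is.matrix(strategies) || ncol(strategies) != 2 ||
      nrow(strategies) != n) {
    stop("`strategies` must be a 2-column matrix with one row per agent",
         call. = FALSE)
  }
  if (any(strategies != round(strategies)) ||
      any(strategies < 0 | strategies > 7)) {
    stop("strategy levels must be integers in 0..7", call. = FALSE)
  }
  storage.mode(strategies) <- "integer"
  strategies
}

#' Game configuration
#'
#' Bundles the payoff constants, evolutionary parameters and run length of
#' a metanorms game. The defaults are the standard experimental settings:
#' temptation `T = 3`, hurt `H = -1`, enforcement `E = -2`, punishment
#' `P = -9`, meta-enforcement `ME = -2`, meta-punishment `MP = -9`,
#' mutation rate 0.01 per bit, 4 rounds per generation, 50000 generations
#' and 50 agents.
#'
#' @param temptation Payoff gained by a defector (T).
#' @param hurt Payoff inflicted on every other agent per defection (H).
#' @param enforcement Cost paid to punish a defector (E).
#' @param punishment Payoff received by a punished defector (P).
#' @param meta_enforcement Cost paid to meta-punish a non-punisher (ME).
#' @param meta_punishment Payoff received by a meta-punished agent (MP).
#' @param mutation_rate Per-bit flip probability in `[0, 1]`.
#' @param rounds_per_generation Rounds played before each selection step.
#' @param generations Number of generations to simulate.
#' @param n_agents Expected number of agents (consistency check only; the
#'   network determines the actual count).
#' @param seed Optional integer seed applied by [run_simulation()].
#' @param include_self Whether the roulette-wheel candidate pool is
#'   `N(i) + {i}` (default) or the neighbourhood alone.
#' @return An object of class `"game_config"`.
#' @export
game_config <- function(temptation = 3, hurt = -1, enforcement = -2,
                        punishment = -9, meta_enforcement = -2,
                        meta_punishment = -9, mutation_rate = 0.01,
                        rounds_per_generation = 4, generations = 50000,
                        n_agents = 50, seed = NULL, include_self = TRUE) {
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("`mutation_rate` must be in [0, 1]", call. = FALSE)
  }
  if (rounds_per_generation < 1) {
    stop("`rounds_per_generation` must be at least 1", call. = FALSE)
  }
  if (generations < 0) stop("`generations` must be >= 0", call. = FALSE)
  structure(
    list(temptation = temptation, hurt = hurt, enforcement = enforcement,
         punishment = punishment, meta_enforcement = meta_enforcement,
         meta_punishment = meta_punishment, mutation_rate = mutation_rate,
         rounds_per_generation = as.integer(rounds_per_generation),
         generations = as.integer(generations),
         n_agents = as.integer(n_agents), seed = seed,
         include_self = isTRUE(include_self)),
    class = "game_config"
  )
}

payoff_vector <- function(config) {
  c(config$temptation, config$hurt, config$enforcement, config$punishment,
    config$meta_enforcement, config$meta_punishment)
}

#' @export
print.game_config <- function(x, ...) {
  cat("Metanorms game configuration\n")
  cat(sprintf("  payoffs: T=%g H=%g E=%g P=%g ME=%g MP=%g\n",
              x$temptation, x$hurt, x$enforcement, x$punishment,
              x$meta_enforcement, x$meta_punishment))
  cat(sprintf("  mutation %g/bit, %d rounds/generation, %d generations\n",
              x$mutation_rate, x$rounds_per_generation, x$generations))
  cat(sprintf("  %d agents, selection pool %s\n", x$n_agents,
              if (x$include_self) "N(i) + self" else "N(i)"))
  invisible(x)
}

#' Play one round of the metanorms game
#'
#' Executes the three stages once. Stage 1: each agent draws an
#' observability value `s ~ U(0,1)` and defects iff its boldness exceeds
#' `s`; a defector gains the temptation payoff and every other agent in
#' the population is hurt (the spillover cost of defection is global).
#' Stage 2: each network neighbour of a defector observes the defection
#' independently with probability `s` and, if it observes, punishes with
#' probability equal to its vengefulness, paying the enforcement cost
#' while the defector receives the punishment payoff. Stage 3: for every
#' observed-but-unpunished defection, each common neighbour of defector
#' and non-punisher sees the non-punishment with the same probability `s`
#' and meta-punishes with probability equal to its vengefulness, paying
#' the meta-enforcement cost while the non-punisher receives the
#' meta-punishment payoff.
#'
#' @param net An undirected simple igraph object.
#' @param strategies Integer strategy matrix (see [make_strategies()]).
#' @param config A [game_config()].
#' @return List with `payoff` (per-agent round payoff) and the event
#'   counts `n_defect`, `n_punish`, `n_meta`.
#' @export
play_round <- function(net, strategies, config = game_config()) {
  adj <- as_adjacency0(net)
  strategies <- check_strategies(strategies, length(adj))
  cpp_play_round(adj, strategies[, 1], strategies[, 2],
                 payoff_vector(config))
}

#' Monte-Carlo payoff estimate over repeated rounds
#'
#' Plays `nrounds` independent rounds with fixed strategies and returns the
#' population-mean payoff of each round plus per-agent means — the
#' simulation side of the closed-form equivalence checks.
#'
#' @inheritParams play_round
#' @param nrounds Number of rounds to sample.
#' @return List with `round_mean` (length `nrounds`) and `agent_mean`.
#' @export
sample_round_payoffs <- function(net, strategies, config = game_config(),
                                 nrounds = 1e5) {
  adj <- as_adjacency0(net)
  strategies <- check_strategies(strategies, length(adj))
  cpp_play_rounds(adj, strategies[, 1], strategies[, 2],
                  payoff_vector(config), as.integer(nrounds))
}

#' Apply one synchronous selection-and-mutation update
#'
#' Local roulette-wheel selection: each agent considers the candidate pool
#' of its neighbours (plus itself unless `config$include_self` is FALSE;
#' isolated agents always keep themselves as the sole candidate), assigns
#' each candidate a fitness equal to its accumulated payoff minus the pool
#' minimum, and copies the joint (boldness, vengefulness) bit-strings of
#' one candidate drawn with probability proportional to fitness (uniformly
#' when all fitnesses are zero). Every bit of both copied 3-bit strings is
#' then flipped independently with probability `config$mutation_rate`.
#' All agents update synchronously from the old generation's strategies
#' and payoffs.
#'
#' @inheritParams play_round
#' @param payoffs Numeric vector of accumulated generation payoffs.
#' @return New integer strategy matrix.
#' @export
evolve_generation <- function(net, strategies, payoffs,
                              config = game_config()) {
  adj <- as_adjacency0(net)
  strategies <- check_strategies(strategies, length(adj))
  if (length(payoffs) != length(adj)) {
    stop("`payoffs` must have one entry per agent", call. = FALSE)
  }
  out <- cpp_evolve(adj, strategies[, 1], strategies[, 2],
                    as.numeric(payoffs), config$mutation_rate,
                    config$include_self)
  colnames(out) <- c("b_level", "v_level")
  out
}

#' Run a full metanorms simulation
#'
#' Initializes every agent with a uniformly random joint strategy (unless
#' `init` is given), then repeats for each generation: reset payoffs to
#' zero, play `rounds_per_generation` rounds with fresh observability
#' draws, and apply the synchronous selection-and-mutation update. The
#' population mean boldness and vengefulness are recorded each generation.
#' Runs are bit-reproducible given the same network, configuration and
#' seed.
#'
#' @param net An undirected simple igraph object.
#' @param config A [game_config()]; `config$generations` rounds the run.
#' @param init Optional initial strategy matrix; `NULL` for random.
#' @param snapshot_stride If positive, full strategy matrices are stored
#'   every this many generations.
#' @return An object of class `"metanorm_trajectory"`: a data frame with
#'   columns `generation` (0 = initial state), `mean_boldness`,
#'   `mean_vengefulness`, carrying the configuration, network statistics
#'   and event totals as attributes.
#' @examples
#' net <- generate_watts(20, 4, 0.1, seed = 1)
#' traj <- run_simulation(net, game_config(generations = 50, seed = 42))
#' tail(traj, 3)
#' @export
run_simulation <- function(net, config = game_config(), init = NULL,
                           snapshot_stride = 0) {
  adj <- as_adjacency0(net)
  n <- length(adj)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init)) {
    b0 <- integer(0)
    v0 <- integer(0)
  } else {
    init <- check_strategies(init, n)
    b0 <- init[, 1]
    v0 <- init[, 2]
  }
  res <- cpp_run_simulation(adj, b0, v0, payoff_vector(config),
                            config$mutation_rate,
                            config$rounds_per_generation,
                            config$generations, config$include_self,
                            as.integer(snapshot_stride))
  traj <- data.frame(generation = 0:config$generations,
                     mean_boldness = res$mean_b,
                     mean_vengefulness = res$mean_v)
  attr(traj, "config") <- config
  attr(traj, "network_stats") <- network_stats(net)
  attr(traj, "events") <- c(n_defect = res$n_defect,
                            n_punish = res$n_punish, n_meta = res$n_meta)
  if (snapshot_stride > 0) {
    attr(traj, "snapshots") <- res$snapshots
    attr(traj, "snapshot_generation") <- res$snapshot_generation
  }
  class(traj) <- c("metanorm_trajectory", "data.frame")
  traj
}

#' @export
print.metanorm_trajectory <- function(x, ...) {
  ns <- attr(x, "network_stats")
  cat(sprintf(
    "Metanorms trajectory: %d generations on %d agents (<k>=%.2f, Lambda=%.2f)\n",
    nrow(x) - 1L, ns$n, ns$avg_degree, ns$interconnectedness))
  last <- x[nrow(x), ]
  cat(sprintf("  final mean boldness %.3f, mean vengefulness %.3f\n",
              last$mean_boldness, last$mean_vengefulness))
  invisible(x)
}
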