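# Analytic abstraction of the metanorms game: expected one-round payoffs,
# mutant gradients, ESS identification and the minimal-interconnectedness
# threshold.
#
# With the observability draw s ~ U(0,1) shared by all observers of one
# defection, the relevant moments for a defector with boldness b are
#   P(defect)                      = b
#   P(defect & one observer sees)  = E[s 1(s<b)]   = b^2 / 2
#   P(defect & observe & meta-see) = E[s^2 1(s<b)] = b^3 / 3.
# Boldness and vengefulness are treated as continuous in [0,1] here; the
# simulator stays on the discrete 8-level grid.

#' Exact expected one-round payoff of every agent
#'
#' Computes the expectation of each agent's single-round payoff for an
#' arbitrary network and arbitrary per-agent (boldness, vengefulness)
#' values, by summing the expected temptation, hurt, enforcement,
#' punishment, meta-enforcement and meta-punishment contributions over
#' all (defector, observer, meta-observer) configurations the topology
#' admits.
#'
#' @param net An undirected simple igraph object.
#' @param b,v Numeric vectors in `[0, 1]`, one entry per agent (continuous
#'   values are allowed; the analytic model relaxes the 8-level grid).
#' @param config A [game_config()] (payoffs only are used).
#' @return Numeric vector of expected one-round payoffs.
#' @export
expected_payoff_exact <- function(net, b, v, config = game_config()) {
  validate_network(net)
  n <- igraph::vcount(net)
  if (length(b) == 1) b <- rep(b, n)
  if (length(v) == 1) v <- rep(v, n)
  if (length(b) != n || length(v) != n) {
    stop("`b` and `v` must have one entry per agent", call. = FALSE)
  }
  stopifnot(all(b >= 0 & b <= 1), all(v >= 0 & v <= 1))
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  b2 <- b^2 / 2
  b3 <- b^3 / 3
  # common-neighbour sums weighted by vengefulness:
  # (A %*% (v * A))[i, j] = sum_l A_il v_l A_lj
  AvA <- A %*% (v * A)
  A1mvA <- A %*% ((1 - v) * A)
  cfg <- config
  drop(
    b * cfg$temptation +
      cfg$hurt * (sum(b) - b) +
      cfg$enforcement * v * (A %*% b2) +
      cfg$punishment * b2 * (A %*% v) +
      cfg$meta_punishment * (1 - v) * ((A * AvA) %*% b3) +
      cfg$meta_enforcement * v * ((A * A1mvA) %*% b3)
  )
}

#' Expected one-round payoff of a homogeneous population
#'
#' Closed form for the population-mean expected payoff when every agent
#' plays the same (boldness, vengefulness) = (b, v), expressed through the
#' topology statistics alone:
#' \deqn{\pi(b,v) = bT + (n-1)bH + \langle k\rangle \frac{b^2}{2} v (E+P)
#'   + 2\Lambda \frac{b^3}{3} v (1-v) (ME+MP)}
#' where \eqn{\langle k\rangle} is the average degree and \eqn{\Lambda}
#' the interconnectedness (mean triplets per agent). The formula agrees
#' with the population mean of [expected_payoff_exact()] on any network
#' and with the agent-wise exact value on vertex-transitive networks.
#'
#' @param stats A `"network_stats"` object (see [network_stats()] or
#'   [homogeneous_stats()]).
#' @param b,v Population boldness / vengefulness in `[0, 1]` (vectorized).
#' @param config A [game_config()].
#' @return Numeric vector of expected one-round payoffs.
#' @export
expected_payoff_homogeneous <- function(stats, b, v,
                                        config = game_config()) {
  stopifnot(inherits(stats, "network_stats"))
  cfg <- config
  b * cfg$temptation +
    (stats$n - 1) * b * cfg$hurt +
    stats$avg_degree * (b^2 / 2) * v * (cfg$enforcement + cfg$punishment) +
    2 * stats$interconnectedness * (b^3 / 3) * v * (1 - v) *
      (cfg$meta_enforcement + cfg$meta_punishment)
}

#' Expected one-round payoff of a single mutant
#'
#' Payoff of one agent playing `(b_m, v_m)` embedded — with the network's
#' average degree and interconnectedness — in an otherwise homogeneous
#' incumbent population at `(b, v)`. Incumbent behaviour is held fixed:
#' the mutant is punished at the incumbents' vengefulness, pays
#' enforcement according to its own `v_m`, and so on.
#'
#' @inheritParams expected_payoff_homogeneous
#' @param b_m,v_m Mutant boldness / vengefulness in `[0, 1]`.
#' @param b,v Incumbent population boldness / vengefulness.
#' @return Numeric expected one-round payoff of the mutant.
#' @export
mutant_payoff <- function(stats, b_m, v_m, b, v, config = game_config()) {
  stopifnot(inherits(stats, "network_stats"))
  cfg <- config
  kavg <- stats$avg_degree
  lam <- stats$interconnectedness
  b_m * cfg$temptation +
    (stats$n - 1) * b * cfg$hurt +
    cfg$enforcement * v_m * kavg * (b^2 / 2) +
    cfg$punishment * (b_m^2 / 2) * kavg * v +
    cfg$meta_punishment * (1 - v_m) * 2 * lam * (b^3 / 3) * v +
    cfg$meta_enforcement * v_m * 2 * lam * (b^3 / 3) * (1 - v)
}

#' Mutant payoff gradient at the incumbent state
#'
#' Partial derivatives of [mutant_payoff()] with respect to the mutant's
#' own boldness and vengefulness, evaluated at mutant = incumbent. This is
#' the drift vector of the analytic gradient maps: a positive component
#' means a lone deviant gains by increasing that trait.
#'
#' @inheritParams expected_payoff_homogeneous
#' @return Named numeric vector `c(db, dv)`.
#' @export
mutant_gradient <- function(stats, b, v, config = game_config()) {
  stopifnot(inherits(stats, "network_stats"))
  cfg <- config
  kavg <- stats$avg_degree
  lam <- stats$interconnectedness
  db <- cfg$temptation + cfg$punishment * b * kavg * v
  dv <- cfg$enforcement * kavg * b^2 / 2 +
    2 * lam * (b^3 / 3) *
      (cfg$meta_enforcement * (1 - v) - cfg$meta_punishment * v)
  c(db = db, dv = dv)
}

# second derivative of the mutant payoff in b_m (constant in b_m)
mutant_curvature_b <- function(stats, v, config) {
  config$punishment * stats$avg_degree * v
}

#' Identify evolutionary stable states
#'
#' Searches the unit square of homogeneous (boldness, vengefulness) states
#' for strict evolutionary stable states under the mutant-payoff necessary
#' conditions: no lone mutant may profit from changing either trait. The
#' mutant payoff is quadratic in the mutant's boldness and linear in its
#' vengefulness, so interior vengefulness can at best be neutrally stable;
#' strict ESS lie on the edges `v = 0` or `v = 1`, where boldness must be
#' either an interior maximum of the mutant payoff or pinned to a boundary
#' with the gradient pointing outward (Karush-Kuhn-Tucker-style sign
#' conditions at `b, v` in `{0, 1}`).
#'
#' A state is labelled `"collapse"` when `b >= 6/7` and `v <= 1/7` (the
#' norm-collapse corner) and `"cooperative"` when `b <= 1/2` and
#' `v >= 1/2` (vigilant, near-compliant populations); anything else is
#' `"other"`. An empty cooperative set is a valid result.
#'
#' @inheritParams expected_payoff_homogeneous
#' @param grid_resolution Points per axis used to bracket sign changes of
#'   the boldness gradient along each edge.
#' @param tolerance Zero threshold for the gradient conditions.
#' @return An object of class `"ess_result"`: data frame with columns
#'   `boldness`, `vengefulness`, `label`, and the diagnostics `db`, `dv`,
#'   `curvature_b`.
#' @examples
#' find_ess(network_stats(generate_er(50, 1, seed = 1)))  # complete K50
#' @export
find_ess <- function(stats, config = game_config(), grid_resolution = 201,
                     tolerance = 1e-8) {
  stopifnot(inherits(stats, "network_stats"), grid_resolution >= 2)
  states <- list()
  for (v_edge in c(0, 1)) {
    dbf <- function(b) mutant_gradient(stats, b, v_edge, config)[["db"]]
    curv <- mutant_curvature_b(stats, v_edge, config)
    bs <- seq(0, 1, length.out = grid_resolution)
    dbs <- vapply(bs, dbf, numeric(1))
    cand <- numeric(0)
    # interior stationary points of the mutant payoff in b_m
    sign_change <- which(dbs[-1] * dbs[-length(dbs)] < 0)
    for (ix in sign_change) {
      root <- stats::uniroot(dbf, c(bs[ix], bs[ix + 1]),
                             tol = tolerance)$root
      if (curv < -tolerance) cand <- c(cand, root) # strict local max
    }
    # grid points where the gradient vanishes identically
    flat <- which(abs(dbs) <= tolerance)
    if (length(flat) && curv < -tolerance) {
      cand <- c(cand, bs[flat])
    }
    # boundary candidates: gradient must not point into the interior
    if (dbf(1) >= -tolerance &&
        (dbf(1) > tolerance || curv < -tolerance)) {
      cand <- c(cand, 1)
    }
    if (dbf(0) <= tolerance &&
        (dbf(0) < -tolerance || curv < -tolerance)) {
      cand <- c(cand, 0)
    }
    cand <- unique(round(cand, 10))
    for (b_star in cand) {
      g <- mutant_gradient(stats, b_star, v_edge, config)
      # strict stability in v_m: the linear slope must push against
      # the occupied boundary
      v_ok <- if (v_edge == 1) g[["dv"]] > tolerance else
        g[["dv"]] < -tolerance
      if (!v_ok) next
      states[[length(states) + 1]] <- data.frame(
        boldness = b_star, vengefulness = v_edge,
        db = g[["db"]], dv = g[["dv"]],
        curvature_b = mutant_curvature_b(stats, v_edge, config))
    }
  }
  out <- if (length(states)) do.call(rbind, states) else
    data.frame(boldness = numeric(0), vengefulness = numeric(0),
               db = numeric(0), dv = numeric(0), curvature_b = numeric(0))
  out$label <- ifelse(out$boldness >= 6 / 7 & out$vengefulness <= 1 / 7,
                      "collapse",
                      ifelse(out$boldness <= 0.5 & out$vengefulness >= 0.5,
                             "cooperative", "other"))
  out <- out[order(out$boldness), c("boldness", "vengefulness", "label",
                                    "db", "dv", "curvature_b")]
  rownames(out) <- NULL
  class(out) <- c("ess_result", "data.frame")
  out
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf("Evolutionary stable states found: %d\n", nrow(x)))
  if (nrow(x)) {
    print.data.frame(cbind(x[, 1:3],
                           round(x[, c("db", "dv")], 6)), row.names = FALSE)
  }
  invisible(x)
}

has_cooperative_ess <- function(stats, config, ...) {
  ess <- find_ess(stats, config, ...)
  any(ess$label == "cooperative")
}

#' Minimal interconnectedness for a cooperative ESS
#'
#' For a hypothetical homogeneous-statistics network with the given
#' average degree, finds by bisection the smallest interconnectedness
#' (mean triplets per agent) at which [find_ess()] reports a cooperative
#' ESS. Sparse or weakly clustered networks fall below the threshold:
#' without enough triangles the meta-punishment channel is too weak to
#' keep vigilance profitable.
#'
#' @param avg_degree Average degree of the hypothetical network.
#' @param config A [game_config()].
#' @param n Agent count of the hypothetical network.
#' @param tol Absolute bisection tolerance on the threshold.
#' @param lambda_max Upper search bound; `Inf` is returned (with a
#'   warning) if no cooperative ESS exists even there.
#' @return The threshold `Lambda*` (scalar; `Inf` if unattainable).
#' @export
minimal_interconnectedness <- function(avg_degree, config = game_config(),
                                       n = config$n_agents, tol = 1e-4,
                                       lambda_max = NULL) {
  stopifnot(avg_degree >= 0)
  exists_at <- function(lam) {
    has_cooperative_ess(homogeneous_stats(n, avg_degree, lam), config)
  }
  if (exists_at(0)) return(0)
  hi <- if (is.null(lambda_max)) max(1, avg_degree^2) else lambda_max
  tries <- 0
  while (!exists_at(hi)) {
    hi <- hi * 2
    tries <- tries + 1
    if (tries > 30) {
      warning("no cooperative ESS up to the search bound; returning Inf")
      return(Inf)
    }
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (exists_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Analytic gradient map over the strategy square
#'
#' Evaluates [mutant_gradient()] on a regular grid over `[0, 1]^2`,
#' yielding the drift direction and speed of the predicted population
#' movement at every (mean boldness, mean vengefulness) state.
#'
#' @inheritParams expected_payoff_homogeneous
#' @param resolution Grid points per axis (>= 2).
#' @return An object of class `"gradient_field"`: data frame with columns
#'   `b`, `v`, `db`, `dv`, `speed`; the statistics and payoffs used are
#'   attached as attributes.
#' @export
gradient_map <- function(stats, config = game_config(), resolution = 71) {
  stopifnot(inherits(stats, "network_stats"), resolution >= 2)
  grid <- expand.grid(b = seq(0, 1, length.out = resolution),
                      v = seq(0, 1, length.out = resolution),
                      KEEP.OUT.ATTRS = FALSE)
  g <- mapply(function(b, v) mutant_gradient(stats, b, v, config),
              grid$b, grid$v)
  out <- data.frame(b = grid$b, v = grid$v, db = g["db", ], dv = g["dv", ],
                    speed = sqrt(g["db", ]^2 + g["dv", ]^2))
  attr(out, "network_stats") <- stats
  attr(out, "payoffs") <- payoff_vector(config)
  class(out) <- c("gradient_field", "data.frame")
  out
}
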