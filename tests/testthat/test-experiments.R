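test_that("zone classification is pure, inclusive and exhaustive", {
  cls <- classify_state(c(1, 0, 0.5, 6 / 7, 1 / 7), c(0, 1, 0.5, 1 / 7, 6 / 7))
  expect_equal(as.character(cls),
               c("collapse", "establishment", "neither", "collapse",
                 "establishment"))
  # just inside the open region
  expect_equal(as.character(classify_state(6 / 7 - 1e-9, 0)), "neither")
  expect_error(zone_spec(collapse_min_b = 0.1, collapse_max_v = 0.9),
               "disjoint")
})

test_that("occupancy fractions are exact zone frequencies summing to one", {
  pinned <- data.frame(generation = 0:99, mean_boldness = 1,
                       mean_vengefulness = 0)
  occ <- occupancy(pinned)
  expect_equal(c(occ$collapse, occ$establishment, occ$neither), c(1, 0, 0))

  alt <- data.frame(generation = 0:99,
                    mean_boldness = rep(c(1, 0), 50),
                    mean_vengefulness = rep(c(0, 1), 50))
  occ <- occupancy(alt)
  expect_equal(occ$collapse, 0.5)
  expect_equal(occ$establishment, 0.5)
  expect_equal(occ$collapse + occ$establishment + occ$neither, 1)

  expect_error(occupancy(alt[0, ]), "nonempty")
  # burn-in drops early generations
  mixed <- data.frame(generation = 0:9,
                      mean_boldness = c(rep(0.5, 5), rep(1, 5)),
                      mean_vengefulness = c(rep(0.5, 5), rep(0, 5)))
  expect_equal(occupancy(mixed, burn_in = 5)$collapse, 1)
  expect_error(occupancy(mixed, burn_in = 50), "burn-in")
})

test_that("occupancy of replicate runs agrees across seeds within tolerance", {
  net <- generate_watts(50, 4, 0.2, seed = 3)
  cfg <- game_config(generations = 1500)
  fracs <- vapply(1:6, function(s) {
    cfg$seed <- 1000 + s
    occupancy(run_simulation(net, cfg))$collapse
  }, numeric(1))
  # collapse-dominated topology: all replicates find the same regime
  expect_true(all(fracs > 0.5))
  expect_lt(stats::sd(fracs), 0.2)
})

test_that("sweeps are shaped, reproducible and topology-sensitive", {
  net <- generate_watts(50, 4, 0.2, seed = 3)
  cfg <- game_config(generations = 300, seed = 77)
  sw <- sweep_occupancy(list(net), cfg, seeds_per_net = 4)
  expect_equal(nrow(sw), 4)
  expect_equal(sw$net_id, rep(1, 4))
  expect_equal(sw$collapse + sw$establishment + sw$neither, rep(1, 4))
  # bit-for-bit reproducibility under the same master seed
  sw2 <- sweep_occupancy(list(net), cfg, seeds_per_net = 4)
  expect_identical(sw, sw2)

  # trees cannot sustain the norm: matched triangle-rich ensemble earns
  # strictly more establishment time
  trees <- lapply(1:3, function(s) generate_ba(50, 1, seed = s))
  rich <- lapply(1:3, function(s) {
    radius2_closure(generate_ba(50, 3, seed = s))
  })
  cfg <- game_config(generations = 1500, seed = 42)
  sw_tree <- sweep_occupancy(trees, cfg, seeds_per_net = 1)
  sw_rich <- sweep_occupancy(rich, cfg, seeds_per_net = 1)
  expect_lt(mean(sw_tree$establishment), 0.01)
  expect_gt(mean(sw_rich$establishment), mean(sw_tree$establishment))
})

test_that("binning and trend statistics summarize sweeps correctly", {
  # synthetic sweep table with a known structure: establishment grows
  # with interconnectedness and falls with degree
  set.seed(12)
  df <- expand.grid(avg_degree = seq(4, 20, by = 2),
                    interconnectedness = seq(2, 50, by = 4))
  df$sqrt_interconnectedness <- sqrt(df$interconnectedness)
  df$establishment <- with(df, pmin(1, pmax(0,
    0.02 * interconnectedness - 0.01 * avg_degree + rnorm(nrow(df), 0, 0.01))))
  df$collapse <- pmax(0, 1 - df$establishment)
  df$neither <- 1 - df$collapse - df$establishment

  expect_gt(occupancy_trend(df), 0.8)
  expect_lt(occupancy_trend(df, vs = "avg_degree",
                            within = "interconnectedness"), 0)
  binned <- occupancy_trend(df, n_bins = 4)
  expect_gt(binned, 0.8)
  expect_equal(sum(attr(binned, "per_bin")[, "n"]), nrow(df))

  b2 <- bin_occupancy(df, bins = 4)
  expect_true(all(c("x_bin", "y_bin", "establishment", "n_runs") %in%
                    names(b2)))
  expect_equal(sum(b2$n_runs), nrow(df))
})

test_that("empirical drift maps detect selection pressure and its absence", {
  net <- generate_er(20, 1)
  # no payoffs, no mutation: copying identical strategies moves nothing
  null_cfg <- game_config(temptation = 0, hurt = 0, enforcement = 0,
                          punishment = 0, meta_enforcement = 0,
                          meta_punishment = 0, mutation_rate = 0, seed = 5)
  dm <- empirical_drift_map(net, null_cfg, resolution = 3, reps = 5,
                            horizon = 1)
  expect_equal(nrow(dm), 9)
  expect_true(all(dm$speed == 0))

  # triangle-free network at the collapse corner: no selection signal
  cyc <- generate_watts(20, 2, 0)
  cfg0 <- game_config(mutation_rate = 0, seed = 6)
  dm2 <- empirical_drift_map(cyc, cfg0, resolution = 2, reps = 10,
                             horizon = 1)
  corner <- dm2[dm2$b == 1 & dm2$v == 0, ]
  expect_equal(corner$speed, 0)

  # strong punishment on the complete graph drives boldness down at a
  # bold, vigilant state
  cfg <- game_config(seed = 7)
  dm3 <- empirical_drift_map(net, cfg, resolution = 8, reps = 60,
                             horizon = 1)
  cell <- dm3[abs(dm3$b - 6 / 7) < 0.01 & abs(dm3$v - 6 / 7) < 0.01, ]
  expect_lt(cell$db, 0)
})

test_that("empirical drift directions correlate with the analytic field", {
  # selection needs heterogeneity: over one generation from a homogeneous
  # start only mutation moves the means, so the map is measured over a
  # few generations and the mutation-only drift (payoff-free control with
  # the same seed and replication layout) is subtracted out
  net <- generate_er(20, 1)
  cfg <- game_config(seed = 11)
  dm <- empirical_drift_map(net, cfg, resolution = 4, reps = 80,
                            horizon = 3)
  ctrl_cfg <- game_config(temptation = 0, hurt = 0, enforcement = 0,
                          punishment = 0, meta_enforcement = 0,
                          meta_punishment = 0, seed = 11)
  ctrl <- empirical_drift_map(net, ctrl_cfg, resolution = 4, reps = 80,
                              horizon = 3)
  sel_db <- dm$db - ctrl$db
  sel_dv <- dm$dv - ctrl$dv
  ns <- network_stats(net)
  cos_sim <- mapply(function(b, v, db, dv) {
    g <- mutant_gradient(ns, b, v, cfg)
    na <- sqrt(g[["db"]]^2 + g[["dv"]]^2)
    ne <- sqrt(db^2 + dv^2)
    if (na < 1e-9 || ne < 1e-4) return(NA_real_)
    (g[["db"]] * db + g[["dv"]] * dv) / (na * ne)
  }, dm$b, dm$v, sel_db, sel_dv)
  expect_gt(mean(cos_sim, na.rm = TRUE), 0.3)
})
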