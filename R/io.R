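# File formats, run manifests and the command-line dispatcher.

#' Read an interaction network from a file
#'
#' Supports plain edge lists (one whitespace-separated pair of integer
#' agent ids per line, `#` comments allowed; 0-based ids by default) and
#' GraphML. Self-loops are rejected with the offending line number;
#' duplicate edges are collapsed with a warning.
#'
#' @param path File to read.
#' @param format `"edgelist"`, `"graphml"`, or `"auto"` (by extension;
#'   anything not ending in `.graphml`/`.xml` is treated as an edge list).
#' @param zero_based For edge lists: whether ids in the file are 0-based
#'   (default) or 1-based.
#' @param n Optional total agent count (to preserve trailing isolated
#'   agents that no edge mentions).
#' @return An undirected simple igraph object.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml"),
                         zero_based = TRUE, n = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE)) {
      "graphml"
    } else "edgelist"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    return(validate_network(igraph::simplify(g, remove.loops = FALSE)))
  }
  lines <- readLines(path)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(nzchar(stripped))
  if (!length(keep)) stop("no edges in ", path, call. = FALSE)
  pairs <- matrix(NA_integer_, nrow = length(keep), ncol = 2)
  for (r in seq_along(keep)) {
    tok <- strsplit(stripped[keep[r]], "[[:space:],]+")[[1]]
    ids <- suppressWarnings(as.integer(tok))
    if (length(ids) != 2 || anyNA(ids)) {
      stop(sprintf("malformed edge on line %d of %s: '%s'", keep[r], path,
                   lines[keep[r]]), call. = FALSE)
    }
    if (ids[1] == ids[2]) {
      stop(sprintf("self-loop on line %d of %s: '%s'", keep[r], path,
                   lines[keep[r]]), call. = FALSE)
    }
    pairs[r, ] <- ids
  }
  if (zero_based) pairs <- pairs + 1L
  if (any(pairs < 1)) {
    stop("negative agent id; is the file 1-based? (set zero_based = FALSE)",
         call. = FALSE)
  }
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (anyDuplicated(key)) {
    warning("duplicate edges collapsed in ", path)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  nv <- max(pairs, if (is.null(n)) 0L else n)
  new_network(nv, as.integer(t(pairs)), "file", list(path = path))
}

#' Write an interaction network to a file
#'
#' @param net An undirected simple igraph object.
#' @param path Output file.
#' @param format As in [read_network()].
#' @param zero_based Write 0-based ids in edge lists (default).
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path,
                          format = c("auto", "edgelist", "graphml"),
                          zero_based = TRUE) {
  validate_network(net)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE)) {
      "graphml"
    } else "edgelist"
  }
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = FALSE)
    if (zero_based) el <- el - 1L
    writeLines(paste(el[, 1], el[, 2]), path)
  }
  invisible(path)
}

#' Write tabular results to CSV or JSON
#'
#' Deterministic column order; numeric columns are rounded to a fixed
#' number of significant digits (default 10) before writing.
#'
#' @param rows Data frame (or coercible list) of results.
#' @param path Output file.
#' @param format `"csv"`, `"json"` or `"auto"` (by extension).
#' @param digits Significant digits for numeric columns.
#' @return Invisibly, `path`.
#' @export
write_results <- function(rows, path, format = c("auto", "csv", "json"),
                          digits = 10) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else
      "csv"
  }
  df <- as.data.frame(rows)
  if (!nrow(df)) stop("refusing to write empty results", call. = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an experiment bit-identically:
#' resolved configuration, seeds, package version, timestamp and the list
#' of output files.
#'
#' @param path Manifest path (JSON).
#' @param config A [game_config()] (or any list).
#' @param outputs Character vector of produced files.
#' @param extra Optional named list of additional fields (e.g. generator
#'   parameters).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, config, outputs = character(),
                           extra = list()) {
  manifest <- c(list(
    package = "metanorms",
    version = as.character(utils::packageVersion("metanorms")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    outputs = outputs), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# --- command-line interface ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: metanorms <command> [--flag value ...]",
    "",
    "commands:",
    "  generate  --model ba|watts|er --n N [--m M|--k K --beta B|--p P]",
    "            [--radius 1|2] [--seed S] --out net.graphml",
    "  stats     --net FILE [--out stats.json]",
    "  simulate  --net FILE [--generations G] [--rounds R] [--mutation MU]",
    "            [--seed S] [--config FILE.json] --out traj.csv",
    "  occupancy --net FILE [--generations G] [--seed S] [--burn-in B]",
    "            [--out occ.json]",
    "  sweep     --networks N [--seeds-per-net K] [--generations G]",
    "            [--seed S] --out sweep.csv",
    "  analyze   --net FILE [--resolution R] --out gradient.csv",
    "  ess       --net FILE",
    "  threshold --kavg-range A:B:STEP --out curve.csv",
    "  driftmap  --net FILE [--grid R] [--reps N] [--horizon H] [--seed S]",
    "            --out drift.csv",
    "",
    "Game payoffs default to T=3 H=-1 E=-2 P=-9 ME=-2 MP=-9; override with",
    "--payoffs T=3,H=-1,... . Flags override values from --config.",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  flags
}

flag_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) return(default)
  as.numeric(flags[[key]])
}

cli_config <- function(flags) {
  base <- list()
  if (!is.null(flags$config)) {
    base <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
  }
  cfg <- game_config()
  for (nm in intersect(names(base), names(cfg))) cfg[[nm]] <- base[[nm]]
  if (!is.null(flags$payoffs)) {
    kv <- strsplit(strsplit(flags$payoffs, ",")[[1]], "=")
    full <- c(T = "temptation", H = "hurt", E = "enforcement",
              P = "punishment", ME = "meta_enforcement",
              MP = "meta_punishment")
    for (p in kv) {
      nm <- full[[toupper(p[1])]]
      if (is.null(nm)) stop("unknown payoff: ", p[1], call. = FALSE)
      cfg[[nm]] <- as.numeric(p[2])
    }
  }
  if (!is.null(flags$generations)) {
    cfg$generations <- as.integer(flag_num(flags, "generations"))
  }
  if (!is.null(flags$rounds)) {
    cfg$rounds_per_generation <- as.integer(flag_num(flags, "rounds"))
  }
  if (!is.null(flags$mutation)) {
    cfg$mutation_rate <- flag_num(flags, "mutation")
  }
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flag_num(flags, "seed"))
  cfg
}

cli_generate <- function(flags) {
  model <- flags$model
  n <- as.integer(flag_num(flags, "n", 50))
  seed <- if (is.null(flags$seed)) NULL else
    as.integer(flag_num(flags, "seed"))
  g <- switch(model,
    ba = generate_ba(n, as.integer(flag_num(flags, "m", 2)), seed),
    watts = generate_watts(n, as.integer(flag_num(flags, "k", 4)),
                           flag_num(flags, "beta", 0), seed),
    er = generate_er(n, flag_num(flags, "p", 0.1), seed),
    stop("unknown model: ", model, call. = FALSE))
  if (identical(flag_num(flags, "radius", 1), 2)) g <- radius2_closure(g)
  write_network(g, flags$out)
  write_manifest(paste0(flags$out, ".manifest.json"),
                 list(command = "generate", model = model, n = n,
                      seed = seed, flags = flags),
                 outputs = flags$out)
  0L
}

cli_stats <- function(flags) {
  ns <- network_stats(read_network(flags$net))
  out <- list(n = ns$n, avg_degree = ns$avg_degree,
              interconnectedness = ns$interconnectedness,
              mean_clustering = ns$mean_clustering,
              degree_dist = as.list(ns$degree_dist),
              clustering_by_degree = as.list(ns$clustering_by_degree))
  if (is.null(flags$out)) {
    cat(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA),
        "\n")
  } else {
    jsonlite::write_json(out, flags$out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  0L
}

cli_simulate <- function(flags) {
  net <- read_network(flags$net)
  cfg <- cli_config(flags)
  stride <- as.integer(flag_num(flags, "snapshots", 0))
  traj <- run_simulation(net, cfg, snapshot_stride = stride)
  write_results(as.data.frame(traj), flags$out)
  write_manifest(paste0(flags$out, ".manifest.json"), cfg,
                 outputs = flags$out,
                 extra = list(command = "simulate", net = flags$net))
  0L
}

cli_occupancy <- function(flags) {
  net <- read_network(flags$net)
  cfg <- cli_config(flags)
  occ <- occupancy(run_simulation(net, cfg),
                   burn_in = flag_num(flags, "burn-in", 0))
  out <- list(collapse = occ$collapse, establishment = occ$establishment,
              neither = occ$neither, generations = occ$generations)
  if (is.null(flags$out)) {
    cat(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA),
        "\n")
  } else {
    jsonlite::write_json(out, flags$out, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    write_manifest(paste0(flags$out, ".manifest.json"), cfg,
                   outputs = flags$out,
                   extra = list(command = "occupancy", net = flags$net))
  }
  0L
}

cli_sweep <- function(flags) {
  cfg <- cli_config(flags)
  nets <- sample_network_ensemble(as.integer(flag_num(flags, "networks", 10)),
                                  n = cfg$n_agents, seed = cfg$seed)
  df <- sweep_occupancy(nets, cfg,
                        seeds_per_net =
                          as.integer(flag_num(flags, "seeds-per-net", 3)))
  write_results(df, flags$out)
  write_manifest(paste0(flags$out, ".manifest.json"), cfg,
                 outputs = flags$out, extra = list(command = "sweep"))
  0L
}

cli_analyze <- function(flags) {
  ns <- network_stats(read_network(flags$net))
  cfg <- cli_config(flags)
  gm <- gradient_map(ns, cfg,
                     resolution = as.integer(flag_num(flags, "resolution",
                                                      71)))
  write_results(gm, flags$out)
  0L
}

cli_ess <- function(flags) {
  ns <- network_stats(read_network(flags$net))
  ess <- find_ess(ns, cli_config(flags))
  if (is.null(flags$out)) print(ess) else write_results(ess, flags$out)
  0L
}

cli_threshold <- function(flags) {
  rng <- as.numeric(strsplit(flags[["kavg-range"]], ":")[[1]])
  if (length(rng) != 3) {
    stop("--kavg-range must be A:B:STEP", call. = FALSE)
  }
  cfg <- cli_config(flags)
  kavg <- seq(rng[1], rng[2], by = rng[3])
  lam <- vapply(kavg, minimal_interconnectedness, numeric(1), config = cfg)
  write_results(data.frame(avg_degree = kavg, lambda_star = lam),
                flags$out)
  0L
}

cli_driftmap <- function(flags) {
  net <- read_network(flags$net)
  cfg <- cli_config(flags)
  dm <- empirical_drift_map(net, cfg,
                            resolution = as.integer(flag_num(flags, "grid",
                                                             8)),
                            reps = as.integer(flag_num(flags, "reps", 200)),
                            horizon = as.integer(flag_num(flags, "horizon",
                                                          1)))
  write_results(dm, flags$out)
  0L
}

#' Command-line dispatcher
#'
#' Entry point behind the `inst/exec/metanorms` script. Dispatches the
#' subcommands `generate`, `stats`, `simulate`, `occupancy`, `sweep`,
#' `analyze`, `ess`, `threshold` and `driftmap` with configuration merged
#' as defaults < `--config` file < flags, and writes a run manifest next
#' to each output file.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success).
#' @export
metanorms_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  handler <- switch(cmd,
    generate = cli_generate, stats = cli_stats, simulate = cli_simulate,
    occupancy = cli_occupancy, sweep = cli_sweep, analyze = cli_analyze,
    ess = cli_ess, threshold = cli_threshold, driftmap = cli_driftmap,
    NULL)
  if (is.null(handler)) {
    message("unknown command: ", cmd, "\n", cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    flags <- parse_flags(args[-1])
    needs_net <- cmd %in% c("stats", "simulate", "occupancy", "analyze",
                            "ess", "driftmap")
    if (needs_net && is.null(flags$net)) {
      stop("missing required --net", call. = FALSE)
    }
    needs_out <- cmd %in% c("generate", "simulate", "sweep", "analyze",
                            "threshold", "driftmap")
    if (needs_out && is.null(flags$out)) {
      stop("missing required --out", call. = FALSE)
    }
    handler(flags)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
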