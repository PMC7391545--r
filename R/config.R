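#' Defaults shared by the run-configuration layer
#'
#' The defaults are the protocol's own values: a 15-generation sib-mating
#' horizon, 3 replicate patches per line, a 450-line panel, 220 females per
#' experimental-evolution transfer, 200 crosses per type in the outbred
#' designs.
#' @keywords internal
.hb_defaults <- list(
  inbreeding = list(generations = 15L, mode = "exact",
                    initial = c(A = 1, B = 0, C = 0, D = 0)),
  genedrop = list(n_lines = 10000L, generations = 15L, n_loci = 1L),
  panel = list(n_lines = 450L, generations = 15L, replicates_per_line = 3L,
               failure_prob = NULL),
  design = list(kind = "matched-pairs-4", populations = c("A", "B", "C", "D"),
                crosses_per_type = 200L, census_rule = "minimum",
                available = NULL),
  evolve = list(target = 220L, history = NULL, label = NULL)
)

#' Load and validate a run configuration
#'
#' Configurations are flat YAML files with a `subcommand` key, an optional
#' `seed` and `out` directory, and one nested block named after the
#' subcommand holding its parameters. Unknown keys are rejected so typos
#' fail loudly; omitted parameters take the documented defaults.
#'
#' ```yaml
#' subcommand: inbreeding
#' seed: 1
#' inbreeding:
#'   generations: 15
#'   mode: exact
#' ```
#'
#' @param path Path to a YAML configuration file.
#' @return A list of class `"run_config"` with elements `subcommand`,
#'   `seed`, `out` and `params` (the defaults overlaid with the file's
#'   block).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  run_config_from_list(raw)
}

#' Build a run configuration from a list
#'
#' Programmatic equivalent of [load_config()]; validates the same contract.
#'
#' @param raw Named list as produced by parsing a config file.
#' @return A `"run_config"` object.
#' @export
run_config_from_list <- function(raw) {
  if (is.null(raw$subcommand) ||
      !raw$subcommand %in% names(.hb_defaults)) {
    stop("config must name a subcommand, one of: ",
         paste(names(.hb_defaults), collapse = ", "))
  }
  sub <- raw$subcommand
  allowed_top <- c("subcommand", "seed", "out", sub)
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  params <- .hb_defaults[[sub]]
  block <- raw[[sub]]
  if (!is.null(block)) {
    bad <- setdiff(names(block), names(params))
    if (length(bad)) {
      stop("unknown key(s) in '", sub, "' block: ", paste(bad, collapse = ", "))
    }
    params[names(block)] <- block
  }
  cfg <- structure(list(subcommand = sub,
                        seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                        out = if (is.null(raw$out)) "." else raw$out,
                        params = params),
                   class = "run_config")
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  p <- cfg$params
  err <- function(key, msg) stop("config ", cfg$subcommand, "/", key, ": ", msg)
  chk_pos <- function(key) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      err(key, "must be a positive integer")
    }
  }
  switch(cfg$subcommand,
    inbreeding = {
      chk_pos("generations")
      if (!p$mode %in% c("exact", "floating")) err("mode", "must be exact or floating")
    },
    genedrop = {
      chk_pos("n_lines"); chk_pos("generations"); chk_pos("n_loci")
    },
    panel = {
      chk_pos("n_lines"); chk_pos("generations"); chk_pos("replicates_per_line")
      if (is.null(p$failure_prob)) err("failure_prob", "is required")
      if (p$failure_prob < 0 || p$failure_prob > 1) {
        err("failure_prob", "must be in [0, 1]")
      }
    },
    design = {
      chk_pos("crosses_per_type")
      if (!p$kind %in% c("matched-pairs-4", "round-robin-3")) {
        err("kind", "must be matched-pairs-4 or round-robin-3")
      }
      if (!p$census_rule %in% c("minimum", "as-available")) {
        err("census_rule", "must be minimum or as-available")
      }
    },
    evolve = {
      chk_pos("target")
      if (is.null(p$history)) err("history", "is required (path to availability TSV)")
    })
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run config:", x$subcommand, "(seed", x$seed, "-> ", x$out, ")\n")
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

#' Execute a run configuration
#'
#' Dispatches to exactly one module pipeline, writes its TSV/JSON artifacts
#' into the output directory and returns (and writes) a run report listing
#' every file produced, the configuration echo, package version and a
#' timestamp. Data artifacts are deterministic: the same configuration and
#' seed produce byte-identical files (the report's timestamp is the one
#' intentionally non-reproducible field, which is why it lives in the report
#' and not in any artifact).
#'
#' @param cfg A [load_config()] result.
#' @return Invisibly, the run report (also written to `report.json` in the
#'   output directory).
#' @export
dispatch_run <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("expected a 'run_config' object")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$params
  art <- function(name) file.path(cfg$out, name)
  files <- character(0)
  summary <- list()
  if (cfg$subcommand == "inbreeding") {
    init <- cross_type_distribution(p$initial[["A"]], p$initial[["B"]],
                                    p$initial[["C"]], p$initial[["D"]],
                                    mode = p$mode)
    tr <- inbreeding_trajectory(p$generations, init)
    write_trajectory(tr, art("inbreeding_trajectory.tsv"), "tsv")
    write_trajectory(tr, art("inbreeding_trajectory.json"), "json")
    files <- c("inbreeding_trajectory.tsv", "inbreeding_trajectory.json")
    last <- tr[nrow(tr), ]
    summary <- list(f_final = last$f, p_fully_inbred_final = last$p_fully_inbred,
                    f_percent = round(100 * last$f, 1),
                    p_percent = round(100 * last$p_fully_inbred, 1))
  } else if (cfg$subcommand == "genedrop") {
    mc <- estimate_inbreeding_mc(p$n_lines, p$generations, p$n_loci,
                                 seed = cfg$seed)
    write_tsv_artifact(as.data.frame(mc), art("genedrop_estimates.tsv"))
    files <- "genedrop_estimates.tsv"
    last <- mc[nrow(mc), ]
    summary <- list(f_hat_final = last$f_hat, f_se_final = last$f_se,
                    n_lines = p$n_lines)
  } else if (cfg$subcommand == "panel") {
    panel <- simulate_line_panel(p$n_lines, p$generations,
                                 p$replicates_per_line, p$failure_prob,
                                 seed = cfg$seed)
    write_panel_trajectory(panel, art("panel_trajectory.tsv"), "tsv")
    write_panel_trajectory(panel, art("panel_summary.json"), "json")
    files <- c("panel_trajectory.tsv", "panel_summary.json")
    summary <- list(surviving_lines = panel$survivors[length(panel$survivors)])
  } else if (cfg$subcommand == "design") {
    design <- crossing_design(p$kind, p$populations, p$crosses_per_type)
    combos <- enumerate_combinations(design)
    sched <- build_schedule(design)
    stopifnot(isTRUE(validate_schedule(sched)))
    write_schedule(sched, art("schedule.tsv"), "tsv")
    write_schedule(sched, art("schedule.json"), "json")
    combo_df <- data.frame(combination = as.character(combos),
                           mito_origin = attr(combos, "mito_origin"))
    write_tsv_artifact(combo_df, art("combinations.tsv"))
    files <- c("schedule.tsv", "schedule.json", "combinations.tsv")
    summary <- list(n_combinations = length(combos),
                    mito_balanced = mito_representation(combos)$balanced)
    if (!is.null(p$available)) {
      avail <- unlist(p$available)
      cens <- founding_census(avail, p$census_rule)
      write_tsv_artifact(
        data.frame(combination = names(cens$per_combination),
                   count = as.integer(cens$per_combination)),
        art("founding_census.tsv"))
      files <- c(files, "founding_census.tsv")
      summary$census_total <- cens$total
    }
  } else if (cfg$subcommand == "evolve") {
    history <- read_tsv_artifact(p$history)
    reg <- track_regime(history, p$target, p$label)
    write_regime_log(reg, art("regime_log.tsv"))
    files <- "regime_log.tsv"
    summary <- list(
      effective_generations_final =
        reg$effective_generations[nrow(reg)])
  }
  report <- list(config = list(subcommand = cfg$subcommand, seed = cfg$seed,
                               out = cfg$out, params = p),
                 version = as.character(utils::packageVersion("hapbreed")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 files = as.list(files),
                 summary = summary,
                 warnings = list())
  jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}

#' Command-line entry point
#'
#' Thin wrapper used by the installed `exec/hapbreed.R` script:
#' `Rscript exec/hapbreed.R --config FILE [--seed N] [--out DIR]`. Flags
#' override the corresponding config keys.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the run report.
#' @export
hapbreed_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  take <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  path <- take("--config")
  if (is.null(path)) {
    stop("usage: hapbreed --config FILE [--seed N] [--out DIR]")
  }
  cfg <- load_config(path)
  seed <- take("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- take("--out")
  if (!is.null(out)) cfg$out <- out
  dispatch_run(cfg)
}
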