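#' Load a configuration file
#'
#' Reads a YAML configuration, applies defaults for unset fields, rejects
#' unknown keys and validates numeric ranges. An empty file yields the
#' full default configuration. `tbid_start: .inf` (or `~`) keeps the tBid
#' stimulus off.
#'
#' @param path path to a YAML file.
#' @return a validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must be a YAML mapping")
  # YAML 1.1 resolves a bare `n` key as a boolean; map it back
  names(vals)[names(vals) == "FALSE"] <- "n"
  vals <- lapply(vals, function(v) {
    if (is.character(v) && v %in% c(".inf", "inf", "Inf")) Inf
    else if (is.null(v)) Inf
    else v
  })
  do.call(sim_config, vals)
}

#' Write a configuration file
#'
#' Serializes a resolved configuration to YAML; [load_config()] of the
#' result round-trips to an identical configuration.
#'
#' @param cfg a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(config_canonical_yaml(cfg), path)
  invisible(path)
}

#' Write run or ensemble results to a directory
#'
#' Writes `timeseries.csv` (population time series), `agents.csv`
#' (per-agent, per-step phase/phenotype/potentials in long format),
#' `census.json`, `config_resolved.yaml` and `manifest.json` (seed,
#' config hash, package version). For ensembles, writes `stats.csv`
#' (per-run statistics) and `summary.csv` instead of the per-agent log.
#'
#' @param result a `mito_run` or `mito_ensemble`.
#' @param out output directory (created if missing).
#' @return the manifest list, invisibly.
#' @export
write_results <- function(result, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("cannot create output directory: ", out)
  manifest <- list(package = "mitofate",
                   version = as.character(utils::packageVersion("mitofate")),
                   seed = result$config$seed,
                   config_hash = config_hash(result$config))
  write_config(result$config, file.path(out, "config_resolved.yaml"))
  if (inherits(result, "mito_run")) {
    utils::write.csv(result$timeseries, file.path(out, "timeseries.csv"),
                     row.names = FALSE)
    n <- result$config$n
    used <- result$steps_run
    agents <- data.frame(
      step = rep(seq_len(used), times = n),
      agent = rep(seq_len(n), each = used),
      phase = as.vector(result$agents$phase),
      phenotype = as.vector(result$agents$phenotype),
      mitophagy = as.vector(result$agents$mitophagy),
      apoptosis = as.vector(result$agents$apoptosis))
    utils::write.csv(agents, file.path(out, "agents.csv"),
                     row.names = FALSE)
    seeds <- data.frame(agent = seq_len(n), position = result$seeds$pos0,
                        bax0 = result$seeds$bax0,
                        bcl20 = result$seeds$bcl20)
    utils::write.csv(seeds, file.path(out, "population_seeds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(result$census),
                         file.path(out, "census.json"), auto_unbox = TRUE)
  } else if (inherits(result, "mito_ensemble")) {
    utils::write.csv(as.data.frame(result$stats),
                     file.path(out, "stats.csv"), row.names = FALSE)
    utils::write.csv(result$summary, file.path(out, "summary.csv"),
                     row.names = FALSE)
  } else {
    stop("result must be a mito_run or mito_ensemble")
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a written run back
#'
#' Re-reads the tabular outputs of [write_results()] for a single run.
#'
#' @param out the directory written by [write_results()].
#' @return list with `timeseries`, `agents`, `census`, `config`.
#' @export
read_results <- function(out) {
  list(timeseries = utils::read.csv(file.path(out, "timeseries.csv")),
       agents = utils::read.csv(file.path(out, "agents.csv")),
       census = jsonlite::read_json(file.path(out, "census.json"),
                                    simplifyVector = TRUE),
       config = load_config(file.path(out, "config_resolved.yaml")))
}

#' Render a snapshot of the simulation world
#'
#' Draws four panels at the final recorded step of a run: mitophagy-
#' phenotype agents (blue), apoptosis-phenotype agents (red), the released
#' cytochrome c layer (green ramp) and a merged panel, mirroring the
#' simulation snapshot figures. Colors are fixed; output is a PNG.
#'
#' @param result a `mito_run`.
#' @param world optional world environment for the layer state; when
#'   absent only agent channels are drawn from the trajectory log.
#' @param out output PNG path.
#' @param step step to render (defaults to the last recorded step).
#' @return `out`, invisibly.
#' @export
render_snapshot <- function(result, out, world = NULL, step = NULL) {
  if (result$steps_run == 0) stop("no recorded steps to render")
  if (is.null(step)) step <- result$steps_run
  if (step < 1 || step > result$steps_run)
    stop("no snapshot data for step ", step)
  phen <- result$agents$phenotype[step, ]
  pos <- result$seeds$pos0  # positions at seeding; live layout if world given
  if (!is.null(world)) pos <- world$pos
  row <- (pos - 1L) %% GRID_N + 1L
  col <- (pos - 1L) %/% GRID_N + 1L
  cytc <- if (!is.null(world)) world$layers$cytc else matrix(0, GRID_N, GRID_N)
  grDevices::png(out, width = 1200, height = 320)
  op <- graphics::par(mfrow = c(1, 4), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  panel <- function(keep, colr, title) {
    graphics::plot(NA, xlim = c(0.5, GRID_N + 0.5),
                   ylim = c(0.5, GRID_N + 0.5), axes = FALSE, asp = 1,
                   xlab = "", ylab = "", main = title)
    graphics::rect(0.5, 0.5, GRID_N + 0.5, GRID_N + 0.5)
    graphics::points(col[keep], row[keep], pch = 15, col = colr, cex = 1.4)
  }
  panel(phen == PHEN_MITOPHAGY, "blue3", "mitophagy")
  panel(phen == PHEN_APOPTOSIS, "red3", "apoptosis")
  graphics::image(t(cytc), col = grDevices::hcl.colors(32, "Greens 3",
                                                       rev = TRUE),
                  axes = FALSE, main = "cytochrome c")
  panel(phen != PHEN_NONE,
        ifelse(phen[phen != PHEN_NONE] == PHEN_MITOPHAGY, "blue3", "red3"),
        "merged")
  invisible(out)
}
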