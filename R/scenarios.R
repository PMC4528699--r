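#' Named scenario presets
#'
#' Returns a fully resolved scenario specification reproducing one of the
#' in-silico experiments: a named list of simulation conditions (full
#' configurations), the reference condition for fold changes, and the
#' scenario type. Registry:
#' \describe{
#'   \item{fig1_single}{single mitochondrion, tBid dose sweep with
#'     activation delays 0/10/50 for all three LIR variants.}
#'   \item{fig3_no_tbid / fig3_tbid}{AV = 75 random, 20 % pre-activation,
#'     variants WT/SE2/SA2, without / with tBid at t = 5.}
#'   \item{fig4_av_sweep / fig4_delayed}{AV total 25/75/200, tBid at
#'     t = 5 / t = 10.}
#'   \item{fig6_radial}{radial AV rings of radius 2/4/6/8 versus random
#'     placement at constant total.}
#'   \item{fig7_bax_het}{Gaussian Bax heterogeneity, sd 0/0.1/0.3/0.6.}
#'   \item{fig7_bcl2_inhib}{decreasing Bcl2 mean at sd 0.1.}
#'   \item{s6_homogeneous}{random versus homogeneous AV layer, no tBid.}
#'   \item{s7_ros}{environmental ROS production x1/5, x1, x4 plus
#'     degradation halved/doubled.}
#'   \item{s12_mobility}{all four mitochondrion/AV mobility combinations.}
#' }
#'
#' @param name registry name.
#' @param variant LIR variant for the presets that do not sweep variants.
#' @param av_total AV total for `fig6_radial`.
#' @param seed base seed stored in every condition.
#' @return a `scenario_spec` list with `name`, `type`, `conditions`,
#'   `reference`.
#' @export
preset <- function(name, variant = "WT", av_total = 75, seed = 1L) {
  registry <- scenario_registry()
  if (!name %in% names(registry))
    stop("unknown scenario '", name, "'; registry: ",
         paste(names(registry), collapse = ", "))
  spec <- registry[[name]](variant = variant, av_total = av_total)
  spec$name <- name
  spec$conditions <- lapply(spec$conditions, function(ov)
    sim_config(utils::modifyList(ov, list(seed = seed))))
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec> ", x$name, " (", x$type, "): ",
      length(x$conditions), " conditions [",
      paste(names(x$conditions), collapse = ", "), "], reference ",
      x$reference, "\n", sep = "")
  invisible(x)
}

scenario_registry <- function() {
  base3 <- list(steps = 100L, av_mode = "random", av_total = 75,
                preactivated_fraction = 0.2, mobile = TRUE)
  variants3 <- function(extra) {
    conds <- lapply(c(WT = "WT", SE2 = "SE2", SA2 = "SA2"), function(v)
      utils::modifyList(c(base3, extra), list(variant = v)))
    conds
  }
  list(
    fig1_single = function(variant, av_total) {
      list(type = "single",
           conditions = list(),   # handled by run_scenario dispatch
           sweep = list(tbid = c(0, 0.3, 0.6, 0.9), delay = c(0, 10, 50),
                        variants = c("WT", "SE2", "SA2")),
           reference = NA_character_)
    },
    fig3_no_tbid = function(variant, av_total)
      list(type = "population", conditions = variants3(list()),
           reference = "WT"),
    fig3_tbid = function(variant, av_total)
      list(type = "population",
           conditions = variants3(list(tbid_start = 5)),
           reference = "WT"),
    fig4_av_sweep = function(variant, av_total)
      list(type = "population",
           conditions = lapply(c(av25 = 25, av75 = 75, av200 = 200),
                               function(a) utils::modifyList(
                                 base3, list(av_total = a, tbid_start = 5,
                                             variant = variant))),
           reference = "av75"),
    fig4_delayed = function(variant, av_total)
      list(type = "population",
           conditions = lapply(c(av25 = 25, av75 = 75, av200 = 200),
                               function(a) utils::modifyList(
                                 base3, list(av_total = a, tbid_start = 10,
                                             variant = variant))),
           reference = "av75"),
    fig6_radial = function(variant, av_total) {
      radii <- c(ring2 = 2, ring4 = 4, ring6 = 6, ring8 = 8)
      conds <- lapply(radii, function(r) utils::modifyList(
        base3, list(av_mode = "radial", av_radius = r, av_ring_width = 1,
                    av_total = av_total, tbid_start = 5, variant = variant)))
      conds$random <- utils::modifyList(
        base3, list(av_total = av_total, tbid_start = 5, variant = variant))
      list(type = "population", conditions = conds, reference = "ring8")
    },
    fig7_bax_het = function(variant, av_total)
      list(type = "population",
           conditions = lapply(c(sd0 = 0, sd0.1 = 0.1, sd0.3 = 0.3,
                                 sd0.6 = 0.6),
                               function(s) utils::modifyList(
                                 base3, list(bax_sd = s, tbid_start = 5,
                                             variant = variant))),
           reference = "sd0"),
    fig7_bcl2_inhib = function(variant, av_total)
      list(type = "population",
           conditions = lapply(c(bcl2_1 = 1, bcl2_0.75 = 0.75,
                                 bcl2_0.5 = 0.5, bcl2_0.25 = 0.25),
                               function(m) utils::modifyList(
                                 base3, list(bcl2_mean = m, bcl2_sd = 0.1,
                                             tbid_start = 5,
                                             variant = variant))),
           reference = "bcl2_1"),
    s6_homogeneous = function(variant, av_total)
      list(type = "population",
           conditions = list(
             random = utils::modifyList(base3, list(variant = variant)),
             homogeneous = utils::modifyList(
               base3, list(av_mode = "homogeneous", variant = variant))),
           reference = "random"),
    s7_ros = function(variant, av_total) {
      std <- config_defaults()
      conds <- list(
        prod_x0.2 = list(k_ros_env = std$k_ros_env / 5),
        prod_x1 = list(),
        prod_x4 = list(k_ros_env = std$k_ros_env * 4),
        sod_x0.5 = list(k_sod = std$k_sod / 2),
        sod_x2 = list(k_sod = std$k_sod * 2))
      conds <- lapply(conds, function(ov)
        utils::modifyList(base3, c(ov, list(variant = variant,
                                            tbid_start = 5))))
      list(type = "population", conditions = conds, reference = "prod_x1")
    },
    s12_mobility = function(variant, av_total)
      list(type = "population",
           conditions = list(
             both_static = utils::modifyList(
               base3, list(mobile = FALSE, av_mobile = FALSE,
                           variant = variant, tbid_start = 5)),
             mito_mobile = utils::modifyList(
               base3, list(mobile = TRUE, av_mobile = FALSE,
                           variant = variant, tbid_start = 5)),
             av_mobile = utils::modifyList(
               base3, list(mobile = FALSE, av_mobile = TRUE,
                           variant = variant, tbid_start = 5)),
             both_mobile = utils::modifyList(
               base3, list(mobile = TRUE, av_mobile = TRUE,
                           variant = variant, tbid_start = 5))),
           reference = "both_static")
  )
}

#' Run a scenario and tabulate comparison statistics
#'
#' Executes a 50-run (by default) ensemble per condition and returns the
#' comparison table: for each condition and statistic the across-run mean,
#' standard deviation, coefficient of variation and fold change versus the
#' scenario's reference condition. The `fig1_single` preset instead sweeps
#' a single mitochondrion over tBid dose, activation delay and variant,
#' returning final potentials per combination.
#'
#' @param spec a `scenario_spec` from [preset()].
#' @param n_runs ensemble size per condition.
#' @return list with `table` (comparison data frame) and `ensembles`
#'   (named list of `mito_ensemble`s), or for single-mitochondrion
#'   scenarios a data frame of final potentials.
#' @export
run_scenario <- function(spec, n_runs = 50) {
  if (!inherits(spec, "scenario_spec")) stop("spec must come from preset()")
  if (spec$type == "single") return(run_single_scenario(spec))
  ensembles <- lapply(spec$conditions, run_ensemble, n_runs = n_runs)
  stats <- c("max_total_mitophagy", "max_total_mitophagy_30",
             "census_mitophagy", "census_apoptosis", "cytc_total")
  rows <- list()
  for (cond in names(ensembles)) {
    s <- ensembles[[cond]]$summary
    for (st in stats) {
      i <- match(st, s$statistic)
      ref <- ensembles[[spec$reference]]$summary
      ref_mean <- ref$mean[match(st, ref$statistic)]
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, statistic = st, mean = s$mean[i], sd = s$sd[i],
        cv = s$cv[i],
        fold_vs_reference = if (!is.na(ref_mean) && ref_mean > 0)
          s$mean[i] / ref_mean else NA_real_)
    }
  }
  list(table = do.call(rbind, rows), ensembles = ensembles)
}

run_single_scenario <- function(spec, duration = 50) {
  sw <- spec$sweep
  grid <- expand.grid(variant = sw$variants, delay = sw$delay,
                      tbid = sw$tbid, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    rates <- make_rate_constants(g$variant)
    st <- initial_state()
    # tBid-free lead-in for the delay, then tBid on for the remainder
    if (g$delay > 0) {
      st <- integrate_update(st, list(ros = 0.2, av = 1, tbid = 0), rates,
                             g$delay)$state
    }
    res <- integrate_update(st, list(ros = 0.2, av = 1, tbid = g$tbid),
                            rates, duration)
    data.frame(g, mitophagy = mitophagy_potential(res$state),
               apoptosis = apoptosis_potential(res$state))
  })
  do.call(rbind, out)
}

#' Annotate the population phases of a run
#'
#' `activation_end` is the first step at which any agent holds a
#' provisional phenotype; `competition_end` is the first step at which all
#' eventually-committed agents have committed. Runs in which no agent
#' activates (or none commits) report the sentinel `steps_run`.
#'
#' @param result a `mito_run`.
#' @return list with `activation_end`, `competition_end`.
#' @export
annotate_phases <- function(result) {
  if (result$steps_run == 0)
    stop("cannot annotate an empty time series")
  phen <- result$agents$phenotype
  any_prov <- which(rowSums(phen != PHEN_NONE) > 0)
  activation_end <- if (length(any_prov)) min(any_prov) else result$steps_run
  cs <- result$committed_step
  competition_end <- if (any(!is.na(cs))) max(cs, na.rm = TRUE)
  else result$steps_run
  list(activation_end = activation_end,
       competition_end = max(activation_end, competition_end))
}

#' Coefficient of variation of an ensemble statistic
#'
#' Across-run sd/mean of a summary statistic (sample standard deviation).
#' A zero mean has no defined CV and is reported as `NA`.
#'
#' @param ensemble a `mito_ensemble`.
#' @param statistic one of the columns of `ensemble$stats`.
#' @return numeric CV (or `NA`).
#' @export
cv_across_runs <- function(ensemble, statistic) {
  if (ensemble$n_runs < 2) stop("CV requires at least 2 runs")
  x <- ensemble$stats[, statistic]
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}
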