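config_defaults <- function() {
  list(
    # engine
    steps = 200L, ode_every = 2L, ode_duration = 1.0, commit_window = 15L,
    theta_act = 0.42, k_deg = 0.3, momp_burst_steps = 4L, momp_ros_frac = 2.0,
    dt = 0.005, seed = 1L,
    # reaction network
    variant = "WT", r_f = 0.1, r_r = 0.01, r_lir = NA_real_,
    k_ros_bax = 0.1, k_cas_av = 0.1, k_momp = 0.5, alpha_bcl2 = 80,
    # population
    n = 100L, bnip3_level = 1.0, bax_mean = 1.0, bax_sd = 0.0,
    bcl2_mean = 1.0, bcl2_sd = 0.0, preactivated_fraction = 0.2,
    mobile = TRUE, av_mobile = FALSE,
    # environment
    av_mode = "random", av_total = 75, av_radius = 6, av_ring_width = 1,
    d_ros = 0.4, d_tbid = 0.4, d_cytc = 0.4,
    k_ros_env = 0.08, k_sod = 0.1,
    tbid_start = Inf, tbid_rate = 0.25, tbid_steps = 4L, tbid_cap = 0.9
  )
}

#' Simulation configuration
#'
#' Builds a fully resolved configuration with defaults applied, covering
#' the reaction network (rates, LIR variant), the environment (AV spatial
#' distribution, diffusion fractions, ROS source/degradation, tBid
#' schedule), the population (size, Gaussian Bax/Bcl2 heterogeneity,
#' pre-activation, mobility) and the engine (step counts, two-time-scale
#' cadence, commitment window, execution rates). Unknown fields are
#' rejected; numeric ranges are validated. The `provenance` attribute
#' records which fields were user-set versus defaulted.
#'
#' @param ... named overrides of any default field.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.list(user[[1]]) && is.null(names(user)[1]))
    user <- user[[1]]
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (length(user) > 0 && (is.null(names(user)) || any(names(user) == "")))
    stop("all config overrides must be named")
  cfg <- utils::modifyList(defaults, user)
  attr(cfg, "provenance") <- stats::setNames(
    ifelse(names(defaults) %in% names(user), "user", "default"),
    names(defaults))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$steps >= 0, "steps must be >= 0")
  chk(cfg$ode_every >= 1, "ode_every must be >= 1")
  chk(cfg$ode_duration >= 0, "ode_duration must be >= 0")
  chk(cfg$commit_window >= 1, "commit_window must be >= 1")
  chk(cfg$theta_act >= 0, "theta_act must be >= 0")
  chk(cfg$k_deg >= 0 && cfg$k_deg <= 1, "k_deg must lie in [0, 1]")
  chk(cfg$momp_burst_steps >= 1, "momp_burst_steps must be >= 1")
  chk(cfg$dt > 0, "dt must be > 0")
  chk(cfg$variant %in% names(LIR_VARIANTS),
      "variant must be one of WT, SE2, SA2")
  chk(cfg$n >= 1 && cfg$n <= 400, "n must lie in [1, 400]")
  chk(cfg$bax_sd >= 0 && cfg$bcl2_sd >= 0, "sds must be >= 0")
  chk(cfg$bax_mean >= 0 && cfg$bcl2_mean >= 0, "means must be >= 0")
  chk(cfg$preactivated_fraction >= 0 && cfg$preactivated_fraction <= 1,
      "preactivated_fraction must lie in [0, 1]")
  chk(cfg$av_mode %in% c("random", "homogeneous", "radial"),
      "av_mode must be random, homogeneous or radial")
  chk(cfg$av_total >= 0, "av_total must be >= 0")
  chk(cfg$av_radius >= 0 && cfg$av_radius <= 10,
      "av_radius must lie in [0, 10]")
  for (f in c("d_ros", "d_tbid", "d_cytc"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste(f, "must lie in [0, 1]"))
  for (f in c("k_ros_env", "k_sod", "tbid_rate", "tbid_cap", "r_f", "r_r",
              "k_ros_bax", "k_cas_av", "k_momp", "alpha_bcl2",
              "momp_ros_frac", "bnip3_level"))
    chk(cfg[[f]] >= 0, paste(f, "must be >= 0"))
  chk(cfg$k_sod <= 1, "k_sod must lie in [0, 1]")
  chk(cfg$tbid_steps >= 0, "tbid_steps must be >= 0")
  invisible(cfg)
}

config_rates <- function(cfg) {
  make_rate_constants(cfg$variant, r_f = cfg$r_f, r_r = cfg$r_r,
                      r_lir = if (is.na(cfg$r_lir)) NULL else cfg$r_lir,
                      k_ros_bax = cfg$k_ros_bax, k_cas_av = cfg$k_cas_av,
                      k_momp = cfg$k_momp, alpha_bcl2 = cfg$alpha_bcl2)
}

config_population_spec <- function(cfg) {
  population_spec(n = cfg$n, bnip3_level = cfg$bnip3_level,
                  bax_mean = cfg$bax_mean, bax_sd = cfg$bax_sd,
                  bcl2_mean = cfg$bcl2_mean, bcl2_sd = cfg$bcl2_sd,
                  preactivated_fraction = cfg$preactivated_fraction,
                  mobile = cfg$mobile)
}

# Canonical (sorted-key) YAML serialization used for hashing and round-trips.
config_canonical_yaml <- function(cfg) {
  vals <- unclass(cfg)
  attr(vals, "provenance") <- NULL
  vals <- vals[order(names(vals))]
  vals <- lapply(vals, function(v) if (is.infinite(v)) ".inf" else v)
  yaml::as.yaml(vals)
}

#' Hash a configuration
#'
#' MD5 over the canonical serialization; changes iff any field changes.
#' @param cfg a `sim_config`.
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(config_canonical_yaml(cfg), f)
  unname(tools::md5sum(f))
}
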