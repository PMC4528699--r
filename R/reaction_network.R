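#' @useDynLib mitofate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

SPECIES <- c("bnip3_i", "bnip3_a", "bnip3_av", "bcl2_free", "bcl2_bnip3",
             "bcl2_bax", "bax_i", "bax_a", "cytc_m", "casp3_i", "casp3_a")

LIR_VARIANTS <- c(WT = 0.05, SE2 = 3, SA2 = 0.001)

#' Rate constants for the Bnip3 signaling network
#'
#' Builds the mass-action rate set for one of the three Bnip3 LIR variants:
#' wild type (`"WT"`), the phosphomimetic constitutively LIR-active mutant
#' (`"SE2"`), or the phosphodeficient LIR-inactive mutant (`"SA2"`). Forward
#' binding reactions run at `r_f = 0.1` and reverse at `r_r = 0.01`; the
#' variant only changes the LIR-driven autophagosome binding rate `r_lir`
#' (0.05 / 3 / 0.001 for WT / SE2 / SA2).
#'
#' @param variant one of `"WT"`, `"SE2"`, `"SA2"`.
#' @param r_f forward mass-action rate (per level per time unit).
#' @param r_r reverse rate (per time unit).
#' @param r_lir optional override of the variant AV-binding rate.
#' @param k_ros_bax ROS production per unit active Bax.
#' @param k_cas_av caspase-mediated autophagosome inactivation rate.
#' @param k_momp cytochrome c release rate per unit active Bax.
#' @param alpha_bcl2 dimensionless enhancement of LIR binding by the
#'   Bcl2-Bnip3 complex (Bcl-xL positively regulates mitophagy).
#' @return an object of class `mito_rates`: a named list of the seven rates
#'   plus the variant name.
#' @export
make_rate_constants <- function(variant = c("WT", "SE2", "SA2"),
                                r_f = 0.1, r_r = 0.01, r_lir = NULL,
                                k_ros_bax = 0.1, k_cas_av = 0.05,
                                k_momp = 0.1, alpha_bcl2 = 1) {
  variant <- match.arg(variant)
  if (is.null(r_lir)) r_lir <- unname(LIR_VARIANTS[variant])
  vals <- c(r_f = r_f, r_r = r_r, r_lir = r_lir, k_ros_bax = k_ros_bax,
            k_cas_av = k_cas_av, k_momp = k_momp, alpha_bcl2 = alpha_bcl2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate constants must be finite and >= 0")
  if (r_f <= r_r)
    stop("forward rate r_f must exceed reverse rate r_r")
  structure(c(as.list(vals), list(variant = variant)), class = "mito_rates")
}

rates_param_vector <- function(rates) {
  unlist(rates[c("r_f", "r_r", "r_lir", "k_ros_bax", "k_cas_av", "k_momp",
                 "alpha_bcl2")])
}

#' Initial molecular state of a mitochondrion
#'
#' Intrinsic cytochrome c and procaspase-3 start at 1; a fraction of the
#' total Bnip3 pool can be seeded in the ROS-activated form (20 % in the
#' standard pre-activation scenarios). Free Bcl2 and inactive Bax carry the
#' full Bcl2/Bax totals; all complexes and active species start at zero.
#'
#' @param bnip3_total total Bnip3 level.
#' @param bcl2_total total Bcl2/Bcl-xL level.
#' @param bax_total total Bax level.
#' @param preactivated_fraction fraction of Bnip3 initially ROS-activated.
#' @return named numeric vector over the 11 network species.
#' @export
initial_state <- function(bnip3_total = 1, bcl2_total = 1, bax_total = 1,
                          preactivated_fraction = 0.2) {
  if (any(c(bnip3_total, bcl2_total, bax_total) < 0))
    stop("protein totals must be >= 0")
  if (preactivated_fraction < 0 || preactivated_fraction > 1)
    stop("preactivated_fraction must lie in [0, 1]")
  s <- stats::setNames(numeric(11), SPECIES)
  s["bnip3_i"] <- (1 - preactivated_fraction) * bnip3_total
  s["bnip3_a"] <- preactivated_fraction * bnip3_total
  s["bcl2_free"] <- bcl2_total
  s["bax_i"] <- bax_total
  s["cytc_m"] <- 1
  s["casp3_i"] <- 1
  s
}

#' Mass-action derivatives of the signaling network
#'
#' Right-hand side of the per-mitochondrion ODE system given quasi-static
#' local inputs. The reactions are: ROS activation of Bnip3 (reversible);
#' BH3-mediated sequestration of free Bcl2 by active Bnip3 (the two Bnip3
#' domains act independently, so the LIR-competent pool is not depleted);
#' Bcl2 neutralization of active Bax; tBid-catalyzed Bax activation;
#' Bax-dependent cytochrome c release (MOMP); caspase-3 activation tracking
#' cumulative release; LIR-driven AV binding enhanced by the Bcl2-Bnip3
#' complex; and caspase-mediated AV inactivation. ROS acts as a pure signal
#' and is not consumed.
#'
#' @param state named species vector as from [initial_state()].
#' @param inputs list or named vector with local `ros`, `av`, `tbid` levels.
#' @param rates a `mito_rates` object.
#' @return named derivative vector over the 11 species plus `av`
#'   (local autophagosome pool) and `ros_prod` (ROS emission rate).
#' @export
derivatives <- function(state, inputs, rates) {
  s <- state[SPECIES]
  ros <- inputs[["ros"]]; av <- inputs[["av"]]; tbid <- inputs[["tbid"]]
  v1f <- rates$r_f * s[["bnip3_i"]] * ros
  v1r <- rates$r_r * s[["bnip3_a"]]
  v2f <- rates$r_f * s[["bnip3_a"]] * s[["bcl2_free"]]
  v2r <- rates$r_r * s[["bcl2_bnip3"]]
  v3f <- rates$r_f * s[["bax_a"]] * s[["bcl2_free"]]
  v3r <- rates$r_r * s[["bcl2_bax"]]
  v4  <- rates$r_f * tbid * s[["bax_i"]]
  v5  <- rates$k_momp * s[["bax_a"]] * s[["cytc_m"]]
  v6  <- rates$r_f * (1 - s[["cytc_m"]]) * s[["casp3_i"]]
  v7f <- rates$r_lir * (1 + rates$alpha_bcl2 * s[["bcl2_bnip3"]]) *
    s[["bnip3_a"]] * av
  v7r <- rates$r_r * s[["bnip3_av"]]
  v8  <- rates$k_cas_av * s[["casp3_a"]] * av
  c(bnip3_i = -v1f + v1r,
    bnip3_a = v1f - v1r - v7f + v7r,
    bnip3_av = v7f - v7r,
    bcl2_free = -v2f + v2r - v3f + v3r,
    bcl2_bnip3 = v2f - v2r,
    bcl2_bax = v3f - v3r,
    bax_i = -v4,
    bax_a = v4 - v3f + v3r,
    cytc_m = -v5,
    casp3_i = -v6,
    casp3_a = v6,
    av = -v7f + v7r - v8,
    ros_prod = rates$k_ros_bax * s[["bax_a"]])
}

#' Advance a mitochondrion's state over one update interval
#'
#' Integrates the network with an adaptive stiff-capable solver
#' ([deSolve::lsoda], rtol 1e-6 / atol 1e-9) holding the environmental
#' inputs constant over the interval. The local autophagosome pool is a
#' dynamic state within the interval (binding consumes it, the slow reverse
#' reaction and caspase inactivation also move it), so the reported
#' `av_consumed` is the net drawdown of the cell-local AV pool.
#'
#' @param state named species vector.
#' @param inputs local `ros`, `av`, `tbid` levels.
#' @param rates a `mito_rates` object.
#' @param duration model time to integrate over (default 1).
#' @return list with `state` (advanced, clamped at 0), and `outputs`:
#'   `ros_produced`, `cytc_released`, `av_consumed` (all >= 0) plus
#'   `av_remaining`, the AV pool to write back to the environment.
#' @export
integrate_update <- function(state, inputs, rates, duration = 1) {
  if (duration < 0) stop("duration must be >= 0")
  if (duration == 0) {
    return(list(state = state,
                outputs = list(ros_produced = 0, cytc_released = 0,
                               av_consumed = 0,
                               av_remaining = inputs[["av"]])))
  }
  y0 <- c(state[SPECIES], av = unname(inputs[["av"]]), ros_prod = 0)
  p <- rates_param_vector(rates)
  ros <- inputs[["ros"]]; tbid <- inputs[["tbid"]]
  f <- function(t, y, parms) {
    names(y) <- c(SPECIES, "av", "ros_prod")
    list(unname(derivatives(y, list(ros = ros, av = y[["av"]], tbid = tbid),
                            rates)))
  }
  sol <- deSolve::ode(y = y0, times = c(0, duration), func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-6, atol = 1e-9)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to converge (istate = ",
         attr(sol, "istate")[1], ")")
  yf <- sol[nrow(sol), -1]
  if (any(yf < -1e-9))
    warning("integration produced levels below -1e-9; clamping")
  yf <- pmax(yf, 0)
  new_state <- stats::setNames(yf[seq_along(SPECIES)], SPECIES)
  list(state = new_state,
       outputs = list(
         ros_produced = unname(yf[["ros_prod"]]),
         cytc_released = max(0, unname(state[["cytc_m"]] - yf[["cytc_m"]])),
         av_consumed = max(0, unname(inputs[["av"]] - yf[["av"]])),
         av_remaining = unname(yf[["av"]])))
}

#' Batch-advance many mitochondria at once
#'
#' Compiled fixed-step RK4 (default step 0.005 model time) over the same
#' network as [integrate_update()], applied row-wise to an agent population.
#' Used by the simulation engine; agrees with the adaptive solver to well
#' below the engine's behavioral tolerances (see the methods vignette).
#'
#' @param states numeric matrix, one row per agent, 11 species columns.
#' @param av,ros,tbid per-agent local input vectors.
#' @param rates a `mito_rates` object.
#' @param duration model time per update.
#' @param dt RK4 step size.
#' @return list with `state` matrix, `av`, `ros_produced`, `cytc_released`.
#' @export
integrate_batch <- function(states, av, ros, tbid, rates, duration = 1,
                            dt = 0.005) {
  storage.mode(states) <- "double"
  out <- rk4_batch_cpp(states, as.double(av), as.double(ros), as.double(tbid),
                       rates_param_vector(rates), duration, dt)
  colnames(out$state) <- SPECIES
  out
}

#' Mitophagy potential of a mitochondrion
#'
#' The level of LIR-bound Bnip3-autophagosome complex, the terminal species
#' of the mitophagy branch.
#' @param state named species vector.
#' @return numeric level.
#' @export
mitophagy_potential <- function(state) unname(state[["bnip3_av"]])

#' Apoptosis potential of a mitochondrion
#'
#' The level of active caspase-3, the terminal species of the apoptosis
#' branch.
#' @param state named species vector.
#' @return numeric level.
#' @export
apoptosis_potential <- function(state) unname(state[["casp3_a"]])

#' Single-mitochondrion dose-response curve
#'
#' Sweeps tBid or total Bax for a single mitochondrion integrated under
#' constant local conditions and reports the final mitophagy and apoptosis
#' potentials at each sweep point, together with the crossover value at
#' which mitophagy ceases to dominate (found by bisection on the sign of
#' the potential difference between bracketing sweep points).
#'
#' @param variant LIR variant name.
#' @param sweep numeric vector of sweep values (>= 0, non-empty).
#' @param param which input to sweep: `"tbid"` or `"bax"`.
#' @param bnip3,bcl2,bax,preactivated_fraction initial levels.
#' @param av,ros local environment levels held constant.
#' @param tbid tBid level (used when sweeping Bax).
#' @param duration total integration time per sweep point.
#' @return data frame (`value`, `mitophagy`, `apoptosis`) with attribute
#'   `crossover` (NA if the difference never changes sign).
#' @export
dose_response <- function(variant = "WT", sweep, param = c("tbid", "bax"),
                          bnip3 = 1, bcl2 = 1, bax = 1,
                          preactivated_fraction = 0.2, av = 1, ros = 0.2,
                          tbid = 0.9, duration = 50) {
  param <- match.arg(param)
  if (length(sweep) == 0) stop("sweep must be non-empty")
  if (any(sweep < 0)) stop("sweep values must be >= 0")
  rates <- make_rate_constants(variant)
  eval_point <- function(v) {
    st <- if (param == "bax") {
      initial_state(bnip3, bcl2, v, preactivated_fraction)
    } else {
      initial_state(bnip3, bcl2, bax, preactivated_fraction)
    }
    tb <- if (param == "tbid") v else tbid
    res <- integrate_update(st, list(ros = ros, av = av, tbid = tb), rates,
                            duration)
    c(mitophagy = mitophagy_potential(res$state),
      apoptosis = apoptosis_potential(res$state))
  }
  pts <- t(vapply(sweep, eval_point, c(mitophagy = 0, apoptosis = 0)))
  out <- data.frame(value = sweep, mitophagy = pts[, "mitophagy"],
                    apoptosis = pts[, "apoptosis"])
  diff_sign <- sign(out$mitophagy - out$apoptosis)
  cross <- NA_real_
  flip <- which(diff_sign[-1] != diff_sign[-length(diff_sign)] &
                  diff_sign[-1] != 0)
  if (length(flip) > 0) {
    lo <- sweep[flip[1]]; hi <- sweep[flip[1] + 1]
    g <- function(v) {
      p <- eval_point(v)
      p[["mitophagy"]] - p[["apoptosis"]]
    }
    cross <- bisect_root(g, lo, hi)
  }
  attr(out, "crossover") <- cross
  out
}

# Simple bisection for a sign change of g on [lo, hi].
bisect_root <- function(g, lo, hi, tol = 1e-4, maxit = 60) {
  flo <- g(lo); fhi <- g(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) return(NA_real_)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- g(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
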