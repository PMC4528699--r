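# Independent oracles used across test files. These deliberately re-derive
# the reaction fluxes from a literal reaction table rather than calling the
# package's derivatives(), so the two routes stay independent.

oracle_rhs <- function(y, ros, tbid, rates) {
  with(as.list(c(y, rates)), {
    flux <- list(
      # reaction, rate, stoichiometry (named increments)
      list(r = r_f * bnip3_i * ros,
           d = c(bnip3_i = -1, bnip3_a = 1)),
      list(r = r_r * bnip3_a,
           d = c(bnip3_i = 1, bnip3_a = -1)),
      list(r = r_f * bnip3_a * bcl2_free,    # BH3 domain acts catalytically
           d = c(bcl2_free = -1, bcl2_bnip3 = 1)),
      list(r = r_r * bcl2_bnip3,
           d = c(bcl2_free = 1, bcl2_bnip3 = -1)),
      list(r = r_f * bax_a * bcl2_free,
           d = c(bax_a = -1, bcl2_free = -1, bcl2_bax = 1)),
      list(r = r_r * bcl2_bax,
           d = c(bax_a = 1, bcl2_free = 1, bcl2_bax = -1)),
      list(r = r_f * tbid * bax_i,
           d = c(bax_i = -1, bax_a = 1)),
      list(r = k_momp * bax_a * cytc_m,
           d = c(cytc_m = -1)),
      list(r = r_f * (1 - cytc_m) * casp3_i,
           d = c(casp3_i = -1, casp3_a = 1)),
      list(r = r_lir * (1 + alpha_bcl2 * bcl2_bnip3) * bnip3_a * av,
           d = c(bnip3_a = -1, bnip3_av = 1, av = -1)),
      list(r = r_r * bnip3_av,
           d = c(bnip3_a = 1, bnip3_av = -1, av = 1)),
      list(r = k_cas_av * casp3_a * av,
           d = c(av = -1)),
      list(r = k_ros_bax * bax_a,
           d = c(ros_prod = 1)))
    out <- stats::setNames(numeric(13),
                           c(names(y)))
    for (f in flux) out[names(f$d)] <- out[names(f$d)] + f$r * f$d
    out
  })
}

# Fixed-step explicit Euler on the full (species + av + ros_prod) system.
euler_integrate <- function(state, inputs, rates, duration, h = 1e-4) {
  y <- c(state, av = unname(inputs$av), ros_prod = 0)
  nstep <- round(duration / h)
  p <- unlist(rates[c("r_f", "r_r", "r_lir", "k_ros_bax", "k_cas_av",
                      "k_momp", "alpha_bcl2")])
  # inline mass-action RHS for speed (same reaction list as oracle_rhs)
  for (s in seq_len(nstep)) {
    v1f <- p[["r_f"]] * y[["bnip3_i"]] * inputs$ros
    v1r <- p[["r_r"]] * y[["bnip3_a"]]
    v2f <- p[["r_f"]] * y[["bnip3_a"]] * y[["bcl2_free"]]
    v2r <- p[["r_r"]] * y[["bcl2_bnip3"]]
    v3f <- p[["r_f"]] * y[["bax_a"]] * y[["bcl2_free"]]
    v3r <- p[["r_r"]] * y[["bcl2_bax"]]
    v4 <- p[["r_f"]] * inputs$tbid * y[["bax_i"]]
    v5 <- p[["k_momp"]] * y[["bax_a"]] * y[["cytc_m"]]
    v6 <- p[["r_f"]] * (1 - y[["cytc_m"]]) * y[["casp3_i"]]
    v7f <- p[["r_lir"]] * (1 + p[["alpha_bcl2"]] * y[["bcl2_bnip3"]]) *
      y[["bnip3_a"]] * y[["av"]]
    v7r <- p[["r_r"]] * y[["bnip3_av"]]
    v8 <- p[["k_cas_av"]] * y[["casp3_a"]] * y[["av"]]
    y <- y + h * c(-v1f + v1r,
                   v1f - v1r - v7f + v7r,
                   v7f - v7r,
                   -v2f + v2r - v3f + v3r,
                   v2f - v2r,
                   v3f - v3r,
                   -v4,
                   v4 - v3f + v3r,
                   -v5,
                   -v6,
                   v6,
                   -v7f + v7r - v8,
                   p[["k_ros_bax"]] * y[["bax_a"]])
  }
  y
}

random_test_state <- function() {
  st <- initial_state(runif(1, 0.2, 2), runif(1, 0.2, 2), runif(1, 0.2, 2),
                      runif(1))
  st[c("bnip3_av", "bcl2_bnip3", "bcl2_bax", "bax_a", "casp3_a")] <-
    runif(5, 0, 0.3)
  st
}

conserved_totals <- function(state, cytc_released = 0) {
  c(bnip3 = unname(sum(state[c("bnip3_i", "bnip3_a", "bnip3_av")])),
    bcl2 = unname(sum(state[c("bcl2_free", "bcl2_bnip3", "bcl2_bax")])),
    bax = unname(sum(state[c("bax_i", "bax_a", "bcl2_bax")])),
    cytc = unname(state[["cytc_m"]] + cytc_released),
    casp3 = unname(state[["casp3_i"]] + state[["casp3_a"]]))
}

# Ensembles shared between slow tests (computed once per test session).
.ens_cache <- new.env(parent = emptyenv())
cached_ensemble <- function(key, overrides, n_runs = 50, seed = 100L) {
  id <- paste0(key, "_", n_runs, "_", seed)
  if (is.null(.ens_cache[[id]])) {
    base <- list(steps = 100L, av_mode = "random", av_total = 75,
                 preactivated_fraction = 0.2, mobile = TRUE, seed = seed)
    cfg <- sim_config(utils::modifyList(base, overrides))
    .ens_cache[[id]] <- run_ensemble(cfg, n_runs)
  }
  .ens_cache[[id]]
}

ensemble_stat <- function(e, statistic) {
  e$summary$mean[match(statistic, e$summary$statistic)]
}

small_config <- function(...) {
  sim_config(utils::modifyList(
    list(n = 20L, steps = 40L, av_total = 30, seed = 7L), list(...)))
}
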