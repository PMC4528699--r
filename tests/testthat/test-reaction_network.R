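test_that("rate constants carry the variant LIR binding rates", {
  wt <- make_rate_constants("WT")
  expect_equal(wt$r_lir, 0.05)
  expect_equal(wt$r_f, 0.1)
  expect_equal(wt$r_r, 0.01)
  expect_equal(make_rate_constants("SE2")$r_lir, 3)
  expect_equal(make_rate_constants("SA2")$r_lir, 0.001)
  expect_error(make_rate_constants("XX"))
  expect_error(make_rate_constants("WT", r_f = 0.01, r_r = 0.1),
               "r_f must exceed")
  expect_error(make_rate_constants("WT", k_momp = -1))
})

test_that("initial state splits Bnip3 by pre-activation and seeds unit pools", {
  s <- initial_state(1, 1, 1, 0.2)
  expect_equal(s[["bnip3_i"]], 0.8)
  expect_equal(s[["bnip3_a"]], 0.2)
  expect_equal(s[["cytc_m"]], 1)
  expect_equal(s[["casp3_i"]], 1)
  expect_equal(s[["bcl2_free"]], 1)
  expect_equal(s[["bax_i"]], 1)
  expect_true(all(s[c("bnip3_av", "bcl2_bnip3", "bcl2_bax", "bax_a",
                      "casp3_a")] == 0))
  expect_equal(sum(initial_state(0, 1, 1, 0.2)[1:3]), 0)
  s0 <- initial_state(1, 1, 1, 0)
  expect_equal(s0[["bnip3_a"]], 0)
  expect_equal(s0[["bnip3_i"]], 1)
  expect_error(initial_state(-1, 1, 1, 0.2))
  expect_error(initial_state(1, 1, 1, 1.5))
})

test_that("derivatives match an independent reaction-table evaluation", {
  rates <- make_rate_constants("WT", alpha_bcl2 = 1)
  st <- stats::setNames(rep(0.5, 11), names(initial_state()))
  inp <- list(ros = 1, av = 1, tbid = 0.9)
  d <- derivatives(st, inp, rates)
  y <- c(st, av = 1, ros_prod = 0)
  expect_equal(unname(d), unname(oracle_rhs(y, 1, 0.9, rates)),
               tolerance = 1e-12)
  # quiescent state with no stimuli sits still
  d0 <- derivatives(initial_state(1, 1, 1, 0), list(ros = 0, av = 0, tbid = 0),
                    rates)
  expect_true(all(d0 == 0))
})

test_that("derivatives conserve every protein total by construction", {
  set.seed(11)
  rates <- make_rate_constants("WT", alpha_bcl2 = 80)
  for (i in 1:200) {
    st <- random_test_state()
    d <- derivatives(st, list(ros = runif(1, 0, 2), av = runif(1, 0, 2),
                              tbid = runif(1, 0, 0.9)), rates)
    expect_equal(sum(d[c("bnip3_i", "bnip3_a", "bnip3_av")]), 0,
                 tolerance = 1e-14)
    expect_equal(sum(d[c("bcl2_free", "bcl2_bnip3", "bcl2_bax")]), 0,
                 tolerance = 1e-14)
    expect_equal(sum(d[c("bax_i", "bax_a", "bcl2_bax")]), 0,
                 tolerance = 1e-14)
    expect_equal(sum(d[c("casp3_i", "casp3_a")]), 0, tolerance = 1e-14)
  }
})

test_that("integration preserves totals, positivity and the null interval", {
  set.seed(21)
  rates <- make_rate_constants("WT")
  st <- random_test_state()
  inp <- list(ros = 0.8, av = 1, tbid = 0.5)
  same <- integrate_update(st, inp, rates, 0)
  expect_identical(same$state, st)
  expect_equal(same$outputs$cytc_released, 0)
  for (i in 1:25) {
    st <- random_test_state()
    inp <- list(ros = runif(1, 0, 2), av = runif(1, 0, 2),
                tbid = runif(1, 0, 0.9))
    res <- integrate_update(st, inp, rates, runif(1, 0.5, 8))
    drift <- abs(conserved_totals(res$state, res$outputs$cytc_released) -
                   conserved_totals(st))
    expect_lt(max(drift / pmax(conserved_totals(st), 1e-9)), 1e-6)
    expect_true(all(res$state >= 0))
    expect_gte(res$outputs$ros_produced, 0)
    expect_lte(res$outputs$cytc_released, st[["cytc_m"]] + 1e-9)
  }
})

test_that("LIR-inactive mutant binds almost no autophagosomes", {
  inp <- list(ros = 1, av = 1, tbid = 0)
  st <- initial_state()
  wt <- integrate_update(st, inp, make_rate_constants("WT"), 10)
  sa <- integrate_update(st, inp, make_rate_constants("SA2"), 10)
  se <- integrate_update(st, inp, make_rate_constants("SE2"), 10)
  expect_lt(mitophagy_potential(sa$state),
            0.05 * mitophagy_potential(wt$state))
  # variant ordering on the mitophagy branch
  expect_gte(mitophagy_potential(se$state), mitophagy_potential(wt$state))
  expect_gte(mitophagy_potential(wt$state), mitophagy_potential(sa$state))
})

test_that("adaptive solver agrees with a fixed-step Euler oracle", {
  set.seed(31)
  rates <- make_rate_constants("WT")
  for (i in 1:10) {
    st <- random_test_state()
    inp <- list(ros = runif(1, 0, 1.5), av = runif(1, 0, 1.5),
                tbid = runif(1, 0, 0.9))
    res <- integrate_update(st, inp, rates, 5)
    ref <- euler_integrate(st, inp, rates, 5)
    rel <- abs(res$state - ref[1:11]) / pmax(abs(ref[1:11]), 1e-6)
    expect_lt(max(rel), 1e-3)
    expect_equal(res$outputs$ros_produced, unname(ref[["ros_prod"]]),
                 tolerance = 1e-3)
  }
})

test_that("compiled batch integrator matches the adaptive solver", {
  set.seed(41)
  rates <- make_rate_constants("SE2", alpha_bcl2 = 80)
  n <- 12
  states <- t(vapply(seq_len(n), function(i) random_test_state(),
                     numeric(11)))
  colnames(states) <- names(initial_state())
  av <- runif(n, 0, 2); ros <- runif(n, 0, 2); tbid <- runif(n, 0, 0.9)
  b <- integrate_batch(states, av, ros, tbid, rates, duration = 2)
  for (i in seq_len(n)) {
    ref <- integrate_update(states[i, ], list(ros = ros[i], av = av[i],
                                              tbid = tbid[i]), rates, 2)
    expect_equal(unname(b$state[i, ]), unname(ref$state), tolerance = 1e-4)
    expect_equal(b$av[i], ref$outputs$av_remaining, tolerance = 1e-4)
  }
})

test_that("potentials read the terminal species of each branch", {
  s <- initial_state()
  expect_equal(mitophagy_potential(s), 0)
  expect_equal(apoptosis_potential(s), 0)
  s[["bnip3_av"]] <- 0.7
  expect_equal(mitophagy_potential(s), 0.7)
  # no AV -> no complex; no tBid and no active Bax -> no caspase
  res <- integrate_update(initial_state(), list(ros = 1, av = 0, tbid = 0),
                          make_rate_constants("WT"), 10)
  expect_equal(mitophagy_potential(res$state), 0, tolerance = 1e-9)
  expect_equal(apoptosis_potential(res$state), 0, tolerance = 1e-9)
})

test_that("apoptosis potential rises monotonically with tBid dose", {
  dr <- dose_response("WT", sweep = c(0, 0.3, 0.6, 0.9), param = "tbid",
                      duration = 30)
  expect_true(all(diff(dr$apoptosis) > 0))
  # with tBid absent everywhere the apoptotic branch stays silent
  dr0 <- dose_response("WT", sweep = c(0.5, 1, 2), param = "bax", tbid = 0,
                       duration = 30)
  expect_true(all(dr0$apoptosis == 0))
  expect_error(dose_response("WT", sweep = numeric(0)))
})

test_that("cumulative ROS output increases strictly with tBid", {
  rates <- make_rate_constants("WT")
  ros_out <- vapply(c(0.1, 0.3, 0.6, 0.9), function(tb) {
    integrate_update(initial_state(), list(ros = 0.5, av = 1, tbid = tb),
                     rates, 20)$outputs$ros_produced
  }, numeric(1))
  expect_true(all(diff(ros_out) > 0))
})

test_that("dose-response crossover matches a bisection oracle", {
  dr <- dose_response("SE2", sweep = seq(0, 2, by = 0.25), param = "bax",
                      preactivated_fraction = 0.2, tbid = 0.9, duration = 50)
  cross <- attr(dr, "crossover")
  # a low-Bax region where mitophagy dominates must exist and be contiguous
  dom <- dr$mitophagy > dr$apoptosis
  expect_true(dom[1])
  expect_true(any(!dom))
  expect_equal(which(!dom), seq(max(which(dom)) + 1, nrow(dr)))
  # oracle: bisect the same integrator's potential difference
  g <- function(v) {
    st <- initial_state(1, 1, v, 0.2)
    r <- integrate_update(st, list(ros = 0.2, av = 1, tbid = 0.9),
                          make_rate_constants("SE2"), 50)
    mitophagy_potential(r$state) - apoptosis_potential(r$state)
  }
  lo <- dr$value[max(which(dom))]; hi <- dr$value[max(which(dom)) + 1]
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(cross, (lo + hi) / 2, tolerance = 2e-3)
})
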