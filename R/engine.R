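PHASE_NAIVE <- 0L; PHASE_ACTIVATION <- 1L; PHASE_COMPETITION <- 2L
PHASE_COMMITTED <- 3L
PHEN_NONE <- 0L; PHEN_MITOPHAGY <- 1L; PHEN_APOPTOSIS <- 2L

# --- seeded substreams -------------------------------------------------
# One master seed spawns independent substreams (placement, population,
# movement, AV movement) so that toggling mobility does not perturb
# seeding. Implemented by swapping .Random.seed states.

make_streams <- function(seed, names = c("placement", "population",
                                         "movement", "av_movement")) {
  old <- save_rng()
  on.exit(restore_rng(old))
  streams <- list()
  for (i in seq_along(names)) {
    set.seed((as.integer(seed) + i * 100003L) %% 2147483629L)
    streams[[names[i]]] <- .GlobalEnv$.Random.seed
  }
  streams
}

save_rng <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv)
  else NULL
}

restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", state, envir = .GlobalEnv)
  }
}

stream_eval <- function(world, name, fn) {
  old <- save_rng()
  assign(".Random.seed", world$streams[[name]], envir = .GlobalEnv)
  res <- fn()
  world$streams[[name]] <- get(".Random.seed", envir = .GlobalEnv)
  restore_rng(old)
  res
}

# --- phenotype state machine -------------------------------------------

#' Update an agent's provisional phenotype and phase
#'
#' The provisional phenotype is the dominant potential (mitophagy
#' `bnip3_av` versus apoptosis `casp3_a`) when the maximum exceeds
#' `theta_act`, otherwise none. Phases advance naive -> activation on the
#' first nonzero potential and activation -> competition on the first
#' provisional phenotype. The consecutive counter increments while the
#' phenotype repeats, resets to 1 on a switch and to 0 on none. An exact
#' tie above threshold retains the previous phenotype (mitophagy when
#' there is none), keeping the rule deterministic.
#'
#' @param agent list with `phase`, `phenotype`, `consecutive`.
#' @param mito,apo current potentials.
#' @param theta_act activation threshold.
#' @return updated agent list.
#' @export
update_phenotype <- function(agent, mito, apo, theta_act) {
  if (agent$phase == PHASE_NAIVE && (mito > 0 || apo > 0))
    agent$phase <- PHASE_ACTIVATION
  top <- max(mito, apo)
  prov <- if (top > theta_act) {
    if (mito > apo) PHEN_MITOPHAGY
    else if (apo > mito) PHEN_APOPTOSIS
    else if (agent$phenotype != PHEN_NONE) agent$phenotype
    else PHEN_MITOPHAGY
  } else PHEN_NONE
  if (prov == PHEN_NONE) {
    agent$consecutive <- 0L
  } else if (prov == agent$phenotype) {
    agent$consecutive <- agent$consecutive + 1L
  } else {
    agent$consecutive <- 1L
  }
  agent$phenotype <- prov
  if (agent$phase == PHASE_ACTIVATION && prov != PHEN_NONE)
    agent$phase <- PHASE_COMPETITION
  agent
}

#' Commitment check
#'
#' An agent in the competition phase locks into its provisional phenotype
#' permanently once it has held it for `commit_window` consecutive steps
#' (15 by default, the decision period).
#'
#' @param agent list with `phase`, `phenotype`, `consecutive`.
#' @param commit_window required consecutive steps.
#' @return logical: commits now.
#' @export
check_commitment <- function(agent, commit_window) {
  agent$phase == PHASE_COMPETITION && agent$phenotype != PHEN_NONE &&
    agent$consecutive >= commit_window
}

#' Execute a committed agent for one step
#'
#' Mitophagy-committed agents have every molecular level decay by
#' `1 - k_deg` per step and are removed (marked dead) once the mitophagy
#' potential falls below 1e-3. Apoptosis-committed agents empty their
#' remaining intra-mitochondrial cytochrome c in equal portions over
#' `momp_burst_steps` steps (a single MOMP burst) together with a
#' proportional ROS deposit, then persist ODE-frozen.
#'
#' @param agent list with `phenotype`, `state`, `alive`, `burst_left`,
#'   `burst_amt`.
#' @param k_deg per-step degradation factor for mitophagy execution.
#' @param momp_ros_frac ROS deposited per unit cytochrome c in the burst.
#' @return list with the updated `agent` and `deposits`
#'   (`cytc`, `ros` amounts for the agent's cell).
#' @export
execute_committed <- function(agent, k_deg, momp_ros_frac = 1) {
  deposits <- list(cytc = 0, ros = 0)
  if (agent$phenotype == PHEN_MITOPHAGY) {
    agent$state <- agent$state * (1 - k_deg)
    if (agent$state[["bnip3_av"]] < 1e-3) agent$alive <- FALSE
  } else if (agent$phenotype == PHEN_APOPTOSIS && agent$burst_left > 0) {
    rel <- min(agent$burst_amt, agent$state[["cytc_m"]])
    agent$state[["cytc_m"]] <- agent$state[["cytc_m"]] - rel
    agent$burst_left <- agent$burst_left - 1L
    deposits$cytc <- rel
    deposits$ros <- momp_ros_frac * rel
  }
  list(agent = agent, deposits = deposits)
}

# --- world construction and stepping -----------------------------------

new_world <- function(cfg) {
  w <- new.env(parent = emptyenv())
  w$cfg <- cfg
  w$rates <- config_rates(cfg)
  w$streams <- make_streams(cfg$seed)
  w$layers <- list(
    ros = matrix(if (cfg$k_sod > 0) cfg$k_ros_env / cfg$k_sod else 0,
                 GRID_N, GRID_N),
    av = stream_eval(w, "placement", function()
      build_av_layer(cfg$av_mode, cfg$av_total, cfg$av_radius,
                     cfg$av_ring_width)),
    tbid = matrix(0, GRID_N, GRID_N),
    cytc = matrix(0, GRID_N, GRID_N))
  pop <- stream_eval(w, "population", function()
    seed_population(config_population_spec(cfg)))
  w$pos <- pop$pos
  w$states <- pop$states
  w$bax0 <- pop$bax0
  w$bcl20 <- pop$bcl20
  w$phase <- pop$phase
  w$phenotype <- pop$phenotype
  w$consecutive <- pop$consecutive
  w$alive <- pop$alive
  n <- cfg$n
  w$burst_left <- integer(n)
  w$burst_amt <- numeric(n)
  w$committed_step <- rep(NA_integer_, n)
  w$time_to_phenotype <- rep(NA_integer_, n)
  w$cytc_cum <- 0
  w$t <- 0L
  steps <- cfg$steps
  w$ts <- matrix(NA_real_, steps, 5,
                 dimnames = list(NULL, c("step", "total_mitophagy",
                                         "total_apoptosis", "cytc_step",
                                         "cytc_cum")))
  w$traj_phase <- matrix(NA_integer_, steps, n)
  w$traj_phen <- matrix(NA_integer_, steps, n)
  w$traj_mito <- matrix(NA_real_, steps, n)
  w$traj_apo <- matrix(NA_real_, steps, n)
  w
}

#' Advance the simulation world by one agent-based step
#'
#' Order within a step: environment update (tBid schedule, ROS
#' source/decay/diffusion, cytochrome c diffusion, AV random walk if
#' mobile), mitochondrial movement, ODE updates for alive uncommitted
#' agents (every `ode_every` steps: sample local inputs, integrate,
#' feed ROS/cytochrome c back, draw down local AV), phenotype and
#' commitment update, then execution of committed actions.
#'
#' @param world a world environment from the internal constructor.
#' @return the world, invisibly (modified in place).
#' @export
sim_step <- function(world) {
  cfg <- world$cfg
  t <- world$t + 1L
  world$t <- t
  cytc_step <- 0

  # (a) environment
  world$layers$tbid <- apply_tbid(world$layers$tbid, t, cfg)
  world$layers$ros <- update_ros(world$layers$ros, cfg)
  world$layers$cytc <- diffuse(world$layers$cytc, cfg$d_cytc)
  if (cfg$av_mobile)
    world$layers$av <- stream_eval(world, "av_movement", function()
      move_av_layer(world$layers$av))
  if (cfg$mobile)
    world$pos <- stream_eval(world, "movement", function()
      move_agents(world$pos, world$alive))

  # (b) ODE updates on the slow cadence
  if (t %% cfg$ode_every == 0L) {
    idx <- which(world$alive & world$phase < PHASE_COMMITTED)
    if (length(idx) > 0) {
      cells <- world$pos[idx]
      res <- integrate_batch(world$states[idx, , drop = FALSE],
                             av = world$layers$av[cells],
                             ros = world$layers$ros[cells],
                             tbid = world$layers$tbid[cells],
                             rates = world$rates,
                             duration = cfg$ode_duration, dt = cfg$dt)
      world$states[idx, ] <- res$state
      world$layers$av[cells] <- res$av
      world$layers$ros[cells] <- world$layers$ros[cells] + res$ros_produced
      world$layers$cytc[cells] <- world$layers$cytc[cells] + res$cytc_released
      cytc_step <- cytc_step + sum(res$cytc_released)
    }
  }

  # (c) phenotype / phase / commitment
  for (i in which(world$alive & world$phase < PHASE_COMMITTED)) {
    agent <- list(phase = world$phase[i], phenotype = world$phenotype[i],
                  consecutive = world$consecutive[i])
    agent <- update_phenotype(agent, world$states[i, "bnip3_av"],
                              world$states[i, "casp3_a"], cfg$theta_act)
    if (agent$phenotype != PHEN_NONE && is.na(world$time_to_phenotype[i]))
      world$time_to_phenotype[i] <- t
    if (check_commitment(agent, cfg$commit_window)) {
      agent$phase <- PHASE_COMMITTED
      world$committed_step[i] <- t
      if (agent$phenotype == PHEN_APOPTOSIS) {
        world$burst_left[i] <- cfg$momp_burst_steps
        world$burst_amt[i] <- world$states[i, "cytc_m"] / cfg$momp_burst_steps
      }
    }
    world$phase[i] <- agent$phase
    world$phenotype[i] <- agent$phenotype
    world$consecutive[i] <- agent$consecutive
  }

  # (d) execute committed actions
  for (i in which(world$alive & world$phase == PHASE_COMMITTED)) {
    agent <- list(phenotype = world$phenotype[i],
                  state = world$states[i, ], alive = world$alive[i],
                  burst_left = world$burst_left[i],
                  burst_amt = world$burst_amt[i])
    out <- execute_committed(agent, cfg$k_deg, cfg$momp_ros_frac)
    world$states[i, ] <- out$agent$state
    world$alive[i] <- out$agent$alive
    world$burst_left[i] <- out$agent$burst_left
    if (out$deposits$cytc > 0) {
      cell <- world$pos[i]
      world$layers$cytc[cell] <- world$layers$cytc[cell] + out$deposits$cytc
      world$layers$ros[cell] <- world$layers$ros[cell] + out$deposits$ros
      cytc_step <- cytc_step + out$deposits$cytc
    }
  }

  # record
  world$cytc_cum <- world$cytc_cum + cytc_step
  alive <- world$alive
  world$ts[t, ] <- c(t,
                     sum(world$states[alive, "bnip3_av"]),
                     sum(world$states[alive, "casp3_a"]),
                     cytc_step, world$cytc_cum)
  world$traj_phase[t, ] <- world$phase
  world$traj_phen[t, ] <- world$phenotype
  world$traj_mito[t, ] <- ifelse(alive, world$states[, "bnip3_av"], 0)
  world$traj_apo[t, ] <- ifelse(alive, world$states[, "casp3_a"], 0)
  invisible(world)
}

#' Run one simulation
#'
#' Executes the configured number of agent-based steps (ending early once
#' every mitochondrion has committed and all MOMP bursts have finished)
#' and collects the population time series, per-agent trajectories and the
#' final phenotype census.
#'
#' @param config a [sim_config()].
#' @return a `mito_run` list: `census` (mitophagy / apoptosis /
#'   uncommitted counts), `timeseries` data frame (`step`,
#'   `total_mitophagy`, `total_apoptosis`, `cytc_step`, `cytc_cum`),
#'   `agents` trajectory matrices, `committed_step`, `time_to_phenotype`,
#'   per-agent seeds (`bax0`, `bcl20`, initial positions), the resolved
#'   `config` and its hash.
#' @export
run <- function(config) {
  if (!inherits(config, "sim_config")) config <- sim_config(config)
  world <- new_world(config)
  pos0 <- world$pos
  for (t in seq_len(config$steps)) {
    sim_step(world)
    if (all(world$phase == PHASE_COMMITTED) && all(world$burst_left == 0L))
      break
  }
  used <- world$t
  census <- c(mitophagy = sum(world$phase == PHASE_COMMITTED &
                                world$phenotype == PHEN_MITOPHAGY),
              apoptosis = sum(world$phase == PHASE_COMMITTED &
                                world$phenotype == PHEN_APOPTOSIS))
  census <- c(census, uncommitted = config$n - sum(census))
  structure(list(
    census = census,
    timeseries = as.data.frame(world$ts[seq_len(used), , drop = FALSE]),
    agents = list(phase = world$traj_phase[seq_len(used), , drop = FALSE],
                  phenotype = world$traj_phen[seq_len(used), , drop = FALSE],
                  mitophagy = world$traj_mito[seq_len(used), , drop = FALSE],
                  apoptosis = world$traj_apo[seq_len(used), , drop = FALSE]),
    committed_step = world$committed_step,
    time_to_phenotype = world$time_to_phenotype,
    final_states = world$states,
    final_alive = world$alive,
    seeds = list(bax0 = world$bax0, bcl20 = world$bcl20, pos0 = pos0),
    cytc_total = world$cytc_cum,
    steps_run = used,
    config = config,
    config_hash = config_hash(config)),
    class = "mito_run")
}

#' @export
print.mito_run <- function(x, ...) {
  cat("<mito_run> ", x$steps_run, " steps, census:",
      " mitophagy=", x$census[["mitophagy"]],
      " apoptosis=", x$census[["apoptosis"]],
      " uncommitted=", x$census[["uncommitted"]],
      ", total cytc released=", format(x$cytc_total, digits = 4), "\n",
      sep = "")
  invisible(x)
}

run_stats <- function(res) {
  ts <- res$timeseries
  early <- ts$total_mitophagy[ts$step <= 30]
  c(max_total_mitophagy = if (nrow(ts)) max(ts$total_mitophagy) else 0,
    max_total_mitophagy_30 = if (length(early)) max(early) else 0,
    census_mitophagy = unname(res$census[["mitophagy"]]),
    census_apoptosis = unname(res$census[["apoptosis"]]),
    census_uncommitted = unname(res$census[["uncommitted"]]),
    cytc_total = res$cytc_total)
}

#' Run an ensemble of simulations
#'
#' Repeats [run()] with seeds `seed, seed + 1, ...` (each run representing
#' one simulated cell) and summarizes across-run mean, standard deviation
#' and coefficient of variation of the maximal total mitophagy potential
#' (overall and within the first 30 steps), final census counts and total
#' cytochrome c release.
#'
#' @param config a [sim_config()]; its `seed` is the ensemble base seed.
#' @param n_runs ensemble size (50 in the standard protocol).
#' @param keep_runs keep full per-run results (memory-heavy); per-run
#'   summary statistics are always kept.
#' @return a `mito_ensemble` list with `stats` (runs x statistics matrix),
#'   `summary` data frame and optionally `runs`.
#' @export
run_ensemble <- function(config, n_runs = 50, keep_runs = FALSE) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (!inherits(config, "sim_config")) config <- sim_config(config)
  runs <- vector("list", n_runs)
  stats_mat <- NULL
  for (k in seq_len(n_runs)) {
    cfg_k <- config
    cfg_k$seed <- config$seed + k - 1L
    res <- run(cfg_k)
    st <- run_stats(res)
    if (is.null(stats_mat))
      stats_mat <- matrix(NA_real_, n_runs, length(st),
                          dimnames = list(NULL, names(st)))
    stats_mat[k, ] <- st
    if (keep_runs) runs[[k]] <- res
  }
  means <- colMeans(stats_mat)
  sds <- apply(stats_mat, 2, stats::sd)
  if (n_runs == 1) sds[] <- 0
  summary <- data.frame(statistic = colnames(stats_mat), mean = means,
                        sd = sds,
                        cv = ifelse(means > 0, sds / means, NA_real_),
                        row.names = NULL)
  structure(list(stats = stats_mat, summary = summary,
                 runs = if (keep_runs) runs else NULL,
                 n_runs = n_runs, config = config),
            class = "mito_ensemble")
}

#' @export
print.mito_ensemble <- function(x, ...) {
  cat("<mito_ensemble> ", x$n_runs, " runs\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

ensemble_mean <- function(ens, statistic) {
  ens$summary$mean[match(statistic, ens$summary$statistic)]
}
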