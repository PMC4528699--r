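#' Population specification
#'
#' Describes how the mitochondrial agent population is seeded: population
#' size, total Bnip3, Gaussian Bax/Bcl2 parameters (truncated at zero by
#' resampling), the LIR pre-activation fraction, and whether the organelles
#' are mobile.
#'
#' @param n number of mitochondria (<= 400, one per cell at seeding).
#' @param bnip3_level total Bnip3 per mitochondrion.
#' @param bax_mean,bax_sd Gaussian parameters for initial Bax.
#' @param bcl2_mean,bcl2_sd Gaussian parameters for initial Bcl2.
#' @param preactivated_fraction fraction of Bnip3 seeded active.
#' @param mobile whether mitochondria perform a random walk.
#' @return a `population_spec` list.
#' @export
population_spec <- function(n = 100, bnip3_level = 1, bax_mean = 1,
                            bax_sd = 0, bcl2_mean = 1, bcl2_sd = 0,
                            preactivated_fraction = 0.2, mobile = TRUE) {
  if (n < 1 || n > GRID_N^2)
    stop("population size must lie in [1, 400]")
  if (bax_sd < 0 || bcl2_sd < 0) stop("standard deviations must be >= 0")
  if (bax_mean < 0 || bcl2_mean < 0) stop("means must be >= 0")
  structure(list(n = as.integer(n), bnip3_level = bnip3_level,
                 bax_mean = bax_mean, bax_sd = bax_sd, bcl2_mean = bcl2_mean,
                 bcl2_sd = bcl2_sd,
                 preactivated_fraction = preactivated_fraction,
                 mobile = isTRUE(mobile)),
            class = "population_spec")
}

# Gaussian truncated at zero by resampling (protein levels are non-negative).
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < 0)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Seed the mitochondrial agent population
#'
#' Places `n` agents in distinct uniformly chosen lattice cells and draws
#' each agent's Bax and Bcl2 totals from the spec's truncated Gaussians.
#' All agents start in the naive phase with no provisional phenotype.
#'
#' @param spec a [population_spec()].
#' @return list with `pos` (linear cell indices), `states` (n x 11 species
#'   matrix), `bax0`/`bcl20` draws, and the per-agent bookkeeping vectors
#'   used by the engine (phase, phenotype, consecutive counter, alive flag).
#' @export
seed_population <- function(spec) {
  n <- spec$n
  pos <- sample.int(GRID_N^2, n)
  bax0 <- rtruncnorm0(n, spec$bax_mean, spec$bax_sd)
  bcl20 <- rtruncnorm0(n, spec$bcl2_mean, spec$bcl2_sd)
  states <- matrix(0, n, length(SPECIES),
                   dimnames = list(NULL, SPECIES))
  for (i in seq_len(n)) {
    states[i, ] <- initial_state(spec$bnip3_level, bcl20[i], bax0[i],
                                 spec$preactivated_fraction)
  }
  list(pos = pos, states = states, bax0 = bax0, bcl20 = bcl20,
       phase = rep(0L, n),        # 0 naive, 1 activation, 2 competition, 3 committed
       phenotype = rep(0L, n),    # 0 none, 1 mitophagy, 2 apoptosis
       consecutive = rep(0L, n),
       alive = rep(TRUE, n))
}

# von Neumann neighbors of a linear cell index on the 20 x 20 grid.
cell_neighbors <- function(cell) {
  row <- (cell - 1L) %% GRID_N + 1L
  col <- (cell - 1L) %/% GRID_N + 1L
  nb <- integer(0)
  if (row > 1L) nb <- c(nb, cell - 1L)
  if (row < GRID_N) nb <- c(nb, cell + 1L)
  if (col > 1L) nb <- c(nb, cell - GRID_N)
  if (col < GRID_N) nb <- c(nb, cell + GRID_N)
  nb
}

#' Move mitochondria one random-walk step
#'
#' Iterates the alive agents in a randomized order; each jumps to a
#' uniformly chosen unoccupied von Neumann neighbor, or stays put if all
#' neighbors are occupied. Volume exclusion (one agent per cell) is
#' maintained by updating occupancy atomically per agent.
#'
#' @param pos linear cell indices of all agents.
#' @param alive logical vector; dead (degraded) agents do not move or block.
#' @return updated position vector.
#' @export
move_agents <- function(pos, alive) {
  occupied <- logical(GRID_N^2)
  occupied[pos[alive]] <- TRUE
  order <- sample(which(alive))
  for (i in order) {
    nb <- cell_neighbors(pos[i])
    free <- nb[!occupied[nb]]
    if (length(free) > 0) {
      new <- if (length(free) == 1) free else free[sample.int(length(free), 1)]
      occupied[pos[i]] <- FALSE
      occupied[new] <- TRUE
      pos[i] <- new
    }
  }
  pos
}

# Random walk of AV layer content: each nonzero cell's content jumps to a
# uniformly chosen von Neumann neighbor. Mass-conserving.
move_av_layer <- function(layer) {
  new <- matrix(0, GRID_N, GRID_N)
  cells <- which(layer > 0)
  for (cell in cells) {
    nb <- cell_neighbors(cell)
    dest <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
    new[dest] <- new[dest] + layer[cell]
  }
  new
}
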