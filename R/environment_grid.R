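GRID_N <- 20L

#' Build an autophagosome (AV) layer
#'
#' Distributes a total AV level over the 20 x 20 lattice in one of three
#' spatial modes. `random` places one unit AV in each of `total` distinct
#' uniformly chosen cells, so an AV level of N covers N/400 of the cell
#' area (75 approximates 20 % coverage). `homogeneous` spreads the total
#' equally over all 400 cells. `radial` concentrates the total equally over
#' the annulus of cells whose center distance from the grid center lies in
#' `[radius - ring_width, radius]`, mimicking peri-nuclear versus peripheral
#' autophagosome localization.
#'
#' @param mode `"random"`, `"homogeneous"` or `"radial"`.
#' @param total total AV level (integer and <= 400 in random mode).
#' @param radius ring radius in cells (radial mode, <= 10).
#' @param ring_width annulus thickness in cells.
#' @return 20 x 20 non-negative matrix summing to `total`.
#' @export
build_av_layer <- function(mode = c("random", "homogeneous", "radial"),
                           total = 75, radius = 6, ring_width = 1) {
  mode <- match.arg(mode)
  if (total < 0) stop("total AV level must be >= 0")
  layer <- matrix(0, GRID_N, GRID_N)
  if (mode == "random") {
    if (abs(total - round(total)) > 1e-9)
      stop("random AV placement requires an integer total (one unit per cell)")
    total <- round(total)
    if (total > GRID_N^2)
      stop("random AV placement cannot exceed 400 units (one per cell)")
    cells <- sample.int(GRID_N^2, total)
    layer[cells] <- 1
  } else if (mode == "homogeneous") {
    layer[] <- total / GRID_N^2
  } else {
    if (radius < 0 || radius > GRID_N / 2)
      stop("ring radius must lie in [0, 10] cells")
    ring <- ring_cells(radius, ring_width)
    if (length(ring) == 0)
      stop("radial ring of radius ", radius, ", width ", ring_width,
           " contains no cells")
    layer[ring] <- total / length(ring)
  }
  layer
}

# Linear indices of cells whose center distance from the grid center falls
# in [radius - ring_width, radius]. Cell centers at (i - 0.5, j - 0.5),
# grid center at (10, 10).
ring_cells <- function(radius, ring_width) {
  ctr <- GRID_N / 2
  idx <- expand.grid(row = seq_len(GRID_N), col = seq_len(GRID_N))
  d <- sqrt((idx$row - 0.5 - ctr)^2 + (idx$col - 0.5 - ctr)^2)
  which(d >= radius - ring_width & d <= radius)
}

#' Nearest-neighbor diffusion on the closed lattice
#'
#' Symmetric per-edge exchange: every cell sends `fraction / 4` of its
#' content across each of its existing von Neumann edges (an interior cell
#' therefore exports `fraction` in total; edge and corner cells export
#' proportionally less over their 3 or 2 edges). The boundary is no-flux -
#' nothing leaves the cell perimeter - total mass is conserved exactly,
#' and a uniform field is a fixed point.
#'
#' @param layer 20 x 20 matrix.
#' @param fraction per-step diffusion fraction in \[0, 1\].
#' @return diffused matrix.
#' @export
diffuse <- function(layer, fraction) {
  if (fraction < 0 || fraction > 1)
    stop("diffusion fraction must lie in [0, 1]")
  if (fraction == 0) return(layer)
  n <- nrow(layer)
  share <- fraction * layer / 4    # flux along one edge
  new <- layer
  new[-1, ] <- new[-1, ] + share[-n, ] - share[-1, ]   # vertical exchange
  new[-n, ] <- new[-n, ] + share[-1, ] - share[-n, ]
  new[, -1] <- new[, -1] + share[, -n] - share[, -1]   # horizontal exchange
  new[, -n] <- new[, -n] + share[, -1] - share[, -n]
  new
}

#' Update the ROS layer for one environmental step
#'
#' Applies first-order degradation (superoxide dismutase proxy,
#' `1 - k_sod`), then adds the constant non-mitochondrial production
#' `k_ros_env` to every cell and any mitochondrial deposits at their
#' positions, then diffuses. With no deposits the uniform fixed point is
#' `k_ros_env / k_sod`.
#'
#' @param layer 20 x 20 ROS matrix.
#' @param params list with `k_ros_env`, `k_sod`, `d_ros`.
#' @param deposits optional list of `list(cell = linear index, amount)`.
#' @return updated matrix.
#' @export
update_ros <- function(layer, params, deposits = list()) {
  layer <- layer * (1 - params$k_sod)
  layer <- layer + params$k_ros_env
  for (d in deposits) {
    if (d$amount < 0) stop("ROS deposits must be >= 0")
    layer[d$cell] <- layer[d$cell] + d$amount
  }
  diffuse(layer, params$d_ros)
}

#' Apply the tBid activation schedule
#'
#' During the ramp (`step` in `[tbid_start, tbid_start + tbid_steps)`) adds
#' `tbid_rate` to every cell, capped at `tbid_cap`; outside the ramp the
#' layer is left alone. The layer then diffuses (a no-op while spatially
#' uniform). The standard schedule adds 0.25 per step for 4 steps from
#' t = 5, reaching the model tBid level of 0.9.
#'
#' @param layer 20 x 20 tBid matrix.
#' @param step zero-based ABM step index.
#' @param params list with `tbid_start`, `tbid_rate`, `tbid_steps`,
#'   `tbid_cap`, `d_tbid`.
#' @return updated matrix.
#' @export
apply_tbid <- function(layer, step, params) {
  if (step < 0) stop("step must be >= 0")
  if (is.finite(params$tbid_start) &&
      step >= params$tbid_start &&
      step < params$tbid_start + params$tbid_steps) {
    layer <- pmin(layer + params$tbid_rate, params$tbid_cap)
  }
  diffuse(layer, params$d_tbid)
}

#' Read the local environment at one cell
#'
#' A mitochondrion interacts only with its current cell; this returns the
#' ROS, AV and tBid levels there.
#'
#' @param layers list with `ros`, `av`, `tbid` matrices.
#' @param cell linear cell index (1..400) or `c(row, col)`.
#' @return list with `ros`, `av`, `tbid`.
#' @export
sample_local <- function(layers, cell) {
  cell <- as_cell_index(cell)
  list(ros = layers$ros[cell], av = layers$av[cell], tbid = layers$tbid[cell])
}

#' Deposit to (or withdraw from) one cell of a layer
#'
#' Negative amounts are withdrawals floored at zero; the attribute
#' `withdrawn` on the result reports the amount actually removed.
#'
#' @param layer 20 x 20 matrix.
#' @param cell linear cell index or `c(row, col)`.
#' @param amount level to add (negative to withdraw).
#' @return updated matrix with attribute `withdrawn`.
#' @export
deposit <- function(layer, cell, amount) {
  cell <- as_cell_index(cell)
  old <- layer[cell]
  new <- max(0, old + amount)
  layer[cell] <- new
  attr(layer, "withdrawn") <- if (amount < 0) old - new else 0
  layer
}

as_cell_index <- function(cell) {
  if (length(cell) == 2) {
    if (any(cell < 1) || any(cell > GRID_N)) stop("cell is off the grid")
    return((cell[2] - 1L) * GRID_N + cell[1])
  }
  if (cell < 1 || cell > GRID_N^2) stop("cell is off the grid")
  as.integer(cell)
}
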