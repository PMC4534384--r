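# Shared plumbing for the rate-based network models: grid input arrives as
# a phase-binned population rate vector per axis. A bin pools every grid
# cell in a module that shares the given phase on that axis (the 2D
# extension of the models), so its tuning is the hexagonal rate map
# marginalised over the orthogonal axis: (cos(p - phi) + 1.5) / 4.5.

axis_marginal_rate <- function(p, phi) (cos(p - phi) + 1.5) / 4.5

# Phase-bin centres for every module along one axis.
axis_bins <- function(sys) {
  purrr::map_dfr(seq_len(nrow(sys)), function(i) {
    m <- sys$cells_per_axis[i]
    tibble(module = sys$module[i], bin = seq_len(m),
           phi = TWO_PI * (seq_len(m) - 1) / m)
  })
}

# Population rate vector for a phase code along one axis.
axis_population <- function(code, sys, axis, bins = axis_bins(sys)) {
  code <- check_code(code, sys)
  p <- code[[c("p_x", "p_y")[axis]]]
  axis_marginal_rate(p[bins$module], bins$phi)
}

#' Build a distance-cell array
#'
#' One array decodes absolute position along a single grid axis: one
#' distance cell per preferred location on `[0, C)` at resolution `delta`
#' (so `C / delta` cells, bounded by the system capacity), each receiving
#' input from every phase-binned grid cell with synaptic weight equal to
#' that cell's mean rate at the preferred location, row-normalised to a
#' maximum of 1. Winner-take-all competition then makes the array report
#' the encoded position.
#'
#' @param sys a [grid_system()] with shared axes.
#' @param axis axis index (1 or 2).
#' @param resolution preferred-location spacing `delta` in cm; must divide
#'   the capacity. Default `s_M / 4`.
#' @return object of class `distance_cell_array`.
#' @export
build_distance_cells <- function(sys, axis = 1,
                                 resolution = min(sys$scale_cm) / 4) {
  C <- system_period(sys, axis = axis)
  if (!is.finite(C)) {
    abort("infinite capacity; configure rationally related scales")
  }
  n_cells <- C / resolution
  if (abs(n_cells - round(n_cells)) > 1e-9) {
    abort("resolution must divide the system capacity")
  }
  n_cells <- round(n_cells)
  preferred <- (seq_len(n_cells) - 1) * resolution
  bins <- axis_bins(sys)
  s <- axis_scales(sys, axis)
  # phase of each preferred location in each module on this axis
  p_loc <- outer(preferred, s, function(d, si) wrap_2pi(TWO_PI * (d %% si) / si))
  W <- axis_marginal_rate(p_loc[, bins$module, drop = FALSE],
                          matrix(bins$phi, n_cells, nrow(bins), byrow = TRUE))
  W <- W / apply(W, 1, max)
  structure(
    list(sys = sys, axis = axis, resolution = resolution, capacity = C,
         preferred_cm = preferred, weights = W, bins = bins),
    class = "distance_cell_array"
  )
}

#' @export
print.distance_cell_array <- function(x, ...) {
  cat(sprintf(
    "<distance_cell_array> axis %d: %d cells on [0, %g) cm at %g cm\n",
    x$axis, length(x$preferred_cm), x$capacity, x$resolution))
  invisible(x)
}

#' Tidy a distance-cell array
#'
#' @param x a `distance_cell_array`.
#' @param ... unused.
#' @return long tibble of synaptic weights: `preferred_cm`, `module`,
#'   `bin`, `phi`, `weight`.
#' @exportS3Method
tidy.distance_cell_array <- function(x, ...) {
  tidyr::expand_grid(
    preferred_cm = x$preferred_cm,
    x$bins
  ) |>
    mutate(weight = as.vector(t(x$weights)))
}

#' Winner-take-all activation of a distance-cell array
#'
#' Net input to each distance cell is the dot product of its weights with
#' the grid population rates for the code; the winner is the argmax (ties
#' broken towards the smallest preferred location) and all other cells are
#' silenced.
#'
#' @param arr a [build_distance_cells()] array.
#' @param code a `phase_code` for a single location.
#' @return one-row tibble: `winner` (cell index), `preferred_cm`, `rate`,
#'   `success`.
#' @export
activate_wta <- function(arr, code) {
  rates <- axis_population(code, arr$sys, arr$axis, arr$bins)
  input <- as.vector(arr$weights %*% rates)
  if (all(input <= 0)) {
    return(tibble(winner = NA_integer_, preferred_cm = NA_real_,
                  rate = 0, success = FALSE))
  }
  w <- which.max(input)   # first max = smallest preferred location
  tibble(winner = w, preferred_cm = arr$preferred_cm[w],
         rate = input[w], success = TRUE)
}

#' Read out a signed displacement from two distance-cell arrays
#'
#' The current- and goal-location arrays both project to a "move up" and a
#' "move down" readout neuron with weights increasing linearly in opposite
#' directions along the axis (`l / C` up-weight and `(C - l) / C`
#' down-weight for the goal array, roles swapped for the current array).
#' The rate difference `up - down` is then `2 * (goal - current) / C`, an
#' affine function of the displacement, inverted and wrapped to the signed
#' range `[-C/2, C/2)`.
#'
#' @param arr_current,arr_goal arrays from [build_distance_cells()] on the
#'   same axis.
#' @param code_a,code_b phase codes of the current and goal locations.
#' @return one-row tibble: `d_cm`, `up_rate`, `down_rate`, `success`.
#' @export
readout_displacement <- function(arr_current, arr_goal, code_a, code_b) {
  stopifnot(arr_current$axis == arr_goal$axis)
  C <- arr_current$capacity
  cur <- activate_wta(arr_current, code_a)
  gol <- activate_wta(arr_goal, code_b)
  if (!cur$success || !gol$success) {
    return(tibble(d_cm = NA_real_, up_rate = NA_real_,
                  down_rate = NA_real_, success = FALSE))
  }
  up <- gol$preferred_cm / C + (C - cur$preferred_cm) / C
  down <- (C - gol$preferred_cm) / C + cur$preferred_cm / C
  d <- wrap_signed((up - down) * C / 2, C)
  tibble(d_cm = d, up_rate = up, down_rate = down, success = TRUE)
}

#' Decode a 2D translation vector with distance cells
#'
#' Runs [readout_displacement()] on each principal axis (current and goal
#' arrays per axis) and assembles the components into a translation
#' vector. Exact to the array resolution for noise-free codes.
#'
#' @param code_a,code_b phase codes of current and goal locations.
#' @param sys a [grid_system()] with shared axes.
#' @param resolution array resolution in cm (default `s_M / 4`).
#' @param arrays optional prebuilt list `list(axis1, axis2)` of
#'   distance-cell arrays, to amortise construction over many decodes.
#' @return one-row tibble of class `decode_report`: `d_axis1_cm`,
#'   `d_axis2_cm`, `dx_cm`, `dy_cm`, `success`.
#' @export
decode_distance_cells <- function(code_a, code_b, sys,
                                  resolution = min(sys$scale_cm) / 4,
                                  arrays = NULL) {
  if (!shared_axes(sys)) abort("distance-cell decoding requires shared axes")
  if (is.null(arrays)) {
    arrays <- list(build_distance_cells(sys, 1, resolution),
                   build_distance_cells(sys, 2, resolution))
  }
  r1 <- readout_displacement(arrays[[1]], arrays[[1]], code_a, code_b)
  r2 <- readout_displacement(arrays[[2]], arrays[[2]], code_a, code_b)
  if (!r1$success || !r2$success) {
    out <- tibble(d_axis1_cm = NA_real_, d_axis2_cm = NA_real_,
                  dx_cm = NA_real_, dy_cm = NA_real_, success = FALSE)
  } else {
    out <- translation_vector(r1$d_cm, r2$d_cm, sys)
    out$success <- TRUE
  }
  class(out) <- c("decode_report", class(out))
  out
}
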