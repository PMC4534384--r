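#' Define a grid-cell system
#'
#' A grid system is an ordered set of grid modules, largest spatial scale
#' first. Each module is a population of grid cells sharing a hexagonal
#' firing lattice of scale `scale_cm`; position within one lattice tile is
#' expressed as a pair of spatial phases in `[0, 2*pi)` along two
#' non-collinear principal axes of the pattern (separated by `pi/3` for a
#' regular hexagonal grid, so that the scale is equal along both).
#'
#' @param scales_cm numeric vector of module scales in cm, non-increasing.
#' @param orientation angle of the first principal axis in radians
#'   (recycled across modules).
#' @param axis_separation angle between the two principal axes in radians,
#'   in `(0, pi)`; default `pi/3`.
#' @param ellipticity ratio of the scale along axis 2 to axis 1; default 1
#'   (circularly symmetric fields).
#' @param cells_per_axis number of phase bins per axis used by the network
#'   models (the module's sheet is `cells_per_axis^2` cells); default 32.
#' @return a tibble of class `grid_system`, one row per module, with columns
#'   `module`, `scale_cm`, `orientation`, `axis_separation`, `ellipticity`,
#'   `cells_per_axis`.
#' @examples
#' sys <- grid_system(c(50, 30, 20))
#' encode_location(c(75, 0), sys)
#' @export
grid_system <- function(scales_cm, orientation = 0, axis_separation = pi / 3,
                        ellipticity = 1, cells_per_axis = 32) {
  if (length(scales_cm) < 1) abort("at least one module is required")
  if (any(!is.finite(scales_cm)) || any(scales_cm <= 0)) {
    abort("module scales must be positive and finite")
  }
  if (any(diff(scales_cm) > 0)) {
    abort("module scales must be ordered largest first (non-increasing)")
  }
  sys <- tibble(
    module = seq_along(scales_cm),
    scale_cm = as.numeric(scales_cm),
    orientation = rep_len(as.numeric(orientation), length(scales_cm)),
    axis_separation = rep_len(as.numeric(axis_separation), length(scales_cm)),
    ellipticity = rep_len(as.numeric(ellipticity), length(scales_cm)),
    cells_per_axis = rep_len(as.integer(cells_per_axis), length(scales_cm))
  )
  if (any(sys$axis_separation <= 0 | sys$axis_separation >= pi)) {
    abort("axis_separation must lie strictly between 0 and pi")
  }
  if (any(sys$ellipticity <= 0)) abort("ellipticity must be positive")
  if (any(sys$cells_per_axis < 2)) abort("cells_per_axis must be at least 2")
  class(sys) <- c("grid_system", class(sys))
  sys
}

#' Do all modules share their axes?
#'
#' TRUE when every module has the same orientation and axis separation (to
#' 1e-12 rad), in which case 2D decoding decomposes into two independent
#' 1D problems along the shared axes.
#'
#' @param sys a `grid_system`.
#' @return logical scalar.
#' @export
shared_axes <- function(sys) {
  all(abs(sys$orientation - sys$orientation[1]) < 1e-12) &&
    all(abs(sys$axis_separation - sys$axis_separation[1]) < 1e-12)
}

#' Axis basis matrix of a module (or shared system)
#'
#' Columns are the unit vectors of the two principal axes in the world
#' frame. The basis is generally non-orthogonal.
#'
#' @param orientation,axis_separation angles in radians.
#' @return 2x2 matrix with the axis unit vectors as columns.
#' @export
axis_basis <- function(orientation, axis_separation = pi / 3) {
  if (abs(sin(axis_separation)) < 1e-12) {
    abort("grid axes are collinear; cannot form a basis")
  }
  cbind(
    c(cos(orientation), sin(orientation)),
    c(cos(orientation + axis_separation), sin(orientation + axis_separation))
  )
}

# Effective per-axis scale of each module: ellipticity multiplies axis 2.
axis_scales <- function(sys, axis) {
  if (axis == 1) sys$scale_cm else sys$scale_cm * sys$ellipticity
}

# Coerce a location argument to a tibble with id, x_cm, y_cm.
as_locations <- function(loc) {
  if (is.numeric(loc)) {
    if (length(loc) == 1) loc <- c(loc, 0)
    stopifnot(length(loc) == 2)
    loc <- tibble(x_cm = loc[1], y_cm = loc[2])
  }
  loc <- as_tibble(loc)
  if (!all(c("x_cm", "y_cm") %in% names(loc))) {
    abort("locations need columns x_cm and y_cm")
  }
  if (!all(is.finite(loc$x_cm)) || !all(is.finite(loc$y_cm))) {
    abort("locations must be finite")
  }
  if (!"id" %in% names(loc)) loc$id <- seq_len(nrow(loc))
  loc[, c("id", "x_cm", "y_cm")]
}

#' Project world locations onto the grid axes
#'
#' Expresses each location as `u * xhat + v * yhat` where `xhat`, `yhat`
#' are the (non-orthogonal) axis unit vectors: an exact linear solve of the
#' 2x2 basis system. Requires all modules to share axes; with per-module
#' axes the same projection is applied inside [encode_location()] per
#' module.
#'
#' @param locations data frame with columns `x_cm`, `y_cm` (and optional
#'   `id`), or a numeric `c(x, y)`.
#' @param sys a `grid_system` with shared axes.
#' @return tibble with columns `id`, `u_cm`, `v_cm` (coordinates along
#'   axes 1 and 2).
#' @export
project_onto_axes <- function(locations, sys) {
  if (!shared_axes(sys)) {
    abort("project_onto_axes requires a system with shared axes")
  }
  loc <- as_locations(locations)
  B <- axis_basis(sys$orientation[1], sys$axis_separation[1])
  uv <- solve(B, rbind(loc$x_cm, loc$y_cm))
  tibble(id = loc$id, u_cm = uv[1, ], v_cm = uv[2, ])
}

#' Encode locations as modular phase codes
#'
#' The forward model: each module represents a location by its residue
#' within one grid tile, as a phase pair. Along axis j of module i with
#' effective scale s (axis 2 is scaled by the module's ellipticity),
#' `p = 2*pi * (coord mod s) / s`, wrapped to `[0, 2*pi)`. The phase origin
#' of every module is the world origin, so the code of the origin is all
#' zeros and the code is periodic with period s along each axis.
#'
#' @inheritParams project_onto_axes
#' @param sys a `grid_system`.
#' @return tibble of class `phase_code` with columns `id`, `module`,
#'   `p_x`, `p_y` (one row per location per module; phases in radians).
#' @examples
#' sys <- grid_system(c(50, 30, 20))
#' encode_location(c(75, 0), sys)  # phases pi, pi, 3*pi/2 on axis 1
#' @export
encode_location <- function(locations, sys) {
  loc <- as_locations(locations)
  code <- purrr::map_dfr(seq_len(nrow(sys)), function(i) {
    B <- axis_basis(sys$orientation[i], sys$axis_separation[i])
    uv <- solve(B, rbind(loc$x_cm, loc$y_cm))
    sx <- axis_scales(sys, 1)[i]
    sy <- axis_scales(sys, 2)[i]
    tibble(
      id = loc$id,
      module = sys$module[i],
      p_x = wrap_2pi(TWO_PI * (uv[1, ] %% sx) / sx),
      p_y = wrap_2pi(TWO_PI * (uv[2, ] %% sy) / sy)
    )
  })
  code <- arrange(code, .data$id, .data$module)
  class(code) <- c("phase_code", class(code))
  code
}

# Validate a single-location phase code against a system.
check_code <- function(code, sys, arg = "code") {
  code <- as_tibble(code)
  if (!all(c("module", "p_x", "p_y") %in% names(code))) {
    abort(paste0(arg, " needs columns module, p_x, p_y"))
  }
  if ("id" %in% names(code) && length(unique(code$id)) > 1) {
    abort(paste0(arg, " must encode a single location"))
  }
  code <- arrange(code, .data$module)
  if (!identical(as.integer(code$module), as.integer(sys$module))) {
    abort(paste0(arg, " modules do not match the system"))
  }
  code
}

#' Build a phase code from raw phase values
#'
#' Convenience constructor used when phases are given directly (e.g. a
#' published worked example) rather than computed from a location.
#'
#' @param p_x,p_y numeric vectors of per-module phases in radians (wrapped
#'   to `[0, 2*pi)`); one entry per module, largest scale first.
#' @return tibble of class `phase_code`.
#' @export
phase_code <- function(p_x, p_y = rep(0, length(p_x))) {
  stopifnot(length(p_x) == length(p_y))
  code <- tibble(
    id = 1L, module = seq_along(p_x),
    p_x = wrap_2pi(p_x), p_y = wrap_2pi(p_y)
  )
  class(code) <- c("phase_code", class(code))
  code
}

#' Phase difference between two encoded locations
#'
#' Per module and axis, `dp = (p(b) - p(a)) mod 2*pi`. The result depends
#' only on the displacement `b - a`, not on the individual locations: the
#' quantity every decoder in this package consumes.
#'
#' @param code_a,code_b single-location `phase_code` tibbles from the same
#'   system (current and goal locations).
#' @return tibble of class `phase_diff` with columns `module`, `dp_x`,
#'   `dp_y`.
#' @export
phase_difference <- function(code_a, code_b) {
  a <- arrange(as_tibble(code_a), .data$module)
  b <- arrange(as_tibble(code_b), .data$module)
  if (nrow(a) != nrow(b) || !identical(as.integer(a$module), as.integer(b$module))) {
    abort("phase codes come from systems with different modules")
  }
  dp <- tibble(
    module = a$module,
    dp_x = wrap_2pi(b$p_x - a$p_x),
    dp_y = wrap_2pi(b$p_y - a$p_y)
  )
  class(dp) <- c("phase_diff", class(dp))
  dp
}

#' Build a phase difference from raw values
#'
#' @param dp_x,dp_y numeric vectors of per-module phase differences in
#'   radians, largest scale first; wrapped to `[0, 2*pi)`.
#' @return tibble of class `phase_diff`.
#' @export
phase_diff <- function(dp_x, dp_y = rep(0, length(dp_x))) {
  stopifnot(length(dp_x) == length(dp_y))
  dp <- tibble(
    module = seq_along(dp_x),
    dp_x = wrap_2pi(dp_x), dp_y = wrap_2pi(dp_y)
  )
  class(dp) <- c("phase_diff", class(dp))
  dp
}

#' Hexagonal firing-rate map of one grid cell
#'
#' Three-cosine model: the sum of cosines over the three reciprocal-lattice
#' wave vectors of the module's firing lattice, shifted by the cell's phase
#' offset and affinely rescaled so the rate lies in `[0, 1]` with maxima
#' (exactly 1) at the cell's field centres. For the regular hexagonal case
#' the minimum (0) sits at the centroids of three adjacent fields.
#'
#' @param cell_phase_offset numeric pair: the cell's phase offset
#'   `(off_x, off_y)` in radians along the two axes.
#' @param locations locations to evaluate (as in [encode_location()]).
#' @param module one-row slice of a `grid_system` (a single module).
#' @return numeric vector of rates in `[0, 1]`, one per location.
#' @export
rate_map <- function(cell_phase_offset, locations, module) {
  stopifnot(length(cell_phase_offset) == 2, nrow(module) == 1)
  loc <- as_locations(locations)
  B <- axis_basis(module$orientation, module$axis_separation)
  a1 <- module$scale_cm * B[, 1]
  a2 <- module$scale_cm * module$ellipticity * B[, 2]
  # reciprocal basis: b_i . a_j = 2*pi * delta_ij
  Binv <- solve(cbind(a1, a2))      # rows are b_i / 2*pi
  k1 <- TWO_PI * Binv[1, ]
  k2 <- TWO_PI * Binv[2, ]
  k3 <- -(k1 + k2)
  r0 <- (cell_phase_offset[1] / TWO_PI) * a1 +
    (cell_phase_offset[2] / TWO_PI) * a2
  dx <- loc$x_cm - r0[1]
  dy <- loc$y_cm - r0[2]
  s <- cos(k1[1] * dx + k1[2] * dy) +
    cos(k2[1] * dx + k2[2] * dy) +
    cos(k3[1] * dx + k3[2] * dy)
  (s + 1.5) / 4.5
}

#' Population activity of a module's phase sheet
#'
#' Evaluates [rate_map()] for every cell on the module's uniform
#' `cells_per_axis` x `cells_per_axis` sheet of phase offsets over the unit
#' tile: a single activity bump whose peak cell has the phase offset that
#' [encode_location()] assigns to the location.
#'
#' @param locations a single location (as in [encode_location()]).
#' @param module one-row slice of a `grid_system`.
#' @return tibble with columns `cell`, `off_x`, `off_y` (the cell's phase
#'   offset in radians) and `rate`.
#' @export
population_activity <- function(locations, module) {
  stopifnot(nrow(module) == 1)
  m <- module$cells_per_axis
  offs <- TWO_PI * (seq_len(m) - 1) / m
  grid <- tidyr::expand_grid(off_x = offs, off_y = offs)
  loc <- as_locations(locations)
  if (nrow(loc) != 1) abort("population_activity takes a single location")
  rate <- vapply(
    seq_len(nrow(grid)),
    function(i) rate_map(c(grid$off_x[i], grid$off_y[i]), loc, module),
    numeric(1)
  )
  tibble(cell = seq_len(nrow(grid)), off_x = grid$off_x,
         off_y = grid$off_y, rate = rate)
}

#' Read a grid-system configuration file
#'
#' YAML with a `modules` list (`scale_cm`, optional `orientation_rad`,
#' `cells_per_axis`, `ellipticity`), optional `axis_separation_rad` and
#' `seed`.
#'
#' @param path path to the YAML file.
#' @return list with elements `system` (a [grid_system()]) and `seed`.
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$modules)) abort("config has no 'modules' entry")
  sep <- cfg$axis_separation_rad %||% (pi / 3)
  get <- function(field, default) {
    vapply(cfg$modules, function(m) as.numeric(m[[field]] %||% default),
           numeric(1))
  }
  sys <- grid_system(
    scales_cm = get("scale_cm", NA_real_),
    orientation = get("orientation_rad", 0),
    axis_separation = sep,
    ellipticity = get("ellipticity", 1),
    cells_per_axis = get("cells_per_axis", 32)
  )
  list(system = sys, seed = cfg$seed %||% NULL)
}

#' Read a locations table
#'
#' CSV with header `id,x_cm,y_cm`.
#'
#' @param path path to the CSV file.
#' @return tibble with columns `id`, `x_cm`, `y_cm`.
#' @export
read_locations <- function(path) {
  loc <- readr::read_csv(path, show_col_types = FALSE)
  as_locations(loc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
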