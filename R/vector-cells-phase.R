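#' Theta firing phase of a goal-coding grid cell
#'
#' Idealised axis-aligned phase precession: a grid cell's theta firing
#' phase is a linear function of its field's spatial phase offset from the
#' current location, spanning the full theta cycle over one grid tile
#' (pi rad at field entry, 0 at the field centre, -pi at the exit). Cells
#' coding the current location fire at the theta trough (0 rad); a goal
#' less than half a scale ahead fires at a later (positive) phase. The
#' mapping is the identity on the wrapped circle: `dp` in `[0, 2*pi)`
#' re-expressed on `(-pi, pi]`.
#'
#' @param dp_axis spatial phase difference(s) of the goal from the current
#'   location along the precession axis, radians in `[0, 2*pi)`.
#' @param module unused (the mapping is scale-free); kept so callers can
#'   map over modules.
#' @return theta phase(s) in `(-pi, pi]`.
#' @examples
#' precession_phase(c(0, pi))  # 0 and pi: a goal one large-scale ahead
#' @export
precession_phase <- function(dp_axis, module = NULL) {
  wrap_pi(wrap_2pi(dp_axis))
}

#' Spikes emitted in one theta cycle by goal-coding grid cells
#'
#' For each designated goal, the grid cells encoding it fire once per
#' module per theta cycle, at the theta phase given by
#' [precession_phase()] of their spatial phase difference from the current
#' location on the precession axis. Several goals coexist in one cycle
#' with distinct phase patterns; spikes carry an explicit goal tag.
#'
#' @param sys a [grid_system()].
#' @param code_a phase code of the current location.
#' @param goal_codes a single `phase_code` or a list of them, one per
#'   active goal.
#' @param axis precession axis (1 or 2).
#' @return tibble of spikes: `goal_id`, `module`, `axis`,
#'   `theta_phase_rad`.
#' @export
emit_theta_cycle <- function(sys, code_a, goal_codes, axis = 1) {
  if (inherits(goal_codes, "phase_code")) goal_codes <- list(goal_codes)
  purrr::map_dfr(seq_along(goal_codes), function(g) {
    dp <- phase_difference(code_a, goal_codes[[g]])
    dpv <- dp[[c("dp_x", "dp_y")[axis]]]
    tibble(goal_id = g, module = dp$module, axis = axis,
           theta_phase_rad = precession_phase(dpv))
  })
}

#' Decode displacements from a theta-cycle phase pattern
#'
#' A bank of template vector cells, one per displacement bin on
#' `(-C/2, C/2]`, each sensitive to the pattern of theta firing phases
#' across modules that its displacement produces
#' (`wrap(2*pi*d/s_i)` per module). Each goal's observed phase vector is
#' matched by summed squared circular distance; the best template wins,
#' ties and near-ties (a second template within `ambiguity_tol`) go to the
#' smaller absolute displacement and are flagged.
#'
#' @param spikes spike tibble from [emit_theta_cycle()].
#' @param sys a [grid_system()].
#' @param axis precession axis the spikes refer to.
#' @param resolution template spacing in cm (default `s_M / 4`).
#' @param ambiguity_tol score gap (rad^2) under which a match is flagged
#'   ambiguous.
#' @return tibble, one row per goal: `goal_id`, `d_cm`, `score`,
#'   `ambiguous`.
#' @export
phase_template_decode <- function(spikes, sys, axis = 1,
                                  resolution = min(sys$scale_cm) / 4,
                                  ambiguity_tol = 1e-9) {
  C <- system_period(sys, axis = axis)
  s <- axis_scales(sys, axis)
  # templates span (-C/2, C/2]: at the boundary, where +C/2 and -C/2 are
  # indistinguishable, the forward (positive) displacement is reported
  d_grid <- seq(-C / 2 + resolution, C / 2, by = resolution)
  ord <- order(abs(d_grid), -d_grid)
  d_grid <- d_grid[ord]
  templates <- vapply(d_grid, function(d) wrap_pi(TWO_PI * d / s),
                      numeric(nrow(sys)))   # M x n_templates
  if (!is.matrix(templates)) templates <- matrix(templates, nrow = 1)
  purrr::map_dfr(split(spikes, spikes$goal_id), function(sp) {
    sp <- arrange(sp, .data$module)
    stopifnot(nrow(sp) == nrow(sys))
    score <- colSums(circ_dist(templates, sp$theta_phase_rad)^2)
    w <- which.min(score)   # d_grid ordered by |d|: first min = smaller |d|
    near <- sum(score <= score[w] + ambiguity_tol)
    tibble(goal_id = sp$goal_id[1], d_cm = d_grid[w], score = score[w],
           ambiguous = near > 1)
  })
}

#' Decode a 2D translation vector with phase-coded vector cells
#'
#' Two grid populations precess along the two principal axes; each axis'
#' theta-phase pattern is template-decoded independently and the
#' components assembled into a translation vector.
#'
#' @inheritParams decode_distance_cells
#' @return one-row tibble of class `decode_report`.
#' @export
decode_phase_cells <- function(code_a, code_b, sys,
                               resolution = min(sys$scale_cm) / 4) {
  if (!shared_axes(sys)) abort("phase-cell decoding requires shared axes")
  res <- lapply(1:2, function(axis) {
    spikes <- emit_theta_cycle(sys, code_a, code_b, axis = axis)
    phase_template_decode(spikes, sys, axis = axis, resolution = resolution)
  })
  out <- translation_vector(res[[1]]$d_cm, res[[2]]$d_cm, sys)
  out$success <- !res[[1]]$ambiguous && !res[[2]]$ambiguous
  class(out) <- c("decode_report", class(out))
  out
}
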