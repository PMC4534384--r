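#' Linear look-ahead sweep along one axis
#'
#' Simulated constant-speed movement decoupled from real motion: starting
#' from the current phase code, every module's phase on the chosen axis is
#' advanced by `2*pi * step_size / s_i` per step (faster for smaller
#' scales), and after each step the swept code is compared with the target
#' code. Coincidence -- simultaneous activity in the grid cells encoding
#' the target in every module -- is declared when the largest circular
#' phase error across modules falls below `tol`; the number of steps to
#' first coincidence (equivalently, the integrated readout activity) is
#' proportional to the distance swept. Phases on the other axis are
#' untouched: a sweep activates "bands" of cells sharing the swept-axis
#' phase.
#'
#' @param code_start,code_target phase codes of the start and target
#'   locations.
#' @param sys a [grid_system()].
#' @param axis axis index (1 or 2).
#' @param direction +1 or -1.
#' @param step_size step in cm; at most `s_M / 8` so no module's phase
#'   advances more than pi/4 per step.
#' @param max_distance sweep limit in cm (default `C/2`, covering every
#'   unambiguous displacement).
#' @param tol coincidence tolerance in rad; default half the per-step
#'   phase advance of the smallest-scale module (`pi * step_size / s_M`),
#'   the smallest tolerance that guarantees detection at the sweep step
#'   nearest an arbitrary real-valued displacement. When the step equals
#'   the phase-bin spacing `s_M / cells_per_axis` this coincides with half
#'   the phase-bin width of the smallest module.
#' @return one-row tibble of class `sweep_result`: `axis`, `direction`,
#'   `detected`, `distance_cm`, `steps`, `integrator`.
#' @export
sweep <- function(code_start, code_target, sys, axis = 1, direction = 1,
                  step_size = min(sys$scale_cm) / 8, max_distance = NULL,
                  tol = NULL) {
  stopifnot(direction %in% c(-1, 1))
  s <- axis_scales(sys, axis)
  if (step_size > min(s) / 8 + 1e-12) {
    abort("step_size must be at most s_M / 8")
  }
  if (is.null(max_distance)) max_distance <- system_period(sys, axis) / 2
  if (is.null(tol)) tol <- pi * step_size / min(s)
  a <- check_code(code_start, sys, "code_start")
  b <- check_code(code_target, sys, "code_target")
  col <- c("p_x", "p_y")[axis]
  p0 <- a[[col]]
  pt <- b[[col]]
  k <- 0:floor(max_distance / step_size + 1e-9)
  # phase error of every module at every step: length(k) x M
  err <- vapply(seq_along(s), function(i) {
    circ_dist(p0[i] + direction * TWO_PI * k * step_size / s[i], pt[i])
  }, numeric(length(k)))
  if (!is.matrix(err)) err <- matrix(err, nrow = length(k))
  worst <- apply(err, 1, max)
  hit <- which(worst <= tol)
  # a step-0 hit is legitimate when the codes differ by less than the
  # guaranteed-detection tolerance; beyond that the tolerance is too loose
  if (length(hit) > 0 && hit[1] == 1 &&
      max(circ_dist(p0, pt)) > pi * step_size / min(s)) {
    warn("coincidence tolerance fires at step 0 for distinct codes")
  }
  if (length(hit) == 0) {
    out <- tibble(axis = axis, direction = direction, detected = FALSE,
                  distance_cm = NA_real_, steps = NA_integer_,
                  integrator = NA_real_)
  } else {
    steps <- k[hit[1]]
    out <- tibble(axis = axis, direction = direction, detected = TRUE,
                  distance_cm = steps * step_size, steps = steps,
                  integrator = steps * step_size)
  }
  class(out) <- c("sweep_result", class(out))
  out
}

#' Look-ahead sweep initiated from the goal
#'
#' Identical contract to [sweep()] with the roles of the two codes
#' reversed: a search from the goal location for the current one. For a
#' displacement `d` detected by a forward sweep in direction +1, the
#' goal-initiated sweep detects the same distance in direction -1 (the
#' signed result is negated).
#'
#' @param code_goal,code_current phase codes of goal and current
#'   locations.
#' @inheritParams sweep
#' @return one-row tibble of class `sweep_result`.
#' @export
sweep_from_goal <- function(code_goal, code_current, sys, axis = 1,
                            direction = 1,
                            step_size = min(sys$scale_cm) / 8,
                            max_distance = NULL, tol = NULL) {
  sweep(code_goal, code_current, sys, axis = axis, direction = direction,
        step_size = step_size, max_distance = max_distance, tol = tol)
}

#' Decode a 2D translation vector by linear look-ahead
#'
#' Runs bidirectional sweeps on each principal axis against the target
#' code and keeps, per axis, the direction whose coincidence comes first
#' (nearest), resolving the sign; the signed distances are assembled into
#' a translation vector and the summed steps of the winning sweeps are
#' reported as the latency.
#'
#' @inheritParams decode_distance_cells
#' @param step_size sweep step in cm (default `s_M / 8`).
#' @param tol coincidence tolerance in rad (default as in [sweep()]).
#' @return one-row tibble of class `decode_report` with an extra
#'   `latency_steps` column.
#' @export
decode_lookahead <- function(code_a, code_b, sys,
                             step_size = min(sys$scale_cm) / 8,
                             tol = NULL) {
  if (!shared_axes(sys)) abort("look-ahead decoding requires shared axes")
  per_axis <- lapply(1:2, function(axis) {
    fwd <- sweep(code_a, code_b, sys, axis, +1, step_size, tol = tol)
    bwd <- sweep(code_a, code_b, sys, axis, -1, step_size, tol = tol)
    cand <- bind_rows(fwd, bwd)
    cand <- cand[cand$detected, ]
    if (nrow(cand) == 0) return(NULL)
    cand <- cand[order(cand$distance_cm, -cand$direction), ][1, ]
    cand
  })
  if (any(vapply(per_axis, is.null, logical(1)))) {
    out <- tibble(d_axis1_cm = NA_real_, d_axis2_cm = NA_real_,
                  dx_cm = NA_real_, dy_cm = NA_real_,
                  latency_steps = NA_integer_, success = FALSE)
  } else {
    d1 <- per_axis[[1]]$direction * per_axis[[1]]$distance_cm
    d2 <- per_axis[[2]]$direction * per_axis[[2]]$distance_cm
    out <- translation_vector(d1, d2, sys)
    out$latency_steps <- per_axis[[1]]$steps + per_axis[[2]]$steps
    out$success <- TRUE
  }
  class(out) <- c("decode_report", class(out))
  out
}
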