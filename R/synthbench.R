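#' Canonical worked-example scenarios
#'
#' The small desk-checkable cases used throughout the documentation and
#' tests: a three-module system (scales 50, 30, 20 cm) with a 75 cm
#' displacement along axis 1 and with the 2D displacement (75, 37.5) cm
#' along the two axes, and a two-module system (30, 20 cm) with a goal
#' 30 cm ahead, both from the origin and shifted to a 45 cm start (the
#' shifted pair demonstrates that phase differences, and theta phase
#' patterns, depend only on the displacement).
#'
#' @return tibble with one row per scenario: `name`, list-column
#'   `scales_cm`, start and goal coordinates along the grid axes.
#' @export
worked_examples <- function() {
  tibble(
    name = c("oneD_d75", "twoD_d75_37.5", "theta_goal30", "theta_goal30_shifted"),
    scales_cm = list(c(50, 30, 20), c(50, 30, 20), c(30, 20), c(30, 20)),
    start_a1_cm = c(0, 0, 0, 45),
    start_a2_cm = 0,
    goal_a1_cm = c(75, 75, 30, 75),
    goal_a2_cm = c(0, 37.5, 0, 0)
  )
}

# run fn with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate random navigation scenarios
#'
#' Start locations are uniform over a square work area in axis
#' coordinates; displacements are uniform within `(-C/2, C/2)` per axis
#' (the unambiguous range of the code), so every scenario is decodable in
#' principle. Deterministic under `seed`.
#'
#' @param sys a [grid_system()].
#' @param n number of scenarios.
#' @param seed integer seed.
#' @param kappa von Mises concentration of phase noise applied to the
#'   codes at decode time (`Inf` = noise-free).
#' @param work_area side of the square (cm) the start locations are drawn
#'   from; default one system period.
#' @return tibble: `scenario`, start/goal cartesian coordinates, true
#'   axis-wise and cartesian displacement, `kappa`, `seed`.
#' @export
random_scenarios <- function(sys, n, seed = 1, kappa = Inf,
                             work_area = NULL) {
  C1 <- system_period(sys, axis = 1)
  C2 <- system_period(sys, axis = 2)
  if (is.null(work_area)) work_area <- max(C1, C2)
  B <- axis_basis(sys$orientation[1], sys$axis_separation[1])
  with_seed(seed, function() {
    s1 <- runif(n, 0, work_area)
    s2 <- runif(n, 0, work_area)
    d1 <- runif(n, -C1 / 2, C1 / 2)
    d2 <- runif(n, -C2 / 2, C2 / 2)
    start <- B %*% rbind(s1, s2)
    disp <- B %*% rbind(d1, d2)
    tibble(
      scenario = seq_len(n),
      start_x_cm = start[1, ], start_y_cm = start[2, ],
      goal_x_cm = start[1, ] + disp[1, ], goal_y_cm = start[2, ] + disp[2, ],
      true_d1_cm = d1, true_d2_cm = d2,
      true_dx_cm = disp[1, ], true_dy_cm = disp[2, ],
      kappa = kappa, seed = seed
    )
  })
}

#' Add circular phase noise to a code
#'
#' Independent von Mises jitter on every per-module, per-axis phase,
#' wrapped back to `[0, 2*pi)`. `kappa = Inf` is the identity.
#'
#' @param code a `phase_code`.
#' @param kappa von Mises concentration (larger = less noise).
#' @param seed optional integer; when given the draw is deterministic and
#'   the global RNG state is left untouched.
#' @return a `phase_code` with jittered phases.
#' @export
perturb_code <- function(code, kappa, seed = NULL) {
  jitter_fn <- function() {
    n <- nrow(code)
    code$p_x <- wrap_2pi(code$p_x + rvonmises(n, 0, kappa))
    code$p_y <- wrap_2pi(code$p_y + rvonmises(n, 0, kappa))
    code
  }
  with_seed(seed, jitter_fn)
}

bench_models <- c("algorithmic", "distance", "vector_rate", "vector_phase",
                  "lookahead")

#' Run every decoder over a set of scenarios
#'
#' The cross-model evaluation harness: encodes each scenario's start and
#' goal (optionally jittered), hands the codes to the requested decoders,
#' and records the estimated against the true translation vector. A
#' decode counts as a success when each axis component is within
#' `max(model resolution, s_M / 4)` of the truth, measured circularly
#' (the code is periodic, so an estimate of +C/2 against a truth of -C/2
#' is an error of 0, not C); `error_cm` is the Euclidean length of the
#' wrapped per-axis error mapped through the axis basis. On noise-free
#' scenarios all five decoders agree to their respective resolutions.
#'
#' @param scenarios tibble from [random_scenarios()] (or any tibble with
#'   `scenario`, start/goal cartesian columns and `true_d1_cm`,
#'   `true_d2_cm`, `kappa`, `seed`).
#' @param sys a [grid_system()] with shared axes.
#' @param models subset of
#'   `c("algorithmic", "distance", "vector_rate", "vector_phase",
#'   "lookahead")`.
#' @param resolution array/template resolution for the network decoders in
#'   cm (default `s_M / 4`).
#' @param step_size look-ahead step in cm (default `s_M / 8`).
#' @return object of class `nav_benchmark` with `records` (one row per
#'   scenario x model) and `summary` (per model); see [tidy.nav_benchmark()]
#'   and [glance.nav_benchmark()].
#' @export
run_benchmark <- function(scenarios, sys, models = bench_models,
                          resolution = min(sys$scale_cm) / 4,
                          step_size = min(sys$scale_cm) / 8) {
  models <- match.arg(models, bench_models, several.ok = TRUE)
  s_floor <- min(sys$scale_cm) / 4
  dist_arrays <- vec_arrays <- NULL
  if ("distance" %in% models) {
    dist_arrays <- list(build_distance_cells(sys, 1, resolution),
                        build_distance_cells(sys, 2, resolution))
  }
  if ("vector_rate" %in% models) {
    vec_arrays <- list(build_vector_cells(sys, 1, resolution),
                       build_vector_cells(sys, 2, resolution))
  }
  records <- purrr::map_dfr(seq_len(nrow(scenarios)), function(r) {
    sc <- scenarios[r, ]
    code_a <- encode_location(c(sc$start_x_cm, sc$start_y_cm), sys)
    code_b <- encode_location(c(sc$goal_x_cm, sc$goal_y_cm), sys)
    if (is.finite(sc$kappa)) {
      code_a <- perturb_code(code_a, sc$kappa, seed = sc$seed + 2L * sc$scenario)
      code_b <- perturb_code(code_b, sc$kappa, seed = sc$seed + 2L * sc$scenario + 1L)
    }
    dp <- phase_difference(code_a, code_b)
    purrr::map_dfr(models, function(model) {
      est <- switch(model,
        algorithmic = decode_planefit(dp, sys,
                                      residual_threshold = if (is.finite(sc$kappa)) 1 else 1e-6),
        distance = decode_distance_cells(code_a, code_b, sys, arrays = dist_arrays),
        vector_rate = decode_vector_cells(code_a, code_b, sys, arrays = vec_arrays),
        vector_phase = decode_phase_cells(code_a, code_b, sys, resolution),
        lookahead = decode_lookahead(code_a, code_b, sys, step_size)
      )
      model_res <- switch(model, algorithmic = 0, lookahead = step_size,
                          resolution)
      tol <- max(model_res, s_floor)
      # axis errors are circular: the code is periodic with period C, so
      # +C/2 and -C/2 are the same displacement
      C1 <- system_period(sys, axis = 1)
      C2 <- system_period(sys, axis = 2)
      e1 <- wrap_signed(est$d_axis1_cm - sc$true_d1_cm, C1)
      e2 <- wrap_signed(est$d_axis2_cm - sc$true_d2_cm, C2)
      ok <- !is.na(est$d_axis1_cm) &&
        abs(e1) <= tol + 1e-9 && abs(e2) <= tol + 1e-9
      B <- axis_basis(sys$orientation[1], sys$axis_separation[1])
      err_cart <- if (is.na(est$d_axis1_cm)) NA_real_ else {
        sqrt(sum((B %*% c(e1, e2))^2))
      }
      tibble(
        scenario_id = sc$scenario, model = model,
        true_d1 = sc$true_d1_cm, true_d2 = sc$true_d2_cm,
        est_d1 = est$d_axis1_cm, est_d2 = est$d_axis2_cm,
        true_dx = sc$true_dx_cm, true_dy = sc$true_dy_cm,
        est_dx = est$dx_cm, est_dy = est$dy_cm,
        error_cm = err_cart,
        success = ok,
        latency_steps = if ("latency_steps" %in% names(est)) {
          est$latency_steps
        } else NA_integer_
      )
    })
  })
  summary <- records |>
    group_by(.data$model) |>
    summarise(
      n = dplyr::n(),
      success_rate = mean(.data$success),
      mean_error_cm = mean(.data$error_cm, na.rm = TRUE),
      max_error_cm = max(.data$error_cm, na.rm = TRUE),
      mean_latency_steps = mean(.data$latency_steps, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(records = records, summary = summary, sys = sys,
         resolution = resolution, step_size = step_size),
    class = "nav_benchmark"
  )
}

#' @export
print.nav_benchmark <- function(x, ...) {
  cat(sprintf("<nav_benchmark> %d scenarios x %d models\n",
              length(unique(x$records$scenario_id)),
              length(unique(x$records$model))))
  print(x$summary)
  invisible(x)
}

#' Per-decode records of a benchmark
#' @param x a `nav_benchmark`.
#' @param ... unused.
#' @return tibble, one row per scenario and model.
#' @exportS3Method
tidy.nav_benchmark <- function(x, ...) x$records

#' Per-model summary of a benchmark
#' @param x a `nav_benchmark`.
#' @param ... unused.
#' @return tibble, one row per model: success rate, mean/max error,
#'   mean look-ahead latency.
#' @exportS3Method
glance.nav_benchmark <- function(x, ...) x$summary

#' Write benchmark outputs
#'
#' `records.csv` (one row per scenario and model) and `summary.json`
#' (per-model statistics). Byte-identical across runs for a fixed seed
#' and configuration.
#'
#' @param bench a `nav_benchmark`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_benchmark <- function(bench, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bench$records, file.path(out_dir, "records.csv"))
  jsonlite::write_json(bench$summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(out_dir)
}
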