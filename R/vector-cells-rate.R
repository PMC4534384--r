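#' Build a rate-coded vector-cell array
#'
#' Each vector cell encodes one displacement on `[-C/2, C/2)` along an
#' axis and receives multiplicative input from every pair of phase-binned
#' grid cells (current-location cell, goal-location cell) in every module
#' whose wrapped phase difference matches its displacement:
#' `d = (dp/2*pi + n) * s_i` for some integer `n`. Every module therefore
#' contributes `cells_per_axis` pairs to every vector cell (one goal bin
#' per current bin).
#'
#' @param sys a [grid_system()] with shared axes.
#' @param axis axis index (1 or 2).
#' @param resolution displacement spacing in cm; must divide the capacity
#'   and be no finer than the phase-bin spacing of the smallest module
#'   (`s_M / cells_per_axis`). Default `s_M / 4`.
#' @param variable_resolution if TRUE, displacement spacing widens with
#'   distance as `resolution * max(1, |d| / s_1)`, trading precision for
#'   far goals against array size (re-decoding *en route* restores
#'   precision as the goal nears).
#' @return object of class `vector_cell_array`.
#' @export
build_vector_cells <- function(sys, axis = 1,
                               resolution = min(sys$scale_cm) / 4,
                               variable_resolution = FALSE) {
  C <- system_period(sys, axis = axis)
  if (!is.finite(C)) abort("infinite capacity; use rationally related scales")
  bin_cm <- min(axis_scales(sys, axis) / sys$cells_per_axis)
  if (resolution < bin_cm - 1e-12) {
    abort("resolution finer than the phase-bin spacing of the smallest module")
  }
  if (variable_resolution) {
    d_pos <- 0
    while (TRUE) {
      nxt <- d_pos[length(d_pos)] +
        resolution * max(1, d_pos[length(d_pos)] / sys$scale_cm[1])
      if (nxt >= C / 2) break
      d_pos <- c(d_pos, nxt)
    }
    d_neg <- -d_pos[d_pos > 0 & -d_pos >= -C / 2]
    displacements <- sort(c(d_neg, d_pos))
  } else {
    n_cells <- C / resolution
    if (abs(n_cells - round(n_cells)) > 1e-9) {
      abort("resolution must divide the system capacity")
    }
    displacements <- seq(-C / 2, C / 2 - resolution, by = resolution)
  }
  bins <- axis_bins(sys)
  s <- axis_scales(sys, axis)
  m <- sys$cells_per_axis
  # pair table: for each vector cell, global indices of (current, goal)
  # phase bins whose difference matches the cell's displacement
  offset <- c(0, cumsum(m))[seq_len(nrow(sys))]
  pairs <- lapply(displacements, function(d) {
    idx <- purrr::map(seq_len(nrow(sys)), function(i) {
      k <- seq_len(m[i])
      dphi <- TWO_PI * (d %% s[i]) / s[i]
      goal_bin <- (round((TWO_PI * (k - 1) / m[i] + dphi) / (TWO_PI / m[i]))) %% m[i] + 1
      cbind(cur = offset[i] + k, goal = offset[i] + goal_bin)
    })
    do.call(rbind, idx)
  })
  structure(
    list(sys = sys, axis = axis, resolution = resolution, capacity = C,
         displacements_cm = displacements, pairs = pairs, bins = bins),
    class = "vector_cell_array"
  )
}

#' @export
print.vector_cell_array <- function(x, ...) {
  cat(sprintf(
    "<vector_cell_array> axis %d: %d cells on [-%g, %g) cm\n",
    x$axis, length(x$displacements_cm), x$capacity / 2, x$capacity / 2))
  invisible(x)
}

#' Activate a vector-cell array with simultaneous current and goal codes
#'
#' Input to each vector cell is the sum over its grid-cell pairs of the
#' product of the presynaptic rates (multiplicative synapses), with the
#' current- and goal-coding populations active at once. Winner-take-all
#' leaves the maximally driven cell; ties break towards the smallest
#' absolute displacement. The winner is unchanged by any joint translation
#' of the two locations, since only phase differences enter.
#'
#' @param arr a [build_vector_cells()] array.
#' @param code_a,code_b phase codes of current and goal locations.
#' @return one-row tibble: `d_cm` (winner displacement), `rate`, `success`.
#' @export
activate_vector_cells <- function(arr, code_a, code_b) {
  r_a <- axis_population(code_a, arr$sys, arr$axis, arr$bins)
  r_b <- axis_population(code_b, arr$sys, arr$axis, arr$bins)
  input <- vapply(arr$pairs, function(p) {
    sum(r_a[p[, "cur"]] * r_b[p[, "goal"]])
  }, numeric(1))
  if (all(input <= 0)) {
    return(tibble(d_cm = NA_real_, rate = 0, success = FALSE))
  }
  ord <- order(abs(arr$displacements_cm), arr$displacements_cm)
  w <- ord[which.max(input[ord])]
  tibble(d_cm = arr$displacements_cm[w], rate = input[w], success = TRUE)
}

#' Decode a 2D translation vector with rate-coded vector cells
#'
#' Runs [activate_vector_cells()] on an array per principal axis and
#' assembles the winning displacements into a translation vector.
#'
#' @inheritParams decode_distance_cells
#' @param arrays optional prebuilt `list(axis1, axis2)` of vector-cell
#'   arrays.
#' @return one-row tibble of class `decode_report`.
#' @export
decode_vector_cells <- function(code_a, code_b, sys,
                                resolution = min(sys$scale_cm) / 4,
                                arrays = NULL) {
  if (!shared_axes(sys)) abort("vector-cell decoding requires shared axes")
  if (is.null(arrays)) {
    arrays <- list(build_vector_cells(sys, 1, resolution),
                   build_vector_cells(sys, 2, resolution))
  }
  r1 <- activate_vector_cells(arrays[[1]], code_a, code_b)
  r2 <- activate_vector_cells(arrays[[2]], code_a, code_b)
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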