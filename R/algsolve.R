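#' System period (capacity) along a grid axis
#'
#' The smallest displacement C > 0 along the axis after which every
#' module's phase returns to its starting value, so the joint phase code
#' repeats. Within `[-C/2, C/2)` each set of phase differences corresponds
#' to a unique displacement; C is bounded by the least common multiple of
#' the module scales. Two routes are provided: exact rational reduction of
#' the scale ratios (continued fractions, denominator cap 1e6) and a
#' numeric phase-coincidence scan at a given resolution.
#'
#' @param sys a [grid_system()].
#' @param axis which principal axis (1 or 2; axis 2 uses the elliptic
#'   scales).
#' @param method `"auto"` tries the rational route and falls back to the
#'   scan; `"lcm"` and `"scan"` force one route.
#' @param resolution scan step in cm.
#' @param max_range scan limit in cm; if no coincidence is found the system
#'   is reported effectively aperiodic with `Inf`.
#' @return capacity in cm (possibly `Inf`).
#' @examples
#' system_period(grid_system(c(50, 30, 20)))  # 300
#' @export
system_period <- function(sys, axis = 1, method = c("auto", "lcm", "scan"),
                          resolution = 0.01, max_range = 1e5) {
  method <- match.arg(method)
  stopifnot(resolution > 0)
  s <- axis_scales(sys, axis)
  if (method %in% c("auto", "lcm")) {
    fr <- lapply(s, rationalize)
    if (!any(vapply(fr, is.null, logical(1)))) {
      # common denominator D = lcm of dens; period = lcm of numerators / D
      dens <- vapply(fr, function(f) f$den, numeric(1))
      nums <- vapply(fr, function(f) f$num, numeric(1))
      D <- Reduce(lcm2, dens)
      ints <- nums * (D / dens)
      L <- Reduce(lcm2, ints)
      if (L / D < .Machine$double.xmax && L < 2^53) return(L / D)
    }
    if (method == "lcm") {
      warn("scales not rationally related within tolerance; period unknown")
      return(Inf)
    }
  }
  # coincidence scan: first d > 0 where all phases are back at 0
  phase_tol <- pi * resolution / min(s)
  d <- seq(resolution, max_range, by = resolution)
  err <- rep(0, length(d))
  for (si in s) err <- pmax(err, circ_dist(TWO_PI * d / si, 0))
  hit <- which(err <= phase_tol)
  if (length(hit) == 0) {
    warn("no phase coincidence within max_range; effectively aperiodic")
    return(Inf)
  }
  d[hit[1]]
}

# Per-axis capacities as a length-2 vector (memo-free; cheap for the
# rational route used everywhere internally).
system_capacity <- function(sys) {
  c(system_period(sys, axis = 1), system_period(sys, axis = 2))
}

#' Enumerate coherent unwrap candidates for one axis
#'
#' Each module's wrapped phase difference stands for an infinite set of
#' unwrapped phases `dp + 2*pi*n`. A candidate is one coherent integer set
#' `{n_i}` across modules, anchored to a displacement hypothesis taken from
#' module 1 (`d = (dp_1/2*pi + n_1) * s_1`) with the remaining wrap counts
#' snapped to the nearest integer; this covers every displacement in
#' `[-C/2, C/2]` without an exhaustive product over modules.
#'
#' @param dp a `phase_diff` tibble.
#' @param sys a [grid_system()].
#' @param axis axis index (1 or 2).
#' @return tibble with one row per candidate: `d_hyp` (cm), list-columns
#'   `n` (integer wrap counts) and `unwrapped` (radians).
#' @export
unwrap_candidates <- function(dp, sys, axis = 1) {
  if (nrow(sys) == 0) abort("empty grid system")
  dpv <- dp[[c("dp_x", "dp_y")[axis]]]
  stopifnot(length(dpv) == nrow(sys))
  s <- axis_scales(sys, axis)
  C <- system_period(sys, axis = axis)
  if (!is.finite(C)) abort("system period is infinite; bound the enumeration with rational scales")
  n1_lo <- floor((-C / 2) / s[1] - dpv[1] / TWO_PI) - 1
  n1_hi <- ceiling((C / 2) / s[1] - dpv[1] / TWO_PI) + 1
  cand <- purrr::map_dfr(seq(n1_lo, n1_hi), function(n1) {
    d_hyp <- (dpv[1] / TWO_PI + n1) * s[1]
    nn <- round(d_hyp / s - dpv / TWO_PI)
    nn[1] <- n1
    tibble(d_hyp = d_hyp, n = list(as.integer(nn)),
           unwrapped = list(dpv + TWO_PI * nn),
           key = paste(nn, collapse = ","))
  })
  cand <- cand[!duplicated(cand$key), setdiff(names(cand), "key")]
  cand
}

# Line through the origin: unwrapped phase u vs inverse scale x.
fit_origin_line <- function(u, inv_s) {
  slope <- sum(u * inv_s) / sum(inv_s^2)
  resid <- sqrt(mean((u - slope * inv_s)^2))
  list(d = slope / TWO_PI, residual = resid)
}

#' Decode a 1D displacement by line fitting
#'
#' The algorithmic decoder: for each coherent unwrap candidate, fit a
#' straight line through the origin to unwrapped phase differences against
#' inverse module scale; the slope divided by `2*pi` is the displacement.
#' The candidate with smallest rms misfit whose displacement lies within
#' `[-C/2, C/2)` wins. Noise-free inputs give a residual of 0 to numerical
#' precision.
#'
#' @inheritParams unwrap_candidates
#' @param residual_threshold rms misfit (radians) below which the decode is
#'   flagged successful.
#' @return one-row tibble of class `decode_report`: `d_cm`, `residual`,
#'   `success`, `axis`, list-column `n`.
#' @examples
#' sys <- grid_system(c(50, 30, 20))
#' decode_linefit(phase_diff(c(pi, pi, 3 * pi / 2)), sys)  # 75 cm
#' @export
decode_linefit <- function(dp, sys, axis = 1, residual_threshold = 1e-6) {
  s <- axis_scales(sys, axis)
  C <- system_period(sys, axis = axis)
  cand <- unwrap_candidates(dp, sys, axis = axis)
  fits <- purrr::map_dfr(seq_len(nrow(cand)), function(k) {
    f <- fit_origin_line(cand$unwrapped[[k]], 1 / s)
    tibble(d_cm = f$d, residual = f$residual, n = cand$n[k])
  })
  fits <- fits[fits$d_cm >= -C / 2 - 1e-9 & fits$d_cm < C / 2 - 1e-9, ]
  if (nrow(fits) == 0) abort("no candidate within capacity; should not happen")
  fits <- fits[order(fits$residual, abs(fits$d_cm)), ]
  best <- fits[1, ]
  rep <- tibble(
    d_cm = best$d_cm, residual = best$residual,
    success = best$residual <= residual_threshold,
    axis = axis, n = best$n
  )
  class(rep) <- c("decode_report", class(rep))
  rep
}

# Assemble a translation vector tibble from axis components.
translation_vector <- function(d_axis1, d_axis2, sys) {
  B <- axis_basis(sys$orientation[1], sys$axis_separation[1])
  cart <- B %*% c(d_axis1, d_axis2)
  tibble(d_axis1_cm = d_axis1, d_axis2_cm = d_axis2,
         dx_cm = cart[1], dy_cm = cart[2])
}

#' Decode a 2D translation vector by plane fitting
#'
#' With shared module axes the 2D problem decomposes exactly into two
#' independent 1D line fits, one per principal axis; the two components are
#' assembled into a translation vector via the axis basis. With per-module
#' axes or ellipticity differences, a single plane through the origin is
#' fit to the family of points (axis direction over scale, unwrapped
#' phase) across all modules and axes; both paths agree when axes are
#' shared.
#'
#' @inheritParams decode_linefit
#' @return one-row tibble of class `decode_report` with columns
#'   `d_axis1_cm`, `d_axis2_cm`, `dx_cm`, `dy_cm`, `residual`, `success`.
#' @examples
#' sys <- grid_system(c(50, 30, 20))
#' dp <- phase_diff(c(pi, pi, 3 * pi / 2), c(3 * pi / 2, pi / 2, 7 * pi / 4))
#' decode_planefit(dp, sys)  # (75, 37.5) cm along the axes
#' @export
decode_planefit <- function(dp, sys, residual_threshold = 1e-6) {
  if (shared_axes(sys)) {
    r1 <- decode_linefit(dp, sys, axis = 1, residual_threshold)
    r2 <- decode_linefit(dp, sys, axis = 2, residual_threshold)
    out <- translation_vector(r1$d_cm, r2$d_cm, sys)
    out$residual <- sqrt((r1$residual^2 + r2$residual^2) / 2)
    out$success <- r1$success && r2$success
  } else {
    out <- plane_fit_general(dp, sys, residual_threshold)
  }
  class(out) <- c("decode_report", class(out))
  out
}

# General plane fit: modules may differ in orientation/ellipticity.
# Unknown is the cartesian displacement g; each module/axis contributes
# one equation (u_ji . g) / s_ji = dp_ji/2pi + n_ji. Hypotheses are
# anchored on module 1's integer pair; other wrap counts snap to the
# nearest integer given the implied g.
plane_fit_general <- function(dp, sys, residual_threshold = 1e-6) {
  M <- nrow(sys)
  dirs <- lapply(seq_len(M), function(i) {
    axis_basis(sys$orientation[i], sys$axis_separation[i])
  })
  s_x <- axis_scales(sys, 1); s_y <- axis_scales(sys, 2)
  # axis coordinates of g come from the dual basis (rows of the inverted
  # basis matrix), not from projection onto the axis unit vectors
  A <- do.call(rbind, lapply(seq_len(M), function(i) {
    Bi_inv <- solve(dirs[[i]])
    rbind(Bi_inv[1, ] / s_x[i], Bi_inv[2, ] / s_y[i])
  }))                                   # (2M) x 2
  frac <- c(rbind(dp$dp_x, dp$dp_y)) / TWO_PI  # order: m1x, m1y, m2x, m2y, ...
  C1 <- system_period(sys, axis = 1); C2 <- system_period(sys, axis = 2)
  n1x <- seq(floor(-C1 / (2 * s_x[1]) - frac[1]) - 1,
             ceiling(C1 / (2 * s_x[1]) - frac[1]) + 1)
  n1y <- seq(floor(-C2 / (2 * s_y[1]) - frac[2]) - 1,
             ceiling(C2 / (2 * s_y[1]) - frac[2]) + 1)
  AtA_inv <- solve(crossprod(A))
  best <- NULL
  for (nx in n1x) for (ny in n1y) {
    d1 <- (frac[1] + nx) * s_x[1]
    d2 <- (frac[2] + ny) * s_y[1]
    g0 <- dirs[[1]] %*% c(d1, d2)       # implied cartesian displacement
    n <- round(A %*% g0 - frac)
    n[1] <- nx; n[2] <- ny
    rhs <- frac + n
    g <- AtA_inv %*% crossprod(A, rhs)
    resid <- sqrt(mean((TWO_PI * (A %*% g - rhs))^2))
    ax <- solve(dirs[[1]], g)           # components on module-1 axes
    if (ax[1] < -C1 / 2 - 1e-9 || ax[1] >= C1 / 2 - 1e-9) next
    if (ax[2] < -C2 / 2 - 1e-9 || ax[2] >= C2 / 2 - 1e-9) next
    if (is.null(best) || resid < best$resid - 1e-15 ||
        (abs(resid - best$resid) <= 1e-15 && sum(ax^2) < sum(best$ax^2))) {
      best <- list(resid = resid, g = g, ax = ax)
    }
  }
  if (is.null(best)) abort("no plane-fit candidate within capacity")
  tibble(
    d_axis1_cm = best$ax[1], d_axis2_cm = best$ax[2],
    dx_cm = best$g[1], dy_cm = best$g[2],
    residual = best$resid, success = best$resid <= residual_threshold
  )
}

#' Brute-force displacement oracle
#'
#' Independent check on the algorithmic decoder: scans every displacement
#' on a grid over `[-C/2, C/2)` per axis at the given resolution, scores
#' each by the summed squared circular distance between its predicted
#' phase differences and the observed ones, and returns the minimiser.
#' Intended for tests; the score is separable across axes for shared-axis
#' systems, which keeps the full 2D scan cheap.
#'
#' @inheritParams decode_planefit
#' @param resolution scan step in cm (at most `s_M / 20`).
#' @return one-row tibble with `d_axis1_cm`, `d_axis2_cm`, `dx_cm`,
#'   `dy_cm`, `score`.
#' @export
brute_force_oracle <- function(dp, sys, resolution = 1) {
  if (!shared_axes(sys)) abort("oracle implemented for shared-axis systems")
  if (resolution > min(sys$scale_cm) / 20 + 1e-12) {
    abort("oracle resolution must be at most s_M / 20")
  }
  score_axis <- function(axis) {
    s <- axis_scales(sys, axis)
    C <- system_period(sys, axis = axis)
    d <- seq(-C / 2, C / 2 - resolution, by = resolution)
    dpv <- dp[[c("dp_x", "dp_y")[axis]]]
    sc <- rep(0, length(d))
    for (i in seq_along(s)) {
      sc <- sc + circ_dist(dpv[i], TWO_PI * d / s[i])^2
    }
    list(d = d, score = sc)
  }
  a1 <- score_axis(1); a2 <- score_axis(2)
  total <- outer(a1$score, a2$score, "+")
  ix <- which(total == min(total), arr.ind = TRUE)[1, ]
  out <- translation_vector(a1$d[ix[1]], a2$d[ix[2]], sys)
  out$score <- min(total)
  out
}
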