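#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange bind_rows group_by summarise ungroup
#' @importFrom stats rnorm runif lm coef
NULL

TWO_PI <- 2 * pi

#' Wrap angles to [0, 2*pi)
#'
#' Non-negative wrapped remainder; values within 1e-12 of 2*pi snap to 0 so
#' that phases computed from exact multiples of a scale stay on the half-open
#' interval.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector in `[0, 2*pi)`.
#' @keywords internal
wrap_2pi <- function(theta) {
  w <- theta %% TWO_PI
  w[w >= TWO_PI - 1e-12] <- 0
  w
}

#' Wrap angles to (-pi, pi]
#' @param theta numeric vector of angles in radians.
#' @return numeric vector in `(-pi, pi]`.
#' @keywords internal
wrap_pi <- function(theta) {
  w <- theta %% TWO_PI
  w[w > pi + 1e-12] <- w[w > pi + 1e-12] - TWO_PI
  # keep exactly pi on the positive branch
  w[abs(w + pi) < 1e-12] <- pi
  w
}

#' Circular distance between angles
#' @param a,b numeric vectors of angles in radians.
#' @return absolute circular distance in `[0, pi]`.
#' @keywords internal
circ_dist <- function(a, b) {
  d <- (a - b) %% TWO_PI
  pmin(d, TWO_PI - d)
}

#' Wrap a displacement into the signed range [-C/2, C/2)
#' @keywords internal
wrap_signed <- function(d, capacity) {
  ((d + capacity / 2) %% capacity) - capacity / 2
}

#' Continued-fraction rationalization of a positive real
#'
#' Returns integers p, q with p/q within `tol` of `x` and q bounded by
#' `max_den`, or NULL when no such fraction exists (value treated as
#' irrational for the purposes of exact period computation).
#'
#' @keywords internal
rationalize <- function(x, tol = 1e-9, max_den = 1e6) {
  stopifnot(x > 0)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- x
  for (i in 1:64) {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) return(NULL)
    if (abs(x - h / k) < tol * max(1, abs(x))) {
      return(list(num = h, den = k))
    }
    frac <- b - a
    if (frac < 1e-15) return(list(num = h, den = k))
    b <- 1 / frac
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
  }
  NULL
}

gcd2 <- function(a, b) {
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. `kappa = Inf` returns `mu`
#' exactly; `kappa = 0` is uniform on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0, may be `Inf`).
#' @return numeric vector of angles in `(-pi, pi]` (plus `mu`).
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (is.infinite(kappa)) return(rep(wrap_pi(mu), n))
  if (kappa == 0) return(wrap_pi(runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_pi(out + mu)
}
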