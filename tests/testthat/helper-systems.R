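# canonical systems used across the suite
sys3 <- function(...) grid_system(c(50, 30, 20), ...)
sys2 <- function(...) grid_system(c(30, 20), ...)

# worked-example phase sets (axis 1 for d = 75; axis 2 for d = 37.5)
DP_75 <- c(pi, pi, 3 * pi / 2)
DP_37.5 <- c(3 * pi / 2, pi / 2, 7 * pi / 4)

# random locations in a box, as a tibble
random_locs <- function(n, half_width = 500) {
  tibble::tibble(
    x_cm = stats::runif(n, -half_width, half_width),
    y_cm = stats::runif(n, -half_width, half_width)
  )
}
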