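# shared fixtures: typical Abeta42-like kinetics at 3 uM, hour-scale
# half-time, secondary-nucleation dominated (lambda/kappa ~ 0.06)

default_params <- function() kinetic_params(k_n = 1e-4, k_2 = 1e4, k_plus = 3e6)
default_init <- function() initial_state(3e-6)
default_grid <- function(hours = 6, n = 301) seq(0, hours * 3600, length.out = n)

# random parameter set constrained to the secondary-nucleation regime
random_regime_params <- function() {
  k_plus <- 10^stats::runif(1, 5.5, 6.8)
  k_2 <- 10^stats::runif(1, 3.5, 4.8)
  m0 <- 10^stats::runif(1, -6, -5.2)
  kappa <- sqrt(2 * k_plus * k_2 * m0^3)
  # lambda/kappa in [0.01, 0.09]
  ratio <- stats::runif(1, 0.01, 0.09)
  k_n <- (ratio * kappa)^2 / (2 * k_plus * m0^2)
  list(params = kinetic_params(k_n, k_2, k_plus), init = initial_state(m0),
       kappa = kappa)
}

# mono-exponential / J-modulated decay builders on the measurement schedules
r1_series <- function(rate, noise = 0, residue = 20) {
  d <- seq(0.002, 2, length.out = 16)
  y <- exp(-rate * d)
  if (noise > 0) y <- y * (1 + stats::rnorm(16, sd = noise))
  relaxation_series(residue, "H", d, y, state = "dia", kind = "R1")
}

r2_series <- function(rate, j = 6, noise = 0, residue = 20, state = "dia") {
  d <- seq(0.005, 0.2, length.out = 16)
  y <- exp(-rate * d) * cos(pi * j * d)
  if (noise > 0) y <- y * (1 + stats::rnorm(16, sd = noise))
  relaxation_series(residue, "H", d, y, state = state, kind = "R2",
                    j_hnha = j)
}

stejskal_dataset <- function(D, noise = 0, ...) {
  g <- seq(0.02, 0.45, length.out = 16)
  b <- stejskal_tanner_b(g, 5e-3, 150e-3)
  I <- exp(-b * D)
  if (noise > 0) I <- I * (1 + stats::rnorm(16, sd = noise))
  diffusion_dataset(g, I, ...)
}
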