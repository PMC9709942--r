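#' A pulsed-field-gradient diffusion decay
#'
#' @param gradient gradient strengths (T/m, or arbitrary linear units if a
#'   calibration constant is folded into `gamma` downstream); >= 8 points.
#' @param intensity signal intensities (positive).
#' @param delta gradient pulse length (s).
#' @param Delta diffusion time (s).
#' @param temperature sample temperature (K).
#' @param metal `"none"`, `"Cu"`, `"Zn"` or `"Ag"`.
#' @param ratio metal:peptide molar ratio.
#' @return An object of class `diffusion_dataset`.
#' @export
diffusion_dataset <- function(gradient, intensity, delta = 5e-3,
                              Delta = 150e-3, temperature = 281,
                              metal = c("none", "Cu", "Zn", "Ag"),
                              ratio = 0) {
  metal <- match.arg(metal)
  stopifnot(length(gradient) == length(intensity), length(gradient) >= 8,
            all(intensity > 0))
  structure(list(gradient = gradient, intensity = intensity, delta = delta,
                 Delta = Delta, temperature = temperature, metal = metal,
                 ratio = ratio),
            class = "diffusion_dataset")
}

#' Stejskal-Tanner b-factor
#'
#' `b = (gamma * delta * g)^2 (Delta - delta/3)` for rectangular gradient
#' pulses; the attenuation is `I = I0 exp(-b D)`.
#'
#' @param gradient gradient strength (T/m).
#' @param delta gradient pulse length (s).
#' @param Delta diffusion time (s).
#' @param gamma gyromagnetic ratio of the observed nucleus (rad s^-1 T^-1).
#' @return b in s m^-2.
#' @export
stejskal_tanner_b <- function(gradient, delta, Delta,
                              gamma = 2.6752218744e8) {
  (gamma * delta * gradient)^2 * (Delta - delta / 3)
}

#' Fit a translational diffusion coefficient
#'
#' Log-linear least squares of the Stejskal-Tanner attenuation against the
#' b-factor. A `poor_fit` flag is raised when the attenuation is
#' non-monotone beyond what the residual scatter explains.
#'
#' @param ds a [diffusion_dataset()].
#' @param gamma gyromagnetic ratio used in the b-factor.
#' @return List with `D` (m^2/s), `se`, `I0` (fitted zero-gradient
#'   intensity), `poor_fit`.
#' @export
fit_diffusion <- function(ds, gamma = 2.6752218744e8) {
  stopifnot(inherits(ds, "diffusion_dataset"))
  b <- stejskal_tanner_b(ds$gradient, ds$delta, ds$Delta, gamma)
  fit <- stats::lm(log(ds$intensity) ~ b)
  D <- -unname(stats::coef(fit)[2])
  se <- suppressWarnings(summary(fit)$coefficients[2, "Std. Error"])
  ord <- order(b)
  steps <- diff(log(ds$intensity[ord]))
  resid_sd <- stats::sd(stats::resid(fit))
  poor <- D <= 0 || mean(steps > 3 * max(resid_sd, 1e-12)) > 0.2
  list(D = D, se = se, I0 = exp(unname(stats::coef(fit)[1])),
       poor_fit = poor)
}

#' Dynamic viscosity of water
#'
#' Vogel-Fulcher-Tammann parameterization for liquid water, adequate for
#' 273-373 K.
#'
#' @param temperature K.
#' @return Viscosity in Pa s.
#' @export
water_viscosity <- function(temperature = 281) {
  1e-3 * exp(-3.7188 + 578.919 / (temperature - 137.546))
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' `R_h = k_B T / (6 pi eta D)`. Absolute radii depend on the viscosity
#' convention; a calibration mode solves for an effective viscosity from a
#' reference (D, R_h) pair, after which radii of other measurements in the
#' same medium are internally consistent (ratios of radii equal inverse
#' ratios of diffusion coefficients regardless of the convention).
#'
#' @param D translational diffusion coefficient (m^2/s).
#' @param temperature K.
#' @param viscosity dynamic viscosity (Pa s); defaults to tabulated water.
#' @param reference optional list `list(D = ..., r_h = ...)` (m^2/s,
#'   Angstrom); when supplied, the effective viscosity is solved from it and
#'   `viscosity` is ignored.
#' @return R_h in Angstrom.
#' @export
hydrodynamic_radius <- function(D, temperature = 281, viscosity = NULL,
                                reference = NULL) {
  stopifnot(all(D > 0), temperature > 0)
  kb <- 1.380649e-23
  if (!is.null(reference)) {
    viscosity <- kb * temperature /
      (6 * pi * reference$D * reference$r_h * 1e-10)
  } else if (is.null(viscosity)) {
    viscosity <- water_viscosity(temperature)
  }
  kb * temperature / (6 * pi * viscosity * D) * 1e10
}

#' Effective viscosity implied by a (D, R_h) pair
#'
#' @param D m^2/s.
#' @param r_h Angstrom.
#' @param temperature K.
#' @return Pa s.
#' @export
effective_viscosity <- function(D, r_h, temperature = 281) {
  1.380649e-23 * temperature / (6 * pi * D * r_h * 1e-10)
}

#' Two-state global fit of diffusion titrations
#'
#' Global fit of per-metal titration series of diffusion coefficients to a
#' fast-exchange two-state (free / metal-bound) model:
#' \deqn{D_{obs}/D_{free} = 1 + p_B (D_B/D_{free} - 1), \quad
#'       p_B = \min(c_{metal} \cdot ratio, 1)}
#' with one shared `D_B/D_free` across metals, a bound-population slope
#' `c_metal` per metal, and a free-state coefficient `D_free` per series.
#' `D_B/D_free > 1` reflects compaction of the bound state.
#'
#' The bound population grows linearly in the titration ratio (tight
#' stoichiometric binding) but cannot exceed unity; the saturation plateau
#' is what makes the shared `D_B/D_free` identifiable separately from the
#' per-metal slopes (below saturation only the products
#' `c_metal (D_B/D_free - 1)` are determined), so at least one series
#' should extend past its equivalence point.
#'
#' @param data data frame with columns `metal`, `ratio`, `D` (m^2/s); every
#'   metal series must include a ratio-0 anchor.
#' @return List of class `two_state_fit`: `db_over_dfree`, `se`, `slopes`
#'   (per metal), `d_free` (per metal), `points` (input plus fitted `p_B`
#'   and a `flagged` column for p_B outside [0, 1]).
#' @export
two_state_global_fit <- function(data) {
  stopifnot(all(c("metal", "ratio", "D") %in% names(data)))
  metals <- unique(data$metal)
  for (m in metals)
    if (!any(data$metal == m & data$ratio == 0))
      stop("series without ratio-0 anchor: ", m)
  midx <- match(data$metal, metals)
  nm <- length(metals)
  # parameters: log r (shared), slopes (per metal), log D_free (per metal)
  model <- function(par) {
    r <- exp(par[1])
    slopes <- par[2:(1 + nm)]
    dfree <- exp(par[(2 + nm):(1 + 2 * nm)])
    pb <- pmin(slopes[midx] * data$ratio, 1)
    dfree[midx] * (1 + pb * (r - 1))
  }
  d0 <- vapply(metals, function(m)
    mean(data$D[data$metal == m & data$ratio == 0]), numeric(1))
  # data-driven starts: the largest observed relative D estimates the bound
  # plateau; low-ratio secants estimate the per-metal population slopes
  r0 <- max(data$D / d0[midx])
  r0 <- max(r0, 1.01)
  slope0 <- vapply(seq_len(nm), function(i) {
    di <- data[data$metal == metals[i] & data$ratio > 0, ]
    sec <- (di$D / d0[i] - 1) / (di$ratio * (r0 - 1))
    max(stats::median(sec), 0.05)
  }, numeric(1))
  par0 <- c(log(r0), slope0, log(d0))
  res_fn <- function(par) (data$D - model(par)) / mean(data$D)
  fit <- minpack.lm::nls.lm(par = par0, fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- fit$par
  r <- exp(par[1])
  se_r <- tryCatch({
    covm <- solve(fit$hessian) * 2 * fit$deviance /
      (length(data$D) - length(par))
    sqrt(covm[1, 1]) * r
  }, error = function(e) NA_real_)
  slopes <- stats::setNames(par[2:(1 + nm)], metals)
  dfree <- stats::setNames(exp(par[(2 + nm):(1 + 2 * nm)]), metals)
  pb <- pmin(slopes[midx] * data$ratio, 1)
  points <- data
  points$p_B <- unname(pb)
  points$flagged <- slopes[midx] * data$ratio < 0 |
    slopes[midx] * data$ratio > 1
  structure(list(db_over_dfree = r, se = se_r, slopes = slopes,
                 d_free = dfree, points = points,
                 deviance = fit$deviance),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("Two-state global fit: D_B/D_free = %.4f", x$db_over_dfree))
  if (is.finite(x$se)) cat(sprintf(" +/- %.4f", x$se))
  cat("\nBound-population slopes per metal:\n")
  print(round(x$slopes, 3))
  invisible(x)
}
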