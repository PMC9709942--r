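#' A single aggregation trace with condition metadata
#'
#' @param t time (s), increasing.
#' @param signal fluorescence signal (normalized or raw).
#' @param cu_conc Cu(II) concentration (M).
#' @param ab_conc total peptide concentration (M).
#' @param dye reporter dye, `"ThT"` or `"pFTAA"`.
#' @param seeded logical; was the reaction seeded with pre-formed fibrils?
#' @param seed_mass seed mass concentration (M); 0 if unseeded.
#' @param replicate replicate identifier.
#'
#' @return An object of class `aggregation_trace` (a data frame with columns
#'   `t` and `signal`; the conditions are attributes).
#' @export
aggregation_trace <- function(t, signal, cu_conc = 0, ab_conc = 3e-6,
                              dye = "ThT", seeded = FALSE, seed_mass = 0,
                              replicate = 1L) {
  stopifnot(length(t) == length(signal), all(diff(t) > 0))
  out <- data.frame(t = t, signal = signal)
  attr(out, "cu_conc") <- cu_conc
  attr(out, "ab_conc") <- ab_conc
  attr(out, "dye") <- dye
  attr(out, "seeded") <- seeded
  attr(out, "seed_mass") <- seed_mass
  attr(out, "replicate") <- replicate
  class(out) <- c("aggregation_trace", "data.frame")
  out
}

trace_meta <- function(tr, what) attr(tr, what)

#' Normalize a trace using its fitted sigmoid baseline and plateau
#'
#' Min-max normalization with the baseline and amplitude taken from the
#' sigmoid fit rather than from raw extremes. Cu(II) quenches the final ThT
#' amplitude, so absolute amplitude information is deliberately discarded:
#' all conditions are mapped to a common 0-1 fibril-mass scale.
#'
#' @param trace an [aggregation_trace()].
#' @return The trace with `signal` rescaled to baseline 0, plateau 1.
#' @export
normalize_trace <- function(trace) {
  ht <- extract_halftime(trace$t, trace$signal)
  trace$signal <- (trace$signal - ht$baseline) / ht$amplitude
  attr(trace, "normalization") <- ht[c("baseline", "amplitude")]
  trace
}

#' Closed-form fibril mass parameterized by the combined rate constants
#'
#' A single unseeded trace determines only the products `k_n k_plus` and
#' `k_plus k_2` (through `lambda` and `kappa`), not the three constants
#' separately; this is the two-parameter model used for individual trace
#' fitting.
#'
#' @param t time (s).
#' @param kn_kplus product k_n * k_plus.
#' @param kplus_k2 product k_plus * k_2.
#' @param m0 initial monomer concentration (M).
#' @param n_c,n_2 reaction orders.
#' @return Normalized fibril mass alpha(t).
#' @export
alpha_from_products <- function(t, kn_kplus, kplus_k2, m0, n_c = 2, n_2 = 2) {
  # any k_plus > 0 with matching k_n, k_2 gives identical alpha; use 1
  params <- kinetic_params(k_n = kn_kplus, k_2 = kplus_k2, k_plus = 1,
                           n_c = n_c, n_2 = n_2)
  init <- initial_state(m0)
  closed_form_alpha(params, init, t)
}

fit_products_one <- function(trace, m0, n_c, n_2, start = NULL) {
  tr <- trace
  y <- tr$signal
  t <- tr$t
  if (is.null(start)) {
    # seed kappa from the observed half-time: near the midpoint the trace
    # rises on the 1/kappa time scale
    ht <- try(extract_halftime(t, y), silent = TRUE)
    t50 <- if (inherits(ht, "try-error")) stats::median(t) else ht$tau_half
    kap0 <- 3 / max(t50, min(diff(t)))
    B0 <- kap0^2 / (2 * m0^(n_2 + 1))
    A0 <- 0.01 * B0 * m0^(n_2 + 1 - n_c)   # lambda/kappa = 0.1
    start <- list(lA = log10(A0), lB = log10(B0))
  }
  fit <- minpack.lm::nlsLM(
    y ~ alpha_from_products(t, 10^lA, 10^lB, m0, n_c, n_2),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  list(kn_kplus = unname(10^cf["lA"]), kplus_k2 = unname(10^cf["lB"]),
       chi2 = sum(stats::resid(fit)^2), fit = fit)
}

#' Fit each aggregation trace individually with the combined rate constants
#'
#' Per-trace least squares of the closed-form model with the two combined
#' rate constants `k_n k_plus` and `k_plus k_2` free. Values are also
#' reported relative to the Cu-free trace, mirroring the diagnostic in which
#' a strong Cu dependence of `k_n k_plus` at nearly constant `k_plus k_2`
#' implicates primary nucleation and/or elongation.
#'
#' @param traces list of normalized [aggregation_trace()] objects (one per
#'   condition; average replicates first, see [average_replicates()]).
#' @param n_c,n_2 reaction orders.
#'
#' @return A data frame with one row per trace: `cu_conc`, `kn_kplus`,
#'   `kplus_k2`, `rel_kn_kplus`, `rel_kplus_k2`, `chi2`, `converged`.
#' @export
fit_individual <- function(traces, n_c = 2, n_2 = 2) {
  stopifnot(length(traces) >= 1)
  rows <- lapply(traces, function(tr) {
    m0 <- trace_meta(tr, "ab_conc")
    res <- try(fit_products_one(tr, m0, n_c, n_2), silent = TRUE)
    if (inherits(res, "try-error"))
      return(data.frame(cu_conc = trace_meta(tr, "cu_conc"), kn_kplus = NA,
                        kplus_k2 = NA, chi2 = NA, converged = FALSE))
    data.frame(cu_conc = trace_meta(tr, "cu_conc"), kn_kplus = res$kn_kplus,
               kplus_k2 = res$kplus_k2, chi2 = res$chi2, converged = TRUE)
  })
  out <- do.call(rbind, rows)
  ref <- which(out$cu_conc == min(out$cu_conc))[1]
  out$rel_kn_kplus <- out$kn_kplus / out$kn_kplus[ref]
  out$rel_kplus_k2 <- out$kplus_k2 / out$kplus_k2[ref]
  out
}

#' Average replicate traces per condition after normalization
#'
#' @param traces list of [aggregation_trace()] replicates (shared time grid
#'   within each condition).
#' @param normalize normalize each replicate (sigmoid baseline/plateau)
#'   before averaging.
#' @return A list with one averaged `aggregation_trace` per Cu condition;
#'   each carries the per-point replicate standard deviation as column `sd`
#'   when replicates exist.
#' @export
average_replicates <- function(traces, normalize = TRUE) {
  if (normalize) traces <- lapply(traces, normalize_trace)
  key <- vapply(traces, function(tr)
    paste(trace_meta(tr, "cu_conc"), trace_meta(tr, "dye"),
          trace_meta(tr, "seeded")), "")
  lapply(split(traces, key), function(grp) {
    sig <- vapply(grp, function(tr) tr$signal, numeric(nrow(grp[[1]])))
    sig <- matrix(sig, nrow = nrow(grp[[1]]))
    avg <- grp[[1]]
    avg$signal <- rowMeans(sig)
    if (ncol(sig) > 1) avg$sd <- apply(sig, 1, stats::sd)
    attr(avg, "n_replicates") <- length(grp)
    avg
  })
}

#' Constrained global fit with a single free rate constant
#'
#' The two rate constants other than `free_constant` are fixed at the values
#' determined from the Cu-free trace; the free constant is refit for every Cu
#' condition (relative to its Cu-free value, which is 1 by construction).
#' Because the shared constants are frozen, the conditions decouple into
#' one-parameter fits whose weighted residuals sum to a global chi-squared
#' that is comparable across the three choices of free constant: the lowest
#' chi-squared identifies which single rate constant Cu(II) modulates.
#'
#' In product space (`A = k_n k_plus`, `B = k_plus k_2`) a relative factor
#' `rho` on the free constant acts as: `k_plus`: A and B both scale by `rho`;
#' `k_n`: only A; `k_2`: only B.
#'
#' @param traces list of per-condition traces (normalized, replicates
#'   averaged; must include the Cu = 0 condition). Traces may carry a `sd`
#'   column used as per-point weights.
#' @param free_constant `"k_plus"`, `"k_2"` or `"k_n"`.
#' @param n_c,n_2 reaction orders.
#'
#' @return A list of class `global_fit` with `free_constant`, per-condition
#'   `conditions` data frame (`cu_conc`, `rel`, `chi2`), the fixed baseline
#'   products `kn_kplus0`, `kplus_k20`, and `chi2_global`.
#' @export
fit_global_single_free <- function(traces, free_constant = c("k_plus", "k_2", "k_n"),
                                   n_c = 2, n_2 = 2) {
  free_constant <- match.arg(free_constant)
  cu <- vapply(traces, trace_meta, numeric(1), what = "cu_conc")
  if (!any(cu == 0)) stop("a Cu = 0 reference condition is required")
  traces <- traces[order(cu)]
  cu <- sort(cu)
  ref_tr <- traces[[1]]
  m0 <- trace_meta(ref_tr, "ab_conc")
  base <- fit_products_one(ref_tr, m0, n_c, n_2)
  A0 <- base$kn_kplus
  B0 <- base$kplus_k2
  fit_one <- function(tr) {
    t <- tr$t
    y <- tr$signal
    w <- if (!is.null(tr$sd) && all(tr$sd > 0)) 1 / tr$sd^2 else rep(1, length(y))
    model <- function(lrho) {
      rho <- 10^lrho
      A <- if (free_constant %in% c("k_plus", "k_n")) A0 * rho else A0
      B <- if (free_constant %in% c("k_plus", "k_2")) B0 * rho else B0
      alpha_from_products(t, A, B, m0, n_c, n_2)
    }
    # Levenberg-Marquardt on raw residuals: tolerant of the near-zero
    # gradient that arises when the free constant barely moves the trace
    # (e.g. k_n in the secondary-dominated regime)
    fit <- minpack.lm::nls.lm(par = c(lrho = 0),
                              fn = function(p) sqrt(w) * (y - model(p[1])),
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    list(rel = unname(10^fit$par[1]), chi2 = fit$deviance)
  }
  per <- lapply(traces, fit_one)
  conditions <- data.frame(
    cu_conc = cu,
    rel = vapply(per, `[[`, numeric(1), "rel"),
    chi2 = vapply(per, `[[`, numeric(1), "chi2"),
    row.names = NULL)
  # the reference is part of the fit too; its rel is ~1 by construction
  structure(list(free_constant = free_constant, conditions = conditions,
                 kn_kplus0 = A0, kplus_k2o = B0, kplus_k20 = B0,
                 n_c = n_c, n_2 = n_2, m0 = m0,
                 chi2_global = sum(conditions$chi2)),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global fit, free constant %s: chi2 = %.4g\n",
              x$free_constant, x$chi2_global))
  print(x$conditions)
  invisible(x)
}

#' Select the modulated rate constant by global chi-squared
#'
#' Runs [fit_global_single_free()] for all three candidate free constants and
#' ranks them by global chi-squared.
#'
#' @inheritParams fit_global_single_free
#' @return A list with `best` (name of the selected constant), `chi2` (named
#'   vector) and `fits` (the three `global_fit` objects).
#' @export
select_free_constant <- function(traces, n_c = 2, n_2 = 2) {
  cands <- c("k_plus", "k_2", "k_n")
  fits <- lapply(cands, function(fc)
    fit_global_single_free(traces, fc, n_c = n_c, n_2 = n_2))
  names(fits) <- cands
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2_global")
  list(best = names(which.min(chi2)), chi2 = chi2, fits = fits)
}

#' Initial elongation rate from a highly seeded trace
#'
#' In strongly seeded reactions growth is dominated by fibril-end elongation
#' and the initial slope of the fibril-mass signal is proportional to
#' `k_plus`. The slope is obtained by a linear fit over an initial window
#' (default 9 min), excluding a burn-in equilibration phase (default 1 min).
#'
#' @param trace a seeded [aggregation_trace()].
#' @param window fit window length (s) from time zero.
#' @param burn_in initial duration (s) excluded from the fit.
#' @return A list with `slope` (signal s^-1), `intercept` and `n_points`.
#' @export
seeded_elongation_rate <- function(trace, window = 9 * 60, burn_in = 60) {
  if (!isTRUE(trace_meta(trace, "seeded")))
    stop("trace is not flagged as seeded")
  sel <- trace$t > burn_in & trace$t <= window
  if (sum(sel) < 4)
    stop("insufficient data: fewer than 4 points in the fit window")
  fit <- stats::lm(signal ~ t, data = trace[sel, ])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n_points = sum(sel))
}

#' Relative seeded elongation rates across Cu conditions
#'
#' @param traces list of seeded traces (must include Cu = 0).
#' @inheritParams seeded_elongation_rate
#' @return Data frame `cu_conc`, `slope`, `rel_rate` (slope / Cu-free slope).
#' @export
seeded_relative_rates <- function(traces, window = 9 * 60, burn_in = 60) {
  cu <- vapply(traces, trace_meta, numeric(1), what = "cu_conc")
  if (!any(cu == 0)) stop("a Cu = 0 reference condition is required")
  slopes <- vapply(traces, function(tr)
    seeded_elongation_rate(tr, window, burn_in)$slope, numeric(1))
  data.frame(cu_conc = cu, slope = slopes,
             rel_rate = slopes / slopes[which(cu == 0)[1]])
}

#' Free monomer fraction under 1:1 metal binding
#'
#' Exact solution of the 1:1 binding equilibrium at total metal `c_metal`,
#' total peptide `m_tot` and dissociation constant `kd`: the bound complex is
#' the smaller root of the binding quadratic and the free fraction is
#' `1 - bound/m_tot`.
#'
#' @param ratio metal:peptide molar ratio(s), >= 0.
#' @param kd dissociation constant (M), > 0.
#' @param m_tot total peptide concentration (M).
#' @return Free monomer fraction in (0, 1].
#' @export
free_monomer_fraction <- function(ratio, kd, m_tot) {
  stopifnot(all(ratio >= 0), kd > 0, m_tot > 0)
  ct <- ratio * m_tot
  s <- m_tot + ct + kd
  bound <- (s - sqrt(s^2 - 4 * m_tot * ct)) / 2
  pmax(1 - bound / m_tot, 0)
}

#' Apparent dissociation constant from relative elongation rates
#'
#' Monomer-sequestration model: the metal-bound monomer is aggregation-inert,
#' so the relative elongation rate equals the free monomer fraction,
#' `k_plus / k_plus0 = f(ratio; K_D)`. `K_D` is fit by least squares on the
#' relative rates. The error range follows a two-sided procedure: a refit on
#' error-weighted data and a refit with the three largest-error points
#' removed; the spread of the three estimates is the reported range.
#'
#' @param ratios metal:peptide molar ratios (>= 0).
#' @param rel_rates relative elongation rates in (0, 1.2].
#' @param errors optional standard errors of `rel_rates`.
#' @param m_tot total peptide concentration (M).
#'
#' @return A list of class `kd_fit`: `kd_app` (M), `kd_range` (M, length 2),
#'   `unbounded` flag, and `curve(ratio)` giving the fitted relative rate.
#' @export
fit_kd_from_elongation <- function(ratios, rel_rates, errors = NULL,
                                   m_tot = 3e-6) {
  stopifnot(length(ratios) == length(rel_rates), all(ratios >= 0))
  if (max(1 - rel_rates) < 0.05) {
    return(structure(list(kd_app = NA_real_, kd_range = c(NA_real_, NA_real_),
                          unbounded = TRUE), class = "kd_fit"))
  }
  one_fit <- function(r, y, w) {
    fit <- minpack.lm::nlsLM(
      y ~ free_monomer_fraction(r, 10^lkd, m_tot),
      start = list(lkd = log10(m_tot)), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 300))
    unname(10^stats::coef(fit)["lkd"])
  }
  kd <- one_fit(ratios, rel_rates, rep(1, length(ratios)))
  ests <- kd
  if (!is.null(errors) && all(is.finite(errors)) && all(errors > 0)) {
    ests <- c(ests, one_fit(ratios, rel_rates, 1 / errors^2))
    keep <- rank(-errors, ties.method = "first") > 3
    if (sum(keep) >= 3)
      ests <- c(ests, one_fit(ratios[keep], rel_rates[keep],
                              rep(1, sum(keep))))
  }
  structure(list(kd_app = kd, kd_range = range(ests), unbounded = FALSE,
                 m_tot = m_tot,
                 curve = function(ratio) free_monomer_fraction(ratio, kd, m_tot)),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (isTRUE(x$unbounded)) {
    cat("Apparent K_D: unbounded (no measurable rate reduction)\n")
  } else {
    cat(sprintf("Apparent K_D = %.3g M (range %.3g - %.3g M)\n",
                x$kd_app, x$kd_range[1], x$kd_range[2]))
  }
  invisible(x)
}

#' Fold change of generated nucleation units across Cu conditions
#'
#' For each condition of a [fit_global_single_free()] result, reconstructs
#' absolute rate constants from the fitted products and a reference
#' elongation rate constant, integrates the nucleation-rate profile over the
#' full reaction, and reports the integral relative to the Cu-free condition.
#' A reduction of `k_plus` alone prolongs the monomer supply and increases
#' the integral: slowing elongation promotes oligomer generation.
#'
#' @param fit a `global_fit` object.
#' @param init [initial_state()] of the reactions.
#' @param k_plus_ref absolute Cu-free elongation rate constant (M^-1 s^-1)
#'   used to split the fitted products into individual constants (default
#'   3e6, typical for this peptide).
#' @param method `"closed_form"` or `"ode"` trajectory pipeline.
#' @param t_end integration horizon (s); default 12 Cu-free half-rise times,
#'   enough for monomer depletion in every condition.
#'
#' @return Data frame `cu_conc`, `rel` (free-constant value), `n_units` (M),
#'   `fold_change`.
#' @export
oligomer_fold_change <- function(fit, init, k_plus_ref = 3e6,
                                 method = c("closed_form", "ode"),
                                 t_end = NULL) {
  stopifnot(inherits(fit, "global_fit"), inherits(init, "initial_state"))
  method <- match.arg(method)
  kn0 <- fit$kn_kplus0 / k_plus_ref
  k20 <- fit$kplus_k20 / k_plus_ref
  if (is.null(t_end)) {
    kap0 <- sqrt(2 * k_plus_ref * k20 * init$m0^(fit$n_2 + 1))
    worst <- min(fit$conditions$rel)
    t_end <- 12 / (kap0 * sqrt(max(worst, 1e-3)))
  }
  tg <- seq(0, t_end, length.out = 600)
  integral_for <- function(rel) {
    kn <- kn0; k2 <- k20; kp <- k_plus_ref
    if (fit$free_constant == "k_plus") kp <- kp * rel
    if (fit$free_constant == "k_n") kn <- kn * rel
    if (fit$free_constant == "k_2") k2 <- k2 * rel
    p <- kinetic_params(kn, k2, kp, fit$n_c, fit$n_2)
    traj <- if (method == "closed_form")
      fibril_mass_closed_form(p, init, tg) else solve_moment_odes(p, init, tg)
    prof <- nucleation_rate_profile(p, traj)
    utils::tail(prof$n_units, 1)
  }
  ok <- is.finite(fit$conditions$rel)
  if (any(!ok)) warning("non-converged conditions excluded")
  conds <- fit$conditions[ok, ]
  n_units <- vapply(conds$rel, integral_for, numeric(1))
  ref <- which(conds$cu_conc == min(conds$cu_conc))[1]
  data.frame(cu_conc = conds$cu_conc, rel = conds$rel, n_units = n_units,
             fold_change = n_units / n_units[ref])
}
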