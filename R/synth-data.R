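#' Configuration for the synthetic-data generator
#'
#' Ground truth for every data stream the pipeline consumes. Defaults are
#' the study conditions: 3 uM Abeta42-like kinetics with half-time on the
#' hour scale, Cu levels 0-10 uM, five replicates, an apparent monomer
#' dissociation constant of 0.7 uM acting through elongation, a saturating
#' final-amplitude quench calibrated to ~60% at 10 uM Cu, 16-delay
#' relaxation schedules (0.002-2 s for R1, 5-200 ms for R2), 16-gradient
#' Stejskal-Tanner decays (delta 5 ms, Delta 150 ms), and a two-state
#' diffusion truth D_B/D_free = 1.094 from D_free = 6.82e-11 m^2/s.
#'
#' @param seed integer random seed; identical configurations regenerate
#'   identical data.
#' @param params kinetic truth ([kinetic_params()]).
#' @param m_tot total peptide concentration (M) for unseeded kinetics.
#' @param cu_levels Cu(II) concentrations (M).
#' @param n_replicates replicates per condition.
#' @param kd_truth monomer-binding dissociation constant (M); scales
#'   `k_plus` by the free monomer fraction.
#' @param quench_max,quench_k saturating ThT quench: final amplitude is
#'   multiplied by `1 - quench_max * cu / (cu + quench_k)`.
#' @param noise fractional Gaussian noise per data kind (of signal
#'   amplitude for plate-reader traces, of first-point intensity for NMR).
#' @param t_max,n_time time grid for unseeded traces (s, points).
#' @param seed_mass seeded kinetics: seed mass concentration (M).
#' @param seed_p0 concentration of elongation-competent fibril ends in the
#'   seed stock (M). This, not the seed mass, sets the initial elongation
#'   flux `2 k_plus m0 P0`; the default keeps the seeded trace linear over
#'   the initial fit window, as the study design (a 9-min linear fit)
#'   presumes.
#' @param m0_seeded monomer concentration in seeded experiments (M).
#' @param r1_truth,r2_dia_truth baseline amide-proton rates (s^-1).
#' @param j_hnha scalar coupling (Hz) used in R2 generation and fitting.
#' @param pre_model_cfg [pre_model()] used for PRE truth.
#' @param blind_dia,blind_para_hn,blind_para_c13 blind-sphere radii
#'   (Angstrom) thresholding visibility in dia and para experiments.
#' @param d_free free-state diffusion coefficient (m^2/s).
#' @param db_over_dfree bound/free diffusion ratio truth.
#' @param pb_slopes bound-population slope per metal (per unit ratio).
#' @param diff_ratios titration ratios per metal.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    params = kinetic_params(k_n = 1e-4, k_2 = 1e4, k_plus = 3e6),
    m_tot = 3e-6,
    cu_levels = c(0, 2.5, 5, 7.5, 10) * 1e-6,
    n_replicates = 5L,
    kd_truth = 0.7e-6,
    quench_max = 0.72, quench_k = 2e-6,
    noise = list(tht = 0.03, relax = 0.02, diffusion = 0.005),
    t_max = 15 * 3600, n_time = 301L,
    seed_mass = 1.5e-6, seed_p0 = 2e-11, m0_seeded = 3.2e-6,
    r1_truth = 2.5, r2_dia_truth = 10, j_hnha = 6,
    pre_model_cfg = pre_model(),
    blind_dia = 9.0, blind_para_hn = 6.5, blind_para_c13 = 4.5,
    d_free = 6.82e-11, db_over_dfree = 1.094,
    pb_slopes = c(Cu = 1.2, Zn = 0.9, Ag = 0.6),
    diff_ratios = seq(0, 1.2, by = 0.1)) {
  structure(as.list(environment()), class = "generator_config")
}

quench_factor <- function(cu, cfg) {
  1 - cfg$quench_max * cu / (cu + cfg$quench_k)
}

#' Generate unseeded dye-reported aggregation traces
#'
#' For each Cu level, `k_plus` is scaled by the free monomer fraction at the
#' truth K_D (metal-bound monomers are aggregation-inert), the normalized
#' fibril mass follows the closed-form rate law, the final amplitude is
#' multiplied by the Cu-dependent quench factor, and i.i.d. Gaussian noise
#' (fraction of the quenched amplitude) is added.
#'
#' @param cfg a [generator_config()].
#' @return List of [aggregation_trace()] objects (conditions x replicates),
#'   with attribute `"truth"` (per-condition data frame of the scaled
#'   constants, quench factors and free fractions).
#' @export
gen_tht_traces <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  tg <- seq(0, cfg$t_max, length.out = cfg$n_time)
  init <- initial_state(cfg$m_tot)
  truth <- data.frame(cu_conc = cfg$cu_levels)
  truth$f_free <- free_monomer_fraction(truth$cu_conc / cfg$m_tot,
                                        cfg$kd_truth, cfg$m_tot)
  truth$k_plus <- cfg$params$k_plus * truth$f_free
  truth$quench <- quench_factor(truth$cu_conc, cfg)
  traces <- list()
  for (i in seq_along(cfg$cu_levels)) {
    p <- kinetic_params(cfg$params$k_n, cfg$params$k_2, truth$k_plus[i],
                        cfg$params$n_c, cfg$params$n_2)
    alpha <- fibril_mass_closed_form(p, init, tg)$alpha
    clean <- alpha * truth$quench[i]
    for (rep in seq_len(cfg$n_replicates)) {
      sig <- clean + stats::rnorm(length(tg),
                                  sd = cfg$noise$tht * truth$quench[i])
      traces[[length(traces) + 1]] <- aggregation_trace(
        tg, sig, cu_conc = cfg$cu_levels[i], ab_conc = cfg$m_tot,
        replicate = rep)
    }
  }
  attr(traces, "truth") <- truth
  traces
}

#' Generate highly seeded aggregation traces
#'
#' Moment-ODE trajectories dominated by fibril-end elongation, with a short
#' equilibration transient multiplying the first moments of the signal,
#' mirroring the burn-in phase excluded from initial-slope fits.
#'
#' @param cfg a [generator_config()].
#' @param t_max,n_time trace duration (s) and points.
#' @param equilibration time constant (s) of the initial transient.
#' @param noise fractional Gaussian noise; defaults to `cfg$noise$tht`.
#' @return List of seeded [aggregation_trace()]s (one per Cu level) with
#'   attribute `"truth"`.
#' @export
gen_seeded_traces <- function(cfg, t_max = 30 * 60, n_time = 181L,
                              equilibration = 20, noise = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(noise)) noise <- cfg$noise$tht
  set.seed(cfg$seed + 1L)
  tg <- seq(0, t_max, length.out = n_time)
  P0 <- cfg$seed_p0
  init <- initial_state(cfg$m0_seeded, P0 = P0, M0 = cfg$seed_mass)
  truth <- data.frame(cu_conc = cfg$cu_levels)
  truth$f_free <- free_monomer_fraction(truth$cu_conc / cfg$m0_seeded,
                                        cfg$kd_truth, cfg$m0_seeded)
  truth$k_plus <- cfg$params$k_plus * truth$f_free
  truth$P0 <- P0
  traces <- lapply(seq_along(cfg$cu_levels), function(i) {
    p <- kinetic_params(cfg$params$k_n, cfg$params$k_2, truth$k_plus[i],
                        cfg$params$n_c, cfg$params$n_2)
    traj <- solve_moment_odes(p, init, tg)
    # signal on the normalized new-mass scale, with equilibration transient
    sig <- (traj$alpha - traj$alpha[1]) * (1 - exp(-tg / equilibration))
    sig <- sig + stats::rnorm(length(tg), sd = noise)
    aggregation_trace(tg, sig, cu_conc = cfg$cu_levels[i],
                      ab_conc = cfg$m0_seeded, seeded = TRUE,
                      seed_mass = cfg$seed_mass)
  })
  attr(traces, "truth") <- truth
  traces
}

#' Generate relaxation decay series with known rates
#'
#' Mono-exponential R1 decays and J-modulated R2 decays on the measurement
#' schedules (16 delays, 0.002-2 s and 5-200 ms respectively), with
#' multiplicative Gaussian noise relative to the first-point intensity.
#' Para-state R2 rates are the dia rates plus the supplied PRE truth.
#'
#' @param cfg a [generator_config()].
#' @param residues residue numbers.
#' @param gamma2 per-residue PRE truth (s^-1), recycled; 0 for pure dia.
#' @return List with elements `r1`, `r2_dia`, `r2_para` (lists of
#'   [relaxation_series()]) and `truth` data frame.
#' @export
gen_relaxation <- function(cfg, residues = 17:36, gamma2 = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 2L)
  gamma2 <- rep_len(gamma2, length(residues))
  d_r1 <- seq(0.002, 2, length.out = 16)
  d_r2 <- seq(0.005, 0.200, length.out = 16)
  truth <- data.frame(residue = residues,
                      r1 = cfg$r1_truth * (1 + 0.1 * sin(residues / 3)),
                      r2_dia = cfg$r2_dia_truth * (1 + 0.1 * cos(residues / 4)),
                      gamma2 = gamma2)
  truth$r2_para <- truth$r2_dia + truth$gamma2
  noisy <- function(y) y * (1 + stats::rnorm(length(y), sd = cfg$noise$relax))
  mk_r1 <- function(res, r)
    relaxation_series(res, "H", d_r1, noisy(exp(-r * d_r1)),
                      state = "dia", kind = "R1")
  mk_r2 <- function(res, r, state)
    relaxation_series(res, "H", d_r2,
                      noisy(exp(-r * d_r2) * cos(pi * cfg$j_hnha * d_r2)),
                      state = state, kind = "R2", j_hnha = cfg$j_hnha)
  list(r1 = mapply(mk_r1, residues, truth$r1, SIMPLIFY = FALSE),
       r2_dia = mapply(mk_r2, residues, truth$r2_dia,
                       MoreArgs = list(state = "dia"), SIMPLIFY = FALSE),
       r2_para = mapply(mk_r2, residues, truth$r2_para,
                        MoreArgs = list(state = "para"), SIMPLIFY = FALSE),
       truth = truth)
}

#' Toy coordinates of a chain folded around a paramagnetic centre
#'
#' Deterministic 3D positions: the N-terminal segment spirals around the
#' metal at the origin so that nucleus-metal distances grow with sequence
#' separation from the binding region; used as PRE ground truth.
#'
#' @param residues residue numbers.
#' @param atoms atom names generated per residue.
#' @return Data frame `residue`, `atom`, `x`, `y`, `z`, `r` (Angstrom
#'   distance to the centre at the origin).
#' @export
toy_coordinates <- function(residues = 1:23,
                            atoms = c("H", "C", "CA", "CB")) {
  grid <- expand.grid(residue = residues, atom = atoms,
                      stringsAsFactors = FALSE)
  # radial distance grows with separation from the binding region (res ~6);
  # atom-specific offsets keep nuclei of one residue distinct
  off <- c(H = 0.8, C = 0.4, CA = 0.0, CB = -0.6)[grid$atom]
  rad <- 3.2 + 0.75 * abs(grid$residue - 6)^1.05 + off
  th <- 0.8 * grid$residue + c(H = 0.2, C = 0.05, CA = 0, CB = -0.15)[grid$atom]
  z <- 0.4 * (grid$residue - 6)
  data.frame(residue = grid$residue, atom = grid$atom,
             x = rad * cos(th), y = rad * sin(th), z = z,
             r = sqrt((rad * cos(th))^2 + (rad * sin(th))^2 + z^2))
}

#' Generate PRE truth and visibility records from toy coordinates
#'
#' Computes per-nucleus Gamma2 from the toy distances via
#' [distance_to_pre()] (13C nuclei scaled by the gyromagnetic-ratio
#' squared), then thresholds visibility on the blind-sphere radii: nuclei
#' inside the dia blind sphere are dia-invisible; of those, nuclei outside
#' the para blind sphere are para-recovered.
#'
#' @param cfg a [generator_config()].
#' @param coords toy coordinates (default [toy_coordinates()]).
#' @return List: `truth` (coordinates with `gamma2`, visibility flags),
#'   `records` (visibility table for [classify_constraints()], covering
#'   dia-invisible nuclei), `gamma2` (data frame for PRE-bearing,
#'   dia-visible nuclei).
#' @export
gen_pre_profile <- function(cfg, coords = toy_coordinates()) {
  stopifnot(inherits(cfg, "generator_config"))
  gamma_ratio2 <- (6.728284e7 / 2.6752218744e8)^2   # (gammaC / gammaH)^2
  cls <- ifelse(coords$atom == "H", "HN", "C13")
  scale <- ifelse(cls == "HN", 1, gamma_ratio2)
  gamma2 <- distance_to_pre(coords$r, cfg$pre_model_cfg) * scale
  blind_para <- ifelse(cls == "HN", cfg$blind_para_hn, cfg$blind_para_c13)
  dia_visible <- coords$r >= cfg$blind_dia
  para_visible <- coords$r >= blind_para
  truth <- cbind(coords, gamma2 = gamma2, nucleus_class = cls,
                 dia_visible = dia_visible, para_visible = para_visible)
  experiment <- ifelse(cls == "HN", "HSQC",
                       ifelse(coords$atom == "C", "CON",
                              ifelse(coords$atom == "CA", "CaCO", "CbCaCO")))
  inv <- !dia_visible
  records <- data.frame(residue = coords$residue[inv],
                        atom = coords$atom[inv],
                        experiment = experiment[inv],
                        dia_visible = FALSE,
                        para_visible = para_visible[inv],
                        nucleus_class = cls[inv])
  g2 <- data.frame(residue = coords$residue[dia_visible & cls == "HN"],
                   atom = coords$atom[dia_visible & cls == "HN"],
                   gamma2 = gamma2[dia_visible & cls == "HN"])
  list(truth = truth, records = records, gamma2 = g2)
}

#' Generate pulsed-field-gradient decays from the two-state truth
#'
#' For each metal and titration ratio, the observed diffusion coefficient is
#' `D_free (1 + p_B (D_B/D_free - 1))` with `p_B = slope * ratio`; decays
#' follow the Stejskal-Tanner law over 16 gradient strengths with Gaussian
#' noise.
#'
#' @param cfg a [generator_config()].
#' @param gradients gradient strengths (T/m).
#' @return List of [diffusion_dataset()]s with attribute `"truth"`.
#' @export
gen_diffusion <- function(cfg,
                          gradients = seq(0.02, 0.45, length.out = 16)) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 3L)
  out <- list()
  truth <- expand.grid(metal = names(cfg$pb_slopes), ratio = cfg$diff_ratios,
                       stringsAsFactors = FALSE)
  truth$p_B <- pmin(cfg$pb_slopes[truth$metal] * truth$ratio, 1)
  truth$D <- cfg$d_free * (1 + truth$p_B * (cfg$db_over_dfree - 1))
  for (i in seq_len(nrow(truth))) {
    b <- stejskal_tanner_b(gradients, 5e-3, 150e-3)
    I <- exp(-b * truth$D[i])
    I <- I * (1 + stats::rnorm(length(I), sd = cfg$noise$diffusion))
    out[[i]] <- diffusion_dataset(gradients, pmax(I, 1e-6),
                                  metal = truth$metal[i],
                                  ratio = truth$ratio[i])
  }
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic structural ensemble
#'
#' Conformers are random rigid transformations of a toy backbone plus
#' Gaussian coordinate scatter of known magnitude; used to exercise
#' [rmsd_to_mean()] with a controllable precision scale.
#'
#' @param n_conformers number of models.
#' @param n_residues residues (heavy backbone N, CA, C, O per residue).
#' @param scatter per-coordinate Gaussian displacement (Angstrom).
#' @param seed random seed.
#' @return A `structure_ensemble`.
#' @export
gen_ensemble <- function(n_conformers = 5, n_residues = 14, scatter = 1.0,
                         seed = 1L) {
  set.seed(seed)
  atoms <- c("N", "CA", "C", "O")
  n_atoms <- n_residues * length(atoms)
  base <- cbind(seq_len(n_atoms) * 0.9,
                2 * sin(seq_len(n_atoms) / 2),
                2 * cos(seq_len(n_atoms) / 3))
  rand_rot <- function() {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
             2 * (q[2] * q[4] + q[1] * q[3]),
             2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
             2 * (q[3] * q[4] - q[1] * q[2]),
             2 * (q[2] * q[4] - q[1] * q[3]),
             2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
           3, 3, byrow = TRUE)
  }
  conf <- lapply(seq_len(n_conformers), function(i) {
    pert <- base + matrix(stats::rnorm(3 * n_atoms, sd = scatter), ncol = 3)
    pert %*% rand_rot() + matrix(stats::rnorm(3, sd = 10), n_atoms, 3,
                                 byrow = TRUE)
  })
  at <- data.frame(resno = rep(seq_len(n_residues), each = length(atoms)),
                   resid = "ALA", elety = rep(atoms, n_residues))
  structure_ensemble(conf, at)
}
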