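#' Amyloid-beta(1-40) sequence
#'
#' One-letter sequence, 1-based numbering used by all restraint functions.
#' @return Character vector of 40 one-letter codes.
#' @export
abeta40_sequence <- function() {
  strsplit("DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV", "")[[1]]
}

aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

residue_name3 <- function(resno) {
  seq1 <- abeta40_sequence()
  unname(aa3[seq1[resno]])
}

#' Per-residue relaxation decay series
#'
#' @param residue residue number (1-based).
#' @param atom atom name (IUPAC/PDB v3), e.g. `"H"` for the amide proton.
#' @param delays relaxation delays (s), >= 8 points.
#' @param intensities peak intensities (arbitrary units).
#' @param state `"dia"` or `"para"`.
#' @param kind `"R1"` or `"R2"`.
#' @param j_hnha 3J(HN-HA) scalar coupling (Hz); required for R2 fitting,
#'   where it modulates the decay.
#' @return An object of class `relaxation_series`.
#' @export
relaxation_series <- function(residue, atom, delays, intensities,
                              state = c("dia", "para"), kind = c("R1", "R2"),
                              j_hnha = NULL) {
  state <- match.arg(state)
  kind <- match.arg(kind)
  stopifnot(length(delays) == length(intensities), length(delays) >= 8,
            all(is.finite(intensities)))
  structure(list(residue = residue, atom = atom, delays = delays,
                 intensities = intensities, state = state, kind = kind,
                 j_hnha = j_hnha),
            class = "relaxation_series")
}

#' Fit a longitudinal relaxation rate (R1)
#'
#' Mono-exponential with free amplitude and offset,
#' `I(t) = A exp(-R1 t) + c`.
#'
#' @param series a `relaxation_series` with `kind = "R1"`.
#' @return List with `rate` (s^-1), `se`, `amplitude`, `offset`,
#'   `negative_rate` flag (intensity grows with delay).
#' @export
fit_r1 <- function(series) {
  stopifnot(inherits(series, "relaxation_series"), series$kind == "R1")
  t <- series$delays
  y <- series$intensities
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    return(list(rate = 0, se = 0, amplitude = 0, offset = mean(y),
                negative_rate = FALSE))
  }
  span <- y[which.min(t)] - y[which.max(t)]
  r0 <- max(1 / diff(range(t)), 1e-3)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-R * t) + c0,
    start = list(A = span, R = r0, c0 = min(y)),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["R", "Std. Error"],
                 error = function(e) NA_real_)
  list(rate = unname(cf["R"]), se = se, amplitude = unname(cf["A"]),
       offset = unname(cf["c0"]), negative_rate = unname(cf["R"]) < 0)
}

#' Fit a transverse relaxation rate (R2) with J-coupling modulation
#'
#' Amide-proton R2 decays measured as spin echoes are modulated by the
#' 3J(HN-HA) coupling; the model is `I(tau) = A exp(-R2 tau) cos(pi J tau)`
#' with `J` fixed to its supplied (literature) value, not fitted.
#'
#' @param series a `relaxation_series` with `kind = "R2"` and `j_hnha` set.
#' @return List with `rate` (s^-1), `se`, `amplitude`.
#' @export
fit_r2_jmod <- function(series) {
  stopifnot(inherits(series, "relaxation_series"), series$kind == "R2")
  if (is.null(series$j_hnha))
    stop("j_hnha coupling is required for R2 fitting")
  J <- series$j_hnha
  t <- series$delays
  y <- series$intensities
  r0 <- max(2 / diff(range(t)), 1)
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-R * t) * cos(pi * J * t),
    start = list(A = y[which.min(t)], R = r0),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["R", "Std. Error"],
                 error = function(e) NA_real_)
  list(rate = unname(cf["R"]), se = se, amplitude = unname(cf["A"]))
}

#' Transverse PRE (Gamma2) from paired para/dia R2 rates
#'
#' `Gamma2 = R2(para) - R2(dia)` per residue, with propagated uncertainty.
#' Negative differences within their propagated error are clipped to zero
#' and flagged; residues present in only one state are listed and skipped.
#'
#' @param r2_para,r2_dia data frames with columns `residue`, `atom`, `rate`,
#'   `se`.
#' @return Data frame `residue`, `atom`, `gamma2` (s^-1), `se`, `clipped`.
#'   Skipped residues are in attribute `"unmatched"`.
#' @export
compute_pre <- function(r2_para, r2_dia) {
  m <- merge(r2_para, r2_dia, by = c("residue", "atom"),
             suffixes = c("_para", "_dia"))
  unmatched <- c(
    setdiff(paste(r2_para$residue, r2_para$atom),
            paste(m$residue, m$atom)),
    setdiff(paste(r2_dia$residue, r2_dia$atom),
            paste(m$residue, m$atom)))
  gamma2 <- m$rate_para - m$rate_dia
  se <- sqrt(m$se_para^2 + m$se_dia^2)
  clipped <- gamma2 < 0 & abs(gamma2) <= se
  gamma2[clipped] <- 0
  out <- data.frame(residue = m$residue, atom = m$atom, gamma2 = gamma2,
                    se = se, clipped = clipped)
  attr(out, "unmatched") <- unmatched
  if (length(unmatched))
    warning("unmatched nuclei skipped: ", paste(unmatched, collapse = ", "))
  out
}

#' Effective correlation time of the electron-nucleus interaction
#'
#' Harmonic combination of the rotational correlation time and the effective
#' electron relaxation time, `tau_c = (tau_r^-1 + tau_s^-1)^-1`.
#'
#' @param tau_r rotational correlation time (s), > 0.
#' @param tau_s effective electron relaxation time (s), > 0; may be `Inf`.
#' @return tau_c in the same unit as the inputs.
#' @examples
#' correlation_time(2.56e-9, 5.0e-9)  # 1.69 ns
#' @export
correlation_time <- function(tau_r, tau_s) {
  stopifnot(tau_r > 0, tau_s > 0)
  1 / (1 / tau_r + 1 / tau_s)
}

#' Physical model for PRE-to-distance conversion
#'
#' Constants of the Solomon dipolar relaxation expression for a nucleus at
#' distance r from an S = 1/2 paramagnetic centre:
#' \deqn{\Gamma_2 = \frac{1}{15} \left(\frac{\mu_0}{4\pi}\right)^2
#'   \gamma_H^2 g^2 \mu_B^2 S(S+1) r^{-6} [4 J(0) + 3 J(\omega_H)]}
#' with spectral density \eqn{J(\omega) = \tau_c / (1 + \omega^2 \tau_c^2)}.
#' Note the sensitivity to the electron g-factor is weak in distance terms
#' (r scales as g^(1/3)); the free-electron value is the default and Cu(II)
#' EPR values (2.1-2.2) can be supplied instead.
#'
#' @param field_mhz proton Larmor frequency (MHz).
#' @param tau_r,tau_s rotational / electron correlation times (s).
#' @param g electron g-factor.
#' @param S electron spin quantum number (1/2 for Cu(II)).
#' @param gamma_h proton gyromagnetic ratio (rad s^-1 T^-1).
#' @return Object of class `pre_model` with the derived `tau_c`, `omega_h`
#'   and dipolar prefactor (m^6 s^-2).
#' @export
pre_model <- function(field_mhz = 950, tau_r = 2.56e-9, tau_s = 5.0e-9,
                      g = 2.0023, S = 0.5, gamma_h = 2.6752218744e8) {
  mu0_over_4pi <- 1e-7         # T m / A
  mu_b <- 9.2740100783e-24     # J / T
  tau_c <- correlation_time(tau_r, tau_s)
  prefactor <- (1 / 15) * mu0_over_4pi^2 * gamma_h^2 * g^2 * mu_b^2 *
    S * (S + 1)
  structure(list(field_mhz = field_mhz, omega_h = 2 * pi * field_mhz * 1e6,
                 tau_r = tau_r, tau_s = tau_s, tau_c = tau_c, g = g, S = S,
                 gamma_h = gamma_h, prefactor = prefactor),
            class = "pre_model")
}

spectral_density <- function(omega, tau_c) tau_c / (1 + (omega * tau_c)^2)

pre_dipolar_scale <- function(model) {
  # Gamma2 * r^6, in m^6 s^-1
  model$prefactor * (4 * spectral_density(0, model$tau_c) +
                       3 * spectral_density(model$omega_h, model$tau_c))
}

#' Convert a transverse PRE into a distance
#'
#' Inverts the Solomon expression: `r = (scale / Gamma2)^(1/6)`. The exact
#' algebraic inverse of [distance_to_pre()].
#'
#' @param gamma2 transverse PRE (s^-1), > 0.
#' @param model a [pre_model()].
#' @return Distance in Angstrom.
#' @export
pre_to_distance <- function(gamma2, model = pre_model()) {
  if (any(gamma2 <= 0))
    stop("distance is undefined for non-positive Gamma2")
  (pre_dipolar_scale(model) / gamma2)^(1 / 6) * 1e10
}

#' Predicted transverse PRE at a given distance
#'
#' @param r_angstrom distance to the paramagnetic centre (Angstrom), > 0.
#' @param model a [pre_model()].
#' @return Gamma2 in s^-1.
#' @export
distance_to_pre <- function(r_angstrom, model = pre_model()) {
  stopifnot(all(r_angstrom > 0))
  pre_dipolar_scale(model) / (r_angstrom * 1e-10)^6
}

#' Peak-visibility annotations for one nucleus in one experiment
#'
#' @param residue residue number.
#' @param atom atom name.
#' @param experiment `"HSQC"`, `"CON"`, `"CaCO"` or `"CbCaCO"`.
#' @param dia_visible,para_visible visibility in the conventional (dia) and
#'   paramagnetically tailored (para) version of the experiment.
#' @param nucleus_class `"HN"` or `"C13"`; sets which blind-sphere shell
#'   applies.
#' @return One-row data frame; rbind records into a table for
#'   [classify_constraints()].
#' @export
visibility_record <- function(residue, atom, experiment,
                              dia_visible, para_visible,
                              nucleus_class = c("HN", "C13")) {
  nucleus_class <- match.arg(nucleus_class)
  data.frame(residue = residue, atom = atom, experiment = experiment,
             dia_visible = dia_visible, para_visible = para_visible,
             nucleus_class = nucleus_class)
}

#' Default Cu(II) binding-ligand atoms of amyloid-beta
#'
#' The nitrogen of the NH2 terminus, the backbone amide oxygen of D1, the
#' N-epsilon of H6 and the N-delta of H13 or H14 (alternative fourth
#' ligand).
#'
#' @param fourth `13` or `14`: which histidine provides the fourth ligand.
#' @return Data frame `residue`, `atom`.
#' @export
cu_abeta_ligands <- function(fourth = 13) {
  stopifnot(fourth %in% c(13, 14))
  data.frame(residue = c(1, 1, 6, fourth),
             atom = c("N", "O", "NE2", "ND1"))
}

#' Classify nuclei into distance restraints
#'
#' Combines visibility annotations across experiments, PRE distances and the
#' binding-ligand list into one restraint per nucleus:
#' \itemize{
#'   \item ligand atoms: 1.8-2.3 Angstrom (coordination bond);
#'   \item PRE nuclei: `r +/- 0.5` Angstrom;
#'   \item recovered only in para-experiments (between the two blind
#'     spheres): 6.5-9.0 Angstrom for amide protons, 4.5-9.0 for 13C nuclei;
#'   \item invisible even in para-experiments (inside the para blind
#'     sphere): upper limit 6.5 Angstrom (lower limit 2.5, just above
#'     coordination contact);
#'   \item dia-visible nuclei without measurable PRE, inside the modelled
#'     N-terminal segment: lower limit 9.0 Angstrom (outside the dia blind
#'     sphere), no upper limit.
#' }
#' Precedence when a nucleus qualifies for several classes:
#' ligand > PRE > shell > para_invisible > dia_visible.
#'
#' @param records data frame of [visibility_record()] rows.
#' @param pre_distances optional data frame `residue`, `atom`, `r`
#'   (Angstrom) from [pre_to_distance()].
#' @param ligand_atoms optional data frame `residue`, `atom`
#'   (default [cu_abeta_ligands()]).
#' @param modeled_residues residues covered by the structural model; only
#'   these receive dia-visible lower-bound restraints.
#' @param pre_halfwidth half-width of the PRE distance interval (Angstrom).
#' @return Data frame of class `restraint_set`: `residue`, `resname`,
#'   `atom`, `lower`, `upper` (Angstrom; `Inf` = no upper limit),
#'   `provenance`. Nuclei with no applicable class are returned with
#'   provenance `"unconstrained"` and NA bounds.
#' @export
classify_constraints <- function(records, pre_distances = NULL,
                                 ligand_atoms = cu_abeta_ligands(),
                                 modeled_residues = 1:23,
                                 pre_halfwidth = 0.5) {
  stopifnot(all(c("residue", "atom", "experiment", "dia_visible",
                  "para_visible", "nucleus_class") %in% names(records)))
  key <- paste(records$residue, records$atom)
  conflicts <- unlist(lapply(split(records, paste(key, records$experiment)),
    function(g) {
      if (length(unique(g$dia_visible)) > 1 || length(unique(g$para_visible)) > 1)
        paste0(g$residue[1], ":", g$atom[1], " (", g$experiment[1], ")")
      else NULL
    }))
  if (length(conflicts))
    stop("conflicting visibility records for: ",
         paste(conflicts, collapse = ", "))
  rows <- lapply(split(records, key), function(g) {
    res <- g$residue[1]; atm <- g$atom[1]; ncl <- g$nucleus_class[1]
    dia <- any(g$dia_visible); para <- any(g$para_visible)
    lig <- !is.null(ligand_atoms) &&
      any(ligand_atoms$residue == res & ligand_atoms$atom == atm)
    pre_r <- if (!is.null(pre_distances)) {
      hit <- pre_distances$residue == res & pre_distances$atom == atm
      if (any(hit)) pre_distances$r[which(hit)[1]] else NA_real_
    } else NA_real_
    if (lig) {
      b <- c(1.8, 2.3); prov <- "ligand"
    } else if (is.finite(pre_r)) {
      b <- c(pre_r - pre_halfwidth, pre_r + pre_halfwidth); prov <- "PRE"
    } else if (!dia && para) {
      b <- if (ncl == "HN") c(6.5, 9.0) else c(4.5, 9.0); prov <- "shell"
    } else if (!dia && !para) {
      b <- c(2.5, 6.5); prov <- "para_invisible"
    } else if (dia && res %in% modeled_residues) {
      b <- c(9.0, Inf); prov <- "dia_visible"
    } else {
      b <- c(NA_real_, NA_real_); prov <- "unconstrained"
    }
    data.frame(residue = res, resname = residue_name3(res), atom = atm,
               lower = b[1], upper = b[2], provenance = prov)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue, out$atom), ]
  rownames(out) <- NULL
  # PRE distances for nuclei absent from the visibility table still
  # contribute restraints
  if (!is.null(pre_distances)) {
    extra <- !(paste(pre_distances$residue, pre_distances$atom) %in%
                 paste(out$residue, out$atom))
    if (any(extra)) {
      pd <- pre_distances[extra, ]
      out <- rbind(out, data.frame(
        residue = pd$residue, resname = residue_name3(pd$residue),
        atom = pd$atom, lower = pd$r - pre_halfwidth,
        upper = pd$r + pre_halfwidth, provenance = "PRE"))
      out <- out[order(out$residue, out$atom), ]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Write restraints in the torsion-angle-dynamics dialect
#'
#' Writes upper- and lower-limit files (one line per bound: residue number,
#' residue name, atom name, distance in Angstrom, the format consumed by
#' torsion-angle-dynamics structure calculation). Output is byte-stable for
#' identical input ordering. Restraints with provenance `"unconstrained"`
#' are skipped; infinite upper bounds appear only in the lower-limit file.
#'
#' @param restraints a `restraint_set` from [classify_constraints()].
#' @param upl_path,lol_path output paths for upper and lower limit files.
#' @return Invisibly, `c(upl_path, lol_path)`.
#' @export
write_restraints <- function(restraints, upl_path, lol_path) {
  stopifnot(inherits(restraints, "data.frame"))
  known <- c("N", "O", "C", "CA", "CB", "CG", "CD", "CE", "H", "HN", "HA",
             "HB", "ND1", "NE2", "NE", "NZ", "HE21", "HE22", "OD1", "OD2",
             "OE1", "OE2", "CD1", "CD2", "CE1", "CE2", "CZ", "CG1", "CG2")
  bad <- setdiff(unique(restraints$atom), known)
  if (length(bad))
    stop("atom names not in the adopted nomenclature table: ",
         paste(bad, collapse = ", "))
  use <- restraints$provenance != "unconstrained" &
    is.finite(restraints$lower)
  r <- restraints[use, ]
  fmt <- function(res, name, atom, d)
    sprintf("%4d %-4s %-5s %6.2f", res, name, atom, d)
  hdr <- "# residue resname atom bound_angstrom"
  upl <- c(hdr, fmt(r$residue, r$resname, r$atom, r$upper)[is.finite(r$upper)])
  lol <- c(hdr, fmt(r$residue, r$resname, r$atom, r$lower)[r$lower > 0])
  writeLines(upl, upl_path)
  writeLines(lol, lol_path)
  invisible(c(upl_path, lol_path))
}

#' Read a restraint file written by [write_restraints()]
#'
#' @param path an `.upl` or `.lol` file.
#' @return Data frame `residue`, `resname`, `atom`, `bound`.
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(residue = integer(), resname = character(),
                      atom = character(), bound = numeric()))
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(residue = as.integer(vapply(parts, `[`, "", 1)),
             resname = vapply(parts, `[`, "", 2),
             atom = vapply(parts, `[`, "", 3),
             bound = as.numeric(vapply(parts, `[`, "", 4)))
}

#' Per-residue intensity attenuation profile
#'
#' Intensity ratio I/I0 of a metal-titrated (holo) spectrum relative to the
#' metal-free (apo) reference, clipped at zero. Residues with zero reference
#' intensity are excluded and flagged.
#'
#' @param holo,apo data frames with columns `residue`, `intensity`.
#' @return Data frame `residue`, `ratio`; excluded residues in attribute
#'   `"excluded"`.
#' @export
attenuation_profile <- function(holo, apo) {
  m <- merge(holo, apo, by = "residue", suffixes = c("_holo", "_apo"))
  bad <- m$intensity_apo == 0
  out <- data.frame(residue = m$residue[!bad],
                    ratio = pmax(m$intensity_holo[!bad] /
                                   m$intensity_apo[!bad], 0))
  attr(out, "excluded") <- m$residue[bad]
  out
}
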