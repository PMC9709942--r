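test_that("R1 fit recovers noiseless and constant decays", {
  expect_equal(fit_r1(r1_series(2.0))$rate, 2.0, tolerance = 1e-6)
  d <- seq(0.002, 2, length.out = 16)
  const <- relaxation_series(20, "H", d, rep(1, 16), kind = "R1")
  expect_equal(fit_r1(const)$rate, 0)
})

test_that("R1 recovery within 5% at 2% noise over 100 seeds", {
  set.seed(202)
  rates <- replicate(100, fit_r1(r1_series(3.1, noise = 0.02))$rate)
  expect_lt(abs(median(rates) / 3.1 - 1), 0.05)
  expect_gt(mean(abs(rates / 3.1 - 1) < 0.05), 0.9)
})

test_that("J-modulated R2 fit reduces to mono-exponential at J = 0", {
  s <- r2_series(20, j = 0)
  expect_equal(fit_r2_jmod(s)$rate, 20, tolerance = 1e-6)
  expect_error(fit_r2_jmod(relaxation_series(5, "H", s$delays, s$intensities,
                                             kind = "R2")),
               "j_hnha")
})

test_that("J-modulated R2 recovery within 5% at 2% noise", {
  set.seed(203)
  rates <- replicate(100, fit_r2_jmod(r2_series(25, j = 6, noise = 0.02))$rate)
  expect_lt(abs(median(rates) / 25 - 1), 0.05)
  # the fitted amplitude is the zero-delay intensity regardless of J
  for (j in c(0, 6, 11))
    expect_equal(fit_r2_jmod(r2_series(25, j = j))$amplitude, 1,
                 tolerance = 1e-6)
})

test_that("PRE differences behave additively and clip within error", {
  para <- data.frame(residue = 1:3, atom = "H", rate = c(18, 10, 9.8),
                     se = c(0.5, 0.5, 0.5))
  dia <- data.frame(residue = 1:3, atom = "H", rate = c(10, 10, 10),
                    se = c(0.5, 0.5, 0.5))
  pre <- compute_pre(para, dia)
  expect_equal(pre$gamma2, c(8, 0, 0))
  expect_true(pre$clipped[3])
  # common offset on both states leaves Gamma2 unchanged
  pre2 <- compute_pre(transform(para, rate = rate + 5),
                      transform(dia, rate = rate + 5))
  expect_equal(pre2$gamma2, pre$gamma2)
})

test_that("unmatched residues are skipped with a warning", {
  para <- data.frame(residue = 1:2, atom = "H", rate = c(12, 13), se = 0.1)
  dia <- data.frame(residue = 2:3, atom = "H", rate = c(10, 10), se = 0.1)
  expect_warning(pre <- compute_pre(para, dia), "unmatched")
  expect_equal(nrow(pre), 1)
})

test_that("correlation time is the harmonic combination", {
  expect_equal(correlation_time(2.56, 5.0), 1.69, tolerance = 0.005)
  expect_equal(correlation_time(3, Inf), 3)
  expect_equal(correlation_time(2, 2), 1)
})

test_that("PRE-distance conversion round-trips and follows r^-6", {
  m <- pre_model()
  r <- c(4, 8, 12, 20)
  expect_equal(pre_to_distance(distance_to_pre(r, m), m), r,
               tolerance = 1e-10)
  # multiplying Gamma2 by 64 halves the distance
  g <- distance_to_pre(8, m)
  expect_equal(pre_to_distance(64 * g, m), 4, tolerance = 1e-10)
  expect_error(pre_to_distance(0, m), "undefined")
})

test_that("conversion is strictly monotone in both directions", {
  m <- pre_model()
  g <- seq(5, 500, length.out = 50)
  expect_true(all(diff(pre_to_distance(g, m)) < 0))
  r <- seq(3, 25, length.out = 50)
  expect_true(all(diff(distance_to_pre(r, m)) < 0))
})

test_that("the distance window of the study maps to physically large PREs", {
  # with the Solomon prefactor at 950 MHz and tau_c = 1.69 ns, nuclei
  # restrained to 7.6-9.1 A correspond to Gamma2 of order 1e2 s^-1
  m <- pre_model()
  g <- distance_to_pre(c(7.6, 9.1), m)
  expect_true(all(g > 1 & g < 1e3))
})

test_that("constraint classification follows the reported shell rules", {
  recs <- rbind(
    visibility_record(3, "H", "HSQC", FALSE, TRUE, "HN"),
    visibility_record(8, "C", "CON", FALSE, TRUE, "C13"),
    visibility_record(1, "C", "CON", FALSE, FALSE, "C13"),
    visibility_record(20, "H", "HSQC", TRUE, TRUE, "HN"),
    visibility_record(30, "H", "HSQC", TRUE, TRUE, "HN"))
  rs <- classify_constraints(recs, ligand_atoms = NULL)
  get <- function(res, atom) rs[rs$residue == res & rs$atom == atom, ]
  expect_equal(unlist(get(3, "H")[c("lower", "upper")]),
               c(lower = 6.5, upper = 9.0))
  expect_equal(unlist(get(8, "C")[c("lower", "upper")]),
               c(lower = 4.5, upper = 9.0))
  expect_equal(get(1, "C")$upper, 6.5)
  expect_identical(get(1, "C")$provenance, "para_invisible")
  # dia-visible in the modelled segment: lower bound 9 A, no upper bound
  expect_equal(get(20, "H")$lower, 9.0)
  expect_equal(get(20, "H")$upper, Inf)
  # outside the modelled segment: unconstrained
  expect_identical(get(30, "H")$provenance, "unconstrained")
})

test_that("precedence is ligand > PRE > shell and total", {
  recs <- rbind(
    visibility_record(6, "NE2", "HSQC", FALSE, FALSE, "HN"),
    visibility_record(3, "H", "HSQC", FALSE, TRUE, "HN"))
  pre_d <- data.frame(residue = 3, atom = "H", r = 8.0)
  rs <- classify_constraints(recs, pre_distances = pre_d)
  expect_identical(rs$provenance[rs$residue == 6], "ligand")
  expect_equal(unlist(rs[rs$residue == 6, c("lower", "upper")]),
               c(lower = 1.8, upper = 2.3))
  # the PRE interval overrides the shell for E3's amide
  expect_identical(rs$provenance[rs$residue == 3], "PRE")
  expect_equal(unlist(rs[rs$residue == 3, c("lower", "upper")]),
               c(lower = 7.5, upper = 8.5))
  # every nucleus maps to exactly one row
  expect_equal(nrow(rs), 2)
})

test_that("conflicting visibility records are rejected with the nucleus named", {
  recs <- rbind(
    visibility_record(3, "H", "HSQC", FALSE, TRUE, "HN"),
    visibility_record(3, "H", "HSQC", FALSE, FALSE, "HN"))
  expect_error(classify_constraints(recs), "3:H")
})

test_that("the reported visibility census yields 42 para-derived restraints", {
  rs <- classify_constraints(cu_abeta_visibility(), ligand_atoms = NULL)
  para_derived <- rs$provenance %in% c("shell", "para_invisible")
  expect_equal(sum(para_derived), 42)
  expect_equal(nrow(rs), 42)
  expect_equal(sum(rs$provenance == "shell"), 17)   # 6 HN + 3 + 3 + 5 13C
  expect_equal(sum(rs$provenance == "para_invisible"), 25)
})

test_that("restraint files round-trip and apply the +/- 0.5 A PRE rule", {
  pre_d <- data.frame(residue = 3, atom = "H", r = 8.0)
  recs <- visibility_record(4, "H", "HSQC", FALSE, TRUE, "HN")
  rs <- classify_constraints(recs, pre_distances = pre_d, ligand_atoms = NULL)
  upl <- tempfile(fileext = ".upl"); lol <- tempfile(fileext = ".lol")
  write_restraints(rs, upl, lol)
  up <- read_restraints(upl); lo <- read_restraints(lol)
  expect_equal(up$bound[up$residue == 3], 8.5)
  expect_equal(lo$bound[lo$residue == 3], 7.5)
  expect_equal(up$bound[up$residue == 4], 9.0)
  expect_equal(lo$bound[lo$residue == 4], 6.5)
  # byte stability for identical input
  upl2 <- tempfile(); write_restraints(rs, upl2, tempfile())
  expect_identical(readLines(upl), readLines(upl2))
})

test_that("empty restraint sets give headers only; bad atoms are named", {
  rs <- classify_constraints(
    visibility_record(30, "H", "HSQC", TRUE, TRUE, "HN"),
    ligand_atoms = NULL)   # unconstrained only
  upl <- tempfile(); lol <- tempfile()
  write_restraints(rs, upl, lol)
  expect_equal(nrow(read_restraints(upl)), 0)
  bad <- rs; bad$atom <- "QX9"; bad$provenance <- "shell"; bad$lower <- 1
  expect_error(write_restraints(bad, upl, lol), "QX9")
})

test_that("attenuation profiles ratio, clip and exclude correctly", {
  apo <- data.frame(residue = 1:5, intensity = c(10, 10, 10, 0, 10))
  holo <- data.frame(residue = 1:5, intensity = c(0, 5, 10, 5, -1))
  at <- attenuation_profile(holo, apo)
  expect_equal(at$ratio, c(0, 0.5, 1, 0))
  expect_equal(attr(at, "excluded"), 4)
  ident <- attenuation_profile(apo, apo)
  expect_true(all(ident$ratio[ident$residue != 4] == 1))
})
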