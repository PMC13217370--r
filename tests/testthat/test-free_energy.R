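test_that("Gibbs composition is the E + ZPE + Hth - TS sum and is linear", {
  expect_identical(gibbs_from_components(0, 0, 0, 0), 0)
  expect_identical(gibbs_from_components(-100, 10, 5, 20), -105)
  set.seed(42)
  for (i in 1:100) {
    x <- stats::rnorm(4, sd = 50)
    expect_equal(gibbs_from_components(x[1], x[2], x[3], x[4]),
                 x[1] + x[2] + x[3] - x[4])
  }
  # superposition in each argument
  set.seed(7)
  a <- stats::rnorm(4); b <- stats::rnorm(4)
  expect_equal(gibbs_from_components(a[1] + b[1], a[2] + b[2],
                                     a[3] + b[3], a[4] + b[4]),
               gibbs_from_components(a[1], a[2], a[3], a[4]) +
                 gibbs_from_components(b[1], b[2], b[3], b[4]))
  expect_error(gibbs_from_components(NaN), "finite")
})

test_that("Sackur-Tetrode entropy matches the argon benchmark and its scaling laws", {
  # argon, 298.15 K, 1 atm ideal-gas molar volume (equivalent concentration
  # P/RT).  Reference: tabulated standard entropy of argon 154.846 J/mol/K
  # at 1 bar, shifted to 1 atm by -R ln(1.01325) => 154.737 J/mol/K.
  c_atm <- 101325 / (R_GAS * 298.15) / 1e3   # mol/L
  S <- sackur_tetrode_entropy(6.6335e-26, 298.15, c_atm)
  expect_equal(S, 154.737, tolerance = 1e-4)
  # doubling T at fixed molar volume adds (3/2) R ln 2
  expect_equal(sackur_tetrode_entropy(6.6335e-26, 2 * 298.15, c_atm) - S,
               1.5 * R_GAS * log(2), tolerance = 1e-10)
  # halving concentration (doubling molar volume) adds R ln 2
  expect_equal(sackur_tetrode_entropy(6.6335e-26, 298.15, c_atm / 2) - S,
               R_GAS * log(2), tolerance = 1e-10)
  # strictly increasing in T and in molar volume
  Ts <- seq(200, 400, by = 25)
  expect_true(all(diff(sapply(Ts, function(Ti)
    sackur_tetrode_entropy(1e-25, Ti, 0.1))) > 0))
  cs <- 10^seq(-3, 1, by = 0.5)
  expect_true(all(diff(sapply(cs, function(ci)
    sackur_tetrode_entropy(1e-25, 300, ci))) < 0))
  expect_error(sackur_tetrode_entropy(-1, 300, 1), "positive")
})

test_that("profile construction validates its invariants", {
  expect_error(free_energy_profile(c(1, 2), c(0, 0)), "length")
  expect_error(free_energy_profile(c(1, 3, 2), c(-1, 5, 0)), "increasing")
  expect_error(free_energy_profile(c(1, 2, 3), c(-1, 5, 2)), "reference")
  expect_error(free_energy_profile(c(1, 2, 3), c(-1, 5, 0), a = 5), "within")
})

test_that("build_profile round-trips well depth and barrier height", {
  p <- build_profile(dG0 = anchors$dG0_rt, Ea = anchors$Ea_rt)
  th <- extract_thermo(p)
  expect_equal(th$dG0, anchors$dG0_rt, tolerance = 1e-6)
  expect_equal(th$Ea, anchors$Ea_rt, tolerance = 1e-6)
  expect_true(th$bound)
  # flat limit
  p0 <- build_profile(0, 0)
  expect_true(all(abs(p0$G) < 1e-12))
  # random admissible parameter sets
  set.seed(11)
  for (i in 1:50) {
    dG0 <- stats::runif(1, -80, -5)
    Ea <- stats::runif(1, 0.5, 100)
    r_well <- stats::runif(1, 1.5, 4)
    r_barrier <- r_well + stats::runif(1, 2, 8)
    p <- build_profile(dG0, Ea, r_well = r_well, r_barrier = r_barrier,
                       a = 1, r_max = 40)
    th <- extract_thermo(p)
    expect_equal(th$dG0, dG0, tolerance = 1e-6)
    expect_equal(th$Ea, Ea, tolerance = 1e-6)
  }
  expect_error(build_profile(-10, 5, r_well = 6, r_barrier = 5), "r_well")
})

test_that("extract_thermo flags unbound / barrierless profiles and refines", {
  # monotone decreasing towards the separated state: no interior minimum
  r <- seq(2, 40, length.out = 50)
  G <- 30 * exp(-(r - 2) / 3); G[length(G)] <- 0
  th <- extract_thermo(free_energy_profile(r, G))
  expect_false(th$bound)
  expect_identical(th$dG0, 0)
  # dense-grid refinement changes nothing beyond grid resolution
  p_coarse <- build_profile(-20, 30, n_points = 200)
  p_fine <- build_profile(-20, 30, n_points = 4000)
  expect_equal(extract_thermo(p_coarse)$dG0, extract_thermo(p_fine)$dG0,
               tolerance = 1e-6)
  expect_equal(extract_thermo(p_coarse)$Ea, extract_thermo(p_fine)$Ea,
               tolerance = 1e-6)
})

test_that("profile file I/O round-trips and validates", {
  p <- build_profile(-30, 40, n_points = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, f)
  q <- read_profile(f, T_K = p$T_K, a = p$a)
  expect_equal(q$r, p$r, tolerance = 1e-9)
  expect_equal(q$G, p$G, tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "2 -5", "1 3", "40 0"), bad)
  expect_error(read_profile(bad), "increasing")
  # the shipped synthetic profile carries the anchor well/barrier scalars
  shipped <- system.file("extdata", "profile_pb_probe_298K_synthetic.tsv",
                         package = "pulsefet")
  th <- extract_thermo(read_profile(shipped))
  expect_equal(th$dG0, anchors$dG0_rt, tolerance = 1e-6)
  expect_equal(th$Ea, anchors$Ea_rt, tolerance = 1e-6)
})

test_that("dielectric interpolation hits both anchors", {
  expect_equal(water_dielectric(298), 78.36)
  expect_equal(water_dielectric(333), 66.77)
  expect_equal(water_dielectric(315.5), (78.36 + 66.77) / 2)
})
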