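test_that("Smoluchowski rate reaches the flat-profile diffusion limit", {
  flat <- free_energy_profile(r = seq(10, 40, length.out = 11),
                              G = rep(0, 11), a = 10)
  k <- smoluchowski_rate(flat, D = 1e-9)
  # 4 pi D NA a in M^-1 s^-1 (a = 1 nm)
  expect_equal(k, 4 * pi * 1e-9 * N_AVO * 1e-9 * 1e3, tolerance = 1e-9)
})

test_that("Smoluchowski quadrature matches the square-barrier closed form", {
  RT <- R_GAS * 298 / 1e3
  D <- 1e-9
  for (Ea in c(5, 20, 50)) {
    aA <- 4; bA <- 10; rmaxA <- 40
    Gsq <- function(r) ifelse(r <= bA, Ea, 0)
    k <- smoluchowski_rate(Gsq, D = D, a = aA, T_K = 298, r_max = rmaxA,
                           breaks = bA)
    I_ang <- exp(Ea / RT) * (1 / aA - 1 / bA) + 1 / bA   # includes tail
    k_closed <- 4 * pi * D * N_AVO / (I_ang * 1e10) * 1e3
    expect_equal(k, k_closed, tolerance = 1e-6)
  }
})

test_that("Smoluchowski rate falls monotonically with barrier height", {
  ks <- sapply(c(0, 10, 20, 40, 60), function(Ea) {
    p <- build_profile(-30, Ea)
    smoluchowski_rate(p, D = 1e-9)
  })
  expect_true(all(diff(ks) < 0))
})

test_that("Smoluchowski quadrature is converged against panel refinement", {
  # smooth functional profile: the adaptive quadrature must be insensitive
  # to its requested tolerance and to how the domain is partitioned
  G <- function(r) -30 * exp(-(r - 2.5)^2 / 0.5) + 25 * exp(-(r - 6)^2 / 0.5)
  k_ref <- smoluchowski_rate(G, D = 1e-9, a = 1.5, T_K = 298, r_max = 40,
                             rel_tol = 1e-12)
  k_loose <- smoluchowski_rate(G, D = 1e-9, a = 1.5, T_K = 298, r_max = 40,
                               rel_tol = 1e-6)
  k_panels <- smoluchowski_rate(G, D = 1e-9, a = 1.5, T_K = 298, r_max = 40,
                                breaks = seq(2, 39, by = 0.5))
  expect_equal(k_loose, k_ref, tolerance = 1e-4)
  expect_equal(k_panels, k_ref, tolerance = 1e-8)
})

test_that("Arrhenius law: barrierless limit, log-linearity, direct value", {
  expect_equal(arrhenius_rate(3.7e8, 0, 310), 3.7e8)
  Ts <- seq(280, 360, by = 10)
  lnk <- log(arrhenius_rate(1e10, anchors$Ea_rt, Ts))
  fit <- stats::lm(lnk ~ I(1 / Ts))
  expect_equal(unname(stats::coef(fit)[2]), -anchors$Ea_rt * 1e3 / R_GAS,
               tolerance = 1e-9)
  expect_equal(arrhenius_rate(1e10, 76.32, 298),
               1e10 * exp(-76320 / (R_GAS * 298)), tolerance = 1e-12)
})

test_that("dissociation constant obeys the standard-state conventions", {
  expect_equal(dissociation_constant(0, 298), 1)
  # frozen from exp(-43840 / (8.314462618 * 298))
  expect_equal(dissociation_constant(anchors$dG0_rt, 298), 2.068704e-8,
               tolerance = 1e-6)
  set.seed(3)
  for (dG in stats::runif(10, -60, 60))
    expect_equal(dissociation_constant(dG, 310) *
                   dissociation_constant(-dG, 310), 1, tolerance = 1e-12)
})

test_that("detailed-balance reverse rates reproduce the printed anchors", {
  kr_rt <- reverse_rate(anchors$kf_rt, anchors$dG0_rt, anchors$T_rt)
  expect_equal(signif(kr_rt, 2), anchors$kr_rt)          # 1.1e-3 /s
  kr_hot <- reverse_rate(anchors$kf_hot, anchors$dG0_hot, anchors$T_hot)
  expect_equal(signif(kr_hot, 1), anchors$kr_hot)        # 3e-1 /s
  # Kd = 1 standard-state identity
  expect_equal(reverse_rate(1234, 0, 300), 1234)
})

test_that("detailed balance links the Smoluchowski rate, dG0 and Kd exactly", {
  p <- build_profile(-35, 30)
  kf <- smoluchowski_rate(p, D = 1e-9)
  th <- extract_thermo(p)
  expect_equal(reverse_rate(kf, th$dG0, p$T_K) / kf,
               dissociation_constant(th$dG0, p$T_K), tolerance = 1e-14)
})

test_that("rate-ratio ordering ranks pulsed > isothermal-RT > sustained-hot", {
  res <- rate_ratio_ordering(anchor_rates_rt(), anchor_rates_hot())
  expect_equal(unname(res$ratios["pulsed"]), 1.22e5 / 1.1e-3,
               tolerance = 1e-12)          # ~1.11e8
  expect_equal(unname(res$ratios["isothermal_rt"]), 5.33e4 / 1.1e-3,
               tolerance = 1e-12)          # ~4.85e7
  expect_equal(unname(res$ratios["sustained_hot"]), 1.22e5 / 3e-1,
               tolerance = 1e-12)          # ~4.07e5
  expect_true(res$ordered)
  # equality fails the strict ordering
  same <- rate_set(298, 1e5, 1e-2)
  expect_false(rate_ratio_ordering(same, same)$ordered)
  # brute-force comparison on random rate sets
  set.seed(5)
  for (i in 1:20) {
    rt <- rate_set(298, 10^stats::runif(1, 2, 6), 10^stats::runif(1, -4, 0))
    hot <- rate_set(333, 10^stats::runif(1, 2, 6), 10^stats::runif(1, -4, 0))
    res <- rate_ratio_ordering(rt, hot)
    expect_identical(res$ordered,
                     hot$kf / rt$kr > rt$kf / rt$kr &&
                       rt$kf / rt$kr > hot$kf / hot$kr)
  }
})

test_that("rate_set enforces detailed balance and positivity", {
  expect_error(rate_set(298, 1e4, 1e-3, Kd = 5), "detailed balance")
  expect_error(rate_set(298, -1, 1e-3), "kf")
  expect_error(rate_ratio_ordering(rate_set(298, 1, 0), anchor_rates_hot()),
               "non-zero")
})

test_that("effective-Arrhenius interpolation passes through both anchors", {
  fit <- arrhenius_fit(anchors$kf_rt, anchors$T_rt,
                       anchors$kf_hot, anchors$T_hot)
  expect_equal(arrhenius_rate(fit$A, fit$Ea, anchors$T_rt), anchors$kf_rt,
               tolerance = 1e-10)
  expect_equal(arrhenius_rate(fit$A, fit$Ea, anchors$T_hot), anchors$kf_hot,
               tolerance = 1e-10)
  fn <- rate_interpolator(anchor_rates_rt(), anchor_rates_hot())
  mid <- fn(315)
  expect_true(mid$kf > anchors$kf_rt && mid$kf < anchors$kf_hot)
  expect_true(mid$kr > anchors$kr_rt && mid$kr < anchors$kr_hot)
  expect_equal(mid$Kd, mid$kr / mid$kf)
  expect_warning(fn(350), "clamped")
})

test_that("rate_table tabulates monotone interpolated rates", {
  fn <- rate_interpolator(anchor_rates_rt(), anchor_rates_hot())
  tab <- rate_table(fn, seq(298, 333, by = 5))
  expect_true(all(diff(tab$kf) > 0))
  expect_true(all(diff(tab$kr) > 0))
  expect_true(all(diff(tab$Kd) > 0))
})
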