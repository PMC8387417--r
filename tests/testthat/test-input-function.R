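test_that("parent-fraction model solves its anchor in closed form", {
  pf <- parent_fraction_model(plateau = 0, anchor = c(5, 0.16))
  expect_equal(pf$rate, log(1 / 0.16) / 5, tolerance = 1e-12)
  expect_equal(parent_fraction(pf, 0), 1)
  expect_equal(parent_fraction(pf, 5), 0.16, tolerance = 1e-12)
  expect_equal(parent_fraction(pf, 10), 0.16^2, tolerance = 1e-12)  # 0.0256
  tt <- seq(0, 60, by = 0.5)
  expect_true(all(diff(parent_fraction(pf, tt)) <= 0))
  expect_error(parent_fraction_model(plateau = 0.2, anchor = c(5, 0.16)),
               "unsolvable")
})

test_that("parent-fraction fitting recovers plateau and rate from a table", {
  truth <- parent_fraction_model(plateau = 0.07, rate = 0.35)
  tt <- c(0.5, 1, 2, 5, 10, 20, 40, 60)
  fit <- fit_parent_fraction(tt, parent_fraction(truth, tt))
  expect_equal(fit$rate, truth$rate, tolerance = 1e-6)
  expect_equal(fit$plateau, truth$plateau, tolerance = 1e-6)
})

test_that("plasma conversion applies the fixed 1:1.14 count ratio", {
  expect_equal(whole_blood_to_plasma(100), 114)
  expect_equal(whole_blood_to_plasma(0), 0)
  expect_equal(whole_blood_to_plasma(57.3, ratio = 1), 57.3)
})

test_that("metabolite-corrected input combines ratio, parent fraction, blood", {
  m <- default_idif()
  Cp <- metabolite_corrected_input(m)
  # at the 5-min anchor the parent fraction is exactly 0.16
  expect_equal(Cp(5), 1.14 * 0.16 * whole_blood(m, 5), tolerance = 1e-12)
  tt <- seq(0, 60, by = 0.25)
  expect_true(all(Cp(tt) >= 0))
  # pf == 1 and unit ratio collapse the correction
  m2 <- idif_model(m$amplitudes, m$rates, m$t_peak, plasma_ratio = 1,
                   pf = parent_fraction_model(plateau = 0, rate = 0))
  expect_equal(metabolite_corrected_input(m2)(tt), whole_blood(m2, tt),
               tolerance = 1e-12)
  expect_error(Cp(m$t_max + 10), "outside the fitted domain")
})

test_that("frame averaging of the blood model matches fine-grid quadrature", {
  m <- default_idif()
  s <- default_frame_schedule()
  fa <- frame_average_blood(m, s)
  # oracle: midpoint rule on a 0.0005-min grid within each frame
  oracle <- vapply(seq_len(n_frames(s)), function(i) {
    g <- seq(s$start[i], s$end[i], length.out = 401)
    mid <- (g[-1] + g[-length(g)]) / 2
    mean(whole_blood(m, mid))
  }, numeric(1))
  expect_lt(max(abs(fa - oracle) / max(oracle)), 5e-4)
  # integral preserved to within 0.5 %
  expect_equal(sum(fa * frame_durations(s)),
               sum(oracle * frame_durations(s)), tolerance = 5e-3)
})

test_that("degenerate single-exponential tail averages analytically", {
  s <- frame_schedule(c(30, 40), c(40, 50))
  m <- idif_model(c(100, 0, 0), c(0.1, 1, 2), t_peak = 0.5)
  fa <- frame_average_blood(m, s)
  lam <- 0.1
  exact <- 100 / lam *
    (exp(-lam * (s$start - 0.5)) - exp(-lam * (s$end - 0.5))) / 10
  expect_equal(fa, exact, tolerance = 1e-12)
})

test_that("IDIF fitting recovers a known 3-exponential input", {
  m <- default_idif()
  s <- default_frame_schedule()
  wb <- tac(s, frame_average_blood(m, s), region_label = "whole blood")
  fit <- fit_idif(wb, n_starts = 4)
  expect_lt(abs(sum(fit$amplitudes) - sum(m$amplitudes)) / sum(m$amplitudes),
            0.005)
  expect_equal(fit$rates, m$rates, tolerance = 0.005)
  expect_lt(fit$chi, 1e-6)
  # deterministic: the multi-start grid is fixed
  fit2 <- fit_idif(wb, n_starts = 4)
  expect_identical(fit$amplitudes, fit2$amplitudes)
  expect_identical(fit$chi, fit2$chi)
})

test_that("IDIF fit handles nested single-exponential truth", {
  s <- default_frame_schedule()
  m <- idif_model(c(120, 0, 0), c(0.8, 5, 10), t_peak = 0.4)
  wb <- tac(s, frame_average_blood(m, s), region_label = "whole blood")
  fit <- fit_idif(wb, n_starts = 6)
  expect_lt(fit$chi, 1e-6)
  # the dominant recovered component matches the true rate within 1 %
  main <- which.max(fit$amplitudes)
  expect_equal(fit$rates[main], 0.8, tolerance = 0.01)
  expect_lt(sum(fit$amplitudes[-main]) / sum(fit$amplitudes), 0.02)
})

test_that("IDIF fitting is scale-equivariant", {
  m <- default_idif()
  s <- default_frame_schedule()
  wb1 <- tac(s, frame_average_blood(m, s))
  wb2 <- tac(s, 3.7 * frame_average_blood(m, s))
  f1 <- fit_idif(wb1, n_starts = 2)
  f2 <- fit_idif(wb2, n_starts = 2)
  expect_equal(f2$amplitudes, 3.7 * f1$amplitudes, tolerance = 1e-6)
  expect_equal(f2$rates, f1$rates, tolerance = 1e-8)
})

test_that("chi does not increase with more multi-starts", {
  cfg <- tiny_generator(noise_scale = 0.3)
  coh <- simulate_cohort(cfg, seed = 5)
  wb <- coh$blood_tacs[[1]]
  chis <- vapply(c(1, 2, 4, 8), function(k) fit_idif(wb, n_starts = k)$chi,
                 numeric(1))
  expect_true(all(diff(chis) <= 1e-9))
})

test_that("IDIF fit rejects inadequate input", {
  s <- frame_schedule(0:5, 1:6)
  expect_error(fit_idif(tac(s, rep(1, 6))), "at least 8 frames")
  s2 <- default_frame_schedule()
  expect_error(fit_idif(tac(s2, rep(0, 78))), "positive")
})
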