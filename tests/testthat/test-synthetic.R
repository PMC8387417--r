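test_that("simulators are deterministic given a seed", {
  s <- default_frame_schedule()
  a <- simulate_idif(c(150, 25, 8), c(4, 0.5, 0.03), 0.5, s, seed = 3,
                     noise_scale = 0.2)
  b <- simulate_idif(c(150, 25, 8), c(4, 0.5, 0.03), 0.5, s, seed = 3,
                     noise_scale = 0.2)
  expect_identical(a$concentration, b$concentration)
  cfg <- tiny_generator()
  c1 <- simulate_cohort(cfg, seed = 11)
  c2 <- simulate_cohort(cfg, seed = 11)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$brain_tacs[[1]]$concentration,
                   c2$brain_tacs[[1]]$concentration)
  expect_error(simulate_idif(c(1, 1, 1), c(-1, 2, 3), 0.5, s),
               "strictly positive")
})

test_that("noiseless tissue simulation equals the forward model exactly", {
  idif <- default_idif()
  s <- default_frame_schedule()
  p <- wt_baseline_params()
  y <- simulate_tissue_tac(p, idif, s, noise_scale = 0)
  expect_identical(y$concentration, model_tac_2tcm(p, idif, s)$concentration)
  expect_false(y$noisy)
})

test_that("frame noise follows the duration-scaled law", {
  idif <- default_idif()
  s <- default_frame_schedule()
  p <- wt_baseline_params()
  mu <- model_tac_2tcm(p, idif, s)$concentration
  frame <- 70  # a 5-min frame
  draws <- vapply(1:500, function(k) {
    simulate_tissue_tac(p, idif, s, noise_scale = 0.3,
                        seed = k)$concentration[frame]
  }, numeric(1))
  expected_sd <- 0.3 * sqrt(mu[frame] / frame_durations(s)[frame])
  expect_lt(abs(sd(draws) / expected_sd - 1), 0.1)
  expect_lt(abs(mean(draws) - mu[frame]) / mu[frame], 0.05)
})

test_that("occupancy scales k3 only, following the Hill curve", {
  cfg <- generator_config(n_per_group = 3, cv = 0, pre084 = NULL,
                          noise_scale = 0)
  coh <- simulate_cohort(cfg, seed = 2)
  tr <- coh$truth
  base_k3 <- cfg$baseline$WT$k3
  veh <- tr[tr$dose_mg_per_kg == 0, ]
  expect_equal(veh$k3, rep(base_k3, nrow(veh)), tolerance = 1e-12)
  expect_equal(veh$ro_true, rep(0, nrow(veh)))
  d30 <- tr[tr$dose_mg_per_kg == 30, ]
  ro30 <- hill_occupancy(cfg$hill, 30)
  expect_equal(d30$k3, rep(base_k3 * (1 - ro30 / 100), nrow(d30)),
               tolerance = 1e-12)
  # K1, k2, k4 untouched by dose
  expect_equal(unique(tr$K1), cfg$baseline$WT$K1)
  expect_equal(unique(tr$k4), cfg$baseline$WT$k4)
  # saturation: the Hill curve approaches ro_max from below
  expect_lt(hill_occupancy(cfg$hill, 1e6), cfg$hill$ro_max + 1e-9)
  expect_equal(hill_occupancy(cfg$hill, 1e9), cfg$hill$ro_max,
               tolerance = 1e-6)
})

test_that("generator defaults reproduce the vehicle whole-brain means", {
  cfg <- generator_config(cv = 0, noise_scale = 0, n_per_group = 1,
                          pre084 = NULL)
  coh <- simulate_cohort(cfg, seed = 1)
  veh <- coh$truth[coh$truth$dose_mg_per_kg == 0, ][1, ]
  expect_equal(veh$bp_true, 1.02, tolerance = 1e-9)
  expect_equal(veh$vt_true, 15.15, tolerance = 1e-9)
})

test_that("noiseless cohorts round-trip through the 2TCM fit within 1 %", {
  cfg <- tiny_generator(noise_scale = 0, cv = 0.1)
  coh <- simulate_cohort(cfg, seed = 8)
  for (id in coh$metadata$animal_id) {
    fit <- fit_2tcm(coh$brain_tacs[[id]], coh$idif_true[[id]], n_starts = 2)
    truth_bp <- coh$truth$bp_true[coh$truth$animal_id == id]
    expect_lt(abs(fit$macros$bp_nd / truth_bp - 1), 0.01)
  }
})

test_that("group-mean %ID/g decreases with dose", {
  cfg <- generator_config(n_per_group = 3, noise_scale = 0, cv = 0,
                          pre084 = NULL, genotypes = "WT")
  coh <- simulate_cohort(cfg, seed = 4)
  pct <- vapply(coh$metadata$animal_id, function(id) {
    i <- which(coh$metadata$animal_id == id)
    inj <- injection_record(id, "WT", injected_MBq =
                              coh$metadata$injected_MBq[i], weight_g = 25)
    percent_id_per_gram(coh$brain_tacs[[id]], inj)$pct_id_g
  }, numeric(1))
  m <- tapply(pct, coh$metadata$dose_mg_per_kg, mean)
  expect_true(all(diff(m[order(as.numeric(names(m)))]) < 0))
  # vehicle calibration: near the observed 7.75 %ID/g
  expect_lt(abs(m[["0"]] / 7.75 - 1), 0.15)
})

test_that("ARG simulator honours its degenerate limits", {
  cfg <- tiny_generator()
  dens <- default_region_densities()
  # dose 0, no noise, no gain spread: intensities equal configured densities
  sim0 <- simulate_arg_cohort(generator_config(doses = 0, n_per_group = 2,
                                               pre084 = NULL),
                              noise_sd = 0, gain_cv = 0, seed = 1)
  merged <- merge(sim0$measurements,
                  data.frame(structure = names(dens), density = dens))
  expect_equal(merged$intensity, merged$density, tolerance = 1e-12)
  # full occupancy with zero background kills the specific signal
  sat <- generator_config(doses = c(0, 30), n_per_group = 2, pre084 = NULL,
                          hill = hill_params(100, 1e-6, 1))
  sim1 <- simulate_arg_cohort(sat, noise_sd = 0, gain_cv = 0, seed = 1)
  hot <- merge(sim1$measurements, sim1$truth)
  neural <- hot[hot$structure != "muscle" & hot$dose_mg_per_kg == 30, ]
  expect_lt(max(neural$intensity), 1e-5)
  muscle <- hot[hot$structure == "muscle", ]
  expect_equal(unique(muscle$intensity), dens[["muscle"]], tolerance = 1e-12)
  expect_error(
    simulate_arg_cohort(cfg, region_densities = c("caudate" = 1)),
    "muscle")
})

test_that("written cohort files are byte-identical across runs", {
  cfg <- tiny_generator()
  coh <- simulate_cohort(cfg, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_csv(coh, d1)
  write_cohort_csv(simulate_cohort(cfg, seed = 21), d2)
  f1 <- list.files(d1)
  expect_true(length(f1) >= 5)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
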