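#' Synthetic cohort generator configuration
#'
#' Defines the study design emulated by the generator: two genotypes at
#' oral doses {0, 1, 10, 30} mg/kg with 4-5 animals per cell, a 60-min
#' dynamic scan, two-tissue-compartment brain kinetics whose group means
#' reproduce the study's whole-brain macro-parameters (vehicle BP_ND 1.02,
#' Vt 15.15), a rise-then-three-exponential whole-blood input, 16% parent
#' fraction at 5 min, plasma:whole-blood 1.14, frame-duration-scaled
#' Gaussian noise, and a Hill-Langmuir occupancy curve whose defaults were
#' obtained once by least squares against the observed group-mean
#' occupancies (14.30% at 1, 62.63% at 10, 64.44% at 30 mg/kg). Occupancy
#' acts multiplicatively on `k3` only (receptor availability). An optional
#' reference-agonist arm (`PRE-084`, 4 WT animals at 1 mg/kg with ~17.6%
#' occupancy) mirrors the comparison arm of the design.
#'
#' @param doses Dose levels in mg/kg; must include 0 (vehicle).
#' @param n_per_group Animals per genotype x dose cell (>= 1).
#' @param genotypes Genotype labels.
#' @param baseline Named list (per genotype) of [two_tissue_params()]
#'   vehicle kinetics. Both genotypes default to the same kinetics (the
#'   observed baseline difference, BP 0.88 vs 1.02, is within noise); set
#'   them apart for power studies.
#' @param hill A [hill_params()] occupancy curve.
#' @param pre084 `NULL`, or a list `list(n, dose, genotype, ro)` for the
#'   reference-agonist arm.
#' @param noise_scale Frame noise magnitude: frame SD is
#'   `noise_scale * sqrt(C / dt)`.
#' @param cv Animal-level log-normal coefficient of variation on K1..k4.
#' @param injected_MBq `c(mean, sd)` of injected activity (MBq).
#' @param weight_g `c(mean, sd)` of body weight (g), truncated to 15-45 g.
#' @param idif Blood-curve settings: amplitude fractions, rates (per min),
#'   `t_peak` (min), `peak_per_MBq` (peak blood concentration per injected
#'   MBq, kBq/mL; calibrated so vehicle %ID/g is ~7.75), and `cv`
#'   (animal-level variation of the peak).
#' @param pf_plateau,pf_anchor Parent-fraction model settings.
#' @param plasma_ratio Plasma:whole-blood ratio.
#' @param schedule A [frame_schedule].
#' @param seed Default seed used by the simulators.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    doses = c(0, 1, 10, 30),
    n_per_group = 5,
    genotypes = c("WT", "KO"),
    baseline = NULL,
    hill = hill_params(ro_max = 64.66365096258, d50 = 1.85631051530,
                       hill_n = 2.03528716308),
    pre084 = list(n = 4, dose = 1, genotype = "WT", ro = 17.64),
    noise_scale = 0.1,
    cv = 0.1,
    injected_MBq = c(7.77, 0.81),
    weight_g = c(27, 3),
    idif = list(frac = c(0.82, 0.13, 0.05), rates = c(4, 0.5, 0.03),
                t_peak = 0.5, peak_per_MBq = 814.98, cv = 0.1),
    pf_plateau = 0, pf_anchor = c(5, 0.16),
    plasma_ratio = 1.14,
    schedule = default_frame_schedule(),
    seed = 1) {
  if (!0 %in% doses) stop("doses must include 0 (vehicle)")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (is.null(baseline)) {
    base <- two_tissue_params(K1 = 0.75, k2 = 0.1, k3 = 0.051, k4 = 0.05,
                              vB = 0.05)
    baseline <- stats::setNames(rep(list(base), length(genotypes)), genotypes)
  }
  stopifnot(inherits(hill, "hill_params"))
  structure(
    list(doses = sort(doses), n_per_group = n_per_group,
         genotypes = genotypes, baseline = baseline, hill = hill,
         pre084 = pre084, noise_scale = noise_scale, cv = cv,
         injected_MBq = injected_MBq, weight_g = weight_g, idif = idif,
         pf_plateau = pf_plateau, pf_anchor = pf_anchor,
         plasma_ratio = plasma_ratio, schedule = schedule, seed = seed),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config: %s x doses {%s} mg/kg, n = %d/cell%s, noise %.3g>\n",
    paste(x$genotypes, collapse = "/"),
    paste(x$doses, collapse = ", "), x$n_per_group,
    if (!is.null(x$pre084)) " + reference arm" else "", x$noise_scale))
  invisible(x)
}

#' Simulate a whole-blood curve from the rise-then-three-exponential model
#'
#' @param amplitudes,rates,t_peak Whole-blood model parameters (three
#'   amplitudes in kBq/mL, three positive per-minute rates).
#' @param schedule A [frame_schedule].
#' @param seed Optional seed (deterministic output for a given seed).
#' @param noise_scale Frame noise magnitude (0 = noiseless frame averages).
#' @return A whole-blood [tac].
#' @export
simulate_idif <- function(amplitudes, rates, t_peak = 0.5, schedule,
                          seed = NULL, noise_scale = 0) {
  model <- idif_model(amplitudes, rates, t_peak,
                      t_max = max(schedule$end, 60))
  mu <- frame_average_blood(model, schedule)
  add_frame_noise(mu, schedule, noise_scale, seed,
                  region_label = "whole blood")
}

add_frame_noise <- function(mu, schedule, noise_scale, seed, region_label) {
  if (noise_scale == 0) {
    return(tac(schedule, mu, region_label = region_label))
  }
  sd_i <- noise_scale * sqrt(pmax(mu, 0) / frame_durations(schedule))
  conc <- with_seed(seed, mu + stats::rnorm(length(mu), 0, sd_i))
  tac(schedule, conc, region_label = region_label, noisy = TRUE)
}

#' Simulate a parent-fraction model from its 5-minute anchor
#'
#' Convenience wrapper around [parent_fraction_model()] using the measured
#' anchor convention (parent fraction at 5 min post-dose).
#'
#' @param pf_at_5min Parent fraction at 5 min (default 0.16).
#' @param plateau Late-time plateau (must be below `pf_at_5min`).
#' @return A [parent_fraction_model()].
#' @export
simulate_parent_fraction <- function(pf_at_5min = 0.16, plateau = 0) {
  parent_fraction_model(plateau = plateau, anchor = c(5, pf_at_5min))
}

#' Simulate a tissue time-activity curve
#'
#' Noiseless mean from the 2TCM forward model plus zero-mean Gaussian
#' frame noise with standard deviation `noise_scale * sqrt(C / dt)` -- the
#' variance structure (inverse to frame duration) that frame-duration
#' weighting assumes.
#'
#' @param params A [two_tissue_params()].
#' @param input_model An [idif_model()].
#' @param schedule A [frame_schedule].
#' @param noise_scale Noise magnitude (0 = noiseless).
#' @param seed Optional seed.
#' @return A brain [tac].
#' @export
simulate_tissue_tac <- function(params, input_model, schedule,
                                noise_scale = 0, seed = NULL) {
  mu <- model_tac_2tcm(params, input_model, schedule)$concentration
  add_frame_noise(mu, schedule, noise_scale, seed,
                  region_label = "whole brain")
}

#' Simulate a full PET cohort
#'
#' Generates, for every animal of the configured design: ground-truth
#' kinetic parameters (baseline kinetics with log-normal animal variation,
#' `k3` scaled by `1 - RO_true(dose)/100` from the Hill curve), an
#' injection record, a per-animal whole-blood input model and noisy blood
#' curve, and a noisy brain curve. The same seed reproduces the cohort
#' exactly.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return A list of class `pet_cohort`: `metadata` (data frame),
#'   `blood_tacs`, `brain_tacs` (named lists of [tac]), `truth` (per-animal
#'   true parameters, macros and occupancy), `idif_true` (named list of the
#'   true per-animal [idif_model()]), `config`.
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  design <- cohort_design(cfg)
  pf <- parent_fraction_model(cfg$pf_plateau, anchor = cfg$pf_anchor)
  t_max <- max(cfg$schedule$end, 60)

  with_seed(seed, {
    rows <- vector("list", nrow(design))
    blood <- brain <- idifs <- stats::setNames(vector("list", nrow(design)),
                                               design$animal_id)
    for (i in seq_len(nrow(design))) {
      g <- design$genotype[i]
      ro_true <- if (design$drug[i] == "PRE-084") {
        cfg$pre084$ro
      } else {
        hill_occupancy(cfg$hill, design$dose[i])
      }
      base <- cfg$baseline[[g]]
      sdlog <- sqrt(log(1 + cfg$cv^2))
      jit <- stats::rlnorm(4, -sdlog^2 / 2, sdlog)
      pars <- two_tissue_params(
        K1 = base$K1 * jit[1], k2 = base$k2 * jit[2],
        k3 = base$k3 * jit[3] * (1 - ro_true / 100),
        k4 = base$k4 * jit[4], vB = base$vB)
      inj <- max(stats::rnorm(1, cfg$injected_MBq[1], cfg$injected_MBq[2]),
                 0.5)
      wt <- min(max(stats::rnorm(1, cfg$weight_g[1], cfg$weight_g[2]), 15.5),
                44.5)
      peak <- cfg$idif$peak_per_MBq * inj *
        stats::rlnorm(1, -log(1 + cfg$idif$cv^2) / 2,
                      sqrt(log(1 + cfg$idif$cv^2)))
      idif <- idif_model(peak * cfg$idif$frac, cfg$idif$rates,
                         cfg$idif$t_peak, plasma_ratio = cfg$plasma_ratio,
                         pf = pf, t_max = t_max)
      idifs[[i]] <- idif
      blood[[i]] <- add_frame_noise(
        frame_average_blood(idif, cfg$schedule), cfg$schedule,
        cfg$noise_scale, NULL, "whole blood")
      brain[[i]] <- simulate_tissue_tac(pars, idif, cfg$schedule,
                                        cfg$noise_scale, NULL)
      mac <- derive_macros(pars)
      rows[[i]] <- data.frame(
        animal_id = design$animal_id[i], genotype = g, drug = design$drug[i],
        dose_mg_per_kg = design$dose[i], injected_MBq = inj, weight_g = wt,
        scan_minutes = total_duration(cfg$schedule),
        K1 = pars$K1, k2 = pars$k2, k3 = pars$k3, k4 = pars$k4, vB = pars$vB,
        bp_true = mac$bp_nd, vt_true = mac$vt, vs_true = mac$vs,
        ro_true = ro_true, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    metadata <- truth[c("animal_id", "genotype", "drug", "dose_mg_per_kg",
                        "injected_MBq", "weight_g", "scan_minutes")]
    structure(list(metadata = metadata, blood_tacs = blood,
                   brain_tacs = brain, truth = truth, idif_true = idifs,
                   config = cfg),
              class = "pet_cohort")
  })
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat(sprintf("<pet_cohort: %d animals (%s), %d frames>\n",
              nrow(x$metadata),
              paste(sort(unique(x$metadata$genotype)), collapse = "/"),
              n_frames(x$config$schedule)))
  invisible(x)
}

# study design grid: genotype x dose x replicate animal, plus the optional
# reference-agonist arm, with deterministic animal ids
cohort_design <- function(cfg) {
  design <- expand.grid(genotype = cfg$genotypes, dose = cfg$doses,
                        idx = seq_len(cfg$n_per_group),
                        stringsAsFactors = FALSE)
  design$drug <- "blarcamesine"
  if (!is.null(cfg$pre084)) {
    pre <- expand.grid(genotype = cfg$pre084$genotype,
                       dose = cfg$pre084$dose,
                       idx = seq_len(cfg$pre084$n), stringsAsFactors = FALSE)
    pre$drug <- "PRE-084"
    design <- rbind(design, pre)
  }
  design <- design[order(design$genotype, design$drug, design$dose,
                         design$idx), ]
  design$animal_id <- sprintf("m%03d", seq_len(nrow(design)))
  design
}

#' Default regional binding densities for the autoradiography simulator
#'
#' Arbitrary-unit mean intensities reflecting the wide, region-specific
#' distribution of sigma-1 receptors (cerebellum and pons high, caudate
#' lower), with muscle -- which carries no specific binding of interest --
#' as the dose-independent internal control.
#'
#' @return Named numeric vector over [arg_structures()].
#' @export
default_region_densities <- function() {
  c("frontal cortex" = 1.0, "caudate" = 0.85, "hippocampus" = 0.95,
    "thalamus" = 1.15, "amygdala" = 0.9, "pons" = 1.25,
    "cerebellum" = 1.35, "muscle" = 0.35)
}

#' Simulate an ex vivo autoradiography cohort
#'
#' Per animal and structure, three replicate intensities
#' `gain * (density * (1 - RO_true/100) * (1 + eps) + background)` with
#' zero-mean Gaussian `eps`; muscle is unaffected by dose; `gain` is a
#' per-animal film/screen exposure factor that the muscle normalization
#' must cancel.
#'
#' @param cfg A [generator_config()].
#' @param region_densities Named densities over [arg_structures()] (must
#'   include `"muscle"`).
#' @param cohort Optional [simulate_cohort()] result: reuses its animals
#'   and true occupancies (the post-scan design); otherwise a fresh design
#'   is drawn from `cfg`.
#' @param noise_sd Replicate noise SD (relative).
#' @param background Additive background intensity.
#' @param gain_cv Animal-level exposure-gain coefficient of variation.
#' @param seed Integer seed.
#' @return List with `measurements` (`animal_id, structure, replicate,
#'   intensity`), `metadata`, and `truth` (per-animal RO).
#' @export
simulate_arg_cohort <- function(cfg, region_densities =
                                  default_region_densities(),
                                cohort = NULL, noise_sd = 0.05,
                                background = 0, gain_cv = 0.2,
                                seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  if (any(region_densities <= 0)) stop("densities must be positive")
  if (!"muscle" %in% names(region_densities)) {
    stop("region_densities must include a muscle entry")
  }
  check_arg_structures(names(region_densities))
  if (is.null(cohort)) {
    # true occupancy is a deterministic function of dose: a full kinetic
    # cohort is not needed, only the design grid
    design <- cohort_design(cfg)
    truth <- data.frame(
      animal_id = design$animal_id, genotype = design$genotype,
      drug = design$drug, dose_mg_per_kg = design$dose,
      ro_true = ifelse(design$drug == "PRE-084", cfg$pre084$ro,
                       hill_occupancy(cfg$hill, design$dose)),
      stringsAsFactors = FALSE)
    metadata <- truth[c("animal_id", "genotype", "drug", "dose_mg_per_kg")]
  } else {
    truth <- cohort$truth[c("animal_id", "genotype", "drug",
                            "dose_mg_per_kg", "ro_true")]
    metadata <- cohort$metadata
  }
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      gain <- stats::rlnorm(1, 0, sqrt(log(1 + gain_cv^2)))
      for (s in names(region_densities)) {
        ro <- if (s == "muscle") 0 else truth$ro_true[i]
        mu <- region_densities[[s]] * (1 - ro / 100)
        eps <- stats::rnorm(3, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = truth$animal_id[i], structure = s, replicate = 1:3,
          intensity = pmax(gain * (mu * (1 + eps) + background), 0),
          stringsAsFactors = FALSE)
      }
    }
    list(measurements = do.call(rbind, rows),
         metadata = metadata, truth = truth)
  })
}

#' Write a simulated cohort to the CSV interchange dialects
#'
#' Emits one TAC CSV per region per animal
#' (`<animal>_brain.csv`, `<animal>_blood.csv`), the cohort metadata CSV
#' and the ground-truth table.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in cohort$metadata$animal_id) {
    write_tac_csv(cohort$brain_tacs[[id]],
                  file.path(dir, paste0(id, "_brain.csv")))
    write_tac_csv(cohort$blood_tacs[[id]],
                  file.path(dir, paste0(id, "_blood.csv")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "cohort_metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "cohort_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
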