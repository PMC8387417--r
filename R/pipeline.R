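#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]:
#' generator settings, fit settings, uptake window, statistics settings.
#' A configuration is a plain named list serializable to a single YAML
#' document; unknown keys are rejected.
#'
#' @param path Optional YAML file to read.
#' @param ... Named overrides of the defaults (nested lists merged one
#'   level deep, e.g. `generator = list(n_per_group = 4)`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    seed = 1L,
    generator = list(doses = c(0, 1, 10, 30), n_per_group = 5,
                     genotypes = c("WT", "KO"), noise_scale = 0.1,
                     cv = 0.1, pre084 = TRUE,
                     hill = list(ro_max = 64.66365096258,
                                 d50 = 1.85631051530,
                                 hill_n = 2.03528716308)),
    fit = list(n_starts = 8, weighting = "duration", idif_n_starts = 4),
    uptake = list(window = c(30, 40)),
    arg = list(noise_sd = 0.05, gain_cv = 0.2, background = 0),
    stats = list(trend_scores = "numeric", n_perm = 10000)
  )
  user <- list(...)
  if (!is.null(path)) {
    user <- utils::modifyList(yaml::read_yaml(path), user)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(bad)) {
        stop(sprintf("unknown key(s) in '%s': %s", k,
                     paste(bad, collapse = ", ")))
      }
      defaults[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param cfg A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_to_generator <- function(cfg) {
  g <- cfg$generator
  generator_config(
    doses = g$doses, n_per_group = g$n_per_group, genotypes = g$genotypes,
    hill = hill_params(g$hill$ro_max, g$hill$d50, g$hill$hill_n),
    pre084 = if (isTRUE(g$pre084)) {
      list(n = 4, dose = 1, genotype = "WT", ro = 17.64)
    },
    noise_scale = g$noise_scale, cv = g$cv, seed = cfg$seed)
}

#' Run the full occupancy analysis pipeline
#'
#' Executes the study's analysis flow end to end: cohort simulation (or a
#' user-supplied cohort), per-animal input-function fits, 2TCM fits and
#' macro-parameters, receptor occupancy with Hill-Langmuir dose-response,
#' %ID/g uptake, autoradiography summaries, and the stratified
#' nonparametric test battery. All outputs are plain CSV/JSON files; the
#' same configuration and seed reproduce the bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param seed Integer seed (default `config$seed`).
#' @param cohort Optional [simulate_cohort()] result to analyse instead of
#'   simulating one.
#' @return Invisibly, a list with `fits`, `occupancy`, `hill`, `uptake`,
#'   `table1`, `arg`, `stats`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = config$seed, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package_version = as.character(utils::packageVersion("occupet")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = seed, stages = list())
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log$stages[[name]] <<- "ok"
    res
  }

  gen_cfg <- config_to_generator(config)
  if (is.null(cohort)) {
    cohort <- stage("simulate", simulate_cohort(gen_cfg, seed = seed))
  }
  meta <- cohort$metadata

  fits <- stage("fit", {
    rows <- lapply(meta$animal_id, function(id) {
      idif <- fit_idif(cohort$blood_tacs[[id]],
                       n_starts = config$fit$idif_n_starts)
      fit <- fit_2tcm(cohort$brain_tacs[[id]], idif,
                      n_starts = config$fit$n_starts,
                      weighting = config$fit$weighting)
      inj <- injection_record(
        id, meta$genotype[meta$animal_id == id],
        drug = meta$drug[meta$animal_id == id],
        dose_mg_per_kg = meta$dose_mg_per_kg[meta$animal_id == id],
        injected_MBq = meta$injected_MBq[meta$animal_id == id],
        weight_g = meta$weight_g[meta$animal_id == id])
      upt <- percent_id_per_gram(cohort$brain_tacs[[id]], inj,
                                 window = config$uptake$window)
      data.frame(animal_id = id, genotype = inj$genotype, drug = inj$drug,
                 dose = inj$dose_mg_per_kg, K1 = fit$params$K1,
                 k2 = fit$params$k2, k3 = fit$params$k3, k4 = fit$params$k4,
                 vB = fit$params$vB, bp_k3k4 = fit$macros$bp_nd,
                 vt = fit$macros$vt, vs = fit$macros$vs, chi = fit$chi,
                 idif_chi = idif$chi, pct_id_g = upt$pct_id_g,
                 boundary = fit$boundary, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  occ <- stage("occupancy", suppressWarnings(
    receptor_occupancy(fits$bp_k3k4, fits$genotype, fits$dose,
                       drug = fits$drug, animal_id = fits$animal_id)))

  hill_fits <- stage("hill", {
    blc <- occ$per_animal[occ$per_animal$drug == "blarcamesine", ]
    lapply(split(blc, blc$genotype), function(g) {
      tryCatch(fit_hill(g$dose, g$ro_pct),
               error = function(e) conditionMessage(e))
    })
  })

  table1 <- stage("summary", make_table1(fits, occ))

  arg <- stage("arg", {
    sim <- simulate_arg_cohort(gen_cfg, cohort = cohort,
                               noise_sd = config$arg$noise_sd,
                               gain_cv = config$arg$gain_cv,
                               background = config$arg$background,
                               seed = seed + 2000L)
    norm <- normalize_to_muscle(summarize_animal(sim$measurements))
    ann <- merge(norm, meta[c("animal_id", "genotype", "drug",
                              "dose_mg_per_kg")], by = "animal_id")
    names(ann)[names(ann) == "dose_mg_per_kg"] <- "dose"
    list(measurements = sim$measurements,
         summary = summarize_arg_cohort(sim$measurements, meta),
         normalized = ann,
         reference = tryCatch(reference_ratios(ann),
                              warning = function(w) {
                                suppressWarnings(reference_ratios(ann))
                              }))
  })

  stats_report <- stage("stats", pipeline_stats(fits, occ, arg$normalized,
                                                config))

  # outputs
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(occ$per_animal[c("animal_id", "genotype", "drug", "dose",
                                    "bp", "ro_pct")],
                   file.path(out_dir, "occupancy.csv"), row.names = FALSE)
  utils::write.csv(table1, file.path(out_dir, "table1_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(arg$summary, file.path(out_dir, "arg_summary.csv"),
                   row.names = FALSE)
  dose_grid <- seq(0, max(fits$dose), length.out = 121)
  dr <- do.call(rbind, lapply(names(hill_fits), function(g) {
    h <- hill_fits[[g]]
    if (!inherits(h, "hill_params")) return(NULL)
    data.frame(genotype = g, dose = dose_grid,
               ro_fit = hill_occupancy(h, dose_grid))
  }))
  if (!is.null(dr)) {
    utils::write.csv(dr, file.path(out_dir, "dose_response.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(stats_report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fits = fits, occupancy = occ, hill = hill_fits,
                 table1 = table1, arg = arg, stats = stats_report,
                 log = log))
}

make_table1 <- function(fits, occ) {
  fmt <- function(m, s) {
    ifelse(is.na(m), "N/A", sprintf("%.2f ± %.2f", m, s))
  }
  cells <- split(fits, interaction(fits$genotype, fits$drug, fits$dose,
                                   drop = TRUE))
  rows <- lapply(cells, function(g) {
    key <- occ$group_summary$genotype == g$genotype[1] &
      occ$group_summary$drug == g$drug[1] &
      occ$group_summary$dose == g$dose[1]
    ro_m <- if (any(key)) occ$group_summary$ro_mean[key] else NA_real_
    ro_s <- if (any(key)) occ$group_summary$ro_sd[key] else NA_real_
    data.frame(
      genotype = g$genotype[1], drug = g$drug[1], dose = g$dose[1],
      n = nrow(g),
      bp_mean = mean(g$bp_k3k4), bp_sd = stats::sd(g$bp_k3k4),
      vt_mean = mean(g$vt), vt_sd = stats::sd(g$vt),
      vs_mean = mean(g$vs), vs_sd = stats::sd(g$vs),
      ro_mean = ro_m, ro_sd = ro_s,
      pctidg_mean = mean(g$pct_id_g), pctidg_sd = stats::sd(g$pct_id_g),
      bp = fmt(mean(g$bp_k3k4), stats::sd(g$bp_k3k4)),
      vt = fmt(mean(g$vt), stats::sd(g$vt)),
      vs = fmt(mean(g$vs), stats::sd(g$vs)),
      ro = fmt(ro_m, ro_s),
      pct_id_g = fmt(mean(g$pct_id_g), stats::sd(g$pct_id_g)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genotype, out$drug, out$dose), ]
  rownames(out) <- NULL
  out
}

pipeline_stats <- function(fits, occ, arg_normalized, config) {
  blc <- fits[fits$drug == "blarcamesine", ]
  res <- list()
  safe <- function(name, code) {
    r <- tryCatch(code, error = function(e) {
      list(method = name, warning = paste("not computed:",
                                          conditionMessage(e)))
    }, warning = function(w) {
      list(method = name, warning = paste("not computed:",
                                          conditionMessage(w)))
    })
    res[[name]] <<- if (inherits(r, "occupet_test")) {
      list(method = r$method, statistic = unname(r$statistic),
           p = r$p.value)
    } else r
  }
  for (v in c("bp_k3k4", "vt", "vs", "pct_id_g")) {
    safe(paste0("trend_", v), linear_by_linear_trend(
      blc[[v]], blc$dose, strata = blc$genotype,
      score_type = config$stats$trend_scores))
    safe(paste0("genotype_", v), van_elteren(
      blc[[v]], blc$genotype, blc$dose))
  }
  ro <- occ$per_animal[occ$per_animal$drug == "blarcamesine", ]
  safe("trend_ro", linear_by_linear_trend(ro$ro_pct, ro$dose,
                                          strata = ro$genotype,
                                          score_type =
                                            config$stats$trend_scores))
  d1 <- fits[fits$dose == 1 & fits$genotype == "WT", ]
  if (length(unique(d1$drug)) == 2) {
    safe("drug_pctidg_exact_wilcoxon", wilcoxon_rank_sum(
      d1$pct_id_g[d1$drug == "blarcamesine"],
      d1$pct_id_g[d1$drug == "PRE-084"], exact = TRUE))
  }
  safe("regression_pctidg", {
    r <- regression_dose_genotype(blc, response = "pct_id_g")
    list(method = "linear regression of %ID/g on genotype and dose",
         coefficients = as.data.frame(r$coefficients))
  })
  if (!is.null(arg_normalized)) {
    safe("arg_loglink", {
      r <- loglink_regression_clustered(
        normalized_intensity ~ genotype + dose + structure,
        data = arg_normalized, cluster = arg_normalized$animal_id)
      list(method = "log-link regression of ARG, cluster-robust",
           coefficients = as.data.frame(unclass(r$coefficients)))
    })
    a1 <- arg_normalized[arg_normalized$dose == 1 &
                           arg_normalized$genotype == "WT", ]
    if (length(unique(a1$drug)) == 2) {
      safe("arg_drug_van_elteren", van_elteren(
        a1$normalized_intensity, a1$drug, a1$structure))
    }
  }
  res
}
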