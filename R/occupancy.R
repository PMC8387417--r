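#' Receptor occupancy from binding potentials
#'
#' In a between-subjects design occupancy cannot be formed per animal from
#' its own baseline, so each treated animal's binding potential is compared
#' with the *median* vehicle (dose 0) binding potential of its genotype:
#' `RO = (median_BP0 - BP) / median_BP0 * 100`. After all values are
#' computed, any occupancy `<= 0` is replaced by the lowest strictly
#' positive occupancy observed within the same genotype (across its dose
#' groups and drug arms). Vehicle animals contribute the baseline but are
#' excluded from occupancy reporting.
#'
#' @param bp Numeric vector of binding potentials (`k3/k4`), one per animal,
#'   all positive.
#' @param genotype Character/factor of genotypes, same length.
#' @param dose Numeric doses in mg/kg (0 = vehicle), same length.
#' @param drug Optional drug arm labels (vehicle animals are shared across
#'   arms of the same genotype); default a single arm.
#' @param animal_id Optional animal identifiers.
#' @return An object of class `occupancy_result`: `per_animal` (data frame
#'   of treated animals with `ro_pct`), `raw` (all animals, unclipped
#'   `ro_raw`), `median_bp0` and `clip_value` per genotype, and
#'   `group_summary` (mean, SD, n per genotype x drug x dose).
#' @examples
#' ro <- receptor_occupancy(
#'   bp = c(1.0, 1.1, 0.9, 0.5, 0.35),
#'   genotype = rep("WT", 5), dose = c(0, 0, 0, 10, 30))
#' ro$per_animal
#' @export
receptor_occupancy <- function(bp, genotype, dose, drug = NULL,
                               animal_id = NULL) {
  n <- length(bp)
  stopifnot(length(genotype) == n, length(dose) == n)
  if (any(!is.finite(bp)) || any(bp <= 0)) {
    stop("binding potentials must be positive and finite")
  }
  if (is.null(drug)) drug <- rep("drug", n)
  if (is.null(animal_id)) animal_id <- sprintf("a%02d", seq_len(n))
  genotype <- as.character(genotype)
  d <- data.frame(animal_id = as.character(animal_id), genotype = genotype,
                  drug = as.character(drug), dose = dose, bp = bp,
                  stringsAsFactors = FALSE)

  median_bp0 <- vapply(split(d, d$genotype), function(g) {
    v <- g$bp[g$dose == 0]
    if (!length(v)) {
      stop(sprintf("no vehicle (dose 0) animals for genotype '%s'",
                   g$genotype[1]))
    }
    stats::median(v)  # even counts: midpoint of the two central values
  }, numeric(1))

  d$ro_raw <- (median_bp0[d$genotype] - d$bp) / median_bp0[d$genotype] * 100

  treated <- d[d$dose > 0, , drop = FALSE]
  clip_value <- vapply(unique(treated$genotype), function(g) {
    pos <- treated$ro_raw[treated$genotype == g & treated$ro_raw > 0]
    if (!length(pos)) {
      stop(sprintf(
        "no positive occupancy in genotype '%s'; clipping undefined", g))
    }
    min(pos)
  }, numeric(1))
  treated$ro_pct <- ifelse(treated$ro_raw <= 0,
                           clip_value[treated$genotype], treated$ro_raw)

  cells <- split(treated,
                 interaction(treated$genotype, treated$drug, treated$dose,
                             drop = TRUE))
  group_summary <- do.call(rbind, lapply(cells, function(g) {
    data.frame(genotype = g$genotype[1], drug = g$drug[1], dose = g$dose[1],
               ro_mean = mean(g$ro_pct), ro_sd = stats::sd(g$ro_pct),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  group_summary <- group_summary[order(group_summary$genotype,
                                       group_summary$drug,
                                       group_summary$dose), ]
  rownames(group_summary) <- NULL

  structure(
    list(per_animal = treated, raw = d, median_bp0 = median_bp0,
         clip_value = clip_value, group_summary = group_summary),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat("Receptor occupancy (median vehicle baseline, positive clipping)\n")
  cat("median BP(0):",
      paste(sprintf("%s = %.3g", names(x$median_bp0), x$median_bp0),
            collapse = ", "), "\n\n")
  print(x$group_summary, row.names = FALSE)
  invisible(x)
}

#' Percent injected dose per gram over a time window
#'
#' Duration-weighted mean tissue concentration over the frames intersecting
#' the window (partial frames weighted by their overlap), converted to
#' percent of the injected activity per gram of tissue assuming unit
#' tissue density (1 g/mL).
#'
#' @param tac_obj A [tac] (kBq/mL), decay-corrected by package convention
#'   (see `decay_corrected` switch).
#' @param injection An [injection_record()].
#' @param window Two times in minutes, default `c(30, 40)`; must lie inside
#'   the scan.
#' @param decay_corrected If `TRUE` (default) the computation requires a
#'   decay-corrected curve and corrects one that is not.
#' @return Object of class `uptake_result` with `pct_id_g` and `window`.
#' @examples
#' s <- frame_schedule(c(30, 35), c(35, 40))
#' inj <- injection_record("m1", "WT", injected_MBq = 7.77, weight_g = 25)
#' percent_id_per_gram(tac(s, c(77.7, 77.7)), inj)  # 1 %ID/g
#' @export
percent_id_per_gram <- function(tac_obj, injection, window = c(30, 40),
                                decay_corrected = TRUE) {
  stopifnot(inherits(tac_obj, "tac"), inherits(injection, "injection_record"))
  sched <- tac_obj$schedule
  if (window[1] >= window[2]) stop("window must be increasing")
  if (window[1] < sched$start[1] - 1e-9 ||
      window[2] > sched$end[n_frames(sched)] + 1e-9) {
    stop("uptake window is not covered by the scan")
  }
  if (decay_corrected && !tac_obj$decay_corrected) {
    tac_obj <- decay_correct(tac_obj, direction = "to_injection")
  }
  overlap <- pmax(pmin(sched$end, window[2]) - pmax(sched$start, window[1]), 0)
  mean_conc <- sum(overlap * tac_obj$concentration) / sum(overlap)
  pct <- mean_conc / (injection$injected_MBq * 1000) * 100  # kBq/mL vs kBq
  structure(list(pct_id_g = max(pct, 0), window = window,
                 mean_conc_kBq_per_mL = mean_conc),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat(sprintf("%%ID/g over [%g, %g] min: %.4g\n",
              x$window[1], x$window[2], x$pct_id_g))
  invisible(x)
}
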