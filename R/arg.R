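#' Brain structures quantified by ex vivo autoradiography
#'
#' The seven neural structures sampled in coronal sections, plus thigh
#' muscle as the internal normalization control.
#'
#' @param include_muscle Include `"muscle"` in the vocabulary.
#' @return Character vector of structure names.
#' @export
arg_structures <- function(include_muscle = TRUE) {
  s <- c("frontal cortex", "caudate", "hippocampus", "thalamus",
         "amygdala", "pons", "cerebellum")
  if (include_muscle) c(s, "muscle") else s
}

#' Mean pixel intensity within a region of interest
#'
#' @param image Numeric matrix of pixel intensities.
#' @param mask Logical matrix of the same shape, with at least one `TRUE`.
#' @return Arithmetic mean of masked pixels.
#' @export
roi_mean <- function(image, mask) {
  stopifnot(is.matrix(image), is.logical(mask))
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask must have identical dimensions")
  }
  if (!any(mask)) stop("ROI mask is empty")
  mean(image[mask])
}

check_arg_structures <- function(structure) {
  bad <- setdiff(unique(structure), arg_structures())
  if (length(bad)) {
    stop("unknown structure label(s): ", paste(bad, collapse = ", "))
  }
}

#' Average triplicate ROI measurements per animal and structure
#'
#' Each region is sampled on three slices per animal; replicates are
#' averaged to one value per animal per structure.
#'
#' @param measurements Data frame with columns `animal_id`, `structure`,
#'   `replicate`, `intensity` (the ARG CSV dialect).
#' @return Data frame `animal_id, structure, intensity` of per-animal means.
#' @export
summarize_animal <- function(measurements) {
  need <- c("animal_id", "structure", "intensity")
  stopifnot(all(need %in% names(measurements)))
  check_arg_structures(measurements$structure)
  if (any(measurements$intensity < 0)) stop("intensities must be >= 0")
  agg <- stats::aggregate(intensity ~ animal_id + structure,
                          data = measurements, FUN = mean)
  agg[order(agg$animal_id, agg$structure), ]
}

#' Normalize structure means to the animal's muscle mean
#'
#' Muscle is unaffected by dose and serves as an internal exposure control:
#' dividing by it makes the result invariant to per-animal global exposure
#' scaling (film/screen gain). Muscle itself is excluded from the output.
#'
#' @param per_structure_means Output of [summarize_animal()] (must contain
#'   a `"muscle"` row per animal).
#' @return Data frame `animal_id, structure, normalized_intensity`.
#' @export
normalize_to_muscle <- function(per_structure_means) {
  d <- per_structure_means
  check_arg_structures(d$structure)
  out <- do.call(rbind, lapply(split(d, d$animal_id), function(a) {
    m <- a$intensity[a$structure == "muscle"]
    if (!length(m)) stop("animal ", a$animal_id[1], " has no muscle entry")
    if (m[1] <= 0) stop("animal ", a$animal_id[1], " has zero muscle signal")
    neural <- a[a$structure != "muscle", , drop = FALSE]
    data.frame(animal_id = neural$animal_id, structure = neural$structure,
               normalized_intensity = neural$intensity / m[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Structure-to-reference ratios
#'
#' With no reference region available for this radioligand, each
#' structure's mean is referenced to the overall mean across the
#' structures of interest. When genotype and dose columns are supplied the
#' structure means are adjusted for them through the cluster-robust
#' log-link regression ([loglink_regression_clustered()]); otherwise (or
#' for a degenerate single-cell design) the unadjusted grand mean is used
#' with a warning. In the unadjusted path the ratios average to 1 by
#' construction.
#'
#' @param normalized Data frame from [normalize_to_muscle()], optionally
#'   with `genotype` and `dose` columns for adjustment.
#' @param adjust Attempt model-based adjustment (default `TRUE` when the
#'   design allows it).
#' @return Data frame `structure, mean_intensity, reference_ratio`.
#' @export
reference_ratios <- function(normalized, adjust = TRUE) {
  d <- normalized
  stopifnot(all(c("structure", "normalized_intensity") %in% names(d)))
  if (length(unique(d$structure)) < 2) stop("need at least 2 structures")
  covars <- c(
    if ("genotype" %in% names(d) && length(unique(d$genotype)) > 1)
      "genotype",
    if ("dose" %in% names(d) && length(unique(d$dose)) > 1) "factor(dose)"
  )
  adjustable <- adjust && length(covars) > 0
  if (adjustable) {
    f <- stats::reformulate(c(covars, "structure"),
                            response = "normalized_intensity")
    fit <- loglink_regression_clustered(f, data = d, cluster = d$animal_id)
    grid <- unique(d[intersect(c("genotype", "dose"), names(d))])
    means <- vapply(sort(unique(d$structure)), function(s) {
      g <- grid
      g$structure <- s
      mean(stats::predict(fit$model, newdata = g, type = "response"))
    }, numeric(1))
  } else {
    if (adjust) {
      warning("design too degenerate for adjustment; ",
              "using the unadjusted grand mean")
    }
    means <- vapply(split(d$normalized_intensity, d$structure), mean,
                    numeric(1))
  }
  data.frame(structure = names(means), mean_intensity = as.numeric(means),
             reference_ratio = as.numeric(means) / mean(means),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohort-level autoradiography summary
#'
#' Muscle-normalized group means per genotype, drug, dose and structure.
#'
#' @param measurements ARG measurement table (`animal_id, structure,
#'   replicate, intensity`).
#' @param metadata Cohort metadata with `animal_id, genotype, drug,
#'   dose_mg_per_kg`.
#' @return Data frame `genotype, drug, dose, structure, normalized_mean,
#'   normalized_sd, n`.
#' @export
summarize_arg_cohort <- function(measurements, metadata) {
  norm <- normalize_to_muscle(summarize_animal(measurements))
  d <- merge(norm, metadata, by = "animal_id")
  cells <- split(d, interaction(d$genotype, d$drug, d$dose_mg_per_kg,
                                d$structure, drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(g) {
    data.frame(genotype = g$genotype[1], drug = g$drug[1],
               dose = g$dose_mg_per_kg[1], structure = g$structure[1],
               normalized_mean = mean(g$normalized_intensity),
               normalized_sd = stats::sd(g$normalized_intensity),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$genotype, out$drug, out$dose, out$structure), ]
  rownames(out) <- NULL
  out
}
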