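#' Time-activity curve
#'
#' A frame-averaged radioactivity concentration curve for one region (brain
#' VOI, whole blood, ...) on a [frame_schedule]. Concentrations are kBq/mL.
#' Negative frame values are physically impossible for a noiseless curve and
#' are only accepted when the curve is flagged as noisy.
#'
#' @param schedule A [frame_schedule].
#' @param concentration Numeric vector, one value per frame (kBq/mL).
#' @param region_label Region name, e.g. `"whole brain"` or `"whole blood"`.
#' @param decay_corrected Logical; `TRUE` means corrected to injection time.
#' @param noisy Logical; set by simulators that add measurement noise,
#'   permitting negative values.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, concentration, region_label = "",
                decay_corrected = TRUE, noisy = FALSE) {
  stopifnot(inherits(schedule, "frame_schedule"))
  concentration <- as.numeric(concentration)
  if (length(concentration) != n_frames(schedule)) {
    stop("need exactly one concentration per frame")
  }
  if (any(!is.finite(concentration))) stop("concentrations must be finite")
  if (!noisy && any(concentration < 0)) {
    stop("negative concentrations are only allowed for noisy curves")
  }
  structure(
    list(schedule = schedule, concentration = concentration,
         region_label = region_label,
         decay_corrected = isTRUE(decay_corrected), noisy = isTRUE(noisy)),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac '%s': %d frames over %.4g min; peak %.4g kBq/mL%s%s>\n",
              x$region_label, n_frames(x$schedule),
              total_duration(x$schedule), max(x$concentration, 0),
              if (x$decay_corrected) ", decay-corrected" else "",
              if (x$noisy) ", noisy" else ""))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(
    frame_start = x$schedule$start,
    frame_end = x$schedule$end,
    concentration = x$concentration
  )
}

#' Decay-correct a time-activity curve (or undo the correction)
#'
#' Measured activity decays physically with the isotope half-life;
#' correcting to injection time multiplies each frame by
#' `exp(log(2) * t_mid / half_life)`, undoing divides by it. The curve's
#' `decay_corrected` flag records its current state; requesting the state it
#' is already in is an error (double correction).
#'
#' @param x A [tac].
#' @param half_life Isotope half-life in minutes (default fluorine-18,
#'   109.77 min).
#' @param direction `"to_injection"` or `"undo"`.
#' @return The transformed [tac] with the flag toggled.
#' @export
decay_correct <- function(x, half_life = F18_HALF_LIFE_MIN,
                          direction = c("to_injection", "undo")) {
  stopifnot(inherits(x, "tac"), half_life > 0)
  direction <- match.arg(direction)
  if (direction == "to_injection" && x$decay_corrected) {
    stop("curve is already decay-corrected")
  }
  if (direction == "undo" && !x$decay_corrected) {
    stop("curve is not decay-corrected; nothing to undo")
  }
  lambda <- log(2) / half_life
  f <- exp(lambda * frame_midpoints(x$schedule))
  x$concentration <- if (direction == "to_injection") {
    x$concentration * f
  } else {
    x$concentration / f
  }
  x$decay_corrected <- direction == "to_injection"
  x
}

#' Read / write the TAC CSV interchange format
#'
#' Columns `frame_start_s, frame_end_s, concentration_kBq_per_mL` (times in
#' seconds, header mandatory), one file per region per animal.
#'
#' @param path File path.
#' @param region_label,decay_corrected,noisy Passed to [tac()] when reading.
#' @return `read_tac_csv` returns a [tac]; `write_tac_csv` returns `path`
#'   invisibly.
#' @export
read_tac_csv <- function(path, region_label = "", decay_corrected = TRUE,
                         noisy = FALSE) {
  d <- utils::read.csv(path)
  need <- c("frame_start_s", "frame_end_s", "concentration_kBq_per_mL")
  if (!all(need %in% names(d))) {
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  }
  tac(frame_schedule(d$frame_start_s / 60, d$frame_end_s / 60),
      d$concentration_kBq_per_mL, region_label = region_label,
      decay_corrected = decay_corrected, noisy = noisy)
}

#' @rdname read_tac_csv
#' @param x A [tac] to write.
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  utils::write.csv(
    data.frame(frame_start_s = x$schedule$start * 60,
               frame_end_s = x$schedule$end * 60,
               concentration_kBq_per_mL = x$concentration),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Injection record for one animal
#'
#' @param animal_id Animal identifier.
#' @param genotype `"WT"` or `"KO"`.
#' @param drug Drug arm label (e.g. `"blarcamesine"`, `"PRE-084"`).
#' @param dose_mg_per_kg Oral dose in mg/kg (0 for vehicle).
#' @param injected_MBq Injected activity at injection time, MBq.
#' @param weight_g Body weight in grams; must lie in `weight_bounds`.
#' @param weight_bounds Plausible rodent weight range (g).
#' @return An object of class `injection_record`.
#' @export
injection_record <- function(animal_id, genotype = c("WT", "KO"),
                             drug = "blarcamesine", dose_mg_per_kg = 0,
                             injected_MBq, weight_g,
                             weight_bounds = c(15, 45)) {
  genotype <- match.arg(genotype)
  if (!is.numeric(injected_MBq) || injected_MBq <= 0) {
    stop("injected activity must be positive")
  }
  if (weight_g < weight_bounds[1] || weight_g > weight_bounds[2]) {
    stop(sprintf("weight %.1f g outside plausible range [%g, %g]",
                 weight_g, weight_bounds[1], weight_bounds[2]))
  }
  if (dose_mg_per_kg < 0) stop("dose must be non-negative")
  structure(
    list(animal_id = as.character(animal_id), genotype = genotype,
         drug = drug, dose_mg_per_kg = dose_mg_per_kg,
         injected_MBq = injected_MBq, weight_g = weight_g),
    class = "injection_record"
  )
}
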