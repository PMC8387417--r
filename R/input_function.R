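#' Parent-fraction model for radiometabolite correction
#'
#' The fraction of plasma radioactivity attributable to the intact parent
#' radioligand, modelled as
#' `pf(t) = plateau + (1 - plateau) * exp(-rate * t)` so that `pf(0) = 1`
#' (no metabolism at injection) and pf decays monotonically towards
#' `plateau`. The default calibration anchors the curve at 16% parent
#' 5 minutes post-injection.
#'
#' @param plateau Late-time parent fraction (in `[0, 1)`).
#' @param rate Decay rate of the parent fraction, per minute. Exactly one of
#'   `rate` or `anchor` must be given.
#' @param anchor Length-2 numeric `c(time_min, fraction)` through which the
#'   curve must pass; `rate` is solved in closed form. Default `c(5, 0.16)`.
#' @return An object of class `pf_model`; evaluate it with
#'   [parent_fraction()].
#' @examples
#' pf <- parent_fraction_model()      # pf(5) = 0.16, plateau 0
#' parent_fraction(pf, c(0, 5, 10))
#' @export
parent_fraction_model <- function(plateau = 0, rate = NULL,
                                  anchor = c(5, 0.16)) {
  stopifnot(plateau >= 0, plateau < 1)
  if (is.null(rate)) {
    t0 <- anchor[1]
    f0 <- anchor[2]
    if (t0 <= 0) stop("anchor time must be positive")
    if (f0 <= plateau) {
      stop("anchor fraction must exceed the plateau (otherwise unsolvable)")
    }
    if (f0 > 1) stop("anchor fraction cannot exceed 1")
    rate <- -log((f0 - plateau) / (1 - plateau)) / t0
  }
  if (rate < 0) stop("parent-fraction rate must be non-negative")
  structure(list(plateau = plateau, rate = rate), class = "pf_model")
}

#' Evaluate a parent-fraction model
#' @param model A [parent_fraction_model()].
#' @param t Times in minutes.
#' @return Parent fraction in `[0, 1]` at each `t`.
#' @export
parent_fraction <- function(model, t) {
  stopifnot(inherits(model, "pf_model"))
  model$plateau + (1 - model$plateau) * exp(-model$rate * t)
}

#' Fit a parent-fraction model to measured (time, fraction) pairs
#'
#' Least-squares fit of the plateau-plus-exponential form to a measured
#' metabolite table (e.g. from a separate blood-sampling cohort).
#'
#' @param times Sampling times, minutes.
#' @param fractions Measured parent fractions in `[0, 1]`.
#' @param fix_plateau Optional fixed plateau; if `NULL` the plateau is free.
#' @return A [parent_fraction_model()] with an `rss` attribute.
#' @export
fit_parent_fraction <- function(times, fractions, fix_plateau = NULL) {
  stopifnot(length(times) == length(fractions), length(times) >= 2,
            all(fractions >= 0), all(fractions <= 1))
  resid_fn <- function(p) {
    pl <- if (is.null(fix_plateau)) p[2] else fix_plateau
    fractions - (pl + (1 - pl) * exp(-p[1] * times))
  }
  start <- c(rate = 0.3, if (is.null(fix_plateau)) c(plateau = 0.05))
  lower <- c(0, if (is.null(fix_plateau)) 0)
  upper <- c(10, if (is.null(fix_plateau)) 0.999)
  fit <- minpack.lm::nls.lm(start, lower, upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  pl <- if (is.null(fix_plateau)) unname(fit$par[2]) else fix_plateau
  out <- parent_fraction_model(plateau = pl, rate = unname(fit$par[1]))
  attr(out, "rss") <- fit$deviance
  out
}

#' @export
print.pf_model <- function(x, ...) {
  cat(sprintf("<pf_model: plateau %.3g, rate %.4g /min (pf(5) = %.3g)>\n",
              x$plateau, x$rate, parent_fraction(x, 5)))
  invisible(x)
}

#' Image-derived input function model
#'
#' The whole-blood curve from a left-ventricle VOI is modelled as a linear
#' rise from zero to the peak at `t_peak`, followed by the sum of three
#' decaying exponentials:
#' `wb(t) = sum(A) * t / t_peak` for `t <= t_peak`, and
#' `wb(t) = sum_j A_j * exp(-lambda_j * (t - t_peak))` after the peak.
#' The metabolite-corrected plasma input is
#' `Cp(t) = plasma_ratio * pf(t) * wb(t)`, with a fixed plasma:whole-blood
#' ratio (default 1.14) and a [parent_fraction_model()].
#'
#' @param amplitudes Three non-negative exponential amplitudes, kBq/mL.
#' @param rates Three positive decay rates, per minute (stored sorted
#'   descending, amplitudes permuted alongside).
#' @param t_peak Peak time, minutes (> 0).
#' @param plasma_ratio Plasma to whole-blood activity ratio (> 0).
#' @param pf A [parent_fraction_model()].
#' @param t_max End of validity domain, minutes (scan end).
#' @return Object of class `idif_model`.
#' @export
idif_model <- function(amplitudes, rates, t_peak = 0.5, plasma_ratio = 1.14,
                       pf = parent_fraction_model(), t_max = 60) {
  stopifnot(length(amplitudes) == 3, length(rates) == 3)
  if (any(rates <= 0)) stop("exponential rates must be strictly positive")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (t_peak <= 0 || t_peak >= t_max) stop("t_peak must lie inside (0, t_max)")
  if (plasma_ratio <= 0) stop("plasma:whole-blood ratio must be positive")
  o <- order(rates, decreasing = TRUE)
  structure(
    list(amplitudes = as.numeric(amplitudes[o]), rates = as.numeric(rates[o]),
         t_peak = t_peak, plasma_ratio = plasma_ratio, pf = pf,
         t_max = t_max, chi = NA_real_),
    class = "idif_model"
  )
}

#' @export
print.idif_model <- function(x, ...) {
  cat(sprintf(
    "<idif_model: peak %.4g kBq/mL at %.3g min; rates %s /min; ratio %.3g%s>\n",
    sum(x$amplitudes), x$t_peak,
    paste(signif(x$rates, 3), collapse = ", "), x$plasma_ratio,
    if (is.finite(x$chi)) sprintf("; chi %.3g", x$chi) else ""))
  invisible(x)
}

#' Evaluate the whole-blood model
#' @param model An [idif_model()].
#' @param t Times, minutes, within `[0, t_max]`.
#' @return Whole-blood concentration, kBq/mL.
#' @export
whole_blood <- function(model, t) {
  check_input_domain(model, t)
  peak <- sum(model$amplitudes)
  out <- ifelse(t <= model$t_peak, peak * t / model$t_peak, 0)
  late <- t > model$t_peak
  if (any(late)) {
    u <- t[late] - model$t_peak
    out[late] <- colSums(model$amplitudes * exp(-outer(model$rates, u)))
  }
  out
}

check_input_domain <- function(model, t) {
  if (any(t < -1e-9) || any(t > model$t_max + 1e-9)) {
    stop(sprintf("evaluation outside the fitted domain [0, %g] min",
                 model$t_max))
  }
}

#' Whole blood to plasma conversion
#'
#' Applies the fixed plasma:whole-blood count ratio (default 1:1.14).
#'
#' @param c_wb Whole-blood concentration(s), kBq/mL.
#' @param ratio Plasma:whole-blood ratio.
#' @return Plasma concentration(s).
#' @examples
#' whole_blood_to_plasma(100)  # 114
#' @export
whole_blood_to_plasma <- function(c_wb, ratio = 1.14) {
  stopifnot(ratio > 0)
  c_wb * ratio
}

#' Metabolite-corrected plasma input function
#'
#' Returns the continuous parent-plasma input
#' `Cp(t) = plasma_ratio * pf(t) * wb(t)` as a function of minutes,
#' evaluable anywhere in the model's fitted domain.
#'
#' @param model An [idif_model()].
#' @return A function `Cp(t)`.
#' @export
metabolite_corrected_input <- function(model) {
  stopifnot(inherits(model, "idif_model"))
  force(model)
  function(t) {
    whole_blood(model, t) * model$plasma_ratio * parent_fraction(model$pf, t)
  }
}

#' Fit the rise-then-three-exponential model to a whole-blood curve
#'
#' Frame-duration-weighted nonlinear least squares over a fixed,
#' deterministic multi-start grid of rate triplets (no hidden randomness:
#' two calls on the same data give the same answer). The reported `chi` is
#' the reduced weighted chi-square, i.e. the frame-duration-weighted
#' residual sum of squares per degree of freedom, the criterion used to
#' choose the best fit.
#'
#' @param wb_tac A whole-blood [tac] with at least 8 frames and positive
#'   total activity.
#' @param n_starts Number of multi-start rate triplets to try (1--8).
#' @param plasma_ratio,pf Passed through to the returned [idif_model()].
#' @return A fitted [idif_model()] with `chi`, `converged` and `n_starts_used`
#'   fields set.
#' @export
fit_idif <- function(wb_tac, n_starts = 8, plasma_ratio = 1.14,
                     pf = parent_fraction_model()) {
  stopifnot(inherits(wb_tac, "tac"))
  if (n_frames(wb_tac$schedule) < 8) stop("need at least 8 frames")
  if (sum(wb_tac$concentration) <= 0) stop("total activity must be positive")
  sched <- wb_tac$schedule
  obs <- wb_tac$concentration
  w <- frame_durations(sched)
  w <- w / sum(w)
  sw <- sqrt(w)
  peak_frame <- which.max(obs)
  tp0 <- max(frame_midpoints(sched)[peak_frame], 0.05)
  peak0 <- max(obs)
  t_max <- sched$end[n_frames(sched)]

  # fixed multi-start grid of rate triplets (per minute), fastest first
  rate_grid <- list(
    c(10, 1, 0.1), c(5, 0.5, 0.05), c(20, 2, 0.2), c(8, 0.8, 0.01),
    c(3, 0.3, 0.03), c(15, 1.5, 0.015), c(6, 0.2, 0.02), c(12, 0.6, 0.005)
  )
  n_starts <- max(1L, min(as.integer(n_starts), length(rate_grid)))

  resid_fn <- function(p) {
    m <- try(idif_model(amplitudes = p[1:3], rates = p[4:6], t_peak = p[7],
                        plasma_ratio = plasma_ratio, pf = pf, t_max = t_max),
             silent = TRUE)
    if (inherits(m, "try-error")) return(rep(1e6, length(obs)))
    sw * (obs - frame_average_blood(m, sched))
  }

  best <- NULL
  tried <- 0L
  for (i in seq_len(n_starts)) {
    start <- c(peak0 * c(0.7, 0.2, 0.1), rate_grid[[i]], tp0)
    fit <- try(minpack.lm::nls.lm(
      par = start,
      lower = c(0, 0, 0, 1e-4, 1e-4, 1e-4, 0.02),
      upper = c(Inf, Inf, Inf, 100, 100, 100, min(tp0 + 2, t_max / 2)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    tried <- tried + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("no IDIF multi-start converged")
  p <- best$par
  dof <- max(length(obs) - length(p), 1L)
  model <- idif_model(amplitudes = p[1:3], rates = p[4:6], t_peak = p[7],
                      plasma_ratio = plasma_ratio, pf = pf, t_max = t_max)
  model$chi <- best$deviance / dof
  model$converged <- best$info %in% 1:3
  model$n_starts_used <- tried
  class(model) <- c("idif_fit", "idif_model")
  model
}

#' Frame-average the whole-blood model onto a schedule
#'
#' Exact analytic frame integrals of the rise-then-exponential model (frames
#' straddling the peak are split there), divided by frame duration.
#'
#' @param model An [idif_model()].
#' @param schedule A [frame_schedule].
#' @return Numeric vector of frame-averaged concentrations.
#' @export
frame_average_blood <- function(model, schedule) {
  a <- schedule$start
  b <- schedule$end
  tp <- model$t_peak
  peak <- sum(model$amplitudes)
  n <- n_frames(schedule)
  out <- numeric(n)
  # rise portion: integral of peak*t/tp over [a, min(b, tp)]
  lo <- pmin(a, tp)
  hi <- pmin(b, tp)
  out <- out + peak / tp * (hi^2 - lo^2) / 2
  # tail portion over [max(a, tp), b], in u = t - tp coordinates
  lo <- pmax(a - tp, 0)
  hi <- pmax(b - tp, 0)
  for (j in 1:3) {
    lam <- model$rates[j]
    out <- out + model$amplitudes[j] / lam * (exp(-lam * lo) - exp(-lam * hi))
  }
  out / (b - a)
}

#' Serialize a fitted input-function model to JSON
#' @param model An [idif_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idif_json <- function(model, path) {
  jsonlite::write_json(
    list(amplitudes_kBq_per_mL = model$amplitudes,
         rates_per_min = model$rates, t_peak_min = model$t_peak,
         plasma_to_whole_blood = model$plasma_ratio,
         parent_fraction = list(plateau = model$pf$plateau,
                                rate_per_min = model$pf$rate),
         chi = model$chi, t_max_min = model$t_max),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
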