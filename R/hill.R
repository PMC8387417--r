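#' Hill-Langmuir dose-response parameters
#'
#' Saturating occupancy-versus-dose relation
#' `RO(d) = ro_max * d^n / (d50^n + d^n)`: `ro_max` is the occupancy
#' plateau in percent, `d50` the dose of half-maximal occupancy in mg/kg,
#' and `n` the Hill cooperativity exponent.
#'
#' @param ro_max Plateau occupancy, percent, in `(0, 100]`.
#' @param d50 Half-maximal dose, mg/kg (> 0).
#' @param hill_n Cooperativity exponent (> 0).
#' @return Object of class `hill_params`.
#' @export
hill_params <- function(ro_max, d50, hill_n) {
  if (ro_max <= 0 || ro_max > 100) stop("ro_max must lie in (0, 100]")
  if (d50 <= 0) stop("d50 must be positive")
  if (hill_n <= 0) stop("hill_n must be positive")
  structure(list(ro_max = ro_max, d50 = d50, hill_n = hill_n),
            class = "hill_params")
}

#' Evaluate a Hill-Langmuir curve
#' @param params A [hill_params()] (or `hill_fit`).
#' @param dose Doses, mg/kg (non-negative).
#' @return Occupancy in percent; monotone non-decreasing in dose.
#' @export
hill_occupancy <- function(params, dose) {
  stopifnot(all(dose >= 0))
  dn <- dose^params$hill_n
  params$ro_max * dn / (params$d50^params$hill_n + dn)
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<Hill-Langmuir: ro_max %.4g%%, d50 %.4g mg/kg, n %.3g%s>\n",
              x$ro_max, x$d50, x$hill_n,
              if (isTRUE(attr(x, "wide_uncertainty")))
                " [d50/n poorly identified]" else ""))
  invisible(x)
}

#' Fit a Hill-Langmuir curve to occupancy data
#'
#' Bounded least squares over a small deterministic multi-start grid.
#' Requires at least three distinct non-zero dose levels for the full
#' three-parameter fit, or two when the Hill exponent is fixed. Degenerate
#' data (near-constant occupancy) return a plateau-only answer flagged with
#' attribute `wide_uncertainty` rather than failing.
#'
#' @param doses Doses in mg/kg (zeros allowed; RO(0) = 0 is implied by the
#'   functional form).
#' @param ro Occupancy values, percent.
#' @param fix_n Optional fixed Hill exponent.
#' @return A `hill_fit` object (inherits [hill_params()]) with fields `rss`
#'   and `fitted`, and attribute `wide_uncertainty` when d50/n are not
#'   identified.
#' @examples
#' d <- c(1, 10, 30)
#' fit_hill(d, hill_occupancy(hill_params(64, 3.5, 1.6), d))
#' @export
fit_hill <- function(doses, ro, fix_n = NULL) {
  stopifnot(length(doses) == length(ro), all(doses >= 0))
  nz <- length(unique(doses[doses > 0]))
  need <- if (is.null(fix_n)) 3 else 2
  if (nz < need) {
    stop(sprintf("need at least %d distinct non-zero dose levels", need))
  }
  d_max <- max(doses)
  resid_fn <- function(p) {
    n <- if (is.null(fix_n)) p[3] else fix_n
    dn <- doses^n
    ro - p[1] * dn / (p[2]^n + dn)
  }
  grid <- expand.grid(ro_max = c(max(ro), 80),
                      d50 = c(0.3, 3, 30) * d_max / 30,
                      n = if (is.null(fix_n)) c(0.8, 1.6) else NA)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    start <- c(grid$ro_max[i], grid$d50[i],
               if (is.null(fix_n)) grid$n[i])
    fit <- try(minpack.lm::nls.lm(
      par = pmax(start, 1e-3), lower = c(1e-6, 1e-6, if (is.null(fix_n)) 0.05),
      upper = c(100, 10 * d_max, if (is.null(fix_n)) 5),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("Hill-Langmuir fit failed from every start")
  p <- best$par
  n_hat <- if (is.null(fix_n)) p[3] else fix_n
  out <- hill_params(min(p[1], 100), p[2], n_hat)
  out$rss <- best$deviance
  out$fitted <- hill_occupancy(out, doses)
  # d50 is unidentifiable when the data show no dose-dependence
  span <- diff(range(ro))
  if (!is.finite(span) || span < 1e-8 * max(abs(ro), 1) ||
      p[2] > 0.999 * 10 * d_max) {
    attr(out, "wide_uncertainty") <- TRUE
    warning("occupancy shows no usable dose-dependence; ",
            "d50 and n are not identified")
  }
  class(out) <- c("hill_fit", "hill_params")
  out
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ro_max = object$ro_max, d50 = object$d50, hill_n = object$hill_n)
}

#' @export
predict.hill_fit <- function(object, dose, ...) hill_occupancy(object, dose)

#' @export
plot.hill_fit <- function(x, doses = NULL, ro = NULL, ...) {
  dmax <- if (!is.null(doses)) max(doses) else x$d50 * 10
  dd <- seq(0, dmax, length.out = 200)
  graphics::plot(dd, hill_occupancy(x, dd), type = "l", lwd = 2,
                 col = "firebrick", xlab = "dose (mg/kg)",
                 ylab = "receptor occupancy (%)",
                 main = "Hill-Langmuir dose-response", ylim = c(0, 100), ...)
  if (!is.null(doses) && !is.null(ro)) graphics::points(doses, ro)
  invisible(x)
}
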