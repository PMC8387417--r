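#' Two-tissue compartment model parameters
#'
#' Micro-rate constants of the 2TCM: `K1` (mL cm-3 min-1, plasma to tissue),
#' `k2` (min-1, tissue to plasma), `k3` (min-1, binding), `k4` (min-1,
#' dissociation), plus the fractional blood volume `vB` of the VOI.
#'
#' @param K1,k2,k3,k4 Rate constants; `K1 >= 0`, `k2, k4 > 0`, `k3 >= 0`.
#' @param vB Blood volume fraction in `[0, 1)`.
#' @return Object of class `two_tissue_params`.
#' @export
two_tissue_params <- function(K1, k2, k3, k4, vB = 0.05) {
  if (K1 < 0) stop("K1 must be non-negative")
  if (k2 <= 0 || k4 <= 0) stop("k2 and k4 must be strictly positive")
  if (k3 < 0) stop("k3 must be non-negative")
  if (vB < 0 || vB >= 1) stop("vB must lie in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "two_tissue_params")
}

#' @export
print.two_tissue_params <- function(x, ...) {
  cat(sprintf("<2TCM params: K1 %.4g, k2 %.4g, k3 %.4g, k4 %.4g, vB %.3g>\n",
              x$K1, x$k2, x$k3, x$k4, x$vB))
  invisible(x)
}

# ---- stable convolution primitives -----------------------------------------
# conv0: int_0^t exp(-alpha (t - s)) exp(-mu s) ds
#      = t exp(-alpha t) phi1((alpha - mu) t)
# conv1: int_0^t exp(-alpha (t - s)) s exp(-mu s) ds
#      = t^2 exp(-alpha t) psi((alpha - mu) t)
# with phi1(z) = (e^z - 1)/z and psi(z) = (e^z (z - 1) + 1)/z^2; both are
# evaluated in overflow-free branches so alpha ~= mu costs no precision.

conv0 <- function(mu, alpha, t) {
  z <- (alpha - mu) * t
  out <- numeric(length(t))
  small <- abs(z) < 30
  if (any(small)) {
    zs <- z[small]
    phi1 <- ifelse(abs(zs) < 1e-9, 1 + zs / 2, expm1(zs) / zs)
    out[small] <- t[small] * exp(-alpha * t[small]) * phi1
  }
  if (any(!small)) {
    tb <- t[!small]
    out[!small] <- (exp(-mu * tb) - exp(-alpha * tb)) / (alpha - mu)
  }
  out
}

conv1 <- function(mu, alpha, t) {
  z <- (alpha - mu) * t
  out <- numeric(length(t))
  tiny <- abs(z) < 1e-4
  mid <- !tiny & abs(z) < 30
  big <- abs(z) >= 30
  if (any(tiny)) {
    zs <- z[tiny]
    psi <- 0.5 + zs / 3 + zs^2 / 8 + zs^3 / 30
    out[tiny] <- t[tiny]^2 * exp(-alpha * t[tiny]) * psi
  }
  if (any(mid)) {
    zs <- z[mid]
    out[mid] <- t[mid]^2 * exp(-alpha * t[mid]) * (exp(zs) * (zs - 1) + 1) / zs^2
  }
  if (any(big)) {
    tb <- t[big]
    beta <- alpha - mu
    out[big] <- (exp(-mu * tb) * (beta * tb - 1) + exp(-alpha * tb)) / beta^2
  }
  out
}

# Decompose the (optionally metabolite-corrected) input into exponential
# terms: rise piece  f1(t) = sum c_i t^{p_i} e^{-mu_i t}  on [0, t_peak],
# tail piece f2(u) = sum d_j e^{-mu_j u} in u = t - t_peak coordinates.
input_exp_terms <- function(model, corrected = TRUE) {
  tp <- model$t_peak
  slope <- sum(model$amplitudes) / tp
  if (corrected) {
    r <- model$plasma_ratio
    pl <- model$pf$plateau
    k <- model$pf$rate
    rise <- list(c = c(r * slope * pl, r * slope * (1 - pl)),
                 p = c(1L, 1L), mu = c(0, k))
    tail_d <- c(r * pl * model$amplitudes,
                r * (1 - pl) * exp(-k * tp) * model$amplitudes)
    tail_mu <- c(model$rates, model$rates + k)
  } else {
    rise <- list(c = slope, p = 1L, mu = 0)
    tail_d <- model$amplitudes
    tail_mu <- model$rates
  }
  keep_r <- rise$c != 0
  keep_t <- tail_d != 0
  list(tp = tp,
       rise = list(c = rise$c[keep_r], p = rise$p[keep_r], mu = rise$mu[keep_r]),
       tail = list(d = tail_d[keep_t], mu = tail_mu[keep_t]))
}

# y_alpha(t) = int_0^t exp(-alpha (t - s)) f(s) ds for the piecewise input
conv_with_input <- function(alpha, terms, t) {
  tp <- terms$tp
  rise_val <- function(tt) {
    y <- numeric(length(tt))
    for (i in seq_along(terms$rise$c)) {
      ci <- terms$rise$c[i]
      mui <- terms$rise$mu[i]
      y <- y + ci * if (terms$rise$p[i] == 1L) conv1(mui, alpha, tt) else
        conv0(mui, alpha, tt)
    }
    y
  }
  out <- numeric(length(t))
  pre <- t <= tp
  if (any(pre)) out[pre] <- rise_val(t[pre])
  if (any(!pre)) {
    y_tp <- rise_val(tp)
    u <- t[!pre] - tp
    y <- y_tp * exp(-alpha * u)
    for (j in seq_along(terms$tail$d)) {
      y <- y + terms$tail$d[j] * conv0(terms$tail$mu[j], alpha, u)
    }
    out[!pre] <- y
  }
  out
}

#' Continuous 2TCM tissue curve
#'
#' Pointwise-exact tissue concentration
#' `C_T(t) = (1 - vB) * (C1(t) + C2(t)) + vB * C_wb(t)`, where the
#' compartment system `dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2`,
#' `dC2/dt = k3 C1 - k4 C2` (zero initial conditions) is solved by the
#' closed-form bi-exponential impulse response with eigen-rates
#' `alpha_{1,2} = ((k2 + k3 + k4) -/+ sqrt((k2 + k3 + k4)^2 - 4 k2 k4)) / 2`
#' convolved analytically with the piecewise-exponential plasma input. A
#' repeated eigenvalue (`k3 = 0`, `k2 = k4`) is handled by its analytic
#' limit via an infinitesimal symmetric eigenvalue split. The blood
#' spillover term uses the whole-blood (not plasma) curve.
#'
#' @param params A [two_tissue_params()].
#' @param input_model An [idif_model()].
#' @param t Times in minutes within the input model's domain.
#' @return Tissue concentration at each `t`, kBq/mL.
#' @export
two_tissue_curve <- function(params, input_model, t) {
  stopifnot(inherits(params, "two_tissue_params"),
            inherits(input_model, "idif_model"))
  check_input_domain(input_model, t)
  s <- params$k2 + params$k3 + params$k4
  disc <- s^2 - 4 * params$k2 * params$k4
  disc <- max(disc, (1e-7 * s)^2)  # analytic limit for repeated eigenvalues
  sq <- sqrt(disc)
  a1 <- (s - sq) / 2
  a2 <- (s + sq) / 2
  conv_part <- 0
  if (params$K1 > 0) {
    c1 <- params$K1 * (params$k3 + params$k4 - a1) / (a2 - a1)
    c2 <- params$K1 * (a2 - params$k3 - params$k4) / (a2 - a1)
    terms <- input_exp_terms(input_model, corrected = TRUE)
    conv_part <- c1 * conv_with_input(a1, terms, t) +
      c2 * conv_with_input(a2, terms, t)
  }
  (1 - params$vB) * conv_part + params$vB * whole_blood(input_model, t)
}

# 8-point Gauss-Legendre rule on [-1, 1]
.gl8_x <- c(-0.9602898564975363, -0.7966664774136267, -0.5255324099163290,
            -0.1834346424956498, 0.1834346424956498, 0.5255324099163290,
            0.7966664774136267, 0.9602898564975363)
.gl8_w <- c(0.1012285362903763, 0.2223810344533745, 0.3137066458778873,
            0.3626837833783620, 0.3626837833783620, 0.3137066458778873,
            0.2223810344533745, 0.1012285362903763)

# Quadrature nodes/weights for frame means; frames straddling `split_at`
# are split there so every subinterval is smooth. Weights are scaled so the
# weighted sum of node values per frame is the frame *mean*.
build_frame_quadrature <- function(schedule, split_at = NULL) {
  a <- schedule$start
  b <- schedule$end
  nodes <- list()
  wts <- list()
  idx <- list()
  for (i in seq_along(a)) {
    cuts <- c(a[i], b[i])
    if (!is.null(split_at) && split_at > a[i] + 1e-12 &&
        split_at < b[i] - 1e-12) {
      cuts <- c(a[i], split_at, b[i])
    }
    for (k in seq_len(length(cuts) - 1L)) {
      lo <- cuts[k]
      hi <- cuts[k + 1L]
      nodes[[length(nodes) + 1L]] <- (lo + hi) / 2 + (hi - lo) / 2 * .gl8_x
      wts[[length(wts) + 1L]] <- .gl8_w * (hi - lo) / 2 / (b[i] - a[i])
      idx[[length(idx) + 1L]] <- rep(i, 8L)
    }
  }
  list(t = unlist(nodes), w = unlist(wts), frame = unlist(idx),
       n = length(a))
}

frame_means_from_nodes <- function(values, quad) {
  as.numeric(rowsum(values * quad$w, quad$frame, reorder = TRUE))
}

#' Frame-averaged 2TCM prediction
#'
#' Evaluates [two_tissue_curve()] and averages it over each frame of the
#' schedule with Gauss-Legendre quadrature (frames split at the input
#' peak), which is exact to machine precision for these smooth curves.
#'
#' @param params A [two_tissue_params()].
#' @param input_model An [idif_model()].
#' @param schedule A [frame_schedule] within the input model's domain.
#' @return A noiseless [tac] (`region_label = "model"`).
#' @export
model_tac_2tcm <- function(params, input_model, schedule) {
  quad <- build_frame_quadrature(schedule, split_at = input_model$t_peak)
  vals <- two_tissue_curve(params, input_model, quad$t)
  tac(schedule, frame_means_from_nodes(vals, quad), region_label = "model")
}

#' Macro-parameters of the 2TCM
#'
#' Binding potential `BP_ND = k3/k4`, total distribution volume
#' `Vt = (K1/k2) (1 + k3/k4)` and volume of specific binding
#' `Vs = Vt - K1/k2 = K1 k3 / (k2 k4)`. `Vs = Vt * BP / (1 + BP)` holds
#' exactly, and `Vt - Vs` is the non-displaceable volume `K1/k2`.
#'
#' @param params A [two_tissue_params()] (requires `k2 > 0`, `k4 > 0`).
#' @return Object of class `macro_params` with fields `bp_nd`, `vt`, `vs`.
#' @examples
#' derive_macros(two_tissue_params(0.75, 0.1, 0.051, 0.05))
#' @export
derive_macros <- function(params) {
  stopifnot(inherits(params, "two_tissue_params"))
  if (params$k2 <= 0 || params$k4 <= 0) {
    stop("k2 and k4 must be positive to derive macro-parameters")
  }
  bp <- params$k3 / params$k4
  vnd <- params$K1 / params$k2
  structure(list(bp_nd = bp, vt = vnd * (1 + bp), vs = vnd * bp),
            class = "macro_params")
}

#' @export
print.macro_params <- function(x, ...) {
  cat(sprintf("<macros: BP_ND %.4g, Vt %.4g, Vs %.4g mL/cm3>\n",
              x$bp_nd, x$vt, x$vs))
  invisible(x)
}
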