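# shared fixtures, all built in code

default_idif <- function(peak = 183, t_max = 120) {
  idif_model(peak * c(0.82, 0.13, 0.05), c(4, 0.5, 0.03), t_peak = 0.5,
             plasma_ratio = 1.14, pf = parent_fraction_model(),
             t_max = t_max)
}

wt_baseline_params <- function() {
  two_tissue_params(K1 = 0.75, k2 = 0.1, k3 = 0.051, k4 = 0.05, vB = 0.05)
}

tiny_generator <- function(...) {
  generator_config(n_per_group = 2, pre084 = NULL, genotypes = "WT", ...)
}

# independent 2TCM oracle: adaptive ODE integration (deSolve) carrying a
# cumulative-integral state, so frame means come out of the solver itself
ode_2tcm_frame_means <- function(params, input_model, schedule,
                                 rtol = 1e-10) {
  Cp <- metabolite_corrected_input(input_model)
  deriv <- function(t, y, parms) {
    cp <- Cp(t)
    d1 <- params$K1 * cp - (params$k2 + params$k3) * y[1] + params$k4 * y[2]
    d2 <- params$k3 * y[1] - params$k4 * y[2]
    ct <- (1 - params$vB) * (y[1] + y[2]) +
      params$vB * whole_blood(input_model, t)
    list(c(d1, d2, ct))
  }
  tout <- unique(c(schedule$start, schedule$end))
  sol <- deSolve::ode(c(0, 0, 0), tout, deriv, NULL, method = "lsoda",
                      rtol = rtol, atol = 1e-12)
  diff(sol[, 4]) / frame_durations(schedule)
}

# brute-force exact two-sided Wilcoxon p by enumerating group assignments
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  W <- sum(r[seq_len(n1)])
  sums <- utils::combn(length(pooled), n1, FUN = function(i) sum(r[i]))
  min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
}
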