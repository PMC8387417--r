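#' Log-link regression with animal-level cluster-robust inference
#'
#' Gaussian-family generalized linear regression with a log link (the
#' family is switchable), with sandwich (cluster-robust) standard errors
#' grouped by animal: the simplest construction consistent with
#' "adjusted for clustering within animal". Repeated measurements on one
#' animal (e.g. several brain structures) therefore do not inflate the
#' effective sample size.
#'
#' @param formula Model formula; the response must be positive.
#' @param data Data frame.
#' @param cluster Cluster identifier vector (one entry per row), typically
#'   the animal id.
#' @param family A GLM family; default `gaussian(link = "log")`, with
#'   `Gamma(link = "log")` the natural alternative.
#' @return Object of class `loglink_fit`: `model` (the `glm`), `vcov`
#'   (cluster-robust), `coefficients` (Wald table with robust SEs).
#' @export
loglink_regression_clustered <- function(formula, data, cluster,
                                         family = stats::gaussian("log")) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (any(y <= 0)) stop("log-link regression requires positive responses")
  X <- stats::model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) {
    qrx <- qr(X)
    aliased <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  # start the IRLS from the linear fit on the log scale
  start <- stats::coef(stats::lm.fit(X, log(y)))
  fit <- stats::glm(formula, data = data, family = family, start = start)
  vc <- sandwich::vcovCL(fit, cluster = cluster)
  tab <- lmtest::coeftest(fit, vcov. = vc)
  structure(
    list(model = fit, vcov = vc,
         coefficients = tab[, , drop = FALSE], cluster = cluster),
    class = "loglink_fit"
  )
}

#' @export
print.loglink_fit <- function(x, ...) {
  cat("Log-link regression, cluster-robust (sandwich) inference\n\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.loglink_fit <- function(object, ...) stats::coef(object$model)

#' @export
vcov.loglink_fit <- function(object, ...) object$vcov

#' Linear regression of uptake on genotype and dose
#'
#' Ordinary least squares of %ID/g on a genotype indicator and the numeric
#' dose, the standard screen for a dose effect on tracer uptake.
#'
#' @param data Data frame with columns `pct_id_g`, `genotype`, `dose`.
#' @param response Response column name (default `"pct_id_g"`).
#' @return List with the `lm` `model` and its `coefficients` table; when
#'   there are no residual degrees of freedom the table carries `NA`
#'   p-values and a warning is issued ("insufficient n").
#' @export
regression_dose_genotype <- function(data, response = "pct_id_g") {
  stopifnot(all(c(response, "genotype", "dose") %in% names(data)))
  f <- stats::reformulate(c("genotype", "dose"), response = response)
  fit <- stats::lm(f, data = data)
  if (stats::df.residual(fit) < 1) {
    warning("insufficient n for inference on genotype and dose")
  }
  tab <- stats::coef(summary(fit))
  list(model = fit, coefficients = tab)
}
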