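#' Wilcoxon rank-sum (Mann-Whitney) test with exact enumeration
#'
#' Rank-sum test using midranks for ties. In exact mode the full
#' permutation distribution of the first-group rank sum is enumerated over
#' all assignments of the pooled observations (feasible at the small group
#' sizes of a typical preclinical cohort), and the two-sided p-value is
#' twice the smaller tail probability, capped at 1. The asymptotic mode
#' uses the normal approximation with the tie-corrected conditional
#' variance.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact `TRUE`, `FALSE`, or `NULL` (exact when `length(x) +
#'   length(y) <= exact_cap`).
#' @param exact_cap Largest combined sample size for which enumeration is
#'   attempted (default 20); requesting exact beyond it is an error.
#' @return An object of classes `occupet_test` and `htest`: `statistic` is
#'   the standardized rank-sum statistic `z`, with the raw rank sum `W`,
#'   per-group sizes and the `exact` flag attached.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), exact = TRUE)$p.value  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL, exact_cap = 20) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  if (is.null(exact)) exact <- N <= exact_cap
  if (exact && N > exact_cap) {
    stop(sprintf(
      "exact enumeration with n = %d exceeds the cap (%d); use exact = FALSE",
      N, exact_cap))
  }
  r <- rank(c(x, y))  # midranks
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (exact) {
    sums <- utils::combn(N, n1, FUN = function(i) sum(r[i]))
    eps <- 1e-9
    p_lo <- mean(sums <= W + eps)
    p_hi <- mean(sums >= W - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "Exact Wilcoxon rank-sum test (full enumeration, midranks)"
  } else {
    # continuity-corrected normal approximation, as in stats::wilcox.test
    zc <- if (sigma2 > 0) {
      (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    } else 0
    p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(zc)) else 1
    p <- min(p, 1)
    method <- "Wilcoxon rank-sum test (normal approximation, tie-corrected)"
  }
  new_occupet_test(statistic = c(z = z), p.value = p, method = method,
                   data.name = "x vs y",
                   extra = list(W = W, n_per_group = c(n1, n2),
                                exact = exact))
}

new_occupet_test <- function(statistic, p.value, method, data.name,
                             extra = list()) {
  out <- c(list(statistic = statistic, p.value = p.value, method = method,
                data.name = data.name, alternative = "two.sided"), extra)
  class(out) <- c("occupet_test", "htest")
  out
}

#' van Elteren's stratified Wilcoxon rank-sum test
#'
#' Combines per-stratum Wilcoxon rank-sum statistics with van Elteren's
#' locally optimal weights `1 / (n_s + 1)` (with `n_s` the stratum size)
#' and standardizes against the conditional null mean and tie-corrected
#' variance; the two-sided p-value comes from the normal approximation, or
#' optionally from stratum-wise label permutations. With a single stratum
#' the statistic equals the asymptotic Wilcoxon rank-sum statistic exactly.
#'
#' @param values Numeric measurements.
#' @param group Two-level group labels (e.g. drug arm).
#' @param stratum Stratum labels (e.g. brain structure or dose level).
#' @param permutation If `TRUE`, also compute a permutation p-value.
#' @param n_perm Number of stratum-wise label shuffles (default 10000).
#' @param seed Seed for the permutation draw (stored in the result).
#' @return An `occupet_test`; strata containing a single group are dropped
#'   with a warning (an error if none remain).
#' @export
van_elteren <- function(values, group, stratum, permutation = FALSE,
                        n_perm = 10000, seed = 1) {
  stopifnot(length(values) == length(group), length(values) == length(stratum))
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("'group' must have exactly two levels")
  g1 <- levels(group)[1]
  keep <- rep(TRUE, length(values))
  for (s in unique(stratum)) {
    i <- stratum == s
    if (length(unique(group[i])) < 2) {
      warning(sprintf("stratum '%s' has a single group; dropped", s))
      keep[i] <- FALSE
    }
  }
  if (!any(keep)) stop("no stratum contains both groups")
  values <- values[keep]
  group <- group[keep]
  stratum <- stratum[keep]

  stat_contrib <- function(v, g) {
    n_s <- length(v)
    n1 <- sum(g == g1)
    n2 <- n_s - n1
    r <- rank(v)
    w <- 1 / (n_s + 1)
    ties <- table(r)
    var_s <- n1 * n2 / 12 *
      ((n_s + 1) - sum(ties^3 - ties) / (n_s * (n_s - 1)))
    c(T = w * sum(r[g == g1]), E = w * n1 * (n_s + 1) / 2, V = w^2 * var_s)
  }
  per <- vapply(split(seq_along(values), stratum), function(i) {
    stat_contrib(values[i], group[i])
  }, numeric(3))
  Tsum <- sum(per["T", ])
  Esum <- sum(per["E", ])
  Vsum <- sum(per["V", ])
  if (Vsum <= 0) stop("all strata are degenerate (zero variance)")
  z <- (Tsum - Esum) / sqrt(Vsum)
  p <- 2 * stats::pnorm(-abs(z))
  extra <- list(n_per_group = table(group), weights = "1/(n_s + 1)",
                exact = FALSE)
  if (permutation) {
    obs <- abs(Tsum - Esum)
    idx <- split(seq_along(values), stratum)
    perm_stat <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      gp <- group
      for (i in idx) gp[i] <- gp[sample(i)]
      per_b <- vapply(idx, function(i) stat_contrib(values[i], gp[i]),
                      numeric(3))
      abs(sum(per_b["T", ]) - sum(per_b["E", ]))
    }, numeric(1)))
    extra$p.value.permutation <- (1 + sum(perm_stat >= obs - 1e-12)) /
      (n_perm + 1)
    extra$n_perm <- n_perm
    extra$seed <- seed
  }
  new_occupet_test(c(z = z), p, "van Elteren stratified rank-sum test",
                   "values by group, stratified", extra)
}

#' Stratified linear-by-linear association test of trend
#'
#' Nonparametric trend test across ordered dose levels: within each
#' stratum the statistic `T_s = sum(score_i * rank(value_i))` (midranks)
#' is centered and scaled by its conditional permutation mean and
#' variance, strata are combined additively, and a two-sided p-value is
#' taken from the normal approximation (optionally from stratum-wise
#' permutations). Scores default to the numeric dose values; `score_type =
#' "rank"` replaces them by the rank order of the levels.
#'
#' @param values Numeric measurements.
#' @param doses Ordered dose (or other ordinal) values, same length.
#' @param strata Optional stratum labels (e.g. genotype); `NULL` = one
#'   stratum.
#' @param score_type `"numeric"` (use dose values as scores) or `"rank"`
#'   (use 1, 2, 3, ... over the sorted distinct levels).
#' @param permutation,n_perm,seed As in [van_elteren()].
#' @return An `occupet_test` with standardized statistic `z`; positive `z`
#'   means values increase with dose.
#' @export
linear_by_linear_trend <- function(values, doses, strata = NULL,
                                   score_type = c("numeric", "rank"),
                                   permutation = FALSE, n_perm = 10000,
                                   seed = 1) {
  score_type <- match.arg(score_type)
  stopifnot(length(values) == length(doses))
  if (is.null(strata)) strata <- rep(1L, length(values))
  if (length(unique(doses)) < 2) stop("need at least 2 ordered dose levels")
  scores <- if (score_type == "rank") {
    match(doses, sort(unique(doses)))
  } else {
    as.numeric(doses)
  }
  contrib <- function(v, a) {
    n <- length(v)
    b <- rank(v)
    Ts <- sum(a * b)
    Es <- n * mean(a) * mean(b)
    Vs <- sum((a - mean(a))^2) * sum((b - mean(b))^2) / (n - 1)
    c(T = Ts, E = Es, V = Vs)
  }
  idx <- split(seq_along(values), strata)
  per <- vapply(idx, function(i) contrib(values[i], scores[i]), numeric(3))
  Vsum <- sum(per["V", ])
  if (Vsum <= 0) {
    stop("constant values (or scores) in all strata; trend variance is zero")
  }
  z <- (sum(per["T", ]) - sum(per["E", ])) / sqrt(Vsum)
  p <- 2 * stats::pnorm(-abs(z))
  extra <- list(scores = score_type, exact = FALSE)
  if (permutation) {
    obs <- abs(sum(per["T", ]) - sum(per["E", ]))
    perm_stat <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      vp <- values
      for (i in idx) vp[i] <- vp[sample(i)]
      per_b <- vapply(idx, function(i) contrib(vp[i], scores[i]), numeric(3))
      abs(sum(per_b["T", ]) - sum(per_b["E", ]))
    }, numeric(1)))
    extra$p.value.permutation <- (1 + sum(perm_stat >= obs - 1e-12)) /
      (n_perm + 1)
    extra$n_perm <- n_perm
    extra$seed <- seed
  }
  new_occupet_test(c(z = z), p,
                   "Stratified linear-by-linear association test of trend",
                   "values by dose", extra)
}
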