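#' Radioactivity quantities and unit conversion
#'
#' Activity is stored as a value plus unit. Conversions use the exact
#' definition 1 Ci = 37 GBq (so 1 uCi = 0.037 MBq); the conversion graph is
#' closed and round-trips are exact to machine precision.
#'
#' @param value Numeric activity value (finite).
#' @param unit One of `"Bq"`, `"kBq"`, `"MBq"`, `"GBq"`, `"uCi"`, `"mCi"`,
#'   `"Ci"` (the micro sign is accepted for `"uCi"`).
#' @return An object of class `activity_quantity`.
#' @examples
#' convert_activity(activity_quantity(12.8, "Ci"), "GBq")  # 473.6
#' @export
activity_quantity <- function(value, unit) {
  unit <- normalize_activity_unit(unit)
  value <- as.numeric(value)
  if (any(!is.finite(value))) stop("activity value must be finite")
  structure(list(value = value, unit = unit), class = "activity_quantity")
}

# factors to Bq; curie branch exact via 1 Ci = 3.7e10 Bq
.activity_factors <- c(
  Bq = 1, kBq = 1e3, MBq = 1e6, GBq = 1e9,
  uCi = 3.7e4, mCi = 3.7e7, Ci = 3.7e10
)

normalize_activity_unit <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1L)
  u <- sub("^µ", "u", unit)
  if (!u %in% names(.activity_factors)) {
    stop(sprintf("unknown activity unit '%s'", unit))
  }
  u
}

#' Convert an activity quantity to another unit
#'
#' @param q An [activity_quantity()], or a plain numeric (then `from` is
#'   required).
#' @param target_unit Unit to convert to.
#' @param from Source unit when `q` is numeric.
#' @return An `activity_quantity` in `target_unit`.
#' @examples
#' convert_activity(210, "MBq", from = "uCi")$value  # 7.77
#' @export
convert_activity <- function(q, target_unit, from = NULL) {
  if (is.numeric(q)) {
    if (is.null(from)) stop("'from' unit required for a numeric input")
    q <- activity_quantity(q, from)
  }
  stopifnot(inherits(q, "activity_quantity"))
  target_unit <- normalize_activity_unit(target_unit)
  value <- q$value * .activity_factors[[q$unit]] /
    .activity_factors[[target_unit]]
  activity_quantity(value, target_unit)
}

#' @export
print.activity_quantity <- function(x, ...) {
  cat(format(x$value), x$unit, "\n")
  invisible(x)
}

#' Physical half-life of fluorine-18, in minutes
#' @export
F18_HALF_LIFE_MIN <- 109.77
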