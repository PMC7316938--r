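# Descriptive statistics for deviation tables and the two-way
# absolute-agreement single-measures intraclass correlation (McGraw-Wong
# ICC(A,1)) used for inter-observer reliability.

#' Descriptive summary of a vector of measurements
#'
#' Mean, standard deviation, minimum and maximum. The SD divisor defaults to
#' the population form (divisor n): recomputing the cohort table footer from
#' per-implant values matches the printed SD with divisor n, not n - 1. The
#' sample form (n - 1) is available via `divisor = "sample"`.
#'
#' @param values Numeric vector; must contain no missing values (filter
#'   before calling).
#' @param divisor `"population"` (default, divisor n) or `"sample"`
#'   (divisor n - 1, requires n >= 2).
#' @param metric Optional metric name stamped on the returned row.
#' @return A one-row data frame: `metric`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
describe <- function(values, divisor = c("population", "sample"),
                     metric = NA_character_) {
  divisor <- match.arg(divisor)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("describe() needs at least one value", call. = FALSE)
  if (anyNA(values)) stop("values contain NA; filter missing values before describe()", call. = FALSE)
  n <- length(values)
  if (divisor == "sample" && n < 2L) {
    stop("sample SD needs n >= 2", call. = FALSE)
  }
  m <- mean(values)
  s <- if (divisor == "population") sqrt(mean((values - m)^2)) else sd(values)
  data.frame(metric = metric, n = n, mean = m, sd = s,
             min = min(values), max = max(values), stringsAsFactors = FALSE)
}

#' Intraclass correlation, two-way model, absolute agreement, single measures
#'
#' ICC(A,1) in McGraw-Wong notation: the inter-observer reliability of a
#' single measurement when k observers each rate the same n subjects and
#' systematic observer differences count as disagreement. Computed from the
#' two-way ANOVA decomposition (rows = subjects, columns = observers):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' The point estimate is identical under the two-way random and two-way
#' mixed models. Confidence bounds use the standard F-quantile construction
#' with Satterthwaite degrees of freedom.
#'
#' @param ratings n x k numeric matrix: n subjects (rows) rated by k
#'   observers (columns), same metric and units, no missing cells.
#' @param confidence Confidence level for the interval (default 0.95).
#' @return A list: `icc`, `ci_low`, `ci_high`, `confidence`, `n`, `k`, and
#'   the mean squares `ms_rows`, `ms_cols`, `ms_err`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(5, 8, 2)
#' ratings <- cbind(truth + rnorm(5, 0, 0.3), truth + rnorm(5, 0, 0.3))
#' icc_absolute_single(ratings)
#' @export
icc_absolute_single <- function(ratings, confidence = 0.95) {
  x <- as.matrix(ratings)
  storage.mode(x) <- "double"
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("ratings need at least 2 subjects and 2 observers", call. = FALSE)
  if (anyNA(x)) stop("ratings contain missing cells; drop incomplete subjects first", call. = FALSE)
  if (!(confidence > 0 && confidence < 1)) stop("confidence must be in (0, 1)", call. = FALSE)
  grand <- mean(x)
  if (sum((x - grand)^2) <= 0) {
    stop("undefined coefficient: ratings have zero total variance", call. = FALSE)
  }
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2) /
    ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - confidence
  if (mse == 0 && msc == 0) {
    # Perfect agreement: observers identical, interval degenerates at 1.
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], confidence = confidence,
       n = n, k = k, ms_rows = msr, ms_cols = msc, ms_err = mse)
}

#' Mean absolute difference between paired measurements
#'
#' @param a,b Numeric vectors of equal length.
#' @return The mean of |a_i - b_i|.
#' @export
mean_absolute_difference <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) == 0L) stop("need at least one pair", call. = FALSE)
  mean(abs(a - b))
}

#' Summarise a cohort of deviation records
#'
#' One summary row per deviation metric (angular, global, lateral, depth).
#' Missing values are excluded listwise per metric, so an implant with an
#' undefined lateral deviation still contributes to the other three rows and
#' a fully missing implant contributes to none; each row's `n` reflects its
#' own exclusions.
#'
#' @param records A list of `deviation_record`s, or a data frame with
#'   columns `angular_deg`, `global_mm`, `lateral_mm`, `depth_mm` (such as
#'   the packaged cohort fixture or [deviations_table()] output).
#' @param divisor SD divisor, as in [describe()].
#' @return A four-row data frame of summaries, in the order angular, global,
#'   lateral, depth.
#' @export
summarise_cohort <- function(records, divisor = c("population", "sample")) {
  divisor <- match.arg(divisor)
  if (is.data.frame(records)) {
    tab <- records
  } else {
    tab <- deviations_table(records)
  }
  metrics <- c("angular_deg", "global_mm", "lateral_mm", "depth_mm")
  missing_cols <- setdiff(metrics, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("records lack column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  rows <- lapply(metrics, function(mname) {
    v <- tab[[mname]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      stop(sprintf("all records missing for metric %s", mname), call. = FALSE)
    }
    describe(v, divisor = divisor, metric = mname)
  })
  do.call(rbind, rows)
}
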