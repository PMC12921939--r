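#' Pair per-location measurements from two devices
#'
#' Joins projection-device and head-mounted measurements by subject, eye and
#' location, and adds the harmonized column
#' `hmp_db_equivalent = to_octopus_equivalent(hmp_db_raw, offset_db)`.
#'
#' @param octopus_fields,hmp_fields Measured-field tibbles (columns
#'   `subject_id`, `eye`, `x_deg`, `y_deg`, `sensitivity_db`) from
#'   [run_exam()] or [read_field_csv()].
#' @param offset_db Sensitivity-scale offset applied in harmonization.
#' @return A tibble of paired observations: `subject_id`, `eye`, `x_deg`,
#'   `y_deg`, `octopus_db`, `hmp_db_raw`, `hmp_db_equivalent`.
#' @export
pair_fields <- function(octopus_fields, hmp_fields, offset_db = 14) {
  need <- c("subject_id", "eye", "x_deg", "y_deg", "sensitivity_db")
  for (nm in c("octopus_fields", "hmp_fields")) {
    df <- get(nm)
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      stop(nm, " is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(octopus_fields) == 0 || nrow(hmp_fields) == 0) {
    stop("cannot pair empty field tables", call. = FALSE)
  }
  a <- dplyr::select(octopus_fields, dplyr::all_of(need))
  a <- dplyr::rename(a, octopus_db = "sensitivity_db")
  b <- dplyr::select(hmp_fields, dplyr::all_of(need))
  b <- dplyr::rename(b, hmp_db_raw = "sensitivity_db")
  pairs <- dplyr::inner_join(a, b,
                             by = c("subject_id", "eye", "x_deg", "y_deg"))
  if (nrow(pairs) == 0) {
    stop("no matching (subject, eye, location) pairs between the two tables",
         call. = FALSE)
  }
  if (nrow(pairs) < nrow(a) || nrow(pairs) < nrow(b)) {
    stop("unmatched records: ", nrow(a), " vs ", nrow(b),
         " rows but only ", nrow(pairs), " pairs", call. = FALSE)
  }
  dplyr::mutate(pairs,
                hmp_db_equivalent = to_octopus_equivalent(.data$hmp_db_raw,
                                                          offset_db))
}

#' Censor pairs outside the head-mounted device's measurable band
#'
#' Regression between the devices is only meaningful where neither floor nor
#' ceiling effects distort the head-mounted measurement. Keeps rows whose
#' projection sensitivity lies strictly between the band limits (defaults:
#' larger than 14 and smaller than 30 dB); order-preserving.
#'
#' @param pairs Paired-observation tibble from [pair_fields()].
#' @param lower,upper Strict censoring bounds in projection dB.
#' @return The retained subset of `pairs`.
#' @export
censor_for_regression <- function(pairs, lower = 14, upper = 30) {
  stopifnot("octopus_db" %in% names(pairs))
  dplyr::filter(pairs, .data$octopus_db > lower, .data$octopus_db < upper)
}

#' Deming errors-in-variables regression
#'
#' Fits a straight line when *both* variables carry measurement error, by
#' minimizing the lambda-weighted perpendicular squared distances. With
#' `lambda = 1` (equal error variances) this is orthogonal / total
#' least-squares regression. The closed-form slope is
#' \deqn{b = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}},}
#' with intercept \eqn{\bar y - b \bar x}. Confidence intervals use the
#' leave-one-out jackknife with a normal approximation.
#'
#' @param data A data frame, or `NULL` to pass bare numeric vectors.
#' @param x,y Column names (tidy-eval) when `data` is a data frame, or
#'   numeric vectors when `data` is `NULL`. Defaults `octopus_db`,
#'   `hmp_db_raw` match the [pair_fields()] schema.
#' @param lambda Ratio of error variances (y-error variance over x-error
#'   variance); 1 assumes equal errors.
#' @param conf_level Confidence level for the jackknife intervals.
#' @return An object of class `deming_fit` with [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' d <- data.frame(octopus_db = 1:10, hmp_db_raw = 2 * (1:10) + 1)
#' glance(deming_fit(d))$slope  # 2
#' @export
deming_fit <- function(data = NULL, x = octopus_db, y = hmp_db_raw,
                       lambda = 1, conf_level = 0.95) {
  if (is.null(data)) {
    xv <- x
    yv <- y
  } else {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  if (length(xv) != length(yv)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 3) stop("Deming regression needs at least 3 finite pairs",
                  call. = FALSE)
  if (stats::sd(xv) == 0) {
    stop("x values are all identical; the line is vertical", call. = FALSE)
  }
  est <- deming_point(xv, yv, lambda)
  jack <- vapply(seq_len(n), function(i) {
    deming_point(xv[-i], yv[-i], lambda)
  }, numeric(2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt((n - 1) / n * rowSums((jack - rowMeans(jack))^2))
  structure(
    list(slope = est[["slope"]], intercept = est[["intercept"]],
         slope_se = se[[1]], intercept_se = se[[2]],
         slope_ci = est[["slope"]] + c(-1, 1) * z * se[[1]],
         intercept_ci = est[["intercept"]] + c(-1, 1) * z * se[[2]],
         n = n, lambda = lambda, conf_level = conf_level,
         data = tibble::tibble(x = xv, y = yv)),
    class = "deming_fit"
  )
}

# closed-form Deming slope/intercept for one sample
deming_point <- function(xv, yv, lambda) {
  sxx <- stats::var(xv)
  syy <- stats::var(yv)
  sxy <- stats::cov(xv, yv)
  if (sxy == 0) {
    # degenerate geometry: no linear association to orient the line
    if (syy == lambda * sxx) {
      stop("degenerate geometry: Deming slope is undefined (zero covariance)",
           call. = FALSE)
    }
    slope <- if (syy < lambda * sxx) 0 else Inf
    if (!is.finite(slope)) {
      stop("degenerate geometry: vertical Deming line", call. = FALSE)
    }
  } else {
    slope <- (syy - lambda * sxx +
                sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) /
      (2 * sxy)
  }
  c(slope = slope, intercept = mean(yv) - slope * mean(xv))
}

#' @export
print.deming_fit <- function(x, ...) {
  cat("Deming regression (lambda =", x$lambda, ", n =", x$n, ")\n")
  cat(sprintf("  slope     %.3f  (%d%% CI %.3f to %.3f)\n", x$slope,
              round(100 * x$conf_level), x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.2f dB (%d%% CI %.2f to %.2f)\n", x$intercept,
              round(100 * x$conf_level), x$intercept_ci[1],
              x$intercept_ci[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.deming_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    conf.low = c(x$intercept_ci[1], x$slope_ci[1]),
    conf.high = c(x$intercept_ci[2], x$slope_ci[2])
  )
}

#' @exportS3Method generics::glance
glance.deming_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, n = x$n,
                 lambda = x$lambda)
}

#' Bland-Altman analysis of paired measurements
#'
#' Computes the differences `d = x - y`, their mean and SD (n - 1
#' denominator), and the 95% limits of agreement `mean +/- 1.96 * SD`.
#'
#' @inheritParams deming_fit
#' @return An object of class `bland_altman` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
bland_altman <- function(data = NULL, x = octopus_db, y = hmp_db_raw) {
  if (is.null(data)) {
    xv <- x
    yv <- y
  } else {
    xv <- rlang::eval_tidy(rlang::enquo(x), data)
    yv <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  if (length(xv) != length(yv)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 2) {
    stop("Bland-Altman needs at least 2 finite pairs", call. = FALSE)
  }
  d <- xv - yv
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         n = length(d),
         data = tibble::tibble(mean = (xv + yv) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: mean difference %.2f dB (SD %.2f), LoA [%.2f, %.2f], n = %d\n",
    x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("mean_difference", "loa_low", "loa_high"),
    estimate = c(x$mean_diff, x$loa_low, x$loa_high)
  )
}

#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' Floor-detection contingency counts
#'
#' Classifies every paired location by whether the projection device found
#' low sensitivity (below `octopus_cut`; the condition) and whether the
#' head-mounted device hit its floor (raw estimate exactly 0 dB; the test):
#' `tp` = floored and truly low, `fn` = not floored but truly low, `fp` =
#' floored but not low, `tn` = neither.
#'
#' @param pairs Paired-observation tibble from [pair_fields()].
#' @param octopus_cut Condition threshold in projection dB (default 14, the
#'   head-mounted floor on the projection-equivalent scale).
#' @return A one-row tibble of class `floor_contingency`: `tn`, `fn`, `fp`,
#'   `tp`, `n`.
#' @export
contingency_counts <- function(pairs, octopus_cut = 14) {
  stopifnot(all(c("octopus_db", "hmp_db_raw") %in% names(pairs)))
  low <- pairs$octopus_db < octopus_cut
  floored <- pairs$hmp_db_raw == 0
  out <- tibble::tibble(
    tn = sum(!floored & !low),
    fn = sum(!floored & low),
    fp = sum(floored & !low),
    tp = sum(floored & low),
    n = nrow(pairs)
  )
  class(out) <- c("floor_contingency", class(out))
  out
}

#' Diagnostic sensitivity and specificity from contingency counts
#'
#' `sensitivity = tp / (tp + fn)`; `specificity = tn / (tn + fp)`.
#'
#' @param counts A one-row data frame with columns `tn`, `fn`, `fp`, `tp`
#'   (e.g. from [contingency_counts()]).
#' @return A one-row tibble with columns `sensitivity` and `specificity`.
#'   A zero denominator is an error (the metric is undefined, not 0).
#' @examples
#' diagnostic_metrics(data.frame(tn = 1001, fn = 191, fp = 55, tp = 385))
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(all(c("tn", "fn", "fp", "tp") %in% names(counts)))
  counts <- counts[1, ]
  if (counts$tp + counts$fn == 0) {
    stop("diagnostic sensitivity undefined: no condition-positive locations",
         call. = FALSE)
  }
  if (counts$tn + counts$fp == 0) {
    stop("diagnostic specificity undefined: no condition-negative locations",
         call. = FALSE)
  }
  tibble::tibble(
    sensitivity = counts$tp / (counts$tp + counts$fn),
    specificity = counts$tn / (counts$tn + counts$fp)
  )
}

#' Full between-device agreement report
#'
#' Runs the complete comparison on matched field pairs: scale harmonization,
#' band censoring, Deming regression (on raw scales, uncorrected for offset),
#' Bland-Altman limits of agreement (on pairs with projection sensitivity
#' above the floor cut), and the floor-detection contingency with diagnostic
#' metrics (on all pairs).
#'
#' @inheritParams pair_fields
#' @param regression_band Strict censoring bounds (projection dB) for the
#'   regression subset.
#' @param octopus_cut Floor cut for Bland-Altman inclusion and the
#'   contingency condition.
#' @param ba_floor_rule `"floor_as_zero"` keeps head-mounted floor values as
#'   raw 0 dB in the Bland-Altman differences; `"drop_floored"` excludes
#'   floored pairs instead.
#' @param lambda Deming error-variance ratio.
#' @return An object of class `agreement_report`: list with elements
#'   `pairs`, `deming`, `bland_altman`, `contingency`, `metrics`, `options`.
#'   Has `tidy()`, `glance()` and `summary()` methods; serialize with
#'   [report_to_json()].
#' @export
compare_fields <- function(octopus_fields, hmp_fields,
                           offset_db = 14,
                           regression_band = c(14, 30),
                           octopus_cut = 14,
                           ba_floor_rule = c("floor_as_zero", "drop_floored"),
                           lambda = 1) {
  ba_floor_rule <- match.arg(ba_floor_rule)
  pairs <- pair_fields(octopus_fields, hmp_fields, offset_db = offset_db)
  reg <- censor_for_regression(pairs, regression_band[1], regression_band[2])
  dem <- deming_fit(reg, lambda = lambda)
  ba_pairs <- dplyr::filter(pairs, .data$octopus_db > octopus_cut)
  if (ba_floor_rule == "drop_floored") {
    ba_pairs <- dplyr::filter(ba_pairs, .data$hmp_db_raw > 0)
  }
  ba <- bland_altman(ba_pairs)
  counts <- contingency_counts(pairs, octopus_cut = octopus_cut)
  metrics <- diagnostic_metrics(counts)
  structure(
    list(pairs = pairs, deming = dem, bland_altman = ba,
         contingency = counts, metrics = metrics,
         options = list(offset_db = offset_db,
                        regression_band = regression_band,
                        octopus_cut = octopus_cut,
                        ba_floor_rule = ba_floor_rule,
                        lambda = lambda,
                        n_pairs = nrow(pairs),
                        n_regression = nrow(reg),
                        n_bland_altman = ba$n)),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Between-device agreement report\n")
  cat(sprintf("  %d paired locations (%d in regression band, %d in Bland-Altman)\n",
              x$options$n_pairs, x$options$n_regression,
              x$options$n_bland_altman))
  print(x$deming)
  print(x$bland_altman)
  cat(sprintf(
    "  floor detection: tp=%d fn=%d fp=%d tn=%d -> sensitivity %.2f, specificity %.2f\n",
    x$contingency$tp, x$contingency$fn, x$contingency$fp, x$contingency$tn,
    x$metrics$sensitivity, x$metrics$specificity))
  invisible(x)
}

#' @export
summary.agreement_report <- function(object, ...) print(object)

#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$deming), component = "deming"),
    dplyr::mutate(tidy(x$bland_altman), component = "bland_altman"),
    tibble::tibble(
      component = "diagnostics",
      term = c("sensitivity", "specificity"),
      estimate = c(x$metrics$sensitivity, x$metrics$specificity)
    )
  )
}

#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    deming_slope = x$deming$slope,
    deming_intercept = x$deming$intercept,
    ba_mean_diff = x$bland_altman$mean_diff,
    ba_loa_low = x$bland_altman$loa_low,
    ba_loa_high = x$bland_altman$loa_high,
    sensitivity = x$metrics$sensitivity,
    specificity = x$metrics$specificity,
    n_pairs = x$options$n_pairs
  )
}

#' Serialize an agreement report to JSON
#'
#' Writes all statistics, counts and options (not the raw pairs) so a report
#' is auditable and machine-readable.
#'
#' @param report An `agreement_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  payload <- list(
    deming = list(
      slope = report$deming$slope,
      intercept = report$deming$intercept,
      slope_ci = report$deming$slope_ci,
      intercept_ci = report$deming$intercept_ci,
      lambda = report$deming$lambda,
      n = report$deming$n
    ),
    bland_altman = list(
      mean_diff = report$bland_altman$mean_diff,
      sd_diff = report$bland_altman$sd_diff,
      loa = c(report$bland_altman$loa_low, report$bland_altman$loa_high),
      n = report$bland_altman$n
    ),
    contingency = as.list(report$contingency[1, ]),
    metrics = as.list(report$metrics[1, ]),
    options = report$options
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
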