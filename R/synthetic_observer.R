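#' Default loss-pattern parameters per diagnosis
#'
#' Ground-truth fields start from a "hill of vision"
#' `H(e) = peak - decay * e` (dB at eccentricity `e` degrees) and subtract a
#' diagnosis-specific loss pattern:
#'
#' * `normal` — no loss.
#' * `OMD` (occult macular dystrophy) — a Gaussian central depression
#'   `depth * exp(-e^2 / (2 * radius^2))`.
#' * `STGD` (Stargardt disease) — an annular "bull's-eye" depression
#'   `depth * exp(-(e - ring_radius)^2 / (2 * width^2))`, optionally with an
#'   absolute central scotoma inside `scotoma_radius`.
#' * `RP` (retinitis pigmentosa) — concentric loss: sensitivity preserved
#'   inside `preserved_radius`, falling sigmoidally
#'   (`depth / (1 + exp(-(e - preserved_radius) / width))`) to absolute loss
#'   outside.
#'
#' Finite truths are clipped to `[-10, 45]` dB on the projection-equivalent
#' scale; values driven below -10 dB become `-Inf` (absolute scotoma).
#'
#' @param diagnosis One of `"normal"`, `"OMD"`, `"STGD"`, `"RP"`.
#' @return A named list of pattern parameters (all dB or degrees).
#' @export
field_pattern_params <- function(diagnosis) {
  diagnosis <- match.arg(diagnosis, c("normal", "OMD", "STGD", "RP"))
  base <- list(peak = 33, decay = 0.5)
  extra <- switch(diagnosis,
    normal = list(),
    OMD = list(depth = 20, radius = 4),
    STGD = list(depth = 25, ring_radius = 4, width = 1.5, scotoma_radius = 0),
    RP = list(depth = 60, preserved_radius = 4, width = 1)
  )
  c(base, extra)
}

#' Synthesize a ground-truth sensitivity field
#'
#' Evaluates the hill of vision minus the diagnosis pattern (see
#' [field_pattern_params()]) at every grid location, then adds independent
#' per-location Gaussian jitter. Truths are expressed on the
#' projection-equivalent decibel scale so one ground truth can drive exams on
#' any device; `-Inf` encodes an absolute scotoma. Uses the R session RNG:
#' call `set.seed()` for reproducibility.
#'
#' @param diagnosis `"normal"`, `"OMD"`, `"STGD"` or `"RP"`.
#' @param params Pattern parameters; defaults from [field_pattern_params()].
#'   Partial lists are completed with the defaults.
#' @param grid Test grid tibble from [generate_10_2()].
#' @param jitter_sd Per-location Gaussian jitter SD in dB (0 disables).
#' @param subject_id,eye Identifiers stored in the output.
#' @return A tibble: `subject_id`, `eye`, `diagnosis`, `x_deg`, `y_deg`,
#'   `true_db` (finite in `[-10, 45]`, or `-Inf`).
#' @examples
#' set.seed(1)
#' f <- make_true_field("OMD")
#' range(f$true_db[is.finite(f$true_db)])
#' @export
make_true_field <- function(diagnosis,
                            params = list(),
                            grid = generate_10_2(),
                            jitter_sd = 1,
                            subject_id = "S1",
                            eye = "OD") {
  diagnosis <- match.arg(diagnosis, c("normal", "OMD", "STGD", "RP"))
  eye <- match.arg(eye, c("OD", "OS"))
  p <- utils::modifyList(field_pattern_params(diagnosis), params)
  stopifnot(all(c("x_deg", "y_deg") %in% names(grid)))
  e <- sqrt(grid$x_deg^2 + grid$y_deg^2)
  hill <- p$peak - p$decay * e
  loss <- switch(diagnosis,
    normal = 0,
    OMD = p$depth * exp(-e^2 / (2 * p$radius^2)),
    STGD = p$depth * exp(-(e - p$ring_radius)^2 / (2 * p$width^2)),
    RP = p$depth / (1 + exp(-(e - p$preserved_radius) / p$width))
  )
  s <- hill - loss
  if (jitter_sd > 0) s <- s + stats::rnorm(length(s), 0, jitter_sd)
  if (diagnosis == "STGD" && p$scotoma_radius > 0) {
    s[e <= p$scotoma_radius] <- -Inf
  }
  s[s < -10] <- -Inf
  s[is.finite(s) & s > 45] <- 45
  tibble::tibble(
    subject_id = subject_id, eye = eye, diagnosis = diagnosis,
    x_deg = grid$x_deg, y_deg = grid$y_deg, true_db = s
  )
}

#' Create a frequency-of-seeing observer
#'
#' Wraps a ground-truth field with a psychometric response model: the
#' probability of pressing the button for a stimulus at `s` dB when the true
#' threshold is `t` dB is
#' `fp + (1 - fp - fn) * pnorm((t - s) / slope_sd)`
#' (higher dB = dimmer stimulus, so stimuli brighter than threshold are
#' usually seen). An absolute scotoma (`t = -Inf`) responds only through the
#' false-positive rate.
#'
#' @param true_field Tibble from [make_true_field()].
#' @param slope_sd Spread of the frequency-of-seeing curve in dB (> 0).
#' @param fp_rate,fn_rate False-positive / false-negative response rates;
#'   both in `[0, 1)` with `fp_rate + fn_rate < 1`.
#' @return An object of class `perisim_observer`.
#' @export
psychometric_observer <- function(true_field,
                                  slope_sd = 1.5,
                                  fp_rate = 0.03,
                                  fn_rate = 0.03) {
  stopifnot(all(c("x_deg", "y_deg", "true_db") %in% names(true_field)))
  if (!(slope_sd > 0)) stop("`slope_sd` must be > 0", call. = FALSE)
  if (fp_rate < 0 || fn_rate < 0 || fp_rate + fn_rate >= 1) {
    stop("need 0 <= fp_rate, fn_rate and fp_rate + fn_rate < 1",
         call. = FALSE)
  }
  structure(
    list(true_field = true_field, slope_sd = slope_sd,
         fp_rate = fp_rate, fn_rate = fn_rate),
    class = "perisim_observer"
  )
}

#' @export
print.perisim_observer <- function(x, ...) {
  tf <- x$true_field
  cat(sprintf(
    "<perisim_observer> %s %s (%s), %d locations, sigma=%g dB, fp=%g, fn=%g\n",
    tf$subject_id[1], tf$eye[1], tf$diagnosis[1], nrow(tf),
    x$slope_sd, x$fp_rate, x$fn_rate))
  invisible(x)
}

#' Probability that an observer reports a stimulus as seen
#'
#' @param observer A `perisim_observer`.
#' @param true_db True threshold(s) in dB (`-Inf` for absolute scotoma), on
#'   the same scale as `stimulus_db`.
#' @param stimulus_db Stimulus level(s) in dB.
#' @return Probability of a "seen" response (vectorized).
#' @export
seen_probability <- function(observer, true_db, stimulus_db) {
  stopifnot(inherits(observer, "perisim_observer"))
  fp <- observer$fp_rate
  fn <- observer$fn_rate
  p <- fp + (1 - fp - fn) * stats::pnorm((true_db - stimulus_db) /
                                           observer$slope_sd)
  p[is.infinite(true_db) & true_db < 0] <- fp
  p
}

#' Draw a seen/not-seen response at one grid location
#'
#' @param observer A `perisim_observer`.
#' @param x,y Grid location in degrees (must exist in the observer's field).
#' @param stimulus_db Stimulus level in dB on the observer's truth scale.
#' @return Logical: `TRUE` if the stimulus was reported seen. Uses the
#'   session RNG.
#' @export
respond <- function(observer, x, y, stimulus_db) {
  stopifnot(inherits(observer, "perisim_observer"))
  tf <- observer$true_field
  i <- which(tf$x_deg == x & tf$y_deg == y)
  if (length(i) != 1) {
    stop("location (", x, ", ", y, ") not in the observer's grid",
         call. = FALSE)
  }
  stats::runif(1) < seen_probability(observer, tf$true_db[i], stimulus_db)
}

#' Configure a simulated study cohort
#'
#' Defaults mirror a small inherited-retinal-disease pilot cohort: 1 normal
#' subject, 2 with occult macular dystrophy, 3 with Stargardt disease and 6
#' with retinitis pigmentosa, both eyes tested per subject. Subjects share a
#' per-subject hill-of-vision shift (inter-subject variability); eyes of one
#' subject share pattern parameters and differ only by independent
#' per-location jitter.
#'
#' @param n_normal,n_omd,n_stgd,n_rp Subject counts per diagnosis (>= 0).
#' @param subject_sd SD in dB of the per-subject hill-height shift.
#' @param jitter_sd Per-location truth jitter SD in dB.
#' @param slope_sd,fp_rate,fn_rate Observer response-model parameters, see
#'   [psychometric_observer()].
#' @param pattern_params Optional named list of per-diagnosis parameter
#'   overrides, e.g. `list(OMD = list(depth = 25))`.
#' @return An object of class `perisim_cohort_config`.
#' @export
cohort_config <- function(n_normal = 1, n_omd = 2, n_stgd = 3, n_rp = 6,
                          subject_sd = 2, jitter_sd = 1,
                          slope_sd = 1.5, fp_rate = 0.03, fn_rate = 0.03,
                          pattern_params = list()) {
  counts <- c(normal = n_normal, OMD = n_omd, STGD = n_stgd, RP = n_rp)
  if (any(counts < 0)) stop("subject counts must be >= 0", call. = FALSE)
  structure(
    list(counts = counts, subject_sd = subject_sd, jitter_sd = jitter_sd,
         slope_sd = slope_sd, fp_rate = fp_rate, fn_rate = fn_rate,
         pattern_params = pattern_params),
    class = "perisim_cohort_config"
  )
}

#' Generate a cohort of paired-eye observers
#'
#' Creates `2 * sum(counts)` observers (both eyes per subject). Fully
#' reproducible: the same `seed` yields an identical cohort.
#'
#' @param config A [cohort_config()].
#' @param grid Test grid tibble.
#' @param seed Integer seed for the cohort RNG (optional; if `NULL`, uses the
#'   session RNG state).
#' @return A list of `perisim_observer` objects, class `perisim_cohort`.
#' @seealso [cohort_truths()] to extract all ground truths as one tibble.
#' @export
generate_cohort <- function(config = cohort_config(),
                            grid = generate_10_2(),
                            seed = NULL) {
  stopifnot(inherits(config, "perisim_cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  observers <- list()
  for (dx in names(config$counts)) {
    n <- config$counts[[dx]]
    if (n == 0) next
    for (i in seq_len(n)) {
      sid <- sprintf("%s%02d", toupper(dx), i)
      shift <- stats::rnorm(1, 0, config$subject_sd)
      params <- utils::modifyList(
        list(peak = field_pattern_params(dx)$peak + shift),
        config$pattern_params[[dx]] %||% list()
      )
      for (eye in c("OD", "OS")) {
        tf <- make_true_field(dx, params = params, grid = grid,
                              jitter_sd = config$jitter_sd,
                              subject_id = sid, eye = eye)
        observers[[length(observers) + 1]] <-
          psychometric_observer(tf, slope_sd = config$slope_sd,
                                fp_rate = config$fp_rate,
                                fn_rate = config$fn_rate)
      }
    }
  }
  structure(observers, class = "perisim_cohort")
}

#' Collect all ground truths of a cohort into one tibble
#'
#' @param cohort A `perisim_cohort` from [generate_cohort()].
#' @return A tibble with one row per subject, eye and location.
#' @export
cohort_truths <- function(cohort) {
  stopifnot(inherits(cohort, "perisim_cohort"))
  purrr::map_dfr(cohort, "true_field")
}

#' @export
print.perisim_cohort <- function(x, ...) {
  truths <- cohort_truths(x)
  tab <- table(dplyr::distinct(truths, .data$subject_id,
                               .data$diagnosis)$diagnosis)
  cat(sprintf("<perisim_cohort> %d observers (%d subjects x 2 eyes)\n",
              length(x), length(x) / 2))
  cat("  subjects:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
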