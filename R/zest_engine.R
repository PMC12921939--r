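#' ZEST procedure control parameters
#'
#' The exam engine is a ZEST (Zippy Estimation by Sequential Testing)
#' Bayesian staircase: it maintains a probability mass function over
#' candidate thresholds on the device's decibel scale, presents each stimulus
#' at the posterior mean, and multiplies the pmf by the likelihood of the
#' observed response under a cumulative-Gaussian listener model. The listener
#' model is the engine's *assumption* and may deliberately differ from the
#' simulated observer's true parameters (model misspecification experiments).
#'
#' @param domain_step Spacing of the threshold domain in dB.
#' @param guard_db Guard band in dB extending the domain below 0 and above
#'   the device's dynamic range, so floor/ceiling posteriors can express
#'   themselves.
#' @param stop_sd Stop when the posterior SD falls below this many dB.
#' @param max_presentations Hard cap on presentations per location.
#' @param sigma_model,fp_model,fn_model Likelihood (listener-model)
#'   parameters: psychometric spread, false-positive and false-negative
#'   rates.
#' @return A list of class `perisim_zest_control`.
#' @export
zest_control <- function(domain_step = 0.5, guard_db = 5,
                         stop_sd = 1.5, max_presentations = 12,
                         sigma_model = 1.5, fp_model = 0.03,
                         fn_model = 0.03) {
  stopifnot(domain_step > 0, guard_db >= 0, stop_sd > 0,
            max_presentations >= 1, sigma_model > 0)
  structure(
    list(domain_step = domain_step, guard_db = guard_db, stop_sd = stop_sd,
         max_presentations = max_presentations, sigma_model = sigma_model,
         fp_model = fp_model, fn_model = fn_model),
    class = "perisim_zest_control"
  )
}

#' Initialize a ZEST state for one location
#'
#' The threshold domain spans `[-guard_db, dynamic_range + guard_db]` in
#' `domain_step` increments; the prior defaults to uniform. A supplied prior
#' (any non-negative weights over the domain) is normalized.
#'
#' @param device A `perisim_device`.
#' @param prior Optional numeric vector of prior weights, one per domain
#'   level.
#' @param control A [zest_control()].
#' @return A list of class `perisim_zest_state` with elements `domain`,
#'   `pdf`, `n_presentations`, `finished`.
#' @export
zest_init <- function(device, prior = NULL, control = zest_control()) {
  stopifnot(inherits(device, "perisim_device"))
  dr <- dynamic_range(device)
  domain <- seq(-control$guard_db, dr + control$guard_db,
                by = control$domain_step)
  if (is.null(prior)) {
    pdf <- rep(1 / length(domain), length(domain))
  } else {
    if (length(prior) != length(domain)) {
      stop("`prior` must have one weight per domain level (",
           length(domain), ")", call. = FALSE)
    }
    if (any(prior < 0) || sum(prior) <= 0) {
      stop("`prior` weights must be non-negative with positive sum",
           call. = FALSE)
    }
    pdf <- prior / sum(prior)
  }
  structure(
    list(domain = domain, pdf = pdf, n_presentations = 0L,
         finished = FALSE, dynamic_range = dr, control = control),
    class = "perisim_zest_state"
  )
}

zest_pdf_mean <- function(state) sum(state$domain * state$pdf)

zest_pdf_sd <- function(state) {
  m <- zest_pdf_mean(state)
  sqrt(sum((state$domain - m)^2 * state$pdf))
}

#' Advance a ZEST state by one presentation
#'
#' The stimulus level is the posterior mean clamped to
#' `[0, dynamic_range]`, converted to a luminance increment and snapped to
#' the device's achievable ladder ([quantize_increment()]); the actually
#' presentable level (after quantization) is what the observer is asked
#' about. The posterior is updated by the listener-model likelihood of the
#' response and renormalized. The state finishes when the posterior SD drops
#' below `stop_sd` or the presentation cap is reached.
#'
#' @param state A `perisim_zest_state` (not finished).
#' @param device The `perisim_device` being simulated.
#' @param respond_fn Callback `function(stimulus_db) -> logical` giving the
#'   observer's seen/not-seen response at a device-scale level.
#' @return The updated state.
#' @export
zest_step <- function(state, device, respond_fn) {
  stopifnot(inherits(state, "perisim_zest_state"))
  if (state$finished) {
    stop("zest_step() called on a finished state", call. = FALSE)
  }
  ctl <- state$control
  target <- min(max(zest_pdf_mean(state), 0), state$dynamic_range)
  delta_L <- quantize_increment(device,
                                increment_from_sensitivity(device, target))
  stim <- sensitivity_from_increment(device, delta_L)
  seen <- isTRUE(respond_fn(stim))
  p_seen <- ctl$fp_model +
    (1 - ctl$fp_model - ctl$fn_model) *
      stats::pnorm((state$domain - stim) / ctl$sigma_model)
  lik <- if (seen) p_seen else 1 - p_seen
  pdf <- state$pdf * lik
  state$pdf <- pdf / sum(pdf)
  state$n_presentations <- state$n_presentations + 1L
  if (zest_pdf_sd(state) < ctl$stop_sd ||
        state$n_presentations >= ctl$max_presentations) {
    state$finished <- TRUE
  }
  state
}

#' Final threshold estimate from a finished ZEST state
#'
#' The posterior mean, clamped to `[0, dynamic_range]`. An estimate of
#' exactly 0 dB signals the device floor: the brightest stimulus was not
#' reliably seen.
#'
#' @param state A finished `perisim_zest_state`.
#' @return Sensitivity estimate in dB on the device scale.
#' @export
zest_estimate <- function(state) {
  stopifnot(inherits(state, "perisim_zest_state"))
  if (!state$finished) {
    stop("zest_estimate() called before the procedure finished",
         call. = FALSE)
  }
  min(max(zest_pdf_mean(state), 0), state$dynamic_range)
}

#' Run a full simulated exam of one observer on one device
#'
#' Runs an independent ZEST procedure at every grid location, interleaved in
#' randomized order (each presentation goes to a uniformly chosen unfinished
#' location), as a perimeter would. Ground truths are stored on the
#' projection-equivalent scale; the exam converts them to the device's own
#' scale by subtracting the rounded scale offset before responding, so one
#' truth drives any device.
#'
#' @param device A `perisim_device`.
#' @param observer A `perisim_observer`.
#' @param control A [zest_control()].
#' @param offset_db Scale offset subtracted from projection-equivalent truths
#'   to obtain device-scale thresholds. Default: the rounded offset between a
#'   318 cd/m^2 reference maximum increment and this device's maximum (0 for
#'   the projection preset, 14 for the head-mounted preset).
#' @param threshold_shift_db Optional extra dB added to device-scale
#'   thresholds — a hook for device-specific physiological effects such as
#'   adaptation differences under different backgrounds (default 0).
#' @return A tibble (`subject_id`, `eye`, `device`, `x_deg`, `y_deg`,
#'   `sensitivity_db`, `n_presentations`); estimates on the device scale,
#'   within `[0, dynamic_range(device)]`. Uses the session RNG: call
#'   `set.seed()` for reproducibility.
#' @examples
#' set.seed(7)
#' obs <- psychometric_observer(make_true_field("normal", jitter_sd = 0))
#' exam <- run_exam(iowa_hmp(), obs)
#' range(exam$sensitivity_db)
#' @export
run_exam <- function(device, observer, control = zest_control(),
                     offset_db = NULL, threshold_shift_db = 0) {
  stopifnot(inherits(device, "perisim_device"),
            inherits(observer, "perisim_observer"))
  tf <- observer$true_field
  if (is.null(offset_db)) {
    offset_db <- round(10 * log10(318 / device$delta_L_max))
  }
  t_dev <- tf$true_db - offset_db + threshold_shift_db
  n_loc <- nrow(tf)
  states <- lapply(seq_len(n_loc), function(i) zest_init(device,
                                                         control = control))
  active <- seq_len(n_loc)
  while (length(active) > 0) {
    i <- if (length(active) == 1) active else sample(active, 1)
    states[[i]] <- zest_step(
      states[[i]], device,
      function(stim_db) {
        stats::runif(1) < seen_probability(observer, t_dev[i], stim_db)
      }
    )
    if (states[[i]]$finished) active <- setdiff(active, i)
  }
  tibble::tibble(
    subject_id = tf$subject_id,
    eye = tf$eye,
    device = device$name,
    x_deg = tf$x_deg,
    y_deg = tf$y_deg,
    sensitivity_db = vapply(states, zest_estimate, numeric(1)),
    n_presentations = vapply(states, function(s) s$n_presentations,
                             integer(1))
  )
}

#' Simulate a whole study: cohort truths plus paired exams on two devices
#'
#' Generates a cohort ([generate_cohort()]), then examines every observer on
#' every device. The master seed fully determines all stochastic output.
#'
#' @param config A [cohort_config()].
#' @param devices Named-or-not list of `perisim_device` objects (default: the
#'   projection and head-mounted presets).
#' @param control A [zest_control()].
#' @param seed Master integer seed.
#' @param out_dir Optional directory: if given, writes `truths.csv`,
#'   `measured_<device>.csv` per device, and `config.yaml` (the resolved
#'   configuration including the seed).
#' @return A list with elements `truths` (tibble), `measured` (one tibble,
#'   all devices), `cohort`, and `seed`.
#' @export
simulate_study <- function(config = cohort_config(),
                           devices = list(octopus900(), iowa_hmp()),
                           control = zest_control(),
                           seed = 1,
                           out_dir = NULL) {
  set.seed(seed)
  cohort <- generate_cohort(config)
  truths <- cohort_truths(cohort)
  measured <- purrr::map_dfr(devices, function(dev) {
    purrr::map_dfr(cohort, function(obs) run_exam(dev, obs,
                                                  control = control))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_field_csv(truths, file.path(out_dir, "truths.csv"))
    for (dev in devices) {
      write_field_csv(dplyr::filter(measured, .data$device == dev$name),
                      file.path(out_dir,
                                paste0("measured_", dev$name, ".csv")))
    }
    resolved <- list(
      seed = seed,
      cohort = unclass(config),
      zest = unclass(control),
      devices = lapply(devices, unclass)
    )
    yaml::write_yaml(resolved, file.path(out_dir, "config.yaml"))
  }
  list(truths = truths, measured = measured, cohort = cohort, seed = seed)
}
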