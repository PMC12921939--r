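#' Define a perimetric device model
#'
#' A device model captures the stimulus capabilities of one perimeter: its
#' background luminance, the brightest and dimmest luminance increments it can
#' present, the number of discrete display levels (RGB displays offer 255
#' equally spaced increments; projection perimeters are effectively
#' continuous), and any neutral-density filter in the optical path.
#'
#' The perimetric decibel scale is anchored at each device's own maximum
#' increment: 0 dB is the brightest stimulus *that device* can show, so two
#' devices with different `delta_L_max` place 0 dB at different physical
#' luminances. [offset_between()] quantifies that difference and
#' [to_octopus_equivalent()] harmonizes scales.
#'
#' @param name Text label for the device.
#' @param background_luminance Background luminance in cd/m^2 (must be > 0).
#' @param delta_L_max Brightest presentable luminance increment, cd/m^2.
#' @param delta_L_min Dimmest reliably presentable increment, cd/m^2. Together
#'   with `delta_L_max` this sets the dynamic range.
#' @param n_levels Number of equally spaced achievable increments between
#'   `delta_L_min` and `delta_L_max`. Use `Inf` for a continuous (projection)
#'   device; displays typically have 255.
#' @param nd_filter_od Optical density of a neutral-density filter between
#'   screen and eye (0 = none). A filter of density d attenuates luminance by
#'   a factor `10^d`.
#' @param stimulus_size_deg Stimulus diameter in degrees of visual angle
#'   (0.43 for a Goldmann III target).
#' @param stimulus_duration_ms Stimulus duration in milliseconds.
#' @param display_min_increment Optional metadata: the display's smallest
#'   renderable luminance step in cd/m^2 (may differ from the effective
#'   `delta_L_min` used for the dynamic range).
#'
#' @return An object of class `perisim_device`.
#' @examples
#' device_model("toy", background_luminance = 10,
#'              delta_L_max = 100, delta_L_min = 10)
#' @seealso [octopus900()], [iowa_hmp()], [dynamic_range()]
#' @export
device_model <- function(name,
                         background_luminance,
                         delta_L_max,
                         delta_L_min,
                         n_levels = Inf,
                         nd_filter_od = 0,
                         stimulus_size_deg = 0.43,
                         stimulus_duration_ms = 100,
                         display_min_increment = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  if (!(background_luminance > 0)) {
    stop("`background_luminance` must be > 0", call. = FALSE)
  }
  if (!(delta_L_min > 0 && delta_L_min < delta_L_max)) {
    stop("need 0 < delta_L_min < delta_L_max", call. = FALSE)
  }
  if (!(is.infinite(n_levels) || n_levels >= 2)) {
    stop("`n_levels` must be >= 2 (or Inf for a continuous device)",
         call. = FALSE)
  }
  if (nd_filter_od < 0) stop("`nd_filter_od` must be >= 0", call. = FALSE)
  structure(
    list(
      name = name,
      background_luminance = background_luminance,
      delta_L_max = delta_L_max,
      delta_L_min = delta_L_min,
      n_levels = n_levels,
      nd_filter_od = nd_filter_od,
      stimulus_size_deg = stimulus_size_deg,
      stimulus_duration_ms = stimulus_duration_ms,
      display_min_increment = display_min_increment
    ),
    class = "perisim_device"
  )
}

#' @export
print.perisim_device <- function(x, ...) {
  cat("<perisim_device> ", x$name, "\n", sep = "")
  cat(sprintf("  background        %g cd/m^2\n", x$background_luminance))
  cat(sprintf("  increment range   %g - %g cd/m^2 (%s levels)\n",
              x$delta_L_min, x$delta_L_max,
              if (is.infinite(x$n_levels)) "continuous" else x$n_levels))
  cat(sprintf("  dynamic range     %.1f dB\n", dynamic_range(x)))
  if (x$nd_filter_od > 0) {
    cat(sprintf("  ND filter         %.1f OD\n", x$nd_filter_od))
  }
  cat(sprintf("  stimulus          Goldmann-size %.2f deg, %g ms\n",
              x$stimulus_size_deg, x$stimulus_duration_ms))
  invisible(x)
}

#' Built-in device presets
#'
#' `octopus900()` models a projection perimeter with a legacy low-photopic
#' background (1.27 cd/m^2) and a 318 cd/m^2 maximum increment; its minimum
#' increment defaults to 0.1594 cd/m^2 so the device spans a 33 dB dynamic
#' range. Projection optics make the increment effectively continuous.
#'
#' `iowa_hmp()` models a smartphone-based head-mounted perimeter viewed
#' through a 0.6 OD neutral-density filter: background 10 cd/m^2, maximum
#' increment 12.76 cd/m^2, 255 discrete display levels, and an effective
#' minimum increment of 0.3206 cd/m^2 giving a 16 dB dynamic range. The
#' display's smallest renderable step (0.13 cd/m^2) is retained as metadata;
#' the effective floor of reliable presentation is wider than one raw step.
#'
#' @return A `perisim_device`.
#' @examples
#' dynamic_range(octopus900())  # 33 dB
#' dynamic_range(iowa_hmp())    # 16 dB
#' @export
octopus900 <- function() {
  device_model(
    name = "octopus900",
    background_luminance = 1.27,
    delta_L_max = 318,
    delta_L_min = 0.1594,
    n_levels = Inf,
    nd_filter_od = 0
  )
}

#' @rdname octopus900
#' @export
iowa_hmp <- function() {
  device_model(
    name = "iowa_hmp",
    background_luminance = 10,
    delta_L_max = 12.76,
    delta_L_min = 0.3206,
    n_levels = 255,
    nd_filter_od = 0.6,
    display_min_increment = 0.13
  )
}

#' Convert a luminance increment to perimetric sensitivity
#'
#' Perimetric sensitivity is `10 * log10(delta_L_max / delta_L)` dB: the
#' attenuation, relative to the device's brightest stimulus, of the increment
#' that is just detected. 0 dB is the brightest presentable stimulus; higher
#' values mean dimmer (harder) stimuli.
#'
#' @param device A `perisim_device`.
#' @param delta_L Luminance increment(s) in cd/m^2; must be > 0.
#' @return Sensitivity in dB (vectorized over `delta_L`).
#' @examples
#' sensitivity_from_increment(octopus900(), 31.8)  # 10 dB
#' @export
sensitivity_from_increment <- function(device, delta_L) {
  stopifnot(inherits(device, "perisim_device"))
  if (any(!(delta_L > 0))) {
    stop("`delta_L` must be > 0", call. = FALSE)
  }
  10 * log10(device$delta_L_max / delta_L)
}

#' Convert perimetric sensitivity back to a luminance increment
#'
#' Inverse of [sensitivity_from_increment()]: `delta_L_max * 10^(-s/10)`.
#'
#' @param device A `perisim_device`.
#' @param s Sensitivity in dB (any real value; vectorized).
#' @return Luminance increment(s) in cd/m^2.
#' @export
increment_from_sensitivity <- function(device, s) {
  stopifnot(inherits(device, "perisim_device"))
  device$delta_L_max * 10^(-s / 10)
}

#' Sensitivity-scale offset between two devices
#'
#' Because each device anchors 0 dB at its own maximum increment, identical
#' physical stimuli map to decibel values differing by
#' `10 * log10(delta_L_max_a / delta_L_max_b)`. For the shipped presets the
#' offset from the projection perimeter to the head-mounted perimeter is
#' 13.97 dB, conventionally rounded to 14 dB.
#'
#' @param device_a,device_b `perisim_device` objects.
#' @return Offset in dB; antisymmetric under argument swap.
#' @examples
#' round(offset_between(octopus900(), iowa_hmp()))  # 14
#' @export
offset_between <- function(device_a, device_b) {
  stopifnot(inherits(device_a, "perisim_device"),
            inherits(device_b, "perisim_device"))
  10 * log10(device_a$delta_L_max / device_b$delta_L_max)
}

#' Harmonize head-mounted sensitivities onto the projection scale
#'
#' Adds the (rounded) scale offset to every measured value except exact 0 dB:
#' a 0 dB measurement means the brightest stimulus was *not* reliably seen
#' (floor), carries no threshold information, and therefore stays 0.
#'
#' @param s_hmp Sensitivities in dB on the head-mounted device's own scale;
#'   must be >= 0. Vectorized.
#' @param offset Scale offset in dB (rounded to the nearest integer before
#'   applying; default 14).
#' @return Sensitivities on the projection-equivalent scale.
#' @examples
#' to_octopus_equivalent(c(0, 5, 16))  # 0, 19, 30
#' @export
to_octopus_equivalent <- function(s_hmp, offset = 14) {
  if (any(s_hmp < 0)) {
    stop("`s_hmp` must be >= 0 (0 dB encodes the device floor)", call. = FALSE)
  }
  ifelse(s_hmp > 0, s_hmp + round(offset), 0)
}

#' Dynamic range of a device
#'
#' The span of measurable sensitivities,
#' `10 * log10(delta_L_max / delta_L_min)` dB. Sensitivities below 0 dB
#' (stimuli brighter than the device can show) hit the floor; sensitivities
#' above the dynamic range (stimuli dimmer than the device can show) hit the
#' ceiling.
#'
#' @param device A `perisim_device`.
#' @return Dynamic range in dB.
#' @export
dynamic_range <- function(device) {
  stopifnot(inherits(device, "perisim_device"))
  10 * log10(device$delta_L_max / device$delta_L_min)
}

#' Screen luminance needed behind a neutral-density filter
#'
#' A filter of optical density `nd_od` attenuates by `10^nd_od`, so reaching
#' a target luminance at the eye requires the screen to emit
#' `target * 10^nd_od`.
#'
#' @param target Desired luminance at the eye, cd/m^2 (> 0).
#' @param nd_od Filter optical density (>= 0).
#' @return Required screen luminance in cd/m^2.
#' @examples
#' screen_setting_for_background(10, 0.6)  # 39.8
#' @export
screen_setting_for_background <- function(target, nd_od) {
  if (any(!(target > 0))) stop("`target` must be > 0", call. = FALSE)
  if (any(nd_od < 0)) stop("`nd_od` must be >= 0", call. = FALSE)
  target * 10^nd_od
}

#' Snap a luminance increment to the device's achievable ladder
#'
#' Display devices can only render `n_levels` equally spaced increments
#' between `delta_L_min` and `delta_L_max`. Requested increments snap to the
#' nearest achievable level; values outside the range clamp to the nearest
#' endpoint. Continuous devices (`n_levels = Inf`) only clamp.
#'
#' @param device A `perisim_device`.
#' @param delta_L Requested increment(s) in cd/m^2, > 0.
#' @return Achievable increment(s); idempotent, always within
#'   `[delta_L_min, delta_L_max]`.
#' @export
quantize_increment <- function(device, delta_L) {
  stopifnot(inherits(device, "perisim_device"))
  if (any(!(delta_L > 0))) stop("`delta_L` must be > 0", call. = FALSE)
  lo <- device$delta_L_min
  hi <- device$delta_L_max
  x <- pmin(pmax(delta_L, lo), hi)
  if (is.infinite(device$n_levels)) {
    return(x)
  }
  step <- (hi - lo) / (device$n_levels - 1)
  k <- round((x - lo) / step)
  pmin(pmax(lo + k * step, lo), hi)
}

#' Load a device model from a configuration file or list
#'
#' Accepts a YAML or JSON file (extension-detected) or an already-parsed
#' named list with the [device_model()] field names. A single string naming a
#' preset (`"octopus900"` or `"iowa_hmp"`) returns that preset, optionally
#' modified by fields given in the file/list form.
#'
#' @param config Path to a YAML/JSON file, a named list, or a preset name.
#' @return A `perisim_device`.
#' @examples
#' device_from_config("iowa_hmp")
#' device_from_config(list(preset = "octopus900", name = "octopus_custom"))
#' @export
device_from_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (config %in% c("octopus900", "iowa_hmp")) {
      return(switch(config, octopus900 = octopus900(), iowa_hmp = iowa_hmp()))
    }
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    stop("`config` must be a preset name, file path, or named list",
         call. = FALSE)
  }
  base <- list()
  if (!is.null(config$preset)) {
    base <- unclass(device_from_config(config$preset))
    config$preset <- NULL
  }
  fields <- utils::modifyList(base, config)
  allowed <- names(formals(device_model))
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown) > 0) {
    stop("unknown device config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(device_model, fields)
}
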