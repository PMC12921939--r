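# Shared test helpers: independent oracles and small fixtures.

# Numeric Deming oracle: minimize the lambda-weighted perpendicular squared
# distance sum((y - a - b*x)^2 / (lambda + b^2)) directly, independent of the
# closed-form implementation. Multi-start Nelder-Mead for robustness.
deming_oracle <- function(x, y, lambda = 1) {
  obj <- function(par) sum((y - par[1] - par[2] * x)^2 / (lambda + par[2]^2))
  starts <- list(
    c(0, 1),
    unname(stats::coef(stats::lm(y ~ x))),
    c(mean(y) - mean(x), stats::sd(y) / stats::sd(x))
  )
  fits <- lapply(starts, function(s) {
    stats::optim(s, obj, control = list(reltol = 1e-14, maxit = 5000))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  c(intercept = best$par[1], slope = best$par[2])
}

# Observer with a single known threshold at one grid location.
single_location_observer <- function(true_db, slope_sd = 1.5,
                                     fp = 0.03, fn = 0.03) {
  tf <- tibble::tibble(subject_id = "S", eye = "OD", diagnosis = "normal",
                       x_deg = 1L, y_deg = 1L, true_db = true_db)
  psychometric_observer(tf, slope_sd = slope_sd, fp_rate = fp, fn_rate = fn)
}

# Run one full ZEST procedure against a known threshold (device scale).
run_single_zest <- function(device, true_db, control = zest_control(),
                            slope_sd = 1.5, fp = 0.03, fn = 0.03) {
  obs <- single_location_observer(true_db, slope_sd, fp, fn)
  st <- zest_init(device, control = control)
  while (!st$finished) {
    st <- zest_step(st, device, function(s) {
      stats::runif(1) < seen_probability(obs, true_db, s)
    })
  }
  st
}

# Minimal measured-field tibble for agreement tests.
measured_tbl <- function(values, device = "dev", subject_id = "S1",
                         eye = "OD") {
  grid <- generate_10_2()[seq_along(values), ]
  tibble::tibble(subject_id = subject_id, eye = eye, device = device,
                 x_deg = grid$x_deg, y_deg = grid$y_deg,
                 sensitivity_db = values,
                 n_presentations = 4L)
}
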