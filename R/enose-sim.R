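#' Construct a single sensor curve
#'
#' @param sensor_id Sensor label.
#' @param times Sampling times in seconds, strictly increasing.
#' @param voltages Raw sensor response (arbitrary units, > 0), same length.
#' @return A `sensor_curve` list.
#' @export
sensor_curve <- function(sensor_id, times, voltages) {
  if (length(times) != length(voltages)) stop("times and voltages differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(voltages <= 0)) stop("voltages must be > 0 everywhere")
  structure(list(sensor_id = sensor_id, times = as.numeric(times),
                 voltages = as.numeric(voltages)),
            class = "sensor_curve")
}

#' Construct an e-nose sample from 13 sensor curves
#'
#' @param curves List of 13 [sensor_curve()] objects with distinct sensor
#'   ids and identical time bases.
#' @return An `enose_sample` list.
#' @export
enose_sample <- function(curves) {
  if (length(curves) != 13L) stop("an e-nose sample requires exactly 13 curves")
  ids <- vapply(curves, function(cv) cv$sensor_id, "")
  if (anyDuplicated(ids)) stop("duplicate sensor id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  t0 <- curves[[1]]$times
  same <- vapply(curves, function(cv) identical(cv$times, t0), TRUE)
  if (!all(same)) stop("all curves must share one time base")
  names(curves) <- ids
  structure(list(curves = curves, times = t0), class = "enose_sample")
}

#' Acquisition protocol timing
#'
#' The three-phase acquisition: 120 s baseline with clean air, 40 s
#' headspace injection, 60 s recovery — 220 s total, sampled at 1 Hz at
#' t = 1..220 s. The feature window for the maximum sensor response is
#' 121-140 s (20 samples, both endpoints included).
#'
#' @return Named list with `times`, `baseline_end`, `injection_end`,
#'   `total`, and `msr_window`.
#' @export
enose_protocol <- function() {
  list(times = seq_len(220), baseline_end = 120, injection_end = 160,
       total = 220, msr_window = c(121, 140))
}

#' Simulate one 13-channel e-nose acquisition
#'
#' Generates the raw voltage curves of the 220 s protocol for one fruit.
#' For sensor *s* with baseline `V0_s`, amplitude `A_s` and rise constant
#' `tau_s`:
#' * baseline phase (t <= 120 s): `V0_s` plus linear drift and noise;
#' * injection (120 < t <= 160): saturating rise
#'   `V0_s * (1 + A_s * (1 - exp(-(t - 120)/tau_s)))`;
#' * recovery (t > 160): exponential return toward `V0_s` with time
#'   constant `2 * tau_s`.
#'
#' The amplitude couples aroma to fruit chemistry:
#' `A_s = gain_s * (1 + kappa * z)` where `z` is the standardised soluble
#' solids content of the fruit and `kappa` the profile's coupling constant
#' (default 0.3). Sweeter fruit therefore emit a proportionally stronger
#' headspace response on every channel, which is what lets e-nose features
#' predict physicochemical targets downstream. A multiplicative amplitude
#' disturbance and additive voltage noise, both scaled by the profile's
#' `noise_scale`, model acquisition variability; at `noise_scale = 0` the
#' curves follow the closed forms exactly.
#'
#' @param profile A `kiwi_region_profile`.
#' @param physchem Physicochemical record of the fruit (named vector); only
#'   `ssc` enters the coupling.
#' @param amp_noise Fractional sd of the per-sensor amplitude disturbance
#'   at `noise_scale = 1` (default 0.05).
#' @param voltage_noise Additive voltage noise sd at `noise_scale = 1`
#'   (default 0.002).
#' @param drift Baseline drift slope sd in volts/s at `noise_scale = 1`
#'   (default 2e-5).
#' @return An [enose_sample()].
#' @export
simulate_enose_sample <- function(profile, physchem,
                                  amp_noise = 0.05,
                                  voltage_noise = 0.002,
                                  drift = 2e-5) {
  stopifnot(inherits(profile, "kiwi_region_profile"))
  proto <- enose_protocol()
  tt <- proto$times
  ns <- profile$noise_scale
  zc <- .ssc_latent_constants()
  z <- (physchem[["ssc"]] - zc[["center"]]) / zc[["scale"]]
  ids <- names(profile$sensor_gain)
  curves <- lapply(ids, function(s) {
    v0 <- profile$sensor_v0[[s]]
    tau <- profile$sensor_tau[[s]]
    amp <- profile$sensor_gain[[s]] * (1 + profile$kappa * z)
    amp <- amp * (1 + amp_noise * ns * rnorm(1))
    slope <- drift * ns * rnorm(1)
    rise_end <- amp * (1 - exp(-40 / tau))
    y <- numeric(length(tt))
    bl <- tt <= proto$baseline_end
    inj <- tt > proto$baseline_end & tt <= proto$injection_end
    rec <- tt > proto$injection_end
    y[bl] <- v0 + slope * tt[bl]
    y[inj] <- v0 * (1 + amp * (1 - exp(-(tt[inj] - proto$baseline_end) / tau)))
    y[rec] <- v0 * (1 + rise_end * exp(-(tt[rec] - proto$injection_end) / (2 * tau)))
    if (ns > 0 && voltage_noise > 0) {
      y <- y + rnorm(length(y), sd = voltage_noise * ns)
    }
    y <- pmax(y, 1e-6)
    sensor_curve(s, tt, y)
  })
  enose_sample(curves)
}
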