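#' Baseline-normalise a sensor curve
#'
#' Fractional change from baseline: `Ys(t) = (Xs(t) - Xs(0)) / Xs(0)`,
#' where the baseline `Xs(0)` is estimated as the mean raw response over
#' the last stretch of the baseline phase (default 110-120 s), which is
#' robust to sample noise. The transform is invariant to any positive
#' gain applied to the raw curve.
#'
#' @param curve A [sensor_curve()].
#' @param baseline_window Two-element window (s) over which `Xs(0)` is
#'   averaged, endpoints inclusive.
#' @return A `normalized_curve` list with `sensor_id`, `times`, `values`
#'   and the estimated `baseline`.
#' @export
normalize_curve <- function(curve, baseline_window = c(110, 120)) {
  stopifnot(inherits(curve, "sensor_curve"))
  sel <- curve$times >= baseline_window[1] & curve$times <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  x0 <- mean(curve$voltages[sel])
  if (!is.finite(x0) || x0 <= 0) {
    stop(sprintf("invalid signal [%s]: non-positive baseline estimate", curve$sensor_id))
  }
  structure(list(sensor_id = curve$sensor_id, times = curve$times,
                 values = (curve$voltages - x0) / x0, baseline = x0),
            class = "normalized_curve")
}

#' Maximum sensor response (MSR) of a normalised curve
#'
#' The maximum of the normalised response over the headspace window
#' (default 121-140 s, endpoints inclusive). Only samples inside the
#' window enter the maximum.
#'
#' @param norm A `normalized_curve` from [normalize_curve()].
#' @param window Two-element time window in seconds.
#' @return Scalar MSR.
#' @export
compute_msr <- function(norm, window = enose_protocol()$msr_window) {
  stopifnot(inherits(norm, "normalized_curve"))
  sel <- norm$times >= window[1] & norm$times <= window[2]
  if (!any(sel)) stop("MSR window contains no samples")
  max(norm$values[sel])
}

#' Extract the 13 MSR features of an e-nose sample
#'
#' Normalises each of the 13 sensor curves and takes the maximum sensor
#' response over the headspace window, in the sample's fixed sensor order.
#'
#' @param sample An [enose_sample()].
#' @param window MSR window (s), passed to [compute_msr()].
#' @param baseline_window Baseline window (s), passed to
#'   [normalize_curve()].
#' @return Named numeric vector of length 13 (sensor ids).
#' @export
extract_enose_features <- function(sample, window = enose_protocol()$msr_window,
                                   baseline_window = c(110, 120)) {
  stopifnot(inherits(sample, "enose_sample"))
  out <- vapply(sample$curves, function(cv) {
    compute_msr(normalize_curve(cv, baseline_window), window)
  }, numeric(1))
  stopifnot(length(out) == 13L, all(is.finite(out)))
  out
}

#' Per-region mean MSR table
#'
#' The 3 x 13 table of per-region mean sensor responses behind the radar
#' plot summary of regional aroma profiles.
#'
#' @param labels Region labels, one per sample.
#' @param features Matrix (samples x 13) of MSR features, or a list of
#'   feature vectors.
#' @return Data frame with `region` plus the 13 sensor columns.
#' @export
region_msr_summary <- function(labels, features) {
  if (is.list(features)) features <- do.call(rbind, features)
  labels <- factor(as.character(labels), levels = region_labels())
  if (length(labels) != nrow(features)) stop("labels and features differ in length")
  if (any(table(labels) == 0)) {
    stop("every region needs at least one sample; missing: ",
         paste(region_labels()[table(labels) == 0], collapse = ", "))
  }
  means <- apply(features, 2, function(col) tapply(col, labels, mean))
  data.frame(region = rownames(means), means, row.names = NULL,
             check.names = FALSE)
}
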