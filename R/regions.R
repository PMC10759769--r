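#' Region labels for the three kiwifruit growing areas
#'
#' The three orchard regions in Guilan province covered by the study design:
#' Talesh (west), Langarud (east) and Rasht (centre), with stable integer
#' codes 1, 2 and 3 in that order.
#'
#' @return Character vector of the three region names, in code order.
#' @export
region_labels <- function() {
  c("Talesh", "Langarud", "Rasht")
}

#' Integer codes for region labels
#'
#' @param labels Character vector or factor of region names.
#' @return Integer vector (Talesh = 1, Langarud = 2, Rasht = 3).
#' @export
region_codes <- function(labels) {
  codes <- match(as.character(labels), region_labels())
  if (anyNA(codes)) {
    stop("unknown region label(s): ",
         paste(setdiff(as.character(labels), region_labels()), collapse = ", "))
  }
  codes
}

#' Names of the physicochemical attributes
#'
#' Fixed field order of a physicochemical record: firmness (kg/cm^2),
#' soluble solids content SSC (°Brix), titratable acidity TA (% citric
#' acid), Brix-acid ratio BAR (= SSC/TA), pH, vitamin C (mg/100 g), total
#' phenolics TP (mg GAE/100 g), total anthocyanins TAC (mg CGE/100 g),
#' DPPH radical scavenging (%), FRAP (µmol/g), and the free sugars
#' sucrose, glucose, fructose (%).
#'
#' @return Character vector of the 13 attribute names.
#' @export
physchem_fields <- function() {
  c("firmness", "ssc", "ta", "bar", "ph", "vitamin_c", "tp", "tac",
    "dpph", "frap", "sucrose", "glucose", "fructose")
}

# Per-region attribute means reported for ripened 'Khoni' kiwifruit.
# Rows in region code order. BAR is carried as a mean target only; sampled
# records always recompute BAR as SSC/TA.
.physchem_region_means <- function() {
  m <- rbind(
    Talesh   = c(0.76, 18.63, 0.58, 31.79, 3.83, 84.84,  93.18, 3.27, 60.84,  9.38, 0.76, 1.30, 0.94),
    Langarud = c(0.63, 20.96, 0.55, 38.12, 3.75, 94.19, 104.91, 3.49, 67.12, 10.68, 0.79, 1.32, 0.98),
    Rasht    = c(1.20, 17.40, 0.63, 27.50, 3.71, 74.07,  88.37, 2.64, 57.25,  8.48, 0.74, 1.38, 0.91)
  )
  colnames(m) <- physchem_fields()
  m
}

# Standardisation constants for the latent aroma coupling: the sample's SSC
# is standardised against the grand mean and the between-region spread of
# the regional SSC means.
.ssc_latent_constants <- function() {
  ssc <- .physchem_region_means()[, "ssc"]
  c(center = mean(ssc), scale = sd(ssc))
}

#' Default sensor identifiers of the 13-channel e-nose array
#'
#' Eight MQ-series and five TGS-series metal-oxide gas sensors. The names
#' are labels only; any 13 distinct identifiers may be substituted.
#'
#' @return Character vector of 13 sensor ids.
#' @export
enose_sensor_ids <- function() {
  c("MQ2", "MQ3", "MQ4", "MQ5", "MQ6", "MQ8", "MQ9", "MQ135",
    "TGS813", "TGS822", "TGS2600", "TGS2602", "TGS2610")
}

# Baseline sensor-array constants: per-sensor gain shape (relative MSR
# amplitude of an "average" fruit), baseline voltage V0 and rise time
# constant tau (s). Values are arbitrary but fixed, spanning the dynamic
# range a MOS array shows in fruit headspace work.
.sensor_array_constants <- function() {
  ids <- enose_sensor_ids()
  list(
    gain = setNames(c(1.80, 0.90, 1.50, 1.20, 1.00, 0.70, 1.60, 1.40,
                      0.80, 1.30, 0.60, 1.10, 0.95), ids),
    v0   = setNames(seq(0.45, 0.93, length.out = 13), ids),
    tau  = setNames(c(7, 9, 8, 11, 10, 12, 7.5, 8.5, 13, 9.5, 14, 10.5, 12.5), ids)
  )
}

# Region multipliers on sensor gain at full separation. Langarud fruit emit
# the richest volatile headspace, so its multiplier is the largest.
.region_gain_delta <- c(Talesh = 0.00, Langarud = 0.30, Rasht = -0.12)

# Signed RGB offsets of the locule base colour at full separation: the
# growing region expresses itself most strongly in locule pigmentation.
.region_locule_shift <- rbind(
  Talesh   = c(0, 0, 0),
  Langarud = c(-12, 6, 2),
  Rasht    = c(10, -5, -2)
)

# Smaller skin-colour offsets so whole-fruit appearance also carries a
# (weaker) regional signal.
.region_skin_shift <- rbind(
  Talesh   = c(4, 2, 0),
  Langarud = c(-6, 4, 1),
  Rasht    = c(6, -3, -1)
)

#' Generative profiles for the three growing regions
#'
#' Builds the per-region parameter sets that drive the synthetic generator:
#' physicochemical attribute means, fractional coefficients of variation,
#' e-nose sensor gains, and region-specific colour/shape offsets for the
#' image renderer.
#'
#' `separation` interpolates the between-region structure: at 1 the
#' physicochemical means equal the reported per-region values and the
#' sensor-gain ordering puts Langarud highest on every channel; at 0 all
#' three regions collapse onto the grand mean and share identical gains.
#' `noise_scale` scales every within-region noise source (attribute CVs,
#' sensor noise, shape jitter); 0 gives deterministic samples.
#'
#' @param separation Non-negative scalar scaling between-region differences.
#' @param noise_scale Non-negative scalar scaling within-region noise.
#' @param physchem_cv Fractional coefficient of variation applied to every
#'   attribute before `noise_scale` (default 0.05).
#' @param kappa Coupling constant between the standardised SSC of a fruit
#'   and its e-nose amplitude (default 0.3); see [simulate_enose_sample()].
#' @return Named list of three `kiwi_region_profile` objects.
#' @export
make_region_profiles <- function(separation = 1, noise_scale = 1,
                                 physchem_cv = 0.05, kappa = 0.3) {
  if (!is.numeric(separation) || length(separation) != 1L || is.na(separation) ||
      separation < 0) {
    stop("`separation` must be a non-negative scalar")
  }
  if (!is.numeric(noise_scale) || length(noise_scale) != 1L || is.na(noise_scale) ||
      noise_scale < 0) {
    stop("`noise_scale` must be a non-negative scalar")
  }
  if (physchem_cv <= 0 || physchem_cv >= 0.5) {
    stop("`physchem_cv` must lie in (0, 0.5)")
  }
  means <- .physchem_region_means()
  grand <- colMeans(means)
  arr <- .sensor_array_constants()
  profs <- lapply(region_labels(), function(lbl) {
    mu <- grand + separation * (means[lbl, ] - grand)
    gain <- arr$gain * (1 + separation * .region_gain_delta[[lbl]])
    structure(list(
      label = lbl,
      code = region_codes(lbl),
      physchem_means = mu,
      physchem_cv = setNames(rep(physchem_cv, length(mu)), names(mu)),
      noise_scale = noise_scale,
      separation = separation,
      kappa = kappa,
      sensor_gain = gain,
      sensor_tau = arr$tau,
      sensor_v0 = arr$v0,
      locule_color_shift = separation * .region_locule_shift[lbl, ],
      skin_color_shift = separation * .region_skin_shift[lbl, ],
      shape_jitter = 0.04
    ), class = "kiwi_region_profile")
  })
  names(profs) <- region_labels()
  profs
}

#' @export
print.kiwi_region_profile <- function(x, ...) {
  cat("<kiwi_region_profile>", x$label,
      sprintf("(code %d, separation %.2f, noise %.2f)\n",
              x$code, x$separation, x$noise_scale))
  cat("  physchem means:\n")
  print(round(x$physchem_means, 3))
  invisible(x)
}

#' Draw one physicochemical record from a region profile
#'
#' Each attribute is drawn from a normal law with the profile mean and
#' standard deviation `mean * cv * noise_scale`, truncated below at 10% of
#' the mean so every value stays positive. pH is additionally confined to
#' [2, 7]. The Brix-acid ratio is never sampled: it is recomputed as
#' SSC / TA after sampling, so the identity `bar == ssc / ta` holds exactly
#' for every record.
#'
#' Randomness comes from the R session RNG; seed the stream (or use
#' [generate_dataset()]) for reproducibility.
#'
#' @param profile A `kiwi_region_profile` from [make_region_profiles()].
#' @return Named numeric vector over [physchem_fields()].
#' @export
sample_physchem <- function(profile) {
  stopifnot(inherits(profile, "kiwi_region_profile"))
  mu <- profile$physchem_means
  sds <- mu * profile$physchem_cv * profile$noise_scale
  x <- rnorm(length(mu), mean = mu, sd = sds)
  x <- pmax(x, 0.1 * mu)
  names(x) <- names(mu)
  x["ph"] <- min(max(x["ph"], 2), 7)
  x["bar"] <- x["ssc"] / x["ta"]
  x
}

#' Validate a physicochemical record
#'
#' Checks positivity, the `bar == ssc/ta` identity (to 1e-9), and the pH
#' range [2, 7].
#'
#' @param record Named numeric vector over [physchem_fields()].
#' @return The record, invisibly; errors on violation.
#' @export
validate_physchem <- function(record) {
  fields <- physchem_fields()
  if (!all(fields %in% names(record))) {
    stop("record is missing field(s): ",
         paste(setdiff(fields, names(record)), collapse = ", "))
  }
  record <- record[fields]
  if (any(!is.finite(record)) || any(record <= 0)) {
    stop("all physicochemical values must be finite and > 0")
  }
  if (abs(record[["bar"]] - record[["ssc"]] / record[["ta"]]) > 1e-9) {
    stop("bar must equal ssc / ta (within 1e-9)")
  }
  if (record[["ph"]] < 2 || record[["ph"]] > 7) {
    stop("ph must lie in [2, 7]")
  }
  invisible(record)
}
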