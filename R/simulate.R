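# Synthetic instrument: generates bead files and EV samples with known
# ground truth under a declared noise model -- multiplicative log-normal
# noise on every optical signal, additive Gaussian electronic noise, and a
# hard triggering threshold.  Everything downstream (calibration, gating,
# profiling) is testable against the generator's hidden truth columns.

#' Synthetic instrument model
#'
#' Declares the transfer function from physics to channel values.  Scatter:
#' I = gain * sigma_eff(d) * LN(1, cv) + N(0, noise_sd), with events below
#' the trigger threshold discarded -- small particles are genuinely "lost in
#' noise", as on a real small-particle cytometer.  Fluorescence: per-channel
#' gain, log-normal photon noise, additive autofluorescence, and spillover
#' mixing across detectors.  All intensities are arbitrary instrument units;
#' physical units only appear after calibration.
#'
#' @param scatter_gain Scatter intensity per nm^2 of effective
#'   cross-section (this is 10^beta of the scatter calibration;
#'   default 10^2.5).
#' @param scatter_cv Coefficient of variation of the multiplicative optical
#'   noise (default 0.05).
#' @param electronic_noise_sd SD of additive Gaussian electronic noise in
#'   scatter units (default 200).
#' @param trigger_threshold Hard trigger on \code{trigger_channel}
#'   (default 1500): with the default gain this hides a 60 nm polystyrene
#'   bead in background while keeping an 80 nm bead comfortably detectable.
#' @param trigger_channel Channel carrying the trigger (default
#'   \code{"VSSC_H"}).
#' @param fluorescence_cv CV of multiplicative fluorescence noise
#'   (default 0.15).
#' @param autofluorescence Named vector of per-channel autofluorescence
#'   medians (default 50 for calcein and the three tetraspanin detectors).
#' @param autofluorescence_sd Named vector of per-channel autofluorescence
#'   SDs (default 10).
#' @param spillover A \code{\link{estimate_spillover}}-style matrix over the
#'   marker detectors (default: modest PE-family spillover among
#'   CD9/CD63/CD81).
#' @param flow_rate Sample flow rate, uL/min (default 10).
#' @param acquired_volume Acquired volume, uL (default 20).
#' @param optics The \code{\link{optical_config}} of the scatter channel.
#' @return A list of class \code{"instrument_model"}.
#' @export
instrument_model <- function(scatter_gain = 10^2.5, scatter_cv = 0.05,
                             electronic_noise_sd = 200,
                             trigger_threshold = 1500,
                             trigger_channel = "VSSC_H",
                             fluorescence_cv = 0.15,
                             autofluorescence = c(calcein = 50, CD9 = 50,
                                                  CD63 = 50, CD81 = 50),
                             autofluorescence_sd = c(calcein = 10, CD9 = 10,
                                                     CD63 = 10, CD81 = 10),
                             spillover = default_spillover(),
                             flow_rate = 10, acquired_volume = 20,
                             optics = optical_config()) {
  stopifnot(scatter_gain > 0, scatter_cv >= 0, electronic_noise_sd >= 0)
  structure(list(scatter_gain = scatter_gain, scatter_cv = scatter_cv,
                 electronic_noise_sd = electronic_noise_sd,
                 trigger_threshold = trigger_threshold,
                 trigger_channel = trigger_channel,
                 fluorescence_cv = fluorescence_cv,
                 autofluorescence = autofluorescence,
                 autofluorescence_sd = autofluorescence_sd,
                 spillover = spillover,
                 flow_rate = flow_rate, acquired_volume = acquired_volume,
                 optics = optics),
            class = "instrument_model")
}

#' @rdname instrument_model
#' @export
default_spillover <- function() {
  S <- diag(3)
  dimnames(S) <- list(c("CD9", "CD63", "CD81"), c("CD9", "CD63", "CD81"))
  S["CD9", "CD63"] <- 0.02
  S["CD63", "CD81"] <- 0.08
  S["CD81", "CD63"] <- 0.05
  structure(S, class = c("spillover_matrix", "matrix", "array"))
}

#' Named instrument profiles
#'
#' Two synthetic instrument sensitivities mirroring the machines the
#' workflow targets.  \code{"conventional"} has the default high trigger and
#' electronic noise: a 60 nm polystyrene bead is lost in background and
#' vesicles below roughly 100 nm are not detected.  \code{"nanoscale"}
#' shares the same gain but has ten-fold lower electronic noise and trigger,
#' so it resolves the lower tail of a typical vesicle size distribution
#' (down to roughly 65 nm) -- the profile to use when a sizing study must
#' see the whole population.
#'
#' @param name \code{"conventional"} or \code{"nanoscale"}.
#' @param ... Overrides passed on to \code{\link{instrument_model}}.
#' @return An \code{\link{instrument_model}}.
#' @export
instrument_profile <- function(name = c("conventional", "nanoscale"), ...) {
  name <- match.arg(name)
  switch(name,
         conventional = instrument_model(...),
         nanoscale = instrument_model(electronic_noise_sd = 20,
                                      trigger_threshold = 150,
                                      flow_rate = 1, acquired_volume = 2, ...))
}

#' Synthetic EV population specification
#'
#' Describes one vesicle population: a log-normal diameter distribution, the
#' optical particle family, the fraction of vesicles containing active
#' esterase (hence convertible to fluorescent calcein), and surface-antigen
#' copy numbers per marker.  Copy numbers default to Poisson with mean 20
#' per positive marker -- a low-copy scenario knob, not a biological claim.
#'
#' @param count Number of vesicles (before triggering).
#' @param median_diameter,gsd Log-normal diameter distribution: median (nm)
#'   and geometric SD (defaults 120 nm, 1.4).
#' @param esterase_positive_fraction Fraction of intact, esterase-containing
#'   vesicles (default 0.8).
#' @param calcein_brightness Median calcein intensity of an
#'   esterase-positive vesicle (default 2000 units).
#' @param combination_probs Named probabilities over tetraspanin
#'   combinations, e.g. \code{c("CD9" = 0.3, "CD63+CD81" = 0.2,
#'   "CD9+CD63+CD81" = 0.1, "none" = 0.4)}; must sum to 1.  Markers named in
#'   a combination carry antigen; others carry none.
#' @param antigen_mean Mean antigen copies per positive marker
#'   (Poisson; default 20).
#' @param brightness_per_copy Fluorescence units per antigen copy
#'   (default 50).
#' @param model Particle family: function diameter ->
#'   \code{\link{particle_model}} (default \code{\link{ev_default_model}}).
#' @return A list of class \code{"population_spec"}.
#' @export
population_spec <- function(count, median_diameter = 120, gsd = 1.4,
                            esterase_positive_fraction = 0.8,
                            calcein_brightness = 2000,
                            combination_probs = c("CD9" = 0.3,
                                                  "CD63+CD81" = 0.2,
                                                  "CD9+CD63+CD81" = 0.1,
                                                  "none" = 0.4),
                            antigen_mean = 20, brightness_per_copy = 50,
                            model = ev_default_model) {
  stopifnot(count >= 0, median_diameter > 0, gsd >= 1,
            esterase_positive_fraction >= 0, esterase_positive_fraction <= 1)
  if (abs(sum(combination_probs) - 1) > 1e-8)
    stop("'combination_probs' must sum to 1", call. = FALSE)
  structure(list(count = as.integer(count),
                 median_diameter = median_diameter, gsd = gsd,
                 esterase_positive_fraction = esterase_positive_fraction,
                 calcein_brightness = calcein_brightness,
                 combination_probs = combination_probs,
                 antigen_mean = antigen_mean,
                 brightness_per_copy = brightness_per_copy,
                 model = model),
            class = "population_spec")
}

# log-normal with median 1 and the given CV
rln_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

scatter_channels <- function(instrument, sigma, n) {
  gain <- instrument$scatter_gain
  h <- gain * sigma * rln_cv(n, instrument$scatter_cv) +
    stats::rnorm(n, 0, instrument$electronic_noise_sd)
  a <- h * rln_cv(n, 0.02)        # area tracks height for single particles
  f <- 0.3 * gain * sigma * rln_cv(n, instrument$scatter_cv) +
    stats::rnorm(n, 0, instrument$electronic_noise_sd)
  data.frame(VSSC_H = h, VSSC_A = a, FSC_H = f)
}

apply_trigger <- function(df, instrument) {
  ch <- instrument$trigger_channel
  if (!ch %in% names(df)) return(df)
  df[df[[ch]] >= instrument$trigger_threshold, , drop = FALSE]
}

#' Generate synthetic calibration bead files
#'
#' Emulates the three bead products the workflow calibrates against:
#' \describe{
#'   \item{\code{"nist"}}{polystyrene size standards at 60, 80, 101, 125 and
#'     151 nm (RI 1.61); per-event scatter = gain * sigma_eff * log-normal
#'     noise + electronic noise, then the hard trigger -- so the 60 nm
#'     population is largely lost, as on a conventional instrument.}
#'   \item{\code{"abc_ladder"}}{antibody-binding-capacity populations at the
#'     assigned ABC values 5e3, 2e4, 8e4, 2.5e5 plus an unstained blank.}
#'   \item{\code{"liposome_standard"}}{a membrane-dye-stained liposome
#'     standard, log-normal diameters with median 110 nm spanning roughly
#'     80-140 nm; dye intensity proportional to surface area.}
#' }
#'
#' @param kind One of \code{"nist"}, \code{"abc_ladder"},
#'   \code{"liposome_standard"}.
#' @param instrument An \code{\link{instrument_model}}.
#' @param n_per_population Events per population before triggering.
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @param diameters,ri NIST bead diameters (nm) and refractive index.
#' @param abc_values Assigned ABC ladder (ascending).
#' @param abc_channel Detector for the ABC ladder (default \code{"CD9"}).
#' @param liposome_median,liposome_gsd Liposome standard size distribution
#'   (median 110 nm, GSD 1.15 spans ~80-140 nm).
#' @param dye_gain Dye intensity per nm^2 of membrane (default 1).
#' @return An \code{\link{event_table}} with hidden \code{true_*} columns
#'   (\code{true_population}, \code{true_diameter} or \code{true_abc}).
#' @export
generate_bead_file <- function(kind = c("nist", "abc_ladder",
                                        "liposome_standard"),
                               instrument = instrument_model(),
                               n_per_population = 2000, seed = 1,
                               diameters = c(60, 80, 101, 125, 151),
                               ri = 1.61,
                               abc_values = c(5e3, 2e4, 8e4, 2.5e5),
                               abc_channel = "CD9",
                               liposome_median = 110, liposome_gsd = 1.15,
                               dye_gain = 1) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  n <- as.integer(n_per_population)
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    event_table(df, flow_rate = instrument$flow_rate,
                acquired_volume = instrument$acquired_volume,
                seed = as.integer(seed))
  }
  if (kind == "nist") {
    if (n == 0L) return(empty(c("VSSC_H", "VSSC_A", "FSC_H",
                                "true_population", "true_diameter")))
    sigma <- vapply(diameters, function(d)
      effective_scattering_cross_section(particle_model(d, ri),
                                         instrument$optics)$sigma_effective,
      numeric(1))
    parts <- lapply(seq_along(diameters), function(i) {
      df <- scatter_channels(instrument, rep(sigma[i], n), n)
      df$true_population <- i
      df$true_diameter <- diameters[i]
      df
    })
    df <- apply_trigger(do.call(rbind, parts), instrument)
  } else if (kind == "abc_ladder") {
    if (n == 0L) return(empty(c(abc_channel, "true_population", "true_abc")))
    af <- instrument$autofluorescence[[abc_channel]]
    af_sd <- instrument$autofluorescence_sd[[abc_channel]]
    # per-ABC fluorescence: 1 unit of gain per antibody, log-normal noise
    parts <- lapply(seq_along(abc_values), function(i) {
      intens <- abc_values[i] * rln_cv(n, instrument$fluorescence_cv) +
        stats::rnorm(n, af, af_sd)
      df <- stats::setNames(data.frame(intens), abc_channel)
      df$true_population <- i
      df$true_abc <- abc_values[i]
      df
    })
    blank <- stats::setNames(data.frame(stats::rnorm(n, af, af_sd)), abc_channel)
    blank$true_population <- 0
    blank$true_abc <- 0
    df <- rbind(do.call(rbind, parts), blank)
  } else {
    if (n == 0L) return(empty(c("vfred", "true_diameter")))
    d <- stats::rlnorm(n, log(liposome_median), log(liposome_gsd))
    intens <- dye_gain * pi * d^2 * rln_cv(n, instrument$fluorescence_cv)
    df <- data.frame(vfred = intens, true_diameter = d)
  }
  event_table(df, flow_rate = instrument$flow_rate,
              acquired_volume = instrument$acquired_volume,
              seed = as.integer(seed))
}

#' Generate a synthetic EV sample with ground truth
#'
#' Draws vesicles from one or more \code{\link{population_spec}}s: diameters
#' are log-normal; scatter channels come from the Mie cross-section of each
#' vesicle's true diameter (interpolated on a fine curve); calcein is
#' autofluorescence only for esterase-negative vesicles and brightness *
#' log-normal noise otherwise; marker channels are antigen copies * per-copy
#' brightness, mixed through the instrument's spillover matrix, plus
#' autofluorescence.  The hard trigger is applied last.  Ground truth stays
#' in \code{true_*} columns (excluded from FCS export).
#'
#' @param populations A \code{\link{population_spec}} or list of them.
#' @param instrument An \code{\link{instrument_model}}.
#' @param seed Integer seed (bit-reproducible output).
#' @param dilution_factor Recorded in the table metadata (default 1).
#' @return An \code{\link{event_table}} with channels \code{VSSC_H},
#'   \code{VSSC_A}, \code{FSC_H}, \code{calcein}, \code{CD9}, \code{CD63},
#'   \code{CD81} and truth columns \code{true_diameter},
#'   \code{true_esterase}, \code{true_combination} (index into
#'   \code{attr(,"combinations")}), and per-marker \code{true_*_copies}.
#' @export
generate_ev_sample <- function(populations, instrument = instrument_model(),
                               seed = 1, dilution_factor = 1) {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  set.seed(as.integer(seed))
  markers <- rownames(instrument$spillover)
  combo_names_all <- unique(unlist(lapply(populations, function(p)
    names(p$combination_probs))))
  parts <- lapply(populations, function(pop) {
    n <- pop$count
    if (n == 0L) return(NULL)
    d <- stats::rlnorm(n, log(pop$median_diameter), log(pop$gsd))
    grid <- seq(max(10, floor(min(d)) - 1), ceiling(max(d)) + 1, by = 1)
    curve <- cross_section_curve(grid, instrument$optics, pop$model)
    sigma <- stats::approx(curve$diameter, curve$sigma, xout = d)$y
    df <- scatter_channels(instrument, sigma, n)
    esterase <- stats::runif(n) < pop$esterase_positive_fraction
    af <- instrument$autofluorescence
    af_sd <- instrument$autofluorescence_sd
    calcein_sig <- ifelse(esterase,
                          pop$calcein_brightness * rln_cv(n, instrument$fluorescence_cv),
                          0)
    df$calcein <- calcein_sig + stats::rnorm(n, af[["calcein"]], af_sd[["calcein"]])
    combo <- sample(names(pop$combination_probs), n, replace = TRUE,
                    prob = pop$combination_probs)
    copies <- matrix(0L, n, length(markers), dimnames = list(NULL, markers))
    for (mk in markers) {
      inin <- vapply(strsplit(combo, "+", fixed = TRUE),
                     function(s) mk %in% s, logical(1))
      copies[inin, mk] <- stats::rpois(sum(inin), pop$antigen_mean)
    }
    signal <- copies * pop$brightness_per_copy *
      matrix(rln_cv(n * length(markers), instrument$fluorescence_cv),
             n, length(markers))
    mixed <- signal %*% instrument$spillover
    for (j in seq_along(markers)) {
      df[[markers[j]]] <- mixed[, j] +
        stats::rnorm(n, af[[markers[j]]], af_sd[[markers[j]]])
    }
    df$true_diameter <- d
    df$true_esterase <- as.numeric(esterase)
    df$true_combination <- match(combo, combo_names_all)
    for (mk in markers) df[[paste0("true_", mk, "_copies")]] <- copies[, mk]
    df
  })
  df <- do.call(rbind, parts)
  df <- apply_trigger(df, instrument)
  out <- event_table(df, flow_rate = instrument$flow_rate,
                     acquired_volume = instrument$acquired_volume,
                     dilution_factor = dilution_factor,
                     seed = as.integer(seed))
  attr(out, "combinations") <- combo_names_all
  out
}

#' Generate a control sample (no vesicles)
#'
#' Buffer + calcein control: autofluorescence and electronic noise only, on
#' the same channels as \code{\link{generate_ev_sample}}.  Used to place the
#' calcein threshold and to background-correct enumeration counts.
#'
#' @param n Number of events.
#' @param instrument An \code{\link{instrument_model}}.
#' @param seed Integer seed.
#' @return An \code{\link{event_table}}.
#' @export
generate_buffer_control <- function(n, instrument = instrument_model(),
                                    seed = 1) {
  set.seed(as.integer(seed))
  markers <- rownames(instrument$spillover)
  af <- instrument$autofluorescence
  af_sd <- instrument$autofluorescence_sd
  df <- data.frame(
    VSSC_H = abs(stats::rnorm(n, instrument$trigger_threshold * 1.05,
                              instrument$electronic_noise_sd)),
    VSSC_A = abs(stats::rnorm(n, instrument$trigger_threshold * 1.05,
                              instrument$electronic_noise_sd)),
    FSC_H = abs(stats::rnorm(n, 0, instrument$electronic_noise_sd)))
  df$calcein <- stats::rnorm(n, af[["calcein"]], af_sd[["calcein"]])
  for (mk in markers) df[[mk]] <- stats::rnorm(n, af[[mk]], af_sd[[mk]])
  event_table(df, flow_rate = instrument$flow_rate,
              acquired_volume = instrument$acquired_volume,
              seed = as.integer(seed))
}

#' Generate an engineered calcein titration scenario
#'
#' Signal follows a saturating (Michaelis-type) curve in dye concentration
#' while the buffer background grows linearly; the defaults place the
#' corrected-count plateau at 1 uM and the stain-index peak at 10 uM,
#' mirroring the structure of a real titration across 8 concentrations
#' between 0.1 and 200 uM.
#'
#' @param concentrations Dye concentrations in uM.
#' @param n_max Saturating corrected count.
#' @param k_count Half-saturation of the count curve, uM (default 0.08:
#'   counts plateau by 1 uM).
#' @param k_signal Half-saturation of the positive-median curve, uM
#'   (default 6: stain index peaks at 10 uM as background grows).
#' @param peak_intensity Saturating positive median intensity.
#' @param noise Draw counts from Poisson (default \code{TRUE}).
#' @param seed Integer seed.
#' @return A \code{\link{titration_points}} data frame.
#' @export
generate_titration_series <- function(concentrations = c(0.1, 0.5, 1, 5, 10,
                                                         50, 100, 200),
                                      n_max = 20000, k_count = 0.08,
                                      k_signal = 6, peak_intensity = 5000,
                                      noise = TRUE, seed = 1) {
  set.seed(as.integer(seed))
  cc <- concentrations
  expected <- n_max * cc / (cc + k_count)
  buffer <- 50 * cc                       # autofluorescent background
  sample_counts <- expected + buffer
  if (noise) {
    sample_counts <- stats::rpois(length(cc), sample_counts)
    buffer <- stats::rpois(length(cc), buffer)
  }
  titration_points(concentration = cc,
                   sample_positive_count = round(sample_counts),
                   buffer_positive_count = round(buffer),
                   positive_median_intensity = peak_intensity * cc / (cc + k_signal),
                   negative_median_intensity = 100 + 2 * cc,
                   negative_sd = 50 + 4 * cc)
}

#' Generate a serial dilution series
#'
#' Expected calcein-positive counts scale as 1/dilution with Poisson
#' sampling -- the null (non-swarming) behaviour a dilution-linearity check
#' should call linear.
#'
#' @param base_count Expected count at dilution factor 1.
#' @param dilution_factors Dilution factors (default 1, 2, 4, ..., 32).
#' @param noise Poisson-sample the counts (default \code{TRUE}).
#' @param seed Integer seed.
#' @return A data frame with \code{dilution_factor} and \code{count}.
#' @export
generate_dilution_series <- function(base_count = 50000,
                                     dilution_factors = 2^(0:5),
                                     noise = TRUE, seed = 1) {
  set.seed(as.integer(seed))
  expected <- base_count / dilution_factors
  count <- if (noise) stats::rpois(length(expected), expected) else round(expected)
  data.frame(dilution_factor = dilution_factors, count = count)
}
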