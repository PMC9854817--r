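#' Describe one Raman peak for the synthetic generator
#'
#' A peak is a Lorentzian line with a fixed centre and width whose amplitude
#' is modulated per diagnostic class, emulating the between-group intensity
#' differences seen in serum spectra.
#'
#' @param center Peak centre in cm^-1.
#' @param width Full width at half maximum in cm^-1 (> 0).
#' @param base_amplitude Peak height in arbitrary intensity units (>= 0).
#' @param class_multipliers Named numeric vector of positive scale factors,
#'   one per diagnostic class; classes not named default to 1.
#' @return An object of class \code{peak_spec}.
#' @export
peak_spec <- function(center, width = 16, base_amplitude = 1,
                      class_multipliers = c(HC = 1, BC = 1, DCIS = 1)) {
  if (!is.finite(center)) stop("'center' must be finite")
  if (!is.finite(width) || width <= 0) stop("'width' must be > 0")
  if (!is.finite(base_amplitude) || base_amplitude < 0)
    stop("'base_amplitude' must be >= 0")
  if (is.null(names(class_multipliers)) || any(class_multipliers <= 0))
    stop("'class_multipliers' must be a named vector of positive factors")
  structure(list(center = center, width = width,
                 base_amplitude = base_amplitude,
                 class_multipliers = class_multipliers),
            class = "peak_spec")
}

#' Default serum peak set
#'
#' Eleven Lorentzian peaks at the positions characteristic of serum Raman
#' spectra (ascorbic acid/amide at 593, serine/glutathione at 810,
#' proline/valine at 950, phenylalanine at 1004 and 1576, beta-carotene at
#' 1154 and 1514, nucleic acid at 1280, collagen/phospholipid at 1445, and
#' protein O-H bands at 2517 and 2662 cm^-1). Base amplitudes make the two
#' beta-carotene bands the strongest. The class multipliers encode the
#' assumed disease effect: carotenoid bands are attenuated in breast cancer
#' and intermediately in DCIS, while protein/lipid bands are mildly
#' elevated. Between-group effect sizes are a modelling choice, not measured
#' values, and are fully configurable.
#'
#' @return List of \code{\link{peak_spec}} objects.
#' @export
default_peaks <- function() {
  carot <- c(HC = 1, BC = 0.55, DCIS = 0.75)
  prot  <- c(HC = 1, BC = 1.30, DCIS = 1.15)
  none  <- c(HC = 1, BC = 1, DCIS = 1)
  list(
    peak_spec(593,  base_amplitude = 0.25, class_multipliers = none),
    peak_spec(810,  base_amplitude = 0.20, class_multipliers = none),
    peak_spec(950,  base_amplitude = 0.35, class_multipliers = prot),
    peak_spec(1004, base_amplitude = 0.45, class_multipliers = prot),
    peak_spec(1154, base_amplitude = 1.00, class_multipliers = carot),
    peak_spec(1280, base_amplitude = 0.30, class_multipliers = none),
    peak_spec(1445, base_amplitude = 0.50, class_multipliers = prot),
    peak_spec(1514, base_amplitude = 0.90, class_multipliers = carot),
    peak_spec(1576, base_amplitude = 0.30, class_multipliers = prot),
    peak_spec(2517, base_amplitude = 0.25, class_multipliers = none),
    peak_spec(2662, base_amplitude = 0.25, class_multipliers = none)
  )
}

#' Configuration for the synthetic spectrum generator
#'
#' Defines the study conditions emulated by \code{\link{generate_dataset}}:
#' class sizes matching a serum cohort of 241 healthy controls, 463 breast
#' cancer and 100 DCIS patients; five replicate acquisitions averaged per
#' sample; additive Gaussian noise; and multiplicative lognormal amplitude
#' jitter per peak per sample.
#'
#' @param n_per_class Named integer vector of samples per class.
#' @param peaks List of \code{\link{peak_spec}} objects.
#' @param baseline_coeffs Polynomial coefficients (ascending powers) of the
#'   fluorescence-like background, evaluated on the axis rescaled to
#'   \code{[0, 1]}; the default cubic is positive everywhere with magnitude
#'   comparable to the peak heights.
#' @param noise_sd Standard deviation of the additive noise per acquisition,
#'   in intensity units.
#' @param jitter_sd Standard deviation (log scale) of the per-peak lognormal
#'   amplitude jitter; multiplicative so intensities stay positive.
#' @param replicates Acquisitions averaged per sample (>= 1).
#' @param seed Root RNG seed; per-sample streams are derived from it by a
#'   counter, so generation is order-independent.
#' @param axis_start,axis_stop,axis_n Wavenumber axis parameters.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n_per_class = c(HC = 241, BC = 463, DCIS = 100),
                             peaks = default_peaks(),
                             baseline_coeffs = c(1.0, 2.4, -3.0, 1.0),
                             noise_sd = 0.02,
                             jitter_sd = 0.05,
                             replicates = 5,
                             seed = 1,
                             axis_start = 400, axis_stop = 4000,
                             axis_n = 1698) {
  if (is.null(names(n_per_class)) || any(n_per_class <= 0) ||
      any(n_per_class != round(n_per_class)))
    stop("'n_per_class' must be a named vector of positive integer counts")
  if (!length(peaks) || !all(vapply(peaks, inherits, TRUE, "peak_spec")))
    stop("'peaks' must be a list of peak_spec objects")
  if (!is.numeric(baseline_coeffs) || !length(baseline_coeffs))
    stop("'baseline_coeffs' must be a non-empty numeric vector")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1) stop("'replicates' must be >= 1")
  structure(list(n_per_class = n_per_class, peaks = peaks,
                 baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, replicates = replicates,
                 seed = as.integer(seed),
                 axis_start = axis_start, axis_stop = axis_stop,
                 axis_n = axis_n),
            class = "generator_config")
}

lorentzian <- function(axis, center, fwhm) {
  hw <- fwhm / 2
  1 / (1 + ((axis - center) / hw)^2)
}

eval_baseline <- function(axis, coeffs) {
  u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  drop(outer(u, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

#' Render a noise-free spectrum
#'
#' Sums Lorentzian peaks (each scaled by the label's class multiplier and an
#' optional per-peak jitter factor) on top of the polynomial background.
#' Deterministic; negative values are returned as-is, never clamped.
#'
#' @param axis Wavenumber axis.
#' @param peaks List of \code{\link{peak_spec}} objects.
#' @param baseline_coeffs Background polynomial coefficients (ascending
#'   powers of the axis rescaled to \code{[0, 1]}).
#' @param label Diagnostic class used to look up multipliers; \code{NULL}
#'   uses multiplier 1 for every peak.
#' @param jitter Optional numeric vector, one multiplicative factor per peak.
#' @return A \code{\link{spectrum_set}} with a single spectrum.
#' @export
render_clean_spectrum <- function(axis, peaks, baseline_coeffs, label = NULL,
                                  jitter = NULL) {
  check_axis(axis)
  y <- eval_baseline(axis, baseline_coeffs)
  if (is.null(jitter)) jitter <- rep(1, length(peaks))
  rng <- range(axis)
  for (i in seq_along(peaks)) {
    p <- peaks[[i]]
    if (p$center < rng[1] - p$width || p$center > rng[2] + p$width)
      warning(sprintf("peak centre %.1f cm^-1 lies outside the axis range",
                      p$center))
    m <- 1
    if (!is.null(label)) {
      m <- p$class_multipliers[[as.character(label)]]
      if (is.null(m) || is.na(m)) m <- 1
    }
    y <- y + p$base_amplitude * m * jitter[i] *
      lorentzian(axis, p$center, p$width)
  }
  spectrum_set(axis, matrix(y, nrow = 1),
               labels = if (is.null(label)) NULL else as.character(label),
               sample_ids = "clean")
}

# Per-sample RNG stream derived from the root seed by a counter, so each
# sample's randomness is independent of how many samples precede it.
sample_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 2654435761) %% 2147483647)
}

#' Generate a labelled synthetic dataset
#'
#' For each sample: draw one lognormal jitter factor per peak, render the
#' clean class spectrum, simulate \code{replicates} noisy acquisitions
#' (i.i.d. additive Gaussian noise) and average them -- mirroring a protocol
#' in which five spectra per serum drop are acquired and their mean is
#' analysed. Fully reproducible from the config seed.
#'
#' @param config A \code{\link{generator_config}}.
#' @return A \code{\link{spectrum_set}} of \code{sum(n_per_class)} spectra.
#' @examples
#' cfg <- generator_config(n_per_class = c(HC = 5, BC = 5, DCIS = 3),
#'                         seed = 42)
#' gen <- generate_dataset(cfg)
#' table(gen$labels)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  axis <- make_axis(config$axis_start, config$axis_stop, config$axis_n)
  n_total <- sum(config$n_per_class)
  intens <- matrix(NA_real_, n_total, length(axis))
  labels <- character(n_total)
  ids <- character(n_total)
  counter <- 0L
  row <- 0L
  for (cls in names(config$n_per_class)) {
    for (i in seq_len(config$n_per_class[[cls]])) {
      counter <- counter + 1L
      row <- row + 1L
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(sample_seed(config$seed, counter))
      jit <- stats::rlnorm(length(config$peaks), meanlog = 0,
                           sdlog = config$jitter_sd)
      clean <- render_clean_spectrum(axis, config$peaks,
                                     config$baseline_coeffs, cls, jit)
      y <- clean$intensities[1, ]
      acc <- numeric(length(axis))
      for (r in seq_len(config$replicates))
        acc <- acc + y + stats::rnorm(length(axis), 0, config$noise_sd)
      intens[row, ] <- acc / config$replicates
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, envir = globalenv())
      labels[row] <- cls
      ids[row] <- sprintf("%s_%04d", cls, i)
    }
  }
  spectrum_set(axis, intens, labels, ids,
               class_order = names(config$n_per_class))
}
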