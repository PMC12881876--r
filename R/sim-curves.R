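#' Suture curve generator parameters
#'
#' Bundles the generative controls of one suture's interdigitation. The
#' defaults (per suture) are the package's fixed study conditions: amplitudes
#' and wave counts ordered coronal >= sagittal >= interfrontal, with an
#' age profile that makes interfrontal and sagittal complexity decline through
#' ontogeny while the coronal declines and then rises again in adults.
#'
#' @param suture suture name (sets the per-suture defaults).
#' @param amplitude interdigitation depth as a fraction of suture length.
#' @param n_waves number of interdigitation waves along the suture.
#' @param phase_jitter SD (radians) of smooth per-wave phase noise.
#' @param noise_sd isotropic coordinate noise, fraction of suture length.
#' @param age_profile `"decline"`, `"late_rise"` or `"constant"` — how
#'   `(amplitude, n_waves)` scale with relative age (in percent of adult
#'   centroid size).
#' @param bow dorsal/lateral bowing of the base arc (fraction of length).
#' @param tilt oblique-plane tilt in radians (coronal only; the plane normal
#'   stays in the y-z plane so an x-rotation can flatten it).
#' @return a `suture_params` list.
#' @export
suture_params <- function(suture = SUTURE_NAMES,
                          amplitude = NULL, n_waves = NULL,
                          phase_jitter = 0.3, noise_sd = 8e-4,
                          age_profile = NULL, bow = 0.06, tilt = NULL) {
  suture <- match.arg(suture)
  defaults <- list(
    interfrontal = list(amplitude = 0.030, n_waves = 9, age_profile = "decline", tilt = 0),
    sagittal = list(amplitude = 0.045, n_waves = 13, age_profile = "decline", tilt = 0),
    coronal = list(amplitude = 0.065, n_waves = 18, age_profile = "late_rise", tilt = 0.3)
  )[[suture]]
  structure(
    list(
      suture = suture,
      amplitude = amplitude %||% defaults$amplitude,
      n_waves = n_waves %||% defaults$n_waves,
      phase_jitter = phase_jitter, noise_sd = noise_sd,
      age_profile = age_profile %||% defaults$age_profile,
      bow = bow, tilt = tilt %||% defaults$tilt
    ),
    class = "suture_params"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Age-profile multipliers applied to (amplitude, n_waves); age in percent of
# adult centroid size.
age_profile_multipliers <- function(profile, relative_age) {
  amp <- switch(profile,
    constant = 1,
    decline = pmax(0.25, 1.6 - 0.011 * relative_age),
    late_rise = pmax(0.2, 1.35 - 0.010 * relative_age) +
      0.65 / (1 + exp(-(relative_age - 92) / 3)),
    stop("unknown age profile: ", profile, call. = FALSE)
  )
  list(amplitude = amp, n_waves = 1)
}

#' Generate one synthetic suture curve
#'
#' Builds an ordered 500-point 3D curve: a gently bowed base arc of unit
#' length plus sinusoidal interdigitation whose amplitude and frequency are
#' scaled by the age profile, a smooth per-wave phase jitter, and isotropic
#' coordinate noise. Midline sutures (interfrontal, sagittal) are laid in the
#' horizontal plane along the anteroposterior (x) axis with deviations along
#' y; the coronal suture runs mediolaterally inside an oblique plane tilted by
#' `tilt` about the x axis (normal in the y-z plane), with deviations along x.
#' Fully reproducible given `(params, relative_age, seed)`.
#'
#' @param params a [suture_params()] list.
#' @param relative_age percentage of adult centroid size (100 = adult).
#' @param seed integer seed.
#' @param n points along the curve (default 500).
#' @param amplitude_factor,waves_factor extra multiplicative effects (species
#'   or clade level), default 1.
#' @return an n x 3 point matrix in the unit-skull frame (to be placed and
#'   scaled by the specimen generator).
#' @export
generate_suture_curve <- function(params, relative_age = 100, seed = 1L, n = 500L,
                                  amplitude_factor = 1, waves_factor = 1) {
  stopifnot(inherits(params, "suture_params"))
  mult <- age_profile_multipliers(params$age_profile, relative_age)
  a <- params$amplitude * mult$amplitude * amplitude_factor
  waves <- max(1, round(params$n_waves * mult$n_waves * waves_factor))
  s <- seq(0, 1, length.out = n)
  set.seed(seed)
  phases <- rnorm(waves + 1, 0, params$phase_jitter)
  phase_s <- approx(seq(0, 1, length.out = waves + 1), phases, xout = s)$y
  envelope <- sin(pi * s) # pins interdigitation to zero at the endpoints
  dev <- a * envelope * sin(2 * pi * waves * s + phase_s)
  base <- params$bow * sin(pi * s)
  pts <- if (params$suture == "coronal") {
    tau <- params$tilt
    e_along <- c(0, cos(tau), -sin(tau)) # mediolateral, in-plane
    e_dev <- c(1, 0, 0) # anteroposterior deviations
    outer(s, e_along) + outer(base + dev, e_dev)
  } else {
    cbind(s, base + dev, 0)
  }
  if (params$noise_sd > 0) {
    pts <- pts + matrix(rnorm(3 * n, 0, params$noise_sd), ncol = 3)
  }
  pts
}
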