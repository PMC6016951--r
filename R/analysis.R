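# Experiment battery: temporal-frequency tuning, direction tuning,
# photon-noise and motion-coherence signal-to-noise experiments, and
# response histograms, for the full detector and its two partial
# variants.

default_freq_grid <- function() c(0.1, 0.2, 0.5, 1, 2, 5, 10)

#' Temporal-frequency tuning curves
#'
#' Runs the detector on full-duration drifting gratings (36 deg
#' wavelength, 100% contrast) at each temporal frequency, along the
#' preferred and/or null direction, for each variant. The scalar
#' response is the time-mean of the rectified population output after
#' the onset transient; responses are normalised to each variant's own
#' preferred-direction peak.
#'
#' @param variants Character vector of \code{\link{detector_variants}}.
#' @param freqs Temporal frequencies in Hz (default the log-spaced grid
#'   0.1, 0.2, 0.5, 1, 2, 5, 10).
#' @param directions Subset of \code{c("pd", "nd")}.
#' @param dims,pitch,dt Movie geometry, see \code{\link{make_grating}}.
#' @param params Detector parameters.
#' @param n_receptors Receptor grid size.
#' @param t_min Start of the response-averaging window, seconds.
#'
#' @return A data frame with columns \code{variant}, \code{direction},
#'   \code{tf}, \code{response} (mV) and \code{response_norm}.
#' @export
temporal_frequency_tuning <- function(variants = detector_variants,
                                      freqs = default_freq_grid(),
                                      directions = c("pd", "nd"),
                                      dims = c(200L, 200L, 1000L),
                                      pitch = 0.9, dt = 0.01,
                                      params = detector_params(),
                                      n_receptors = 40L, t_min = 1) {
  rows <- list()
  for (f in freqs) {
    for (dir in directions) {
      g <- make_grating(f, direction = if (dir == "pd") 0 else 180,
                        dims = dims, pitch = pitch, dt = dt)
      pw <- pathway_signals(downsample(g, n_receptors))
      for (v in variants) {
        out <- run_detector_from_pathways(pw, v, params)
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, direction = dir, tf = f,
          response = mean_response(out, t_min)
        )
      }
    }
  }
  res <- do.call(rbind, rows)
  # normalise to each variant's PD peak
  for (v in unique(res$variant)) {
    ref <- max(res$response[res$variant == v & res$direction == "pd"])
    res$response_norm[res$variant == v] <-
      res$response[res$variant == v] / ref
  }
  res
}

#' Direction tuning curves
#'
#' Runs the detector on 1 Hz (by default) gratings drifting in each
#' direction; each variant's curve is normalised to its own peak.
#'
#' @param directions Motion directions in deg (default 0 to 330 in
#'   30-deg steps; 0 = preferred).
#' @param tf Temporal frequency, Hz.
#' @inheritParams temporal_frequency_tuning
#'
#' @return A data frame with columns \code{variant}, \code{direction}
#'   (deg), \code{response} (mV) and \code{response_norm}.
#' @export
direction_tuning <- function(variants = detector_variants,
                             directions = seq(0, 330, by = 30), tf = 1,
                             dims = c(200L, 200L, 1000L), pitch = 0.9,
                             dt = 0.01, params = detector_params(),
                             n_receptors = 40L, t_min = 1) {
  rows <- list()
  for (th in directions) {
    g <- make_grating(tf, direction = th, dims = dims, pitch = pitch, dt = dt)
    pw <- pathway_signals(downsample(g, n_receptors))
    for (v in variants) {
      out <- run_detector_from_pathways(pw, v, params)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, direction = th, response = mean_response(out, t_min)
      )
    }
  }
  res <- do.call(rbind, rows)
  for (v in unique(res$variant)) {
    sel <- res$variant == v
    res$response_norm[sel] <- res$response[sel] / max(res$response[sel])
  }
  res
}

#' Signal-to-noise ratio of a detector response
#'
#' SNR = (mean response during the preferred-direction window minus the
#' mean during the null-direction window) divided by the square root of
#' the response variance. The variance is, by default, pooled over both
#' windows after subtracting each window's own mean; \code{var_mode}
#' switches to a single-window variance.
#'
#' @param population Rectified population time series (mV).
#' @param t Frame times, seconds.
#' @param windows List with elements \code{pd} and \code{nd}, each
#'   \code{c(start, end)} in seconds (defaults: 0.5--4.5 and 5.5--9.5).
#' @param var_mode \code{"pooled"}, \code{"pd"} or \code{"nd"}.
#'
#' @return A one-row data frame with \code{mean_pd}, \code{mean_nd},
#'   \code{var_pd}, \code{var_nd}, \code{variance} (the one used),
#'   \code{snr} and \code{degenerate} (TRUE when the variance is zero,
#'   in which case \code{snr} is \code{Inf} with the sign of the mean
#'   difference).
#' @export
snr <- function(population, t,
                windows = list(pd = c(0.5, 4.5), nd = c(5.5, 9.5)),
                var_mode = c("pooled", "pd", "nd")) {
  var_mode <- match.arg(var_mode)
  x_pd <- population[t >= windows$pd[1] & t < windows$pd[2]]
  x_nd <- population[t >= windows$nd[1] & t < windows$nd[2]]
  if (!length(x_pd) || !length(x_nd)) {
    stop("response does not cover both analysis windows", call. = FALSE)
  }
  m_pd <- mean(x_pd); m_nd <- mean(x_nd)
  v_pd <- stats::var(x_pd); v_nd <- stats::var(x_nd)
  pooled <- (sum((x_pd - m_pd)^2) + sum((x_nd - m_nd)^2)) /
    (length(x_pd) + length(x_nd) - 2)
  v <- switch(var_mode, pooled = pooled, pd = v_pd, nd = v_nd)
  degenerate <- v == 0
  data.frame(
    mean_pd = m_pd, mean_nd = m_nd, var_pd = v_pd, var_nd = v_nd,
    variance = v,
    snr = if (degenerate) sign(m_pd - m_nd) * Inf else (m_pd - m_nd) / sqrt(v),
    degenerate = degenerate
  )
}

#' Photon-noise experiment
#'
#' For each mean-luminance factor and each replicate seed, corrupts a
#' drifting grating (preferred- then null-direction motion, per
#' \code{\link{pd_nd_schedule}}) with Poisson shot noise, runs every
#' requested detector variant on it, and computes the SNR. The
#' peripheral filtering is shared across variants within a replicate.
#'
#' @param factors Mean-luminance factors (default 1, 2, 4, 8, 16, 32).
#' @param n_reps Replicates per factor.
#' @param seed Master seed; per-replicate seeds are drawn from it.
#' @param tf Grating temporal frequency, Hz.
#' @inheritParams temporal_frequency_tuning
#' @param var_mode Variance window mode, see \code{\link{snr}}.
#'
#' @return A data frame, one row per (factor, replicate, variant), with
#'   the \code{\link{snr}} columns plus \code{factor}, \code{rep},
#'   \code{variant}.
#' @export
photon_noise_experiment <- function(factors = c(1, 2, 4, 8, 16, 32),
                                    n_reps = 10L, seed = 1L, tf = 1,
                                    variants = detector_variants,
                                    dims = c(200L, 200L, 1000L), pitch = 0.9,
                                    dt = 0.01, params = detector_params(),
                                    n_receptors = 40L,
                                    var_mode = "pooled") {
  clean <- make_grating(tf, dims = dims, pitch = pitch, dt = dt,
                        schedule = pd_nd_schedule())
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, length(factors) * n_reps),
                  nrow = length(factors))
  rows <- list()
  for (i in seq_along(factors)) {
    for (r in seq_len(n_reps)) {
      noisy <- apply_photon_noise(clean, factors[i], seed = seeds[i, r])
      pw <- pathway_signals(downsample(noisy, n_receptors))
      rm(noisy)
      for (v in variants) {
        out <- run_detector_from_pathways(pw, v, params)
        s <- snr(out$population, out$t, var_mode = var_mode)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(factor = factors[i], rep = r, variant = v), s
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Motion-coherence experiment
#'
#' For each coherence level and replicate seed, generates a random-dot
#' kinematogram (coherent subset moving rightward during the
#' preferred-direction window, leftward during the null-direction
#' window), runs every requested variant, and computes the SNR.
#'
#' @param coherences Coherence fractions in [0, 1].
#' @inheritParams photon_noise_experiment
#' @param n_dots,speed Dot-field parameters, see \code{\link{make_dots}}.
#'
#' @return A data frame as in \code{\link{photon_noise_experiment}} with
#'   \code{coherence} in place of \code{factor}.
#' @export
coherence_experiment <- function(coherences = c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1),
                                 n_reps = 10L, seed = 1L,
                                 variants = detector_variants,
                                 n_dots = 500L, speed = 36,
                                 dims = c(200L, 200L, 1000L), pitch = 0.9,
                                 dt = 0.01, params = detector_params(),
                                 n_receptors = 40L, var_mode = "pooled") {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(coherences) * n_reps),
                  nrow = length(coherences))
  rows <- list()
  for (i in seq_along(coherences)) {
    for (r in seq_len(n_reps)) {
      mov <- make_dots(coherences[i], n_dots = n_dots, speed = speed,
                       dims = dims, pitch = pitch, dt = dt,
                       schedule = pd_nd_schedule(), seed = seeds[i, r])
      pw <- pathway_signals(downsample(mov, n_receptors))
      rm(mov)
      for (v in variants) {
        out <- run_detector_from_pathways(pw, v, params)
        s <- snr(out$population, out$t, var_mode = var_mode)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(coherence = coherences[i], rep = r, variant = v), s
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Histogram of the population response within a window
#'
#' @param population Population time series.
#' @param t Frame times, seconds.
#' @param window \code{c(start, end)} in seconds.
#' @param breaks Passed to \code{\link[graphics]{hist}}.
#'
#' @return A data frame with bin \code{mid}, \code{count} and bin
#'   \code{width}.
#' @export
response_histogram <- function(population, t, window, breaks = 30) {
  x <- population[t >= window[1] & t < window[2]]
  if (!length(x)) stop("window contains no samples", call. = FALSE)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, width = diff(h$breaks))
}
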