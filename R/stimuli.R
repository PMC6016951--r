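# Synthetic visual stimuli: drifting sine gratings, photon-shot-noise
# corrupted gratings, and random-dot kinematograms, as luminance movies
# over (x, y, t). The default geometry is 200 x 200 pixels covering
# 180 x 180 deg of visual space (0.9 deg/pixel) and 1000 frames of 10 ms
# (10 s). Direction 0 deg is rightward (+x), the preferred direction of
# the detector array.

#' Construct a stimulus movie object
#'
#' A light container for a luminance field over (x, y, t) plus its
#' spatial and temporal resolution.
#'
#' @param luminance 3-D numeric array (nx, ny, nt), luminance >= 0.
#' @param pitch Pixel pitch in deg/pixel.
#' @param dt Frame interval in seconds.
#' @param meta Named list of descriptive metadata.
#'
#' @return An object of class \code{"stimulus_movie"} with elements
#'   \code{luminance}, \code{pitch}, \code{dt}, \code{t} (frame times,
#'   seconds, starting at 0) and \code{meta}.
#' @export
stimulus_movie <- function(luminance, pitch = 0.9, dt = 0.01, meta = list()) {
  d <- dim(luminance)
  if (length(d) != 3L) stop("`luminance` must be a 3-D array", call. = FALSE)
  structure(
    list(
      luminance = luminance, pitch = pitch, dt = dt,
      t = (seq_len(d[3]) - 1) * dt, meta = meta
    ),
    class = "stimulus_movie"
  )
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$luminance)
  cat(sprintf(
    "<stimulus_movie> %d x %d px (%.1f deg/px), %d frames (dt = %g s)\n",
    d[1], d[2], x$pitch, d[3], x$dt
  ))
  if (length(x$meta)) {
    cat("  ", paste(names(x$meta),
                    vapply(x$meta, function(v) paste(format(v), collapse = ","),
                           ""),
                    sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Motion schedule of the noise experiments
#'
#' The stimulus timeline used for the signal-to-noise experiments:
#' stationary 0--0.5 s, preferred-direction motion 0.5--4.5 s, stationary
#' 4.5--5.5 s, null-direction motion 5.5--9.5 s.
#'
#' @return A data frame with columns \code{start}, \code{end} (seconds)
#'   and \code{sign} (+1 preferred, -1 null, 0 stationary).
#' @export
pd_nd_schedule <- function() {
  data.frame(
    start = c(0, 0.5, 4.5, 5.5),
    end   = c(0.5, 4.5, 5.5, 9.5),
    sign  = c(0, 1, 0, -1)
  )
}

# Per-frame motion sign (+1/-1/0) from a schedule; frames outside any
# scheduled interval are stationary.
schedule_signs <- function(schedule, t) {
  s <- numeric(length(t))
  for (i in seq_len(nrow(schedule))) {
    s[t >= schedule$start[i] & t < schedule$end[i]] <- schedule$sign[i]
  }
  s
}

#' Generate a drifting sine grating movie
#'
#' Luminance \eqn{I(x,y,t) = m (1 + c \sin(2\pi[(x\cos\theta +
#' y\sin\theta)/\lambda - f\, t_{eff}]))}, where the effective time
#' advances only while the schedule prescribes motion (sign +1 drifts
#' along \code{direction}, sign -1 along the opposite direction) and the
#' grating orientation is perpendicular to the motion axis.
#'
#' @param tf Temporal frequency in Hz (cycles of contrast per second at a
#'   fixed point during motion).
#' @param direction Motion direction in deg; 0 = rightward.
#' @param wavelength Spatial wavelength in deg (default 36).
#' @param mean_lum Mean luminance (default 0.5).
#' @param contrast Michelson contrast in [0, 1] (default 1: modulation
#'   from 0 to 1).
#' @param dims Integer vector (nx, ny, nt).
#' @param pitch Pixel pitch, deg/pixel.
#' @param dt Frame interval, seconds.
#' @param schedule Motion schedule data frame (\code{start}, \code{end},
#'   \code{sign}); \code{NULL} means continuous motion for the whole
#'   movie.
#'
#' @return A \code{\link{stimulus_movie}}.
#' @export
#' @examples
#' g <- make_grating(1, dims = c(50, 50, 100))
#' range(g$luminance)  # [0, 1]
make_grating <- function(tf, direction = 0, wavelength = 36, mean_lum = 0.5,
                         contrast = 1, dims = c(200L, 200L, 1000L),
                         pitch = 0.9, dt = 0.01, schedule = NULL) {
  if (wavelength <= 0) stop("`wavelength` must be positive", call. = FALSE)
  if (contrast < 0 || contrast > 1) {
    stop("`contrast` must lie in [0, 1]", call. = FALSE)
  }
  nx <- dims[1]; ny <- dims[2]; nt <- dims[3]
  t <- (seq_len(nt) - 1) * dt
  s <- if (is.null(schedule)) rep(1, nt) else schedule_signs(schedule, t)
  # effective elapsed motion time at each frame
  t_eff <- dt * c(0, cumsum(s[-nt]))
  th <- direction * pi / 180
  xdeg <- (seq_len(nx) - 1) * pitch
  ydeg <- (seq_len(ny) - 1) * pitch
  spatial <- 2 * pi * outer(xdeg * cos(th), ydeg * sin(th), "+") / wavelength
  # sin(S - T) = sin(S) cos(T) - cos(S) sin(T): two rank-1 products are
  # much cheaper than evaluating sin() on the full (x, y, t) array
  phase_t <- 2 * pi * tf * t_eff
  lum <- tcrossprod(as.vector(sin(spatial)), cos(phase_t)) -
    tcrossprod(as.vector(cos(spatial)), sin(phase_t))
  lum <- mean_lum * (1 + contrast * lum)
  # guard fp round-off so luminance stays exactly within [lo, hi]
  lum[lum < mean_lum * (1 - contrast)] <- mean_lum * (1 - contrast)
  lum[lum > mean_lum * (1 + contrast)] <- mean_lum * (1 + contrast)
  dim(lum) <- c(nx, ny, nt)
  stimulus_movie(lum, pitch = pitch, dt = dt,
                 meta = list(kind = "grating", tf = tf, direction = direction,
                             wavelength = wavelength, mean_lum = mean_lum,
                             contrast = contrast))
}

#' Corrupt a movie with photon (Poisson) shot noise
#'
#' Each pixel is independently replaced by a Poisson draw with mean
#' \code{factor} times the pixel luminance; larger factors emulate higher
#' mean luminance and hence relatively less shot noise. The noisy movie
#' is then rescaled affinely so that its overall mean and standard
#' deviation (hence contrast) match the clean input, and clamped at 0.
#'
#' @param movie A \code{\link{stimulus_movie}} with non-negative
#'   luminance.
#' @param factor Mean-luminance scaling factor (the experiments use
#'   1, 2, 4, 8, 16, 32).
#' @param seed Optional integer seed, for reproducible draws.
#'
#' @return A \code{\link{stimulus_movie}} with the same geometry.
#' @export
apply_photon_noise <- function(movie, factor, seed = NULL) {
  l <- movie$luminance
  if (any(l < 0)) stop("luminance must be non-negative", call. = FALSE)
  if (factor <= 0) stop("`factor` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rpois(length(l), factor * as.vector(l))
  m0 <- mean(l); s0 <- stats::sd(as.vector(l))
  sn <- stats::sd(draws)
  out <- if (sn == 0) rep(m0, length(draws)) else {
    a <- s0 / sn
    a * draws + (m0 - a * mean(draws))
  }
  out <- pmax(out, 0)
  dim(out) <- dim(l)
  stimulus_movie(out, pitch = movie$pitch, dt = movie$dt,
                 meta = c(movie$meta, list(noise = "poisson",
                                           luminance_factor = factor)))
}

#' Spatial Gaussian blur of a movie
#'
#' Convolves every frame with a normalised 2-D Gaussian kernel with the
#' given half-width (interpreted as full width at half maximum, so
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}). Periodic (wrap-around)
#' boundaries; implemented by FFT convolution.
#'
#' @param movie A \code{\link{stimulus_movie}}.
#' @param half_width Kernel FWHM in deg (default 4.5).
#' @param normalize \code{"sum"} (unit-mass kernel: a uniform movie is
#'   unchanged and the spatial mean is conserved) or \code{"peak"}
#'   (unit-peak kernel: an isolated bright pixel keeps its amplitude and
#'   is widened to the kernel's footprint, as when dilating sparse dot
#'   fields to receptor scale).
#'
#' @return The blurred \code{\link{stimulus_movie}}.
#' @export
gaussian_blur <- function(movie, half_width = 4.5,
                          normalize = c("sum", "peak")) {
  normalize <- match.arg(normalize)
  if (half_width <= 0) stop("`half_width` must be positive", call. = FALSE)
  l <- movie$luminance
  d <- dim(l)
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  sig <- half_width / (2 * sqrt(2 * log(2))) / movie$pitch  # sigma in px
  dx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
  dy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
  k2 <- outer(exp(-dx^2 / (2 * sig^2)), exp(-dy^2 / (2 * sig^2)))
  if (normalize == "sum") k2 <- k2 / sum(k2)
  kf <- stats::fft(k2)
  out <- array(0, d)
  for (k in seq_len(nt)) {
    out[, , k] <- Re(stats::fft(stats::fft(l[, , k]) * kf, inverse = TRUE)) /
      (nx * ny)
  }
  out[out < 0] <- 0  # clip FFT round-off ripple
  stimulus_movie(out, pitch = movie$pitch, dt = movie$dt,
                 meta = c(movie$meta, list(blur_fwhm = half_width)))
}

#' Generate a random-dot kinematogram movie
#'
#' Places \code{n_dots} single-pixel bright dots (luminance 1) on a dark
#' background. A fixed subset of \code{round(coherence * n_dots)} dots
#' moves along \code{coherent_direction} whenever the schedule prescribes
#' preferred-direction motion (and along the opposite direction for
#' null-direction epochs); the remaining dots each move along an
#' independent uniformly random direction that is re-drawn every
#' \code{redirect_interval}. Dot positions are kept in continuous
#' coordinates, rendered to the nearest pixel each frame, and wrap at the
#' movie edges. Finally the movie is spatially low-pass filtered with a
#' unit-peak Gaussian of \code{blur_fwhm} half-width and clamped to
#' [0, 1] (set \code{blur = FALSE} to inspect the raw dot field). The
#' unit-peak convention dilates each dot to receptor scale while keeping
#' its full amplitude; a unit-mass kernel would dilute a single-pixel
#' dot roughly 30-fold, below anything the detector's rectification
#' could ever see.
#'
#' @param coherence Fraction of dots moving coherently, in [0, 1].
#' @param coherent_direction Direction of coherent motion, deg
#'   (0 = rightward).
#' @param n_dots Number of dots (default 500).
#' @param speed Dot speed in deg/s (default 36, one grating wavelength
#'   per second).
#' @param redirect_interval Interval between random re-directions of the
#'   incoherent dots, seconds (default 0.05).
#' @param blur_fwhm Gaussian half-width for the final spatial low-pass,
#'   deg.
#' @param dims,pitch,dt Movie geometry, as in \code{\link{make_grating}}.
#' @param schedule Motion schedule for the coherent subset; defaults to
#'   \code{\link{pd_nd_schedule}}.
#' @param seed Optional integer seed.
#' @param blur If \code{FALSE}, skip the final Gaussian blur.
#'
#' @return A \code{\link{stimulus_movie}}.
#' @export
make_dots <- function(coherence, coherent_direction = 0, n_dots = 500L,
                      speed = 36, redirect_interval = 0.05, blur_fwhm = 4.5,
                      dims = c(200L, 200L, 1000L), pitch = 0.9, dt = 0.01,
                      schedule = pd_nd_schedule(), seed = NULL, blur = TRUE) {
  if (coherence < 0 || coherence > 1) {
    stop("`coherence` must lie in [0, 1]", call. = FALSE)
  }
  if (n_dots < 1) stop("`n_dots` must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nx <- dims[1]; ny <- dims[2]; nt <- dims[3]
  ext_x <- nx * pitch; ext_y <- ny * pitch
  t <- (seq_len(nt) - 1) * dt
  s <- if (is.null(schedule)) rep(1, nt) else schedule_signs(schedule, t)
  n_coh <- round(coherence * n_dots)
  i_coh <- seq_len(n_coh)
  i_inc <- setdiff(seq_len(n_dots), i_coh)
  pos <- cbind(stats::runif(n_dots, 0, ext_x), stats::runif(n_dots, 0, ext_y))
  th_coh <- coherent_direction * pi / 180
  fpe <- max(1L, round(redirect_interval / dt))
  step <- speed * dt
  ang_inc <- numeric(length(i_inc))
  lum <- array(0, c(nx, ny, nt))
  for (k in seq_len(nt)) {
    if (length(i_inc) && (k - 1L) %% fpe == 0L) {
      ang_inc <- stats::runif(length(i_inc), 0, 2 * pi)
    }
    px <- (round(pos[, 1] / pitch) %% nx) + 1L
    py <- (round(pos[, 2] / pitch) %% ny) + 1L
    lum[cbind(px, py, k)] <- 1
    if (length(i_inc)) {
      pos[i_inc, 1] <- pos[i_inc, 1] + step * cos(ang_inc)
      pos[i_inc, 2] <- pos[i_inc, 2] + step * sin(ang_inc)
    }
    if (n_coh && s[k] != 0) {
      th <- if (s[k] > 0) th_coh else th_coh + pi
      pos[i_coh, 1] <- pos[i_coh, 1] + step * cos(th)
      pos[i_coh, 2] <- pos[i_coh, 2] + step * sin(th)
    }
    pos[, 1] <- pos[, 1] %% ext_x
    pos[, 2] <- pos[, 2] %% ext_y
  }
  mov <- stimulus_movie(lum, pitch = pitch, dt = dt,
                        meta = list(kind = "dots", coherence = coherence,
                                    n_dots = n_dots, speed = speed,
                                    coherent_direction = coherent_direction))
  if (blur) {
    mov <- gaussian_blur(mov, blur_fwhm, normalize = "peak")
    mov$luminance[mov$luminance > 1] <- 1  # overlapping dot halos
  }
  mov
}
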